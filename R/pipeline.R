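# End-to-end convenience wrapper: preprocess both layers, correlate
# everything against everything, call significance, build the network.

#' Run the full correlation pipeline
#'
#' Preprocesses each omics layer (median-normalize, minimum-impute, drop
#' degenerate features), stacks the retained features with the markers into
#' one element set, computes all pairwise Pearson correlations with
#' Benjamini-Hochberg FDR control in a single family, calls significance at
#' `r^2 >= r2_min` and `q <= fdr_max`, and builds the significant-edge
#' network.
#'
#' @param proteins,metabolites `AbundanceMatrix` objects (either may be
#'   `NULL`).
#' @param markers optional `MarkerTable` aligned to the protein matrix's
#'   sample order (markers are not normalized, imputed or filtered; Pearson
#'   r is scale-invariant).
#' @param max_ties,impute_scope,order passed to [preprocess_layer()].
#' @param r2_min,fdr_max passed to [call_significant()].
#' @param annotations optional annotation map for node class labels.
#' @return list with `proteins`, `metabolites` (processed matrices),
#'   `reports` (per-layer `PreprocessReport`), `elements` (`ElementSet`),
#'   `table` (flagged `CorrelationTable`), `summary`, and `network`.
#' @export
run_correlation_pipeline <- function(proteins = NULL, metabolites = NULL,
                                     markers = NULL, max_ties = 10L,
                                     impute_scope = "feature",
                                     order = "normalize_first",
                                     r2_min = 0.49, fdr_max = 0.05,
                                     annotations = NULL) {
  reports <- list()
  if (!is.null(proteins)) {
    pp <- preprocess_layer(proteins, max_ties, impute_scope, order)
    proteins <- pp$matrix; reports$protein <- pp$report
  }
  if (!is.null(metabolites)) {
    pm <- preprocess_layer(metabolites, max_ties, impute_scope, order)
    metabolites <- pm$matrix; reports$metabolite <- pm$report
  }
  es <- element_set(proteins, metabolites, markers)
  called <- call_significant(correlate_all(es), r2_min, fdr_max)
  list(proteins = proteins, metabolites = metabolites, reports = reports,
       elements = es, table = called$table,
       summary = correlation_summary(called),
       network = build_network(called, annotations))
}
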