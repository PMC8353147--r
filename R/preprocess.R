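# Preprocessing: per-feature median normalization, minimum-value imputation,
# and degenerate-feature filtering, in that order.

#' Median-normalize an abundance matrix
#'
#' Rescales every feature so that the median of its observed values equals
#' 1.0; the median is computed over observed (non-missing) values only, and
#' missingness is unchanged. Scale-invariant and idempotent.
#'
#' @param m an `AbundanceMatrix`.
#' @return the normalized `AbundanceMatrix`.
#' @export
median_normalize <- function(m) {
  v <- m$values
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs == 0L))
    stop("feature(s) with all values missing: ",
         paste(rownames(v)[n_obs == 0L], collapse = ", "), call. = FALSE)
  med <- apply(v, 1L, median, na.rm = TRUE)
  m$values <- v / med
  m
}

#' Fill missing cells with the observed minimum
#'
#' Replaces every missing cell by the observed minimum — per feature by
#' default, or the global observed minimum of the matrix with
#' `scope = "global"`. Observed cells are untouched; the result has no
#' missing cells. Idempotent.
#'
#' @param m an `AbundanceMatrix` (normally already median-normalized so fill
#'   values are comparable across features).
#' @param scope `"feature"` (default) or `"global"`.
#' @return the imputed `AbundanceMatrix`.
#' @export
impute_minimum <- function(m, scope = c("feature", "global")) {
  scope <- match.arg(scope)
  v <- m$values
  na <- is.na(v)
  if (!any(na)) return(m)
  if (any(rowSums(!na) == 0L))
    stop("feature(s) with all values missing: ",
         paste(rownames(v)[rowSums(!na) == 0L], collapse = ", "),
         call. = FALSE)
  if (scope == "feature") {
    fill <- apply(v, 1L, min, na.rm = TRUE)
    v[na] <- fill[row(v)[na]]
  } else {
    v[na] <- min(v, na.rm = TRUE)
  }
  m$values <- v
  m
}

#' Remove degenerate (low-information) features
#'
#' A feature is degenerate when its single most frequent value occurs in more
#' than `max_ties` samples — typically an artifact of minimum-value
#' imputation. Such features produce spuriously high correlations and are
#' removed before correlation analysis. Tie counting uses exact equality of
#' the stored doubles; surviving features keep their original order and
#' values.
#'
#' @param m an `AbundanceMatrix` with no missing cells (apply after
#'   imputation).
#' @param max_ties maximum allowed modal count (default 10, matching n = 20
#'   samples; guidance for other sizes: `floor(n/2)`).
#' @return list with `matrix` (the filtered `AbundanceMatrix`) and
#'   `removed_ids` (character vector).
#' @export
filter_degenerate <- function(m, max_ties = 10L) {
  n <- ncol(m$values)
  if (max_ties < 1L || max_ties >= n)
    stop("`max_ties` must be in [1, n_samples - 1]; got ", max_ties,
         " with ", n, " samples", call. = FALSE)
  modal <- apply(m$values, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(0L)
    max(tabulate(match(x, unique(x))))
  })
  drop <- modal > max_ties
  removed <- rownames(m$values)[drop]
  m$values <- m$values[!drop, , drop = FALSE]
  list(matrix = m, removed_ids = removed)
}

#' Preprocess one omics layer
#'
#' Runs the full preprocessing chain on a single layer:
#' median-normalize, impute missing cells with the observed minimum, then
#' drop degenerate features. With `order = "impute_first"` imputation
#' precedes normalization instead (the alternative reading of the protocol).
#'
#' @param m an `AbundanceMatrix`.
#' @param max_ties degenerate-feature threshold (see [filter_degenerate()]).
#' @param impute_scope `"feature"` or `"global"` (see [impute_minimum()]).
#' @param order `"normalize_first"` (default) or `"impute_first"`.
#' @return list with `matrix` (processed `AbundanceMatrix`) and `report`
#'   (class `PreprocessReport`): per-feature medians used, imputed-cell
#'   counts per feature, removed ids, and retained/removed totals.
#' @export
preprocess_layer <- function(m, max_ties = 10L,
                             impute_scope = c("feature", "global"),
                             order = c("normalize_first", "impute_first")) {
  impute_scope <- match.arg(impute_scope)
  order <- match.arg(order)
  n_in <- nrow(m$values)
  imputed_per_feature <- as.integer(rowSums(is.na(m$values)))
  names(imputed_per_feature) <- rownames(m$values)
  medians <- apply(m$values, 1L, median, na.rm = TRUE)
  if (order == "normalize_first") {
    m2 <- impute_minimum(median_normalize(m), impute_scope)
  } else {
    m2 <- median_normalize(impute_minimum(m, impute_scope))
  }
  filt <- filter_degenerate(m2, max_ties)
  report <- structure(list(
    layer = m$layer,
    median_used = medians,
    imputed_cells = imputed_per_feature,
    n_imputed_total = as.integer(sum(imputed_per_feature)),
    removed_ids = filt$removed_ids,
    removed_reason = rep("degenerate", length(filt$removed_ids)),
    n_input = n_in,
    n_removed = length(filt$removed_ids),
    n_retained = nrow(filt$matrix$values)
  ), class = "PreprocessReport")
  stopifnot(report$n_removed + report$n_retained == n_in)
  list(matrix = filt$matrix, report = report)
}

#' @export
print.PreprocessReport <- function(x, ...) {
  cat(sprintf(
    "PreprocessReport [%s]: %d features in, %d retained, %d degenerate removed, %d cells imputed\n",
    x$layer, x$n_input, x$n_retained, x$n_removed, x$n_imputed_total))
  invisible(x)
}

#' Write a preprocessing report as JSON
#'
#' @param report a `PreprocessReport`.
#' @param path output path.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
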