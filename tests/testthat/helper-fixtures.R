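# Small builders used across test files.

am <- function(values, layer = "protein",
               fids = paste0("f", seq_len(nrow(values))),
               sids = paste0("s", seq_len(ncol(values)))) {
  dimnames(values) <- list(fids, sids)
  abundance_matrix(values, layer)
}

# one-feature matrix from a plain vector (NA = missing)
am1 <- function(x, layer = "protein") am(matrix(x, nrow = 1), layer)

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# mocked CorrelationTable row-by-row (already flagged when sig given)
mock_corr_table <- function(id1, id2, layer1, layer2, r, p = NULL, q = NULL,
                            significant = NULL) {
  tab <- data.frame(id1 = id1, id2 = id2, layer1 = layer1, layer2 = layer2,
                    r = r,
                    p = if (is.null(p)) pearson_pvalue(r, 20) else p,
                    stringsAsFactors = FALSE)
  tab$q <- if (is.null(q)) bh_adjust(tab$p) else q
  if (!is.null(significant)) {
    tab$significant <- significant
    tab$sign <- ifelse(tab$r >= 0, "positive", "negative")
  }
  class(tab) <- c("CorrelationTable", "data.frame")
  tab
}

# random positive abundance matrix (no structure)
random_am <- function(n_feat, n_samp, layer = "protein", seed = 1) {
  set.seed(seed)
  am(matrix(exp(rnorm(n_feat * n_samp)), n_feat, n_samp), layer,
     fids = sprintf("%s%04d", toupper(substr(layer, 1, 1)), seq_len(n_feat)))
}
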