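# All-pairs Pearson correlation across proteins + metabolites + markers,
# exact t-distribution p-values, Benjamini-Hochberg FDR, significance calls.

#' Pearson product-moment correlation of two vectors
#'
#' @param x,y numeric vectors of equal length (n >= 3), both non-constant.
#' @return the correlation coefficient r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  as.numeric(cor(x, y))
}

#' Two-sided p-value for a Pearson correlation
#'
#' The `cor.test` convention: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred
#' to the t distribution with `n - 2` degrees of freedom, two-sided. For
#' `|r| = 1` the p-value is defined as exactly 0 rather than an underflow
#' artifact. Vectorized over `r`.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @param n sample size (>= 3).
#' @return p-value(s) in \[0, 1\].
#' @export
pearson_pvalue <- function(r, n) {
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1", call. = FALSE)
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * pt(-abs(t), df = n - 2)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with the p-values sorted increasingly,
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1, and mapped back to
#' the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1L)))[ro]
  q
}

#' Assemble the correlation element set
#'
#' Stacks the preprocessed protein and metabolite matrices and, optionally,
#' the marker table into one element-by-sample value matrix with a layer tag
#' per element. Zero-variance elements cannot be correlated and are dropped
#' with a warning.
#'
#' @param proteins,metabolites `AbundanceMatrix` objects (either may be
#'   `NULL`); sample columns must agree in order.
#' @param markers optional `MarkerTable`, already aligned to the same sample
#'   order.
#' @return an `ElementSet`: list with `ids`, `layers`, and the
#'   element-by-sample `values` matrix.
#' @export
element_set <- function(proteins = NULL, metabolites = NULL, markers = NULL) {
  blocks <- list(); layers <- character(0)
  add <- function(vals, layer) {
    blocks[[length(blocks) + 1L]] <<- vals
    layers <<- c(layers, rep(layer, nrow(vals)))
  }
  if (!is.null(proteins)) add(proteins$values, "protein")
  if (!is.null(metabolites)) add(metabolites$values, "metabolite")
  if (!is.null(markers)) add(markers$values, "marker")
  if (!length(blocks)) stop("no elements supplied", call. = FALSE)
  ref <- colnames(blocks[[1L]])
  for (b in blocks)
    if (!identical(colnames(b), ref))
      stop("sample columns disagree across layers", call. = FALSE)
  values <- do.call(rbind, blocks)
  if (anyNA(values))
    stop("element set contains missing values; impute first", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate element id(s) across layers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (ncol(values) < 3L) stop("need at least 3 samples", call. = FALSE)
  keep <- apply(values, 1L, sd) > 0
  if (!all(keep)) {
    warning("dropping zero-variance element(s): ",
            paste(rownames(values)[!keep], collapse = ", "), call. = FALSE)
    values <- values[keep, , drop = FALSE]
    layers <- layers[keep]
  }
  structure(list(ids = rownames(values), layers = layers, values = values),
            class = "ElementSet")
}

#' Build an element set directly from a value matrix
#'
#' Escape hatch for simulation studies (e.g. null calibration on Gaussian
#' data) where the elements do not come from positive abundance matrices.
#'
#' @param values numeric element-by-sample matrix, rownames = element ids.
#' @param layers layer tag(s), recycled to the number of elements.
#' @return an `ElementSet`.
#' @export
as_element_set <- function(values, layers = "protein") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("E%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("N%d", seq_len(ncol(values)))
  if (anyNA(values)) stop("element set cannot contain NA", call. = FALSE)
  if (ncol(values) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (any(apply(values, 1L, sd) == 0))
    stop("zero-variance element(s) present", call. = FALSE)
  structure(list(ids = rownames(values),
                 layers = rep_len(layers, nrow(values)),
                 values = values),
            class = "ElementSet")
}

#' Number of unordered element pairs
#'
#' @param m number of elements.
#' @return `m * (m - 1) / 2`.
#' @export
n_element_pairs <- function(m) as.numeric(m) * (m - 1) / 2

#' All-pairs Pearson correlation with joint FDR control
#'
#' Computes the Pearson correlation, its two-sided t-test p-value, and the
#' Benjamini-Hochberg q-value for every unordered pair of elements. All
#' pairs — protein-protein, metabolite-metabolite, cross-layer and
#' marker-involving — form a single multiple-testing family. Rows are
#' ordered lexicographically by element index (i < j).
#'
#' @param es an `ElementSet`.
#' @return a `CorrelationTable`: data.frame with columns `id1, id2, layer1,
#'   layer2, r, p, q` and attributes `M` (element count) and `n` (sample
#'   count).
#' @export
correlate_all <- function(es) {
  M <- nrow(es$values)
  if (M < 2L) stop("need at least 2 elements", call. = FALSE)
  n <- ncol(es$values)
  cm <- cor(t(es$values))
  # upper triangle in row-major (i < j) order
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  i <- idx[, 1L]; j <- idx[, 2L]
  r <- cm[idx]
  p <- pearson_pvalue(r, n)
  tab <- data.frame(
    id1 = es$ids[i], id2 = es$ids[j],
    layer1 = es$layers[i], layer2 = es$layers[j],
    r = r, p = p, q = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  attr(tab, "M") <- M
  attr(tab, "n") <- n
  class(tab) <- c("CorrelationTable", "data.frame")
  tab
}

#' Call significant correlations
#'
#' A pair is significant when `r^2 >= r2_min` AND `q <= fdr_max`, both
#' boundaries inclusive. The squared-correlation test is evaluated as
#' `|r| >= sqrt(r2_min)` so that the printed boundary (r = 0.70 for
#' r2_min = 0.49) is inclusive under floating point (`0.7^2` rounds just
#' below 0.49 in binary). Adds `significant` and `sign` columns and returns
#' summary counts.
#'
#' @param tab a `CorrelationTable` from [correlate_all()].
#' @param r2_min minimum squared correlation (default 0.49, i.e. |r| >= 0.7).
#' @param fdr_max maximum BH q-value (default 0.05).
#' @return list with `table` (flagged `CorrelationTable`) and `summary`
#'   (list `n_sig`, `n_pos`, `n_neg`).
#' @export
call_significant <- function(tab, r2_min = 0.49, fdr_max = 0.05) {
  if (is.null(tab$q)) stop("q column missing; run correlate_all", call. = FALSE)
  sig <- abs(tab$r) >= sqrt(r2_min) & tab$q <= fdr_max
  tab$significant <- sig
  tab$sign <- ifelse(tab$r >= 0, "positive", "negative")
  s <- list(n_sig = sum(sig),
            n_pos = sum(sig & tab$r >= 0),
            n_neg = sum(sig & tab$r < 0))
  list(table = tab, summary = s)
}

#' Summarize a called correlation table
#'
#' @param called output of [call_significant()].
#' @return list `{M, n, n_pairs, n_sig, n_pos, n_neg, r_min, r_max}` suitable
#'   for [write_summary_json()].
#' @export
correlation_summary <- function(called) {
  tab <- called$table
  c(list(M = attr(tab, "M"), n = attr(tab, "n"), n_pairs = nrow(tab)),
    called$summary,
    list(r_min = min(tab$r), r_max = max(tab$r)))
}
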