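#' Construct an abundance matrix for one omics layer
#'
#' An `AbundanceMatrix` holds one omics layer as a feature-by-sample grid of
#' strictly positive intensities with explicit missingness (`NA`). It is the
#' unit of currency of the preprocessing stage.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   rownames are feature ids, colnames sample ids. `NA` marks missing.
#' @param layer `"protein"` or `"metabolite"`.
#' @return an object of class `AbundanceMatrix`.
#' @examples
#' m <- abundance_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("f1", "f2"), c("s1", "s2", "s3"))), "protein")
#' n_features(m)
#' @export
abundance_matrix <- function(values, layer = c("protein", "metabolite")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  storage.mode(values) <- "double"
  obj <- structure(list(layer = layer, values = values),
                   class = "AbundanceMatrix")
  validate_abundance_matrix(obj)
  obj
}

validate_abundance_matrix <- function(m) {
  v <- m$values
  fid <- rownames(v); sid <- colnames(v)
  if (is.null(fid) || is.null(sid) || nrow(v) == 0L || ncol(v) == 0L)
    stop("abundance matrix must have non-empty feature and sample ids",
         call. = FALSE)
  if (anyDuplicated(fid))
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  obs <- v[!is.na(v)]
  if (any(!is.finite(obs)))
    stop("non-finite abundance value(s) present", call. = FALSE)
  if (any(obs <= 0)) {
    idx <- which(!is.na(v) & v <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive value at feature '%s', sample '%s'",
                 fid[idx[1L]], sid[idx[2L]]), call. = FALSE)
  }
  invisible(m)
}

#' @rdname abundance_matrix
#' @param x an `AbundanceMatrix`.
#' @export
n_features <- function(x) nrow(x$values)

#' @rdname abundance_matrix
#' @export
n_samples <- function(x) ncol(x$values)

#' @rdname abundance_matrix
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname abundance_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix [%s]: %d features x %d samples, %d missing\n",
              x$layer, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Construct a clinical marker table
#'
#' A `MarkerTable` holds per-sample clinical tumor marker values (by default
#' CEA and CA 19-9, in the units they were recorded in — typically ng/ml).
#' Markers enter the correlation analysis as additional elements on their raw
#' clinical scale; Pearson r is affine-invariant, so no rescaling is applied.
#'
#' @param values numeric matrix, markers in rows, samples in columns;
#'   rownames are marker names, colnames sample ids. No missing values.
#' @return an object of class `MarkerTable`.
#' @export
marker_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("marker table must have marker and sample ids", call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate marker or sample id in marker table", call. = FALSE)
  if (anyNA(values))
    stop("missing marker value(s) for sample(s): ",
         paste(colnames(values)[colSums(is.na(values)) > 0], collapse = ", "),
         call. = FALSE)
  if (any(values < 0))
    stop("negative marker value(s) present", call. = FALSE)
  structure(list(values = values), class = "MarkerTable")
}

#' @export
print.MarkerTable <- function(x, ...) {
  cat(sprintf("MarkerTable: %d markers (%s) x %d samples\n",
              nrow(x$values), paste(rownames(x$values), collapse = ", "),
              ncol(x$values)))
  invisible(x)
}

# Reorder a MarkerTable's samples to a reference order; sample sets must match.
align_marker_table <- function(mt, ref_sample_ids) {
  have <- colnames(mt$values)
  extra <- setdiff(have, ref_sample_ids)
  miss <- setdiff(ref_sample_ids, have)
  if (length(extra) || length(miss))
    stop("marker table sample set mismatch; difference: {",
         paste(sort(c(extra, miss)), collapse = ", "), "}", call. = FALSE)
  mt$values <- mt$values[, ref_sample_ids, drop = FALSE]
  mt
}
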