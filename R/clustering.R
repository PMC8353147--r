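# Average-linkage (UPGMA) hierarchical clustering on Pearson-correlation
# distance, for ordering heatmap rows/columns.

#' Pearson correlation distance
#'
#' `d = 1 - r`, the signed correlation distance in \[0, 2\]: perfectly
#' correlated profiles are at distance 0, anti-correlated ones at distance 2
#' (so anti-correlated features cluster apart, as in MeV's default).
#'
#' @param x,y numeric vectors, equal length, non-constant.
#' @return the distance.
#' @export
correlation_distance <- function(x, y) 1 - pearson_r(x, y)

#' Pairwise correlation-distance matrix
#'
#' @param values numeric matrix, items in rows (no constant rows).
#' @return symmetric distance matrix `1 - cor` with zero diagonal.
#' @export
correlation_distances <- function(values) {
  if (any(apply(values, 1L, sd) == 0))
    stop("constant row(s); correlation distance undefined", call. = FALSE)
  d <- 1 - cor(t(values))
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering: at each step the two clusters with the smallest
#' mean inter-cluster distance are merged, at a height equal to that mean
#' (maintained by the Lance-Williams update, which is exact for average
#' linkage). Ties on merge height are broken toward the cluster containing
#' the lowest original item index, so results are reproducible.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (or a
#'   [stats::dist] object).
#' @return an object of class `c("Dendrogram", "hclust")` with the usual
#'   `merge`, `height`, `order`, `labels` components; heights are
#'   non-decreasing (average linkage is monotone).
#' @export
average_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("`d` must be a square matrix or dist", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  diag(d) <- Inf

  code <- -seq_len(n)      # hclust code of each active cluster
  size <- rep(1L, n)
  min_orig <- seq_len(n)   # lowest original index in each cluster (tie-break)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    dm <- min(d[active, active])
    cand <- which(d == dm & outer(active, active, `&`), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key1 <- pmin(min_orig[cand[, 1L]], min_orig[cand[, 2L]])
    key2 <- pmax(min_orig[cand[, 1L]], min_orig[cand[, 2L]])
    pick <- order(key1, key2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    if (min_orig[j] < min_orig[i]) { tmp <- i; i <- j; j <- tmp }

    merge[step, ] <- c(code[i], code[j])
    height[step] <- dm
    # Lance-Williams average-linkage update into slot i
    others <- which(active); others <- others[others != i & others != j]
    if (length(others)) {
      d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[others, i] <- d[i, others]
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    d[j, ] <- Inf; d[, j] <- Inf
    code[i] <- step
    min_orig[i] <- min(min_orig[i], min_orig[j])
  }

  ord <- integer(0)
  walk <- function(node) {
    if (node < 0L) ord <<- c(ord, -node)
    else { walk(merge[node, 1L]); walk(merge[node, 2L]) }
  }
  walk(n - 1L)

  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "average",
                 dist.method = "1 - pearson"),
            class = c("Dendrogram", "hclust"))
}

#' Cluster an abundance matrix on either or both axes
#'
#' Clusters features (rows) and/or samples (columns) by UPGMA on correlation
#' distance and permutes the matrix to dendrogram leaf order. Constant rows
#' cannot be clustered on correlation distance and are excluded with a
#' warning before feature clustering.
#'
#' @param m an `AbundanceMatrix` or plain numeric matrix.
#' @param axis `"both"` (default), `"features"` or `"samples"`.
#' @return list with `features` and `samples` dendrograms (`NULL` when not
#'   requested) and `matrix`, the reordered value matrix.
#' @export
cluster_matrix <- function(m, axis = c("both", "features", "samples")) {
  axis <- match.arg(axis)
  v <- if (inherits(m, "AbundanceMatrix")) m$values else m
  if (anyNA(v)) stop("matrix has missing values; impute first", call. = FALSE)
  fd <- sd_ <- NULL
  if (axis %in% c("both", "features")) {
    keep <- apply(v, 1L, sd) > 0
    if (!all(keep)) {
      warning("excluding constant feature(s) from clustering: ",
              paste(rownames(v)[!keep], collapse = ", "), call. = FALSE)
      v <- v[keep, , drop = FALSE]
    }
    if (nrow(v) < 2L) stop("need at least 2 features to cluster", call. = FALSE)
    fd <- average_linkage(correlation_distances(v))
    v <- v[fd$order, , drop = FALSE]
  }
  if (axis %in% c("both", "samples")) {
    if (ncol(v) < 2L) stop("need at least 2 samples to cluster", call. = FALSE)
    sd_ <- average_linkage(correlation_distances(t(v)))
    v <- v[, sd_$order, drop = FALSE]
  }
  list(features = fd, samples = sd_, matrix = v)
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths are height differences between parent and child merges
#' (leaves at height 0).
#'
#' @param dend a `Dendrogram`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(dend))
  txt <- ape::write.tree(phy)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Convert a dendrogram to a nested list (for JSON export)
#'
#' Internal nodes carry their merge `height` and two `children`; leaves carry
#' their `id`.
#'
#' @param dend a `Dendrogram`.
#' @param path optional file to write JSON to.
#' @return nested list; invisibly when written to file.
#' @export
dendrogram_json <- function(dend, path = NULL) {
  build <- function(node) {
    if (node < 0L) return(list(id = dend$labels[-node]))
    list(height = dend$height[node],
         children = list(build(dend$merge[node, 1L]),
                         build(dend$merge[node, 2L])))
  }
  tree <- build(nrow(dend$merge))
  if (!is.null(path)) {
    jsonlite::write_json(tree, path, auto_unbox = TRUE, digits = NA)
    return(invisible(tree))
  }
  tree
}
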