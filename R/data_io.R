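# Delimited-text readers and writers for abundance matrices, marker tables,
# annotation maps, and the pipeline's tabular/JSON outputs.

MISSING_TOKENS <- c("", "na", "nan")

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Parse a character matrix of cells into doubles, with NA for the accepted
# missing tokens and a hard error (naming row/column) on anything else.
parse_numeric_cells <- function(cells, row_ids, col_ids) {
  x <- trimws(cells)
  missing <- is.na(x) | tolower(x) %in% MISSING_TOKENS
  x[is.na(x)] <- "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- !missing & is.na(out)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = length(row_ids)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 x[bad][1L], row_ids[idx[1L]], col_ids[idx[2L]]),
         call. = FALSE)
  }
  out[missing] <- NA_real_
  matrix(out, nrow = length(row_ids),
         dimnames = list(row_ids, col_ids))
}

read_id_matrix <- function(path, delim = NULL) {
  delim <- infer_delim(path, delim)
  raw <- utils::read.table(path, sep = delim, header = FALSE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(raw) < 2L || ncol(raw) < 2L)
    stop("matrix file must have a header row and at least one data row: ",
         path, call. = FALSE)
  col_ids <- as.character(raw[1L, -1L])
  row_ids <- as.character(raw[-1L, 1L])
  cells <- as.matrix(raw[-1L, -1L, drop = FALSE])
  list(row_ids = row_ids, col_ids = col_ids, cells = cells)
}

#' Read an abundance matrix from delimited text
#'
#' Expects features in rows and samples in columns: first column feature ids,
#' header row sample ids. Empty cells, `NA` and `NaN` (case-insensitive)
#' denote missing values; any other non-numeric token is an error naming the
#' offending cell. Values must be strictly positive.
#'
#' @param path path to a TSV (`.tsv`, default tab) or CSV (`.csv`) file.
#' @param layer `"protein"` or `"metabolite"`.
#' @param delim optional delimiter override.
#' @return an [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path, layer = c("protein", "metabolite"),
                                  delim = NULL) {
  layer <- match.arg(layer)
  parts <- read_id_matrix(path, delim)
  if (anyDuplicated(parts$row_ids))
    stop("duplicate feature id(s): ",
         paste(unique(parts$row_ids[duplicated(parts$row_ids)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(parts$col_ids))
    stop("duplicate sample id(s): ",
         paste(unique(parts$col_ids[duplicated(parts$col_ids)]),
               collapse = ", "), call. = FALSE)
  vals <- parse_numeric_cells(parts$cells, parts$row_ids, parts$col_ids)
  abundance_matrix(vals, layer)
}

#' Write an abundance matrix as TSV
#'
#' Inverse of [read_abundance_matrix()]: missing cells are written as `NA`,
#' and a write/read round trip reproduces ids, values and missingness exactly.
#'
#' @param m an `AbundanceMatrix`.
#' @param path output path.
#' @export
write_abundance_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a clinical marker table
#'
#' Accepts markers-in-rows (first column marker names, header sample ids) or
#' the transposed layout; orientation is auto-detected by looking for the
#' reserved marker names in the first column versus the header. The sample
#' set must match `ref_sample_ids` exactly; columns are reordered to it.
#' Missing marker values are a hard error.
#'
#' @param path delimited text file.
#' @param ref_sample_ids canonical sample order (normally the protein
#'   matrix's [sample_ids()]).
#' @param markers reserved marker names used for orientation detection.
#' @param delim optional delimiter override.
#' @return a [marker_table()] aligned to `ref_sample_ids`.
#' @export
read_marker_table <- function(path, ref_sample_ids,
                              markers = c("CEA", "CA19-9"), delim = NULL) {
  parts <- read_id_matrix(path, delim)
  rows_are_markers <- any(parts$row_ids %in% markers)
  cols_are_markers <- any(parts$col_ids %in% markers)
  if (!rows_are_markers && !cols_are_markers)
    stop("no reserved marker name (", paste(markers, collapse = ", "),
         ") found in '", path, "'", call. = FALSE)
  vals <- parse_numeric_cells(parts$cells, parts$row_ids, parts$col_ids)
  if (!rows_are_markers) vals <- t(vals)
  if (anyNA(vals))
    stop("missing marker value(s) in '", path, "'", call. = FALSE)
  align_marker_table(marker_table(vals), ref_sample_ids)
}

#' Read a feature-to-category annotation map
#'
#' Two-column delimited text, one `(feature_id, category_id)` membership per
#' row; repeated rows are deduplicated. Returns a named list mapping each
#' feature id to its character vector of categories.
#'
#' @param path delimited text file (no header).
#' @param delim optional delimiter override.
#' @return named list of character vectors (possibly empty, with a warning,
#'   for an empty file).
#' @export
read_annotation_map <- function(path, delim = NULL) {
  delim <- infer_delim(path, delim)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    warning("annotation file '", path, "' is empty; returning an empty map",
            call. = FALSE)
    return(structure(list(), names = character(0)))
  }
  df <- utils::read.table(path, sep = delim, header = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("annotation map must have two columns (feature_id, category_id)",
         call. = FALSE)
  df <- unique(df[, 1:2])
  split(df[[2L]], factor(df[[1L]], levels = unique(df[[1L]])))
}

#' Write the correlation edge table as TSV
#'
#' Columns: `id1, id2, layer1, layer2, r, p, q, significant, sign`.
#'
#' @param tab a `CorrelationTable` (see [correlate_all()]).
#' @param path output path.
#' @export
write_correlation_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a summary list as JSON
#'
#' @param x a named list of scalars/vectors.
#' @param path output path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
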