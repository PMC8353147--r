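# Correlation-network construction, anchor subnetworks, biomarker candidate
# selection against tumor markers, pathway-set overlap, Cytoscape exports.

#' Build the significant-correlation network
#'
#' Nodes are the endpoints of significant edges (elements with no significant
#' correlation are excluded); edges are exactly the significant rows of the
#' correlation table, with their r, q and sign. Optional annotations attach a
#' class label per node (multiple categories joined with `;`).
#'
#' @param called output of [call_significant()] (or a flagged
#'   `CorrelationTable` with a `significant` column).
#' @param annotations optional annotation map (named list of character
#'   vectors, see [read_annotation_map()]).
#' @return a `CorrelationNetwork`: list with `nodes` (id, layer, class) and
#'   `edges` (id1, id2, r, q, sign) data frames.
#' @export
build_network <- function(called, annotations = NULL) {
  tab <- if (is.data.frame(called)) called else called$table
  if (is.null(tab$significant))
    stop("significance not called; run call_significant", call. = FALSE)
  ed <- tab[tab$significant, c("id1", "id2", "layer1", "layer2",
                               "r", "q", "sign"), drop = FALSE]
  ed <- ed[order(ed$id1, ed$id2), , drop = FALSE]
  rownames(ed) <- NULL
  ids <- c(ed$id1, ed$id2)
  layers <- c(ed$layer1, ed$layer2)
  keep <- !duplicated(ids)
  nodes <- data.frame(id = ids[keep], layer = layers[keep],
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes$class <- if (is.null(annotations)) rep(NA_character_, nrow(nodes)) else
    vapply(nodes$id, function(id)
      if (is.null(annotations[[id]])) NA_character_ else
        paste(sort(annotations[[id]]), collapse = ";"), character(1))
  structure(list(nodes = nodes,
                 edges = ed[, c("id1", "id2", "r", "q", "sign")]),
            class = "CorrelationNetwork")
}

#' @export
print.CorrelationNetwork <- function(x, ...) {
  cat(sprintf("CorrelationNetwork: %d nodes, %d edges (%d positive)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "positive")))
  invisible(x)
}

#' Extract the subnetwork around anchor elements
#'
#' Keeps the edges incident to at least one anchor (by default positive-sign
#' edges only, as in anchor analyses of metabolic hubs). Reports the degree
#' of each anchor within the subnetwork, the union edge count — each edge
#' counted once, so an anchor-anchor edge contributes one edge but two
#' degrees — and the deduplicated non-anchor partner set.
#'
#' @param net a `CorrelationNetwork`.
#' @param anchors character vector of anchor node ids (non-empty). Anchors
#'   absent from the network yield a warning, not an error.
#' @param positive_only keep positive edges only (default `TRUE`).
#' @return list with `edges`, `anchor_degree` (named), `n_edges` (union edge
#'   count), `partners`, `n_partners`.
#' @export
anchor_subnetwork <- function(net, anchors, positive_only = TRUE) {
  if (!length(anchors)) stop("empty anchor set", call. = FALSE)
  missing <- setdiff(anchors, net$nodes$id)
  if (length(missing))
    warning("anchor(s) not in network: ", paste(missing, collapse = ", "),
            call. = FALSE)
  ed <- net$edges
  if (positive_only) ed <- ed[ed$sign == "positive", , drop = FALSE]
  inc <- ed$id1 %in% anchors | ed$id2 %in% anchors
  ed <- ed[inc, , drop = FALSE]
  rownames(ed) <- NULL
  deg <- vapply(anchors, function(a) sum(ed$id1 == a) + sum(ed$id2 == a),
                integer(1))
  partners <- sort(unique(setdiff(c(ed$id1, ed$id2), anchors)))
  list(edges = ed, anchor_degree = deg, n_edges = nrow(ed),
       partners = partners, n_partners = length(partners))
}

#' Select biomarker candidates correlated with tumor markers
#'
#' Candidate rows are the significant, positive marker-element correlations
#' (element = protein or metabolite). Marker-marker pairs (e.g. CEA vs
#' CA 19-9) are reported separately, and significant negative marker-element
#' correlations go to a side channel, so the headline counts concern
#' positive candidates only.
#'
#' @param called output of [call_significant()] (or flagged table).
#' @param markers character vector of marker element ids present in the
#'   table.
#' @return a `BiomarkerTable`: list with `candidates` (marker, element_id,
#'   element_layer, r, p, q), `marker_marker`, `negatives`, and `summary`
#'   (`n_correlations`, `n_elements`, `n_metabolites`, `n_proteins`).
#' @export
select_biomarkers <- function(called, markers) {
  tab <- if (is.data.frame(called)) called else called$table
  if (is.null(tab$significant))
    stop("significance not called; run call_significant", call. = FALSE)
  present <- markers %in% c(tab$id1, tab$id2)
  if (!any(present))
    stop("no marker found among elements: ",
         paste(markers, collapse = ", "), call. = FALSE)
  is1 <- tab$id1 %in% markers
  is2 <- tab$id2 %in% markers
  mm <- tab[is1 & is2 & tab$significant, , drop = FALSE]
  me <- tab[xor(is1, is2) & tab$significant, , drop = FALSE]
  # orient: marker first
  flip <- me$id2 %in% markers
  cand <- data.frame(
    marker = ifelse(flip, me$id2, me$id1),
    element_id = ifelse(flip, me$id1, me$id2),
    element_layer = ifelse(flip, me$layer1, me$layer2),
    r = me$r, p = me$p, q = me$q, stringsAsFactors = FALSE)
  neg <- cand[cand$r < 0, , drop = FALSE]
  cand <- cand[cand$r > 0, , drop = FALSE]
  cand <- cand[order(cand$marker, cand$element_id), , drop = FALSE]
  rownames(cand) <- rownames(neg) <- NULL
  el <- unique(cand[, c("element_id", "element_layer")])
  structure(list(
    candidates = cand,
    marker_marker = mm[, c("id1", "id2", "r", "p", "q"), drop = FALSE],
    negatives = neg,
    summary = list(n_correlations = nrow(cand),
                   n_elements = nrow(el),
                   n_metabolites = sum(el$element_layer == "metabolite"),
                   n_proteins = sum(el$element_layer == "protein"))
  ), class = "BiomarkerTable")
}

#' @export
print.BiomarkerTable <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "BiomarkerTable: %d positive significant marker correlations over %d elements (%d metabolites, %d proteins)\n",
    s$n_correlations, s$n_elements, s$n_metabolites, s$n_proteins))
  invisible(x)
}

#' Overlap of two annotation maps at the category level
#'
#' Shared categories are the intersection of the category sets of the two
#' maps (e.g. pathways hit by both the protein and the metabolite layer);
#' member counts are the distinct features of each map that belong to at
#' least one shared category.
#'
#' @param mapA,mapB annotation maps (named lists of character vectors).
#' @return list with `shared` (sorted category ids), `n_shared`, `members_a`,
#'   `members_b` (feature id vectors), `n_members_a`, `n_members_b`.
#' @export
pathway_overlap <- function(mapA, mapB) {
  catsA <- unique(unlist(mapA, use.names = FALSE))
  catsB <- unique(unlist(mapB, use.names = FALSE))
  shared <- sort(intersect(catsA, catsB))
  in_shared <- function(map) sort(names(map)[vapply(map, function(s)
    any(s %in% shared), logical(1))])
  ma <- in_shared(mapA); mb <- in_shared(mapB)
  list(shared = shared, n_shared = length(shared),
       members_a = ma, members_b = mb,
       n_members_a = length(ma), n_members_b = length(mb))
}

#' Export a correlation network to Cytoscape-compatible formats
#'
#' `SIF` writes one line per edge, `id1 pos_corr|neg_corr id2`, in
#' deterministic (id1, id2) order. `GraphML` carries node attributes `layer`
#' and `class` and edge attributes `r`, `q`, `sign`. `TSV` writes the edge
#' table.
#'
#' @param net a `CorrelationNetwork`.
#' @param path output file.
#' @param format `"SIF"`, `"GraphML"` or `"TSV"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("SIF", "GraphML", "TSV")) {
  format <- match.arg(format)
  ed <- net$edges[order(net$edges$id1, net$edges$id2), , drop = FALSE]
  if (format == "SIF") {
    rel <- ifelse(ed$sign == "positive", "pos_corr", "neg_corr")
    writeLines(if (nrow(ed)) paste(ed$id1, rel, ed$id2) else character(0),
               path)
  } else if (format == "TSV") {
    utils::write.table(ed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a correlation network to an igraph object
#'
#' @param net a `CorrelationNetwork`.
#' @return an undirected [igraph::graph] with node/edge attributes.
#' @export
as_igraph <- function(net) {
  nodes <- net$nodes
  nodes$class[is.na(nodes$class)] <- ""
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = nodes)
}

#' Read back a GraphML network export
#'
#' @param path a GraphML file written by [export_network()].
#' @return a `CorrelationNetwork`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      layer = igraph::V(g)$layer,
                      class = igraph::V(g)$class,
                      stringsAsFactors = FALSE)
  nodes$class[nodes$class == ""] <- NA_character_
  el <- igraph::as_edgelist(g)
  edges <- data.frame(id1 = pmin(el[, 1L], el[, 2L]),
                      id2 = pmax(el[, 1L], el[, 2L]),
                      r = igraph::E(g)$r, q = igraph::E(g)$q,
                      sign = igraph::E(g)$sign, stringsAsFactors = FALSE)
  edges <- edges[order(edges$id1, edges$id2), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "CorrelationNetwork")
}
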