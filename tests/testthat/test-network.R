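# Table 2 of the source study, as printed: markers vs candidate elements
table2_mock <- function() {
  mets <- c("Hydroquinone", "16beta-oleanadienoate", "SM 28:3",
            "Leucenol", "Benzodioxolylbutanamine")
  prots <- c("IGHV1-69D", "IGLV4-60", "IGKV2-40",
             "Coagulation factor XIII A chain", "Plasma kallikrein")
  layer_of <- function(id) {
    if (id %in% mets) "metabolite"
    else if (id %in% prots) "protein"
    else "marker"
  }
  rows <- list(
    c("CEA", "Hydroquinone", 0.74), c("CEA", "CA19-9", 0.96),
    c("CEA", "IGHV1-69D", 0.74), c("CA19-9", "IGLV4-60", 0.78),
    c("CEA", "IGLV4-60", 0.82), c("CEA", "IGKV2-40", 0.71),
    c("CA19-9", "16beta-oleanadienoate", 0.71),
    c("CEA", "16beta-oleanadienoate", 0.73),
    c("CA19-9", "SM 28:3", 0.76), c("CEA", "SM 28:3", 0.79),
    c("CA19-9", "Coagulation factor XIII A chain", 0.75),
    c("CEA", "Coagulation factor XIII A chain", 0.82),
    c("CA19-9", "Leucenol", 0.72), c("CEA", "Leucenol", 0.76),
    c("CEA", "Plasma kallikrein", 0.70), c("CA19-9", "Plasma kallikrein", 0.74),
    c("CA19-9", "Benzodioxolylbutanamine", 0.81),
    c("CEA", "Benzodioxolylbutanamine", 0.87))
  id1 <- vapply(rows, `[`, character(1), 1)
  id2 <- vapply(rows, `[`, character(1), 2)
  mock_corr_table(id1, id2,
                  layer1 = vapply(id1, layer_of, character(1)),
                  layer2 = vapply(id2, layer_of, character(1)),
                  r = as.numeric(vapply(rows, `[`, character(1), 3)),
                  q = rep(0.01, length(rows)),
                  significant = rep(TRUE, length(rows)))
}

test_that("build_network keeps exactly the significant edges", {
  tab <- mock_corr_table(
    id1 = c("a", "a", "b", "c"), id2 = c("b", "c", "d", "d"),
    layer1 = "protein", layer2 = "metabolite",
    r = c(0.9, 0.8, -0.75, 0.1), q = c(0.01, 0.01, 0.01, 0.8),
    significant = c(TRUE, TRUE, TRUE, FALSE))
  net <- build_network(tab)
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(nrow(net$edges), 3L)
  expect_identical(net$edges$sign, c("positive", "positive", "negative"))
  # empty significant set -> empty network
  tab$significant <- FALSE
  empty <- build_network(tab)
  expect_identical(nrow(empty$nodes), 0L)
  expect_identical(nrow(empty$edges), 0L)
})

test_that("network edge count is conserved from call_significant", {
  es <- element_set(random_am(25, 8, seed = 77))
  out <- call_significant(correlate_all(es), r2_min = 0.3, fdr_max = 0.6)
  net <- build_network(out)
  expect_identical(nrow(net$edges), out$summary$n_sig)
})

test_that("annotations attach class labels to nodes", {
  tab <- mock_corr_table("a", "b", "protein", "metabolite", 0.9,
                         q = 0.01, significant = TRUE)
  net <- build_network(tab, annotations = list(a = c("P2", "P1")))
  expect_identical(net$nodes$class[net$nodes$id == "a"], "P1;P2")
  expect_true(is.na(net$nodes$class[net$nodes$id == "b"]))
})

test_that("anchor subnetwork enumerates the hand-worked toy", {
  tab <- mock_corr_table(
    id1 = c("a", "a", "b", "a", "c"), id2 = c("b", "c", "c", "d", "e"),
    layer1 = "metabolite", layer2 = "metabolite",
    r = rep(0.9, 5), q = rep(0.01, 5), significant = rep(TRUE, 5))
  net <- build_network(tab)
  sub <- anchor_subnetwork(net, c("a", "b"))
  expect_identical(unname(sub$anchor_degree), c(3L, 2L))
  expect_identical(sub$n_edges, 4L)   # a-b, a-c, b-c, a-d (not c-e)
  expect_identical(sub$partners, c("c", "d"))
  expect_identical(sub$n_partners, 2L)
  expect_error(anchor_subnetwork(net, character(0)), "empty")
  expect_warning(none <- anchor_subnetwork(net, c("a", "zz")), "zz")
  # anchors with no incident edges -> empty subnetwork
  sub0 <- suppressWarnings(anchor_subnetwork(net, "zz"))
  expect_identical(sub0$n_edges, 0L)
  expect_identical(sub0$n_partners, 0L)
})

test_that("anchor union matches degree arithmetic on the hub scenario", {
  # two anchor hubs with degrees 120 and 63, whose mutual edge is present:
  # union must be 120 + 63 - 1 = 182 over 126 distinct partners
  partners <- sprintf("mol%03d", 1:126)
  e_glu <- data.frame(id1 = "glutamine", id2 = partners[1:119])
  e_cit <- data.frame(id1 = "citrate", id2 = partners[65:126])
  ed <- rbind(e_glu, e_cit, data.frame(id1 = "glutamine", id2 = "citrate"))
  tab <- mock_corr_table(ed$id1, ed$id2, "metabolite", "metabolite",
                         r = rep(0.8, nrow(ed)), q = rep(0.01, nrow(ed)),
                         significant = rep(TRUE, nrow(ed)))
  sub <- anchor_subnetwork(build_network(tab), c("glutamine", "citrate"))
  expect_identical(unname(sub$anchor_degree), c(120L, 63L))
  expect_identical(sub$n_edges, 182L)
  expect_identical(sub$n_partners, 126L)
  # brute-force check: unique undirected edge keys
  keys <- unique(paste(pmin(sub$edges$id1, sub$edges$id2),
                       pmax(sub$edges$id1, sub$edges$id2)))
  expect_identical(length(keys), 182L)
})

test_that("anchor union formula holds on random small graphs", {
  set.seed(55)
  for (rep in 1:30) {
    k <- sample(4:12, 1)
    ids <- letters[1:k]
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (!any(keep)) next
    ed <- pairs[keep, , drop = FALSE]
    tab <- mock_corr_table(ed[, 1], ed[, 2], "protein", "protein",
                           r = rep(0.9, nrow(ed)), q = rep(0.01, nrow(ed)),
                           significant = rep(TRUE, nrow(ed)))
    net <- build_network(tab)
    anchors <- sample(ids, sample(1:3, 1))
    sub <- suppressWarnings(anchor_subnetwork(net, anchors))
    # union = sum of degrees - extra incidences of anchor-anchor edges
    aa <- sum(sub$edges$id1 %in% anchors & sub$edges$id2 %in% anchors)
    expect_identical(sub$n_edges, sum(sub$anchor_degree) - aa)
    # brute force partner count
    want_partners <- setdiff(unique(c(sub$edges$id1, sub$edges$id2)), anchors)
    expect_identical(sub$n_partners, length(want_partners))
  }
})

test_that("biomarker selection on the toy table counts rows and elements", {
  tab <- mock_corr_table(
    id1 = c("CEA", "CA19-9", "CEA", "CEA", "CEA"),
    id2 = c("e1", "e1", "e2", "e3", "CA19-9"),
    layer1 = "marker",
    layer2 = c("metabolite", "metabolite", "protein", "protein", "marker"),
    r = c(0.9, 0.8, 0.85, -0.75, 0.95),
    q = rep(0.01, 5), significant = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  bm <- select_biomarkers(tab, c("CEA", "CA19-9"))
  expect_identical(bm$summary$n_correlations, 3L)
  expect_identical(bm$summary$n_elements, 2L)
  expect_identical(nrow(bm$marker_marker), 1L)
  expect_identical(bm$negatives$element_id, "e3")
  expect_error(select_biomarkers(tab, "CA125"), "CA125")
})

test_that("biomarker selection reproduces the printed marker table", {
  bm <- select_biomarkers(table2_mock(), c("CEA", "CA19-9"))
  # printed table: 17 marker-element rows over 10 elements (5 + 5),
  # with the strong CEA vs CA19-9 correlation reported separately
  expect_identical(bm$summary$n_correlations, 17L)
  expect_identical(bm$summary$n_elements, 10L)
  expect_identical(bm$summary$n_metabolites, 5L)
  expect_identical(bm$summary$n_proteins, 5L)
  expect_identical(nrow(bm$marker_marker), 1L)
  expect_equal(bm$marker_marker$r, 0.96)
  expect_true(all(bm$candidates$r > 0))
})

test_that("no significant marker rows yields an empty candidate table", {
  tab <- mock_corr_table("CEA", "e1", "marker", "protein", 0.2,
                         q = 0.9, significant = FALSE)
  bm <- select_biomarkers(tab, "CEA")
  expect_identical(nrow(bm$candidates), 0L)
  expect_identical(bm$summary$n_correlations, 0L)
})

test_that("pathway overlap intersects categories and counts members", {
  mapA <- list(f1 = "P1", f2 = c("P1", "P2"), f3 = "P3")
  mapB <- list(g1 = "P2", g2 = c("P3", "P4"))
  ov <- pathway_overlap(mapA, mapB)
  expect_identical(ov$shared, c("P2", "P3"))
  expect_identical(ov$members_a, c("f2", "f3"))
  expect_identical(ov$members_b, c("g1", "g2"))
  # hand-worked minimal example
  ov2 <- pathway_overlap(list(f1 = "P1", f2 = c("P1", "P2")),
                         list(g1 = "P2"))
  expect_identical(ov2$shared, "P2")
  expect_identical(ov2$n_members_a, 1L)
  expect_identical(ov2$n_members_b, 1L)
  # disjoint maps
  ov3 <- pathway_overlap(list(f = "P1"), list(g = "P9"))
  expect_identical(ov3$n_shared, 0L)
  expect_identical(ov3$n_members_a, 0L)
})

test_that("SIF export is deterministic and formats signs", {
  tab <- mock_corr_table(c("b", "a"), c("c", "b"), "protein", "protein",
                         r = c(-0.8, 0.9), q = c(0.01, 0.01),
                         significant = c(TRUE, TRUE))
  net <- build_network(tab)
  p1 <- tempfile(fileext = ".sif"); p2 <- tempfile(fileext = ".sif")
  export_network(net, p1, "SIF")
  export_network(net, p2, "SIF")
  expect_identical(readLines(p1), c("a pos_corr b", "b neg_corr c"))
  expect_identical(readLines(p1), readLines(p2))
  # empty network -> zero lines
  tab$significant <- FALSE
  p3 <- tempfile(fileext = ".sif")
  export_network(build_network(tab), p3, "SIF")
  expect_identical(length(readLines(p3)), 0L)
  expect_error(export_network(net, tempfile(), "DOT"), "should be one of")
})

test_that("GraphML round trip reproduces nodes and edges", {
  tab <- mock_corr_table(c("a", "a", "b"), c("b", "c", "c"),
                         c("protein", "protein", "metabolite"),
                         c("metabolite", "metabolite", "metabolite"),
                         r = c(0.9, -0.8, 0.75),
                         q = c(0.001, 0.002, 0.003),
                         significant = rep(TRUE, 3))
  net <- build_network(tab, annotations = list(c = "lipid"))
  path <- tempfile(fileext = ".graphml")
  export_network(net, path, "GraphML")
  back <- read_network_graphml(path)
  expect_identical(back$nodes$id, net$nodes$id)
  expect_identical(back$nodes$layer, net$nodes$layer)
  expect_identical(back$nodes$class, net$nodes$class)
  expect_identical(back$edges$id1, net$edges$id1)
  expect_identical(back$edges$id2, net$edges$id2)
  expect_equal(back$edges$r, net$edges$r)
  expect_identical(back$edges$sign, net$edges$sign)
})
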