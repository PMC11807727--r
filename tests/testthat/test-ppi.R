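# Interaction graph handling: loading rules, subnetwork extraction, MNC
# (with brute-force oracle), hub ranking, DE overlay.

edge_tbl <- function(a, b, s) {
  tibble::tibble(protein_a = a, protein_b = b, combined_score = s)
}

test_that("score filtering keeps >= threshold and collapses duplicates", {
  et <- edge_tbl(c("A", "B", "C", "D", "E"), c("B", "C", "D", "E", "A"),
                 c(0.71, 0.69, 0.9, 0.7, 0.2))
  g <- load_interactions(et, 0.7)
  expect_equal(igraph::ecount(g), 3L)    # 0.71, 0.9, 0.70 kept
  # duplicate pair keeps the max score
  et2 <- edge_tbl(c("A", "B"), c("B", "A"), c(0.8, 0.75))
  g2 <- load_interactions(et2, 0.7)
  expect_equal(igraph::ecount(g2), 1L)
  expect_equal(igraph::E(g2)$score, 0.8)
  # self-loop dropped with warning
  expect_warning(g3 <- load_interactions(edge_tbl(c("A", "A"), c("A", "B"),
                                                  c(0.9, 0.9)), 0.7),
                 "self-interaction")
  expect_equal(igraph::ecount(g3), 1L)
})

test_that("STRING 0-1000 integer scores are autoscaled", {
  et <- edge_tbl(c("A", "B"), c("B", "C"), c(900, 400))
  g <- load_interactions(et, 0.7)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$score, 0.9)
})

test_that("autoscale off rejects out-of-range scores", {
  et <- edge_tbl("A", "B", 900)
  expect_error(load_interactions(et, 0.7, autoscale = FALSE), "\\[0, 1\\]")
})

test_that("malformed scores and thresholds raise informative errors", {
  et <- edge_tbl(c("A", "B"), c("B", "C"), c(0.9, NA))
  expect_error(load_interactions(et, 0.7), class = "painmodnet_format_error")
  expect_error(load_interactions(edge_tbl("A", "B", 0.9), 1.2), "\\[0, 1\\]")
})

test_that("an empty post-filter edge set yields an empty graph", {
  g <- load_interactions(edge_tbl("A", "B", 0.5), 0.9)
  expect_equal(igraph::vcount(g), 0L)
})

test_that("raising the threshold never adds an edge", {
  set.seed(5)
  et <- edge_tbl(sample(LETTERS[1:10], 40, TRUE), sample(LETTERS[1:10], 40, TRUE),
                 runif(40))
  et <- et[et$protein_a != et$protein_b, ]
  th <- sort(runif(5))
  counts <- vapply(th, function(t) igraph::ecount(load_interactions(et, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("reference subnetwork follows the first-neighbor rule", {
  # path A-B-C-D with reference {A}: nodes {A,B}, edge A-B only
  path <- load_interactions(edge_tbl(c("A", "B", "C"), c("B", "C", "D"),
                                     rep(0.9, 3)), 0.7)
  sub <- extract_reference_subnetwork(path, "A")
  expect_setequal(igraph::V(sub)$name, c("A", "B"))
  expect_equal(igraph::ecount(sub), 1L)
  expect_identical(igraph::V(sub)$is_reference[
    igraph::V(sub)$name == "A"], TRUE)
  # triangle with reference {A}: all 3 nodes and all 3 edges kept
  tri <- load_interactions(edge_tbl(c("A", "B", "C"), c("B", "C", "A"),
                                    rep(0.9, 3)), 0.7)
  sub2 <- extract_reference_subnetwork(tri, "A")
  expect_equal(igraph::vcount(sub2), 3L)
  expect_equal(igraph::ecount(sub2), 3L)
  # reference = all nodes: identity
  sub3 <- extract_reference_subnetwork(tri, c("A", "B", "C"))
  expect_equal(igraph::vcount(sub3), 3L)
  expect_equal(igraph::ecount(sub3), 3L)
  expect_error(extract_reference_subnetwork(tri, character()), "non-empty")
  expect_error(extract_reference_subnetwork(tri, "Z"), "no reference gene")
})

test_that("subnetwork extraction is idempotent", {
  set.seed(6)
  et <- simulate_interaction_graph(sprintf("n%02d", 1:40), 4, seed = 6)
  g <- load_interactions(et, 0.7)
  ref <- intersect(sprintf("n%02d", 1:8), igraph::V(g)$name)
  s1 <- extract_reference_subnetwork(g, ref)
  s2 <- extract_reference_subnetwork(s1, ref)
  expect_setequal(igraph::V(s1)$name, igraph::V(s2)$name)
  expect_equal(igraph::ecount(s1), igraph::ecount(s2))
})

test_that("mnc matches hand-worked cases", {
  # star: 5 mutually non-adjacent leaves -> MNC(center) = 1
  star <- load_interactions(edge_tbl(rep("hub", 5), paste0("L", 1:5),
                                     rep(0.9, 5)), 0.7)
  expect_identical(unname(mnc(star, "hub")), 1L)
  # 4 neighbors forming a path -> MNC = 4
  et <- edge_tbl(c(rep("v", 4), "a", "b", "c"),
                 c("a", "b", "c", "d", "b", "c", "d"), rep(0.9, 7))
  g <- load_interactions(et, 0.7)
  expect_identical(unname(mnc(g, "v")), 4L)
  expect_error(mnc(g, "zz"), "absent")
})

test_that("mnc equals the brute-force oracle on random small graphs", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    nodes <- sprintf("n%02d", 1:n)
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.4
    if (!any(keep)) next
    em <- pairs[keep, , drop = FALSE]
    g <- load_interactions(edge_tbl(em[, 1], em[, 2], rep(0.9, nrow(em))), 0.7)
    vs <- igraph::V(g)$name
    got <- mnc(g, vs)
    want <- vapply(vs, function(v) oracle_mnc(em, v), integer(1))
    expect_identical(unname(got), unname(want))
  }
})

test_that("mnc never exceeds degree; equality on cliques", {
  set.seed(8)
  et <- simulate_interaction_graph(sprintf("n%02d", 1:30), 4, seed = 8)
  g <- load_interactions(et, 0.7)
  vs <- igraph::V(g)$name
  expect_true(all(mnc(g, vs) <= igraph::degree(g)[vs]))
  # clique: mnc = degree, identical rankings
  cl <- t(combn(LETTERS[1:5], 2))
  gc <- load_interactions(edge_tbl(cl[, 1], cl[, 2], rep(0.9, 10)), 0.7)
  expect_identical(rank_hubs(gc, "degree")$node, rank_hubs(gc, "mnc")$node)
  expect_identical(rank_hubs(gc, "degree")$rank, rank_hubs(gc, "mnc")$rank)
})

test_that("hub ranks are dense with lexicographic ties", {
  et <- edge_tbl(c("A", "A", "A", "B", "C"), c("B", "C", "D", "C", "D"),
                 rep(0.9, 5))
  g <- load_interactions(et, 0.7)
  rk <- rank_hubs(g, "degree")
  # degrees: A=3, B=2, C=3, D=2 -> ranks 1,1,2,2; ties alphabetical
  expect_identical(rk$node, c("A", "C", "B", "D"))
  expect_identical(rk$rank, c(1L, 1L, 2L, 2L))
  expect_identical(nrow(rank_hubs(g, "degree", top_n = 2)), 2L)
  # single-rank graph: disjoint edges
  g2 <- load_interactions(edge_tbl(c("A", "C"), c("B", "D"), c(0.9, 0.9)), 0.7)
  expect_true(all(rank_hubs(g2, "degree")$rank == 1L))
})

test_that("DE overlay flags nodes and counts the overlap", {
  et <- edge_tbl(paste0("g", 1:10), c(paste0("g", 2:10), "g1"), rep(0.9, 10))
  g <- load_interactions(et, 0.7)
  de <- tibble::tibble(gene = paste0("g", 1:8),
                       log2fc = c(2, -2, 0.1, 3, -0.2, 1.7, -1.9, 0),
                       fdr = c(0.01, 0.01, 0.01, 0.2, 0.01, 0.001, 0.04, 0.9))
  g <- overlay_de(g, de, fc_min = 1.5, fdr_max = 0.05)
  flags <- stats::setNames(igraph::V(g)$de_flag, igraph::V(g)$name)
  expect_identical(unname(flags[c("g1", "g2", "g3", "g4")]),
                   c("up", "down", "ns", "ns"))  # g4 fails fdr
  expect_identical(unname(flags[c("g6", "g7")]), c("up", "down"))
  expect_identical(unname(flags[c("g9", "g10")]), c("untested", "untested"))
  expect_identical(igraph::graph_attr(g, "n_de"), 4L)
  # empty DE table: all untested, count 0
  g0 <- overlay_de(load_interactions(et, 0.7),
                   tibble::tibble(gene = character(), log2fc = numeric(),
                                  fdr = numeric()))
  expect_true(all(igraph::V(g0)$de_flag == "untested"))
  expect_identical(igraph::graph_attr(g0, "n_de"), 0L)
})

test_that("graph tables expose nodes with degree and edges with scores", {
  et <- edge_tbl(c("A", "B"), c("B", "C"), c(0.9, 0.8))
  g <- load_interactions(et, 0.7)
  tabs <- graph_tables(g)
  expect_setequal(tabs$nodes$node, c("A", "B", "C"))
  expect_identical(tabs$nodes$degree[tabs$nodes$node == "B"], 2)
  expect_identical(nrow(tabs$edges), 2L)
  expect_true("score" %in% names(tabs$edges))
})
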