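# Synthetic generators: planted structure, determinism, error contracts.

test_that("module expression plants correlation structure", {
  sim <- simulate_module_expression(400, 60, c(80, 60), 0.8, 0.6, seed = 1)
  expect_identical(dim(sim$expr), c(400L, 60L))
  labs <- sim$truth$module_of_gene
  expect_identical(sum(labs == 0), 260L)
  expect_identical(sum(labs == 1), 80L)
  expect_identical(sum(labs == 2), 60L)
  m1 <- names(labs)[labs == 1]
  bg <- names(labs)[labs == 0]
  r1 <- abs(stats::cor(t(sim$expr[m1[1:40], ])))
  rb <- abs(stats::cor(t(sim$expr[bg[1:40], ])))
  within_mean <- mean(r1[upper.tri(r1)])
  bg_mean <- mean(rb[upper.tri(rb)])
  expect_gt(within_mean, bg_mean)
  # population within-module correlation is loading^2/(loading^2 + sd^2)
  expect_gt(within_mean, 0.5)
})

test_that("zero loading gives no module signal", {
  sim <- simulate_module_expression(400, 60, c(80, 60), 0, 0.6, seed = 2)
  labs <- sim$truth$module_of_gene
  m1 <- names(labs)[labs == 1]
  bg <- names(labs)[labs == 0]
  r1 <- abs(stats::cor(t(sim$expr[m1[1:40], ])))
  rb <- abs(stats::cor(t(sim$expr[bg[1:40], ])))
  expect_lt(abs(mean(r1[upper.tri(r1)]) - mean(rb[upper.tri(rb)])), 0.05)
})

test_that("generators are deterministic and leave RNG state untouched", {
  a <- simulate_module_expression(100, 20, c(30), seed = 7)
  set.seed(42); before <- .Random.seed
  b <- simulate_module_expression(100, 20, c(30), seed = 7)
  expect_identical(before, .Random.seed)
  expect_identical(a, b)
  e1 <- simulate_interaction_graph(sprintf("g%02d", 1:50), 4, seed = 3)
  e2 <- simulate_interaction_graph(sprintf("g%02d", 1:50), 4, seed = 3)
  expect_identical(e1, e2)
  c1 <- simulate_counts(sprintf("g%02d", 1:50), 3, seed = 4)
  c2 <- simulate_counts(sprintf("g%02d", 1:50), 3, seed = 4)
  expect_identical(c1, c2)
  p1 <- simulate_strain_panels(sprintf("g%02d", 1:10), c("a", "b"), 5, seed = 5)
  p2 <- simulate_strain_panels(sprintf("g%02d", 1:10), c("a", "b"), 5, seed = 5)
  expect_identical(p1, p2)
  g1 <- simulate_gwas_table(sprintf("g%02d", 1:10), c("t1", "t2"), seed = 6)
  g2 <- simulate_gwas_table(sprintf("g%02d", 1:10), c("t1", "t2"), seed = 6)
  expect_identical(g1, g2)
})

test_that("module sizes above n_genes raise a size error", {
  expect_error(simulate_module_expression(100, 10, c(80, 30), seed = 1),
               class = "painmodnet_size_error")
})

test_that("plant_reference_set composes the set as requested", {
  sim <- simulate_module_expression(500, 30, c(300), seed = 1)
  ref <- plant_reference_set(sim$truth, 1, 40, 60, seed = 2)
  expect_length(ref$genes, 100)
  labs <- sim$truth$module_of_gene
  expect_identical(sum(labs[ref$genes] == 1), 40L)
  expect_identical(sum(labs[ref$genes] == 0), 60L)
  expect_identical(ref$truth$reference_genes, ref$genes)
  expect_error(plant_reference_set(sim$truth, 1, 301, 0, seed = 1),
               class = "painmodnet_size_error")
})

test_that("n_in_module = 0 gives a background-rate reference set", {
  sim <- simulate_module_expression(500, 30, c(100), seed = 1)
  ref <- plant_reference_set(sim$truth, 1, 0, 50, seed = 3)
  expect_identical(sum(sim$truth$module_of_gene[ref$genes] == 1), 0L)
})

test_that("interaction graph plants hubs at the top of the degree ranking", {
  genes <- sprintf("h%03d", 1:500)
  hubs <- genes[1:10]
  et <- simulate_interaction_graph(genes, 4, hub_genes = hubs,
                                   hub_degree_boost = 20,
                                   score_range = c(0.7, 1), seed = 5)
  expect_false(any(et$protein_a == et$protein_b))
  key <- paste(pmin(et$protein_a, et$protein_b),
               pmax(et$protein_a, et$protein_b))
  expect_identical(anyDuplicated(key), 0L)
  expect_true(all(et$combined_score >= 0.7 & et$combined_score <= 1))
  g <- load_interactions(et, 0.7)
  expect_equal(igraph::ecount(g), nrow(et))  # none removed at 0.7
  top15 <- rank_hubs(g, "degree", top_n = 15)$node
  expect_gte(sum(hubs %in% top15), 10)
})

test_that("mean_degree below 1 raises a parameter error", {
  expect_error(simulate_interaction_graph(letters, 0.5, seed = 1),
               class = "painmodnet_parameter_error")
})

test_that("count simulator honors shape, planting, and parameter checks", {
  genes <- sprintf("g%04d", 1:5000)
  de <- stats::setNames(rep(c(2, -2), 125), sample(genes, 250))
  cnt <- simulate_counts(genes, 3, c(20, 500), 0.1, de, seed = 1)
  expect_identical(dim(cnt$counts), c(5000L, 6L))
  expect_identical(unname(cnt$groups),
                   rep(c("control", "case"), each = 3))
  expect_true(is.integer(cnt$counts))
  expect_error(simulate_counts(genes, 2.5, seed = 1),
               class = "painmodnet_parameter_error")
  expect_error(simulate_counts(genes, 3, dispersion = 0, seed = 1),
               class = "painmodnet_parameter_error")
  # planted lfc = 0 behaves as null: group means comparable
  cnt0 <- simulate_counts(genes[1:100], 10, c(100, 100), 0.05,
                          stats::setNames(0, genes[1]), seed = 2)
  m <- rowMeans(cnt0$counts[1, 1:10, drop = FALSE]) /
    rowMeans(cnt0$counts[1, 11:20, drop = FALSE])
  expect_lt(abs(log2(m)), 1)
})

test_that("strain panels plant sign-correct correlations and missingness", {
  genes <- sprintf("g%02d", 1:20)
  pairs <- tibble::tibble(gene = c("g01", "g02"), region = c("a", "a"),
                          phenotype = c(1L, 2L), sign = c(1L, -1L))
  pan <- simulate_strain_panels(genes, c("a", "b"), n_phenotypes = 5,
                                correlated_pairs = pairs, rho = 0.7,
                                strain_range = c(40, 40), missing_rate = 0.1,
                                seed = 9)
  expect_named(pan$panels, c("a", "b"))
  pa <- pan$panels$a
  expect_identical(dim(pa$expression), c(20L, 40L))
  expect_identical(dim(pa$phenotypes), c(40L, 5L))
  na_rate <- mean(is.na(pa$phenotypes))
  expect_gt(na_rate, 0.02)
  expect_lt(na_rate, 0.25)
  r1 <- stats::cor(pa$expression["g01", ], pa$phenotypes[, 1],
                   use = "pairwise.complete.obs")
  r2 <- stats::cor(pa$expression["g02", ], pa$phenotypes[, 2],
                   use = "pairwise.complete.obs")
  expect_gt(r1, 0.3)
  expect_lt(r2, -0.3)
  expect_error(simulate_strain_panels(genes, "a", 5, rho = 1.5, seed = 1),
               class = "painmodnet_parameter_error")
})

test_that("gwas table plants strong associations and rejects unknown genes", {
  genes <- sprintf("g%03d", 1:100)
  traits <- sprintf("t%02d", 1:10)
  pairs <- tibble::tibble(gene = sample(genes, 12),
                          trait = sample(traits, 12, replace = TRUE))
  tab <- simulate_gwas_table(genes, traits, pairs, p_strength = 1e-4,
                             seed = 11)
  expect_identical(nrow(tab), 1000L)
  key <- paste(tab$gene, tab$trait)
  pk <- paste(pairs$gene, pairs$trait)
  expect_true(all(tab$p[key %in% pk] < 1e-4))
  # planted pairs survive both significance filters
  counts <- filter_gwas(tab)
  planted_counts <- counts[counts$gene %in% pairs$gene, ]
  expect_true(all(planted_counts$gwas_trait_count >= 1))
  expect_true(all(planted_counts$strict_gwas_count >= 1))
  expect_error(simulate_gwas_table(genes, traits,
                                   tibble::tibble(gene = "nope", trait = "t01"),
                                   seed = 1))
})

test_that("null gwas table matches the nominal significance rate", {
  tab <- simulate_gwas_table(sprintf("g%03d", 1:100), sprintf("t%02d", 1:10),
                             seed = 12)
  rate <- mean(tab$p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(tab))
  expect_lt(abs(rate - 0.05), 3 * se)
})
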