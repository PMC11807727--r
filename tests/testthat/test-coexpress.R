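# Coexpression core: outlier removal, gene selection, soft threshold, TOM
# (with oracle), module detection, eigengenes, merging.

test_that("outlier removal drops exactly the shifted samples", {
  set.seed(1)
  expr <- matrix(rnorm(50 * 22), 50, 22,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("s%02d", 1:22)))
  expr[, 21:22] <- expr[, 21:22] + 10
  res <- remove_outlier_samples(expr, height_cut = 40)
  expect_setequal(res$removed, c("s21", "s22"))
  expect_identical(colnames(res$expr), sprintf("s%02d", 1:20))
})

test_that("outlier removal honors Inf and the sample precondition", {
  expr <- matrix(rnorm(30), 10, 3, dimnames = list(1:10, c("a", "b", "c")))
  res <- remove_outlier_samples(expr, Inf)
  expect_identical(res$expr, expr)
  expect_identical(res$removed, character())
  expect_error(remove_outlier_samples(expr[, 1:2], 5), "at least 3 samples")
})

test_that("top-gene selection sorts by mean with a stable tie rule", {
  expr <- matrix(c(1, 5, 3, 2, 4), 5, 4,
                 dimnames = list(letters[1:5], LETTERS[1:4]))
  kept <- select_top_genes(expr, 2)
  expect_identical(rownames(kept), c("b", "e"))   # means 5 and 4
  expect_identical(select_top_genes(expr, 5), expr)
  expect_identical(select_top_genes(expr, 10), expr)
  # tie at the boundary: earlier row wins
  tied <- matrix(c(2, 2, 2, 1), 4, 3,
                 dimnames = list(c("w", "x", "y", "z"), c("A", "B", "C")))
  expect_identical(rownames(select_top_genes(tied, 2)), c("w", "x"))
})

test_that("TOM matches the double-loop oracle on random matrices", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(4:20, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
    expect_equal(tom_from_adjacency(a), oracle_tom(a), tolerance = 1e-12)
  }
})

test_that("TOM degenerate cases follow the closed forms", {
  # 3 genes with pairwise |r| = 1, beta = 1 -> off-diagonal TOM = 1
  base <- rnorm(10)
  expr <- rbind(g1 = base, g2 = 2 * base + 1, g3 = -base)
  colnames(expr) <- sprintf("s%02d", 1:10)
  tm <- tom_from_expression(expr, beta = 1)
  expect_equal(unname(tm$tom[upper.tri(tm$tom)]), rep(1, 3), tolerance = 1e-12)
  # all-zero adjacency -> off-diagonal 0
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tz <- tom_from_adjacency(z)
  expect_true(all(tz[upper.tri(tz)] == 0))
  expect_true(all(diag(tz) == 1))
})

test_that("TOM is symmetric with entries in [0, 1] on random expression", {
  for (s in 1:5) {
    set.seed(100 + s)
    expr <- matrix(rnorm(30 * 12), 30, 12,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("s%02d", 1:12)))
    tm <- tom_from_expression(expr, beta = sample(1:8, 1))$tom
    expect_equal(tm, t(tm), tolerance = 1e-12)
    expect_true(all(tm >= 0 & tm <= 1))
  }
})

test_that("raising beta never increases an off-diagonal adjacency entry", {
  set.seed(3)
  expr <- matrix(rnorm(25 * 10), 25, 10,
                 dimnames = list(sprintf("g%02d", 1:25),
                                 sprintf("s%02d", 1:10)))
  a2 <- tom_from_expression(expr, 2)$adjacency
  a6 <- tom_from_expression(expr, 6)$adjacency
  expect_true(all(a6 <= a2 + 1e-15))
})

test_that("zero-variance gene correlates as 0 with a warning", {
  expr <- rbind(flat = rep(5, 8), g2 = rnorm(8))
  colnames(expr) <- sprintf("s%02d", 1:8)
  expect_warning(tm <- tom_from_expression(expr, 2), "zero-variance")
  expect_identical(unname(tm$adjacency["flat", "g2"]), 0)
})

test_that("soft-threshold scan has decreasing connectivity and valid choice", {
  sim <- simulate_module_expression(300, 40, c(80, 60), 0.8, 0.6, seed = 4)
  scan <- pick_soft_threshold(sim$expr, powers = 1:10)
  expect_s3_class(scan, "soft_threshold_scan")
  expect_true(all(diff(scan$scan$mean_connectivity) < 0))
  expect_true(scan$chosen_power %in% 1:10)
  # beta = 1 vs beta = 8 mean connectivity ordering
  k1 <- scan$scan$mean_connectivity[scan$scan$power == 1]
  k8 <- scan$scan$mean_connectivity[scan$scan$power == 8]
  expect_gt(k1, k8)
})

test_that("degenerate near-constant connectivity flags the invalid path", {
  # single module, loading 1, zero noise: all |r| = 1, k constant
  sim <- simulate_module_expression(30, 10, c(30), factor_loading = 1,
                                    noise_sd = 1e-9, seed = 5)
  scan <- pick_soft_threshold(sim$expr, powers = 1:3)
  expect_true(any(!scan$scan$valid))
})

test_that("modules are recovered from the default generator", {
  sim <- simulate_module_expression(600, 50, c(150, 120), 0.8, 0.6, seed = 6)
  tm <- tom_from_expression(sim$expr, 6)
  asg <- detect_modules(tm, min_module_size = 50)
  merged <- merge_close_modules(sim$expr, asg)
  expect_gte(length(unique(merged$labels[merged$labels > 0])), 2)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(merged$labels,
                                   sim$truth$module_of_gene)
  expect_gte(ari, 0.8)
})

test_that("min module size governs recovery of small modules", {
  sim <- simulate_module_expression(400, 50, c(60, 60), 0.8, 0.5, seed = 7)
  tm <- tom_from_expression(sim$expr, 6)
  both <- detect_modules(tm, min_module_size = 50)
  expect_gte(sum(unique(both$labels) > 0), 2)
  expect_warning(gray <- detect_modules(tm, min_module_size = 70),
                 "all genes gray")
  expect_true(all(gray$labels == 0))
})

test_that("min_module_size larger than n_genes gives all gray", {
  sim <- simulate_module_expression(60, 20, c(30), seed = 8)
  tm <- tom_from_expression(sim$expr, 4)
  expect_warning(asg <- detect_modules(tm, min_module_size = 61), "gray")
  expect_true(all(asg$labels == 0))
})

test_that("eigengenes follow the SVD definition and its symmetries", {
  sim <- simulate_module_expression(200, 30, c(60), 0.9, 0.3, seed = 9)
  labels <- sim$truth$module_of_gene
  asg <- structure(list(labels = labels), class = "module_assignment")
  me <- module_eigengenes(sim$expr, asg)
  expect_identical(rownames(me), "ME1")
  expect_equal(sum(me[1, ]^2), 1, tolerance = 1e-12)
  members <- names(labels)[labels == 1]
  expect_equal(unname(me[1, ]), unname(oracle_eigengene(sim$expr[members, ])),
               tolerance = 1e-8)
  # permutation invariance of member order
  perm <- sample(seq_along(labels))
  asg2 <- structure(list(labels = labels[perm]), class = "module_assignment")
  me2 <- module_eigengenes(sim$expr[perm, ], asg2)
  expect_equal(me, me2, tolerance = 1e-10)
})

test_that("a module of identical profiles yields that profile as eigengene", {
  prof <- rnorm(20)
  expr <- matrix(rep(prof, each = 5), 5, 20,
                 dimnames = list(sprintf("g%02d", 1:5), sprintf("s%02d", 1:20)))
  expr <- expr + matrix(rnorm(100, sd = 1e-8), 5, 20)
  asg <- structure(list(labels = stats::setNames(rep(1L, 5), rownames(expr))),
                   class = "module_assignment")
  me <- module_eigengenes(expr, asg)
  expect_gt(abs(stats::cor(me[1, ], prof)), 0.999)
})

test_that("eigengene explains at least any single member's share", {
  sim <- simulate_module_expression(100, 25, c(40), 0.8, 0.6, seed = 10)
  labels <- sim$truth$module_of_gene
  members <- names(labels)[labels == 1]
  z <- t(scale(t(sim$expr[members, ])))
  sv <- svd(z)
  # first singular value dominates every other direction, including any
  # single member's normalized profile projection
  proj_member <- max(vapply(seq_len(nrow(z)), function(i) {
    v <- z[i, ] / sqrt(sum(z[i, ]^2))
    sum((z %*% v)^2)
  }, numeric(1)))
  expect_gte(sv$d[1]^2 + 1e-8, proj_member)
})

test_that("over-split modules merge back at 0.25 and merging is idempotent", {
  sim <- simulate_module_expression(300, 40, c(200), 0.9, 0.4, seed = 11)
  labels <- sim$truth$module_of_gene
  # split the planted module in half artificially
  split <- labels
  members <- names(labels)[labels == 1]
  split[members[1:100]] <- 1L
  split[members[101:200]] <- 2L
  asg <- structure(list(labels = split, eigengenes = NULL,
                        merge_history = list(), cut_height = NA_real_),
                   class = "module_assignment")
  merged <- merge_close_modules(sim$expr, asg, 0.25)
  expect_identical(length(unique(merged$labels[merged$labels > 0])), 1L)
  expect_gt(length(merged$merge_history), 0)
  # idempotence
  again <- merge_close_modules(sim$expr, merged, 0.25)
  expect_identical(again$labels, merged$labels)
  # post-condition: retained eigengene dissimilarities >= 0.25
  if (length(unique(merged$labels[merged$labels > 0])) > 1) {
    d <- 1 - stats::cor(t(merged$eigengenes))
    expect_gte(min(d[upper.tri(d)]), 0.25)
  }
})

test_that("cut_height near zero merges nothing", {
  sim <- simulate_module_expression(300, 40, c(100, 80), 0.8, 0.6, seed = 12)
  tm <- tom_from_expression(sim$expr, 6)
  asg <- detect_modules(tm, 50)
  merged <- merge_close_modules(sim$expr, asg, 1e-6)
  expect_identical(merged$labels, asg$labels)
})

test_that("module colors map 0 to gray and 1 to blue", {
  labs <- stats::setNames(c(0L, 1L, 2L, 19L), c("a", "b", "c", "d"))
  cols <- module_colors(labs)
  expect_identical(unname(cols), c("gray", "blue", "brown", "module19"))
})
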