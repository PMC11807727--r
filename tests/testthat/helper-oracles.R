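# Independent oracle implementations used by the [DERIVED] tests. Each is a
# deliberately naive re-derivation (explicit loops, direct enumeration) so a
# bug in the package's vectorized code cannot hide in a shared shortcut.

# Topological overlap by the textbook double loop:
# TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), diag 1.
oracle_tom <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj)
  out <- matrix(0, n, n, dimnames = dimnames(adj))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
      out[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
    }
  }
  out
}

# Hypergeometric upper tail P(X >= x) by direct choose() enumeration:
# population N, K successes, draw m, observed x.
oracle_hyper_upper <- function(x, K, N, m) {
  xs <- x:min(K, m)
  sum(choose(K, xs) * choose(N - K, m - xs)) / choose(N, m)
}

# Lower tail P(X <= x) the same way.
oracle_hyper_lower <- function(x, K, N, m) {
  lo <- max(0, m - (N - K))
  xs <- lo:x
  sum(choose(K, xs) * choose(N - K, m - xs)) / choose(N, m)
}

# Benjamini-Hochberg by the definitional step-up rule.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Maximum neighborhood component via a hand-written BFS over an edge list:
# size of the largest connected component of the subgraph induced by the
# neighbors of v (v excluded).
oracle_mnc <- function(edges, v) {
  nbrs <- unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  if (!length(nbrs)) return(0L)
  sub <- edges[edges[, 1] %in% nbrs & edges[, 2] %in% nbrs, , drop = FALSE]
  seen <- character()
  best <- 0L
  for (s in nbrs) {
    if (s %in% seen) next
    comp <- s
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nx <- unique(c(sub[sub[, 1] == cur, 2], sub[sub[, 2] == cur, 1]))
      nx <- setdiff(nx, comp)
      comp <- c(comp, nx)
      queue <- c(queue, nx)
    }
    seen <- c(seen, comp)
    best <- max(best, length(comp))
  }
  best
}

# Pearson correlation test statistic and two-sided p from first principles
# over pairwise-complete observations.
oracle_cor_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, n = n, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# Cohen's kappa between two membership vectors by the contingency formula.
oracle_kappa <- function(a, b) {
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  (po - pe) / (1 - pe)
}

# Eigengene by explicit PCA: first principal component of the z-scored
# member rows (genes x samples), sign-aligned to the average profile.
oracle_eigengene <- function(expr_members) {
  z <- t(scale(t(expr_members)))
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)$x[, 1]
  pc <- pc / sqrt(sum(pc^2))
  if (stats::cor(pc, colMeans(z)) < 0) pc <- -pc
  pc
}
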