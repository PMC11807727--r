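# Weighted coexpression network core: sample outlier removal, gene selection,
# soft-threshold scan, topological overlap, module detection by hierarchical
# clustering of the TOM dissimilarity, eigengenes and eigengene-based merging.
#
# The network is unsigned: adjacency a_ij = |cor(x_i, x_j)|^beta. Dynamic tree
# cutting is approximated by a static cut at a high quantile of the dendrogram
# merge heights followed by a minimum-size filter; label 0 ("gray") collects
# unassigned genes.

#' Remove outlier samples by average-linkage clustering
#'
#' Samples are clustered on the Euclidean distance between their expression
#' profiles with average linkage; the tree is cut at `height_cut` and every
#' sample outside the largest resulting cluster is dropped.
#'
#' @param expr gene x sample matrix (>= 3 samples).
#' @param height_cut positive cut height; `Inf` keeps all samples.
#' @return list with `expr` (filtered matrix) and `removed` (sample ids).
#' @export
remove_outlier_samples <- function(expr, height_cut) {
  check_expression(expr, min_samples = 3)
  if (!is.finite(height_cut)) {
    return(list(expr = expr, removed = character()))
  }
  if (height_cut <= 0) pmn_abort("height_cut must be positive")
  hc <- stats::hclust(stats::dist(t(expr)), method = "average")
  cl <- stats::cutree(hc, h = height_cut)
  sizes <- table(cl)
  keep_cl <- as.integer(names(sizes)[which.max(sizes)])
  keep <- names(cl)[cl == keep_cl]
  if (!length(keep)) pmn_abort("outlier removal dropped every sample")
  removed <- setdiff(colnames(expr), keep)
  list(expr = expr[, keep, drop = FALSE], removed = removed)
}

#' Keep the genes with highest mean expression
#'
#' Ties at the boundary are broken by input order (earlier rows win); the
#' retained genes keep their original row order.
#'
#' @param expr gene x sample matrix.
#' @param n_top number of genes to keep (>= 1).
#' @return filtered matrix.
#' @export
select_top_genes <- function(expr, n_top) {
  check_expression(expr)
  if (n_top < 1) pmn_abort("n_top must be >= 1")
  if (n_top >= nrow(expr)) return(expr)
  ord <- order(rowMeans(expr), seq_len(nrow(expr)), decreasing = c(TRUE, FALSE),
               method = "radix")
  keep <- sort(ord[seq_len(n_top)])
  expr[keep, , drop = FALSE]
}

#' Scan soft-threshold powers for scale-free fit
#'
#' For each power beta, forms the unsigned adjacency a_ij = |r_ij|^beta,
#' computes connectivities k_i = sum_j a_ij, bins k into 10 equal-width bins
#' and regresses log10(mean frequency) on log10(mean k) over non-empty bins.
#' The signed fit index is R^2 times the sign of the slope (a scale-free
#' degree distribution has negative slope, hence positive index when R^2 is
#' reported the conventional way with the sign flipped). The chosen power is
#' the smallest beta whose signed index reaches `r2_target`, falling back to
#' the argmax over valid entries. Scans with fewer than 3 non-empty bins are
#' flagged invalid and excluded from the choice.
#'
#' @param expr gene x sample matrix.
#' @param powers ascending integer powers (default 1:20).
#' @param r2_target target fit index in (0, 1) (default 0.8).
#' @return object of class `soft_threshold_scan`: list with `scan` (tibble:
#'   power, signed_r2, mean_connectivity, n_bins, valid) and `chosen_power`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.8) {
  check_expression(expr, min_samples = 3)
  if (!length(powers) || is.unsorted(powers)) {
    pmn_abort("powers must be non-empty and ascending")
  }
  if (r2_target <= 0 || r2_target >= 1) pmn_abort("r2_target must be in (0,1)")
  absr <- abs(safe_gene_cor(expr))
  diag(absr) <- 0
  rows <- lapply(powers, function(beta) {
    k <- rowSums(absr^beta)
    fit <- scale_free_fit(k)
    tibble::tibble(power = beta, signed_r2 = fit$signed_r2,
                   mean_connectivity = mean(k), n_bins = fit$n_bins,
                   valid = fit$valid)
  })
  scan <- dplyr::bind_rows(rows)
  valid <- scan[scan$valid, , drop = FALSE]
  chosen <- if (!nrow(valid)) NA_integer_ else {
    hit <- valid$power[valid$signed_r2 >= r2_target]
    if (length(hit)) hit[1] else valid$power[which.max(valid$signed_r2)]
  }
  structure(list(scan = scan, chosen_power = chosen),
            class = "soft_threshold_scan")
}

# Scale-free topology fit of a connectivity vector: 10 equal-width bins,
# log10 frequency vs log10 mean connectivity, signed R^2.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  # a relative range this small collapses the equal-width bin breaks into
  # duplicates, so treat it as constant connectivity
  if (length(k) < 2 || diff(range(k)) <= max(k) * 1e-8) {
    return(list(signed_r2 = NA_real_, n_bins = 0L, valid = FALSE))
  }
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) {
    return(list(signed_r2 = NA_real_, n_bins = sum(ok), valid = FALSE))
  }
  x <- log10(kmean[ok])
  y <- log10(freq[ok] / sum(freq[ok]))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[["x"]]
  list(signed_r2 = -sign(slope) * r2, n_bins = sum(ok), valid = TRUE)
}

#' Topological overlap matrix from expression
#'
#' Unsigned adjacency a_ij = |r_ij|^beta (i != j), connectivity
#' k_i = sum_u a_iu, shared-neighbor weight L_ij = sum_u a_iu a_uj, and
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij); TOM_ii = 1.
#'
#' @param expr gene x sample matrix.
#' @param beta soft-threshold power (>= 1).
#' @return object of class `tom_matrix`: list with `tom` (gene x gene matrix),
#'   `adjacency`, `connectivity`, `beta`.
#' @export
tom_from_expression <- function(expr, beta) {
  check_expression(expr, min_samples = 3)
  if (beta < 1) pmn_abort("beta must be >= 1")
  a <- abs(safe_gene_cor(expr))^beta
  diag(a) <- 0
  tom <- tom_from_adjacency(a)
  structure(list(tom = tom, adjacency = a, connectivity = rowSums(a),
                 beta = beta),
            class = "tom_matrix")
}

#' @rdname tom_from_expression
#' @param adjacency symmetric matrix in \[0, 1\] with zero diagonal.
#' @export
tom_from_adjacency <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                       # diag(a) = 0, so u = i, j terms vanish
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect coexpression modules from a TOM
#'
#' Genes are clustered by average linkage on the dissimilarity 1 - TOM and the
#' tree is cut statically at the `cut_quantile` quantile of its merge heights
#' (an adaptive-cut approximation of dynamic tree cutting). Clusters smaller
#' than `min_module_size` are assigned to gray (label 0); the rest are
#' relabeled 1, 2, ... by decreasing size.
#'
#' @param tomatrix a `tom_matrix` (or a plain TOM matrix).
#' @param min_module_size minimum members per retained module (>= 2).
#' @param cut_quantile quantile of merge heights for the static cut. TOM
#'   dissimilarities saturate near 1 for unrelated genes, so the merges that
#'   assemble modules sit in the low tail of the height distribution; the
#'   default 0.4 cuts above that tail while staying well below the
#'   background-merge plateau.
#' @return object of class `module_assignment`: list with `labels` (named
#'   integer vector, 0 = gray), `eigengenes` (NULL until computed),
#'   `merge_history`, `cut_height`.
#' @export
detect_modules <- function(tomatrix, min_module_size = 50, cut_quantile = 0.4) {
  tom <- if (inherits(tomatrix, "tom_matrix")) tomatrix$tom else tomatrix
  if (min_module_size < 2) pmn_abort("min_module_size must be >= 2")
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut_h <- stats::quantile(hc$height, cut_quantile, names = FALSE)
  raw <- stats::cutree(hc, h = cut_h)
  labels <- relabel_by_size(raw, min_module_size)
  if (!any(labels > 0)) {
    warning("no cluster reached min_module_size; all genes gray",
            call. = FALSE)
  }
  structure(list(labels = labels, eigengenes = NULL, merge_history = list(),
                 cut_height = cut_h),
            class = "module_assignment")
}

# Relabel raw cluster ids: clusters below min_size -> 0; others ranked by
# decreasing size (ties by smallest original id for determinism). A raw id
# of 0 is already gray and never competes for a module label.
relabel_by_size <- function(raw, min_size) {
  sizes <- table(raw)
  sizes <- sizes[names(sizes) != "0"]
  keep <- names(sizes)[sizes >= min_size]
  ord <- keep[order(-as.integer(sizes[keep]), as.integer(keep))]
  new <- stats::setNames(rep(0L, length(raw)), names(raw))
  for (i in seq_along(ord)) new[raw == as.integer(ord[i])] <- i
  new
}

#' Module eigengenes
#'
#' For each non-gray module, member genes are z-scored across samples and the
#' eigengene is the first right-singular vector of the member submatrix (the
#' sample-space first principal component), sign-aligned so its correlation
#' with the module's mean standardized profile is non-negative, and scaled to
#' unit norm.
#'
#' @param expr gene x sample matrix covering the assigned genes.
#' @param assignment a `module_assignment`.
#' @return module x sample matrix with rownames `ME1`, `ME2`, ...
#' @export
module_eigengenes <- function(expr, assignment) {
  stopifnot(inherits(assignment, "module_assignment"))
  labels <- assignment$labels
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) pmn_abort("no non-gray module to summarize")
  me <- t(vapply(mods, function(m) {
    members <- names(labels)[labels == m]
    z <- expr[members, , drop = FALSE]
    z <- t(scale(t(z)))
    z[!is.finite(z)] <- 0          # zero-variance members contribute nothing
    sv <- svd(z, nu = 0, nv = 1)
    v <- sv$v[, 1]
    mean_profile <- colMeans(z)
    if (stats::sd(mean_profile) > 0 &&
        suppressWarnings(stats::cor(v, mean_profile)) < 0) v <- -v
    v / sqrt(sum(v^2))
  }, numeric(ncol(expr))))
  dimnames(me) <- list(paste0("ME", mods), colnames(expr))
  me
}

#' Merge modules with similar eigengenes
#'
#' Iteratively computes eigengenes, clusters them by average linkage on
#' 1 - cor(eigengene pairs), merges every group joined below `cut_height`,
#' relabels by size, and repeats until all retained eigengene pairs are at
#' dissimilarity >= `cut_height`. Gray genes are untouched.
#'
#' @param expr gene x sample matrix.
#' @param assignment a `module_assignment` (pre-merge).
#' @param cut_height eigengene dissimilarity threshold in (0, 1); the
#'   conventional 0.25 corresponds to 75% eigengene similarity.
#' @return a `module_assignment` with merged labels, final `eigengenes` and a
#'   `merge_history` recording each merge round.
#' @export
merge_close_modules <- function(expr, assignment, cut_height = 0.25) {
  stopifnot(inherits(assignment, "module_assignment"))
  if (cut_height <= 0 || cut_height >= 1) pmn_abort("cut_height must be in (0,1)")
  labels <- assignment$labels
  history <- assignment$merge_history
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, structure(list(labels = labels),
                                            class = "module_assignment"))
    d <- 1 - stats::cor(t(me))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hc, h = cut_height)
    if (max(grp) == length(mods)) break  # nothing merges below the threshold
    merged_labels <- labels
    for (g in unique(grp)) {
      members <- mods[grp == g]
      if (length(members) > 1) {
        target <- min(members)
        merged_labels[labels %in% members] <- target
        history[[length(history) + 1L]] <- list(
          merged = paste0("ME", members),
          height = max(d[paste0("ME", members), paste0("ME", members)]))
      }
    }
    labels <- relabel_by_size(merged_labels, min_size = 1)
  }
  out <- structure(list(labels = labels, eigengenes = NULL,
                        merge_history = history,
                        cut_height = assignment$cut_height),
                   class = "module_assignment")
  if (any(labels > 0)) out$eigengenes <- module_eigengenes(expr, out)
  out
}

#' @export
print.module_assignment <- function(x, ...) {
  sizes <- table(x$labels[x$labels > 0])
  cat(sprintf("module_assignment: %d modules (+%d gray genes) over %d genes\n",
              length(sizes), sum(x$labels == 0), length(x$labels)))
  if (length(sizes)) {
    cat("sizes:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat(sprintf("soft_threshold_scan: %d powers, chosen beta = %s\n",
              nrow(x$scan), x$chosen_power))
  print(x$scan, n = nrow(x$scan))
  invisible(x)
}

#' Convenience label aliases mimicking the conventional color vocabulary
#'
#' @param labels integer labels from a `module_assignment`.
#' @return character vector; 0 maps to "gray", 1 to "blue", then a fixed
#'   palette, falling back to `module<k>`.
#' @export
module_colors <- function(labels) {
  palette <- c("blue", "brown", "turquoise", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "royalblue",
               "darkgreen")
  out <- ifelse(labels == 0, "gray",
                ifelse(labels <= length(palette), palette[pmax(labels, 1)],
                       paste0("module", labels)))
  stats::setNames(out, names(labels))
}
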