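# Synthetic input generators. Each generator plants a known structure
# (coexpression modules, reference-set overlap, hubs, fold-change tiers,
# phenotype correlations, trait associations) and records it in a
# `synthetic_truth` object so downstream stages can be validated by recovery.
# All generators take explicit seeds and leave global RNG state untouched.

#' Ground-truth record for synthetic fixtures
#'
#' @param module_of_gene named integer vector, gene -> planted module id
#'   (0 = background).
#' @param reference_genes character vector of planted reference genes.
#' @param de_genes named numeric vector, gene -> planted log2 fold-change.
#' @param hub_genes character vector of degree-boosted genes.
#' @param correlated_pairs tibble(gene, region, phenotype, sign).
#' @param associated_pairs tibble(gene, trait).
#' @param candidate_genes genes planted to satisfy every shortlist criterion.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(module_of_gene = integer(),
                            reference_genes = character(),
                            de_genes = numeric(),
                            hub_genes = character(),
                            correlated_pairs = NULL,
                            associated_pairs = NULL,
                            candidate_genes = character()) {
  mids <- sort(unique(unname(module_of_gene)))
  if (length(mids) && !all(mids == seq_along(mids) - 1 + min(1, min(mids)))) {
    # module ids must be contiguous starting at 0 (background) or 1
    if (!identical(mids, seq(min(mids), max(mids))) || !min(mids) %in% c(0L, 1L)) {
      pmn_abort("planted module ids must be contiguous from 0")
    }
  }
  structure(list(
    module_of_gene = module_of_gene,
    reference_genes = reference_genes,
    de_genes = de_genes,
    hub_genes = hub_genes,
    correlated_pairs = correlated_pairs %||%
      tibble::tibble(gene = character(), region = character(),
                     phenotype = character(), sign = integer()),
    associated_pairs = associated_pairs %||%
      tibble::tibble(gene = character(), trait = character()),
    candidate_genes = candidate_genes
  ), class = "synthetic_truth")
}

#' Simulate an expression matrix with latent-factor coexpression modules
#'
#' Each module m draws one latent sample factor f_m ~ N(0, 1); a member gene
#' is `loading * f_m + e` with e ~ N(0, noise_sd^2), plus a per-gene baseline
#' drawn uniformly on \[4, 12\] (a log-scale microarray-like intensity).
#' Background genes are baseline plus pure noise. Within-module correlation is
#' therefore loading^2 / (loading^2 + noise_sd^2) in population.
#'
#' @param n_genes total genes.
#' @param n_samples samples.
#' @param module_sizes integer vector of planted module sizes; must sum to at
#'   most `n_genes`.
#' @param factor_loading loading in (0, 1\]; 0 allowed to generate pure noise.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @return list with `expr` (gene x sample matrix) and `truth`
#'   ([synthetic_truth()] with `module_of_gene` filled).
#' @export
simulate_module_expression <- function(n_genes, n_samples, module_sizes,
                                       factor_loading = 0.8, noise_sd = 0.6,
                                       seed) {
  if (sum(module_sizes) > n_genes) {
    pmn_abort("module sizes sum above n_genes", "painmodnet_size_error")
  }
  if (factor_loading < 0 || factor_loading > 1) {
    pmn_abort("factor_loading must lie in [0, 1]")
  }
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    samples <- sprintf("S%03d", seq_len(n_samples))
    module <- integer(n_genes)
    start <- 1L
    for (m in seq_along(module_sizes)) {
      module[start:(start + module_sizes[m] - 1L)] <- m
      start <- start + module_sizes[m]
    }
    baseline <- stats::runif(n_genes, 4, 12)
    expr <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                   n_genes, n_samples, dimnames = list(genes, samples))
    for (m in seq_along(module_sizes)) {
      f <- stats::rnorm(n_samples)
      idx <- which(module == m)
      expr[idx, ] <- expr[idx, ] +
        factor_loading * matrix(f, length(idx), n_samples, byrow = TRUE)
    }
    expr <- expr + baseline
    list(expr = expr,
         truth = synthetic_truth(module_of_gene = stats::setNames(module, genes)))
  })
}

#' Plant a reference gene set overlapping one module
#'
#' Draws exactly `n_in_module` genes from the target module and `n_background`
#' from module-0 (background) genes, emulating a curated disease reference set
#' enriched in one coexpression module.
#'
#' @param truth a [synthetic_truth()] with `module_of_gene` filled.
#' @param target_module module id to over-represent.
#' @param n_in_module,n_background set composition.
#' @param seed integer seed.
#' @return list with `genes` (the reference set) and `truth` (updated).
#' @export
plant_reference_set <- function(truth, target_module, n_in_module,
                                n_background, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  in_mod <- names(truth$module_of_gene)[truth$module_of_gene == target_module]
  bg <- names(truth$module_of_gene)[truth$module_of_gene == 0L]
  if (!length(in_mod)) pmn_abort("target module not present in truth")
  if (n_in_module > length(in_mod) || n_background > length(bg)) {
    pmn_abort("reference set oversubscribes module or background",
              "painmodnet_size_error")
  }
  with_seed(seed, {
    ref <- c(if (n_in_module > 0) sample(in_mod, n_in_module) else character(),
             if (n_background > 0) sample(bg, n_background) else character())
    truth$reference_genes <- ref
    list(genes = ref, truth = truth)
  })
}

#' Simulate a scored interaction edge list with planted hubs
#'
#' Grows a preferential-attachment-style graph: nodes are added in random
#' order, each connecting `round(mean_degree / 2)` stubs to existing nodes
#' sampled with probability proportional to (degree + 1). Hub genes then
#' receive `hub_degree_boost` extra stubs each, also preferentially attached.
#' Every edge carries a uniform score in `score_range`; no self-loops or
#' duplicate pairs are produced.
#'
#' @param genes node identifiers.
#' @param mean_degree target mean degree of the base graph (>= 1).
#' @param hub_genes subset of `genes` to boost (may be empty).
#' @param hub_degree_boost extra stubs per hub.
#' @param score_range length-2 numeric, edge-score interval within \[0, 1\].
#' @param seed integer seed.
#' @return tibble(protein_a, protein_b, combined_score).
#' @export
simulate_interaction_graph <- function(genes, mean_degree = 4,
                                       hub_genes = character(),
                                       hub_degree_boost = 0,
                                       score_range = c(0.7, 1.0), seed) {
  if (mean_degree < 1) pmn_abort("mean_degree must be >= 1",
                                 "painmodnet_parameter_error")
  if (!all(hub_genes %in% genes)) pmn_abort("hub_genes must be a subset of genes")
  n <- length(genes)
  m <- max(1L, round(mean_degree / 2))
  with_seed(seed, {
    ord <- sample(genes)
    deg <- stats::setNames(integer(n), ord)
    adj <- new.env(parent = emptyenv())
    ekey <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
    edges_a <- character(0); edges_b <- character(0)
    add_edge <- function(a, b) {
      k <- ekey(a, b)
      if (a == b || !is.null(adj[[k]])) return(FALSE)
      adj[[k]] <- TRUE
      edges_a[[length(edges_a) + 1L]] <<- a
      edges_b[[length(edges_b) + 1L]] <<- b
      deg[[a]] <<- deg[[a]] + 1L
      deg[[b]] <<- deg[[b]] + 1L
      TRUE
    }
    # seed clique over the first m + 1 nodes
    first <- ord[seq_len(min(m + 1L, n))]
    for (i in seq_along(first)) for (j in seq_len(i - 1L)) {
      add_edge(first[i], first[j])
    }
    if (n > m + 1L) {
      for (i in (m + 2L):n) {
        present <- ord[seq_len(i - 1L)]
        w <- deg[present] + 1
        targets <- sample(present, min(m, length(present)), prob = w)
        for (t in targets) add_edge(ord[i], t)
      }
    }
    # boost hubs with preferential extra stubs
    for (h in sample(hub_genes)) {
      added <- 0L; tries <- 0L
      while (added < hub_degree_boost && tries < 50L * (hub_degree_boost + 1L)) {
        w <- deg[ord] + 1
        t <- sample(ord, 1, prob = w)
        if (add_edge(h, t)) added <- added + 1L
        tries <- tries + 1L
      }
    }
    score <- stats::runif(length(edges_a), score_range[1], score_range[2])
    tibble::tibble(protein_a = edges_a, protein_b = edges_b,
                   combined_score = score)
  })
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Per-gene baseline means are drawn log-uniformly from `baseline_mean_range`;
#' case-group means are baseline * 2^lfc for planted genes. Per-sample
#' library-size multipliers are drawn log-normal(0, 0.1) so normalization has
#' real work to do. Counts are NB with the given dispersion (variance
#' mu + dispersion * mu^2).
#'
#' @param genes gene identifiers.
#' @param n_per_group samples per group (single integer, >= 2).
#' @param baseline_mean_range length-2 positive numeric.
#' @param dispersion NB dispersion (> 0); scalar, constant across genes.
#' @param de_genes_with_lfc named numeric vector, gene -> planted log2
#'   fold-change (case vs control); may be empty.
#' @param seed integer seed.
#' @return list with `counts` (integer matrix), `groups` (named character,
#'   "control"/"case"), `lib_factors` (planted multipliers) and `truth`
#'   (tibble gene, lfc for planted genes).
#' @export
simulate_counts <- function(genes, n_per_group, baseline_mean_range = c(20, 500),
                            dispersion = 0.1, de_genes_with_lfc = numeric(),
                            seed) {
  if (length(n_per_group) != 1 || n_per_group != round(n_per_group) ||
      n_per_group < 2) {
    pmn_abort("n_per_group must be a single integer >= 2",
              "painmodnet_parameter_error")
  }
  if (dispersion <= 0) pmn_abort("dispersion must be > 0",
                                 "painmodnet_parameter_error")
  if (length(de_genes_with_lfc) && !all(names(de_genes_with_lfc) %in% genes)) {
    pmn_abort("planted DE genes must appear in the gene list")
  }
  with_seed(seed, {
    n_genes <- length(genes)
    ns <- 2L * n_per_group
    samples <- c(sprintf("ctrl_%d", seq_len(n_per_group)),
                 sprintf("case_%d", seq_len(n_per_group)))
    groups <- stats::setNames(rep(c("control", "case"), each = n_per_group),
                              samples)
    mu0 <- exp(stats::runif(n_genes, log(baseline_mean_range[1]),
                            log(baseline_mean_range[2])))
    names(mu0) <- genes
    lfc <- stats::setNames(numeric(n_genes), genes)
    lfc[names(de_genes_with_lfc)] <- de_genes_with_lfc
    lib <- exp(stats::rnorm(ns, 0, 0.1))
    mu <- cbind(matrix(mu0, n_genes, n_per_group),
                matrix(mu0 * 2^lfc, n_genes, n_per_group))
    mu <- sweep(mu, 2, lib, `*`)
    counts <- matrix(stats::rnbinom(n_genes * ns, mu = mu, size = 1 / dispersion),
                     n_genes, ns, dimnames = list(genes, samples))
    storage.mode(counts) <- "integer"
    list(counts = counts, groups = groups, lib_factors = lib,
         truth = tibble::tibble(gene = names(de_genes_with_lfc),
                                lfc = unname(de_genes_with_lfc)))
  })
}

#' Simulate brain-region strain panels with planted gene-phenotype correlations
#'
#' For each region a strain count is drawn from `strain_range` (mirroring
#' reference-population panels of 27-69 strains), a strain x phenotype matrix
#' of standard-normal phenotype values is generated, and gene expression
#' profiles across strains are pure noise except for planted
#' (gene, region, phenotype, sign) entries, which are constructed with
#' population correlation `sign * rho` to the phenotype vector. A fraction
#' `missing_rate` of phenotype values is set to NA to exercise
#' pairwise-complete correlation.
#'
#' @param genes gene identifiers.
#' @param regions character vector of region names (8 by default downstream).
#' @param n_phenotypes phenotypes per region.
#' @param correlated_pairs tibble(gene, region, phenotype, sign); `phenotype`
#'   as name or index, `sign` in -1/1.
#' @param rho planted correlation magnitude in (0, 1).
#' @param strain_range length-2 integer range of strains per region.
#' @param missing_rate fraction of phenotype values masked as NA.
#' @param seed integer seed.
#' @return list with `panels` (named list of [strain_panel()]) and `truth`
#'   (tibble of the planted pairs with resolved phenotype names).
#' @export
simulate_strain_panels <- function(genes, regions, n_phenotypes = 31,
                                   correlated_pairs = NULL, rho = 0.7,
                                   strain_range = c(27, 69),
                                   missing_rate = 0.1, seed) {
  if (rho <= 0 || rho >= 1) pmn_abort("rho must lie in (0, 1)",
                                      "painmodnet_parameter_error")
  correlated_pairs <- correlated_pairs %||%
    tibble::tibble(gene = character(), region = character(),
                   phenotype = character(), sign = integer())
  if (!all(correlated_pairs$gene %in% genes)) {
    pmn_abort("planted pairs reference unknown genes")
  }
  if (!all(correlated_pairs$region %in% regions)) {
    pmn_abort("planted pairs reference unknown regions")
  }
  phen_names <- sprintf("pheno_%02d", seq_len(n_phenotypes))
  with_seed(seed, {
    resolved <- list()
    panels <- lapply(regions, function(rg) {
      n_s <- if (strain_range[1] == strain_range[2]) strain_range[1] else
        sample(seq(strain_range[1], strain_range[2]), 1)
      strains <- sprintf("BXD%03d", seq_len(n_s))
      phen <- matrix(stats::rnorm(n_s * n_phenotypes), n_s, n_phenotypes,
                     dimnames = list(strains, phen_names))
      expr <- matrix(stats::rnorm(length(genes) * n_s), length(genes), n_s,
                     dimnames = list(genes, strains))
      planted <- correlated_pairs[correlated_pairs$region == rg, , drop = FALSE]
      if (nrow(planted)) {
        for (i in seq_len(nrow(planted))) {
          ph <- planted$phenotype[[i]]
          ph_idx <- if (is.numeric(ph)) as.integer(ph) else match(ph, phen_names)
          if (is.na(ph_idx) || ph_idx < 1 || ph_idx > n_phenotypes) {
            pmn_abort("planted pair references unknown phenotype")
          }
          g <- planted$gene[[i]]
          s <- planted$sign[[i]]
          expr[g, ] <- s * rho * phen[, ph_idx] +
            sqrt(1 - rho^2) * stats::rnorm(n_s)
          resolved[[length(resolved) + 1L]] <<- tibble::tibble(
            gene = g, region = rg, phenotype = phen_names[ph_idx],
            sign = as.integer(s))
        }
      }
      expr <- expr + 8  # log-scale array baseline
      phen[stats::runif(length(phen)) < missing_rate] <- NA_real_
      strain_panel(rg, expr, phen)
    })
    list(panels = stats::setNames(panels, regions),
         truth = if (length(resolved)) dplyr::bind_rows(resolved) else
           tibble::tibble(gene = character(), region = character(),
                          phenotype = character(), sign = integer()))
  })
}

#' Simulate a sparse gene-trait association table
#'
#' Produces the full gene x trait cross with uniform p-values; planted pairs
#' get p drawn uniformly below `p_strength`.
#'
#' @param genes gene identifiers.
#' @param traits trait names.
#' @param associated_pairs tibble(gene, trait) of planted associations.
#' @param p_strength upper bound for planted p-values.
#' @param seed integer seed.
#' @return tibble(gene, trait, p).
#' @export
simulate_gwas_table <- function(genes, traits, associated_pairs = NULL,
                                p_strength = 1e-4, seed) {
  associated_pairs <- associated_pairs %||%
    tibble::tibble(gene = character(), trait = character())
  if (!all(associated_pairs$gene %in% genes) ||
      !all(associated_pairs$trait %in% traits)) {
    pmn_abort("planted associations reference unknown genes or traits")
  }
  with_seed(seed, {
    tab <- tidyr::expand_grid(gene = genes, trait = traits)
    tab$p <- stats::runif(nrow(tab))
    key <- paste(tab$gene, tab$trait, sep = "\r")
    pk <- paste(associated_pairs$gene, associated_pairs$trait, sep = "\r")
    hit <- key %in% pk
    tab$p[hit] <- stats::runif(sum(hit), 0, p_strength)
    tab
  })
}
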