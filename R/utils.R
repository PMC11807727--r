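# Internal helpers shared across stages.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, restoring the
#' caller's RNG state afterwards. Every stochastic generator in the package
#' routes through this, so no function mutates global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Abort with a classed condition so callers/tests can match on class.
pmn_abort <- function(msg, class = "painmodnet_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Check an expression matrix: numeric, finite, unique dimnames.
check_expression <- function(expr, min_samples = 1) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    pmn_abort("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    pmn_abort("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr))) {
    pmn_abort("duplicate gene or sample identifiers in expression matrix")
  }
  if (any(!is.finite(expr))) {
    pmn_abort("expression matrix contains non-finite values")
  }
  if (ncol(expr) < min_samples) {
    pmn_abort(sprintf("expression matrix needs at least %d samples", min_samples))
  }
  invisible(expr)
}

# Pearson correlation between gene rows; zero-variance rows give r = 0 with a
# warning rather than NA (constant probes can survive mean-based selection).
safe_gene_cor <- function(expr) {
  sds <- apply(expr, 1, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    warning(sprintf(
      "%d zero-variance gene(s); their correlations are set to 0", sum(zero)
    ), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(t(expr)))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}
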