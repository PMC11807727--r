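# Readers and writers for the plain-text formats the pipeline consumes:
# expression/counts TSVs, GMT gene-set files, interaction edge lists,
# phenotype panels, association tables and flat key-value configs.

#' Read a gene x sample expression TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; all remaining columns numeric.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  check_expression(m)
  m
}

#' Write a gene x sample matrix as TSV
#'
#' @param expr numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name of the identifier column.
#' @export
write_expression_tsv <- function(expr, path, id_col = "gene_id") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix and its two-column group file
#'
#' @param counts_path TSV of non-negative integer counts (genes x samples).
#' @param groups_path TSV with columns `sample` and `group`.
#' @return list with `counts` (integer matrix) and `groups` (named character
#'   vector, sample -> group), samples ordered as in the count matrix.
#' @export
read_counts_tsv <- function(counts_path, groups_path) {
  counts <- read_expression_tsv(counts_path)
  if (any(counts < 0) || any(counts != round(counts))) {
    pmn_abort("count matrix must contain non-negative integers")
  }
  gdf <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(gdf))) {
    pmn_abort("group file needs columns 'sample' and 'group'")
  }
  groups <- stats::setNames(as.character(gdf$group), as.character(gdf$sample))
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing)) {
    pmn_abort(sprintf("samples missing from group file: %s",
                      paste(missing, collapse = ", ")))
  }
  list(counts = counts, groups = groups[colnames(counts)])
}

#' @rdname read_counts_tsv
#' @param counts integer matrix; @param groups named character vector.
#' @param counts_path,groups_path output paths.
#' @export
write_counts_tsv <- function(counts, groups, counts_path, groups_path) {
  write_expression_tsv(counts, counts_path)
  utils::write.table(
    data.frame(sample = colnames(counts), group = unname(groups[colnames(counts)])),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(counts_path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member genes.
#'
#' @param path GMT file path.
#' @return a `geneset_collection`: list with `sets` (named list of character
#'   vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      pmn_abort(sprintf("malformed GMT line %d: fewer than 3 fields", i),
                class = "painmodnet_format_error")
    }
    nm <- parts[[1]]
    if (nm %in% names(sets)) {
      pmn_abort(sprintf("duplicate gene-set name '%s' (GMT line %d)", nm, i),
                class = "painmodnet_format_error")
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      pmn_abort(sprintf("empty gene set '%s' (GMT line %d)", nm, i),
                class = "painmodnet_format_error")
    }
    sets[[nm]] <- genes
    desc[[nm]] <- parts[[2]]
  }
  geneset_collection(sets, desc)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (non-empty, unique names).
#' @param description optional named character vector of free-text notes.
#' @export
geneset_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    pmn_abort("gene-set names must be present and unique")
  }
  if (any(!lengths(sets))) pmn_abort("gene sets must be non-empty")
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = lapply(sets, as.character),
                 description = description[names(sets)]),
            class = "geneset_collection")
}

#' @rdname read_gmt
#' @param collection a `geneset_collection`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction edge list TSV
#'
#' Expects columns `protein_a`, `protein_b`, `combined_score` (or the first
#' three columns in that order).
#'
#' @param path TSV path.
#' @return tibble with columns protein_a, protein_b, combined_score.
#' @export
read_interactions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "combined_score")
  if (!all(need %in% names(df))) {
    if (ncol(df) < 3) pmn_abort("interaction table needs 3 columns")
    df <- df[, 1:3]
    names(df) <- need
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$combined_score))))
  if (length(bad)) {
    pmn_abort(sprintf("malformed combined_score at line %d", bad[1] + 1L),
              class = "painmodnet_format_error")
  }
  df$combined_score <- as.numeric(df$combined_score)
  tibble::as_tibble(df[need])
}

#' Read a strain-panel directory
#'
#' Each region contributes `<region>_expression.tsv` (gene x strain) and
#' `<region>_phenotypes.tsv` (strain x phenotype; first column `strain`,
#' missing values allowed).
#'
#' @param dir panel directory.
#' @return named list of panels, each a list with `region`, `expression`
#'   (gene x strain matrix) and `phenotypes` (strain x phenotype matrix).
#' @export
read_panel_dir <- function(dir) {
  expr_files <- list.files(dir, pattern = "_expression\\.tsv$", full.names = TRUE)
  if (!length(expr_files)) pmn_abort(sprintf("no panels found under %s", dir))
  panels <- lapply(expr_files, function(f) {
    region <- sub("_expression\\.tsv$", "", basename(f))
    pf <- file.path(dir, paste0(region, "_phenotypes.tsv"))
    if (!file.exists(pf)) {
      pmn_abort(sprintf("missing phenotype table for region '%s'", region))
    }
    expression <- read_expression_tsv(f)
    pdf <- utils::read.delim(pf, check.names = FALSE, stringsAsFactors = FALSE)
    phen <- as.matrix(pdf[, -1, drop = FALSE])
    storage.mode(phen) <- "double"
    rownames(phen) <- as.character(pdf[[1]])
    strain_panel(region, expression, phen)
  })
  stats::setNames(panels, vapply(panels, `[[`, "", "region"))
}

#' Construct a strain panel
#' @param region region name.
#' @param expression gene x strain matrix.
#' @param phenotypes strain x phenotype matrix (NAs allowed).
#' @export
strain_panel <- function(region, expression, phenotypes) {
  if (!identical(colnames(expression), rownames(phenotypes))) {
    pmn_abort(sprintf("strain ids differ between expression and phenotypes (%s)",
                      region))
  }
  structure(list(region = region, expression = expression,
                 phenotypes = phenotypes),
            class = "strain_panel")
}

#' Write one strain panel into a directory
#' @param panel a `strain_panel`.
#' @param dir output directory (created if absent).
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "strain_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(panel$expression,
                       file.path(dir, paste0(panel$region, "_expression.tsv")))
  pdf <- data.frame(strain = rownames(panel$phenotypes), panel$phenotypes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(pdf,
                     file.path(dir, paste0(panel$region, "_phenotypes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a gene-trait association TSV (PheWAS-style)
#' @param path TSV with columns gene, trait, p.
#' @return tibble(gene, trait, p).
#' @export
read_associations_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "trait", "p") %in% names(df))) {
    pmn_abort("association table needs columns gene, trait, p")
  }
  tibble::as_tibble(df[c("gene", "trait", "p")])
}

#' Generic TSV writer for result tables
#' @param tbl data frame; @param path output path.
#' @export
write_table_tsv <- function(tbl, path) {
  utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a flat key-value pipeline config
#'
#' One `key = value` pair per line; values parsed as numeric where possible,
#' `TRUE`/`FALSE` as logical, everything else kept as strings. Round-trips
#' losslessly for the types a [pipeline_config()] holds.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(kv) != 3) pmn_abort(sprintf("malformed config line: %s", ln))
    key <- kv[2]; val <- kv[3]
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else if (!is.na(num)) num
      else if (identical(val, "NULL")) NULL
      else val
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar values.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.null(v)) "NULL"
    else if (is.numeric(v)) format(v, digits = 17, scientific = FALSE)
    else as.character(v)
  }, character(1))
  writeLines(paste(names(config), fmt, sep = " = "), path)
  invisible(path)
}
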