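#' Construct a validated count matrix
#'
#' The basic container for bulk RNA-seq data: a genes-in-rows,
#' samples-in-columns matrix of non-negative read counts. Fractional values
#' are permitted because transcript-level quantification summarized to genes
#' (length-scaled estimated counts) is generally non-integer; they are passed
#' through unrounded to every downstream estimator.
#'
#' @param counts Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: `rownames(counts)`). Identifiers are treated as opaque strings.
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: `colnames(counts)`).
#'
#' @return An object of class `cp_counts`: a list with elements `counts`
#'   (the dimnamed matrix), `gene_ids` and `sample_ids`.
#' @examples
#' cm <- count_matrix(matrix(0:5, 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("s1", "s2"))))
#' cm
#' @export
count_matrix <- function(counts,
                         gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    abort("`counts` must be a numeric matrix.")
  }
  if (is.null(gene_ids)) {
    gene_ids <- paste0("gene", seq_len(nrow(counts)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(ncol(counts)))
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    abort("Identifier lengths do not match the matrix dimensions.")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0) {
    abort(paste0("Duplicated gene id(s): ", toString(head(dup_g, 5))))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    abort(paste0("Duplicated sample id(s): ", toString(head(dup_s, 5))))
  }
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(
      "Counts must be finite and non-negative; first offending cell: gene '",
      gene_ids[bad[1, 1]], "', sample '", sample_ids[bad[1, 2]], "'."
    ))
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, sample_ids = sample_ids),
    class = "cp_counts"
  )
}

#' @export
print.cp_counts <- function(x, ...) {
  cat("<cp_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
    " samples\n",
    sep = ""
  )
  cat("library sizes: ", toString(signif(colSums(x$counts), 4)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cp_counts <- function(x) dim(x$counts)

#' Coerce to a count matrix container
#'
#' @param x A `cp_counts` object, a numeric matrix with dimnames, or a data
#'   frame whose first column holds gene identifiers.
#' @return A `cp_counts` object.
#' @export
as_count_matrix <- function(x) {
  if (inherits(x, "cp_counts")) {
    return(x)
  }
  if (is.data.frame(x)) {
    genes <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- genes
    return(count_matrix(m))
  }
  count_matrix(x)
}

#' Construct a sample design table
#'
#' A design is a tibble with one row per sample, a `sample_id` column, a
#' `group` column assigning each sample to a biological group, and any number
#' of additional covariate columns (for example `replicate` used as a batch
#' covariate in the GLM test).
#'
#' @param x A data frame with a `sample_id` column and at least one more
#'   column.
#' @param group_col Name of the column holding the group label. Defaults to
#'   `"group"` if present, otherwise the first non-`sample_id` column.
#' @return A tibble of class `cp_design` with columns `sample_id`, `group`,
#'   then covariates; the covariate names are stored in the `covariates`
#'   attribute.
#' @export
sample_design <- function(x, group_col = NULL) {
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("Design must contain a `sample_id` column.")
  }
  others <- setdiff(names(x), "sample_id")
  if (length(others) == 0) {
    abort("Design must contain at least one group column.")
  }
  if (is.null(group_col)) {
    group_col <- if ("group" %in% others) "group" else others[[1]]
  }
  if (!group_col %in% others) {
    abort(paste0("Group column '", group_col, "' not found."))
  }
  x$sample_id <- as.character(x$sample_id)
  dup <- unique(x$sample_id[duplicated(x$sample_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated sample id(s) in design: ", toString(dup)))
  }
  grp <- as.character(x[[group_col]])
  if (any(is.na(grp) | grp == "")) {
    abort("Empty group label(s) in design.")
  }
  covars <- setdiff(others, group_col)
  out <- tibble::tibble(sample_id = x$sample_id, group = grp)
  for (cv in covars) out[[cv]] <- x[[cv]]
  structure(out,
    class = c("cp_design", class(out)),
    covariates = covars
  )
}

#' Covariate column names of a design
#' @param sd A `cp_design` object.
#' @return Character vector of covariate column names (possibly empty).
#' @export
design_covariates <- function(sd) attr(sd, "covariates") %||% character(0)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a two-group comparison against a design; returns list with the
# sample ids of each group, in design order.
resolve_comparison <- function(sd, comparison) {
  if (length(comparison) != 2 || comparison[1] == comparison[2]) {
    abort("`comparison` must name exactly two distinct group labels.")
  }
  missing <- setdiff(comparison, unique(sd$group))
  if (length(missing) > 0) {
    abort(paste0("Group(s) not present in design: ", toString(missing)))
  }
  list(
    a = sd$sample_id[sd$group == comparison[1]],
    b = sd$sample_id[sd$group == comparison[2]]
  )
}

# Subset a count matrix to the samples of a two-group comparison, preserving
# design order (group A samples first).
comparison_counts <- function(cm, sd, comparison) {
  cmp <- resolve_comparison(sd, comparison)
  samples <- c(cmp$a, cmp$b)
  missing <- setdiff(samples, cm$sample_ids)
  if (length(missing) > 0) {
    abort(paste0("Design sample(s) absent from counts: ", toString(missing)))
  }
  list(
    counts = cm$counts[, samples, drop = FALSE],
    group = factor(rep(comparison, c(length(cmp$a), length(cmp$b))),
      levels = comparison
    ),
    samples = samples
  )
}

#' Read a count matrix from disk
#'
#' Tabular formats expect a header row of sample identifiers with the first
#' column holding gene identifiers. MatrixMarket triplet input expects two
#' plain-text sidecar files listing the gene and sample identifiers
#' (one per line); cells absent from the triplet list are read as zero.
#'
#' @param path Path to the counts file.
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"mtx"`. `"auto"` infers
#'   from the file extension.
#' @param genes_file,samples_file Sidecar identifier files for `"mtx"` input;
#'   default `<path without .mtx>.genes.txt` / `.samples.txt`.
#' @return A validated [count_matrix()] with row/column order as on disk.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        genes_file = NULL, samples_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv",
      mtx = "mtx",
      "tsv"
    )
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    genes_file <- genes_file %||% paste0(stem, ".genes.txt")
    samples_file <- samples_file %||% paste0(stem, ".samples.txt")
    for (f in c(genes_file, samples_file)) {
      if (!file.exists(f)) abort(paste0("Sidecar file not found: ", f))
    }
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_file)
    sample_ids <- readLines(samples_file)
    if (length(gene_ids) != nrow(m) || length(sample_ids) != ncol(m)) {
      abort("Sidecar identifier counts do not match the matrix dimensions.")
    }
    rownames(m) <- gene_ids
    colnames(m) <- sample_ids
    return(count_matrix(m))
  }
  delim <- if (format == "csv") "," else "\t"
  tab <- suppressWarnings(readr::read_delim(path,
    delim = delim, col_types = readr::cols(
      readr::col_character(), .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  ))
  if (ncol(tab) < 2) abort("Counts table needs a gene column and >= 1 sample.")
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(paste0(
      "Non-numeric cell at row ", prob$row[1], ", column ", prob$col[1],
      " of ", path, "."
    ))
  }
  na_cell <- which(is.na(as.matrix(tab[, -1])), arr.ind = TRUE)
  if (nrow(na_cell) > 0) {
    abort(paste0(
      "Missing or non-numeric value for gene '",
      as.character(tab[[1]])[na_cell[1, 1]], "', sample '",
      names(tab)[-1][na_cell[1, 2]], "'."
    ))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  count_matrix(m)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; a write followed by a read reproduces the
#' values at full precision and preserves row and column order.
#'
#' @param cm A `cp_counts` object.
#' @param path Output path.
#' @param format `"auto"` (from extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("auto", "tsv", "csv", "mtx")) {
  cm <- as_count_matrix(cm)
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv",
      mtx = "mtx",
      "tsv"
    )
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    writeLines(cm$gene_ids, paste0(stem, ".genes.txt"))
    writeLines(cm$sample_ids, paste0(stem, ".samples.txt"))
    return(invisible(path))
  }
  tab <- tibble::as_tibble(cm$counts)
  tab <- tibble::add_column(tab, gene_id = cm$gene_ids, .before = 1)
  if (format == "csv") {
    readr::write_csv(tab, path)
  } else {
    readr::write_tsv(tab, path)
  }
  invisible(path)
}

#' Read a sample design table
#'
#' Expects a TSV with a `sample_id` column and at least one more column; the
#' `group` column (or, failing that, the first non-`sample_id` column) is the
#' group assignment and all remaining columns become covariates.
#'
#' @param path Path to the design TSV.
#' @param group_col Optional explicit group column name.
#' @return A [sample_design()] tibble.
#' @export
read_design <- function(path, group_col = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tab <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  sample_design(tab, group_col = group_col)
}

#' Validate a counts + design pair
#'
#' Checks that the sample sets agree and summarizes the dataset: per-sample
#' library sizes (column sums of the raw counts) and the number of genes with
#' zero counts in every sample.
#'
#' @param cm A `cp_counts` object (or coercible).
#' @param sd A `cp_design` object.
#' @return A list of class `cp_validation` with elements `issues` (character;
#'   empty when nothing is noteworthy), `library_sizes` (tibble of
#'   `sample_id`, `lib_size`), `n_all_zero_genes`, and `n_genes`/`n_samples`.
#'   Disagreeing sample sets are a hard error listing missing/extra ids.
#' @export
validate_dataset <- function(cm, sd) {
  cm <- as_count_matrix(cm)
  missing_in_design <- setdiff(cm$sample_ids, sd$sample_id)
  missing_in_counts <- setdiff(sd$sample_id, cm$sample_ids)
  if (length(missing_in_design) > 0 || length(missing_in_counts) > 0) {
    abort(paste0(
      "Sample sets disagree. In counts but not design: ",
      toString(missing_in_design %||% "none"),
      "; in design but not counts: ",
      toString(missing_in_counts %||% "none"), "."
    ))
  }
  lib <- colSums(cm$counts)
  n_zero <- sum(rowSums(cm$counts) == 0)
  issues <- character(0)
  if (n_zero > 0) {
    issues <- c(issues, paste0(n_zero, " gene(s) have zero counts in every sample."))
  }
  if (any(lib == 0)) {
    issues <- c(issues, paste0(
      "Sample(s) with zero library size: ",
      toString(names(lib)[lib == 0]), "."
    ))
  }
  structure(
    list(
      issues = issues,
      library_sizes = tibble::tibble(sample_id = names(lib), lib_size = unname(lib)),
      n_all_zero_genes = n_zero,
      n_genes = nrow(cm$counts),
      n_samples = ncol(cm$counts)
    ),
    class = "cp_validation"
  )
}

#' @export
print.cp_validation <- function(x, ...) {
  cat(
    "<cp_validation> ", x$n_genes, " genes, ", x$n_samples, " samples; ",
    x$n_all_zero_genes, " all-zero gene(s)\n",
    sep = ""
  )
  if (length(x$issues) == 0) {
    cat("no issues\n")
  } else {
    cat(paste0("- ", x$issues, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the tunable thresholds of a power-aware analysis. Defaults follow
#' the conventions of the power/detectability workflow: two-fold minimal
#' effect at significance 0.01 for power curves; FDR level 0.05 with an
#' expected 10% true positives for the FDR-adjusted per-gene significance
#' level; detectability at power >= 0.8; signature cutoffs 0.7 (power) and
#' 0.01 (FDR); differential expression at FDR < 0.05; top 500 most variable
#' genes for exploration.
#'
#' @param comparison Optional character vector of two group labels.
#' @param alpha Two-sided false-positive rate for single-gene power.
#' @param fold_change Minimal fold change Delta (> 0) the study should detect.
#' @param fdr_level Desired FDR level f used to derive the adjusted
#'   significance level.
#' @param pi1 Expected fraction of truly differentially expressed genes.
#' @param power_detectable_cutoff Power at or above which a gene is called
#'   detectable.
#' @param signature_power_cutoff,signature_fdr_cutoff Cutoffs for signature
#'   construction (confident negatives and positives respectively).
#' @param de_fdr_cutoff FDR below which a gene is called differentially
#'   expressed.
#' @param top_k_variable Number of most-variable genes kept for exploration.
#' @param seed Seed used by every randomized operation (t-SNE, simulation).
#' @return A list of class `cp_config`.
#' @export
analysis_config <- function(comparison = NULL,
                            alpha = 0.01,
                            fold_change = 2,
                            fdr_level = 0.05,
                            pi1 = 0.1,
                            power_detectable_cutoff = 0.8,
                            signature_power_cutoff = 0.7,
                            signature_fdr_cutoff = 0.01,
                            de_fdr_cutoff = 0.05,
                            top_k_variable = 500,
                            seed = 101) {
  stopifnot(
    alpha > 0, alpha < 1, fold_change > 0,
    fdr_level > 0, fdr_level < 1, pi1 > 0, pi1 < 1,
    power_detectable_cutoff >= 0, power_detectable_cutoff <= 1,
    signature_power_cutoff >= 0, signature_power_cutoff <= 1,
    signature_fdr_cutoff >= 0, signature_fdr_cutoff <= 1,
    de_fdr_cutoff >= 0, de_fdr_cutoff <= 1,
    top_k_variable >= 1
  )
  structure(
    list(
      comparison = comparison, alpha = alpha, fold_change = fold_change,
      fdr_level = fdr_level, pi1 = pi1,
      power_detectable_cutoff = power_detectable_cutoff,
      signature_power_cutoff = signature_power_cutoff,
      signature_fdr_cutoff = signature_fdr_cutoff,
      de_fdr_cutoff = de_fdr_cutoff,
      top_k_variable = top_k_variable, seed = seed
    ),
    class = "cp_config"
  )
}
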