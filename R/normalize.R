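#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values normalization factors, one per sample, computed
#' against a reference sample (the one whose upper-quartile relative
#' abundance is closest to the mean upper quartile). Log-ratios are trimmed
#' by 30%, average log-abundances by 5%, and the trimmed mean is
#' precision-weighted; factors are rescaled so their geometric mean is 1.
#'
#' @param cm A `cp_counts` object or numeric count matrix.
#' @return Named numeric vector of positive factors (one per sample).
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' tmm_factors(m) # pure depth change: both factors are 1
#' @export
tmm_factors <- function(cm) {
  cm <- as_count_matrix(cm)
  if (ncol(cm$counts) < 2) abort("TMM needs at least two samples.")
  lib <- colSums(cm$counts)
  if (any(lib == 0)) {
    abort(paste0(
      "Sample(s) with zero library size: ",
      toString(cm$sample_ids[lib == 0]), "."
    ))
  }
  f <- edgeR::calcNormFactors(cm$counts, method = "TMM")
  setNames(f, cm$sample_ids)
}

#' Counts per million
#'
#' CPM for entry (g, s) is `count / effective_library_size * 1e6` where the
#' effective library size is the column sum times the sample's normalization
#' factor. The log variant stabilizes zeros with a pseudocount applied
#' symmetrically: `log2((count + p) / (eff_lib + 2 p) * 1e6)`. Plain CPM uses
#' no pseudocount, so "CPM > 0" is exactly "count > 0".
#'
#' @param cm A `cp_counts` object or matrix.
#' @param factors Optional per-sample normalization factors (default: all 1,
#'   i.e. plain library sizes). Use [tmm_factors()] for TMM-effective sizes.
#' @param log If `TRUE`, return log2 CPM with the pseudocount.
#' @param pseudocount Pseudocount `p` for the log transform (default 0.5).
#' @return Numeric gene x sample matrix.
#' @export
cpm_matrix <- function(cm, factors = NULL, log = FALSE, pseudocount = 0.5) {
  cm <- as_count_matrix(cm)
  lib <- colSums(cm$counts)
  if (is.null(factors)) factors <- rep(1, ncol(cm$counts))
  if (any(factors <= 0)) abort("Normalization factors must be positive.")
  eff <- lib * factors
  if (log) {
    sweep(cm$counts + pseudocount, 2, (eff + 2 * pseudocount) / 1e6, "/") |>
      log2()
  } else {
    sweep(cm$counts, 2, eff / 1e6, "/")
  }
}

#' Full normalization result
#'
#' Convenience wrapper bundling TMM factors, effective library sizes, CPM and
#' log2 CPM for a dataset.
#'
#' @inheritParams cpm_matrix
#' @return A list of class `cp_norm` with elements `tmm_factors`,
#'   `effective_lib_sizes`, `cpm`, `log2cpm`.
#' @export
normalize_counts <- function(cm, pseudocount = 0.5) {
  cm <- as_count_matrix(cm)
  f <- tmm_factors(cm)
  structure(
    list(
      tmm_factors = f,
      effective_lib_sizes = colSums(cm$counts) * f,
      cpm = cpm_matrix(cm, f, log = FALSE),
      log2cpm = cpm_matrix(cm, f, log = TRUE, pseudocount = pseudocount)
    ),
    class = "cp_norm"
  )
}

#' Expression filter for a two-group comparison
#'
#' Keeps a gene when it has CPM > 0 (equivalently count > 0) in at least `m`
#' of the comparison's samples, where `m` is the size of the smaller group.
#' The filter is evaluated only on the samples belonging to the two compared
#' groups.
#'
#' @param cm A `cp_counts` object.
#' @param sd A `cp_design`.
#' @param comparison Character vector of two group labels.
#' @return Integer vector of kept row indices (attribute `m` records the
#'   threshold used).
#' @export
filter_expressed <- function(cm, sd, comparison) {
  cm <- as_count_matrix(cm)
  cc <- comparison_counts(cm, sd, comparison)
  sizes <- table(cc$group)
  if (any(sizes == 0)) abort("Each compared group needs at least one sample.")
  m <- min(sizes)
  kept <- which(rowSums(cc$counts > 0) >= m)
  attr(kept, "m") <- as.integer(m)
  kept
}

# Subset a cp_counts by gene index, keeping ids aligned.
subset_genes <- function(cm, idx) {
  count_matrix(cm$counts[idx, , drop = FALSE])
}

#' Most variable genes by median absolute deviation
#'
#' Ranks genes by the MAD of their log2 CPM across samples (descending) and
#' returns the top `k`. Ties keep the input row order, so the top-`k1` list is
#' always a prefix of the top-`k2` list for `k1 < k2`.
#'
#' @param log2cpm Numeric gene x sample matrix (rownames = gene ids).
#' @param k Number of genes to return (`k <= nrow(log2cpm)`).
#' @return Character vector of gene ids, most variable first.
#' @export
top_variable_genes <- function(log2cpm, k) {
  if (k > nrow(log2cpm)) {
    abort(paste0("k (", k, ") exceeds the number of genes (", nrow(log2cpm), ")."))
  }
  if (k < 1) abort("k must be >= 1.")
  mads <- apply(log2cpm, 1, mad)
  ids <- rownames(log2cpm) %||% as.character(seq_len(nrow(log2cpm)))
  ids[order(-mads)][seq_len(k)]
}

#' Center matrix rows to mean zero
#'
#' @param x Numeric matrix.
#' @return `x` with each row shifted to mean 0.
#' @export
center_rows <- function(x) {
  x - rowMeans(x)
}
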