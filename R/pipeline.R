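#' Run the full power-aware differential-expression pipeline
#'
#' Chains the analysis stages for one two-group comparison: expression
#' filtering (CPM > 0 in at least `m` samples, `m` = smaller group size),
#' TMM normalization, common/tagwise dispersion estimation, gene-wise power
#' at the FDR-adjusted significance level, differential expression (exact
#' test, or quasi-likelihood GLM when covariates are given),
#' Benjamini-Hochberg correction, triage into DE / NDE_DT / NDE_NDT, and
#' signature construction.
#'
#' @param cm A `cp_counts` object (or coercible).
#' @param sd A `cp_design`.
#' @param comparison Character vector of two group labels (overrides
#'   `config$comparison`).
#' @param covariates Optional covariate column names; switches the DE test
#'   to the quasi-likelihood GLM.
#' @param config An [analysis_config()].
#' @return A list of class `cp_pipeline` with elements `kept_genes`,
#'   `norm_factors`, `dispersion`, `detectability`, `de`, `triage`,
#'   `signature`, and `config`.
#' @export
run_pipeline <- function(cm, sd, comparison = NULL, covariates = NULL,
                         config = analysis_config()) {
  cm <- as_count_matrix(cm)
  comparison <- comparison %||% config$comparison
  if (is.null(comparison)) abort("A two-group `comparison` is required.")
  validate_dataset(cm, sd)
  kept <- filter_expressed(cm, sd, comparison)
  cmf <- subset_genes(cm, kept)
  disp <- estimate_dispersion(cmf, sd, comparison)
  det <- genewise_power(cmf, sd, comparison, disp, config = config)
  de <- if (is.null(covariates)) {
    exact_test(cmf, sd, comparison, disp)
  } else {
    glm_ql_test(cmf, sd, comparison, covariates, disp)
  }
  tri <- triage(de, det, config)
  sig <- build_signature(de, det, config)
  structure(
    list(
      kept_genes = cmf$gene_ids,
      norm_factors = tmm_factors(cmf),
      dispersion = disp,
      detectability = det,
      de = de,
      triage = tri,
      signature = sig,
      comparison = comparison,
      config = config
    ),
    class = "cp_pipeline"
  )
}

#' @export
print.cp_pipeline <- function(x, ...) {
  cnt <- attr(x$triage, "counts")
  cat("<cp_pipeline> ", paste(x$comparison, collapse = " vs "), "\n", sep = "")
  cat(
    length(x$kept_genes), "genes after expression filtering;",
    sprintf("common BCOV %.3f\n", x$dispersion$bcov_common)
  )
  cat(sprintf(
    "triage: %d DE, %d NDE&DT, %d NDE&NDT; signature: %d genes\n",
    cnt[["DE"]], cnt[["NDE_DT"]], cnt[["NDE_NDT"]], nrow(x$signature)
  ))
  invisible(x)
}
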