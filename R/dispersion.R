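#' Negative-binomial dispersion and biological coefficient of variation
#'
#' Estimates the common (shared) and tagwise (per-gene) NB dispersions for a
#' two-group comparison by quantile-adjusted conditional maximum likelihood:
#' library sizes are equalized by quantile-matched pseudo-counts and the
#' conditional likelihood given per-group sums is maximized; tagwise
#' estimates are shrunk toward the common value by a weighted-likelihood
#' empirical-Bayes scheme whose strength is `prior_df`. The biological
#' coefficient of variation (BCOV) is the square root of the dispersion: the
#' standard deviation of true relative expression between biological
#' replicates.
#'
#' Counts should already be restricted to expressed genes
#' (see [filter_expressed()]).
#'
#' @param cm A `cp_counts` object.
#' @param sd A `cp_design`.
#' @param comparison Character vector of two group labels; at least one group
#'   must have two or more samples.
#' @param prior_df Shrinkage strength for the tagwise estimates (default 10).
#'   As `prior_df` grows, tagwise estimates collapse onto the common value.
#' @param norm_factors Optional per-sample normalization factors for the
#'   comparison's samples; TMM factors are computed when `NULL`.
#' @return A list of class `cp_dispersion`: `common`, `tagwise` (named),
#'   `bcov_common`, `bcov_tagwise`, `prior_df`, `comparison`, `n_per_group`.
#' @export
estimate_dispersion <- function(cm, sd, comparison, prior_df = 10,
                                norm_factors = NULL) {
  cm <- as_count_matrix(cm)
  cc <- comparison_counts(cm, sd, comparison)
  sizes <- table(cc$group)
  if (max(sizes) < 2) {
    abort(paste0(
      "No group in the comparison has replicates; dispersion cannot be ",
      "estimated. Supply a dispersion value from comparable data instead."
    ))
  }
  d <- edgeR::DGEList(counts = cc$counts, group = cc$group)
  if (is.null(norm_factors)) {
    d <- edgeR::calcNormFactors(d, method = "TMM")
  } else {
    d$samples$norm.factors <- norm_factors
  }
  d <- edgeR::estimateCommonDisp(d)
  d <- edgeR::estimateTagwiseDisp(d, prior.df = prior_df, trend = "none")
  tagwise <- setNames(d$tagwise.dispersion, rownames(cc$counts))
  structure(
    list(
      common = d$common.dispersion,
      tagwise = tagwise,
      bcov_common = sqrt(d$common.dispersion),
      bcov_tagwise = sqrt(tagwise),
      prior_df = prior_df,
      comparison = comparison,
      n_per_group = as.integer(sizes)
    ),
    class = "cp_dispersion"
  )
}

#' @export
print.cp_dispersion <- function(x, ...) {
  cat("<cp_dispersion> ", length(x$tagwise), " genes; comparison ",
    paste(x$comparison, collapse = " vs "), "\n",
    sep = ""
  )
  cat(sprintf(
    "common dispersion %.4g (BCOV %.3g); tagwise range [%.3g, %.3g]; prior df %g\n",
    x$common, x$bcov_common, min(x$tagwise), max(x$tagwise), x$prior_df
  ))
  invisible(x)
}

#' Biological coefficient of variation from dispersion
#'
#' @param phi Non-negative NB dispersion (scalar or vector).
#' @return Elementwise square root of `phi`.
#' @examples
#' bcov(0.04) # 0.2
#' @export
bcov <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < 0)) {
    abort("Dispersion must be finite and non-negative.")
  }
  sqrt(phi)
}
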