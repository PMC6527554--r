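#' Closed-form power for detecting differential expression of one gene
#'
#' Analytic power of a two-group RNA-seq comparison under a
#' negative-binomial model. The test statistic for a fold change Delta with
#' `n` samples per group, average coverage `mu` (reads per sample for the
#' gene) and biological coefficient of variation `sigma` satisfies
#' \deqn{(z_{1-\alpha/2} + z_\beta)^2 = \frac{n \, (\ln \Delta)^2}
#'       {2\,(1/\mu + \sigma^2)}}
#' which, solved for power \eqn{1-\beta} in the favored tail of the
#' two-sided test, gives
#' \deqn{\mathrm{power} = \Phi\!\left(\sqrt{\frac{n (\ln \Delta)^2}
#'       {2 (1/\mu + \sigma^2)}} - z_{1-\alpha/2}\right).}
#' The `1/mu` term is the Poisson counting noise (vanishing with depth); the
#' `sigma^2` floor is the biological variance that no extra depth can remove.
#' At `delta = 1` power degenerates to `alpha / 2` (chance rejection in one
#' tail).
#'
#' @param n Samples per group (> 0).
#' @param delta Fold change Delta (> 0); only `abs(log(delta))` matters.
#' @param alpha Two-sided false-positive rate in (0, 1).
#' @param mu Average coverage (> 0): mean reads per sample for the gene, or a
#'   dataset-level depth expressed in millions of reads.
#' @param sigma Biological coefficient of variation (>= 0).
#' @return Power in `[0, 1]`; vectorized over `mu` and `sigma`.
#' @examples
#' power_single(n = 4, delta = 2, alpha = 0.01, mu = 41.72, sigma = 0.21)
#' @export
power_single <- function(n, delta, alpha, mu, sigma) {
  if (any(n <= 0)) abort("`n` must be positive.")
  if (any(delta <= 0)) abort("`delta` must be positive.")
  if (any(alpha <= 0 | alpha >= 1)) abort("`alpha` must lie in (0, 1).")
  if (any(mu <= 0)) abort("`mu` must be positive.")
  if (any(sigma < 0)) abort("`sigma` must be non-negative.")
  z <- sqrt(n * log(delta)^2 / (2 * (1 / mu + sigma^2)))
  pmin(pmax(pnorm(z - qnorm(1 - alpha / 2)), 0), 1)
}

#' Power as a function of per-group sample size
#'
#' @inheritParams power_single
#' @param n_range Integer vector of per-group sample sizes (each >= 2).
#' @return A tibble of class `cp_power_curve` with columns `n`, `power`;
#'   power is non-decreasing in `n`.
#' @export
power_curve <- function(n_range, delta, alpha, mu, sigma) {
  if (length(n_range) == 0) abort("`n_range` must be non-empty.")
  if (any(n_range < 2)) abort("Sample sizes in `n_range` must be >= 2.")
  out <- tibble::tibble(
    n = as.integer(n_range),
    power = vapply(n_range, power_single,
      numeric(1),
      delta = delta, alpha = alpha, mu = mu, sigma = sigma
    )
  )
  structure(out,
    class = c("cp_power_curve", class(out)),
    delta = delta, alpha = alpha, mu = mu, sigma = sigma
  )
}

#' Smallest per-group sample size reaching a target power
#'
#' Increment search from `n = 2` upward using [power_single()].
#'
#' @inheritParams power_single
#' @param target_power Desired power in (0, 1).
#' @param n_max Search cap (default 1000).
#' @return Smallest integer `n >= 2` with power at least `target_power`.
#' @examples
#' sample_size(delta = 2, alpha = 0.01, mu = 41.72, sigma = 0.21,
#'             target_power = 0.8) # 4
#' @export
sample_size <- function(delta, alpha, mu, sigma, target_power, n_max = 1000) {
  if (target_power <= 0 || target_power >= 1) {
    abort("`target_power` must lie in (0, 1).")
  }
  for (n in 2:n_max) {
    if (power_single(n, delta, alpha, mu, sigma) >= target_power) {
      return(as.integer(n))
    }
  }
  abort(sprintf(
    "Target power %.3g not reached by n = %d (power there: %.4g).",
    target_power, n_max, power_single(n_max, delta, alpha, mu, sigma)
  ))
}

#' FDR-adjusted per-test significance level
#'
#' When m genes are tested jointly, a target false discovery rate `f` is
#' translated into a per-test significance level
#' \deqn{\alpha^* = \frac{r_1 f}{m_0 (1 - f)}}
#' where \eqn{r_1 = \pi_1 m} is the expected number of true positives among
#' the rejections and \eqn{m_0 = (1 - \pi_1) m} the number of true null
#' genes. Gene-wise power is then computed at `alpha_star` instead of a raw
#' alpha.
#'
#' @param f Desired FDR level in (0, 1).
#' @param m Number of genes tested (>= 1).
#' @param pi1 Expected fraction of truly differentially expressed genes in
#'   (0, 1).
#' @param r1,m0 Optional overrides for the expected true positives and true
#'   nulls; defaults `pi1 * m` and `(1 - pi1) * m`.
#' @return `alpha_star` (scalar) with attributes `r1` and `m0`. A
#'   configuration yielding `alpha_star >= 1` is an error.
#' @examples
#' fdr_alpha(f = 0.05, m = 10000, pi1 = 0.1)
#' @export
fdr_alpha <- function(f, m, pi1, r1 = pi1 * m, m0 = (1 - pi1) * m) {
  if (f <= 0 || f >= 1) abort("`f` must lie in (0, 1).")
  if (pi1 <= 0 || pi1 >= 1) abort("`pi1` must lie in (0, 1).")
  if (m < 1) abort("`m` must be >= 1.")
  alpha_star <- r1 * f / (m0 * (1 - f))
  if (alpha_star >= 1) {
    abort(sprintf(
      "Degenerate configuration: alpha_star = %.4g >= 1 (f = %g, pi1 = %g).",
      alpha_star, f, pi1
    ))
  }
  structure(alpha_star, r1 = r1, m0 = m0)
}

#' Gene-wise power and detectability
#'
#' For every gene of a (filtered) comparison, computes power at the
#' FDR-adjusted significance level: `n` is the smaller group size, the
#' effect size is the configured minimal fold change, `mu_g` is the gene's
#' mean raw count across the comparison's samples (its coverage), and
#' `sigma_g` is the tagwise BCOV. A gene is detectable when its power reaches
#' `power_detectable_cutoff`.
#'
#' @param cm A `cp_counts` restricted to the analyzed (filtered) genes.
#' @param sd A `cp_design`.
#' @param comparison Character vector of two group labels.
#' @param disp A [estimate_dispersion()] result covering the genes of `cm`.
#' @param config An [analysis_config()]; uses `fold_change`, `fdr_level`,
#'   `pi1` and `power_detectable_cutoff`.
#' @param mu Optional per-gene coverage override (named or positional
#'   vector); defaults to the mean raw count across the comparison samples.
#' @return A tibble of class `cp_detectability` with columns `gene_id`,
#'   `mean_coverage`, `log2cpm`, `bcov`, `power`, `detectable`; attributes
#'   `alpha_star`, `n`, `m`.
#' @export
genewise_power <- function(cm, sd, comparison, disp,
                           config = analysis_config(), mu = NULL) {
  cm <- as_count_matrix(cm)
  cc <- comparison_counts(cm, sd, comparison)
  genes <- rownames(cc$counts)
  missing <- setdiff(genes, names(disp$tagwise))
  if (length(missing) > 0) {
    abort(paste0(
      "Missing tagwise dispersion for gene(s): ", toString(head(missing, 5))
    ))
  }
  sizes <- table(cc$group)
  n <- min(sizes)
  if (n < 1) abort("Each compared group needs at least one sample.")
  m <- length(genes)
  alpha_star <- fdr_alpha(config$fdr_level, m, config$pi1)
  mu_g <- mu %||% rowMeans(cc$counts)
  if (!is.null(names(mu_g))) mu_g <- mu_g[genes]
  if (any(mu_g <= 0)) {
    abort("Every gene needs positive mean coverage; filter first.")
  }
  sigma_g <- disp$bcov_tagwise[genes]
  f <- tmm_factors(count_matrix(cc$counts))
  log2cpm <- rowMeans(cpm_matrix(count_matrix(cc$counts), f, log = TRUE))
  p <- power_single(
    n = n, delta = config$fold_change, alpha = as.numeric(alpha_star),
    mu = mu_g, sigma = sigma_g
  )
  out <- tibble::tibble(
    gene_id = genes,
    mean_coverage = unname(mu_g),
    log2cpm = unname(log2cpm),
    bcov = unname(sigma_g),
    power = unname(p),
    detectable = unname(p >= config$power_detectable_cutoff)
  )
  structure(out,
    class = c("cp_detectability", class(out)),
    alpha_star = as.numeric(alpha_star), n = as.integer(n), m = m,
    power_detectable_cutoff = config$power_detectable_cutoff
  )
}
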