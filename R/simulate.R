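#' Simulation configuration
#'
#' Parameters of the negative-binomial count generator. Defaults describe a
#' typical deeply sequenced two-group bulk RNA-seq comparison: average depth
#' 34 million reads per sample, biological coefficient of variation 0.24,
#' 10% of genes differentially expressed at fold change 2 (half up, half
#' down), and log-normal baseline abundances spanning roughly four orders of
#' magnitude.
#'
#' @param n_genes Number of genes.
#' @param groups Two group labels.
#' @param n_per_group Samples per group.
#' @param depth_millions Mean library size in millions of reads (ignored
#'   when `lib_sizes` is given).
#' @param depth_sdlog Log-normal sd of library sizes around the mean depth.
#' @param lib_sizes Optional explicit per-sample library sizes
#'   (length `2 * n_per_group`).
#' @param baseline_sdlog Log-normal sd of baseline relative abundances
#'   (normalized to sum to one per sample before scaling by library size).
#' @param bcov Biological coefficient of variation sigma: scalar or
#'   per-gene vector; counts are NB with variance
#'   `mean + sigma^2 * mean^2` (`sigma = 0` degenerates to Poisson).
#' @param de_fraction Fraction pi1 of truly differentially expressed genes.
#' @param fold_change Fold change Delta applied to DE genes in group B.
#' @param direction_balance Fraction of DE genes that are up-regulated.
#' @param effect_split How the fold change of a DE gene is laid out across
#'   the groups: `"onesided"` (default) leaves group A at the baseline and
#'   multiplies group B by `Delta^(+/-1)`; `"symmetric"` splits it in log
#'   space (`Delta^(-1/2)` in A, `Delta^(+1/2)` in B) so the gene's average
#'   coverage stays at the baseline - the layout used when validating the
#'   analytic power model at a fixed coverage.
#' @param seed Random seed.
#' @return A list of class `cp_sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       groups = c("A", "B"),
                       n_per_group = 4,
                       depth_millions = 34,
                       depth_sdlog = 0.1,
                       lib_sizes = NULL,
                       baseline_sdlog = 1.8,
                       bcov = 0.24,
                       de_fraction = 0.1,
                       fold_change = 2,
                       direction_balance = 0.5,
                       effect_split = c("onesided", "symmetric"),
                       seed = 101) {
  effect_split <- match.arg(effect_split)
  stopifnot(
    n_genes >= 1, length(groups) == 2, groups[1] != groups[2],
    n_per_group >= 1, de_fraction >= 0, de_fraction <= 1,
    fold_change > 0, direction_balance >= 0, direction_balance <= 1,
    all(bcov >= 0)
  )
  if (!is.null(lib_sizes) && length(lib_sizes) != 2 * n_per_group) {
    abort("`lib_sizes` must have length 2 * n_per_group.")
  }
  structure(
    list(
      n_genes = n_genes, groups = groups, n_per_group = n_per_group,
      depth_millions = depth_millions, depth_sdlog = depth_sdlog,
      lib_sizes = lib_sizes, baseline_sdlog = baseline_sdlog, bcov = bcov,
      de_fraction = de_fraction, fold_change = fold_change,
      direction_balance = direction_balance, effect_split = effect_split,
      seed = seed
    ),
    class = "cp_sim_config"
  )
}

# NB draw that degenerates to Poisson at sigma = 0.
rnb <- function(n, mu, sigma) {
  out <- numeric(n)
  pois <- sigma == 0
  if (length(sigma) == 1) pois <- rep(pois, n)
  if (length(mu) == 1) mu <- rep(mu, n)
  if (length(sigma) == 1) sigma <- rep(sigma, n)
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / sigma[!pois]^2)
  }
  out
}

#' Simulate a two-group NB count dataset with known truth
#'
#' Counts for gene g in sample s are negative binomial with mean
#' `lib_size(s) * q_g * Delta^{+/-1}` - the baseline relative abundance
#' `q_g` in group A, multiplied (up) or divided (down) by the fold change in
#' group B for DE genes - and dispersion `bcov^2`.
#'
#' @param config A [sim_config()].
#' @return A list of class `cp_sim` with elements `counts`
#'   ([count_matrix()]), `design` ([sample_design()]), and `truth`: a tibble
#'   with `gene_id`, `status` (`null` / `up` / `down`), `true_log2_fc`,
#'   `true_dispersion`.
#' @export
simulate_counts <- function(config = sim_config()) {
  set.seed(config$seed)
  ng <- config$n_genes
  n <- config$n_per_group
  q <- rlnorm(ng, meanlog = 0, sdlog = config$baseline_sdlog)
  q <- q / sum(q)
  lib <- config$lib_sizes %||% round(rlnorm(
    2 * n,
    meanlog = log(config$depth_millions * 1e6) - config$depth_sdlog^2 / 2,
    sdlog = config$depth_sdlog
  ))
  is_de <- runif(ng) < config$de_fraction
  up <- runif(ng) < config$direction_balance
  status <- ifelse(!is_de, "null", ifelse(up, "up", "down"))
  lfc <- ifelse(status == "null", 0,
    ifelse(status == "up", log2(config$fold_change), -log2(config$fold_change))
  )
  sigma <- if (length(config$bcov) == 1) rep(config$bcov, ng) else config$bcov
  group <- rep(config$groups, each = n)
  split <- config$effect_split %||% "onesided"
  counts <- matrix(0, ng, 2 * n)
  for (s in seq_len(2 * n)) {
    in_b <- group[s] == config$groups[2]
    mult <- if (split == "symmetric") {
      2^(lfc * (if (in_b) 0.5 else -0.5))
    } else if (in_b) {
      2^lfc
    } else {
      rep(1, ng)
    }
    counts[, s] <- rnb(ng, mu = lib[s] * q * mult, sigma = sigma)
  }
  gene_ids <- sprintf("g%05d", seq_len(ng))
  sample_ids <- sprintf("s%02d", seq_len(2 * n))
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(
    list(
      counts = count_matrix(counts),
      design = sample_design(
        tibble::tibble(sample_id = sample_ids, group = group)
      ),
      truth = tibble::tibble(
        gene_id = gene_ids, status = status,
        true_log2_fc = lfc, true_dispersion = sigma^2
      )
    ),
    class = "cp_sim"
  )
}

#' Empirical power and type-I error by Monte-Carlo simulation
#'
#' Simulates datasets from `config`, runs the chosen differential-expression
#' test, and reports the rejection rate at level `alpha` separately for the
#' truly-DE and truly-null strata, with binomial Monte-Carlo standard
#' errors. By default the test is run at the true simulated dispersions so
#' the comparison isolates the power model from dispersion-estimation noise;
#' set `dispersion = "estimated"` for the full pipeline behavior.
#'
#' @param config A [sim_config()].
#' @param test `"exact"` or `"glm_ql"`.
#' @param alpha Rejection level for the raw p-values.
#' @param n_reps Number of independent simulated datasets to pool.
#' @param dispersion `"true"` (default) or `"estimated"`.
#' @return A tibble with columns `stratum` (`de` / `null`), `n_genes`,
#'   `rejections`, `rate`, `se`.
#' @export
empirical_power <- function(config = sim_config(),
                            test = c("exact", "glm_ql"),
                            alpha = 0.01, n_reps = 1,
                            dispersion = c("true", "estimated")) {
  test <- match.arg(test)
  dispersion <- match.arg(dispersion)
  reject <- list(de = integer(0), null = integer(0))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1
    sim <- simulate_counts(cfg)
    disp <- if (dispersion == "true") {
      phi <- setNames(sim$truth$true_dispersion, sim$truth$gene_id)
      structure(
        list(
          common = stats::median(phi), tagwise = phi,
          bcov_common = sqrt(stats::median(phi)), bcov_tagwise = sqrt(phi),
          prior_df = Inf, comparison = config$groups,
          n_per_group = rep(config$n_per_group, 2)
        ),
        class = "cp_dispersion"
      )
    } else {
      estimate_dispersion(sim$counts, sim$design, config$groups)
    }
    de <- if (test == "exact") {
      exact_test(sim$counts, sim$design, config$groups, disp)
    } else {
      glm_ql_test(sim$counts, sim$design, config$groups, disp = disp)
    }
    hit <- de$p_value < alpha
    is_de <- sim$truth$status != "null"
    reject$de <- c(reject$de, hit[is_de])
    reject$null <- c(reject$null, hit[!is_de])
  }
  purrr::map_dfr(c("de", "null"), function(st) {
    x <- reject[[st]]
    n <- length(x)
    rate <- if (n > 0) mean(x) else NA_real_
    tibble::tibble(
      stratum = st, n_genes = n, rejections = sum(x),
      rate = rate,
      se = if (n > 0) sqrt(rate * (1 - rate) / n) else NA_real_
    )
  })
}

#' Simulated 32-sample multi-factor use-case dataset
#'
#' A synthetic dataset shaped like a crossed-design breast-cell study: two
#' cell lines x two oxygen levels x treatment status x mRNA fraction, two
#' replicates each (32 samples). Effects are planted hierarchically - the
#' cell-line contrast is the largest, then mRNA fraction, oxygen, and
#' treatment, with a small replicate (batch) effect - so exploratory
#' analyses recover the expected sample structure. The design's `group`
#' column is the four-factor condition label (2 samples per condition);
#' `cell_line`, `oxygen`, `treatment`, `fraction` and `replicate` are
#' carried as covariate columns.
#'
#' @param seed Random seed.
#' @param n_genes Number of genes (default 20000).
#' @param depth_millions Mean library size in millions (default 34).
#' @param bcov Biological coefficient of variation (default 0.24).
#' @return A list of class `cp_sim` with `counts`, `design`, and `truth`
#'   (per-gene log2 effect of each factor plus the dispersion).
#' @export
make_use_case_fixture <- function(seed = 101, n_genes = 20000,
                                  depth_millions = 34, bcov = 0.24) {
  set.seed(seed)
  meta <- expand.grid(
    replicate = c("r1", "r2"),
    fraction = c("total", "polysomal"),
    treatment = c("none", "PP242"),
    oxygen = c("normoxia", "hypoxia"),
    cell_line = c("MCF10A", "MDA-MB-231"),
    stringsAsFactors = FALSE
  )
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  meta$group <- paste(meta$cell_line, meta$oxygen, meta$treatment,
    meta$fraction,
    sep = "_"
  )
  # planted per-factor log2 effects: fraction of affected genes and effect sd
  plant <- list(
    cell_line = c(prop = 0.30, sd = 2.0),
    fraction = c(prop = 0.20, sd = 1.5),
    oxygen = c(prop = 0.15, sd = 1.0),
    treatment = c(prop = 0.10, sd = 0.75),
    replicate = c(prop = 1.00, sd = 0.05)
  )
  effects <- purrr::map(plant, function(p) {
    hit <- runif(n_genes) < p[["prop"]]
    ifelse(hit, rnorm(n_genes, 0, p[["sd"]]), 0)
  })
  q <- rlnorm(n_genes, 0, 1.8)
  q <- q / sum(q)
  lib <- round(rlnorm(nrow(meta), log(depth_millions * 1e6) - 0.005, 0.1))
  second_level <- c(
    cell_line = "MDA-MB-231", fraction = "polysomal",
    oxygen = "hypoxia", treatment = "PP242", replicate = "r2"
  )
  counts <- matrix(0, n_genes, nrow(meta))
  for (s in seq_len(nrow(meta))) {
    lfc <- rep(0, n_genes)
    for (f in names(second_level)) {
      if (meta[[f]][s] == second_level[[f]]) lfc <- lfc + effects[[f]]
    }
    counts[, s] <- rnb(n_genes, mu = lib[s] * q * 2^lfc, sigma = bcov)
  }
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  dimnames(counts) <- list(gene_ids, meta$sample_id)
  design <- sample_design(tibble::as_tibble(
    meta[, c("sample_id", "group", "cell_line", "oxygen", "treatment",
             "fraction", "replicate")]
  ))
  truth <- tibble::tibble(
    gene_id = gene_ids,
    lfc_cell_line = effects$cell_line,
    lfc_fraction = effects$fraction,
    lfc_oxygen = effects$oxygen,
    lfc_treatment = effects$treatment,
    lfc_replicate = effects$replicate,
    true_dispersion = bcov^2
  )
  structure(
    list(counts = count_matrix(counts), design = design, truth = truth),
    class = "cp_sim"
  )
}
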