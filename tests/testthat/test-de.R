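test_that("exact-test p-values equal exhaustive conditional enumeration", {
  phi <- 0.1
  cases <- list(
    c(5, 8, 20, 25),
    c(2, 3, 4, 1),
    c(0, 1, 12, 9),
    c(30, 28, 31, 27)
  )
  for (cnt in cases) {
    m <- rbind(
      gene1 = cnt,
      filler1 = rep(10, 4), filler2 = rep(10, 4), filler3 = rep(10, 4)
    )
    # equalize library sizes so pseudo-counts are the raw counts
    m <- rbind(m, pad = max(colSums(m)) + 50 - colSums(m))
    colnames(m) <- paste0("s", 1:4)
    sd_tbl <- sample_design(tibble::tibble(
      sample_id = colnames(m), group = c("ctrl", "ctrl", "trt", "trt")
    ))
    disp <- fixed_dispersion(rownames(m), phi)
    de <- exact_test(count_matrix(m), sd_tbl, c("ctrl", "trt"), disp,
      norm_factors = rep(1, 4)
    )
    expect_equal(
      de$p_value[de$gene_id == "gene1"],
      exact_p_oracle(cnt[1:2], cnt[3:4], phi),
      tolerance = 1e-10
    )
  }
})

test_that("identical group totals give p = 1 and label swap negates fold changes", {
  m <- rbind(
    gene1 = c(10, 12, 12, 10),
    gene2 = c(5, 50, 20, 9),
    filler = c(40, 40, 40, 40)
  )
  m <- rbind(m, pad = max(colSums(m)) - colSums(m) + 10)
  colnames(m) <- paste0("s", 1:4)
  sd_tbl <- sample_design(tibble::tibble(
    sample_id = colnames(m), group = c("ctrl", "ctrl", "trt", "trt")
  ))
  disp <- fixed_dispersion(rownames(m), 0.1)
  fwd <- exact_test(count_matrix(m), sd_tbl, c("ctrl", "trt"), disp,
    norm_factors = rep(1, 4)
  )
  expect_equal(fwd$p_value[fwd$gene_id == "gene1"], 1)
  rev <- exact_test(count_matrix(m), sd_tbl, c("trt", "ctrl"), disp,
    norm_factors = rep(1, 4)
  )
  expect_equal(fwd$log2_fc, -rev$log2_fc)
  expect_equal(fwd$p_value, rev$p_value)
})

test_that("GLM quasi-likelihood ranking agrees with the exact test on simple designs", {
  sim <- simulate_counts(sim_config(
    n_genes = 800, n_per_group = 4, de_fraction = 0.2,
    lib_sizes = rep(2e5, 8), baseline_sdlog = 1, bcov = 0.2, seed = 61
  ))
  kept <- filter_expressed(sim$counts, sim$design, c("A", "B"))
  cm <- count_matrix(sim$counts$counts[kept, ])
  disp <- estimate_dispersion(cm, sim$design, c("A", "B"))
  de_exact <- exact_test(cm, sim$design, c("A", "B"), disp)
  de_glm <- glm_ql_test(cm, sim$design, c("A", "B"), disp = disp)
  rho <- cor(de_exact$p_value, de_glm$p_value, method = "spearman")
  expect_gte(rho, 0.95)
  expect_gt(cor(de_exact$log2_fc, de_glm$log2_fc), 0.99)
})

test_that("a flat gene yields a null GLM coefficient and batch adjustment keeps type-I control", {
  # flat gene: identical counts everywhere
  set.seed(60)
  m <- rbind(
    flat = rep(20, 8),
    matrix(rpois(56, 60), 7, 8, dimnames = list(paste0("g", 1:7), NULL))
  )
  m <- rbind(m, pad = max(colSums(m)) - colSums(m) + 30) # equal library sizes
  colnames(m) <- paste0("s", 1:8)
  sd_tbl <- sample_design(tibble::tibble(
    sample_id = colnames(m), group = rep(c("ctrl", "trt"), each = 4)
  ))
  disp <- fixed_dispersion(rownames(m), 0.05)
  # the flat gene has zero residual variance; the quasi-dispersion squeeze
  # warns about offsetting it, which is exactly the degenerate case probed
  de <- suppressWarnings(glm_ql_test(count_matrix(m), sd_tbl, c("ctrl", "trt"),
    disp = disp, norm_factors = rep(1, 8)
  ))
  expect_lt(abs(de$log2_fc[de$gene_id == "flat"]), 1e-6)
  expect_gt(de$p_value[de$gene_id == "flat"], 0.99)

  # planted batch effect shifting both groups equally; replicate as covariate
  set.seed(62)
  n_genes <- 1000
  n <- 4
  mu <- exp(rnorm(n_genes, 4.5, 0.8))
  batch_lfc <- ifelse(runif(n_genes) < 0.4, rnorm(n_genes, 0, 0.7), 0)
  rep_lab <- rep(c("r1", "r1", "r2", "r2"), 2)
  grp <- rep(c("ctrl", "trt"), each = n)
  m2 <- vapply(seq_len(2 * n), function(s) {
    mult <- if (rep_lab[s] == "r2") 2^batch_lfc else rep(1, n_genes)
    rnbinom(n_genes, mu = mu * mult, size = 1 / 0.04)
  }, numeric(n_genes))
  dimnames(m2) <- list(sprintf("g%04d", 1:n_genes), sprintf("s%02d", 1:(2 * n)))
  sd2 <- sample_design(tibble::tibble(
    sample_id = colnames(m2), group = grp, replicate = rep_lab
  ))
  disp2 <- fixed_dispersion(rownames(m2), 0.04)
  de2 <- glm_ql_test(count_matrix(m2), sd2, c("ctrl", "trt"),
    covariates = "replicate", disp = disp2
  )
  # all genes are truly null for the group contrast
  rate <- mean(de2$p_value < 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / n_genes)
  expect_gt(rate, 0.05 - band - 0.01)
  expect_lt(rate, 0.05 + band + 0.01)
})

test_that("rank-deficient designs report the aliased columns", {
  toy <- toy_dataset()
  sd_conf <- sample_design(
    tibble::tibble(
      sample_id = paste0("s", 1:4),
      group = c("ctrl", "ctrl", "trt", "trt"),
      batch = c("x", "x", "y", "y") # perfectly confounded with group
    )
  )
  disp <- fixed_dispersion(toy$cm$gene_ids, 0.1)
  expect_error(
    glm_ql_test(toy$cm, sd_conf, c("ctrl", "trt"),
      covariates = "batch", disp = disp
    ),
    "aliased"
  )
})

test_that("Benjamini-Hochberg adjustment equals the hand-computed step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # hand-computed general case: p_(i) * n / i, cumulative minimum from the top
  p <- c(0.005, 0.011, 0.02, 0.04, 0.9)
  expect_equal(bh_adjust(p), c(0.025, 0.0275, 0.03333333, 0.05, 0.9),
    tolerance = 1e-6
  )
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.3)), "0, 1")
})

test_that("triage labels follow the FDR/power rules and partition the genes", {
  de <- tibble::tibble(
    gene_id = paste0("g", 1:3),
    log2_fc = c(1, 0.2, -0.1),
    mean_log2cpm = c(5, 6, 2),
    p_value = c(0.001, 0.2, 0.4),
    fdr = c(0.01, 0.2, 0.2)
  )
  det <- tibble::tibble(
    gene_id = paste0("g", 1:3),
    mean_coverage = c(50, 80, 3),
    log2cpm = c(5, 6, 2),
    bcov = c(0.2, 0.2, 0.4),
    power = c(0.5, 0.9, 0.3),
    detectable = c(FALSE, TRUE, FALSE)
  )
  tri <- triage(de, det, analysis_config())
  expect_equal(as.character(tri$label), c("DE", "NDE_DT", "NDE_NDT"))
  expect_equal(sum(attr(tri, "counts")), 3)

  # random tables always partition
  set.seed(63)
  n <- 500
  de_r <- tibble::tibble(
    gene_id = paste0("g", 1:n), log2_fc = rnorm(n),
    mean_log2cpm = rnorm(n, 5), p_value = runif(n), fdr = runif(n)
  )
  det_r <- tibble::tibble(
    gene_id = paste0("g", 1:n), mean_coverage = exp(rnorm(n, 3)),
    log2cpm = rnorm(n, 5), bcov = runif(n, 0.1, 0.6),
    power = runif(n), detectable = NA
  )
  tri_r <- triage(de_r, det_r, analysis_config())
  expect_equal(sum(attr(tri_r, "counts")), n)
  expect_equal(glance(tri_r)$n_total, n)

  expect_error(triage(de_r[1:10, ], det_r, analysis_config()), "same gene set")
})

test_that("signature construction matches brute-force rule evaluation", {
  # 6-gene toy spanning the rule combinations
  tab <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    fdr = c(0.005, 0.005, 0.5, 0.5, 0.02, 0.009),
    power = c(0.9, 0.2, 0.75, 0.3, 0.71, 0.69)
  )
  de <- tibble::tibble(
    gene_id = tab$gene_id, log2_fc = rnorm(6),
    mean_log2cpm = rnorm(6, 5), p_value = tab$fdr / 2, fdr = tab$fdr
  )
  det <- tibble::tibble(
    gene_id = tab$gene_id, mean_coverage = 1:6, log2cpm = 1:6,
    bcov = rep(0.2, 6), power = tab$power, detectable = tab$power >= 0.8
  )
  cfg <- analysis_config()
  sig <- build_signature(de, det, cfg)
  keep_oracle <- tab$fdr < 0.01 | (tab$fdr >= 0.01 & tab$power >= 0.7)
  expect_setequal(sig$gene_id, tab$gene_id[keep_oracle])
  expect_equal(
    as.character(sig$label[order(sig$gene_id)]),
    ifelse(tab$fdr[keep_oracle] < 0.01, "DE", "NDE_DT")[order(tab$gene_id[keep_oracle])]
  )
  # provenance carries the cutoffs
  expect_equal(attr(sig, "provenance")$signature_power_cutoff, 0.7)

  empty_cfg <- analysis_config(
    signature_fdr_cutoff = 1e-9, signature_power_cutoff = 1
  )
  det_weak <- det
  det_weak$power <- rep(0.1, 6)
  expect_warning(build_signature(de, det_weak, empty_cfg), "empty")
})

test_that("MA data mirrors the DE table and its significance flags", {
  toy <- toy_dataset()
  disp <- fixed_dispersion(toy$cm$gene_ids, 0.1)
  de <- exact_test(
    count_matrix(toy$cm$counts + 1), toy$sd, c("ctrl", "trt"), disp
  )
  ma <- ma_data(de, de_fdr_cutoff = 0.05)
  expect_equal(nrow(ma), nrow(de))
  expect_equal(ma$log2_fc, de$log2_fc)
  expect_equal(ma$mean_log2cpm, de$mean_log2cpm)
  expect_equal(ma$significant, de$fdr < 0.05)
  # hand check of (A, M) arithmetic on a 1-sample-per-group toy
  m <- rbind(g1 = c(40, 10), g2 = c(25, 25))
  colnames(m) <- c("s1", "s2")
  sd1 <- sample_design(tibble::tibble(
    sample_id = c("s1", "s2"), group = c("ctrl", "trt")
  ))
  de1 <- exact_test(count_matrix(m), sd1, c("ctrl", "trt"),
    fixed_dispersion(rownames(m), 0.1),
    norm_factors = c(1, 1)
  )
  a_hand <- rowMeans(log2((m + 0.5) / (colSums(m)[col(m)] + 1) * 1e6))
  expect_equal(de1$mean_log2cpm, unname(a_hand))
  expect_lt(de1$log2_fc[1], 0) # 40 -> 10 is down-regulation in trt
})
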