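test_that("null effect size degenerates to alpha/2 and inputs are validated", {
  for (alpha in c(0.01, 0.05, 0.2)) {
    expect_equal(
      power_single(n = 4, delta = 1, alpha = alpha, mu = 50, sigma = 0.2),
      alpha / 2
    )
  }
  expect_error(power_single(4, 2, 0.01, mu = -1, sigma = 0.2), "mu")
  expect_error(power_single(4, delta = 0, alpha = 0.01, mu = 10, sigma = 0.2), "delta")
  expect_error(power_single(4, 2, alpha = 1.2, mu = 10, sigma = 0.2), "alpha")
})

test_that("power round-trips through the quantile identity", {
  grid <- expand.grid(
    n = c(2, 4, 8), delta = c(1.5, 2, 4), alpha = c(0.01, 0.05),
    mu = c(5, 40, 400), sigma = c(0.1, 0.3, 0.6)
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- power_single(g$n, g$delta, g$alpha, g$mu, g$sigma)
    # away from the tails, where the quantile inversion is well-conditioned
    if (p > 1e-6 && p < 1 - 1e-6) {
      rhs <- g$n * log(g$delta)^2 / (2 * (1 / g$mu + g$sigma^2))
      expect_equal((qnorm(p) + qnorm(1 - g$alpha / 2))^2, rhs,
        tolerance = 1e-9
      )
    }
  }
})

test_that("power is monotone in its drivers", {
  base <- list(n = 4, delta = 2, alpha = 0.01, mu = 40, sigma = 0.2)
  p0 <- do.call(power_single, base)
  expect_gt(power_single(6, 2, 0.01, 40, 0.2), p0)
  expect_gt(power_single(4, 3, 0.01, 40, 0.2), p0)
  expect_gt(power_single(4, 2, 0.01, 80, 0.2), p0)
  expect_lt(power_single(4, 2, 0.01, 40, 0.4), p0)
  expect_lt(power_single(4, 2, 0.001, 40, 0.2), p0)
})

test_that("power curves are non-decreasing and approach one", {
  pc <- power_curve(2:30, delta = 2, alpha = 0.01, mu = 41.72, sigma = 0.21)
  expect_true(all(diff(pc$power) >= 0))
  expect_gt(tail(pc$power, 1), 0.999)
  expect_error(power_curve(integer(0), 2, 0.01, 40, 0.2), "non-empty")
  expect_error(power_curve(1:3, 2, 0.01, 40, 0.2), ">= 2")
})

test_that("sample-size search matches a brute-force scan and respects bounds", {
  # brute-force scan of the power function over n
  scan_n <- function(delta, alpha, mu, sigma, target) {
    powers <- vapply(2:1000, power_single,
      numeric(1),
      delta = delta, alpha = alpha, mu = mu, sigma = sigma
    )
    (2:1000)[which(powers >= target)[1]]
  }
  expect_equal(
    sample_size(2, 0.01, 38.18, 0.31, target_power = 0.8),
    scan_n(2, 0.01, 38.18, 0.31, 0.8)
  )
  # target below the n = 2 power returns the lower bound
  expect_equal(sample_size(8, 0.05, 100, 0.1, target_power = 0.5), 2L)
  expect_error(
    sample_size(1.001, 0.01, 5, 0.9, target_power = 0.99, n_max = 50),
    "not reached"
  )
})

test_that("FDR-adjusted significance follows r1 f / (m0 (1 - f))", {
  a <- fdr_alpha(f = 0.05, m = 10000, pi1 = 0.1)
  expect_equal(attr(a, "r1"), 1000)
  expect_equal(attr(a, "m0"), 9000)
  expect_equal(as.numeric(a), 1000 * 0.05 / (9000 * 0.95))
  expect_equal(as.numeric(a), 0.005847953, tolerance = 1e-6)
  # f -> 0 drives alpha_star to 0
  expect_lt(fdr_alpha(1e-8, 10000, 0.1), 1e-7)
  # f = 0.5 simplifies to r1 / m0
  expect_equal(as.numeric(fdr_alpha(0.5, 1000, 0.2)), 200 / 800)
  # algebraic envelope: f odds x pi1 odds, so for f < 0.5 alpha_star lies
  # between f pi1/(1-pi1) and 2 f pi1/(1-pi1)
  for (f in c(0.01, 0.1, 0.4)) {
    for (pi1 in c(0.05, 0.2, 0.5)) {
      a <- as.numeric(fdr_alpha(f, 5000, pi1))
      expect_gt(a, f * pi1 / (1 - pi1))
      expect_lt(a, 2 * f * pi1 / (1 - pi1))
    }
  }
  expect_error(fdr_alpha(0.9, 100, 0.99), "Degenerate")
})

test_that("gene-wise power composes the adjusted alpha with per-gene coverage and BCOV", {
  set.seed(51)
  n_genes <- 30
  n <- 3
  mu_g <- exp(runif(n_genes, 0, 6))
  m <- vapply(seq_len(2 * n), function(i) {
    rpois(n_genes, mu_g)
  }, numeric(n_genes)) + 1
  dimnames(m) <- list(sprintf("g%02d", 1:n_genes), sprintf("s%02d", 1:(2 * n)))
  sd_tbl <- sample_design(tibble::tibble(
    sample_id = colnames(m), group = rep(c("ctrl", "trt"), each = n)
  ))
  cm <- count_matrix(m)
  disp <- fixed_dispersion(rownames(m), phi = runif(n_genes, 0.01, 0.3))
  cfg <- analysis_config()
  det <- genewise_power(cm, sd_tbl, c("ctrl", "trt"), disp, cfg)

  alpha_star <- fdr_alpha(cfg$fdr_level, n_genes, cfg$pi1)
  # direct evaluation oracle of the composed formula
  expected <- power_single(
    n = n, delta = cfg$fold_change, alpha = as.numeric(alpha_star),
    mu = rowMeans(m), sigma = sqrt(disp$tagwise)
  )
  expect_equal(det$power, unname(expected))
  expect_equal(det$detectable, unname(expected >= 0.8))
  expect_equal(attr(det, "alpha_star"), as.numeric(alpha_star))

  # a gene matching the common coverage/BCOV reproduces single-gene power
  i <- 5
  expect_equal(
    det$power[i],
    unname(power_single(
      n, 2, as.numeric(alpha_star), rowMeans(m)[i], sqrt(disp$tagwise[i])
    ))
  )
})

test_that("gene-wise power is monotone on the coverage-BCOV plane and saturates", {
  toy <- toy_dataset()
  disp <- fixed_dispersion(toy$cm$gene_ids, phi = c(0.01, 0.36, 0.01))
  det <- genewise_power(
    count_matrix(toy$cm$counts + 1), toy$sd, c("ctrl", "trt"), disp,
    analysis_config()
  )
  # within (mu, sigma) ordering: high coverage + low BCOV dominates
  hi <- power_single(2, 2, 0.001, mu = 1000, sigma = 0.01)
  expect_gt(hi, 0.99)
  # fixed mu: power non-increasing in sigma; fixed sigma: non-decreasing in mu
  expect_gt(
    power_single(2, 2, 0.01, 100, 0.1),
    power_single(2, 2, 0.01, 100, 0.6)
  )
  expect_gt(
    power_single(2, 2, 0.01, 100, 0.1),
    power_single(2, 2, 0.01, 1, 0.1)
  )
  expect_true(all(det$detectable == (det$power >= 0.8)))
})
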