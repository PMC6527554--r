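# Independent brute-force oracles used to cross-check the package's
# edgeR-backed operations, plus small fixture builders.

# Trimmed mean of M-values, enumerated explicitly from its published
# definition: reference = sample whose upper-quartile relative abundance is
# closest to the mean upper quartile; 30% two-sided trim on M, 5% on A;
# inverse-asymptotic-variance weights; geometric-mean renormalization.
tmm_factors_oracle <- function(m) {
  lib <- colSums(m)
  f75 <- apply(m, 2, function(x) quantile(x / sum(x), p = 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    r <- m[, ref]
    nO <- lib[j]
    nR <- lib[ref]
    keep <- x > 0 & r > 0
    x <- x[keep]
    r <- r[keep]
    M <- log2((x / nO) / (r / nR))
    A <- 0.5 * log2((x / nO) * (r / nR))
    w <- (nO - x) / (nO * x) + (nR - r) / (nR * r)
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]
    A <- A[fin]
    w <- w[fin]
    if (max(abs(M)) < 1e-6) {
      return(1)
    }
    n <- length(M)
    loM <- floor(n * 0.3) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1
    hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  fac / exp(mean(log(fac)))
}

# Exhaustive conditional NB exact test for one gene with equal library
# sizes: the distribution of the group-A sum given the total is NB(size
# n1/phi) x NB(size n2/phi) renormalized over all splits; the two-sided
# p-value sums the probabilities of every split at most as likely as the
# observed one (minimum-likelihood rejection region).
exact_p_oracle <- function(counts_a, counts_b, phi) {
  n1 <- length(counts_a)
  n2 <- length(counts_b)
  s_obs <- sum(counts_a)
  total <- s_obs + sum(counts_b)
  splits <- 0:total
  pr <- dnbinom(splits, size = n1 / phi, mu = 1) *
    dnbinom(total - splits, size = n2 / phi, mu = 1)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[s_obs + 1] * (1 + 1e-12)])
}

# Plain Pearson correlation from its definition, for cross-checking.
pearson_oracle <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Mean silhouette width for a 2-cluster labelling over sample columns.
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(coords)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1)) |> mean()
}

# Deterministic small count matrix with a design: 3 genes x 4 samples,
# two groups of two.
toy_dataset <- function() {
  m <- matrix(
    c(
      5, 8, 20, 25,
      100, 110, 95, 105,
      0, 1, 3, 0
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4))
  )
  list(
    cm = count_matrix(m),
    sd = sample_design(tibble::tibble(
      sample_id = paste0("s", 1:4),
      group = c("ctrl", "ctrl", "trt", "trt")
    ))
  )
}

# A dispersion object with known values, bypassing estimation.
fixed_dispersion <- function(gene_ids, phi, comparison = c("ctrl", "trt")) {
  phi <- rep_len(phi, length(gene_ids))
  tagwise <- stats::setNames(phi, gene_ids)
  structure(
    list(
      common = stats::median(phi), tagwise = tagwise,
      bcov_common = sqrt(stats::median(phi)), bcov_tagwise = sqrt(tagwise),
      prior_df = Inf, comparison = comparison, n_per_group = c(2L, 2L)
    ),
    class = "cp_dispersion"
  )
}
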