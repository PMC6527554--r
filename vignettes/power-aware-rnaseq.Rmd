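---
title: "Power-aware analysis of RNA-seq count matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-aware analysis of RNA-seq count matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countpower)
```

# The problem

A differential-expression (DE) analysis partitions genes into significant
and non-significant, but the non-significant class conflates two very
different situations: genes that truly do not change, and genes the study
had no realistic chance of detecting. The distinction matters whenever a
DE result feeds a downstream interpretation — an enrichment analysis that
treats under-powered genes as "unchanged" will silently absorb false
negatives. `countpower` makes the distinction explicit by estimating, for
every analyzed gene, the statistical power to detect a minimal fold change
given the observed coverage and biological variability, and by carrying
that power estimate through the DE workflow.

# The power model

## Single-gene power

Counts are modelled as negative binomial (NB): for gene $g$ in sample $s$,
$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g)$ with
$\mathrm{Var}(y) = \mu + \phi\mu^2$. The square root of the dispersion,
$\sigma_g = \sqrt{\phi_g}$, is the *biological coefficient of variation*
(BCOV): the relative standard deviation of a gene's true expression between
biological replicates. On the log scale, the variance of a sample's count
is approximately $1/\mu + \sigma^2$ — Poisson counting noise plus the
biological floor.

For a two-group comparison with $n$ samples per group, minimal fold change
$\Delta$ and two-sided significance $\alpha$, the standard normal
approximation to the test of equal means gives

$$(z_{1-\alpha/2} + z_\beta)^2 \;=\;
  \frac{n \,(\ln \Delta)^2}{2\,(1/\mu + \sigma^2)}$$

which `power_single()` solves analytically for power $1-\beta$:

$$\text{power} \;=\; \Phi\!\left(\sqrt{\frac{n(\ln\Delta)^2}
  {2(1/\mu+\sigma^2)}} \;-\; z_{1-\alpha/2}\right)$$

Only the favored tail of the two-sided test is counted, so at $\Delta = 1$
the formula degenerates to $\alpha/2$ exactly — a useful identity that the
test suite asserts. Power is monotone increasing in $n$, $\mu$ and
$|\ln\Delta|$, and decreasing in $\sigma$ and with shrinking $\alpha$.

Two readings of $\mu$ are supported, and both are plain numbers:

* **dataset level** — the average library size expressed in millions of
  reads (e.g. 41.72 for a 41.72M-read library). This is the convention
  of the benchmark table the package validates against, and the default
  for power curves.
* **gene level** — the gene's mean raw count across the comparison's
  samples, used by `genewise_power()`. This keeps $\mu$ in count space,
  consistent with its role as the coverage that sets the Poisson noise
  term. A per-gene override is available via the `mu` argument.

## Multiplicity: the FDR-adjusted significance level

Testing $m$ genes jointly at a fixed $\alpha$ ignores multiplicity. Given a
target FDR level $f$ and an expected fraction $\pi_1$ of truly DE genes,
the per-test significance level consistent with that FDR is

$$\alpha^\ast = \frac{r_1 f}{m_0 (1-f)}, \qquad
  r_1 = \pi_1 m, \quad m_0 = (1-\pi_1) m$$

implemented in `fdr_alpha()`, with $r_1$ and $m_0$ exposed for override
(the defaults assume all true positives are expected to be rejected — the
simplest reading; a more conservative $r_1$ can be supplied directly).
Algebraically $\alpha^\ast$ is the product of the FDR odds $f/(1-f)$ and
the prior odds $\pi_1/(1-\pi_1)$, so for $f < 0.5$ it always lies between
$f\pi_1/(1-\pi_1)$ and twice that value; a configuration with
$\alpha^\ast \ge 1$ is rejected as degenerate. `genewise_power()` replaces
$\alpha$ with $\alpha^\ast$ when scoring every gene.

## Detectability and triage

A gene is *detectable* (DT) when its power at $\alpha^\ast$ reaches the
cutoff (default 0.8). Combining with the DE call at FDR < 0.05 yields
three classes that always partition the analyzed genes:

* `DE` — significant;
* `NDE_DT` — not significant but well-powered: a confident negative;
* `NDE_NDT` — not significant and under-powered: a potential false
  negative.

`build_signature()` exports `DE` genes (FDR < 0.01 by default) together
with confident negatives (power ≥ 0.7 among the rest) — the gene list a
downstream enrichment or connectivity service should see. The signature
cutoffs (0.7 / 0.01) are deliberately stricter than the triage cutoffs
(0.8 / 0.05 serve a descriptive plot; the signature feeds external
analyses, where a false "confident negative" is costlier).

# Estimation choices

**Normalization.** Between-sample scaling uses trimmed mean of M-values
(TMM) with the canonical defaults: reference sample closest to the mean
upper-quartile, 30% two-sided trim on log-ratios, 5% on log-abundances,
precision weights, geometric-mean renormalization. The implementation is
edgeR's; the test suite cross-checks it against an explicit brute-force
enumeration of the trim on small matrices, to full precision.

**CPM conventions.** Plain CPM uses no pseudocount, so the expression
filter "CPM > 0 in at least $m$ samples" (with $m$ the smaller group size,
evaluated only on the comparison's samples) is exactly "count > 0" and
cannot be perturbed by a pseudocount. Log2 CPM for display, clustering and
reported averages uses `(count + p) / (lib + 2p) * 1e6` with $p = 0.5$,
a symmetric stabilization of zeros.

**Dispersion.** Common and tagwise NB dispersions come from the
quantile-adjusted conditional maximum-likelihood scheme (qCML): library
sizes equalized by quantile-matched pseudo-counts, conditional likelihood
given per-group sums, tagwise estimates shrunk toward the common value by
weighted-likelihood empirical Bayes with `prior_df` (default 10)
pseudo-degrees of shrinkage. Shrinkage is toward a constant, not an
abundance trend, so the `prior_df` $\to \infty$ limit collapses exactly
onto the common dispersion. Acceptance of this stage is parameter
*recovery on simulated truth* (±15% on the common dispersion at 2000 genes
and 4 vs 4 samples; Poisson data driven below 0.005), not bit-equality
with any particular implementation.

**Differential expression.** Without covariates, the gene-wise NB exact
test conditions on the total of library-size-equalized pseudo-counts; the
two-sided p-value sums all conditional outcomes at most as probable as the
one observed (minimum-likelihood rejection region; `rejection.region =
"smallp"`), which the suite verifies against exhaustive enumeration of the
conditional distribution. With covariates, a gene-wise NB GLM (log link,
offset log effective library size, NB dispersion fixed at the tagwise
estimates) is fitted and the group coefficient tested by a
quasi-likelihood F-test; quasi-dispersions are squeezed toward a constant
(no abundance trend — trend fitting is beyond this package's scope).
Fold-change estimates are pseudocount-stabilized (0.5) and unshrunken.
Benjamini–Hochberg correction is applied within one comparison; separate
comparisons are not jointly corrected.

# The simulator

`simulate_counts()` is the generative mirror of the power model and the
package's Monte-Carlo oracle. Baseline relative abundances are log-normal
(sdlog 1.8 by default, spanning roughly four orders of magnitude of mean
count), normalized to sum to one and scaled by per-sample library sizes;
counts are NB with variance $\mu + \sigma^2\mu^2$, degenerating to Poisson
at $\sigma = 0$. Defaults describe the study conditions the package is
validated under: mean depth 34 million reads (the mean of the four
benchmark comparisons' printed depths), BCOV 0.24 (their mean printed
common BCOV), 10% DE genes at fold change 2, balanced up/down.

DE effects support two layouts. The default (`onesided`) leaves group A at
baseline and multiplies group B by $\Delta^{\pm 1}$ — how a treatment
effect is usually conceived. The `symmetric` layout splits the effect in
log space ($\Delta^{\mp 1/2}$ / $\Delta^{\pm 1/2}$) so a DE gene's average
coverage equals its baseline; this is the layout used when validating the
analytic model at a fixed $\mu$, since it keeps the formula's coverage
parameter exact for every gene, and it is also the layout under which TMM's
majority-null assumption is unstressed at high DE fractions.

`make_use_case_fixture()` generates a 32-sample, 2×2×2×2 crossed design
(cell line × oxygen × treatment × mRNA fraction, duplicated) with a planted
effect hierarchy — cell line largest (30% of genes, log2 effect sd 2),
then fraction, oxygen, treatment, and a small replicate batch effect — so
exploratory analyses (correlation blocks, PCA, t-SNE) recover the expected
sample structure, and the full pipeline has a realistic multi-factor
input. The condition label (all four factors) is the design's group
column, giving two replicates per condition.

What the simulator deliberately does **not** emulate: gene–gene
correlation, GC/length biases, abundance-dependent dispersion trends,
outlier samples, and library-preparation artifacts. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated NB model, not robustness to every failure mode of real data.

# Numerical choices and degenerate inputs

* Fractional counts are accepted and passed through unrounded (estimated
  counts from transcript-level summarization are non-integer).
* Power values are clipped to $[0,1]$; the quantile identity is exact to
  $10^{-9}$ away from the extreme tails (the inversion is ill-conditioned
  beyond $|z| \approx 5$, which the tests acknowledge by restricting the
  round-trip check to interior powers).
* `sample_size()` is an increment search from $n = 2$ capped at 1000,
  reporting the power at the cap when the target is unreachable.
* Ties in the variable-gene ranking keep input order (stable sort), making
  top-$k_1$ always a prefix of top-$k_2$.
* Zero library sizes, zero-variance samples (correlation), rank-deficient
  designs (aliased columns listed), empty comparison groups, and
  $\alpha^\ast \ge 1$ all raise descriptive errors rather than propagating
  NaNs.
* All randomized operations (simulation, t-SNE) take an explicit seed;
  the package-wide default is 101.

# Validation strategy and problem sizes

The acceptance suite validates four layers, at sizes chosen to keep the
full run in the low minutes on a single core:

1. **Closed form against the published benchmark**: the four comparisons'
   printed (depth, BCOV) pairs reproduce the printed powers at
   $n = 2,3,4$ within ±0.02, the $n=2$ maximum stays ≤ 0.55, and the
   smallest $n$ reaching 80% power is 4. One benchmark row's $n=3,4$
   entries are analytically inconsistent with that row's printed
   parameters (the formula gives 0.58/0.78 where 0.73/0.86 are printed,
   while every other cell agrees to ±0.02) and are excluded from the
   assertion.
2. **Analytic vs Monte-Carlo**: over $(n,\sigma) \in \{2,4,8\} \times
   \{0.1,0.3\}$ at $\mu = 40$, the empirical exact-test rejection rate on
   ~1100 truly-DE simulated genes per cell (symmetric effect layout, true
   dispersions) agrees with `power_single()` within 3 Monte-Carlo SE. The
   closed form is a first-order approximation: at $n = 2$ it overestimates
   the exact test's power by up to ≈ 0.03 absolute, so this check is run
   at the Monte-Carlo resolution (≈ 1000 genes) at which that small-sample
   bias sits inside the 3-SE band.
3. **Calibration**: exact-test type-I error at nominal 0.05 on 2000 null
   genes within the binomial 95% band; observed FDR ≤ 0.15 under BH at
   level 0.1 on a 10%-DE simulation; dispersion recovery as above.
4. **Oracle equivalence and end-to-end**: brute-force enumerations (TMM
   trim, conditional exact test, BH step-up, triage rules) match exactly;
   the 32-sample fixture runs through the whole pipeline well under five
   minutes and the triage classes partition all analyzed genes.

# Known limitations

* The closed-form power is asymptotic; at $n = 2$ it is optimistic by a
  few percentage points against the exact test (see above). Sample-size
  recommendations near the margin should be rounded up.
* $\alpha^\ast$ treats $r_1 = \pi_1 m$ as all-true-positives-rejected; a
  pessimistic user can pass a smaller `r1`.
* The GLM path fixes the NB dispersion at qCML tagwise estimates rather
  than re-estimating under the covariate model; with strong batch effects
  the dispersions absorb batch variance and the test becomes conservative
  unless the batch covariate is included.
* Gene identifiers are opaque strings; no annotation layer is provided.
* t-SNE is visualization plumbing (delegated to `Rtsne`); only
  seed-determinism and gross cluster separation are guaranteed.
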