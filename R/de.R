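#' Exact negative-binomial test for a two-group comparison
#'
#' Gene-wise conditional exact test of equal group means under the NB model
#' with the supplied tagwise dispersions. Library sizes are equalized by
#' quantile-matched pseudo-counts and the two-sided p-value sums the
#' probabilities of all outcomes at most as likely as the observed split of
#' the conditional total (minimum-likelihood rejection region). Log2 fold
#' changes (group B over group A) are computed from normalized group means
#' stabilized with a pseudocount of 0.5.
#'
#' @param cm A `cp_counts` restricted to the analyzed (filtered) genes.
#' @param sd A `cp_design`.
#' @param comparison Character vector `c(A, B)`; fold changes are B over A.
#' @param disp A [estimate_dispersion()] result covering the genes of `cm`.
#' @param norm_factors Optional per-sample normalization factors for the
#'   comparison's samples (TMM computed when `NULL`).
#' @return A tibble of class `cp_de` with columns `gene_id`, `log2_fc`,
#'   `mean_log2cpm`, `p_value`, `fdr` (Benjamini-Hochberg).
#' @export
exact_test <- function(cm, sd, comparison, disp, norm_factors = NULL) {
  cm <- as_count_matrix(cm)
  if (length(comparison) != 2) {
    abort("The exact test compares exactly two groups; use glm_ql_test() for designs with covariates or more groups.")
  }
  cc <- comparison_counts(cm, sd, comparison)
  genes <- rownames(cc$counts)
  missing <- setdiff(genes, names(disp$tagwise))
  if (length(missing) > 0) {
    abort(paste0("Missing dispersion for gene(s): ", toString(head(missing, 5))))
  }
  d <- edgeR::DGEList(counts = cc$counts, group = cc$group)
  if (is.null(norm_factors)) {
    d <- edgeR::calcNormFactors(d, method = "TMM")
  } else {
    d$samples$norm.factors <- norm_factors
  }
  et <- edgeR::exactTest(d,
    pair = comparison, dispersion = unname(disp$tagwise[genes]),
    rejection.region = "smallp", prior.count = 0.5
  )
  log2cpm <- cpm_matrix(count_matrix(cc$counts), d$samples$norm.factors,
    log = TRUE
  )
  p <- et$table$PValue
  out <- tibble::tibble(
    gene_id = genes,
    log2_fc = et$table$logFC,
    mean_log2cpm = unname(rowMeans(log2cpm)),
    p_value = p,
    fdr = bh_adjust(p)
  )
  structure(out,
    class = c("cp_de", class(out)),
    comparison = comparison, method = "exact"
  )
}

#' Quasi-likelihood NB GLM test with covariates
#'
#' Fits a gene-wise negative-binomial generalized linear model (log link,
#' offset log effective library size, NB dispersion fixed at the tagwise
#' estimates) for the comparison plus any covariate columns of the design,
#' and tests the group coefficient with a quasi-likelihood F-test. The
#' quasi-dispersions are estimated from residual deviances and squeezed
#' toward a constant (no abundance trend) by empirical Bayes.
#'
#' @inheritParams exact_test
#' @param covariates Character vector of covariate column names in `sd`
#'   (e.g. `"replicate"` to adjust for batch); `NULL` for none.
#' @return A tibble of class `cp_de` (same columns as [exact_test()]).
#' @export
glm_ql_test <- function(cm, sd, comparison, covariates = NULL, disp,
                        norm_factors = NULL) {
  cm <- as_count_matrix(cm)
  cc <- comparison_counts(cm, sd, comparison)
  genes <- rownames(cc$counts)
  missing <- setdiff(genes, names(disp$tagwise))
  if (length(missing) > 0) {
    abort(paste0("Missing dispersion for gene(s): ", toString(head(missing, 5))))
  }
  meta <- sd[match(cc$samples, sd$sample_id), , drop = FALSE]
  df <- data.frame(group = cc$group)
  for (cv in covariates) {
    if (!cv %in% names(meta)) {
      abort(paste0("Covariate column '", cv, "' not found in the design."))
    }
    df[[cv]] <- factor(meta[[cv]])
  }
  fml <- stats::as.formula(paste(
    "~", paste(c(covariates, "group"), collapse = " + ")
  ))
  design <- stats::model.matrix(fml, data = df)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    abort(paste0(
      "Design matrix is rank-deficient; aliased column(s): ",
      toString(aliased), "."
    ))
  }
  if (nrow(design) - ncol(design) < 1) {
    abort("No residual degrees of freedom left for the quasi-likelihood test.")
  }
  d <- edgeR::DGEList(counts = cc$counts, group = cc$group)
  if (is.null(norm_factors)) {
    d <- edgeR::calcNormFactors(d, method = "TMM")
  } else {
    d$samples$norm.factors <- norm_factors
  }
  fit <- edgeR::glmQLFit(d, design,
    dispersion = unname(disp$tagwise[genes]),
    abundance.trend = FALSE, robust = FALSE, legacy = TRUE
  )
  coef_name <- paste0("group", comparison[2])
  qlf <- edgeR::glmQLFTest(fit, coef = coef_name)
  log2cpm <- cpm_matrix(count_matrix(cc$counts), d$samples$norm.factors,
    log = TRUE
  )
  p <- qlf$table$PValue
  out <- tibble::tibble(
    gene_id = genes,
    log2_fc = qlf$table$logFC,
    mean_log2cpm = unname(rowMeans(log2cpm)),
    p_value = p,
    fdr = bh_adjust(p)
  )
  structure(out,
    class = c("cp_de", class(out)),
    comparison = comparison, method = "glm_ql", covariates = covariates
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted values, clipped at 1 and monotone
#' in the input p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Triage genes by differential expression and detectability
#'
#' Partitions the analyzed genes into three classes: `DE` (FDR below the
#' cutoff), `NDE_DT` (not differentially expressed but with power at or
#' above the detectability cutoff - a confident negative), and `NDE_NDT`
#' (neither - a potential false negative, under-powered at the current
#' sample size or expression level).
#'
#' @param de A [exact_test()] / [glm_ql_test()] result.
#' @param det A [genewise_power()] result over the same genes.
#' @param config An [analysis_config()]; uses `de_fdr_cutoff` and
#'   `power_detectable_cutoff`.
#' @return A tibble of class `cp_triage` with columns `gene_id`, `log2_fc`,
#'   `fdr`, `power`, `label`; the per-class counts are in the `counts`
#'   attribute (see [glance()]).
#' @export
triage <- function(de, det, config = analysis_config()) {
  if (!setequal(de$gene_id, det$gene_id)) {
    abort("`de` and `det` must cover the same gene set.")
  }
  tab <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(de), "gene_id", "log2_fc", "fdr"),
    dplyr::select(tibble::as_tibble(det), "gene_id", "power"),
    by = "gene_id"
  )
  lab <- dplyr::case_when(
    tab$fdr < config$de_fdr_cutoff ~ "DE",
    tab$power >= config$power_detectable_cutoff ~ "NDE_DT",
    TRUE ~ "NDE_NDT"
  )
  tab$label <- factor(lab, levels = c("DE", "NDE_DT", "NDE_NDT"))
  counts <- table(tab$label)
  structure(tab,
    class = c("cp_triage", class(tab)),
    counts = counts,
    de_fdr_cutoff = config$de_fdr_cutoff,
    power_detectable_cutoff = config$power_detectable_cutoff
  )
}

#' Build a differential-expression signature with confident negatives
#'
#' Exports the gene list a downstream enrichment or connectivity analysis
#' should see: differentially expressed genes (FDR below
#' `signature_fdr_cutoff`) together with confident negatives - genes that are
#' not DE at that cutoff but whose power reaches `signature_power_cutoff`,
#' i.e. genes the study was well-powered to detect and that still showed no
#' signal.
#'
#' @inheritParams triage
#' @param config An [analysis_config()]; uses `signature_fdr_cutoff` and
#'   `signature_power_cutoff`.
#' @return A tibble of class `cp_signature` with columns `gene_id`,
#'   `log2_fc`, `p_value`, `fdr`, `power`, `label` (`DE` or `NDE_DT`);
#'   provenance (comparison, cutoffs, covariates) in attributes. Warns when
#'   empty.
#' @export
build_signature <- function(de, det, config = analysis_config()) {
  if (!setequal(de$gene_id, det$gene_id)) {
    abort("`de` and `det` must cover the same gene set.")
  }
  tab <- dplyr::inner_join(
    dplyr::select(
      tibble::as_tibble(de), "gene_id", "log2_fc", "p_value", "fdr"
    ),
    dplyr::select(tibble::as_tibble(det), "gene_id", "power"),
    by = "gene_id"
  )
  is_de <- tab$fdr < config$signature_fdr_cutoff
  is_neg <- !is_de & tab$power >= config$signature_power_cutoff
  out <- tab[is_de | is_neg, , drop = FALSE]
  out$label <- factor(ifelse(out$fdr < config$signature_fdr_cutoff,
    "DE", "NDE_DT"
  ), levels = c("DE", "NDE_DT"))
  if (nrow(out) == 0) {
    warn("Signature is empty at the configured cutoffs.")
  }
  structure(out,
    class = c("cp_signature", class(out)),
    provenance = list(
      comparison = attr(de, "comparison"),
      method = attr(de, "method"),
      covariates = attr(de, "covariates"),
      signature_fdr_cutoff = config$signature_fdr_cutoff,
      signature_power_cutoff = config$signature_power_cutoff
    )
  )
}

#' MA-plot data
#'
#' Per-gene average log expression (A) and log fold change (M) with a
#' significance flag at the configured DE FDR cutoff.
#'
#' @inheritParams triage
#' @param de_fdr_cutoff FDR cutoff for the significance flag.
#' @return Tibble with columns `gene_id`, `mean_log2cpm`, `log2_fc`,
#'   `significant`.
#' @export
ma_data <- function(de, de_fdr_cutoff = 0.05) {
  tibble::tibble(
    gene_id = de$gene_id,
    mean_log2cpm = de$mean_log2cpm,
    log2_fc = de$log2_fc,
    significant = de$fdr < de_fdr_cutoff
  )
}
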