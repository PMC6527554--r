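#' Tidy a dispersion estimate
#'
#' @param x A `cp_dispersion` object.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `dispersion`, `bcov`.
#' @export
tidy.cp_dispersion <- function(x, ...) {
  tibble::tibble(
    gene_id = names(x$tagwise),
    dispersion = unname(x$tagwise),
    bcov = unname(x$bcov_tagwise)
  )
}

#' One-row summary of a dispersion estimate
#'
#' @param x A `cp_dispersion` object.
#' @param ... Unused.
#' @return A one-row tibble with the common dispersion and BCOV, the prior
#'   df, and the gene count.
#' @export
glance.cp_dispersion <- function(x, ...) {
  tibble::tibble(
    common_dispersion = x$common,
    bcov_common = x$bcov_common,
    prior_df = x$prior_df,
    n_genes = length(x$tagwise)
  )
}

#' Tidy an embedding
#'
#' @param x A `cp_embedding` object.
#' @param ... Unused.
#' @return A tibble with `sample_id` and one `dim<i>` column per component.
#' @export
tidy.cp_embedding <- function(x, ...) {
  co <- x$coordinates
  colnames(co) <- paste0("dim", seq_len(ncol(co)))
  out <- tibble::as_tibble(co)
  tibble::add_column(out, sample_id = rownames(x$coordinates), .before = 1)
}

#' One-row summary of an embedding
#'
#' @param x A `cp_embedding` object.
#' @param ... Unused.
#' @return A one-row tibble: method, dimensions, total explained variance
#'   (PCA only), seed (t-SNE only).
#' @export
glance.cp_embedding <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_samples = nrow(x$coordinates),
    k = ncol(x$coordinates),
    explained_variance = if (is.null(x$explained_variance)) {
      NA_real_
    } else {
      sum(x$explained_variance)
    },
    seed = x$seed %||% NA_real_
  )
}

#' One-row summary of a differential-expression result
#'
#' @param x A `cp_de` tibble.
#' @param ... Unused.
#' @return A one-row tibble: method, gene count, genes at FDR < 0.05.
#' @export
glance.cp_de <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    comparison = paste(attr(x, "comparison"), collapse = " vs "),
    n_genes = nrow(x),
    n_fdr_05 = sum(x$fdr < 0.05)
  )
}

#' Per-class counts of a triage result
#'
#' @param x A `cp_triage` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the DE / NDE_DT / NDE_NDT counts and the
#'   total, which always equals the number of analyzed genes.
#' @export
glance.cp_triage <- function(x, ...) {
  cnt <- attr(x, "counts")
  tibble::tibble(
    n_de = as.integer(cnt[["DE"]]),
    n_nde_dt = as.integer(cnt[["NDE_DT"]]),
    n_nde_ndt = as.integer(cnt[["NDE_NDT"]]),
    n_total = nrow(x)
  )
}

#' One-row summary of a detectability table
#'
#' @param x A `cp_detectability` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the per-test adjusted significance level,
#'   sample size used, and the detectable-gene count.
#' @export
glance.cp_detectability <- function(x, ...) {
  tibble::tibble(
    alpha_star = attr(x, "alpha_star"),
    n_per_group = attr(x, "n"),
    n_genes = nrow(x),
    n_detectable = sum(x$detectable)
  )
}
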