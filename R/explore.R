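#' Sample-sample Pearson correlation matrix
#'
#' @param x Numeric gene x sample matrix (typically log2 CPM).
#' @return Symmetric sample x sample correlation matrix with unit diagonal.
#'   A sample with zero variance across genes is an error.
#' @export
correlation_matrix <- function(x) {
  if (ncol(x) < 2) abort("Need at least two samples.")
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    abort(paste0(
      "Zero-variance sample(s), correlation undefined: ",
      toString(colnames(x)[v == 0] %||% which(v == 0)), "."
    ))
  }
  cor(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the columns of `x` (samples) under either a
#' correlation-based distance (1 - Pearson) or Euclidean distance, with
#' average or complete linkage.
#'
#' @param x Numeric gene x sample matrix.
#' @param distance `"one_minus_correlation"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An [stats::hclust] tree over the samples.
#' @export
hierarchical_cluster <- function(x,
                                 distance = c("one_minus_correlation", "euclidean"),
                                 linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (ncol(x) < 2) abort("Need at least two items to cluster.")
  d <- switch(distance,
    one_minus_correlation = stats::as.dist(1 - correlation_matrix(x)),
    euclidean = dist(t(x))
  )
  if (any(!is.finite(d))) abort("Non-finite distances; check the input matrix.")
  hclust(d, method = linkage)
}

#' PCA embedding of samples
#'
#' Principal components of the gene-centered expression matrix: each gene
#' (row) is shifted to mean zero, then samples are projected onto the top
#' `k` components.
#'
#' @param x Numeric gene x sample matrix.
#' @param k Number of components, `k <= min(samples - 1, genes)`.
#' @return A list of class `cp_embedding` with `coordinates` (sample x k),
#'   `method = "pca"`, and `explained_variance` (fraction per component,
#'   non-increasing).
#' @export
pca_embedding <- function(x, k = 3) {
  k_max <- min(ncol(x) - 1, nrow(x))
  if (k > k_max) {
    abort(paste0("k must be <= min(samples - 1, genes) = ", k_max, "."))
  }
  pc <- prcomp(t(center_rows(x)), center = FALSE, scale. = FALSE)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rownames(coords) <- colnames(x)
  structure(
    list(
      coordinates = coords,
      method = "pca",
      explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
      seed = NULL
    ),
    class = "cp_embedding"
  )
}

#' t-SNE embedding of samples
#'
#' Seeded t-distributed stochastic neighbor embedding of the samples
#' (columns). Identical seeds give identical coordinates.
#'
#' @param x Numeric gene x sample matrix.
#' @param k Output dimension (default 2).
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < (samples - 1) / 3`. Defaults to
#'   `max(1, floor((samples - 1) / 4))`.
#' @param seed Random seed.
#' @return A list of class `cp_embedding` with `coordinates` (sample x k),
#'   `method = "tsne"` and the `seed` used.
#' @export
tsne_embedding <- function(x, k = 2, perplexity = NULL, seed = 101) {
  n <- ncol(x)
  max_perp <- (n - 1) / 3
  perplexity <- perplexity %||% max(1, floor((n - 1) / 4))
  if (perplexity >= max_perp) {
    abort(sprintf(
      "perplexity must be < (samples - 1)/3 = %.2f for %d samples (admissible range: (0, %.2f)).",
      max_perp, n, max_perp
    ))
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(t(x),
    dims = k, perplexity = perplexity,
    check_duplicates = FALSE, pca = TRUE,
    pca_center = TRUE, pca_scale = FALSE
  )
  coords <- fit$Y
  rownames(coords) <- colnames(x)
  colnames(coords) <- paste0("dim", seq_len(k))
  structure(
    list(coordinates = coords, method = "tsne", explained_variance = NULL,
         seed = seed),
    class = "cp_embedding"
  )
}

#' @export
print.cp_embedding <- function(x, ...) {
  cat("<cp_embedding> method ", x$method, "; ", nrow(x$coordinates),
    " samples x ", ncol(x$coordinates), " dims\n",
    sep = ""
  )
  if (!is.null(x$explained_variance)) {
    cat(
      "explained variance:",
      toString(sprintf("%.1f%%", 100 * x$explained_variance)), "\n"
    )
  }
  invisible(x)
}
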