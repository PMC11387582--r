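#' Z-score protein profiles
#'
#' Centers each protein at mean zero and unit spread across samples.
#' The population standard deviation (divisor `n`) is used, so a
#' two-sample protein scales exactly to `{-1, +1}`; this is the convention
#' fixed for the clustering inputs and documented here because the sample-
#' sd alternative gives `{-0.707, +0.707}`. Constant proteins are dropped
#' with a warning.
#'
#' @param mat Wide tibble or matrix of log2 intensities (complete rows).
#' @return Z-scored wide tibble.
#' @export
zscore_proteins <- function(mat) {
  m <- as_protein_matrix(mat)
  if (ncol(m) < 2) stop("need >= 2 observations per protein")
  ctr <- rowMeans(m)
  x <- m - ctr
  pop_sd <- sqrt(rowMeans(x^2))
  drop <- pop_sd <= 0 | !is.finite(pop_sd)
  if (any(drop)) {
    warning(sum(drop), " constant protein(s) dropped before z-scoring")
  }
  as_protein_tbl(x[!drop, , drop = FALSE] / pop_sd[!drop])
}

#' Ward-D2 clustering of proteins with a two-cluster up/down cut
#'
#' Computes Euclidean distances between z-scored protein profiles,
#' agglomerates with Ward-D2 linkage (squared distances inside the Ward
#' criterion, final heights on the original scale), and cuts the tree into
#' two clusters — the structure used to split treatment-responsive
#' proteins into an "up" and a "down" group. The cluster with the higher
#' mean `direction_stat` (typically the mean paired T302 - T0 difference)
#' is labelled `"up"`.
#'
#' @param mat Wide tibble or matrix of the significant proteins' profiles
#'   (complete rows).
#' @param direction_stat Named numeric vector (names = protein IDs) used
#'   to orient the two clusters; default: row means of `mat`.
#' @param scale Z-score proteins before clustering (default TRUE).
#' @return An object of class `protein_clusters`: `assignment` tibble
#'   (`protein_id`, `cluster` in `{1,2}`, `label` in `{"up","down"}`),
#'   the `hclust` object, and the direction means per cluster.
#' @export
ward_cluster_cut2 <- function(mat, direction_stat = NULL, scale = TRUE) {
  m <- as_protein_matrix(mat)
  if (nrow(m) < 2) stop("need >= 2 proteins to cluster")
  z <- if (scale) as_protein_matrix(zscore_proteins(m)) else m
  if (nrow(z) < 2) stop("fewer than 2 proteins left after dropping constants")
  d <- stats::dist(z)
  if (all(d == 0)) stop("all protein profiles identical; nothing to cluster")
  hc <- stats::hclust(d, method = "ward.D2")
  k2 <- stats::cutree(hc, k = 2)

  if (is.null(direction_stat)) {
    direction_stat <- rowMeans(m)
  }
  ds <- direction_stat[rownames(z)]
  means <- tapply(ds, k2, mean, na.rm = TRUE)
  up_cluster <- as.integer(names(means)[which.max(means)])
  assignment <- tibble::tibble(
    protein_id = rownames(z),
    cluster = unname(k2),
    label = ifelse(k2 == up_cluster, "up", "down")
  )
  structure(
    list(assignment = assignment, hclust = hc,
         cluster_direction_means = means, up_cluster = up_cluster),
    class = "protein_clusters"
  )
}

#' @export
print.protein_clusters <- function(x, ...) {
  tab <- table(x$assignment$label)
  cat("<protein_clusters> Ward-D2, k = 2: ",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @param x A `protein_clusters` object.
#' @param ... Unused.
#' @rdname ward_cluster_cut2
#' @export
tidy.protein_clusters <- function(x, ...) x$assignment

#' Principal component analysis of sample profiles
#'
#' PCA of samples over protein features (proteins centered; optionally
#' z-scored). Any pair of dimensions can be inspected — subtype structure
#' in CSF proteomes is not always in the first two components.
#'
#' @param mat Wide tibble or matrix of log2 intensities (complete rows;
#'   impute first if needed).
#' @param dims Integer vector of components to keep (default `1:3`).
#' @param scale Scale proteins to unit variance before PCA (default
#'   FALSE: centered-only).
#' @return An object of class `sma_pca`: `scores` tibble (`sample_id` +
#'   `PCk` columns), `explained` (variance shares, non-increasing), and
#'   the `prcomp` fit.
#' @export
pca_scores <- function(mat, dims = 1:3, scale = FALSE) {
  m <- as_protein_matrix(mat)
  if (anyNA(m)) stop("PCA input must be complete; impute first")
  if (ncol(m) < 2) stop("need >= 2 samples")
  fit <- stats::prcomp(t(m), center = TRUE, scale. = scale)
  rank <- ncol(fit$x)
  if (max(dims) > rank) stop("requested dimension exceeds rank ", rank)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x[, dims, drop = FALSE]) |>
    dplyr::mutate(sample_id = colnames(m), .before = 1)
  structure(
    list(scores = scores, explained = ev[dims], dims = dims, prcomp = fit),
    class = "sma_pca"
  )
}

#' @param x An `sma_pca` object.
#' @param ... Unused.
#' @rdname pca_scores
#' @export
tidy.sma_pca <- function(x, ...) x$scores
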