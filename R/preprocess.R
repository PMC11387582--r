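#' Log2-transform and median-center an intensity table
#'
#' Standard label-free quantification preprocessing: zeros (proteins not
#' quantified in a sample) become missing, values are log2-transformed, and
#' each sample is centered on its median over observed values, removing
#' per-sample additive shifts on the log scale exactly.
#'
#' @param raw Wide tibble (`protein_id` + sample columns) or matrix of
#'   non-negative raw intensities; `0` = not quantified. With
#'   `log2_input = TRUE` the values are taken as already log2-scale (missing
#'   as `NA`) and only median-centering is applied, making the operation
#'   idempotent.
#' @param log2_input Logical; skip the log2 transform.
#' @return Wide tibble of centered log2 intensities with `NA` for missing;
#'   every sample's median over observed values is 0 (to 1e-9).
#' @examples
#' raw <- tibble::tibble(protein_id = c("a", "b"),
#'                       s1 = c(4, 16), s2 = c(8, 0))
#' log2_median_center(raw)
#' @export
log2_median_center <- function(raw, log2_input = FALSE) {
  m <- as_protein_matrix(raw)
  if (log2_input) {
    x <- m
  } else {
    if (any(m < 0, na.rm = TRUE)) stop("raw intensities must be >= 0")
    x <- m
    x[!is.na(x) & x == 0] <- NA
    x <- log2(x)
  }
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2)) {
    stop("sample(s) with fewer than 2 observed values: ",
         paste(colnames(x)[n_obs < 2], collapse = ", "))
  }
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  as_protein_tbl(sweep(x, 2, med, `-`))
}

#' Filter proteins by per-group completeness
#'
#' Keeps proteins observed (non-missing) in at least `min_fraction` of the
#' samples of at least one group, the usual rescue rule that preserves
#' proteins quantified consistently in a single subtype. Protein order is
#' preserved.
#'
#' @param mat Wide tibble or matrix of log2 intensities with `NA` missing.
#' @param metadata Data frame with `sample_id` and the grouping column.
#' @param group Name of the metadata column defining groups (default
#'   `"subtype"`).
#' @param min_fraction Required observed fraction, in `(0, 1]`. Default 0.7.
#' @return Filtered wide tibble.
#' @export
filter_by_completeness <- function(mat, metadata, group = "subtype",
                                   min_fraction = 0.7) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]")
  }
  m <- as_protein_matrix(mat)
  stopifnot(group %in% names(metadata))
  md <- metadata[metadata$sample_id %in% colnames(m), ]
  groups <- split(md$sample_id, md[[group]])
  ok <- Reduce(`|`, lapply(groups, function(ids) {
    rowMeans(!is.na(m[, ids, drop = FALSE])) >= min_fraction
  }))
  if (!any(ok)) warning("completeness filter removed every protein")
  as_protein_tbl(m[ok, , drop = FALSE])
}

#' Impute missing values with the per-protein minimum
#'
#' Replaces each protein's missing values by its minimum observed value, a
#' conservative left-censored imputation for model-fitting stages (the
#' differential tests use pairwise-complete observations instead and never
#' see imputed values).
#'
#' @param mat Wide tibble or matrix with `NA` missing.
#' @return Complete wide tibble. Proteins with no observed value error.
#' @export
impute_min <- function(mat) {
  m <- as_protein_matrix(mat)
  if (any(rowSums(!is.na(m)) == 0)) stop("protein(s) with no observed value")
  mins <- apply(m, 1, min, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx) > 0) m[idx] <- mins[idx[, 1]]
  as_protein_tbl(m)
}

#' Fit a per-protein standardization on a training subset only
#'
#' The classifier contract is leakage-aware: location and scale are
#' estimated on the training samples alone and then applied unchanged to
#' held-out samples. `fit_scaler()` captures per-protein mean and sd
#' (sample sd) from the training matrix; `apply_scaler()` standardizes any
#' matrix over the same proteins. Zero-variance proteins are dropped with a
#' warning.
#'
#' @param train Wide tibble or matrix of complete (imputed) training data.
#' @return `fit_scaler()`: an object of class `protein_scaler`.
#' @examples
#' tr <- tibble::tibble(protein_id = c("a", "b"),
#'                      s1 = c(1, 10), s2 = c(3, 30))
#' sc <- fit_scaler(tr)
#' apply_scaler(sc, tr)  # per-protein mean 0, sd 1
#' @export
fit_scaler <- function(train) {
  m <- as_protein_matrix(train)
  if (anyNA(m)) stop("training matrix must be complete (impute first)")
  ctr <- rowMeans(m)
  scl <- apply(m, 1, stats::sd)
  drop <- scl <= 0 | !is.finite(scl)
  if (any(drop)) {
    warning(sum(drop), " zero-variance protein(s) dropped from scaler")
  }
  structure(
    list(protein_id = rownames(m)[!drop], center = ctr[!drop],
         scale = scl[!drop]),
    class = "protein_scaler"
  )
}

#' @rdname fit_scaler
#' @param scaler A `protein_scaler` from [fit_scaler()].
#' @param mat Matrix or wide tibble to standardize; must contain the
#'   scaler's proteins.
#' @return `apply_scaler()`: standardized wide tibble restricted to the
#'   scaler's proteins.
#' @export
apply_scaler <- function(scaler, mat) {
  stopifnot(inherits(scaler, "protein_scaler"))
  m <- as_protein_matrix(mat)
  missing <- setdiff(scaler$protein_id, rownames(m))
  if (length(missing) > 0) {
    stop("matrix lacks scaler proteins: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  m <- m[scaler$protein_id, , drop = FALSE]
  as_protein_tbl((m - scaler$center) / scaler$scale)
}
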