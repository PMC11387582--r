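#' Convert a wide protein table to a numeric matrix
#'
#' Most functions in this package accept protein abundance data either as a
#' wide tibble whose first column is `protein_id` (remaining columns are
#' samples) or as a numeric matrix with protein row names. This pair of
#' helpers converts between the two representations without reordering.
#'
#' @param x A wide data frame with a `protein_id` column, or a numeric matrix
#'   with row names.
#' @return `as_protein_matrix()` returns a numeric matrix (proteins x
#'   samples) with protein IDs as row names; `as_protein_tbl()` returns the
#'   wide tibble form.
#' @export
as_protein_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("matrix input must have protein row names")
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (!"protein_id" %in% names(x)) {
    stop("data frame input must have a 'protein_id' column")
  }
  ids <- as.character(x$protein_id)
  if (anyDuplicated(ids)) stop("protein_id values must be unique")
  m <- as.matrix(x[setdiff(names(x), "protein_id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname as_protein_matrix
#' @export
as_protein_tbl <- function(x) {
  m <- as_protein_matrix(x)
  dplyr::bind_cols(
    tibble::tibble(protein_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

# Restrict a matrix's columns to a metadata subset, in metadata order.
subset_samples <- function(m, sample_ids) {
  missing <- setdiff(sample_ids, colnames(m))
  if (length(missing) > 0) {
    stop("samples absent from the intensity matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  m[, sample_ids, drop = FALSE]
}
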