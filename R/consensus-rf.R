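#' Configuration of the repeated Random-Forest consensus selector
#'
#' The severity classifier is a Random Forest of shallow trees (1000 trees,
#' at most 3 terminal nodes each) trained on baseline (T0) samples after an
#' 80/20 stratified split, repeated over a sequence of seeds; each repeat
#' records test accuracy and ranks proteins by mean decrease in Gini
#' impurity; the consensus set is the strict intersection of all top-k
#' lists.
#'
#' @param n_trees Trees per forest (default 1000).
#' @param max_nodes Maximum terminal nodes per tree (default 3: depth-
#'   limited stumps, enough to separate three ordered classes on one
#'   marker).
#' @param train_fraction Training proportion per subtype (default 0.8).
#' @param seeds Integer seed sequence; one repeat per seed (default
#'   `1:100`).
#' @param top_k Importance-list length per repeat (default 30).
#' @param mtry Features sampled per split; `NULL` = `floor(sqrt(p))`.
#' @param consensus Either `"strict"` (intersection of all top-k lists,
#'   the default) or `"majority"` (proteins in more than half the lists).
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 1000, max_nodes = 3, train_fraction = 0.8,
                      seeds = 1:100, top_k = 30, mtry = NULL,
                      consensus = c("strict", "majority")) {
  consensus <- match.arg(consensus)
  stopifnot(n_trees >= 1, max_nodes >= 2,
            train_fraction > 0, train_fraction < 1,
            length(seeds) >= 1, top_k >= 1)
  structure(
    list(n_trees = as.integer(n_trees), max_nodes = as.integer(max_nodes),
         train_fraction = train_fraction, seeds = as.integer(seeds),
         n_repeats = length(seeds), top_k = as.integer(top_k),
         mtry = mtry, consensus = consensus),
    class = "rf_config"
  )
}

#' Stratified train/test partition of baseline samples
#'
#' Splits T0 samples into train and test sets preserving subtype
#' proportions: per subtype the train count is `round(train_fraction * n)`,
#' clipped so that every subtype keeps at least one train and one test
#' sample. Deterministic for a given seed.
#'
#' @param metadata Data frame with `sample_id` and `subtype`, already
#'   restricted to one sample per patient (T0).
#' @param train_fraction Training proportion in `(0, 1)`.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test` (disjoint,
#'   jointly exhaustive).
#' @export
stratified_partition <- function(metadata, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            all(c("sample_id", "subtype") %in% names(metadata)))
  counts <- table(metadata$subtype)
  if (any(counts < 2)) {
    stop("every subtype needs >= 2 samples to partition: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  set.seed(seed)
  train <- unlist(lapply(split(metadata$sample_id, metadata$subtype),
                         function(ids) {
    k <- round(train_fraction * length(ids))
    k <- min(max(k, 1L), length(ids) - 1L)  # >=1 train and >=1 test
    sample(ids, k)
  }), use.names = FALSE)
  list(train = train, test = setdiff(metadata$sample_id, train))
}

#' Train one Random-Forest repeat and score it on held-out samples
#'
#' Applies the leakage-aware contract: per-protein minimum imputation and
#' standardization are fitted on the training samples only, then applied to
#' the test samples; a forest of shallow trees is trained and scored by
#' plain proportion correct on the test partition; proteins are ranked by
#' mean decrease in Gini impurity with a deterministic tie-break
#' (importance descending, then protein ID ascending).
#'
#' @param mat Wide tibble or matrix of log2 intensities at T0 (`NA`
#'   missing allowed; imputed internally from the train subset).
#' @param metadata Data frame with `sample_id` and `subtype` covering the
#'   matrix columns.
#' @param partition List with `train` and `test` sample-ID vectors.
#' @param config An [rf_config()].
#' @param seed Integer seed for forest training.
#' @return An object of class `rf_repeat`: `seed`, `train`/`test` IDs,
#'   `accuracy`, an `importance` tibble (`protein_id`, `importance`), and
#'   the `top_k` character vector.
#' @export
train_and_score <- function(mat, metadata, partition, config, seed) {
  m <- as_protein_matrix(mat)
  lab <- stats::setNames(metadata$subtype, metadata$sample_id)
  y_tr <- factor(lab[partition$train])
  if (nlevels(droplevels(y_tr)) < 2) {
    stop("degenerate training set: a single class")
  }
  tr <- subset_samples(m, partition$train)
  te <- subset_samples(m, partition$test)

  # train-only imputation: per-protein minimum observed in the train subset
  obs <- rowSums(!is.na(tr)) > 0
  tr <- tr[obs, , drop = FALSE]
  te <- te[obs, , drop = FALSE]
  mins <- apply(tr, 1, min, na.rm = TRUE)
  fill <- function(z) {
    idx <- which(is.na(z), arr.ind = TRUE)
    if (nrow(idx) > 0) z[idx] <- mins[idx[, 1]]
    z
  }
  scaler <- fit_scaler(suppressWarnings(fill(tr)))
  x_tr <- t(as_protein_matrix(suppressWarnings(apply_scaler(scaler, fill(tr)))))
  x_te <- t(as_protein_matrix(suppressWarnings(apply_scaler(scaler, fill(te)))))

  p <- ncol(x_tr)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(p))) else
    min(as.integer(config$mtry), p)
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = x_tr, y = droplevels(y_tr), ntree = config$n_trees,
    maxnodes = config$max_nodes, mtry = mtry
  )
  pred <- stats::predict(fit, x_te)
  accuracy <- mean(as.character(pred) == as.character(lab[partition$test]))

  imp <- fit$importance[, "MeanDecreaseGini"]
  importance <- tibble::tibble(protein_id = names(imp),
                               importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$protein_id)
  structure(
    list(seed = seed, train = partition$train, test = partition$test,
         accuracy = accuracy, importance = importance,
         top_k = utils::head(importance$protein_id, config$top_k)),
    class = "rf_repeat"
  )
}

#' Run the repeated Random-Forest consensus feature selection
#'
#' The full baseline-classification procedure: for each seed, a stratified
#' train/test split of the T0 samples, a shallow Random Forest, the test
#' accuracy, and the top-k proteins by mean decrease in Gini impurity; then
#' the consensus set of proteins appearing in the top-k list of every
#' repeat (or of a majority, if configured), with a per-protein frequency
#' table. Fully deterministic for a given config.
#'
#' @param mat Wide tibble or matrix of preprocessed log2 intensities; its
#'   columns are restricted to the T0 samples in `metadata`.
#' @param metadata Data frame with `sample_id`, `subtype` and (if present)
#'   `timepoint`, which is used to restrict to T0.
#' @param config An [rf_config()].
#' @return An object of class `rf_consensus`: `repeats` (list of
#'   `rf_repeat`), `accuracies`, `consensus` (character vector),
#'   `frequency` tibble (`protein_id`, `n_top_k`, `mean_importance`), and
#'   the `config`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_design(n_per_subtype = c(6, 6, 6),
#'                                      n_proteins = 80, seed = 3))
#' mat <- log2_median_center(coh$intensities)
#' res <- run_consensus(mat, coh$metadata, rf_config(seeds = 1:5,
#'                                                   n_trees = 200))
#' glance(res)
#' }
#' @export
run_consensus <- function(mat, metadata, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  if (config$n_repeats == 0) stop("config must contain at least one seed")
  md <- metadata
  if ("timepoint" %in% names(md)) md <- md[md$timepoint == "T0", ]
  m <- subset_samples(as_protein_matrix(mat), md$sample_id)
  # canonical row order: the consensus must not depend on input protein order
  m <- m[order(rownames(m)), , drop = FALSE]

  repeats <- lapply(config$seeds, function(s) {
    part <- stratified_partition(md, config$train_fraction, seed = s)
    train_and_score(m, md, part, config, seed = s)
  })
  top_lists <- lapply(repeats, `[[`, "top_k")
  freq_tab <- table(unlist(top_lists))
  consensus <- switch(config$consensus,
    strict = Reduce(intersect, top_lists),
    majority = names(freq_tab)[freq_tab > config$n_repeats / 2]
  )
  mean_imp <- purrr::map_dfr(repeats, ~ .x$importance) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(mean_importance = mean(.data$importance), .groups = "drop")
  frequency <- tibble::tibble(protein_id = names(freq_tab),
                              n_top_k = as.integer(freq_tab)) |>
    dplyr::left_join(mean_imp, by = "protein_id") |>
    dplyr::arrange(dplyr::desc(.data$n_top_k),
                   dplyr::desc(.data$mean_importance), .data$protein_id)
  consensus <- sort(consensus)
  structure(
    list(repeats = repeats,
         accuracies = vapply(repeats, `[[`, numeric(1), "accuracy"),
         consensus = consensus, frequency = frequency, config = config),
    class = "rf_consensus"
  )
}

#' @export
print.rf_consensus <- function(x, ...) {
  cat("<rf_consensus> ", length(x$repeats), " repeats; modal accuracy ",
      modal_accuracy(x), "; consensus set: ", length(x$consensus),
      " protein(s)\n", sep = "")
  if (length(x$consensus) > 0) {
    cat("  ", paste(utils::head(x$consensus, 10), collapse = ", "),
        if (length(x$consensus) > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Modal held-out accuracy across repeats
#'
#' @param x An `rf_consensus` object.
#' @return The most frequent test accuracy across repeats (ties broken
#'   toward the larger accuracy).
#' @export
modal_accuracy <- function(x) {
  stopifnot(inherits(x, "rf_consensus"))
  tab <- table(x$accuracies)
  acc <- as.numeric(names(tab)[tab == max(tab)])
  max(acc)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the consensus frequency table
#'
#' @param x An `rf_consensus` object.
#' @param ... Unused.
#' @return Tibble with one row per protein that entered any top-k list:
#'   `protein_id`, `n_top_k`, `mean_importance`, `in_consensus`.
#' @export
tidy.rf_consensus <- function(x, ...) {
  dplyr::mutate(x$frequency,
                in_consensus = .data$protein_id %in% x$consensus)
}

#' One-row summary of a consensus run
#'
#' @param x An `rf_consensus` object.
#' @param ... Unused.
#' @return Tibble: `n_repeats`, `mean_accuracy`, `modal_accuracy`,
#'   `min_accuracy`, `n_consensus`, `top_k`.
#' @export
glance.rf_consensus <- function(x, ...) {
  tibble::tibble(
    n_repeats = length(x$repeats),
    mean_accuracy = mean(x$accuracies),
    modal_accuracy = modal_accuracy(x),
    min_accuracy = min(x$accuracies),
    n_consensus = length(x$consensus),
    top_k = x$config$top_k
  )
}

#' Spearman correlation of consensus proteins with age
#'
#' For each selected protein, the Spearman rank correlation between its
#' baseline abundance and patient age, with Benjamini-Hochberg adjustment
#' across the selected set. Proteins with constant abundance get `NA` rho.
#'
#' @param mat Wide tibble or matrix of log2 intensities.
#' @param metadata Data frame with `sample_id`, `age_years` and (if
#'   present) `timepoint` (restricted to T0).
#' @param proteins Character vector of protein IDs (e.g. the consensus
#'   set).
#' @return Tibble: `protein_id`, `n`, `rho`, `p_value`, `p_adjusted`.
#' @export
correlate_with_age <- function(mat, metadata, proteins) {
  md <- metadata
  if ("timepoint" %in% names(md)) md <- md[md$timepoint == "T0", ]
  m <- subset_samples(as_protein_matrix(mat), md$sample_id)
  missing <- setdiff(proteins, rownames(m))
  if (length(missing) > 0) {
    stop("proteins absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  res <- purrr::map_dfr(proteins, function(p) {
    x <- m[p, ]
    ok <- !is.na(x) & !is.na(md$age_years)
    if (sum(ok) < 3) {
      return(tibble::tibble(protein_id = p, n = sum(ok),
                            rho = NA_real_, p_value = NA_real_))
    }
    if (stats::sd(x[ok]) == 0) {
      return(tibble::tibble(protein_id = p, n = sum(ok),
                            rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], md$age_years[ok], method = "spearman")
    )
    tibble::tibble(protein_id = p, n = sum(ok),
                   rho = unname(ct$estimate), p_value = ct$p.value)
  })
  dplyr::mutate(res, p_adjusted = bh_adjust_allow_na(.data$p_value))
}

# BH over the non-missing entries, preserving positions of NA.
bh_adjust_allow_na <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- bh_adjust(p[ok])
  out
}
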