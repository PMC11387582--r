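#' Preprocess a raw cohort for analysis
#'
#' The fixed pipeline head shared by all three workflows: log2 transform,
#' per-sample median-centering, then the per-group completeness filter.
#' Imputation and scaling happen later, per analysis (and, for the
#' classifier, per training split — never on the full matrix).
#'
#' @param intensities Wide tibble or matrix of raw intensities (`0` =
#'   missing).
#' @param metadata Sample metadata with `sample_id` and `subtype`.
#' @param min_completeness Required observed fraction in >= 1 subtype
#'   (default 0.7).
#' @param log2_input Input already on the log2 scale (default FALSE).
#' @return Wide tibble of filtered, centered log2 intensities.
#' @export
preprocess_cohort <- function(intensities, metadata, min_completeness = 0.7,
                              log2_input = FALSE) {
  log2_median_center(intensities, log2_input = log2_input) |>
    filter_by_completeness(metadata, group = "subtype",
                           min_fraction = min_completeness)
}

ensure_responder_flags <- function(metadata) {
  if ("responder" %in% names(metadata)) return(metadata)
  if (!"motor_score" %in% names(metadata)) {
    stop("metadata needs either a 'responder' flag or 'motor_score' values")
  }
  flags <- classify_responders(metadata)
  dplyr::left_join(metadata,
                   dplyr::select(flags, "patient_id", "responder"),
                   by = "patient_id")
}

workflow_manifest <- function(workflow, config) {
  list(
    workflow = workflow,
    package = "smaproteo",
    version = as.character(utils::packageVersion("smaproteo")),
    config = config,
    config_hash = rlang::hash(config)
  )
}

#' Baseline severity-stratification workflow
#'
#' The full baseline analysis on T0 samples: preprocessing, marginal
#' PERMANOVA over the design factors (subtype, sex, age tertiles, BMI
#' group, SMN2 copies, response status), the repeated Random-Forest
#' consensus feature selection, and Spearman age correlations of the
#' consensus proteins (age being the one confounded factor the PERMANOVA
#' screen is expected to flag).
#'
#' @param intensities Wide tibble or matrix of raw intensities.
#' @param metadata Sample metadata (see [generate_cohort()] for columns).
#' @param rf An [rf_config()].
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param seed Seed for the PERMANOVA permutations.
#' @param min_completeness Completeness-filter threshold.
#' @param log2_input Input already log2-scale.
#' @return An object of class `sma_baseline`: `permanova` tibble,
#'   `consensus` (`rf_consensus`), `age_correlation` tibble, the
#'   preprocessed `matrix`, and a run `manifest`.
#' @export
run_baseline_workflow <- function(intensities, metadata, rf = rf_config(),
                                  n_permutations = 999, seed = 1L,
                                  min_completeness = 0.7,
                                  log2_input = FALSE) {
  metadata <- ensure_responder_flags(metadata)
  mat <- preprocess_cohort(intensities, metadata, min_completeness,
                           log2_input)
  md_t0 <- metadata[metadata$timepoint == "T0", ]
  if (length(unique(md_t0$subtype)) < 2) stop("need T0 samples for >= 2 subtypes")
  mat_t0 <- as_protein_tbl(subset_samples(as_protein_matrix(mat),
                                          md_t0$sample_id))
  perm <- permanova_screen(mat_t0, md_t0, n_permutations = n_permutations,
                           seed = seed)
  consensus <- run_consensus(mat_t0, md_t0, rf)
  age_cor <- if (length(consensus$consensus) > 0) {
    correlate_with_age(mat_t0, md_t0, consensus$consensus)
  } else {
    tibble::tibble(protein_id = character(0), n = integer(0),
                   rho = numeric(0), p_value = numeric(0),
                   p_adjusted = numeric(0))
  }
  config <- list(rf = unclass(rf), n_permutations = n_permutations,
                 seed = seed, min_completeness = min_completeness)
  structure(
    list(permanova = perm, consensus = consensus, age_correlation = age_cor,
         matrix = mat, manifest = workflow_manifest("baseline", config)),
    class = "sma_baseline"
  )
}

treatment_one_subtype <- function(mat_m, metadata, subtype, gene_sets,
                                  alpha) {
  diff_tab <- paired_treatment_test(mat_m, metadata, subtype = subtype,
                                    alpha = alpha)
  sig <- diff_tab$protein_id[diff_tab$significant]
  clusters <- NULL
  enrichment_up <- enrichment_down <- NULL
  if (length(sig) >= 2) {
    md_s <- metadata[metadata$subtype == subtype, ]
    sub <- subset_samples(mat_m, md_s$sample_id)[sig, , drop = FALSE]
    sub <- as_protein_matrix(impute_min(sub))
    dir_stat <- stats::setNames(diff_tab$effect, diff_tab$protein_id)[sig]
    clusters <- ward_cluster_cut2(sub, direction_stat = dir_stat)
    if (!is.null(gene_sets)) {
      bg <- rownames(mat_m)
      asg <- clusters$assignment
      for (lab in c("up", "down")) {
        q <- asg$protein_id[asg$label == lab]
        res <- if (length(q) > 0) enrich(q, gene_sets, bg) else NULL
        if (lab == "up") enrichment_up <- res else enrichment_down <- res
      }
    }
  }
  list(differential = diff_tab, clusters = clusters,
       enrichment_up = enrichment_up, enrichment_down = enrichment_down)
}

#' Treatment-effect workflow
#'
#' Per-subtype paired differential abundance between T0 and T302 (BH-
#' adjusted), Ward-D2 clustering of each subtype's significant proteins
#' into an up and a down cluster, and (when a gene-set collection is
#' supplied) hypergeometric over-representation of each cluster against
#' the background of all quantified proteins.
#'
#' @inheritParams run_baseline_workflow
#' @param gene_sets Optional `gene_sets` collection from [read_gmt()].
#' @param subtypes Subtypes to analyze (default: all in metadata).
#' @param alpha Adjusted-p threshold for the paired test (default 0.05).
#' @return An object of class `sma_treatment`: per-subtype list with
#'   `differential`, `clusters`, `enrichment_up`, `enrichment_down`, plus
#'   the preprocessed `matrix` and run `manifest`.
#' @export
run_treatment_workflow <- function(intensities, metadata, gene_sets = NULL,
                                   subtypes = NULL, alpha = 0.05,
                                   min_completeness = 0.7,
                                   log2_input = FALSE) {
  mat <- preprocess_cohort(intensities, metadata, min_completeness,
                           log2_input)
  mat_m <- as_protein_matrix(mat)
  if (is.null(subtypes)) subtypes <- sort(unique(metadata$subtype))
  per_subtype <- lapply(stats::setNames(subtypes, subtypes), function(s) {
    treatment_one_subtype(mat_m, metadata, s, gene_sets, alpha)
  })
  config <- list(subtypes = subtypes, alpha = alpha,
                 min_completeness = min_completeness,
                 gene_sets = if (is.null(gene_sets)) NULL else gene_sets$set)
  structure(
    list(per_subtype = per_subtype, matrix = mat,
         manifest = workflow_manifest("treatment", config)),
    class = "sma_treatment"
  )
}

#' Responder-contrast workflow
#'
#' Per subtype: within-patient T302 - T0 change profiles, a PERMANOVA of
#' response status on their Euclidean distances, and the unpaired
#' responder vs non-responder contrast per protein (raw-p significance).
#' Responder flags are derived from motor scores when absent.
#'
#' @inheritParams run_treatment_workflow
#' @param n_permutations,seed PERMANOVA permutations and seed.
#' @param var_equal Pooled-variance t instead of Welch.
#' @return An object of class `sma_responder`: per-subtype list with
#'   `permanova` and `differential`, plus `matrix` and `manifest`.
#' @export
run_responder_workflow <- function(intensities, metadata, subtypes = NULL,
                                   alpha = 0.05, n_permutations = 999,
                                   seed = 1L, var_equal = FALSE,
                                   min_completeness = 0.7,
                                   log2_input = FALSE) {
  metadata <- ensure_responder_flags(metadata)
  mat <- preprocess_cohort(intensities, metadata, min_completeness,
                           log2_input)
  mat_m <- as_protein_matrix(mat)
  if (is.null(subtypes)) subtypes <- sort(unique(metadata$subtype))
  per_subtype <- lapply(stats::setNames(subtypes, subtypes), function(s) {
    md_s <- metadata[metadata$subtype == s, ]
    dm <- delta_matrix(mat_m, md_s)
    flags <- dm$patients$responder
    if (anyNA(flags) || length(unique(flags)) < 2) {
      stop("subtype ", s, " lacks both responder classes")
    }
    delta_complete <- as_protein_matrix(impute_min(dm$delta))
    perm <- permanova(stats::dist(t(delta_complete)),
                      ifelse(flags, "R", "nonR"),
                      n_permutations = n_permutations, seed = seed,
                      factor_name = paste0("responder:", s))
    diff_tab <- responder_contrast(mat_m, metadata, s, alpha = alpha,
                                   var_equal = var_equal)
    list(permanova = perm, differential = diff_tab)
  })
  config <- list(subtypes = subtypes, alpha = alpha,
                 n_permutations = n_permutations, seed = seed,
                 var_equal = var_equal, min_completeness = min_completeness)
  structure(
    list(per_subtype = per_subtype, matrix = mat,
         manifest = workflow_manifest("responder", config)),
    class = "sma_responder"
  )
}

#' Write workflow result tables to a directory
#'
#' Exports every result table of a workflow object as TSV plus the JSON
#' run manifest. Identical inputs and config produce byte-identical
#' files, so a rerun can be verified by file comparison.
#'
#' @param result An `sma_baseline`, `sma_treatment` or `sma_responder`
#'   object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_workflow <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(tb, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(tb, p)
    paths <<- c(paths, p)
  }
  if (inherits(result, "sma_baseline")) {
    put(result$permanova, "permanova")
    put(tidy(result$consensus), "consensus_frequency")
    put(glance(result$consensus), "consensus_summary")
    put(tibble::tibble(seed = result$consensus$config$seeds,
                       accuracy = result$consensus$accuracies),
        "repeat_accuracies")
    put(result$age_correlation, "age_correlation")
  } else if (inherits(result, "sma_treatment")) {
    for (s in names(result$per_subtype)) {
      r <- result$per_subtype[[s]]
      put(r$differential, paste0("differential_", s))
      if (!is.null(r$clusters)) put(tidy(r$clusters), paste0("clusters_", s))
      if (!is.null(r$enrichment_up)) {
        put(r$enrichment_up, paste0("enrichment_up_", s))
      }
      if (!is.null(r$enrichment_down)) {
        put(r$enrichment_down, paste0("enrichment_down_", s))
      }
    }
  } else if (inherits(result, "sma_responder")) {
    for (s in names(result$per_subtype)) {
      r <- result$per_subtype[[s]]
      put(r$permanova, paste0("permanova_", s))
      put(r$differential, paste0("differential_", s))
    }
  } else {
    stop("unsupported result class: ", paste(class(result), collapse = "/"))
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, manifest_path))
}
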