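#' Specify a synthetic paired-timepoint SMA proteomics cohort
#'
#' Defines the design of a simulated cerebrospinal-fluid proteomics study:
#' three severity subtypes (SMA1 most severe), two timepoints per patient
#' (baseline `T0` and post-treatment `T302`), and planted structure with
#' known ground truth for every downstream analysis stage.
#'
#' Intensities are simulated directly on the log2 scale as Gaussian noise
#' around per-protein baselines drawn uniformly from `baseline_range`, with
#' per-sample additive shifts (so per-sample median-centering is
#' non-trivial), then exported on the raw scale with zeros marking values
#' that were "not quantified" (missing completely at random at
#' `missing_rate`).
#'
#' Planted structure, using disjoint protein blocks:
#' \itemize{
#'   \item `n_baseline_markers` proteins shifted monotonically across
#'     subtypes by `baseline_effect` log2 units per severity step, at both
#'     timepoints (the classifier's targets);
#'   \item `n_age_proteins` proteins with a linear age trend of `age_slope`
#'     log2 units per year; ages are drawn per subtype around `age_means`
#'     (younger = more severe), so age is a confounder by construction;
#'   \item a shared treatment set plus one per-subtype set
#'     (`n_treatment_shared`, `n_treatment_subtype`) shifted only at `T302`;
#'     within each subtype-specific set half the proteins move up and half
#'     down by `treatment_effect` log2 units, so the up/down cluster cut has
#'     ground truth in both directions;
#'   \item `n_responder_proteins` proteins with an extra `T302` shift of
#'     `responder_extra_effect` applied only to responder patients
#'     (responders drawn per subtype at `responder_fraction`).
#' }
#'
#' Motor scores (CHOP INTEND for SMA1, HFMSE otherwise) are generated so
#' that the planted responder flags are exactly recoverable from the
#' score-gain rules (CHOP gain >= 4, HFMSE gain >= 3).
#'
#' @param n_per_subtype Integer vector of length 3: patients per subtype
#'   (SMA1, SMA2, SMA3). The study cohort is `c(19, 19, 23)`.
#' @param n_proteins Number of simulated proteins (study scale: 1625).
#' @param n_baseline_markers,baseline_effect Count and per-severity-step
#'   log2 shift of subtype-discriminative proteins.
#' @param age_means,age_sd Per-subtype mean age (years) and common sd;
#'   defaults follow the study's Table of cohort medians (2.1/7.7/15.3 y).
#' @param n_age_proteins,age_slope Count of age-trending proteins and their
#'   slope in log2 units per year.
#' @param n_treatment_shared,n_treatment_subtype,treatment_effect Sizes of
#'   the shared and per-subtype treatment-effect sets and the absolute log2
#'   shift applied at T302.
#' @param responder_fraction Length-3 proportions of responders per subtype
#'   (defaults 11/19, 6/19, 6/23 as in the study population).
#' @param n_responder_proteins,responder_extra_effect Responder-specific
#'   set size and extra T302 shift (log2 units) in responders only.
#' @param noise_sd Residual log2 noise sd.
#' @param sample_shift_sd Sd of the per-sample additive log2 shift.
#' @param missing_rate MCAR missingness proportion in `[0, 0.5)`.
#' @param baseline_range Range (log2 units) of per-protein baseline
#'   abundances.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_design` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_design <- function(n_per_subtype = c(19, 19, 23),
                          n_proteins = 1625,
                          n_baseline_markers = 30,
                          baseline_effect = 1,
                          age_means = c(2.1, 7.7, 15.3),
                          age_sd = 3,
                          n_age_proteins = 20,
                          age_slope = 0.05,
                          n_treatment_shared = 20,
                          n_treatment_subtype = 16,
                          treatment_effect = 1,
                          responder_fraction = c(11 / 19, 6 / 19, 6 / 23),
                          n_responder_proteins = 10,
                          responder_extra_effect = 1,
                          noise_sd = 0.5,
                          sample_shift_sd = 0.3,
                          missing_rate = 0.05,
                          baseline_range = c(20, 35),
                          seed = 1L) {
  design <- list(
    n_per_subtype = as.integer(n_per_subtype),
    n_proteins = as.integer(n_proteins),
    n_baseline_markers = as.integer(n_baseline_markers),
    baseline_effect = baseline_effect,
    age_means = age_means,
    age_sd = age_sd,
    n_age_proteins = as.integer(n_age_proteins),
    age_slope = age_slope,
    n_treatment_shared = as.integer(n_treatment_shared),
    n_treatment_subtype = as.integer(n_treatment_subtype),
    treatment_effect = treatment_effect,
    responder_fraction = responder_fraction,
    n_responder_proteins = as.integer(n_responder_proteins),
    responder_extra_effect = responder_extra_effect,
    noise_sd = noise_sd,
    sample_shift_sd = sample_shift_sd,
    missing_rate = missing_rate,
    baseline_range = baseline_range,
    seed = as.integer(seed)
  )
  validate_cohort_design(design)
  structure(design, class = "cohort_design")
}

validate_cohort_design <- function(d) {
  stopifnot(
    length(d$n_per_subtype) == 3,
    length(d$age_means) == 3,
    length(d$responder_fraction) == 3,
    d$n_proteins >= 1,
    d$noise_sd >= 0, d$age_sd > 0, d$sample_shift_sd >= 0,
    all(d$responder_fraction >= 0), all(d$responder_fraction <= 1),
    length(d$baseline_range) == 2, diff(d$baseline_range) >= 0
  )
  if (any(d$n_per_subtype < 2)) {
    stop("each subtype needs at least 2 patients")
  }
  if (d$missing_rate < 0 || d$missing_rate >= 0.5) {
    stop("missing_rate must lie in [0, 0.5)")
  }
  counts <- c(d$n_baseline_markers, d$n_age_proteins, d$n_treatment_shared,
              d$n_treatment_subtype, d$n_responder_proteins)
  if (any(counts < 0)) stop("planted set sizes must be non-negative")
  n_planted <- d$n_baseline_markers + d$n_age_proteins +
    d$n_treatment_shared + 3L * d$n_treatment_subtype + d$n_responder_proteins
  if (n_planted > d$n_proteins) {
    stop("planted effect sets exceed n_proteins (need ", n_planted,
         ", have ", d$n_proteins, ")")
  }
  invisible(d)
}

sma_subtypes <- c("SMA1", "SMA2", "SMA3")

#' Generate a synthetic cohort with planted ground truth
#'
#' Simulates a full paired-timepoint cohort from a [cohort_design()]:
#' a raw-scale intensity table (zeros mean "not quantified"), per-sample
#' clinical metadata, and a ground-truth record naming every planted
#' protein set and the true responder flags. Byte-identical output is
#' guaranteed for identical design + seed.
#'
#' @param design A [cohort_design()] object.
#' @return An object of class `sma_cohort`: a list with
#' \describe{
#'   \item{intensities}{wide tibble, `protein_id` + one column per sample;
#'     raw-scale values, `0` = not quantified.}
#'   \item{metadata}{tibble with `sample_id`, `patient_id`, `subtype`,
#'     `timepoint`, `age_years`, `sex`, `smn2_copies`, `bmi_group`,
#'     `motor_score`, `responder`.}
#'   \item{truth}{list of planted protein-ID sets (`baseline_marker_ids`,
#'     `age_protein_ids`, `responder_effect_ids`), a signed
#'     `treatment_effects` tibble (`protein_id`, `group`, `effect`), and
#'     per-patient `responder_flags`.}
#'   \item{design}{the input design.}
#' }
#' @examples
#' coh <- generate_cohort(cohort_design(n_per_subtype = c(4, 4, 4),
#'                                      n_proteins = 60, seed = 7))
#' dim(coh$intensities)  # 60 proteins x (1 + 24 samples)
#' @export
generate_cohort <- function(design) {
  if (!inherits(design, "cohort_design")) design <- do.call(cohort_design, design)
  validate_cohort_design(design)
  d <- design
  set.seed(d$seed)

  ## patients and samples ---------------------------------------------------
  n_pat <- sum(d$n_per_subtype)
  patient_id <- sprintf("P%03d", seq_len(n_pat))
  subtype <- factor(rep(sma_subtypes, d$n_per_subtype), levels = sma_subtypes)
  age <- pmax(0.1, stats::rnorm(n_pat,
                                mean = rep(d$age_means, d$n_per_subtype),
                                sd = d$age_sd))
  sex <- sample(c("F", "M"), n_pat, replace = TRUE)
  smn2 <- ifelse(subtype == "SMA1", 2L,
                 ifelse(subtype == "SMA2", 3L,
                        sample(3:4, n_pat, replace = TRUE)))
  bmi_group <- sample(c("underweight", "normal", "overweight"), n_pat,
                      replace = TRUE, prob = c(0.3, 0.5, 0.2))

  responder <- logical(n_pat)
  for (s in sma_subtypes) {
    idx <- which(subtype == s)
    k <- round(d$responder_fraction[match(s, sma_subtypes)] * length(idx))
    if (k > 0) responder[sample(idx, k)] <- TRUE
  }

  ## planted protein blocks (disjoint) --------------------------------------
  pid <- sprintf("PROT%04d", seq_len(d$n_proteins))
  cuts <- cumsum(c(d$n_baseline_markers, d$n_age_proteins,
                   d$n_treatment_shared, rep(d$n_treatment_subtype, 3),
                   d$n_responder_proteins))
  block <- function(i) {
    lo <- if (i == 1) 1L else cuts[i - 1] + 1L
    if (cuts[i] < lo) integer(0) else lo:cuts[i]
  }
  i_base <- block(1); i_age <- block(2); i_shared <- block(3)
  i_sub <- list(SMA1 = block(4), SMA2 = block(5), SMA3 = block(6))
  i_resp <- block(7)

  signed <- function(idx, effect) {
    if (length(idx) == 0) return(numeric(0))
    sgn <- rep(c(1, -1), length.out = length(idx))
    sgn * effect
  }
  eff_sub <- lapply(i_sub, signed, effect = d$treatment_effect)

  ## log2 intensity grid -----------------------------------------------------
  n_samp <- 2L * n_pat
  sample_pat <- rep(seq_len(n_pat), each = 2L)
  timepoint <- rep(c("T0", "T302"), times = n_pat)
  sample_id <- paste0(patient_id[sample_pat], "_", timepoint)

  basal <- stats::runif(d$n_proteins, d$baseline_range[1], d$baseline_range[2])
  x <- matrix(basal, nrow = d$n_proteins, ncol = n_samp,
              dimnames = list(pid, sample_id))

  sev <- as.integer(subtype)[sample_pat] - 2L      # -1, 0, +1 across severity
  x[i_base, ] <- x[i_base, , drop = FALSE] +
    tcrossprod(rep(d$baseline_effect, length(i_base)), sev)
  age_c <- age[sample_pat] - mean(d$age_means)
  x[i_age, ] <- x[i_age, , drop = FALSE] +
    tcrossprod(rep(d$age_slope, length(i_age)), age_c)

  post <- timepoint == "T302"
  x[i_shared, post] <- x[i_shared, post, drop = FALSE] + d$treatment_effect
  for (s in sma_subtypes) {
    cols <- post & subtype[sample_pat] == s
    idx <- i_sub[[s]]
    if (length(idx) > 0 && any(cols)) {
      x[idx, cols] <- x[idx, cols, drop = FALSE] + eff_sub[[s]]
    }
  }
  resp_cols <- post & responder[sample_pat]
  if (length(i_resp) > 0 && any(resp_cols)) {
    x[i_resp, resp_cols] <- x[i_resp, resp_cols, drop = FALSE] +
      d$responder_extra_effect
  }

  x <- x + matrix(stats::rnorm(length(x), sd = d$noise_sd), nrow = nrow(x))
  shift <- stats::rnorm(n_samp, sd = d$sample_shift_sd)
  x <- sweep(x, 2, shift, `+`)

  raw <- 2^x
  if (d$missing_rate > 0) {
    raw[stats::runif(length(raw)) < d$missing_rate] <- 0
  }

  ## motor scores consistent with planted responder flags -------------------
  is1 <- subtype == "SMA1"
  score_t0 <- ifelse(is1, round(stats::runif(n_pat, 8, 30)),
                     ifelse(subtype == "SMA2",
                            round(stats::runif(n_pat, 3, 15)),
                            round(stats::runif(n_pat, 25, 55))))
  thr <- ifelse(is1, 4L, 3L)
  gain <- ifelse(responder, thr + sample(0:5, n_pat, replace = TRUE),
                 sample(-2:2, n_pat, replace = TRUE))
  gain <- ifelse(!responder & gain >= thr, thr - 1L, gain)
  score_t302 <- pmax(0, score_t0 + gain)

  metadata <- tibble::tibble(
    sample_id = sample_id,
    patient_id = patient_id[sample_pat],
    subtype = as.character(subtype)[sample_pat],
    timepoint = timepoint,
    age_years = age[sample_pat],
    sex = sex[sample_pat],
    smn2_copies = smn2[sample_pat],
    bmi_group = bmi_group[sample_pat],
    motor_score = ifelse(post, score_t302[sample_pat], score_t0[sample_pat]),
    responder = responder[sample_pat]
  )

  truth <- list(
    baseline_marker_ids = pid[i_base],
    age_protein_ids = pid[i_age],
    treatment_effects = dplyr::bind_rows(
      tibble::tibble(protein_id = pid[i_shared], group = "shared",
                     effect = rep(d$treatment_effect, length(i_shared))),
      purrr::map_dfr(sma_subtypes, function(s) {
        tibble::tibble(protein_id = pid[i_sub[[s]]], group = s,
                       effect = eff_sub[[s]])
      })
    ),
    responder_effect_ids = pid[i_resp],
    responder_flags = tibble::tibble(patient_id = patient_id,
                                     responder = responder)
  )

  structure(
    list(intensities = as_protein_tbl(raw), metadata = metadata,
         truth = truth, design = d),
    class = "sma_cohort"
  )
}

#' @export
print.sma_cohort <- function(x, ...) {
  m <- x$metadata
  cat("<sma_cohort> ", nrow(x$intensities), " proteins x ", nrow(m),
      " samples (", length(unique(m$patient_id)), " patients; ",
      sum(m$responder & m$timepoint == "T0"), " responders)\n", sep = "")
  invisible(x)
}

#' Score recovery of a planted protein set
#'
#' Compares a selected protein set against a planted ground-truth set over a
#' common protein universe and returns the confusion counts with sensitivity
#' and specificity. Used to audit every pipeline stage against the
#' generator's ground truth.
#'
#' @param selected Character vector of selected protein IDs.
#' @param truth_ids Character vector of planted (true-positive) protein IDs.
#' @param universe Character vector: all candidate protein IDs.
#' @return A one-row tibble: `n_truth`, `n_selected`, `tp`, `fp`, `fn`,
#'   `tn`, `sensitivity`, `specificity`. Confusion counts sum to
#'   `length(universe)`.
#' @examples
#' truth_recovery(c("a", "b"), c("a", "c"), letters[1:5])
#' @export
truth_recovery <- function(selected, truth_ids, universe) {
  selected <- unique(as.character(selected))
  truth_ids <- unique(as.character(truth_ids))
  universe <- unique(as.character(universe))
  bad <- setdiff(c(selected, truth_ids), universe)
  if (length(bad) > 0) {
    stop("IDs outside the stated universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  tp <- length(intersect(selected, truth_ids))
  fp <- length(setdiff(selected, truth_ids))
  fn <- length(setdiff(truth_ids, selected))
  tn <- length(universe) - tp - fp - fn
  tibble::tibble(
    n_truth = length(truth_ids), n_selected = length(selected),
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (length(truth_ids) == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  )
}

#' Write a synthetic cohort to disk
#'
#' Exports the standard interchange artifacts: a tab-separated intensity
#' matrix (`intensities.tsv`), sample metadata (`metadata.tsv`), and a JSON
#' ground-truth sidecar (`truth.json`).
#'
#' @param cohort An `sma_cohort` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sma_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    intensities = file.path(dir, "intensities.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(cohort$intensities, paths[["intensities"]])
  readr::write_tsv(cohort$metadata, paths[["metadata"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
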