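#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, input-checked wrapper around the standard step-up false-discovery-
#' rate adjustment: adjusted values are capped at 1 and monotone over the
#' sorted order, and `adjusted >= raw` always holds.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA`/`NaN` error.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## ---------------------------------------------------------------------------
## PERMANOVA

# Sum over groups of mean within-group squared distance contributions.
permanova_f <- function(d2, grp) {
  n <- nrow(d2)
  a <- length(unique(grp))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Single-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for one grouping
#' factor: the pseudo-F statistic is computed from squared distances as
#' `(SS_between/(a-1)) / (SS_within/(N-a))`, and its null distribution is
#' obtained by permuting group labels. With `exact = TRUE` (feasible for
#' N <= 8) all label permutations are enumerated and the p-value is the
#' exact proportion of permutations (identity included) with `F >=
#' F_observed`; otherwise `p = (#{F_perm >= F_obs} + 1) / (n_permutations
#' + 1)`, so the smallest attainable p is `1/(n_permutations + 1)`.
#'
#' @param d A `dist` object or symmetric distance matrix with zero
#'   diagonal.
#' @param labels Grouping vector, one entry per distance-matrix row; at
#'   least 2 groups with >= 2 members each.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exact Enumerate all permutations instead of sampling.
#' @param factor_name Label recorded in the output.
#' @return A one-row tibble: `factor`, `pseudo_f`, `p_value`,
#'   `n_permutations`, `exact`, `seed`.
#' @examples
#' x <- matrix(rnorm(24), 8, 3)
#' x[1:4, 1] <- x[1:4, 1] + 4
#' permanova(dist(x), rep(c("a", "b"), each = 4), exact = TRUE)
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = 1L,
                      exact = FALSE, factor_name = "group") {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(diag(dm)) > 1e-12)) {
    stop("d must be a square distance matrix with zero diagonal")
  }
  if (anyNA(dm)) stop("distances must not contain NA/NaN")
  if (length(labels) != nrow(dm)) stop("labels length must match d")
  grp <- as.character(labels)
  counts <- table(grp)
  if (length(counts) < 2) stop("need at least 2 groups")
  if (any(counts < 2)) stop("every group needs >= 2 members")

  d2 <- dm^2
  f_obs <- permanova_f(d2, grp)
  n <- nrow(dm)
  if (exact) {
    if (n > 8) stop("exact enumeration supported for n <= 8 only")
    perms <- all_permutations(n)
    f_all <- apply(perms, 1, function(ix) permanova_f(d2, grp[ix]))
    p <- mean(f_all >= f_obs - 1e-12)
    n_permutations <- nrow(perms)
  } else {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_permutations)) {
      f_p <- permanova_f(d2, grp[sample.int(n)])
      if (f_p >= f_obs - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_permutations + 1)
  }
  tibble::tibble(factor = factor_name, pseudo_f = f_obs, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 exact = exact, seed = as.integer(seed))
}

#' Marginal PERMANOVA over several design factors
#'
#' Runs one single-factor [permanova()] per listed metadata column on the
#' Euclidean distance between sample profiles (missing values imputed with
#' the per-protein minimum first). Continuous age is binned into tertiles
#' (`age_group`) because PERMANOVA needs groups; this coding is a package
#' choice, exposed via `age_breaks`.
#'
#' @param mat Wide tibble or matrix of log2 intensities (samples =
#'   columns).
#' @param metadata Data frame with `sample_id` and the factor columns.
#' @param factors Character vector of metadata columns to test; the
#'   special name `"age_group"` bins `age_years` into tertiles.
#' @param n_permutations,seed Passed to [permanova()]; each factor uses
#'   its own derived seed for independence.
#' @param age_breaks Number of age quantile bins (default 3).
#' @return Tibble with one [permanova()] row per factor (factors whose
#'   grouping is degenerate are skipped with a warning).
#' @export
permanova_screen <- function(mat, metadata,
                             factors = c("subtype", "sex", "age_group",
                                         "bmi_group", "smn2_copies",
                                         "responder"),
                             n_permutations = 999, seed = 1L,
                             age_breaks = 3) {
  m <- subset_samples(as_protein_matrix(mat), metadata$sample_id)
  m <- as_protein_matrix(impute_min(m))
  d <- stats::dist(t(m))
  md <- metadata
  if ("age_group" %in% factors) {
    qs <- stats::quantile(md$age_years, probs = seq(0, 1, length.out = age_breaks + 1),
                          na.rm = TRUE)
    md$age_group <- cut(md$age_years, breaks = unique(qs),
                        include.lowest = TRUE)
  }
  purrr::map_dfr(seq_along(factors), function(i) {
    f <- factors[i]
    grp <- as.character(md[[f]])
    counts <- table(grp)
    if (length(counts) < 2 || any(counts < 2)) {
      warning("factor '", f, "' has a degenerate grouping; skipped")
      return(NULL)
    }
    permanova(d, grp, n_permutations = n_permutations,
              seed = seed + i - 1L, factor_name = f)
  })
}

## ---------------------------------------------------------------------------
## ANCOVA screen

#' Age-adjusted per-protein ANCOVA screen at baseline
#'
#' For each protein, fits `abundance ~ age + subtype` on the baseline (T0)
#' samples and tests the subtype term adjusted for age (partial F-test of
#' the age-only model against the full model, i.e. Type-II). In a cohort
#' where age is confounded with severity this keeps purely age-driven
#' proteins out of the significant list. Flags use the raw p-value at
#' `alpha` (the screen feeds clustering, not formal inference).
#'
#' @param mat Wide tibble or matrix of log2 intensities.
#' @param metadata Data frame with `sample_id`, `subtype`, `age_years`
#'   and (if present) `timepoint` (restricted to T0).
#' @param alpha Raw-p significance threshold (default 0.05).
#' @return Tibble: `protein_id`, `contrast`, `n`, `effect` (range of
#'   age-adjusted subtype means, log2 units), `statistic` (F), `p_value`,
#'   `significant`. Zero-variance proteins are excluded with a warning.
#' @export
ancova_screen <- function(mat, metadata, alpha = 0.05) {
  md <- metadata
  if ("timepoint" %in% names(md)) md <- md[md$timepoint == "T0", ]
  if (length(unique(md$subtype)) < 2) stop("need >= 2 subtypes at T0")
  if (any(!is.finite(md$age_years))) stop("age must be finite for all samples")
  m <- subset_samples(as_protein_matrix(mat), md$sample_id)
  subtype <- factor(md$subtype)
  age <- md$age_years

  dropped <- character(0)
  res <- purrr::map_dfr(rownames(m), function(p) {
    y <- m[p, ]
    ok <- !is.na(y)
    if (sum(ok) < length(levels(droplevels(subtype[ok]))) + 2 ||
        length(unique(md$subtype[ok])) < 2 ||
        stats::sd(y[ok]) == 0) {
      dropped <<- c(dropped, p)
      return(NULL)
    }
    fit0 <- stats::lm(y ~ age, subset = ok)
    fit1 <- stats::lm(y ~ age + subtype, subset = ok)
    an <- stats::anova(fit0, fit1)
    cf <- stats::coef(fit1)
    sub_eff <- c(0, cf[grep("^subtype", names(cf))])
    tibble::tibble(protein_id = p, n = sum(ok),
                   effect = diff(range(sub_eff)),
                   statistic = an$F[2], p_value = an$`Pr(>F)`[2])
  })
  if (length(dropped) > 0) {
    warning(length(dropped), " protein(s) excluded from ANCOVA ",
            "(zero variance or insufficient observations)")
  }
  dplyr::mutate(res, contrast = "subtype|age", .after = "protein_id") |>
    dplyr::mutate(significant = .data$p_value < alpha)
}

## ---------------------------------------------------------------------------
## Paired and responder contrasts

# proteins x patients matrix of within-patient log2 differences (T302 - T0),
# pairwise-complete; patients missing either timepoint for a protein get NA.
#' Within-patient T302 - T0 log2 difference matrix
#'
#' Builds the per-patient treatment-change profile used by the paired
#' test, the responder contrast and the responder PERMANOVA: for every
#' protein and patient, `log2(T302) - log2(T0)` where both timepoints are
#' observed, `NA` otherwise.
#'
#' @param mat Wide tibble or matrix of log2 intensities (both timepoints).
#' @param metadata Data frame with `sample_id`, `patient_id`, `timepoint`.
#' @return List: `delta` (proteins x patients matrix) and `patients`
#'   (one-row-per-patient metadata tibble).
#' @export
delta_matrix <- function(mat, metadata) {
  m <- as_protein_matrix(mat)
  md <- metadata[metadata$sample_id %in% colnames(m), ]
  wide <- tidyr::pivot_wider(
    dplyr::select(md, "patient_id", "timepoint", "sample_id"),
    names_from = "timepoint", values_from = "sample_id"
  )
  wide <- wide[!is.na(wide$T0) & !is.na(wide$T302), ]
  delta <- m[, wide$T302, drop = FALSE] - m[, wide$T0, drop = FALSE]
  colnames(delta) <- wide$patient_id
  patients <- dplyr::distinct(
    dplyr::select(md, -"sample_id", -"timepoint",
                  -dplyr::any_of("motor_score"))
  )
  patients <- patients[match(wide$patient_id, patients$patient_id), ]
  list(delta = delta, patients = patients)
}

row_t_onesample <- function(d) {
  n <- rowSums(!is.na(d))
  mean_d <- rowMeans(d, na.rm = TRUE)
  sd_d <- apply(d, 1, stats::sd, na.rm = TRUE)
  t_stat <- mean_d / (sd_d / sqrt(n))
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  p[!is.finite(t_stat)] <- NA_real_   # zero-variance differences
  list(n = unname(n), mean = unname(mean_d), t = unname(t_stat),
       p = unname(p))
}

#' Paired differential abundance between timepoints
#'
#' Per-subtype paired two-sided t-test of each protein's within-patient
#' log2 change (T302 - T0), with Benjamini-Hochberg adjustment across the
#' subtype's tested proteins. Significance uses the adjusted p-value;
#' direction is the sign of the mean paired difference (positive = higher
#' at T302). Proteins with fewer than `min_pairs` complete pairs are
#' skipped.
#'
#' @param mat Wide tibble or matrix of log2 intensities.
#' @param metadata Data frame with `sample_id`, `patient_id`, `subtype`,
#'   `timepoint`.
#' @param subtype Subtype to test (e.g. `"SMA1"`); `NULL` = all patients
#'   pooled.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_pairs Minimum complete pairs per protein (default 3).
#' @return Tibble: `protein_id`, `contrast`, `n_pairs`, `effect` (mean
#'   log2 difference), `statistic`, `p_value`, `p_adjusted`,
#'   `significant`, `direction` (`"up"`/`"down"`).
#' @export
paired_treatment_test <- function(mat, metadata, subtype = NULL,
                                  alpha = 0.05, min_pairs = 3) {
  md <- metadata
  if (!is.null(subtype)) md <- md[md$subtype == subtype, ]
  dm <- delta_matrix(mat, md)
  if (ncol(dm$delta) == 0) stop("no patients with complete timepoint pairs")
  keep <- rowSums(!is.na(dm$delta)) >= min_pairs
  if (!all(keep)) {
    message(sum(!keep), " protein(s) skipped (< ", min_pairs,
            " complete pairs)")
  }
  d <- dm$delta[keep, , drop = FALSE]
  st <- row_t_onesample(d)
  label <- paste0("T302-T0", if (!is.null(subtype)) paste0(":", subtype))
  tibble::tibble(
    protein_id = rownames(d), contrast = label, n_pairs = st$n,
    effect = st$mean, statistic = st$t, p_value = st$p
  ) |>
    dplyr::mutate(
      p_adjusted = bh_adjust_allow_na(.data$p_value),
      significant = !is.na(.data$p_adjusted) & .data$p_adjusted < alpha,
      direction = ifelse(.data$effect > 0, "up", "down")
    )
}

row_t_twosample <- function(d1, d2, var_equal = FALSE) {
  n1 <- rowSums(!is.na(d1)); n2 <- rowSums(!is.na(d2))
  m1 <- rowMeans(d1, na.rm = TRUE); m2 <- rowMeans(d2, na.rm = TRUE)
  v1 <- apply(d1, 1, stats::var, na.rm = TRUE)
  v2 <- apply(d2, 1, stats::var, na.rm = TRUE)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  p[!is.finite(t_stat)] <- NA_real_
  list(n1 = unname(n1), n2 = unname(n2), effect = unname(m1 - m2),
       t = unname(t_stat), p = unname(p))
}

#' Responder vs non-responder fold-change contrast
#'
#' Within one subtype, compares each protein's within-patient log2 change
#' (T302 - T0) between responders and non-responders with an unpaired
#' two-sided t-test (Welch by default). The effect is mean
#' change(responders) minus mean change(non-responders), so positive means
#' a larger post-treatment increase in responders. Significance uses the
#' raw p-value at `alpha`.
#'
#' @param mat Wide tibble or matrix of log2 intensities.
#' @param metadata Data frame with `sample_id`, `patient_id`, `subtype`,
#'   `timepoint`, `responder` (logical).
#' @param subtype Subtype to test.
#' @param alpha Raw-p threshold (default 0.05).
#' @param var_equal Pooled-variance t instead of Welch.
#' @param min_per_class Minimum patients per class per protein (default 2).
#' @return Tibble: `protein_id`, `contrast`, `n_responder`,
#'   `n_nonresponder`, `effect`, `statistic`, `p_value`, `significant`,
#'   `direction`.
#' @export
responder_contrast <- function(mat, metadata, subtype, alpha = 0.05,
                               var_equal = FALSE, min_per_class = 2) {
  md <- metadata[metadata$subtype == subtype, ]
  if (!"responder" %in% names(md)) stop("metadata lacks a 'responder' column")
  dm <- delta_matrix(mat, md)
  flags <- dm$patients$responder
  if (anyNA(flags)) stop("responder flags contain NA for subtype ", subtype)
  if (length(unique(flags)) < 2) {
    stop("subtype ", subtype, " lacks one of the responder classes")
  }
  d_r <- dm$delta[, flags, drop = FALSE]
  d_n <- dm$delta[, !flags, drop = FALSE]
  keep <- rowSums(!is.na(d_r)) >= min_per_class &
    rowSums(!is.na(d_n)) >= min_per_class
  d_r <- d_r[keep, , drop = FALSE]; d_n <- d_n[keep, , drop = FALSE]
  st <- row_t_twosample(d_r, d_n, var_equal = var_equal)
  tibble::tibble(
    protein_id = rownames(d_r),
    contrast = paste0("R-vs-nonR:", subtype),
    n_responder = st$n1, n_nonresponder = st$n2,
    effect = st$effect, statistic = st$t, p_value = st$p
  ) |>
    dplyr::mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha,
                  direction = ifelse(.data$effect > 0, "up", "down"))
}

#' Label responders from motor-score gains
#'
#' Applies the clinical response rules: SMA1 patients (scored on the CHOP
#' INTEND scale, maximum 64) are responders if the score gains at least 4
#' points between T0 and T302; SMA2/SMA3 patients (HFMSE, maximum 66) if
#' the gain is at least 3 points. Patients missing either score get a
#' missing flag.
#'
#' @param metadata Per-sample data frame with `patient_id`, `subtype`,
#'   `timepoint`, `motor_score`.
#' @return Patient-level tibble: `patient_id`, `subtype`, `score_t0`,
#'   `score_t302`, `gain`, `responder`.
#' @examples
#' md <- tibble::tibble(patient_id = c("p1", "p1"), subtype = "SMA1",
#'                      timepoint = c("T0", "T302"), motor_score = c(13, 17))
#' classify_responders(md)  # gain 4 on CHOP: responder
#' @export
classify_responders <- function(metadata) {
  stopifnot(all(c("patient_id", "subtype", "timepoint", "motor_score")
                %in% names(metadata)))
  wide <- tidyr::pivot_wider(
    dplyr::select(metadata, "patient_id", "subtype", "timepoint",
                  "motor_score"),
    names_from = "timepoint", values_from = "motor_score"
  )
  for (tp in c("T0", "T302")) if (!tp %in% names(wide)) wide[[tp]] <- NA_real_
  max_score <- ifelse(wide$subtype == "SMA1", 64, 66)
  bad <- !is.na(wide$T0) & (wide$T0 < 0 | wide$T0 > max_score) |
    !is.na(wide$T302) & (wide$T302 < 0 | wide$T302 > max_score)
  if (any(bad)) {
    stop("motor scores out of scale range for patient(s): ",
         paste(utils::head(wide$patient_id[bad], 5), collapse = ", "))
  }
  thr <- ifelse(wide$subtype == "SMA1", 4, 3)
  tibble::tibble(
    patient_id = wide$patient_id, subtype = wide$subtype,
    score_t0 = wide$T0, score_t302 = wide$T302,
    gain = wide$T302 - wide$T0,
    responder = wide$T302 - wide$T0 >= thr
  )
}
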