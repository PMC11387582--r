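# Small cohort designs used across tests. Overrides are passed straight
# through to cohort_design().
tiny_design <- function(...) {
  args <- list(
    n_per_subtype = c(5, 5, 5), n_proteins = 60,
    n_baseline_markers = 6, baseline_effect = 2,
    n_age_proteins = 4, age_slope = 0.05,
    n_treatment_shared = 4, n_treatment_subtype = 3, treatment_effect = 1,
    n_responder_proteins = 4, responder_extra_effect = 1,
    noise_sd = 0.5, missing_rate = 0.05, seed = 42
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_design, args)
}

# A design with every planted effect and nuisance term switched off.
null_design <- function(...) {
  tiny_design(baseline_effect = 0, treatment_effect = 0,
              responder_extra_effect = 0, age_slope = 0,
              missing_rate = 0, sample_shift_sd = 0, ...)
}

# log2 matrix of a cohort without preprocessing (zeros -> NA, log2 only).
cohort_log2 <- function(coh) {
  m <- as_protein_matrix(coh$intensities)
  m[m == 0] <- NA
  log2(m)
}

# Rand index between two flat cluster assignments.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  mean(same_a == same_b)
}
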