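test_that("BH adjustment equals an independent step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(1)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("pseudo-F matches the Gower-trace oracle and vegan", {
  skip_if_not_installed("vegan")
  set.seed(4)
  for (i in 1:5) {
    x <- matrix(rnorm(10 * 4), 10, 4)
    grp <- rep(c("a", "b"), each = 5)
    d <- dist(x)
    res <- permanova(d, grp, n_permutations = 19, seed = i)
    expect_equal(res$pseudo_f, permanova_f_oracle(as.matrix(d), grp),
                 tolerance = 1e-10)
    ad <- vegan::adonis2(d ~ grp, permutations = 19)
    expect_equal(res$pseudo_f, ad$F[1], tolerance = 1e-10)
  }
})

test_that("duplicated groups give pseudo-F zero and strong separation
           saturates at the minimal p", {
  pts <- matrix(rnorm(12), 4, 3)
  x <- rbind(pts, pts)
  res <- permanova(dist(x), rep(c("a", "b"), each = 4),
                   n_permutations = 99, seed = 1)
  expect_equal(res$pseudo_f, 0, tolerance = 1e-10)
  set.seed(2)
  y <- rbind(matrix(rnorm(15), 5), matrix(rnorm(15) + 50, 5))
  sat <- permanova(dist(y), rep(c("a", "b"), each = 5),
                   n_permutations = 199, seed = 3)
  # minimum attainable p, allowing for random permutations that happen to
  # reproduce the original grouping (which tie with the observed F)
  expect_lte(sat$p_value, 3 / 200)
})

test_that("exact enumeration p matches a brute-force assignment oracle", {
  set.seed(11)
  for (i in 1:20) {
    x <- matrix(rnorm(6 * 3), 6, 3)
    grp <- rep(c("a", "b"), each = 3)
    dm <- as.matrix(dist(x))
    res <- permanova(dist(x), grp, exact = TRUE)
    # oracle: all 20 assignments of 3 samples to group "a"
    combos <- combn(6, 3)
    f_all <- apply(combos, 2, function(ix) {
      g <- rep("b", 6); g[ix] <- "a"
      permanova_f_oracle(dm, g)
    })
    f_obs <- permanova_f_oracle(dm, grp)
    expect_equal(res$p_value, mean(f_all >= f_obs - 1e-12),
                 tolerance = 1e-12)
  }
})

test_that("sampled permutation p converges to the exact p", {
  set.seed(21)
  x <- matrix(rnorm(7 * 3), 7, 3)
  x[1:3, ] <- x[1:3, ] + 1.2
  grp <- rep(c("a", "b"), c(3, 4))
  exact <- permanova(dist(x), grp, exact = TRUE)$p_value
  sampled <- permanova(dist(x), grp, n_permutations = 9999, seed = 5)$p_value
  expect_lt(abs(sampled - exact), 3 * sqrt(exact * (1 - exact) / 9999) + 1e-4)
})

test_that("permanova input validation", {
  d <- dist(matrix(rnorm(12), 4))
  expect_error(permanova(d, rep("a", 4)), "2 groups")
  expect_error(permanova(d, c("a", "a", "a", "b")), ">= 2 members")
  dm <- as.matrix(d); dm[1, 2] <- NA; dm[2, 1] <- NA
  expect_error(permanova(dm, rep(c("a", "b"), 2)), "NA")
})

test_that("ANCOVA keeps purely age-driven proteins at the nominal rate", {
  set.seed(31)
  n <- 30
  md <- tibble::tibble(
    sample_id = paste0("s", 1:n), timepoint = "T0",
    subtype = rep(c("SMA1", "SMA2", "SMA3"), each = n / 3),
    age_years = c(rnorm(n / 3, 2, 1.5), rnorm(n / 3, 8, 2),
                  rnorm(n / 3, 15, 3))
  )
  # every protein a pure linear function of (confounded) age + noise
  m <- t(sapply(1:200, function(i) 0.3 * md$age_years + rnorm(n, sd = 0.5)))
  rownames(m) <- sprintf("p%03d", 1:200); colnames(m) <- md$sample_id
  res <- ancova_screen(m, md)
  # unadjusted, nearly all would be "significant"; adjusted: ~ alpha
  expect_gt(mean(res$significant), 0)  # sanity: table populated
  expect_lt(mean(res$significant), 0.12)
  raw_naive <- sapply(1:50, function(i) {
    anova(lm(m[i, ] ~ factor(md$subtype)))$`Pr(>F)`[1]
  })
  expect_gt(mean(raw_naive < 0.05), 0.5)  # confounding is real
})

test_that("ANCOVA flags subtype shifts orthogonal to age", {
  set.seed(32)
  n <- 30
  md <- tibble::tibble(
    sample_id = paste0("s", 1:n), timepoint = "T0",
    subtype = rep(c("SMA1", "SMA2", "SMA3"), each = n / 3),
    age_years = c(rnorm(n / 3, 2, 1.5), rnorm(n / 3, 8, 2),
                  rnorm(n / 3, 15, 3))
  )
  shift <- rep(c(0, 1.5, 3), each = n / 3)
  m <- rbind(hit = shift + rnorm(n, sd = 0.4),
             flat = rep(1, n))
  colnames(m) <- md$sample_id
  expect_warning(res <- ancova_screen(m, md), "excluded")
  expect_true(res$significant[res$protein_id == "hit"])
  expect_false("flat" %in% res$protein_id)
  expect_gt(res$effect[res$protein_id == "hit"], 1)
})

test_that("paired t statistic matches the textbook formula", {
  t0 <- c(10, 11, 9, 12); t302 <- c(11.5, 11.2, 10.1, 13.0)
  md <- tibble::tibble(
    sample_id = c(paste0("p", 1:4, "_T0"), paste0("p", 1:4, "_T302")),
    patient_id = rep(paste0("p", 1:4), 2),
    subtype = "SMA1",
    timepoint = rep(c("T0", "T302"), each = 4)
  )
  m <- matrix(c(t0, t302), 1, dimnames = list("a", md$sample_id))
  res <- paired_treatment_test(m, md, min_pairs = 3)
  d <- t302 - t0
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(4)))
  expect_equal(res$effect, mean(d))
  expect_equal(res$p_value, t.test(t302, t0, paired = TRUE)$p.value)
  expect_equal(res$direction, "up")
})

test_that("identical timepoints yield no significant proteins", {
  coh <- generate_cohort(tiny_design(missing_rate = 0))
  m <- cohort_log2(coh)
  md <- coh$metadata
  m[, md$sample_id[md$timepoint == "T302"]] <-
    m[, md$sample_id[md$timepoint == "T0"]]
  res <- paired_treatment_test(m, md, subtype = "SMA1")
  expect_equal(sum(res$significant), 0)
})

test_that("a planted shift at study-scale n survives BH in most cohorts", {
  # paired-t power at effect 1, per-measurement sd 0.5, n = 19 pairs is
  # essentially 1; check across simulated cohorts
  set.seed(41)
  hits <- 0L
  for (i in 1:25) {
    d_null <- matrix(rnorm(49 * 19, 0, 0.5 * sqrt(2)), 49)
    d_eff <- matrix(rnorm(19, 1, 0.5 * sqrt(2)), 1)
    d <- rbind(d_eff, d_null)
    rownames(d) <- sprintf("p%02d", 1:50)
    colnames(d) <- paste0("pat", 1:19)
    md <- tibble::tibble(
      sample_id = c(paste0(colnames(d), "_T0"), paste0(colnames(d), "_T302")),
      patient_id = rep(colnames(d), 2), subtype = "SMA2",
      timepoint = rep(c("T0", "T302"), each = 19)
    )
    m <- cbind(matrix(0, 50, 19), d)
    dimnames(m) <- list(rownames(d), md$sample_id)
    res <- paired_treatment_test(m, md)
    if (res$significant[res$protein_id == "p01"]) hits <- hits + 1L
  }
  expect_gte(hits, 24)
})

test_that("responder contrast matches hand-computed Welch and pooled t", {
  d_r <- c(1.2, 0.8, 1.5); d_n <- c(0.1, -0.3, 0.4)
  md <- tibble::tibble(
    sample_id = c(paste0("p", 1:6, "_T0"), paste0("p", 1:6, "_T302")),
    patient_id = rep(paste0("p", 1:6), 2), subtype = "SMA1",
    timepoint = rep(c("T0", "T302"), each = 6),
    responder = rep(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2)
  )
  m <- matrix(c(rep(5, 6), 5 + c(d_r, d_n)), 1,
              dimnames = list("a", md$sample_id))
  welch <- responder_contrast(m, md, "SMA1")
  ref_w <- t.test(d_r, d_n)
  expect_equal(welch$statistic, unname(ref_w$statistic))
  expect_equal(welch$p_value, ref_w$p.value)
  expect_equal(welch$effect, mean(d_r) - mean(d_n))
  pooled <- responder_contrast(m, md, "SMA1", var_equal = TRUE)
  ref_p <- t.test(d_r, d_n, var.equal = TRUE)
  expect_equal(pooled$statistic, unname(ref_p$statistic))
  expect_equal(pooled$p_value, ref_p$p.value)
})

test_that("identical change distributions give zero effect", {
  md <- tibble::tibble(
    sample_id = c(paste0("p", 1:6, "_T0"), paste0("p", 1:6, "_T302")),
    patient_id = rep(paste0("p", 1:6), 2), subtype = "SMA1",
    timepoint = rep(c("T0", "T302"), each = 6),
    responder = rep(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2)
  )
  d <- c(0.5, -0.2, 0.9, 0.5, -0.2, 0.9)  # same values in both classes
  m <- matrix(c(rep(5, 6), 5 + d), 1, dimnames = list("a", md$sample_id))
  res <- responder_contrast(m, md, "SMA1")
  expect_equal(res$effect, 0)
  expect_false(res$significant)
  expect_error(responder_contrast(m, dplyr::mutate(md, responder = TRUE),
                                  "SMA1"), "classes")
})

test_that("a planted responder-only effect has the largest contrast", {
  coh <- generate_cohort(tiny_design(
    n_per_subtype = c(8, 8, 8), n_proteins = 80, responder_extra_effect = 2,
    noise_sd = 0.3, missing_rate = 0, seed = 19
  ))
  m <- cohort_log2(coh)
  res <- dplyr::bind_rows(lapply(c("SMA1", "SMA2", "SMA3"), function(s) {
    responder_contrast(m, coh$metadata, s)
  }))
  pooled <- res |>
    dplyr::group_by(protein_id) |>
    dplyr::summarise(effect = mean(effect))
  top <- pooled$protein_id[order(-abs(pooled$effect))][
    seq_along(coh$truth$responder_effect_ids)]
  expect_gte(length(intersect(top, coh$truth$responder_effect_ids)),
             length(coh$truth$responder_effect_ids) - 1)
})

test_that("responder labeling applies the scale-specific thresholds", {
  md <- tibble::tibble(
    patient_id = rep(c("a", "b", "c"), each = 2),
    subtype = rep(c("SMA1", "SMA3", "SMA2"), each = 2),
    timepoint = rep(c("T0", "T302"), 3),
    motor_score = c(13, 17,  # CHOP +4: responder (boundary inclusive)
                    47, 49,  # HFMSE +2: below threshold
                    10, 13)  # HFMSE +3: responder
  )
  res <- classify_responders(md)
  expect_equal(res$responder[match(c("a", "b", "c"), res$patient_id)],
               c(TRUE, FALSE, TRUE))
  bad <- dplyr::mutate(md, motor_score = c(13, 70, 47, 49, 10, 13))
  expect_error(classify_responders(bad), "out of scale")
})

test_that("default cohort reproduces the study's responder counts", {
  coh <- generate_cohort(cohort_design(seed = 2))
  flags <- coh$truth$responder_flags
  md <- coh$metadata[coh$metadata$timepoint == "T0", ]
  by_sub <- table(md$subtype[md$responder])
  expect_equal(as.integer(by_sub[c("SMA1", "SMA2", "SMA3")]), c(11, 6, 6))
  expect_equal(sum(flags$responder), 23)
})
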