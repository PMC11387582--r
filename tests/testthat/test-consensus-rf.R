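md_t0 <- function(coh) coh$metadata[coh$metadata$timepoint == "T0", ]

test_that("stratified partition rounds per subtype and stays disjoint", {
  md <- tibble::tibble(
    sample_id = paste0("s", 1:61),
    subtype = rep(c("SMA1", "SMA2", "SMA3"), c(19, 19, 23))
  )
  part <- stratified_partition(md, 0.8, seed = 7)
  counts <- table(md$subtype[match(part$train, md$sample_id)])
  expect_equal(as.integer(counts[c("SMA1", "SMA2", "SMA3")]), c(15, 15, 18))
  expect_length(intersect(part$train, part$test), 0)
  expect_setequal(c(part$train, part$test), md$sample_id)
  # determinism per seed
  expect_identical(part, stratified_partition(md, 0.8, seed = 7))
  expect_false(identical(part, stratified_partition(md, 0.8, seed = 8)))
})

test_that("partition clipping guarantees a test sample per subtype", {
  md <- tibble::tibble(sample_id = paste0("s", 1:6),
                       subtype = rep(c("a", "b", "c"), each = 2))
  part <- stratified_partition(md, 0.9, seed = 1)  # round(1.8) = 2, clipped
  counts <- table(md$subtype[match(part$test, md$sample_id)])
  expect_true(all(counts >= 1))
  expect_error(
    stratified_partition(tibble::tibble(sample_id = c("x", "y", "z"),
                                        subtype = c("a", "a", "b")), 0.8, 1),
    ">= 2 samples"
  )
})

test_that("strong planted separation gives perfect held-out accuracy", {
  coh <- generate_cohort(tiny_design(
    n_proteins = 100, n_baseline_markers = 10, baseline_effect = 2,
    noise_sd = 0.5, n_per_subtype = c(10, 10, 10), missing_rate = 0,
    seed = 21
  ))
  md <- md_t0(coh)
  mat <- log2_median_center(coh$intensities)
  cfg <- rf_config(seeds = 1:3, n_trees = 500)
  part <- stratified_partition(md, 0.8, seed = 1)
  rep1 <- train_and_score(
    as_protein_matrix(mat)[, md$sample_id], md, part, cfg, seed = 1
  )
  expect_equal(rep1$accuracy, 1.0)
  expect_true(all(rep1$importance$importance >= 0))
})

test_that("a single perfectly separating feature ranks first by importance", {
  set.seed(5)
  n <- 30
  md <- tibble::tibble(sample_id = paste0("s", 1:n),
                       subtype = rep(c("A", "B"), each = n / 2))
  m <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(sprintf("p%02d", 1:40), md$sample_id))
  m["p01", ] <- c(rnorm(n / 2, -4, 0.2), rnorm(n / 2, 4, 0.2))
  part <- stratified_partition(md, 0.8, seed = 2)
  rep1 <- train_and_score(m, md, part, rf_config(seeds = 1, n_trees = 300),
                          seed = 2)
  expect_equal(rep1$importance$protein_id[1], "p01")
})

test_that("label-permuted data scores near the chance rate", {
  set.seed(17)
  n <- 30
  md <- tibble::tibble(sample_id = paste0("s", 1:n),
                       subtype = sample(rep(c("A", "B"), each = n / 2)))
  m <- matrix(rnorm(50 * n), 50, n,
              dimnames = list(sprintf("p%02d", 1:50), md$sample_id))
  cfg <- rf_config(seeds = 1:20, n_trees = 200, top_k = 10)
  res <- run_consensus(m, md, cfg)
  # chance = 0.5; binomial band for mean over 20 repeats x 6 test samples
  se <- sqrt(0.25 / (20 * 6))
  expect_lt(abs(mean(res$accuracies) - 0.5), 5 * se)
})

test_that("consensus is the strict intersection with consistent frequencies", {
  coh <- generate_cohort(tiny_design(n_proteins = 50, missing_rate = 0,
                                     seed = 8))
  md <- md_t0(coh)
  mat <- log2_median_center(coh$intensities)
  cfg <- rf_config(seeds = 1:6, n_trees = 200, top_k = 10)
  res <- run_consensus(mat, md, cfg)
  for (r in res$repeats) expect_true(all(res$consensus %in% r$top_k))
  expect_lte(length(res$consensus), cfg$top_k)
  # frequency table: consensus proteins appear in all lists, others fewer
  freq <- tidy(res)
  expect_true(all(freq$n_top_k[freq$in_consensus] == 6))
  expect_true(all(freq$n_top_k[!freq$in_consensus] < 6))
  # saturated k: every protein makes every list
  sat <- run_consensus(mat, md, rf_config(seeds = 1:2, n_trees = 100,
                                          top_k = 50))
  expect_setequal(sat$consensus, as_protein_tbl(mat)$protein_id)
})

test_that("consensus is invariant to protein input order and nested in seeds", {
  coh <- generate_cohort(tiny_design(n_proteins = 40, missing_rate = 0,
                                     seed = 13))
  md <- md_t0(coh)
  mat <- as_protein_matrix(log2_median_center(coh$intensities))
  cfg <- rf_config(seeds = 1:4, n_trees = 200, top_k = 10)
  res1 <- run_consensus(mat, md, cfg)
  set.seed(99)
  res2 <- run_consensus(mat[sample(nrow(mat)), ], md, cfg)
  expect_identical(res1$consensus, res2$consensus)
  # strict intersection can only shrink as seeds are added
  res_more <- run_consensus(mat, md, rf_config(seeds = 1:8, n_trees = 200,
                                               top_k = 10))
  expect_true(all(res_more$consensus %in% res1$consensus))
})

test_that("full determinism: same config reproduces the consensus result", {
  coh <- generate_cohort(tiny_design(n_proteins = 40, seed = 2))
  md <- md_t0(coh)
  mat <- log2_median_center(coh$intensities)
  cfg <- rf_config(seeds = 1:3, n_trees = 150, top_k = 8)
  expect_identical(run_consensus(mat, md, cfg)[c("accuracies", "consensus")],
                   run_consensus(mat, md, cfg)[c("accuracies", "consensus")])
})

test_that("Spearman age correlation matches the closed-form rank formula", {
  md <- tibble::tibble(sample_id = paste0("s", 1:6), timepoint = "T0",
                       age_years = c(1, 3, 4, 7, 9, 12))
  m <- rbind(
    inc = c(0.1, 0.5, 0.9, 1.2, 2.0, 3.3),    # strictly increasing: rho 1
    rev = c(6, 5, 4, 3, 2, 1),                # reversed ranks: rho -1
    mix = c(2.0, 1.1, 3.5, 0.7, 5.2, 4.1),
    flat = rep(1, 6)
  )
  colnames(m) <- md$sample_id
  out <- correlate_with_age(m, md, c("inc", "rev", "mix", "flat"))
  expect_equal(out$rho[out$protein_id == "inc"], 1)
  expect_equal(out$rho[out$protein_id == "rev"], -1)
  d <- rank(m["mix", ]) - rank(md$age_years)
  expect_equal(out$rho[out$protein_id == "mix"],
               1 - 6 * sum(d^2) / (6 * (36 - 1)))
  expect_true(is.na(out$rho[out$protein_id == "flat"]))
  expect_true(all(out$p_adjusted >= out$p_value, na.rm = TRUE))
})
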