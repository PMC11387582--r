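# Independent oracles used by both the unit and the acceptance tests.
# Each deliberately takes a different computational route from the package
# implementation it checks.

# Step-up FDR adjustment, written directly from the step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Pseudo-F via Gower double-centering: SS_total = trace of the centered
# inner-product matrix, SS_within from per-group centered blocks.
permanova_f_oracle <- function(dm, grp) {
  n <- nrow(dm)
  g <- -0.5 * dm^2
  j <- diag(n) - matrix(1 / n, n, n)
  gc <- j %*% g %*% j
  ss_total <- sum(diag(gc))
  ss_within <- 0
  for (lev in unique(grp)) {
    idx <- which(grp == lev)
    gi <- -0.5 * dm[idx, idx, drop = FALSE]^2
    ni <- length(idx)
    ji <- diag(ni) - matrix(1 / ni, ni, ni)
    ss_within <- ss_within + sum(diag(ji %*% gi %*% ji))
  }
  a <- length(unique(grp))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# Exact permutation p for two groups of 3 in n = 6 by enumerating all 20
# assignments of three samples to the first group.
permanova_p_enum_oracle <- function(dm, grp) {
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(ix) {
    g <- rep("b", 6); g[ix] <- "a"
    permanova_f_oracle(dm, g)
  })
  mean(f_all >= permanova_f_oracle(dm, grp) - 1e-12)
}

# Upper hypergeometric tail from binomial coefficients.
hyper_tail_oracle <- function(hits, set_size, bg_size, query_size) {
  ks <- hits:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(bg_size - set_size, query_size - ks)) /
    choose(bg_size, query_size)
}

# Greedy Ward agglomeration from raw coordinates: at each step merge the
# pair of clusters minimising |A||B|/(|A|+|B|) * ||centroid_A-centroid_B||^2
# (equivalent to the ward.D2 criterion on Euclidean distances, but computed
# from centroids, not Lance-Williams updates).
ward_merge_oracle <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE])
        cb <- colMeans(x[b, , drop = FALSE])
        cost <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges <- c(merges, list(merged))
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Member sets of each hclust merge node, for comparison with the oracle.
hclust_merge_sets <- function(hc) {
  members <- function(k) {
    if (k < 0) return(-k)
    sort(unlist(lapply(hc$merge[k, ], members)))
  }
  lapply(seq_len(nrow(hc$merge)), members)
}
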