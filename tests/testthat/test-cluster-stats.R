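test_that("the montage neighbourhood is symmetric, irreflexive and connected", {
  nb <- montage_neighbors()
  labels <- montage_1010()$label
  expect_setequal(names(nb), labels)
  for (ch in labels) {
    expect_gte(length(nb[[ch]]), 1)
    expect_false(ch %in% nb[[ch]])
    for (other in nb[[ch]]) expect_true(ch %in% nb[[other]])
  }
  adj <- channel_adjacency(labels)
  expect_true(isSymmetric(adj))
  expect_true(all(!diag(adj)))
})

test_that("identical paired data produce no significant cluster", {
  set.seed(5)
  a <- array(rnorm(10 * 8 * 3 * 5), c(10, 8, 3, 5))
  r <- cluster_permutation_test(a, a, paired = TRUE,
                                channels = cluster_channels, n_perm = 200)
  expect_true(nrow(r$clusters) == 0 || all(r$clusters$p_mc >= 0.05))
})

test_that("a single-channel effect cannot form a cluster when min_chan = 2", {
  # deterministic construction: differences in all channels except Pz have
  # exactly zero mean (t = 0), Pz carries a large effect
  n <- 10; nch <- 8; nf <- 2; nt <- 3
  d <- array(0, c(n, nch, nf, nt))
  d[seq(1, n, 2), , , ] <- -1
  d[seq(2, n, 2), , , ] <- 1
  jitter <- array(rep(seq(-0.1, 0.1, length.out = n), nch * nf * nt),
                  c(n, nch, nf, nt))
  d <- d + jitter
  d[, 4, , ] <- 5 + jitter[, 4, , ]      # channel Pz only
  a <- d; b <- array(0, dim(d))
  r <- cluster_permutation_test(a, b, paired = TRUE,
                                channels = cluster_channels, n_perm = 100,
                                min_chan = 2, seed = 3)
  expect_equal(nrow(r$clusters), 0)
  # with min_chan = 1 the same effect is found and spans a single channel
  r1 <- cluster_permutation_test(a, b, paired = TRUE,
                                 channels = cluster_channels, n_perm = 100,
                                 min_chan = 1, seed = 3)
  expect_gt(nrow(r1$clusters), 0)
  expect_equal(r1$clusters$n_channels[1], 1)
  expect_equal(cluster_channels[unique(r1$members[[1]]$channel)], "Pz")
})

test_that("an effect over three adjacent parietal channels is recovered", {
  set.seed(17)
  nf <- 4; nt <- 6
  a <- array(rnorm(15 * 8 * nf * nt), c(15, 8, nf, nt))
  b <- array(rnorm(15 * 8 * nf * nt), c(15, 8, nf, nt))
  a[, 4:6, 2:3, 2:5] <- a[, 4:6, 2:3, 2:5] + 1.5     # Pz, P3, P4
  r <- cluster_permutation_test(a, b, paired = FALSE,
                                channels = cluster_channels, n_perm = 1000,
                                seed = 7)
  expect_gt(nrow(r$clusters), 0)
  top <- r$clusters[1, ]
  expect_lt(top$p_mc, 0.05)
  expect_equal(top$polarity, 1)
  found <- cluster_channels[unique(r$members[[1]]$channel)]
  expect_gte(length(intersect(found, c("Pz", "P3", "P4"))), 2)
})

test_that("cluster results are reproducible and clusters respect adjacency", {
  set.seed(9)
  a <- array(rnorm(12 * 8 * 3 * 4), c(12, 8, 3, 4))
  b <- array(rnorm(12 * 8 * 3 * 4), c(12, 8, 3, 4))
  a[, 4:6, , ] <- a[, 4:6, , ] + 1
  r1 <- cluster_permutation_test(a, b, paired = TRUE,
                                 channels = cluster_channels, n_perm = 300,
                                 seed = 42)
  r2 <- cluster_permutation_test(a, b, paired = TRUE,
                                 channels = cluster_channels, n_perm = 300,
                                 seed = 42)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$perm_max, r2$perm_max)
  expect_gte(min(r1$clusters$p_mc), 1 / (r1$n_perm + 1))
  # independent connectivity check of the reported members via a double loop
  adj <- channel_adjacency(cluster_channels)
  for (m in r1$members) {
    if (nrow(m) < 2) next
    linked <- matrix(FALSE, nrow(m), nrow(m))
    for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) {
      same_ch <- m$channel[i] == m$channel[j]
      grid_adj <- same_ch &&
        (abs(m$freq_index[i] - m$freq_index[j]) +
           abs(m$time_index[i] - m$time_index[j])) == 1
      chan_adj <- adj[m$channel[i], m$channel[j]] &&
        m$freq_index[i] == m$freq_index[j] &&
        m$time_index[i] == m$time_index[j]
      linked[i, j] <- grid_adj || chan_adj
    }
    # connected: repeated squaring of the reachability matrix
    reach <- linked | diag(nrow(m)) > 0
    for (k in seq_len(ceiling(log2(nrow(m))) + 1)) {
      reach <- (reach %*% reach) > 0
    }
    expect_true(all(reach))
  }
})

test_that("t-tests report the matching Cohen's d", {
  x <- c(2.1, 3.4, 2.8, 3.0, 2.5)
  expect_equal(ttest_effsize(x, x, paired = TRUE)$t, 0)
  expect_equal(ttest_effsize(x, x, paired = TRUE)$cohen_d, 0)
  # differences (0, 1, 2): mean 1, sd 1 -> d = 1
  d <- ttest_effsize(c(1, 2, 3), c(1, 1, 1), paired = TRUE)
  expect_equal(d$cohen_d, 1)
  # hand-computed two-sample pooled t for two fixed 5-element samples
  u <- c(1, 2, 3, 4, 5); v <- c(2, 4, 6, 8, 10)
  sp2 <- (4 * var(u) + 4 * var(v)) / 8
  t_hand <- (mean(u) - mean(v)) / sqrt(sp2 * (2 / 5))
  got <- ttest_effsize(u, v)
  expect_equal(got$t, t_hand)
  expect_equal(got$df, 8)
  expect_equal(got$cohen_d, (mean(u) - mean(v)) / sqrt(sp2))
  # one-sample test against zero
  one <- ttest_effsize(c(0.1, 0.3, 0.2, 0.4))
  expect_equal(one$df, 3)
  expect_error(ttest_effsize(rep(1, 5), rep(2, 5)), "variance")
})

test_that("Pearson correlations recover exact and null relations", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(3, 6)), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "lengths")
  set.seed(77)
  r <- vapply(1:1000, function(k) pearson_correlation(rnorm(20), rnorm(20))$r, 0)
  expect_lt(abs(mean(r)), 0.02)
})
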