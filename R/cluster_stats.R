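#' Cluster-based permutation test over channel x frequency x time data
#'
#' Nonparametric control of multiple comparisons for EEG time-frequency
#' contrasts. Pointwise t-tests (dependent for `paired = TRUE`, pooled
#' two-sample otherwise) are thresholded at the two-tailed `cluster_alpha`
#' quantile; suprathreshold points are clustered by spatio-spectro-temporal
#' adjacency (neighbouring channels at the same grid point, or adjacent
#' frequency/time steps within a channel); clusters spanning fewer than
#' `min_chan` channels are discarded; and the maximum summed-t cluster
#' statistic is compared against its permutation distribution (sign flips of
#' paired differences, or group-label shuffles). Positive and negative
#' clusters are tested against their own tails and Monte-Carlo p-values are
#' reported two-tailed (per-tail `(b + 1) / (n_perm + 1)`, doubled and capped
#' at 1).
#'
#' @param data_a,data_b numeric arrays `subjects x channels x freqs x times`
#'   (a 3-D array is treated as having one frequency). For paired tests the
#'   subject dimensions must match.
#' @param paired dependent-samples test when TRUE.
#' @param channels channel labels, one per channel dimension entry.
#' @param neighbors neighbour list as from [montage_neighbors()].
#' @param n_perm number of permutations (default 1000). For paired designs
#'   all `2^n` sign patterns are enumerated when `2^n <= n_perm`.
#' @param cluster_alpha two-tailed alpha of the cluster-forming pointwise
#'   test (default 0.05).
#' @param min_chan minimal number of distinct channels a cluster must span
#'   (default 2).
#' @param seed integer RNG seed for the Monte-Carlo permutations.
#' @return object of class `cluster_result`: list with `clusters` (data.frame
#'   `id`, `polarity`, `stat`, `p_mc`, `n_points`, `n_channels`), `members`
#'   (list of data.frames `channel`, `freq_index`, `time_index`), `tmap`
#'   (channels x freqs x times t-values), `t_crit`, and the test parameters.
#' @export
cluster_permutation_test <- function(data_a, data_b, paired = FALSE,
                                     channels, neighbors = montage_neighbors(),
                                     n_perm = 1000, cluster_alpha = 0.05,
                                     min_chan = 2, seed = 1) {
  if (n_perm < 1) stopf("`n_perm` must be >= 1")
  data_a <- as_4d(data_a); data_b <- as_4d(data_b)
  dims <- dim(data_a)[-1]
  if (!all(dim(data_b)[-1] == dims)) stopf("data_a and data_b grids differ")
  if (length(channels) != dims[1]) stopf("`channels` length != channel dimension")
  adj <- channel_adjacency(channels, neighbors)
  n_pts <- prod(dims)
  flat <- function(x) matrix(x, nrow = dim(x)[1], ncol = n_pts)
  if (paired) {
    if (dim(data_a)[1] != dim(data_b)[1]) {
      stopf("paired test requires equal subject counts")
    }
    n <- dim(data_a)[1]
    if (n < 2) stopf("need >= 2 subjects")
    D <- flat(data_a) - flat(data_b)
    df <- n - 1
    t_crit <- stats::qt(1 - cluster_alpha / 2, df)
    sumsq <- colSums(D^2)
    t_from_signs <- function(S) {      # S: n_perm x n of +/-1
      M <- (S %*% D) / n
      v <- (matrix(sumsq, nrow(S), n_pts, byrow = TRUE) - n * M^2) / (n - 1)
      v[v < .Machine$double.eps] <- NA
      M / sqrt(v / n)
    }
    t_obs <- t_from_signs(matrix(1, 1, n))[1, ]
    if (2^n <= n_perm) {
      S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      storage.mode(S) <- "double"
    } else {
      S <- withr::with_seed(as.integer(seed), {
        out <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
        out <- unique(out)
        tries <- 0L
        while (nrow(out) < n_perm && tries < 50L) {
          extra <- matrix(sample(c(-1, 1), (n_perm - nrow(out)) * n,
                                 replace = TRUE), ncol = n)
          out <- unique(rbind(out, extra))
          tries <- tries + 1L
        }
        out[seq_len(min(n_perm, nrow(out))), , drop = FALSE]
      })
    }
    t_perm <- t_from_signs(S)
  } else {
    n1 <- dim(data_a)[1]; n2 <- dim(data_b)[1]
    if (n1 < 2 || n2 < 2) stopf("need >= 2 subjects per group")
    Z <- rbind(flat(data_a), flat(data_b))
    N <- n1 + n2
    df <- N - 2
    t_crit <- stats::qt(1 - cluster_alpha / 2, df)
    tot <- colSums(Z)
    totsq <- colSums(Z^2)
    t_from_idx <- function(I) {        # I: n_perm x N membership (1 = group A)
      SA <- I %*% Z
      SA2 <- I %*% Z^2
      MA <- SA / n1
      MB <- (matrix(tot, nrow(I), n_pts, byrow = TRUE) - SA) / n2
      ssA <- SA2 - n1 * MA^2
      ssB <- matrix(totsq, nrow(I), n_pts, byrow = TRUE) - SA2 - n2 * MB^2
      sp2 <- (ssA + ssB) / df
      sp2[sp2 < .Machine$double.eps] <- NA
      (MA - MB) / sqrt(sp2 * (1 / n1 + 1 / n2))
    }
    I_obs <- matrix(0, 1, N); I_obs[1, seq_len(n1)] <- 1
    t_obs <- t_from_idx(I_obs)[1, ]
    I <- withr::with_seed(as.integer(seed), {
      t(vapply(seq_len(n_perm), function(k) {
        v <- numeric(N); v[sample.int(N, n1)] <- 1; v
      }, numeric(N)))
    })
    t_perm <- t_from_idx(I)
  }
  t_obs[is.na(t_obs)] <- 0
  tmap <- array(t_obs, dims)
  # observed clusters per polarity
  obs_pos <- find_clusters(tmap, t_crit, adj, min_chan, polarity = 1)
  obs_neg <- find_clusters(tmap, t_crit, adj, min_chan, polarity = -1)
  # permutation distribution of the max cluster statistic per tail
  max_pos <- numeric(nrow(t_perm))
  max_neg <- numeric(nrow(t_perm))
  for (p in seq_len(nrow(t_perm))) {
    tp <- t_perm[p, ]
    tp[is.na(tp)] <- 0
    tm <- array(tp, dims)
    cp <- find_clusters(tm, t_crit, adj, min_chan, polarity = 1)
    cn <- find_clusters(tm, t_crit, adj, min_chan, polarity = -1)
    max_pos[p] <- if (length(cp$stat)) max(cp$stat) else 0
    max_neg[p] <- if (length(cn$stat)) min(cn$stat) else 0
  }
  np <- nrow(t_perm)
  mk <- function(cl, polarity, ref) {
    if (!length(cl$stat)) return(NULL)
    p_mc <- vapply(cl$stat, function(s) {
      b <- if (polarity > 0) sum(ref >= s) else sum(ref <= s)
      min(1, 2 * (b + 1) / (np + 1))
    }, 0)
    data.frame(polarity = polarity, stat = cl$stat, p_mc = p_mc,
               n_points = cl$n_points, n_channels = cl$n_channels)
  }
  tab <- rbind(mk(obs_pos, 1, max_pos), mk(obs_neg, -1, max_neg))
  members <- c(obs_pos$members, obs_neg$members)
  if (is.null(tab)) {
    tab <- data.frame(polarity = integer(0), stat = numeric(0),
                      p_mc = numeric(0), n_points = integer(0),
                      n_channels = integer(0))
  } else {
    ord <- order(tab$p_mc, -abs(tab$stat))
    tab <- tab[ord, , drop = FALSE]
    members <- members[ord]
    tab$id <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  }
  structure(list(clusters = tab, members = members, tmap = tmap,
                 t_crit = t_crit, channels = channels, paired = paired,
                 n_perm = np, cluster_alpha = cluster_alpha,
                 min_chan = min_chan,
                 perm_max = list(pos = max_pos, neg = max_neg)),
            class = "cluster_result")
}

as_4d <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 3 || length(d) > 4) {
    stopf("data must be a subjects x channels x (freqs x) times array")
  }
  if (length(d) == 3) x <- array(x, c(d[1], d[2], 1, d[3]))
  x
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s test, %d permutations, t_crit = %.3f\n",
              if (x$paired) "paired" else "unpaired", x$n_perm, x$t_crit))
  if (nrow(x$clusters) == 0) cat("  no clusters\n") else
    print(x$clusters[, c("id", "polarity", "stat", "p_mc", "n_points", "n_channels")])
  invisible(x)
}

# connected components of suprathreshold points in a channels x freqs x times
# t-map. Adjacency: same channel and one grid step in frequency OR time, or
# neighbouring channels at the same (freq, time). Returns cluster statistics
# (summed t) and member coordinates; clusters spanning < min_chan distinct
# channels are dropped.
find_clusters <- function(tmap, t_crit, adj, min_chan, polarity = 1) {
  dims <- dim(tmap)
  mask <- if (polarity > 0) tmap > t_crit else tmap < -t_crit
  idx <- which(mask)
  out <- list(stat = numeric(0), n_points = integer(0),
              n_channels = integer(0), members = list())
  if (length(idx) == 0) return(out)
  nch <- dims[1]; nf <- dims[2]; nt <- dims[3]
  coord <- arrayInd(idx, dims)
  key <- (coord[, 3] - 1) * (nch * nf) + (coord[, 2] - 1) * nch + coord[, 1]
  lookup <- integer(nch * nf * nt)
  lookup[key] <- seq_along(idx)
  nb_list <- lapply(seq_len(nch), function(c) which(adj[c, ]))
  visited <- logical(length(idx))
  for (s in seq_along(idx)) {
    if (visited[s]) next
    queue <- s
    visited[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, cur)
      ch <- coord[cur, 1]; fr <- coord[cur, 2]; ti <- coord[cur, 3]
      cand <- integer(0)
      if (fr > 1) cand <- c(cand, (ti - 1) * nch * nf + (fr - 2) * nch + ch)
      if (fr < nf) cand <- c(cand, (ti - 1) * nch * nf + fr * nch + ch)
      if (ti > 1) cand <- c(cand, (ti - 2) * nch * nf + (fr - 1) * nch + ch)
      if (ti < nt) cand <- c(cand, ti * nch * nf + (fr - 1) * nch + ch)
      nbs <- nb_list[[ch]]
      if (length(nbs)) {
        cand <- c(cand, (ti - 1) * nch * nf + (fr - 1) * nch + nbs)
      }
      hit <- lookup[cand]
      hit <- hit[hit > 0]
      hit <- hit[!visited[hit]]
      if (length(hit)) {
        visited[hit] <- TRUE
        queue <- c(queue, hit)
      }
    }
    n_channels <- length(unique(coord[comp, 1]))
    if (n_channels < min_chan) next
    out$stat <- c(out$stat, sum(tmap[idx[comp]]))
    out$n_points <- c(out$n_points, length(comp))
    out$n_channels <- c(out$n_channels, n_channels)
    out$members <- c(out$members, list(data.frame(
      channel = coord[comp, 1], freq_index = coord[comp, 2],
      time_index = coord[comp, 3])))
  }
  out
}

#' t-test with Cohen's d effect size
#'
#' Dependent, independent (pooled variance) or one-sample t-test with the
#' matching Cohen's d: mean difference over the SD of the differences
#' (paired/one-sample) or over the pooled SD (unpaired).
#'
#' @param x numeric vector.
#' @param y optional second sample (omit for a one-sample test against `mu`).
#' @param paired dependent-samples test when TRUE.
#' @param mu null value for the one-sample test (default 0).
#' @return list with `t`, `df`, `p`, `cohen_d`, `mean_diff`.
#' @export
ttest_effsize <- function(x, y = NULL, paired = FALSE, mu = 0) {
  if (is.null(y)) {
    if (length(x) < 2) stopf("need n >= 2")
    if (stats::sd(x) == 0) stopf("zero variance")
    tt <- stats::t.test(x, mu = mu)
    d <- (mean(x) - mu) / stats::sd(x)
    md <- mean(x) - mu
  } else if (paired) {
    if (length(x) != length(y)) stopf("paired test needs equal lengths")
    dif <- x - y
    if (length(dif) < 2) stopf("need n >= 2")
    if (stats::sd(dif) == 0 && mean(dif) == 0) {
      return(list(t = 0, df = length(dif) - 1, p = 1, cohen_d = 0, mean_diff = 0))
    }
    if (stats::sd(dif) == 0) stopf("zero variance of differences")
    tt <- stats::t.test(x, y, paired = TRUE)
    d <- mean(dif) / stats::sd(dif)
    md <- mean(dif)
  } else {
    if (length(x) < 2 || length(y) < 2) stopf("need n >= 2 per sample")
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    if (sp2 == 0) stopf("zero variance")
    tt <- stats::t.test(x, y, var.equal = TRUE)
    d <- (mean(x) - mean(y)) / sqrt(sp2)
    md <- mean(x) - mean(y)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohen_d = d, mean_diff = md)
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stopf("need equal lengths >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
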