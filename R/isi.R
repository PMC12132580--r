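# Inter-spike-interval structure: histograms, ISI-PCA, the bursting index and
# label-shuffle tests.

#' Inter-spike-interval histogram
#'
#' Successive spike-time differences over the whole recording, binned at
#' 0.4 ms up to `max_isi_ms`, normalized by the maximum bin so the histogram
#' peaks at 1 (relative probability).
#'
#' @param spike_times_s sorted spike times (s; needs >= 2 spikes).
#' @param bin_ms bin width (ms, default 0.4).
#' @param max_isi_ms histogram support cap (ms, default 100).
#' @return Object of class `isi_profile`: `bin_centers_ms`, `hist` (max 1),
#'   `peak_isi_ms`, `n_isi` (ISIs within support).
#' @export
isi_histogram <- function(spike_times_s, bin_ms = 0.4, max_isi_ms = 100) {
  if (length(spike_times_s) < 2) stop("needs at least 2 spikes")
  isi_ms <- diff(spike_times_s) * 1000
  edges <- seq(0, max_isi_ms, by = bin_ms)
  counts <- graphics::hist(isi_ms[isi_ms >= 0 & isi_ms < max_isi_ms],
                           breaks = edges, plot = FALSE)$counts
  mx <- max(counts)
  h <- if (mx > 0) counts / mx else counts
  centers <- edges[-1] - bin_ms / 2
  structure(list(bin_centers_ms = centers, hist = h,
                 peak_isi_ms = centers[which.max(counts)],
                 n_isi = sum(counts)),
            class = "isi_profile")
}

#' PCA of ISI histograms
#'
#' Principal components of the mean-centered max-normalized ISI histograms,
#' with fixed sign conventions so downstream indices are reproducible: PC1 is
#' oriented toward short-ISI concentration (its mean over the first
#' `short_isi_ms` of bins exceeds its overall mean), so units whose ISI mass
#' concentrates at short intervals load positively; PC3 is oriented so its
#' mean over the first `short_isi_ms` bins is negative (the short-ISI "dip"
#' that bursty units load negatively on). With these orientations the bursting
#' index `l1 - l3` increases with burst-like ISI structure; a mean-positive
#' PC1 rule inverts the index on Poisson-dominated populations (see the
#' methods vignette).
#'
#' @param hist_matrix units x bins matrix of [isi_histogram()] histograms.
#' @param bin_ms histogram bin width (ms), used to locate the short-ISI bins.
#' @param short_isi_ms extent of the short-ISI region for the PC3 sign rule.
#' @return Object of class `isi_pca`: `components` (bins x K rotation),
#'   `loadings` (units x K scores), `explained_variance`, `center`,
#'   `sign_flipped` (record of orientation choices), `degenerate` flag.
#' @export
isi_pca <- function(hist_matrix, bin_ms = 0.4, short_isi_ms = 10) {
  stopifnot(nrow(hist_matrix) >= 3, ncol(hist_matrix) >= 3)
  if (all(apply(hist_matrix, 2, stats::sd) == 0)) {
    warning("zero-variance ISI matrix: degenerate PCA")
    k <- min(dim(hist_matrix))
    return(structure(list(components = matrix(0, ncol(hist_matrix), k),
                          loadings = matrix(0, nrow(hist_matrix), k),
                          explained_variance = rep(0, k),
                          center = colMeans(hist_matrix),
                          sign_flipped = logical(k), degenerate = TRUE),
                     class = "isi_pca"))
  }
  pc <- stats::prcomp(hist_matrix, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  sco <- pc$x
  k <- ncol(rot)
  flipped <- logical(k)
  short <- seq_len(min(ncol(hist_matrix), round(short_isi_ms / bin_ms)))
  if (mean(rot[short, 1]) < mean(rot[, 1])) {
    rot[, 1] <- -rot[, 1]
    sco[, 1] <- -sco[, 1]
    flipped[1] <- TRUE
  }
  if (k >= 3) {
    if (mean(rot[short, 3]) > 0) {
      rot[, 3] <- -rot[, 3]
      sco[, 3] <- -sco[, 3]
      flipped[3] <- TRUE
    }
  }
  structure(list(components = rot, loadings = sco,
                 explained_variance = pc$sdev^2,
                 center = pc$center, sign_flipped = flipped,
                 degenerate = FALSE),
            class = "isi_pca")
}

#' Bursting index from ISI-PCA loadings
#'
#' The difference between a unit's first and third principal-component
#' loadings, `l1 - l3`, computed after the sign conventions of [isi_pca()]
#' are applied. Large values indicate peaky, burst-like ISI structure.
#'
#' @param l1,l3 loading vectors (or scalars) on PC1 and PC3, or an `isi_pca`
#'   object as the first argument.
#' @return Numeric bursting index per unit.
#' @export
bursting_index <- function(l1, l3 = NULL) {
  if (inherits(l1, "isi_pca")) {
    stopifnot(ncol(l1$loadings) >= 3)
    return(l1$loadings[, 1] - l1$loadings[, 3])
  }
  l1 - l3
}

#' Label-shuffle test of per-cluster medians
#'
#' For each of `n_shuffles` permutations, cluster labels are shuffled across
#' units (preserving cluster sizes) and per-cluster medians recomputed; a
#' cluster is significant when its observed median falls outside the 2.5-97.5
#' percentile band of its shuffled medians.
#'
#' @param values per-unit statistic (e.g. bursting index, OI).
#' @param cluster_labels per-unit cluster labels (>= 2 clusters, no empty
#'   cluster).
#' @param n_shuffles number of permutations (default 500).
#' @param seed integer seed.
#' @param probs percentile band (default `c(0.025, 0.975)`).
#' @return Object of class `shuffle_test`: data frame `clusters` (cluster,
#'   observed_median, lo, hi, significant) and `n_shuffles`.
#' @export
shuffle_test <- function(values, cluster_labels, n_shuffles = 500L, seed = 1L,
                         probs = c(0.025, 0.975)) {
  stopifnot(length(values) == length(cluster_labels))
  labs <- as.factor(cluster_labels)
  if (nlevels(labs) < 2) stop("needs at least 2 clusters")
  if (any(table(labs) == 0)) stop("empty cluster")
  obs <- tapply(values, labs, stats::median)
  sh <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      tapply(values[sample.int(length(values))], labs, stats::median)
    }, numeric(nlevels(labs)))
  })
  sh <- matrix(sh, nrow = nlevels(labs))
  lo <- apply(sh, 1, stats::quantile, probs = probs[1])
  hi <- apply(sh, 1, stats::quantile, probs = probs[2])
  structure(list(clusters = data.frame(cluster = levels(labs),
                                       observed_median = as.numeric(obs),
                                       lo = lo, hi = hi,
                                       significant = obs < lo | obs > hi,
                                       row.names = NULL),
                 n_shuffles = n_shuffles),
            class = "shuffle_test")
}
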