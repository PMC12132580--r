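# Multichannel waveform landmarks, propagation velocities about the soma, the
# asymmetry index, and bootstrap comparisons.

#' Extract per-channel trough and peak landmarks
#'
#' Per channel: trough time = (sub-sample interpolated) argmin of the channel
#' waveform, peak time = argmax after the trough; both referenced to the soma
#' channel trough (soma trough time = 0 by definition). Channels whose
#' waveform is flat are excluded and flagged.
#'
#' @param template a `waveform_template`.
#' @return Data frame: `channel`, `offset_um` (signed distance from the soma
#'   channel, positive toward the pia), `trough_ms`, `peak_ms`, `usable`.
#' @export
extract_landmarks <- function(template) {
  v <- template$voltages
  dt_ms <- 1000 / template$sampling_rate_hz
  nch <- ncol(v)
  soma <- template$soma_channel
  one <- function(ci) {
    w <- v[, ci]
    if (max(w) - min(w) < 1e-12) return(c(NA_real_, NA_real_))
    i_tr <- which.min(w)
    t_tr <- parabolic_peak(-w, i_tr) * dt_ms
    if (i_tr >= length(w)) return(c(t_tr, NA_real_))
    i_pk <- i_tr + which.max(w[(i_tr + 1):length(w)])
    c(t_tr, parabolic_peak(w, i_pk) * dt_ms)
  }
  lm <- vapply(seq_len(nch), one, numeric(2))
  t0 <- lm[1, soma]
  data.frame(channel = seq_len(nch),
             offset_um = template$channel_positions_um$y,
             trough_ms = lm[1, ] - t0,
             peak_ms = lm[2, ] - t0,
             usable = !is.na(lm[1, ]))
}

#' Trim outlier trough times across units within a cluster
#'
#' For each channel, marks units whose trough time falls outside the central
#' 95% of the cluster's trough-time distribution at that channel, so they are
#' excluded from velocity regressions.
#'
#' @param trough_mat units x channels matrix of trough times (ms).
#' @param central fraction of the distribution kept (default 0.95).
#' @return Logical matrix of the same shape; `TRUE` = keep.
#' @export
trim_trough_outliers <- function(trough_mat, central = 0.95) {
  a <- (1 - central) / 2
  keep <- !is.na(trough_mat)
  for (j in seq_len(ncol(trough_mat))) {
    x <- trough_mat[, j]
    ok <- !is.na(x)
    if (sum(ok) < 3) next
    q <- stats::quantile(x[ok], c(a, 1 - a))
    keep[, j] <- ok & x >= q[1] & x <= q[2]
  }
  keep
}

#' Propagation velocities above and below the soma
#'
#' Ordinary least squares of trough time (ms) on signed channel offset (mm,
#' positive toward the pia), fitted separately for channels above
#' (`offset > 0`) and below (`offset < 0`) the soma. Slopes are inverse
#' velocities in ms/mm.
#'
#' @param trough_ms per-channel trough times relative to the soma trough.
#' @param offset_um signed channel offsets (um, positive toward the pia).
#' @param usable optional logical mask of channels to include.
#' @return List: `v_inv_above`, `v_inv_below` (ms/mm; `NA` when a side has
#'   fewer than 2 usable channels).
#' @export
propagation_velocity <- function(trough_ms, offset_um, usable = NULL) {
  if (is.null(usable)) usable <- !is.na(trough_ms)
  d_mm <- offset_um / 1000
  fit_side <- function(sel) {
    sel <- sel & usable
    if (sum(sel) < 2) return(NA_real_)
    x <- d_mm[sel]
    y <- trough_ms[sel]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  list(v_inv_above = fit_side(offset_um > 0),
       v_inv_below = fit_side(offset_um < 0))
}

#' Asymmetry index of propagation velocities
#'
#' Signed orthogonal distance of the point `(x0, y0) = (v_inv_below,
#' v_inv_above)` from the diagonal `y = -x`: `SI = (x0 + y0) / sqrt(2)`
#' (line coefficients a = 1, b = 1, c = 0). Zero for perfectly symmetric
#' bidirectional propagation; the unsigned index drops the direction of the
#' dominance.
#'
#' @param v_inv_below,v_inv_above inverse velocities (ms/mm).
#' @return List: `si_signed`, `si_unsigned`.
#' @export
asymmetry_index <- function(v_inv_below, v_inv_above) {
  si <- (v_inv_below + v_inv_above) / sqrt(2)
  list(si_signed = si, si_unsigned = abs(si))
}

#' Per-unit propagation profile
#'
#' Convenience wrapper: landmarks, side velocities and asymmetry index for one
#' template.
#'
#' @param template a `waveform_template`.
#' @return Object of class `propagation_profile` with the landmark table,
#'   `v_inv_above`, `v_inv_below`, `si_signed`, `si_unsigned`.
#' @export
propagation_profile <- function(template) {
  lm <- extract_landmarks(template)
  v <- propagation_velocity(lm$trough_ms, lm$offset_um, lm$usable)
  si <- asymmetry_index(v$v_inv_below, v$v_inv_above)
  structure(c(list(landmarks = lm), v, si), class = "propagation_profile")
}

#' Bootstrap comparison of per-cluster slope statistics
#'
#' Resamples units with replacement within each cluster (`n_resamples` times)
#' and reports the bootstrap standard deviation of the cluster mean, the
#' pairwise significance matrix (99% percentile CI of the difference of two
#' independent cluster resamples excluding 0), and whether each cluster's mean
#' differs from zero (95% CI excluding 0).
#'
#' @param values per-unit statistic (e.g. `v_inv_below` or the asymmetry
#'   index).
#' @param cluster_labels per-unit cluster labels (each cluster >= 3 units).
#' @param n_resamples bootstrap resamples (default 500).
#' @param seed integer seed.
#' @param pairwise_level confidence level of the pairwise test (default 0.99).
#' @param zero_level confidence level of the nonzero test (default 0.95).
#' @return Object of class `bootstrap_comparison`: `clusters` data frame
#'   (cluster, mean, boot_sd, nonzero), `pairwise_significant` (0/1 symmetric
#'   matrix, zero diagonal), `n_resamples`.
#' @export
bootstrap_compare <- function(values, cluster_labels, n_resamples = 500L,
                              seed = 1L, pairwise_level = 0.99,
                              zero_level = 0.95) {
  labs <- as.factor(cluster_labels)
  sizes <- table(labs)
  if (any(sizes < 3)) {
    stop("every cluster needs >= 3 units; too small: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  }
  K <- nlevels(labs)
  boot_means <- with_seed(seed, {
    vapply(levels(labs), function(k) {
      x <- values[labs == k]
      idx <- matrix(sample.int(length(x), length(x) * n_resamples,
                               replace = TRUE), ncol = n_resamples)
      colMeans(matrix(x[idx], ncol = n_resamples))
    }, numeric(n_resamples))
  })
  a_pair <- (1 - pairwise_level) / 2
  a_zero <- (1 - zero_level) / 2
  sig <- matrix(0L, K, K, dimnames = list(levels(labs), levels(labs)))
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      d <- boot_means[, i] - boot_means[, j]
      ci <- stats::quantile(d, c(a_pair, 1 - a_pair))
      if (ci[1] > 0 || ci[2] < 0) sig[i, j] <- sig[j, i] <- 1L
    }
  }
  nonzero <- vapply(seq_len(K), function(i) {
    ci <- stats::quantile(boot_means[, i], c(a_zero, 1 - a_zero))
    as.integer(ci[1] > 0 || ci[2] < 0)
  }, 0L)
  structure(list(clusters = data.frame(cluster = levels(labs),
                                       mean = as.numeric(tapply(values, labs, mean)),
                                       boot_sd = apply(boot_means, 2, stats::sd),
                                       nonzero = nonzero, row.names = NULL),
                 pairwise_significant = sig, n_resamples = n_resamples),
            class = "bootstrap_comparison")
}
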