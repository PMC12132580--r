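# Trial-based normalized cross-correlograms with analytic interval-jitter
# correction, significance classification, lead-lag (correlogram asymmetry)
# index and the cluster-pair connectivity graph.
#
# Raw CCG for an ordered pair (reference j, target k):
#   CCG_{j<-k}(tau) = (1/M) sum_i sum_t x_ji(t) x_ki(t+tau) / (theta(tau) lj lk)
# with binary trial rasters x, theta(tau) = N - |tau| the triangular overlap
# correction, and lambda the mean spikes per analysis bin, so independent
# stationary trains sit at baseline 1. Positive lags mean the reference leads.

# Binary raster bin indices (1..N) per trial for one unit.
bin_rasters <- function(spike_times_s, trials, window_s, bin_s) {
  N <- round((window_s[2] - window_s[1]) / bin_s)
  lapply(trials$onset_s, function(o) {
    s <- spike_times_s[spike_times_s >= o + window_s[1] &
                         spike_times_s < o + window_s[2]]
    unique(floor((s - o - window_s[1]) / bin_s) + 1L)
  })
}

#' Trial-based normalized cross-correlogram
#'
#' Computes the raw CCG of an ordered unit pair from binary trial rasters over
#' the analysis window (default 0.4-1.0 s after stimulus onset, 1 ms bins,
#' lags to +/-100 ms), normalized by the triangular overlap factor and the
#' per-bin rate product (so independent stationary trains give 1). Positive
#' lags indicate the reference unit leading the target.
#'
#' @param spikes_j,spikes_k absolute spike times (s) of the reference and
#'   target unit.
#' @param trials trial data frame with `onset_s` (M >= 2 trials).
#' @param window_s analysis window relative to onset (s).
#' @param bin_ms CCG bin width (ms).
#' @param max_lag_ms maximum lag (ms).
#' @param normalization `"rate_product"` (the product lambda_j * lambda_k) or
#'   `"geometric_mean"` (sqrt of the product).
#' @return Object of class `ccg_result`: `lags_ms`, `raw`, `corrected`
#'   (`NULL` until [jitter_correct()]), `pair_counts`, `M`, `N`, `theta`,
#'   `lambda_j`, `lambda_k`, plus the rasters needed for jitter correction.
#' @export
compute_ccg <- function(spikes_j, spikes_k, trials,
                        window_s = c(0.4, 1.0), bin_ms = 1, max_lag_ms = 100,
                        normalization = c("rate_product", "geometric_mean")) {
  normalization <- match.arg(normalization)
  M <- nrow(trials)
  if (M < 2) stop("needs at least 2 trials")
  bin_s <- bin_ms / 1000
  N <- round((window_s[2] - window_s[1]) / bin_s)
  L <- round(max_lag_ms / bin_ms)
  if (L >= N) stop("max lag must be smaller than the analysis window")
  rj <- bin_rasters(spikes_j, trials, window_s, bin_s)
  rk <- bin_rasters(spikes_k, trials, window_s, bin_s)
  nj <- sum(lengths(rj))
  nk <- sum(lengths(rk))
  if (nj == 0 || nk == 0) stop("a unit has zero spikes in the analysis window")
  counts <- integer(2L * L + 1L)
  for (i in seq_len(M)) {
    if (length(rj[[i]]) == 0 || length(rk[[i]]) == 0) next
    d <- rep(rk[[i]], each = length(rj[[i]])) - rep(rj[[i]], length(rk[[i]]))
    d <- d[d >= -L & d <= L]
    if (length(d) > 0) counts <- counts + tabulate(d + L + 1L, 2L * L + 1L)
  }
  lags <- seq(-L, L)
  theta <- N - abs(lags)
  lambda_j <- nj / (M * N)
  lambda_k <- nk / (M * N)
  denom <- if (normalization == "rate_product") lambda_j * lambda_k else
    sqrt(lambda_j * lambda_k)
  raw <- counts / (M * theta * denom)
  structure(list(lags_ms = lags * bin_ms, raw = raw, corrected = NULL,
                 pair_counts = counts, M = M, N = N, bin_ms = bin_ms,
                 theta = theta, lambda_j = lambda_j, lambda_k = lambda_k,
                 normalization = normalization,
                 rasters = list(j = rj, k = rk)),
            class = "ccg_result")
}

# Linear cross-correlation sum cc(tau) = sum_t x[t] y[t+tau], tau in -L..L,
# via one FFT over trial-concatenated vectors padded with L+1 zeros.
cross_corr_fft <- function(x, y, L) {
  n <- length(x)
  np <- stats::nextn(n + L + 1L, c(2, 3, 5))
  xp <- c(x, rep(0, np - n))
  yp <- c(y, rep(0, np - n))
  # circular cross-correlation; zero padding >= L kills the wrap-around
  r <- Re(stats::fft(stats::fft(yp) * Conj(stats::fft(xp)), inverse = TRUE)) / np
  c(r[(np - L + 1L):np], r[1:(L + 1L)]) # tau = -L..L
}

#' Jitter correction of a cross-correlogram
#'
#' Subtracts the analytic expectation of the CCG under interval jitter: spikes
#' are (conceptually) redistributed uniformly within non-overlapping windows of
#' `jitter_ms` (anchored at the analysis-window start), independently per
#' train, preserving per-window spike counts. This removes rate covariation
#' slower than the jitter window while leaving fine-timescale structure. The
#' expectation is computed exactly from per-window counts (no Monte-Carlo
#' surrogates), so the result is deterministic.
#'
#' @param ccg a [compute_ccg()] result.
#' @param jitter_ms jitter window (ms; must be >= the CCG bin).
#' @return The `ccg_result` with `corrected` (raw minus jitter expectation,
#'   same normalization) and `jitter_expectation` filled in.
#' @export
jitter_correct <- function(ccg, jitter_ms = 25) {
  stopifnot(inherits(ccg, "ccg_result"))
  if (jitter_ms < ccg$bin_ms) stop("jitter window smaller than the CCG bin")
  W <- round(jitter_ms / ccg$bin_ms)
  N <- ccg$N
  L <- (length(ccg$lags_ms) - 1L) %/% 2L
  win_of <- (seq_len(N) - 1L) %/% W + 1L
  win_len <- tabulate(win_of)
  pad <- L + 1L
  expect_vec <- function(raster_bins) {
    cw <- tabulate(win_of[raster_bins], length(win_len))
    p <- (cw / win_len)[win_of]
    c(p, rep(0, pad))
  }
  X <- unlist(lapply(ccg$rasters$j, expect_vec), use.names = FALSE)
  Y <- unlist(lapply(ccg$rasters$k, expect_vec), use.names = FALSE)
  exp_counts <- cross_corr_fft(X, Y, L)
  denom <- if (ccg$normalization == "rate_product") {
    ccg$lambda_j * ccg$lambda_k
  } else sqrt(ccg$lambda_j * ccg$lambda_k)
  expectation <- exp_counts / (ccg$M * ccg$theta * denom)
  ccg$jitter_expectation <- expectation
  ccg$jitter_ms <- jitter_ms
  ccg$corrected <- ccg$raw - expectation
  ccg
}

#' Classify a corrected CCG as excitatory, inhibitory or not significant
#'
#' Noise statistics come from the corrected CCG values at lags 50-100 ms (both
#' signs pooled). The pair is excitatory when the corrected peak within
#' +/-10 ms of zero lag exceeds the noise mean by more than 7 noise SD;
#' inhibitory when the trough falls below it by more than 5 noise SD
#' (excitatory takes precedence if both hold).
#'
#' @param ccg a jitter-corrected `ccg_result`.
#' @param peak_window_ms extremum search window around zero lag (ms).
#' @param noise_window_ms noise band (ms, absolute lag).
#' @param z_excitatory,z_inhibitory significance thresholds in noise SD.
#' @return Object of class `pair_classification`: `kind` (`"excitatory"`,
#'   `"inhibitory"`, `"ns"`), `extremum_lag_ms`, `extremum_z`, `noise_mean`,
#'   `noise_sd`, `degenerate` flag.
#' @export
classify_pair <- function(ccg, peak_window_ms = 10,
                          noise_window_ms = c(50, 100),
                          z_excitatory = 7, z_inhibitory = 5) {
  stopifnot(inherits(ccg, "ccg_result"))
  if (is.null(ccg$corrected)) stop("run jitter_correct() first")
  al <- abs(ccg$lags_ms)
  noise <- ccg$corrected[al >= noise_window_ms[1] & al <= noise_window_ms[2]]
  mu <- mean(noise)
  sdv <- stats::sd(noise)
  if (!is.finite(sdv) || sdv == 0) {
    return(structure(list(kind = "ns", extremum_lag_ms = NA_real_,
                          extremum_z = NA_real_, noise_mean = mu,
                          noise_sd = sdv, degenerate = TRUE),
                     class = "pair_classification"))
  }
  ctr <- which(al <= peak_window_ms)
  z <- (ccg$corrected[ctr] - mu) / sdv
  i_max <- which.max(z)
  i_min <- which.min(z)
  if (z[i_max] > z_excitatory) {
    kind <- "excitatory"
    lag <- ccg$lags_ms[ctr[i_max]]
    zx <- z[i_max]
  } else if (z[i_min] < -z_inhibitory) {
    kind <- "inhibitory"
    lag <- ccg$lags_ms[ctr[i_min]]
    zx <- z[i_min]
  } else {
    kind <- "ns"
    lag <- NA_real_
    zx <- z[i_max]
  }
  structure(list(kind = kind, extremum_lag_ms = lag, extremum_z = zx,
                 noise_mean = mu, noise_sd = sdv, degenerate = FALSE),
            class = "pair_classification")
}

#' Lead-lag (correlogram asymmetry) index
#'
#' `CA = (R - L) / (R + L)` where `R` is the rectified corrected CCG mass at
#' positive lags within the CA window and `L` the same at negative lags. +1
#' means the reference fully leads the target. Interpretation bands:
#' `|CA| <= 0.3` suggests common input, `|CA| >= 0.4` a synaptic interaction.
#'
#' @param ccg a jitter-corrected `ccg_result` (or any list with `lags_ms` and
#'   `corrected`).
#' @param ca_window_ms window around zero lag (ms, default 10).
#' @return List: `ca`, `band` (`"common_input"`, `"intermediate"`,
#'   `"synaptic"`, or `NA` when undefined).
#' @export
lead_lag_index <- function(ccg, ca_window_ms = 10) {
  if (is.null(ccg$corrected)) stop("run jitter_correct() first")
  lag <- ccg$lags_ms
  v <- pmax(ccg$corrected, 0)
  R <- sum(v[lag > 0 & lag <= ca_window_ms])
  Lm <- sum(v[lag < 0 & lag >= -ca_window_ms])
  if (R + Lm == 0) {
    warning("no rectified CCG mass in the CA window: CA undefined")
    return(list(ca = NA_real_, band = NA_character_))
  }
  ca <- (R - Lm) / (R + Lm)
  band <- if (abs(ca) <= 0.3) "common_input" else
    if (abs(ca) >= 0.4) "synaptic" else "intermediate"
  list(ca = ca, band = band)
}

#' Analyze all unit pairs of a population
#'
#' Computes the jitter-corrected CCG for every unordered unit pair, classifies
#' it and attaches the lead-lag index (reference = the first unit of the
#' pair). Pairs where either unit has no spikes in the analysis window are
#' skipped and logged in the `skipped` attribute.
#'
#' @param spikes named list of absolute spike-time vectors.
#' @param trials trial data frame with `onset_s`.
#' @param meta optional data frame with `unit_id`, `cluster`, `layer` used to
#'   annotate pairs.
#' @param ... passed to [compute_ccg()].
#' @param jitter_ms jitter window (ms).
#' @return Data frame, one row per unordered pair: `ref`, `tgt`, `kind`,
#'   `extremum_lag_ms`, `extremum_z`, `ca`, plus cluster/layer annotations
#'   when `meta` is given.
#' @export
analyze_ccg_pairs <- function(spikes, trials, meta = NULL, ...,
                              jitter_ms = 25) {
  ids <- names(spikes)
  rows <- list()
  skipped <- character()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      cc <- tryCatch(compute_ccg(spikes[[i]], spikes[[j]], trials, ...),
                     error = function(e) NULL)
      if (is.null(cc)) {
        skipped <- c(skipped, paste(ids[i], ids[j], sep = "-"))
        next
      }
      cc <- jitter_correct(cc, jitter_ms)
      cl <- classify_pair(cc)
      ca <- if (cl$kind == "ns") list(ca = NA_real_, band = NA_character_) else
        suppressWarnings(lead_lag_index(cc))
      rows[[length(rows) + 1L]] <- data.frame(
        ref = ids[i], tgt = ids[j], kind = cl$kind,
        extremum_lag_ms = cl$extremum_lag_ms, extremum_z = cl$extremum_z,
        ca = ca$ca, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref = character(), tgt = character(), kind = character(),
               extremum_lag_ms = numeric(), extremum_z = numeric(),
               ca = numeric())
  if (!is.null(meta)) {
    mi <- match(out$ref, meta$unit_id)
    mj <- match(out$tgt, meta$unit_id)
    out$ref_cluster <- meta$cluster[mi]
    out$tgt_cluster <- meta$cluster[mj]
    if ("layer" %in% names(meta)) {
      out$ref_layer <- meta$layer[mi]
      out$tgt_layer <- meta$layer[mj]
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Cluster-pair lead-lag summary and directed graph
#'
#' Aggregates significant excitatory pairs per ordered cluster pair: the
#' median lead-lag index (antisymmetric by construction: CA(B->A) =
#' -CA(A->B)), a two-sided Wilcoxon signed-rank test of the CAs against zero,
#' and a directed edge emitted from the leading cluster with a thickness class
#' by p-value (`"bold"` p < 0.001, `"thin"` p < 0.01).
#'
#' @param pairs data frame as from [analyze_ccg_pairs()] with `ref_cluster`,
#'   `tgt_cluster`, `kind`, `ca` (and optionally `ref_layer`, `tgt_layer`).
#' @param p_thin,p_bold p-value classes for edge thickness.
#' @return Object of class `cluster_pair_summary`: `summary` data frame (one
#'   row per unordered cluster pair: median CA oriented A->B, p, n), `edges`
#'   data frame (source, target, median_ca, p, weight_class, and modal layers
#'   when available).
#' @export
cluster_pair_graph <- function(pairs, p_thin = 0.01, p_bold = 0.001) {
  ex <- pairs[pairs$kind == "excitatory" & !is.na(pairs$ca), , drop = FALSE]
  have_layer <- all(c("ref_layer", "tgt_layer") %in% names(ex))
  cl <- sort(unique(c(pairs$ref_cluster, pairs$tgt_cluster)))
  srows <- list()
  erows <- list()
  modal_layer <- function(k) {
    if (!have_layer) return(NA_character_)
    ls <- c(pairs$ref_layer[pairs$ref_cluster == k],
            pairs$tgt_layer[pairs$tgt_cluster == k])
    if (length(ls) == 0) return(NA_character_)
    names(sort(table(ls), decreasing = TRUE))[1]
  }
  for (a_i in seq_along(cl)) {
    for (b_i in seq_along(cl)) {
      if (b_i <= a_i) next
      A <- cl[a_i]
      B <- cl[b_i]
      fwd <- ex$ref_cluster == A & ex$tgt_cluster == B
      rev_ <- ex$ref_cluster == B & ex$tgt_cluster == A
      cas <- c(ex$ca[fwd], -ex$ca[rev_]) # oriented A -> B
      if (length(cas) == 0) next
      p <- if (all(cas == 0)) 1 else suppressWarnings(
        stats::wilcox.test(cas, mu = 0, exact = FALSE)$p.value)
      med <- stats::median(cas)
      srows[[length(srows) + 1L]] <- data.frame(
        cluster_a = A, cluster_b = B, median_ca = med, p = p,
        n = length(cas), stringsAsFactors = FALSE)
      if (!is.na(p) && p < p_thin && med != 0) {
        src <- if (med > 0) A else B
        tgt <- if (med > 0) B else A
        erows[[length(erows) + 1L]] <- data.frame(
          source = src, target = tgt,
          source_layer = modal_layer(src), target_layer = modal_layer(tgt),
          median_ca = abs(med), p = p,
          weight_class = if (p < p_bold) "bold" else "thin",
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    summary = if (length(srows)) do.call(rbind, srows) else NULL,
    edges = if (length(erows)) do.call(rbind, erows) else
      data.frame(source = character(), target = character(),
                 source_layer = character(), target_layer = character(),
                 median_ca = numeric(), p = numeric(),
                 weight_class = character())),
    class = "cluster_pair_summary")
}
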