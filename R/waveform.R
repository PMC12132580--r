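# Unit curation and single-channel waveform representations.

#' Classify waveform polarity and tri-phasic shape
#'
#' A unit is positive-spiking when its maximum peak precedes its minimum
#' trough; tri-phasic when two local maxima, each at least `theta_tri` times
#' the trough magnitude, flank the global trough (tri-phasic units count as
#' negative-spiking).
#'
#' @param w numeric soma-channel waveform.
#' @param theta_tri flanking-peak threshold as a fraction of the trough
#'   magnitude (default 0.3).
#' @return List with `polarity` (`"negative"`/`"positive"`) and `triphasic`.
#' @export
classify_polarity <- function(w, theta_tri = 0.3) {
  stopifnot(is.numeric(w), length(w) >= 3)
  if (max(w) == min(w)) stop("constant waveform: polarity undefined")
  i_min <- which.min(w)
  i_max <- which.max(w)
  pre <- if (i_min > 1) max(w[1:(i_min - 1)]) else -Inf
  post <- if (i_min < length(w)) max(w[(i_min + 1):length(w)]) else -Inf
  thr <- theta_tri * abs(w[i_min])
  if (pre >= thr && post >= thr) {
    return(list(polarity = "negative", triphasic = TRUE))
  }
  list(polarity = if (i_max < i_min) "positive" else "negative",
       triphasic = FALSE)
}

#' Align and normalize a soma waveform
#'
#' Shifts the waveform so its alignment extremum (trough for negative and
#' tri-phasic units, peak for positive units) sits at the window center, then
#' divides by the maximum absolute value so the extremum is -1 (negative) or
#' +1 (positive). Samples shifted past the window edge are filled by repeating
#' the end value (no wrap-around). Idempotent and scale invariant.
#'
#' @param w numeric waveform.
#' @param polarity `"negative"` or `"positive"`.
#' @param triphasic logical (tri-phasic units align to the trough).
#' @return Normalized, aligned numeric vector of the same length.
#' @export
align_normalize <- function(w, polarity = c("negative", "positive"),
                            triphasic = FALSE) {
  polarity <- match.arg(polarity)
  if (all(w == 0)) stop("all-zero waveform cannot be normalized")
  n <- length(w)
  center <- n %/% 2 + 1L
  i_ext <- if (polarity == "positive" && !triphasic) which.max(w) else which.min(w)
  shift <- center - i_ext
  if (shift > 0) {
    w <- c(rep(w[1], shift), w[seq_len(n - shift)])
  } else if (shift < 0) {
    w <- c(w[(1 - shift):n], rep(w[n], -shift))
  }
  w / max(abs(w))
}

#' Classical waveform features
#'
#' Trough-to-peak width (time from the trough to the following peak),
#' repolarization time (time from that peak until the repolarization curve
#' first falls to half the peak value) and trough-to-peak amplitude scaled to
#' microvolts. Extremum times use parabolic sub-sample interpolation; the
#' half-peak crossing is linearly interpolated. Positive-spiking waveforms are
#' mirrored (negated) before measurement.
#'
#' @param w numeric soma waveform in template units.
#' @param sampling_rate_hz sampling rate.
#' @param scale_to_uV template-to-microvolt factor (default 2.3).
#' @param polarity `"negative"` or `"positive"`.
#' @return List of class `waveform_features`: `ttp_width_ms`,
#'   `repolarization_ms`, `amplitude_uV`.
#' @export
classical_features <- function(w, sampling_rate_hz, scale_to_uV = 2.3,
                               polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  if (polarity == "positive") w <- -w
  n <- length(w)
  dt_ms <- 1000 / sampling_rate_hz
  i_tr <- which.min(w)
  if (i_tr >= n) stop("no peak after trough within the window")
  i_pk <- i_tr + which.max(w[(i_tr + 1):n])
  t_tr <- parabolic_peak(-w, i_tr)
  t_pk <- parabolic_peak(w, i_pk)
  ttp_ms <- (t_pk - t_tr) * dt_ms
  peak_val <- w[i_pk]
  half <- peak_val / 2
  rep_ms <- NA_real_
  if (i_pk < n) {
    below <- which(w[(i_pk + 1):n] <= half)
    if (length(below) > 0) {
      j <- i_pk + below[1]
      # linear interpolation of the crossing between j-1 and j
      frac <- (w[j - 1] - half) / (w[j - 1] - w[j])
      rep_ms <- ((j - 1 + frac) - i_pk) * dt_ms
    }
  }
  amp <- (max(w) - min(w)) * scale_to_uV
  structure(list(ttp_width_ms = ttp_ms, repolarization_ms = rep_ms,
                 amplitude_uV = amp),
            class = "waveform_features")
}

#' Filter units by signal-to-noise ratio
#'
#' Retains units with `lo < snr <= hi` (exclusive low bound, inclusive high
#' bound), preserving order. Defaults follow the curation rule of excluding
#' units with SNR below 0 or above 3.7.
#'
#' @param units list of unit records, each with an `snr` field, or a numeric
#'   vector of SNR values.
#' @param lo,hi bounds (defaults 0 and 3.7).
#' @return The retained subset (same type as the input).
#' @export
snr_filter <- function(units, lo = 0, hi = 3.7) {
  snr <- if (is.numeric(units)) units else vapply(units, `[[`, 0, "snr")
  stopifnot(!anyNA(snr))
  keep <- snr > lo & snr <= hi
  if (is.numeric(units)) units[keep] else units[keep]
}

# Soma-channel waveform of a template (template units).
soma_waveform <- function(template) {
  template$voltages[, template$soma_channel]
}

#' Curate and featurize a unit list
#'
#' Applies the SNR filter, classifies polarity/tri-phasic shape from the soma
#' waveform, computes classical features and the aligned normalized waveform
#' for each retained unit.
#'
#' @param units named list of unit records with `template` and `snr` fields.
#' @param snr_lo,snr_hi SNR bounds for [snr_filter()].
#' @param theta_tri tri-phasic threshold for [classify_polarity()].
#' @return List with `units` (augmented records: `polarity`, `triphasic`,
#'   `features`, `normalized` waveform), and `features` data frame (unit_id,
#'   ttp_width_ms, repolarization_ms, amplitude_uV, snr, polarity, triphasic).
#' @export
curate_units <- function(units, snr_lo = 0, snr_hi = 3.7, theta_tri = 0.3) {
  kept <- snr_filter(units, snr_lo, snr_hi)
  out <- lapply(kept, function(u) {
    w <- soma_waveform(u$template)
    pol <- classify_polarity(w, theta_tri)
    u$polarity <- pol$polarity
    u$triphasic <- pol$triphasic
    u$features <- classical_features(w, u$template$sampling_rate_hz,
                                     u$template$scale_to_uV, pol$polarity)
    u$normalized <- align_normalize(w, pol$polarity, pol$triphasic)
    u
  })
  feat <- data.frame(
    unit_id = vapply(out, `[[`, "", "unit_id"),
    ttp_width_ms = vapply(out, function(u) u$features$ttp_width_ms, 0),
    repolarization_ms = vapply(out, function(u) u$features$repolarization_ms, 0),
    amplitude_uV = vapply(out, function(u) u$features$amplitude_uV, 0),
    snr = vapply(out, `[[`, 0, "snr"),
    polarity = vapply(out, `[[`, "", "polarity"),
    triphasic = vapply(out, `[[`, TRUE, "triphasic"),
    row.names = NULL)
  list(units = out, features = feat)
}
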