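#' Laminar boundary set
#'
#' Ordered laminar compartment borders along the probe axis. Depths are in
#' micrometers from the pia (increasing downward). Five compartments are used
#' throughout: layers 2/3, 4A/B, 4C, 5/6 and white matter (WM). The boundary
#' between 4C and 5/6 is the anchor that current-source-density analysis
#' estimates.
#'
#' @param edges numeric vector of 6 strictly increasing depths (um): top of
#'   2/3, 2/3|4A/B, 4A/B|4C, 4C|5/6, 5/6|WM, bottom of WM.
#' @param inverted logical; `TRUE` for sessions recorded through the calcarine
#'   sulcus where the laminar order is flipped along the probe.
#' @return An object of class `layer_boundaries`.
#' @export
layer_boundaries <- function(edges, inverted = FALSE) {
  stopifnot(length(edges) == 6, all(diff(edges) > 0))
  structure(
    list(edges = as.numeric(edges),
         layers = c("2/3", "4A/B", "4C", "5/6", "WM"),
         anchor = as.numeric(edges[4]),
         inverted = isTRUE(inverted)),
    class = "layer_boundaries")
}

#' @rdname layer_boundaries
#' @export
default_layer_boundaries <- function() {
  # 4A/B + 4C together span ~590 um above the 4C|5/6 anchor, matching
  # macaque V1 estimates used by the laminar distribution analyses.
  layer_boundaries(c(0, 700, 1000, 1290, 1900, 2500))
}

# Layer label for each depth (um from pia, before any inversion).
layer_of <- function(depth_um, boundaries) {
  idx <- findInterval(depth_um, boundaries$edges, rightmost.closed = TRUE)
  out <- rep(NA_character_, length(depth_um))
  ok <- idx >= 1 & idx <= 5
  out[ok] <- boundaries$layers[idx[ok]]
  out
}

#' Stimulus schedule for drifting-grating presentation
#'
#' Drifting Gabor gratings: 36 directions in 10 degree steps, four spatial
#' frequencies, 1 s stimulus with 0.25 s equiluminant inter-stimulus interval,
#' 5-10 repeats, and a fixed screen-update delay added to nominal onset times.
#'
#' @param directions_deg drift directions (degrees, within `[0, 360)`).
#' @param spatial_frequencies_cpd spatial frequencies (cycles/degree).
#' @param stimulus_s stimulus duration (s).
#' @param interstim_s inter-stimulus interval (s).
#' @param repeats repeats per condition.
#' @param screen_delay_ms monitor update delay added to nominal onsets (ms).
#' @param eyes eye conditions presented.
#' @return An object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(directions_deg = seq(0, 350, by = 10),
                              spatial_frequencies_cpd = c(0.5, 1, 2, 4),
                              stimulus_s = 1.0,
                              interstim_s = 0.25,
                              repeats = 10L,
                              screen_delay_ms = 67,
                              eyes = "binocular") {
  stopifnot(all(directions_deg >= 0 & directions_deg < 360),
            !anyDuplicated(directions_deg),
            repeats >= 1, stimulus_s > 0, interstim_s >= 0)
  structure(
    list(directions_deg = as.numeric(directions_deg),
         spatial_frequencies_cpd = as.numeric(spatial_frequencies_cpd),
         stimulus_s = stimulus_s, interstim_s = interstim_s,
         repeats = as.integer(repeats), screen_delay_ms = screen_delay_ms,
         eyes = eyes),
    class = "stimulus_schedule")
}

#' Waveform-class archetype
#'
#' Generative description of one candidate cell class: soma waveform shape
#' (trough-to-peak width, repolarization time, polarity, tri-phasic flag),
#' template amplitude, laminar depth preference, multichannel propagation
#' profile, inter-spike-interval structure and direction/orientation tuning.
#'
#' @param name label, e.g. `"NS-1"`.
#' @param ttp_width_ms trough-to-peak width (ms).
#' @param repolarization_ms peak-to-half-peak repolarization time (ms).
#' @param amplitude_uV trough-to-peak amplitude (uV).
#' @param depth_weights named per-layer sampling weights (must sum to 1);
#'   names from `c("2/3","4A/B","4C","5/6","WM")`.
#' @param polarity `"negative"` or `"positive"`.
#' @param triphasic logical; two major peaks flanking the trough.
#' @param propagation list: `profile` one of `"unidirectional"`,
#'   `"asymmetric_above"`, `"symmetric"`, `"flat"`; `v_inv_ms_mm` inverse
#'   velocity magnitude (ms/mm).
#' @param burst_model list: `type` `"poisson"` or `"bursty"`; for bursty also
#'   `intra_burst_isi_ms`, `burst_size_mean`, `burst_prob`.
#' @param tuning list: `pref_direction_deg`, `target_DI`, `target_OI` (both in
#'   `[0,1]`), `baseline_rate_hz`, `evoked_rate_hz`, `latency_ms`.
#' @return An object of class `class_archetype`.
#' @export
class_archetype <- function(name,
                            ttp_width_ms,
                            repolarization_ms,
                            amplitude_uV,
                            depth_weights,
                            polarity = c("negative", "positive"),
                            triphasic = FALSE,
                            propagation = list(profile = "flat", v_inv_ms_mm = 0),
                            burst_model = list(type = "poisson"),
                            tuning = list(pref_direction_deg = 0, target_DI = 0.3,
                                          target_OI = 0.3, baseline_rate_hz = 1,
                                          evoked_rate_hz = 20, latency_ms = 50)) {
  polarity <- match.arg(polarity)
  stopifnot(ttp_width_ms > 0, repolarization_ms > 0, amplitude_uV > 0)
  known <- c("2/3", "4A/B", "4C", "5/6", "WM")
  if (is.null(names(depth_weights)) || !all(names(depth_weights) %in% known)) {
    stop("depth_weights must be named with known layers: ",
         paste(known, collapse = ", "))
  }
  if (abs(sum(depth_weights) - 1) > 1e-8) stop("depth weights must sum to 1")
  stopifnot(propagation$profile %in%
              c("unidirectional", "asymmetric_above", "symmetric", "flat"))
  stopifnot(burst_model$type %in% c("poisson", "bursty"))
  tn <- tuning
  stopifnot(tn$target_DI >= 0, tn$target_DI <= 1,
            tn$target_OI >= 0, tn$target_OI <= 1,
            tn$baseline_rate_hz >= 0, tn$evoked_rate_hz >= 0,
            tn$latency_ms >= 0)
  structure(
    list(name = name, polarity = polarity, triphasic = isTRUE(triphasic),
         ttp_width_ms = ttp_width_ms, repolarization_ms = repolarization_ms,
         amplitude_uV = amplitude_uV, depth_weights = depth_weights,
         propagation = propagation, burst_model = burst_model, tuning = tuning),
    class = "class_archetype")
}

#' Default archetype set
#'
#' Nine negative-spiking archetypes (four narrow-spiking NS-1..NS-4, four
#' broad-spiking BS-1..BS-4, one tri-phasic TP-1) plus one positive-spiking
#' archetype (POS), parameterized to emulate the qualitative class portraits of
#' laminar V1 recordings: NS classes concentrated in layers 4A/B and 4C, NS-3
#' with the largest amplitude and strongest direction selectivity and a
#' symmetric (stellate-like) propagation profile, NS-1 bursty, orientation
#' selective and unidirectional (pyramidal-like), BS classes broad and mostly
#' propagating toward the pia, BS-4 infragranular, TP-1 very narrow with peaks
#' flanking the trough, POS concentrated in white matter.
#'
#' @return Named list of [class_archetype()] objects.
#' @export
default_archetypes <- function() {
  w <- function(...) {
    x <- c(...)
    x / sum(x)
  }
  a <- list(
    class_archetype("NS-1", 0.18, 0.16, 80,
      w("2/3" = 0.05, "4A/B" = 0.50, "4C" = 0.40, "5/6" = 0.05),
      propagation = list(profile = "unidirectional", v_inv_ms_mm = 0.6),
      burst_model = list(type = "bursty", intra_burst_isi_ms = 4,
                         burst_size_mean = 3, burst_prob = 0.4),
      tuning = list(pref_direction_deg = 30, target_DI = 0.3, target_OI = 0.7,
                    baseline_rate_hz = 1, evoked_rate_hz = 22, latency_ms = 45)),
    class_archetype("NS-2", 0.22, 0.18, 70,
      w("2/3" = 0.08, "4A/B" = 0.40, "4C" = 0.46, "5/6" = 0.06),
      propagation = list(profile = "asymmetric_above", v_inv_ms_mm = 0.5),
      tuning = list(pref_direction_deg = 120, target_DI = 0.3, target_OI = 0.45,
                    baseline_rate_hz = 1, evoked_rate_hz = 20, latency_ms = 45)),
    class_archetype("NS-3", 0.26, 0.20, 160,
      w("2/3" = 0.10, "4A/B" = 0.50, "4C" = 0.18, "5/6" = 0.22),
      propagation = list(profile = "symmetric", v_inv_ms_mm = 0.8),
      tuning = list(pref_direction_deg = 200, target_DI = 0.8, target_OI = 0.6,
                    baseline_rate_hz = 1, evoked_rate_hz = 25, latency_ms = 40)),
    class_archetype("NS-4", 0.30, 0.22, 60,
      w("2/3" = 0.11, "4A/B" = 0.35, "4C" = 0.32, "5/6" = 0.22),
      propagation = list(profile = "symmetric", v_inv_ms_mm = 0.4),
      burst_model = list(type = "bursty", intra_burst_isi_ms = 5,
                         burst_size_mean = 2.5, burst_prob = 0.35),
      tuning = list(pref_direction_deg = 300, target_DI = 0.3, target_OI = 0.3,
                    baseline_rate_hz = 1.5, evoked_rate_hz = 20, latency_ms = 40)),
    class_archetype("BS-1", 0.45, 0.36, 50,
      w("2/3" = 0.10, "4A/B" = 0.15, "4C" = 0.55, "5/6" = 0.20),
      propagation = list(profile = "unidirectional", v_inv_ms_mm = 0.5),
      tuning = list(pref_direction_deg = 80, target_DI = 0.3, target_OI = 0.4,
                    baseline_rate_hz = 2, evoked_rate_hz = 18, latency_ms = 55)),
    class_archetype("BS-2", 0.50, 0.40, 90,
      w("2/3" = 0.25, "4A/B" = 0.15, "4C" = 0.45, "5/6" = 0.15),
      propagation = list(profile = "asymmetric_above", v_inv_ms_mm = 0.6),
      tuning = list(pref_direction_deg = 160, target_DI = 0.15, target_OI = 0.4,
                    baseline_rate_hz = 2, evoked_rate_hz = 18, latency_ms = 55)),
    class_archetype("BS-3", 0.55, 0.44, 85,
      w("2/3" = 0.35, "4A/B" = 0.10, "4C" = 0.40, "5/6" = 0.15),
      propagation = list(profile = "asymmetric_above", v_inv_ms_mm = 0.5),
      tuning = list(pref_direction_deg = 250, target_DI = 0.4, target_OI = 0.5,
                    baseline_rate_hz = 2, evoked_rate_hz = 18, latency_ms = 55)),
    class_archetype("BS-4", 0.60, 0.48, 45,
      w("2/3" = 0.05, "4A/B" = 0.05, "4C" = 0.15, "5/6" = 0.75),
      propagation = list(profile = "asymmetric_above", v_inv_ms_mm = 0.3),
      tuning = list(pref_direction_deg = 340, target_DI = 0.2, target_OI = 0.3,
                    baseline_rate_hz = 2, evoked_rate_hz = 16, latency_ms = 50)),
    class_archetype("TP-1", 0.17, 0.14, 55,
      w("2/3" = 0.05, "4A/B" = 0.20, "4C" = 0.25, "5/6" = 0.30, "WM" = 0.20),
      triphasic = TRUE,
      propagation = list(profile = "symmetric", v_inv_ms_mm = 0.3),
      tuning = list(pref_direction_deg = 10, target_DI = 0.1, target_OI = 0.1,
                    baseline_rate_hz = 2, evoked_rate_hz = 15, latency_ms = 50)),
    class_archetype("POS", 0.30, 0.25, 65,
      w("5/6" = 0.25, "WM" = 0.75),
      polarity = "positive",
      propagation = list(profile = "flat", v_inv_ms_mm = 0),
      tuning = list(pref_direction_deg = 0, target_DI = 0.05, target_OI = 0.05,
                    baseline_rate_hz = 2, evoked_rate_hz = 8, latency_ms = 60))
  )
  stats::setNames(a, vapply(a, `[[`, "", "name"))
}
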