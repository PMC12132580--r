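# Shared fixtures, all generated in code.

# A plain biphasic negative archetype with everything configurable.
test_archetype <- function(name = "X", ttp = 0.25, rep_ms = 0.2, amp = 80,
                           layer = "4C", ...) {
  wts <- stats::setNames(1, layer)
  class_archetype(name, ttp, rep_ms, amp, wts, ...)
}

# Normalized soma waveforms for one synthetic family.
family_waveforms <- function(ttp, n, noise_sd = 0.5, amp = 80) {
  t(vapply(seq_len(n), function(i) {
    tp <- synth_template(test_archetype(ttp = ttp, rep_ms = 0.3 * ttp / 0.2,
                                        amp = amp),
                         seed = sample.int(1e6, 1), noise_sd = noise_sd)
    align_normalize(tp$voltages[, tp$soma_channel], "negative")
  }, numeric(54)))
}

# Homogeneous Poisson spike train over trials spanning [onset-0.25, onset+1].
poisson_session <- function(rate_hz, trials) {
  unlist(lapply(trials$onset_s, function(o) {
    n <- stats::rpois(1, rate_hz * 1.25)
    sort(stats::runif(n, o - 0.25, o + 1))
  }))
}

std_trials <- function(m) data.frame(trial = seq_len(m),
                                     onset_s = (seq_len(m) - 1) * 1.25 + 0.25)

# Reduced stimulus schedule for fast spike synthesis.
mini_schedule <- function(repeats = 5L,
                          directions = seq(0, 330, by = 30)) {
  stimulus_schedule(directions_deg = directions,
                    spatial_frequencies_cpd = 1, repeats = repeats)
}

# Brute-force Eq-4 pair counts: explicit double loop over binned spikes.
bruteforce_ccg_counts <- function(spikes_j, spikes_k, trials,
                                  window_s = c(0.4, 1.0), bin_s = 0.001,
                                  L = 100L) {
  counts <- integer(2L * L + 1L)
  for (i in seq_len(nrow(trials))) {
    o <- trials$onset_s[i]
    bj <- unique(floor((spikes_j[spikes_j >= o + window_s[1] &
                                   spikes_j < o + window_s[2]] -
                          o - window_s[1]) / bin_s) + 1L)
    bk <- unique(floor((spikes_k[spikes_k >= o + window_s[1] &
                                   spikes_k < o + window_s[2]] -
                          o - window_s[1]) / bin_s) + 1L)
    for (a in bj) for (b in bk) {
      tau <- b - a
      if (abs(tau) <= L) counts[tau + L + 1L] <- counts[tau + L + 1L] + 1L
    }
  }
  counts
}

# Minimal jitter-corrected CCG-shaped object for classifier/CA tests.
fake_ccg <- function(corrected, bin_ms = 1) {
  L <- (length(corrected) - 1L) %/% 2L
  structure(list(lags_ms = seq(-L, L) * bin_ms, corrected = corrected,
                 raw = corrected + 1, bin_ms = bin_ms),
            class = "ccg_result")
}
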