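# Synthetic cohort generation: every downstream estimator in the package has a
# planted ground truth here (waveform shape, laminar depth, propagation
# profile, tuning, burstiness, pairwise coupling), so the full pipeline can be
# exercised and calibrated without any recorded data.

#' Synthesize a multichannel waveform template for an archetype
#'
#' Builds an analytic soma waveform (difference of Gaussians; a three-lobe
#' variant for tri-phasic classes; time-reversed for positive-spiking classes)
#' whose realized trough-to-peak width is calibrated to the archetype's
#' `ttp_width_ms`, then lays it out over a linear column of channels: amplitude
#' decays exponentially with distance from the soma channel and per-channel
#' time shifts follow the archetype's propagation profile (`unidirectional`,
#' `asymmetric_above`, `symmetric` or `flat`; channel offsets are positive
#' toward the pia).
#'
#' @param archetype a [class_archetype()].
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param sampling_rate_hz sampling rate (default 30 kHz).
#' @param window_ms template window duration (default 1.8 ms).
#' @param n_channels number of channels (default 11: soma +/- 5).
#' @param pitch_um channel pitch along the probe (um).
#' @param amp_decay_um exponential amplitude decay length with channel
#'   distance (um).
#' @param noise_sd additive Gaussian noise sd in template units (default 0).
#' @return An object of class `waveform_template`: list with `voltages`
#'   (samples x channels matrix, template units), `sampling_rate_hz`,
#'   `channel_positions_um` (data frame, `y` positive toward the pia relative
#'   to the soma channel), `soma_channel`, `scale_to_uV` (2.3).
#' @export
synth_template <- function(archetype, seed = 1L,
                           sampling_rate_hz = 30000,
                           window_ms = 1.8,
                           n_channels = 11L,
                           pitch_um = 20,
                           amp_decay_um = 60,
                           noise_sd = 0) {
  stopifnot(inherits(archetype, "class_archetype"), n_channels %% 2 == 1)
  dt_ms <- 1000 / sampling_rate_hz
  if (archetype$ttp_width_ms < 2 * dt_ms) {
    stop("requested trough-to-peak width unresolvable at this sampling rate")
  }
  if (archetype$ttp_width_ms > 0.6 * window_ms) {
    stop("archetype width too large for the template window")
  }
  n_samples <- round(window_ms / dt_ms)
  t_ms <- (seq_len(n_samples) - 1) * dt_ms

  t0 <- 0.55
  sig_t <- archetype$ttp_width_ms / 4
  sig_p <- archetype$repolarization_ms / 1.1774 # half-width of a Gaussian
  p_amp <- if (archetype$triphasic) 0.5 else 0.4

  base_shape <- function(tt, delta) {
    v <- -exp(-(tt - t0)^2 / (2 * sig_t^2)) +
      p_amp * exp(-(tt - t0 - delta)^2 / (2 * sig_p^2))
    if (archetype$triphasic) {
      v <- v + p_amp * exp(-(tt - t0 + delta)^2 / (2 * (0.8 * sig_p)^2))
    }
    v
  }

  # calibrate the peak offset so the realized trough-to-peak width matches
  fine <- seq(0, window_ms, by = 0.001)
  realized_ttp <- function(delta) {
    v <- base_shape(fine, delta)
    i_tr <- which.min(v)
    i_pk <- i_tr + which.max(v[(i_tr + 1):length(v)])
    fine[i_pk] - fine[i_tr]
  }
  target <- archetype$ttp_width_ms
  f <- function(delta) realized_ttp(delta) - target
  lo <- 0.3 * target
  hi <- 3 * target
  delta <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-5)$root,
                    error = function(e) target)

  shape <- if (archetype$polarity == "positive") {
    function(tt) base_shape(window_ms - tt, delta)
  } else {
    function(tt) base_shape(tt, delta)
  }

  # scale so the soma trough-to-peak span in template units maps to the
  # archetype amplitude after the 2.3 acquisition factor
  soma <- shape(t_ms)
  span <- max(soma) - min(soma)
  scale <- archetype$amplitude_uV / 2.3 / span

  half <- (n_channels - 1L) %/% 2L
  offsets_um <- seq(-half, half) * pitch_um # positive toward the pia
  d_mm <- offsets_um / 1000
  v_inv <- archetype$propagation$v_inv_ms_mm
  dt_shift <- switch(archetype$propagation$profile,
    unidirectional = v_inv * d_mm,
    asymmetric_above = ifelse(d_mm > 0, v_inv * d_mm, 0),
    symmetric = v_inv * abs(d_mm),
    flat = rep(0, n_channels))
  amp_factor <- exp(-abs(offsets_um) / amp_decay_um)

  volt <- vapply(seq_len(n_channels), function(ci) {
    scale * amp_factor[ci] * shape(t_ms - dt_shift[ci])
  }, numeric(n_samples))
  if (noise_sd > 0) {
    volt <- volt + with_seed(seed, matrix(stats::rnorm(length(volt), sd = noise_sd),
                                          nrow = n_samples))
  }
  structure(
    list(voltages = volt,
         sampling_rate_hz = sampling_rate_hz,
         channel_positions_um = data.frame(x = 0, y = offsets_um),
         soma_channel = half + 1L,
         scale_to_uV = 2.3),
    class = "waveform_template")
}

#' Generate a ground-truth synthetic cohort
#'
#' Samples units from the given archetypes: laminar depth from the archetype's
#' per-layer weights inside the session boundaries, an SNR value, and a
#' multichannel template from [synth_template()]. Deterministic for a fixed
#' seed.
#'
#' @param archetypes named list of [class_archetype()] objects.
#' @param n_per_class units per archetype (scalar or vector).
#' @param boundaries a [layer_boundaries()] object.
#' @param schedule a [stimulus_schedule()].
#' @param edges optional data frame of pairwise coupling ground truth with
#'   columns `source`, `target` (unit ids), `lag_ms` (>= 0), `efficacy`
#'   (probability per source spike, in `[0,1]`), `sign` (`"excitatory"` or
#'   `"inhibitory"`).
#' @param seed integer seed.
#' @param snr_range range SNR values are drawn from (uniform).
#' @param template_args list of extra arguments passed to [synth_template()].
#' @return An object of class `gt_cohort`.
#' @export
make_cohort <- function(archetypes = default_archetypes()[1:9],
                        n_per_class = 20L,
                        boundaries = default_layer_boundaries(),
                        schedule = stimulus_schedule(),
                        edges = NULL,
                        seed = 1L,
                        snr_range = c(0.35, 1.05),
                        template_args = list()) {
  if (length(archetypes) < 1) stop("empty archetype list")
  stopifnot(inherits(boundaries, "layer_boundaries"))
  counts <- rep_len(as.integer(n_per_class), length(archetypes))
  for (a in archetypes) {
    if (!all(names(a$depth_weights) %in% boundaries$layers)) {
      stop("depth weights reference unknown layers for archetype ", a$name)
    }
  }
  n_total <- sum(counts)
  seeds <- child_seeds(seed, n_total + 1L)
  units <- vector("list", n_total)
  k <- 0L
  with_seed(seeds[n_total + 1L], {
    for (ai in seq_along(archetypes)) {
      arch <- archetypes[[ai]]
      for (j in seq_len(counts[ai])) {
        k <- k + 1L
        lay <- sample(names(arch$depth_weights), 1L, prob = arch$depth_weights)
        li <- match(lay, boundaries$layers)
        depth <- stats::runif(1, boundaries$edges[li], boundaries$edges[li + 1])
        snr <- stats::runif(1, snr_range[1], snr_range[2])
        tmpl <- do.call(synth_template,
                        c(list(archetype = arch, seed = seeds[k]), template_args))
        units[[k]] <- list(unit_id = sprintf("u%03d", k),
                           archetype = arch$name,
                           depth_um = depth, layer = lay, snr = snr,
                           template = tmpl)
      }
    }
  })
  ids <- vapply(units, `[[`, "", "unit_id")
  stopifnot(!anyDuplicated(ids))
  if (!is.null(edges)) {
    stopifnot(all(c("source", "target", "lag_ms", "efficacy", "sign") %in%
                    names(edges)),
              all(edges$source %in% ids), all(edges$target %in% ids),
              all(edges$efficacy >= 0 & edges$efficacy <= 1),
              all(edges$lag_ms >= 0),
              all(edges$sign %in% c("excitatory", "inhibitory")))
  }
  structure(
    list(units = stats::setNames(units, ids),
         archetypes = archetypes,
         edges = edges, schedule = schedule, boundaries = boundaries,
         seed = as.integer(seed)),
    class = "gt_cohort")
}

#' @export
print.gt_cohort <- function(x, ...) {
  cat("<gt_cohort> ", length(x$units), " units, ",
      length(unique(vapply(x$units, `[[`, "", "archetype"))), " archetypes, ",
      if (is.null(x$edges)) 0L else nrow(x$edges), " coupling edges, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# Von Mises-style direction/orientation concentration solved in closed form so
# the measured DI/OI (which include the baseline rate) hit their targets.
# Rate model during the stimulus for direction difference D from preferred:
#   r(D) = b + E * exp(kd*(cos(D)-1) + ko*(cos(2D)-1))
solve_tuning_kappas <- function(tuning) {
  b <- tuning$baseline_rate_hz
  E <- tuning$evoked_rate_hz
  di <- tuning$target_DI
  oi <- tuning$target_OI
  if (E <= 0) return(list(kd = 0, ko = 0))
  x <- (E * (1 - di) - 2 * b * di) / (E * (1 + di))
  if (x <= 0) {
    warning("target DI unattainable at this baseline/evoked rate; capping kappa")
    kd <- 25
  } else kd <- -log(x) / 2
  r_pref_ori <- b + E * (1 + exp(-2 * kd)) / 2
  rhs_num <- r_pref_ori * (1 - oi) / (1 + oi) - b
  denom <- E * exp(-kd)
  if (rhs_num <= 0) {
    warning("target OI unattainable at this baseline/evoked rate; capping kappa")
    ko <- 25
  } else ko <- -log(rhs_num / denom) / 2
  list(kd = kd, ko = ko)
}

direction_gain <- function(delta_deg, kd, ko) {
  d <- delta_deg * pi / 180
  exp(kd * (cos(d) - 1) + ko * (cos(2 * d) - 1))
}

#' Synthesize spike trains for a cohort
#'
#' Builds the trial table from the cohort's stimulus schedule (conditions in a
#' seeded pseudorandom order within each repeat block) and generates each
#' unit's spike train: baseline Poisson activity over the whole session, evoked
#' Poisson activity during each stimulus at a rate set by the archetype's
#' direction/orientation tuning (concentrations solved so measured DI/OI hit
#' the planted targets), compound bursts (each seed spike spawns a burstlet
#' with the archetype's probability), and pairwise coupling: for each source
#' spike an excitatory edge inserts a target spike at the edge lag with the
#' edge efficacy, an inhibitory edge deletes target spikes in a short window
#' after the lag.
#'
#' @param cohort a [make_cohort()] result.
#' @param seed integer seed.
#' @return An object of class `trial_spike_table`: list with `trials` (data
#'   frame: trial, direction_deg, sf_cpd, eye, onset_s), `spikes` (named list
#'   of absolute spike-time vectors, seconds), `counts` (per-unit data frame of
#'   seed/burst/coupling spike counts) and `schedule`.
#' @export
synth_spikes <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "gt_cohort"))
  sch <- cohort$schedule
  conds <- expand.grid(direction_deg = sch$directions_deg,
                       sf_cpd = sch$spatial_frequencies_cpd,
                       eye = sch$eyes, stringsAsFactors = FALSE)
  period <- sch$stimulus_s + sch$interstim_s
  seeds <- child_seeds(seed, 2L)
  trials <- with_seed(seeds[1L], {
    blocks <- lapply(seq_len(sch$repeats), function(r) {
      conds[sample.int(nrow(conds)), , drop = FALSE]
    })
    tr <- do.call(rbind, blocks)
    tr$trial <- seq_len(nrow(tr))
    tr$onset_s <- sch$interstim_s + (tr$trial - 1) * period
    rownames(tr) <- NULL
    tr[, c("trial", "direction_deg", "sf_cpd", "eye", "onset_s")]
  })
  total_T <- sch$interstim_s + nrow(trials) * period
  delay_s <- sch$screen_delay_ms / 1000

  arch_of <- lapply(cohort$units, function(u) {
    cohort$archetypes[[match(u$archetype,
                             vapply(cohort$archetypes, `[[`, "", "name"))]]
  })

  spikes <- vector("list", length(cohort$units))
  names(spikes) <- names(cohort$units)
  counts <- data.frame(unit_id = names(cohort$units), seed = 0L, burst = 0L,
                       coupled_added = 0L, coupled_removed = 0L)
  with_seed(seeds[2L], {
    for (ui in seq_along(cohort$units)) {
      arch <- arch_of[[ui]]
      tn <- arch$tuning
      kap <- solve_tuning_kappas(tn)
      # baseline over the whole session
      nb <- stats::rpois(1, tn$baseline_rate_hz * total_T)
      st <- stats::runif(nb, 0, total_T)
      # evoked activity per trial
      delta <- trials$direction_deg - tn$pref_direction_deg
      gain <- direction_gain(delta, kap$kd, kap$ko)
      ev_rate <- tn$evoked_rate_hz * gain
      ev_n <- stats::rpois(nrow(trials), ev_rate * sch$stimulus_s)
      if (sum(ev_n) > 0) {
        t0 <- rep(trials$onset_s + delay_s + tn$latency_ms / 1000, ev_n)
        st <- c(st, t0 + stats::runif(sum(ev_n), 0, sch$stimulus_s))
      }
      n_seed <- length(st)
      # compound bursts
      n_burst <- 0L
      bm <- arch$burst_model
      if (bm$type == "bursty" && n_seed > 0 && bm$burst_prob > 0) {
        is_burst <- stats::runif(n_seed) < bm$burst_prob
        extra_n <- stats::rpois(sum(is_burst), max(bm$burst_size_mean - 1, 0))
        src <- rep(st[is_burst], extra_n)
        if (length(src) > 0) {
          ord <- sequence(extra_n)
          gaps <- bm$intra_burst_isi_ms / 1000 *
            stats::runif(length(src), 0.7, 1.3)
          st <- c(st, src + ord * gaps)
          n_burst <- length(src)
        }
      }
      spikes[[ui]] <- sort(st)
      counts$seed[ui] <- n_seed
      counts$burst[ui] <- n_burst
    }
    # pairwise coupling
    if (!is.null(cohort$edges)) {
      for (ei in seq_len(nrow(cohort$edges))) {
        e <- cohort$edges[ei, ]
        src <- spikes[[e$source]]
        sel <- src[stats::runif(length(src)) < e$efficacy]
        if (length(sel) == 0) next
        ti <- match(e$target, names(spikes))
        if (e$sign == "excitatory") {
          add <- sel + e$lag_ms / 1000 + stats::runif(length(sel), -2e-4, 2e-4)
          spikes[[ti]] <- sort(c(spikes[[ti]], add))
          counts$coupled_added[ti] <- counts$coupled_added[ti] + length(add)
        } else {
          tgt <- spikes[[ti]]
          kill <- rep(FALSE, length(tgt))
          for (s in sel) {
            kill <- kill | (tgt > s + e$lag_ms / 1000 &
                              tgt <= s + e$lag_ms / 1000 + 0.003)
          }
          counts$coupled_removed[ti] <- counts$coupled_removed[ti] + sum(kill)
          spikes[[ti]] <- tgt[!kill]
        }
      }
    }
  })
  # enforce strictly increasing times (exact ties are measure-zero but guarded)
  spikes <- lapply(spikes, function(s) {
    while (any(d0 <- diff(s) <= 0)) s[which(d0) + 1L] <- s[which(d0) + 1L] + 1e-9
    s
  })
  structure(list(trials = trials, spikes = spikes, counts = counts,
                 schedule = sch),
            class = "trial_spike_table")
}

#' Synthesize a stimulus-locked LFP with a planted CSD sink
#'
#' Builds an LFP matrix whose second spatial derivative contains one dominant
#' current sink with a known lower edge. The laminar profile is the exact
#' second antiderivative of an antisymmetric Gaussian sink/source pair centered
#' about `sink_depth_um`, so the sink-to-source zero crossing sits exactly at
#' the requested depth and is invariant under symmetric spatial smoothing.
#'
#' @param sink_depth_um lower edge of the sink (um from pia; the sink lies
#'   above it, the balancing source below).
#' @param amplitude sink amplitude (arbitrary LFP units); 0 gives a zero CSD.
#' @param channel_depths_um sorted channel depths (um from pia; >= 5 channels).
#' @param times_s time axis (s).
#' @param width_um half-separation of the sink/source pair (um).
#' @param onset_s stimulus onset on the time axis.
#' @return List with `lfp` (channels x time matrix), `channel_depths_um`,
#'   `times_s`.
#' @export
synth_lfp <- function(sink_depth_um, amplitude = 1,
                      channel_depths_um = seq(0, 2400, by = 20),
                      times_s = seq(0, 0.2, by = 0.001),
                      width_um = 150, onset_s = 0) {
  if (length(channel_depths_um) < 5) {
    stop("five-point CSD undefined for fewer than 5 channels")
  }
  stopifnot(!is.unsorted(channel_depths_um))
  if (sink_depth_um < min(channel_depths_um) ||
      sink_depth_um > max(channel_depths_um)) {
    stop("sink depth outside the probe span")
  }
  sig <- width_um / 1.5
  H <- function(x) x * stats::pnorm(x / sig) + sig^2 * stats::dnorm(x, sd = sig)
  z <- channel_depths_um
  prof <- amplitude * (H(z - (sink_depth_um - width_um)) -
                         H(z - (sink_depth_um + width_um)))
  tt <- pmax(times_s - onset_s, 0)
  tau <- 0.05
  s_t <- (tt / tau) * exp(1 - tt / tau)
  lfp <- outer(prof, s_t)
  list(lfp = lfp, channel_depths_um = z, times_s = times_s)
}
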