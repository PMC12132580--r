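# synthetic cohort generator: determinism, planted structure, recovery loops

test_that("make_cohort is deterministic, counts units, respects depth weights", {
  arch <- default_archetypes()[1:9]
  c1 <- make_cohort(arch, n_per_class = 20, seed = 7)
  c2 <- make_cohort(arch, n_per_class = 20, seed = 7)
  expect_identical(c1, c2)
  expect_length(c1$units, 180)
  expect_false(anyDuplicated(names(c1$units)) > 0)

  # degenerate depth distribution: all mass on layer 4C
  coh <- make_cohort(list(test_archetype(layer = "4C")), n_per_class = 40,
                     seed = 3)
  b <- coh$boundaries$edges
  depths <- vapply(coh$units, `[[`, 0, "depth_um")
  expect_true(all(depths >= b[3] & depths <= b[4]))
  expect_true(all(vapply(coh$units, `[[`, "", "layer") == "4C"))

  expect_error(make_cohort(list(), seed = 1), "empty")
  bad <- test_archetype()
  bad$depth_weights <- c(L99 = 1)
  expect_error(make_cohort(list(bad), seed = 1), "unknown layers")
})

test_that("synth_template plants shape, polarity and propagation profile", {
  flat <- test_archetype(propagation = list(profile = "flat", v_inv_ms_mm = 0))
  tp <- synth_template(flat)
  troughs <- apply(tp$voltages, 2, which.min)
  expect_true(all(troughs == troughs[tp$soma_channel]))

  tri <- test_archetype(ttp = 0.17, rep_ms = 0.14, triphasic = TRUE)
  w <- synth_template(tri)$voltages[, 6]
  i_tr <- which.min(w)
  expect_gt(max(w[1:(i_tr - 1)]), 0.3 * abs(w[i_tr]))
  expect_gt(max(w[(i_tr + 1):length(w)]), 0.3 * abs(w[i_tr]))

  # symmetric profile -> downstream asymmetry index ~ 0 (closed loop)
  sym <- test_archetype(propagation = list(profile = "symmetric",
                                           v_inv_ms_mm = 0.3))
  p <- propagation_profile(synth_template(sym))
  expect_lt(abs(p$si_signed), 0.05)

  too_narrow <- test_archetype(ttp = 0.05)
  expect_error(synth_template(too_narrow, sampling_rate_hz = 10000),
               "unresolvable")
})

test_that("classical features recover archetype widths within 10%", {
  for (arch in default_archetypes()[c("NS-1", "NS-3", "BS-2", "BS-4", "POS")]) {
    tp <- synth_template(arch)
    w <- tp$voltages[, tp$soma_channel]
    pol <- classify_polarity(w)
    f <- classical_features(w, tp$sampling_rate_hz, polarity = pol$polarity)
    expect_lt(abs(f$ttp_width_ms - arch$ttp_width_ms), 0.1 * arch$ttp_width_ms)
    expect_equal(f$amplitude_uV, arch$amplitude_uV, tolerance = 1e-6)
  }
})

test_that("synth_spikes is deterministic and conserves spike counts", {
  arch <- list(test_archetype("A", burst_model = list(
    type = "bursty", intra_burst_isi_ms = 4, burst_size_mean = 3,
    burst_prob = 0.4)), test_archetype("B"))
  edges <- data.frame(source = "u001", target = "u003", lag_ms = 3,
                      efficacy = 0.2, sign = "excitatory")
  coh <- make_cohort(arch, n_per_class = 2, schedule = mini_schedule(),
                     edges = edges, seed = 11)
  t1 <- synth_spikes(coh, seed = 5)
  t2 <- synth_spikes(coh, seed = 5)
  expect_identical(t1$spikes, t2$spikes)
  expect_true(all(vapply(t1$spikes, function(s) all(diff(s) > 0), TRUE)))
  expect_identical(lengths(t1$spikes),
                   stats::setNames(with(t1$counts,
                                        seed + burst + coupled_added -
                                          coupled_removed),
                                   t1$counts$unit_id))
  expect_gt(t1$counts$coupled_added[3], 0)
})

test_that("planted DI is recovered within 0.1 at 36 directions x 10 repeats", {
  arch <- test_archetype(tuning = list(pref_direction_deg = 200,
                                       target_DI = 0.8, target_OI = 0.6,
                                       baseline_rate_hz = 1,
                                       evoked_rate_hz = 25, latency_ms = 40))
  coh <- make_cohort(list(arch), n_per_class = 3,
                     schedule = stimulus_schedule(spatial_frequencies_cpd = 1,
                                                  repeats = 10),
                     seed = 5)
  tbl <- synth_spikes(coh, seed = 7)
  for (id in names(tbl$spikes)) {
    tr <- tuning_analysis(tbl$spikes[[id]], tbl$trials)
    expect_lt(abs(tr$DI - 0.8), 0.1)
    expect_lt(abs(tr$OI - 0.6), 0.1)
    expect_equal(tr$preferred$direction_deg, 200)
  }
})

test_that("non-bursty baseline train has exponential ISIs", {
  arch <- test_archetype(tuning = list(pref_direction_deg = 0, target_DI = 0,
                                       target_OI = 0, baseline_rate_hz = 20,
                                       evoked_rate_hz = 0, latency_ms = 40))
  coh <- make_cohort(list(arch), n_per_class = 1,
                     schedule = mini_schedule(repeats = 10), seed = 2)
  tbl <- synth_spikes(coh, seed = 3)
  isi <- diff(tbl$spikes[[1]])
  p <- suppressWarnings(stats::ks.test(isi, "pexp", rate = 20))$p.value
  expect_gt(p, 0.01)
  expect_lt(abs(1 / mean(isi) - 20), 3)
})

test_that("synth_lfp plants a CSD sink with a known lower edge", {
  lfp <- synth_lfp(1000, amplitude = 5)
  cs <- compute_csd(lfp)
  expect_lt(abs(cs$reversal_depth_um - 1000), 20) # one channel pitch

  # translation equivariance
  cs2 <- compute_csd(synth_lfp(1200, amplitude = 5))
  expect_lt(abs(cs2$reversal_depth_um - cs$reversal_depth_um - 200), 20)

  # zero amplitude -> zero CSD
  cs0 <- compute_csd(synth_lfp(1000, amplitude = 0))
  expect_true(all(abs(cs0$csd[!is.na(cs0$csd)]) < 1e-12))

  expect_error(synth_lfp(1000, channel_depths_um = c(0, 20, 40, 60)),
               "5 channels")
  expect_error(synth_lfp(5000), "outside")
})
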