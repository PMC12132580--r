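# PSTH, responsiveness, latency, selectivity indices, modulation ratio

test_that("compute_psth conserves spike mass and estimates rates", {
  trials <- std_trials(10)
  p0 <- compute_psth(numeric(0), trials$onset_s)
  expect_true(all(p0$rate_hz == 0) && all(p0$sem == 0))

  # one spike in one of 10 trials, mid-window: integral = 1/10 spikes
  p1 <- compute_psth(trials$onset_s[1] + 0.067 + 0.2, trials$onset_s)
  expect_equal(sum(p1$rate_hz) * 0.001, 0.1, tolerance = 0.01)

  set.seed(1)
  trials50 <- std_trials(50)
  sp <- poisson_session(20, trials50)
  p <- compute_psth(sp, trials50$onset_s)
  expect_lt(abs(mean(p$rate_hz) - 20), 2)
})

test_that("responsiveness requires both significance and rate excess", {
  trials <- std_trials(50)
  set.seed(2)
  flat <- poisson_session(10, trials)
  expect_false(responsiveness(flat, trials))
  expect_false(responsiveness(numeric(0), trials))

  on <- trials$onset_s + 0.067
  evoked <- sort(c(unlist(lapply(on, function(o) {
    runif(rpois(1, 20), o, o + 1)
  })), unlist(lapply(on, function(o) runif(rpois(1, 0.5), o - 0.25, o)))))
  expect_true(responsiveness(evoked, trials))
})

test_that("latency finds a planted step and returns NA for flat rates", {
  trials <- std_trials(60)
  set.seed(3)
  on <- trials$onset_s + 0.067
  sp <- sort(c(
    unlist(lapply(on, function(o) runif(rpois(1, 5 * 1.25), o - 0.25, o + 1))),
    unlist(lapply(on, function(o) runif(rpois(1, 45 * 0.95), o + 0.05, o + 1)))))
  p <- compute_psth(sp, trials$onset_s)
  expect_lt(abs(latency(p) - 50), 10)

  # a truly flat rate (regular train, identical across trials) -> no latency
  reg <- unlist(lapply(trials$onset_s, function(o) {
    seq(o - 0.245, o + 1.245, by = 0.01)
  }))
  flat <- compute_psth(reg, trials$onset_s)
  expect_true(is.na(latency(flat)))
})

test_that("DI and OI follow their definitions and are scale invariant", {
  expect_equal(direction_index(30, 10), 0.5)
  expect_equal(direction_index(7, 0), 1)
  expect_equal(direction_index(5, 5), 0)
  expect_warning(di0 <- direction_index(0, 0), "undefined")
  expect_true(is.na(di0))

  expect_equal(orientation_index(40, 10), 0.6)
  expect_equal(orientation_index(3, 3), 0)

  set.seed(4)
  for (i in 1:10) {
    r <- runif(2, 0, 50)
    c_ <- runif(1, 0.1, 10)
    expect_equal(direction_index(r[1], r[2]),
                 direction_index(c_ * r[1], c_ * r[2]))
    expect_equal(orientation_index(r[1], r[2]),
                 orientation_index(c_ * r[1], c_ * r[2]))
  }
})

test_that("modulation ratio distinguishes modulated and constant responses", {
  trials <- std_trials(100)
  on <- trials$onset_s + 0.067
  set.seed(5)
  # r(t) = m (1 + cos 2 pi f t): ratio -> 1
  f <- 4
  sin_sp <- unlist(lapply(on, function(o) {
    tt <- seq(0, 1, by = 1e-4)
    lam <- 30 * (1 + cos(2 * pi * f * tt)) * 1e-4
    (o + tt)[runif(length(tt)) < lam]
  }))
  mr <- modulation_ratio(sin_sp, trials$onset_s, f)
  expect_lt(abs(mr$ratio - 1), 0.1)

  const_sp <- unlist(lapply(on, function(o) sort(runif(rpois(1, 30), o, o + 1))))
  mrc <- modulation_ratio(const_sp, trials$onset_s, f)
  expect_lt(mrc$ratio, 0.2)
  expect_equal(mrc$cell_form, "complex")

  # all spikes at one phase: strongly modulated -> simple
  lock_sp <- unlist(lapply(on, function(o) o + (0:3) / f))
  mrl <- modulation_ratio(lock_sp, trials$onset_s, f)
  expect_gt(mrl$ratio, 1)
  expect_equal(mrl$cell_form, "simple")

  expect_error(modulation_ratio(numeric(0), trials$onset_s, f), "F0 = 0")
  expect_error(modulation_ratio(sin_sp, trials$onset_s, 0.5), "one.*cycle")
})

test_that("tuning_analysis ties preferred-condition selection together", {
  arch <- test_archetype(tuning = list(pref_direction_deg = 90,
                                       target_DI = 0.6, target_OI = 0.5,
                                       baseline_rate_hz = 1,
                                       evoked_rate_hz = 25, latency_ms = 50))
  coh <- make_cohort(list(arch), n_per_class = 1,
                     schedule = stimulus_schedule(spatial_frequencies_cpd = c(1, 2),
                                                  repeats = 8),
                     seed = 5)
  tbl <- synth_spikes(coh, seed = 9)
  tr <- tuning_analysis(tbl$spikes[[1]], tbl$trials)
  dd <- abs(tr$preferred$direction_deg - 90)
  expect_lte(min(dd, 360 - dd), 10) # at most one direction step off
  expect_lt(abs(tr$DI - 0.6), 0.12)
  expect_lt(abs(tr$OI - 0.5), 0.15)
  expect_true(tr$responsive)
  expect_lt(abs(tr$latency_ms - 50), 15)
})
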