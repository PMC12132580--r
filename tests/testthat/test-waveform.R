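# waveform curation: polarity, alignment, classical features, SNR filter

test_that("classify_polarity applies the order and flanking-peak rules", {
  t_ms <- seq(0, 1.8, length.out = 54)
  neg <- -exp(-(t_ms - 0.4)^2 / (2 * 0.05^2)) +
    0.4 * exp(-(t_ms - 0.7)^2 / (2 * 0.1^2))
  expect_identical(classify_polarity(neg),
                   list(polarity = "negative", triphasic = FALSE))
  expect_identical(classify_polarity(rev(neg))$polarity, "positive")

  tri <- -exp(-(t_ms - 0.9)^2 / (2 * 0.05^2)) +
    0.5 * exp(-(t_ms - 0.6)^2 / (2 * 0.08^2)) +
    0.5 * exp(-(t_ms - 1.2)^2 / (2 * 0.08^2))
  expect_identical(classify_polarity(tri),
                   list(polarity = "negative", triphasic = TRUE))

  expect_error(classify_polarity(rep(1, 54)), "constant")
})

test_that("polarity of a time-reversed biphasic waveform always flips", {
  set.seed(4)
  t_ms <- seq(0, 1.8, length.out = 54)
  for (i in 1:25) {
    tr <- runif(1, 0.3, 0.8)
    w <- -runif(1, 0.5, 2) * exp(-(t_ms - tr)^2 / (2 * runif(1, 0.03, 0.1)^2)) +
      0.3 * exp(-(t_ms - tr - runif(1, 0.15, 0.4))^2 / (2 * 0.1^2))
    p1 <- classify_polarity(w)
    p2 <- classify_polarity(rev(w))
    if (!p1$triphasic && !p2$triphasic) {
      expect_false(p1$polarity == p2$polarity)
    }
  }
})

test_that("align_normalize centers the extremum, is idempotent and scale invariant", {
  w <- c(rep(0.01, 19), -1, rep(0.02, 34)) # trough at sample 20, n = 54
  a <- align_normalize(w, "negative")
  expect_equal(which.min(a), 28) # n %/% 2 + 1
  # direct index computation: right shift by 8 with edge fill at the front
  expect_equal(a, c(rep(0.01, 8), w[1:46]) / 1)
  expect_equal(align_normalize(a, "negative"), a)
  expect_equal(align_normalize(w * 10, "negative"), a)
  # already aligned with extremum -1: unchanged
  w2 <- c(rep(0, 27), -1, rep(0, 26))
  expect_equal(align_normalize(w2, "negative"), w2)
  expect_error(align_normalize(rep(0, 54), "negative"), "zero")
})

test_that("classical_features measures ttp, repolarization, amplitude", {
  fs <- 20000 # 0.05 ms samples
  n <- 60
  w <- rep(0, n)
  # symmetric parabolic trough at 0.60 ms, peak at 0.85 ms (exact under
  # parabolic interpolation)
  w[12:14] <- c(-0.9, -1, -0.9)  # trough centered at sample 13 = 0.60 ms
  w[17:19] <- c(0.5, 0.6, 0.5)   # peak centered at sample 18 = 0.85 ms
  f <- classical_features(w, fs, scale_to_uV = 2.3)
  expect_equal(f$ttp_width_ms, 0.25, tolerance = 1e-9)
  expect_equal(f$amplitude_uV, 1.6 * 2.3, tolerance = 1e-9)

  # template units peak - trough = 40 -> 92 uV
  w40 <- rep(0, n)
  w40[13] <- -25
  w40[18] <- 15
  expect_equal(classical_features(w40, fs)$amplitude_uV, 92)

  # linear decay from the peak reaching half-peak 0.40 ms later
  wlin <- rep(0, 40)
  wlin[5] <- -1
  wlin[10:30] <- seq(1, 1 - 20 * 0.0625, by = -0.0625) # half (0.5) 8 samples on
  f2 <- classical_features(wlin, fs)
  expect_equal(f2$repolarization_ms, 0.40, tolerance = 1e-9)
})

test_that("snr_filter uses exclusive low and inclusive high bounds", {
  snr <- c(-0.1, 0, 1.0, 3.7, 3.8)
  expect_equal(snr_filter(snr), c(1.0, 3.7))
  units <- lapply(snr, function(s) list(unit_id = as.character(s), snr = s))
  kept <- snr_filter(units)
  expect_equal(vapply(kept, `[[`, 0, "snr"), c(1.0, 3.7))
  expect_length(snr_filter(numeric(0)), 0)
})

test_that("curate_units produces a consistent feature table", {
  coh <- make_cohort(default_archetypes()[c("NS-1", "BS-3", "POS")],
                     n_per_class = 4, seed = 9)
  cur <- curate_units(coh$units)
  expect_equal(nrow(cur$features), length(cur$units))
  expect_true(all(cur$features$snr > 0 & cur$features$snr <= 3.7))
  pos <- cur$features$polarity == "positive"
  expect_equal(sum(pos), 4)
  norm <- t(vapply(cur$units, `[[`, numeric(54), "normalized"))
  expect_true(all(abs(apply(abs(norm), 1, max) - 1) < 1e-12))
})
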