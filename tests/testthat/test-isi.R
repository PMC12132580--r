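# ISI histograms, ISI-PCA, bursting index, shuffle test

test_that("isi_histogram normalizes to max 1 and locates the peak", {
  train <- seq(0, 1, by = 0.010) # perfectly regular 10 ms
  h <- isi_histogram(train)
  expect_equal(max(h$hist), 1)
  expect_equal(sum(h$hist > 0), 1)
  expect_lt(abs(h$peak_isi_ms - 10), 0.2)

  h2 <- isi_histogram(c(0, 0.005))
  expect_equal(sum(h2$hist), 1)
  expect_lt(abs(h2$peak_isi_ms - 5), 0.2)

  expect_error(isi_histogram(1.0), "2 spikes")

  # shift invariance
  set.seed(1)
  sp <- cumsum(rexp(500, 20))
  expect_identical(isi_histogram(sp)$hist, isi_histogram(sp + 123.4)$hist)
})

test_that("Poisson train gives a decaying ISI histogram at the right rate", {
  set.seed(2)
  sp <- cumsum(rexp(20000, 20))
  h <- isi_histogram(sp)
  isis <- diff(sp)
  expect_lt(abs(1 / mean(isis) - 20), 3)
  # decaying beyond the first bins
  first <- mean(h$hist[5:50])
  last <- mean(h$hist[200:250])
  expect_gt(first, last)
})

test_that("isi_pca reconstructs data, fixes signs, and flags degeneracy", {
  set.seed(3)
  bursty <- t(replicate(20, {
    h <- dgamma(seq(0.2, 100, by = 0.4), shape = 2, rate = 0.4) +
      rnorm(250, sd = 0.002)
    h / max(h)
  }))
  expo <- t(replicate(20, {
    h <- dexp(seq(0.2, 100, by = 0.4), rate = 0.03) + rnorm(250, sd = 0.002)
    h / max(h)
  }))
  m <- rbind(bursty, expo)
  pc <- isi_pca(m)
  expect_false(pc$degenerate)
  # completeness: scores x rotation' + center reproduces the data
  rec <- pc$loadings %*% t(pc$components) +
    matrix(pc$center, nrow(m), ncol(m), byrow = TRUE)
  expect_lt(max(abs(rec - m)), 1e-8)
  # sign conventions: PC1 points toward short-ISI concentration, PC3 dips
  expect_gt(mean(pc$components[1:25, 1]), mean(pc$components[, 1]))
  expect_lt(mean(pc$components[1:25, 3]), 0)
  # PC1 separates the two shapes (two-sample AUC >= 0.9)
  l1 <- pc$loadings[, 1]
  auc <- mean(outer(l1[1:20], l1[21:40], ">")) # P(bursty > expo)
  expect_gte(max(auc, 1 - auc), 0.9)

  expect_warning(deg <- isi_pca(matrix(1, 5, 10)), "degenerate")
  expect_true(deg$degenerate)
  expect_true(all(deg$loadings == 0))
})

test_that("bursting_index is the PC1 - PC3 loading difference", {
  expect_equal(bursting_index(1, 0), 1)
  expect_equal(bursting_index(0.5, -0.5), 1)
  expect_equal(bursting_index(0, 0), 0)
})

test_that("planted bursty units have higher bursting index than Poisson units", {
  mk <- function(bm) test_archetype(tuning = list(
    pref_direction_deg = 0, target_DI = 0.2, target_OI = 0.2,
    baseline_rate_hz = 4, evoked_rate_hz = 15, latency_ms = 40),
    burst_model = bm)
  arch <- list(mk(list(type = "bursty", intra_burst_isi_ms = 4,
                       burst_size_mean = 3, burst_prob = 0.4)),
               mk(list(type = "poisson")))
  arch[[1]]$name <- "bursty"
  arch[[2]]$name <- "poisson"
  coh <- make_cohort(arch, n_per_class = 25,
                     schedule = mini_schedule(repeats = 3), seed = 17)
  tbl <- synth_spikes(coh, seed = 18)
  hm <- t(vapply(tbl$spikes, function(s) isi_histogram(s)$hist, numeric(250)))
  bi <- bursting_index(isi_pca(hm))
  grp <- vapply(coh$units, `[[`, "", "archetype")
  p <- stats::wilcox.test(bi[grp == "bursty"], bi[grp == "poisson"],
                          alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("shuffle_test flags planted outlier clusters and is deterministic", {
  vals <- rep(1, 30)
  labs <- rep(1:3, each = 10)
  none <- shuffle_test(vals, labs, n_shuffles = 100, seed = 4)
  expect_false(any(none$clusters$significant))

  set.seed(5)
  hits <- vapply(1:40, function(i) {
    v <- c(rnorm(10, 10), rnorm(20, 1))
    st <- shuffle_test(v, labs, n_shuffles = 200, seed = i)
    st$clusters$significant[1]
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  v <- rnorm(30)
  s1 <- shuffle_test(v, labs, seed = 9)
  s2 <- shuffle_test(v, labs, seed = 9)
  expect_identical(s1, s2)

  expect_error(shuffle_test(vals, rep(1, 30)), "2 clusters")
})
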