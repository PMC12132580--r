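# WaveMAP clustering, resolution sweep, separability CV, merge map

test_that("build_wavemap is deterministic and handles degenerate input", {
  set.seed(1)
  wf <- rbind(family_waveforms(0.20, 40), family_waveforms(0.55, 40))
  wm1 <- build_wavemap(wf, seed = 11)
  wm2 <- build_wavemap(wf, seed = 11)
  expect_identical(wm1$labels, wm2$labels)
  expect_equal(length(wm1$labels), 80)
  expect_equal(dim(wm1$embedding), c(80, 2))

  same <- matrix(rep(wf[1, ], 100), 100, byrow = TRUE)
  expect_equal(length(unique(build_wavemap(same)$labels)), 1)

  expect_error(build_wavemap(wf[1:10, ]), "fewer waveforms")
})

test_that("planted families are recovered up to refinement", {
  # Louvain at its modularity optimum may subdivide a homogeneous family;
  # the partition must still nest within the planted families and separate
  # them perfectly once clusters are collapsed by majority family.
  set.seed(2)
  truth <- rep(1:2, each = 100)
  wf <- rbind(family_waveforms(0.20, 100), family_waveforms(0.55, 100))
  wm <- build_wavemap(wf, seed = 5)
  mm <- merge_map(truth, wm$labels)
  expect_true(mm$coarsening)
  expect_true(all(mm$absorbed_fraction == 1)) # clean gap: exact nesting
  major <- vapply(split(truth, wm$labels), function(x) {
    as.integer(names(which.max(table(x))))
  }, 0L)
  collapsed <- major[as.character(wm$labels)]
  expect_equal(adjusted_rand_index(collapsed, truth), 1)
})

test_that("resolution_sweep picks the max-modularity resolution and trends up", {
  set.seed(3)
  wf <- rbind(family_waveforms(0.20, 60), family_waveforms(0.55, 60))
  res <- c(0.2, 0.5, 1, 2, 4)
  rs <- resolution_sweep(wf, resolutions = res, n_runs = 6, seed = 13)
  expect_equal(rs$chosen_resolution,
               res[which.max(rs$sweep$modularity_mean)])
  # cluster count non-decreasing in resolution on average
  rho <- stats::cor(rs$sweep$resolution, rs$sweep$n_clusters_mean,
                    method = "spearman")
  expect_gt(rho, 0)
  expect_error(resolution_sweep(wf[1:20, ], resolutions = 1,
                                subsample_frac = 0.5),
               "subsample too small")
})

test_that("single isotropic family has low modularity at all resolutions", {
  set.seed(6)
  wf <- matrix(rnorm(120 * 54), 120) # one isotropic cloud
  rs <- resolution_sweep(wf, resolutions = c(0.5, 1, 2), n_runs = 4, seed = 3)
  expect_true(all(rs$sweep$modularity_mean < 0.4))
})

test_that("separability_cv separates planted clusters and rows sum to 100", {
  set.seed(4)
  wf <- rbind(family_waveforms(0.20, 40), family_waveforms(0.55, 40))
  labels <- rep(1:2, each = 40)
  rep_ <- separability_cv(wf, labels, seed = 21)
  expect_gte(rep_$mean_accuracy, 99)
  expect_true(all(abs(rowSums(rep_$confusion) - 100) < 0.1))

  expect_error(separability_cv(wf, c(rep(1, 77), 2, 2, 2)), "at least")
})

test_that("separability on permuted labels is at chance", {
  set.seed(5)
  wf <- rbind(family_waveforms(0.20, 60), family_waveforms(0.55, 60))
  accs <- vapply(1:3, function(i) {
    separability_cv(wf, sample(rep(1:4, 30)), seed = i)$mean_accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 25), 5)
})

test_that("merge_map reports absorption and coarsening", {
  low <- rep(1:2, each = 10)
  high <- c(rep(1, 5), rep(2, 5), rep(3, 10))
  mm <- merge_map(low, high)
  expect_setequal(mm$mapping[["1"]], c("1", "2"))
  expect_equal(mm$mapping[["2"]], "3")
  expect_true(mm$coarsening)

  ident <- merge_map(low, low)
  expect_true(ident$coarsening)
  expect_equal(lengths(ident$mapping), c("1" = 1L, "2" = 1L))

  set.seed(8)
  rand_mm <- merge_map(sample(1:5, 200, TRUE), sample(1:5, 200, TRUE))
  expect_false(rand_mm$coarsening)

  expect_error(merge_map(1:5, 1:6), "different unit sets")
})

test_that("canonicalize_clusters orders labels by descending median width", {
  labels <- c(2, 2, 7, 7, 5, 5)
  widths <- c(0.2, 0.22, 0.6, 0.58, 0.4, 0.42)
  out <- canonicalize_clusters(labels, widths)
  expect_equal(out, c(3, 3, 1, 1, 2, 2))
})
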