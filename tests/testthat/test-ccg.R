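# cross-correlograms: Eq-4 oracle, jitter correction, classification, lead-lag

test_that("compute_ccg matches the brute-force pair-counting oracle", {
  set.seed(1)
  trials <- std_trials(4)
  sj <- sort(runif(60, 0, 5))
  sk <- sort(runif(80, 0, 5))
  cc <- compute_ccg(sj, sk, trials)
  expect_identical(cc$pair_counts, bruteforce_ccg_counts(sj, sk, trials))
  # normalization identity
  expect_equal(cc$raw, cc$pair_counts /
                 (cc$M * cc$theta * cc$lambda_j * cc$lambda_k))
  expect_equal(cc$theta[cc$lags_ms == 0], cc$N)
  expect_error(compute_ccg(sj, numeric(0), trials), "zero spikes")
  expect_error(compute_ccg(sj, sk, trials[1, ]), "2 trials")
})

test_that("independent trains sit at raw baseline 1 and corrected baseline 0", {
  set.seed(2)
  trials <- std_trials(200)
  sj <- poisson_session(20, trials)
  sk <- poisson_session(20, trials)
  cc <- jitter_correct(compute_ccg(sj, sk, trials))
  expect_lt(abs(mean(cc$raw) - 1), 0.05)
  se <- stats::sd(cc$corrected) / sqrt(length(cc$corrected))
  expect_lt(abs(mean(cc$corrected)), 3 * se)
})

test_that("a shifted copy peaks at its lag and the mirror identity is exact", {
  set.seed(3)
  trials <- std_trials(40)
  sj <- poisson_session(25, trials)
  sk <- sj + 0.005
  cc <- compute_ccg(sj, sk, trials)
  expect_equal(cc$lags_ms[which.max(cc$raw)], 5) # reference leads
  rev_cc <- compute_ccg(sk, sj, trials)
  expect_identical(rev_cc$raw, rev(cc$raw))
})

test_that("geometric-mean normalization is available as a switch", {
  set.seed(8)
  trials <- std_trials(20)
  sj <- poisson_session(10, trials)
  sk <- poisson_session(40, trials)
  a <- compute_ccg(sj, sk, trials)
  b <- compute_ccg(sj, sk, trials, normalization = "geometric_mean")
  expect_equal(b$raw, a$raw * sqrt(a$lambda_j * a$lambda_k))
})

test_that("jitter correction removes slow comodulation, keeps fast structure", {
  set.seed(4)
  trials <- std_trials(150)
  gen_mod <- function() {
    unlist(lapply(trials$onset_s, function(o) {
      tt <- seq(0, 1.25, by = 5e-4) - 0.25
      lam <- 25 * (1 + sin(2 * pi * tt / 0.2)) * 5e-4
      (o - 0.25 + tt)[runif(length(tt)) < lam]
    }))
  }
  cc <- jitter_correct(compute_ccg(gen_mod(), gen_mod(), trials))
  # amplitude of the 200 ms-period component before vs after correction
  proj <- function(v) Mod(sum(v * exp(2i * pi * cc$lags_ms / 200)))
  expect_lt(proj(cc$corrected) / proj(cc$raw - 1), 0.2)

  # planted 2 ms synaptic coupling survives
  sj <- poisson_session(20, trials)
  sk <- sort(c(poisson_session(15, trials),
               sj[runif(length(sj)) < 0.2] + 0.002))
  cc2 <- jitter_correct(compute_ccg(sj, sk, trials))
  base <- mean(cc2$raw[abs(cc2$lags_ms) >= 50])
  raw_peak <- max(cc2$raw[abs(cc2$lags_ms) <= 10]) - base
  cor_peak <- max(cc2$corrected[abs(cc2$lags_ms) <= 10])
  expect_gt(cor_peak / raw_peak, 0.8)
  expect_error(jitter_correct(cc2, jitter_ms = 0.5), "smaller than")
})

test_that("classify_pair applies the 7/5 SD rules around zero lag", {
  set.seed(5)
  noise <- rnorm(201, 0, 0.02)
  flat <- fake_ccg(noise)
  expect_equal(classify_pair(flat)$kind, "ns")

  sdn <- stats::sd(noise[abs(seq(-100, 100)) >= 50])
  exc <- noise
  exc[104] <- 10 * sdn # lag +3 ms
  cl <- classify_pair(fake_ccg(exc))
  expect_equal(cl$kind, "excitatory")
  expect_equal(cl$extremum_lag_ms, 3)
  expect_gt(cl$extremum_z, 7)

  inh <- noise
  inh[97] <- -8 * sdn # lag -4 ms
  cli <- classify_pair(fake_ccg(inh))
  expect_equal(cli$kind, "inhibitory")
  expect_equal(cli$extremum_lag_ms, -4)

  dg <- classify_pair(fake_ccg(rep(0, 201)))
  expect_equal(dg$kind, "ns")
  expect_true(dg$degenerate)
})

test_that("lead_lag_index hits the defining extremes exactly", {
  v <- rep(0, 201)
  v[105] <- 0.5 # all mass at +4 ms
  expect_equal(lead_lag_index(fake_ccg(v))$ca, 1)
  expect_equal(lead_lag_index(fake_ccg(rev(v)))$ca, -1)
  sym <- rep(0, 201)
  sym[c(97, 105)] <- 0.3
  ll <- lead_lag_index(fake_ccg(sym))
  expect_equal(ll$ca, 0)
  expect_equal(ll$band, "common_input")
  expect_warning(und <- lead_lag_index(fake_ccg(rep(-1, 201))), "undefined")
  expect_true(is.na(und$ca))
})

test_that("cluster_pair_graph is antisymmetric and finds planted direction", {
  set.seed(6)
  pairs <- data.frame(
    ref = sprintf("a%d", 1:30), tgt = sprintf("b%d", 1:30),
    kind = "excitatory", extremum_lag_ms = 3, extremum_z = 10,
    ca = pmin(1, rnorm(30, 0.7, 0.2)),
    ref_cluster = "NS", tgt_cluster = "BS",
    ref_layer = "4C", tgt_layer = "2/3")
  g <- cluster_pair_graph(pairs)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$source, "NS")
  expect_equal(g$edges$target, "BS")
  expect_lt(g$edges$p, 0.01)

  # antisymmetry: flipping the orientation of some rows changes nothing
  pairs2 <- pairs
  flip <- seq(1, 30, by = 2)
  pairs2$ref_cluster[flip] <- "BS"
  pairs2$tgt_cluster[flip] <- "NS"
  pairs2$ca[flip] <- -pairs2$ca[flip]
  g2 <- cluster_pair_graph(pairs2)
  expect_equal(abs(g2$summary$median_ca), abs(g$summary$median_ca))
  expect_equal(g2$edges$source, "NS")
})
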