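# Ephys module: event detection, TTX window comparison, Gaussian-histogram
# holding currents, agonist shifts, and Nernst potentials from recipes.

test_that("nernst potential has the right values and symmetries", {
  # in = out -> 0 for any valence
  expect_equal(nernst(1, 10, 10), 0)
  expect_equal(nernst(-2, 3.5, 3.5), 0)
  # antisymmetry under swapping in/out
  expect_equal(nernst(-1, 12.7, 132.5), -nernst(-1, 132.5, 12.7))
  # K+ at 10x gradient, 20 C: classic ~ -58.2 mV (RT/F ln10)
  expect_equal(nernst(1, 100, 10, temp_C = 20), -58.17, tolerance = 0.01)
  expect_error(nernst(-1, 0, 100), "positive")
})

test_that("solution recipes derive chloride totals stoichiometrically", {
  exc <- recipe_internal_excitatory()
  inh <- recipe_internal_inhibitory()
  acsf <- recipe_acsf()
  # 7.7 KCl + 4 NaCl + 2 x 0.5 CaCl2 = 12.7 mM
  expect_equal(exc$cl_mM, 12.7)
  # 1.4 NaCl + 2 x 1.5 MgCl2 + 2 x 0.5 CaCl2 = 5.4 mM
  expect_equal(inh$cl_mM, 5.4)
  # 124 NaCl + 2.5 KCl + 2 x 1 CaCl2 + 2 x 2 MgCl2 = 132.5 mM
  expect_equal(acsf$cl_mM, 132.5)
  # gluconate and HEPES contribute no chloride
  expect_equal(solution_recipe(c(K_gluconate = 140, HEPES = 10))$cl_mM, 0)
  expect_error(solution_recipe(c(KCl = -1)), ">= 0")
})

test_that("reversal potentials match the published values", {
  # excitatory internal vs aCSF at 33 C -> ~ -62 mV
  expect_equal(e_rev_cl(recipe_internal_excitatory()), -62, tolerance = 0.02)
  # inhibitory internal vs aCSF -> ~ -85 mV (within the 32-37 C spread)
  expect_equal(e_rev_cl(recipe_internal_inhibitory()), -85, tolerance = 0.02)
})

test_that("detect_events finds generated events and respects the refractory", {
  sim <- simulate_current_trace(ephys_gen_spec(
    duration_s = 30, event_rate_pre_hz = 2, ttx_onset_s = NA, seed = 5))
  ev <- detect_events(sim$trace, threshold_pA = 15)
  # >= 95% recall with times within 2 ms
  hits <- vapply(sim$truth$time_s,
                 function(t) min(abs(ev$time_s - t)) < 0.002, logical(1))
  expect_gte(mean(hits), 0.95)
  # no spurious detections on this trace
  fp <- vapply(ev$time_s,
               function(t) min(abs(sim$truth$time_s - t)) > 0.005, logical(1))
  expect_equal(sum(fp), 0L)
  expect_true(all(diff(ev$time_s) > 0))
  expect_true(all(ev$amplitude_pA > 0))

  # noise-only trace at 5x noise SD: < 0.05 Hz false rate
  fp_rate <- vapply(1:10, function(s) {
    simn <- simulate_current_trace(ephys_gen_spec(
      duration_s = 20, event_rate_pre_hz = 0, ttx_onset_s = NA, seed = s))
    nrow(detect_events(simn$trace, threshold_pA = 15)) / 20
  }, numeric(1))
  expect_lt(mean(fp_rate), 0.05)

  # two events 1 ms apart with a 5-ms refractory merge into one
  spec <- ephys_gen_spec(duration_s = 1, event_rate_pre_hz = 0,
                         ttx_onset_s = NA, noise_sd_pA = 0, seed = 1)
  sim2 <- simulate_current_trace(spec)
  fs <- sim2$trace$sample_rate_hz
  tau_r <- 0.5 / 1000; tau_d <- 5 / 1000
  tp <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  pk <- exp(-tp / tau_d) - exp(-tp / tau_r)
  tk <- (0:round(0.04 * fs)) / fs
  kern <- (exp(-tk / tau_d) - exp(-tk / tau_r)) / pk
  v <- rep(-100, fs)
  for (t0 in c(0.5, 0.501)) {
    i0 <- floor(t0 * fs) + 1
    v[i0:(i0 + length(kern) - 1)] <-
      v[i0:(i0 + length(kern) - 1)] - 30 * kern
  }
  ev2 <- detect_events(current_trace(v, fs), threshold_pA = 15,
                       min_interval_ms = 5)
  expect_equal(nrow(ev2), 1L)
  # an empty trace is rejected at construction
  expect_error(current_trace(numeric(0), 20000))
})

test_that("ttx_comparison uses the stated windows and conserves counts", {
  # homogeneous train -> equal frequencies
  ev <- data.frame(time_s = seq(0.5, 499.5, by = 1))
  cmp <- ttx_comparison(ev, ttx_onset_s = 200, duration_s = 500)
  expect_equal(cmp$baseline_freq_hz, 1)
  expect_equal(cmp$post_freq_hz, 1)
  # counts are consistent with the full list
  expect_equal(cmp$baseline_n,
               sum(ev$time_s >= 20 & ev$time_s < 200))
  expect_equal(cmp$post_n,
               sum(ev$time_s >= 300 & ev$time_s < 480))
  # no events -> 0/0 Hz
  cmp0 <- ttx_comparison(data.frame(time_s = numeric(0)), 200,
                         duration_s = 500)
  expect_equal(cmp0$baseline_freq_hz, 0)
  expect_equal(cmp0$post_freq_hz, 0)
  # insufficient coverage errors, naming the span
  expect_error(ttx_comparison(ev, 100, duration_s = 500), "coverage")
  expect_error(ttx_comparison(ev, 300, duration_s = 500), "coverage")

  # generator pre 2 Hz / post 1 Hz -> ratio ~ 0.5 on ground-truth trains
  set.seed(77)
  spec <- ephys_gen_spec(duration_s = 480, event_rate_pre_hz = 2,
                         event_rate_post_hz = 1, ttx_onset_s = 200)
  ratios <- vapply(1:100, function(s) {
    tr <- microquant:::simulate_event_train(spec)
    cmp <- ttx_comparison(tr, 200, duration_s = 480)
    cmp$post_freq_hz / cmp$baseline_freq_hz
  }, numeric(1))
  expect_equal(mean(ratios), 0.5, tolerance = 0.05)
})

test_that("holding_current fits the histogram robustly", {
  # constant trace
  expect_equal(holding_current(rep(-50, 1000))$mean_pA, -50)
  # Gaussian noise around -100, SD 5 -> fitted mean within 0.5 pA
  set.seed(42)
  seg <- rnorm(400000, -100, 5)
  hc <- holding_current(seg)
  expect_equal(hc$mean_pA, -100, tolerance = 0.5 / 100)
  expect_equal(hc$method, "gaussian_fit")
  # with sparse 40-pA events the fitted mode beats the plain mean
  sim <- simulate_current_trace(ephys_gen_spec(
    duration_s = 20, event_rate_pre_hz = 1, ttx_onset_s = NA,
    amplitude_mean_pA = 40, amplitude_sd_pA = 1, decay_ms = 50,
    noise_sd_pA = 5, holding_pA = -100, seed = 8))
  hc2 <- holding_current(sim$trace$samples)
  expect_lt(abs(hc2$mean_pA - (-100)), abs(mean(sim$trace$samples) - (-100)))
})

test_that("agonist_current recovers induced steps with the right sign", {
  base <- ephys_gen_spec(duration_s = 120, event_rate_pre_hz = 0.5,
                         ttx_onset_s = NA, agonist_onset_s = 60,
                         noise_sd_pA = 4, holding_pA = -80, seed = 9)
  # no step -> ~0
  b0 <- base; b0$agonist_step_pA <- 0
  sim0 <- simulate_current_trace(b0)
  expect_lt(abs(agonist_current(sim0$trace, 60)$shift_pA), 2)
  # injected -50 pA step -> -50 +- 1
  bneg <- base; bneg$agonist_step_pA <- -50
  simn <- simulate_current_trace(bneg)
  agn <- agonist_current(simn$trace, 60)
  expect_equal(agn$shift_pA, -50, tolerance = 1 / 50)
  # sign follows the step polarity
  bpos <- base; bpos$agonist_step_pA <- 35
  simp <- simulate_current_trace(bpos)
  expect_equal(agonist_current(simp$trace, 60)$shift_pA, 35,
               tolerance = 1.5 / 35)
  expect_error(agonist_current(simn$trace, 5), ">= 20 s")
})

test_that("event-frequency estimator is unbiased over Poisson simulations", {
  set.seed(123)
  spec <- ephys_gen_spec(duration_s = 480, event_rate_pre_hz = 1.5,
                         event_rate_post_hz = 0.7, ttx_onset_s = 200)
  est <- t(vapply(1:500, function(s) {
    tr <- microquant:::simulate_event_train(spec)
    cmp <- ttx_comparison(tr, 200, duration_s = 480)
    c(cmp$baseline_freq_hz, cmp$post_freq_hz)
  }, numeric(2)))
  se_b <- sd(est[, 1]) / sqrt(500)
  se_p <- sd(est[, 2]) / sqrt(500)
  expect_lt(abs(mean(est[, 1]) - 1.5), 2 * se_b)
  expect_lt(abs(mean(est[, 2]) - 0.7), 2 * se_p)
})
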