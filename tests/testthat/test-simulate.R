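# Synthetic-data generators: ground truth must match rendered content, seeds
# must reproduce bit-identically, and stated rates must be honoured.

test_that("trace generator honours rate, kernel area, and determinism", {
  # no events, no noise, no drift -> flat zero trace, empty truth
  flat <- simulate_trace(trace_gen_spec(transient_rate_per_min = 0,
                                        noise_sd_dff = 0, seed = 1))
  expect_equal(flat$trace$values, rep(0, 300))
  expect_equal(nrow(flat$truth), 0L)

  # Poisson mean: 0.13/min over 300 s -> 0.65 events on average
  counts <- vapply(1:1000, function(s) {
    nrow(simulate_trace(trace_gen_spec(seed = s))$truth)
  }, numeric(1))
  expect_equal(mean(counts), 0.65, tolerance = 0.12) # ~4.7 SE band

  # analytic ground-truth area matches numerical integration of the kernel
  num <- oracle_kernel_area(0.4, 1, 8)
  expect_equal(0.4 * (8 + 1 / 2), num, tolerance = 1e-3)
  one <- simulate_trace(trace_gen_spec(transient_rate_per_min = 3, seed = 7))
  expect_true(all(abs(one$truth$area_dff_s - num) < 0.01))

  # invalid specs error
  expect_error(trace_gen_spec(transient_rate_per_min = -1), "must be >= 0")
  expect_error(trace_gen_spec(noise_sd_dff = -0.1), "must be >= 0")

  # same seed and spec give bit-identical output
  a <- simulate_trace(trace_gen_spec(seed = 42))
  b <- simulate_trace(trace_gen_spec(seed = 42))
  expect_identical(a, b)
})

test_that("puncta field generator controls densities and colocalisation", {
  # all densities zero -> background-only images, empty truth
  empty <- simulate_puncta_field(puncta_gen_spec(
    density_pre_per_100um2 = 0, density_post_per_100um2 = 0,
    density_coloc_per_100um2 = 0, noise_sd = 0, seed = 1))
  expect_equal(nrow(empty$truth$pre), 0L)
  expect_true(all(empty$pre$pixels == 10))

  # coloc = pre = post -> every punctum paired by construction
  allc <- simulate_puncta_field(puncta_gen_spec(
    fov_um = 30, density_pre_per_100um2 = 10, density_post_per_100um2 = 10,
    density_coloc_per_100um2 = 10, seed = 2))
  expect_true(all(allc$truth$pre$colocalized))
  expect_true(all(allc$truth$post$colocalized))

  # coloc density above either channel is invalid
  expect_error(puncta_gen_spec(density_coloc_per_100um2 = 60),
               "must not exceed")

  # truth counts follow density x area within Poisson fluctuation
  f <- simulate_puncta_field(puncta_gen_spec(seed = 3))
  a100 <- 102^2 / 100
  expect_lt(abs(nrow(f$truth$pre) - 53 * a100), 4 * sqrt(53 * a100))
  expect_lt(abs(nrow(f$truth$post) - 42 * a100), 4 * sqrt(42 * a100))
  expect_lt(abs(f$truth$n_coloc - 26 * a100), 4 * sqrt(26 * a100))

  # 8-bit clipping, not wrapping
  hot <- simulate_puncta_field(puncta_gen_spec(
    fov_um = 20, punctum_intensity = 250, background_level = 100,
    density_pre_per_100um2 = 10, density_post_per_100um2 = 10,
    density_coloc_per_100um2 = 5, seed = 4))
  expect_true(max(hot$pre$pixels) == 255)
  expect_true(min(hot$pre$pixels) >= 0)

  # determinism
  expect_identical(simulate_puncta_field(puncta_gen_spec(fov_um = 25, seed = 9)),
                   simulate_puncta_field(puncta_gen_spec(fov_um = 25, seed = 9)))
})

test_that("bead scene generator places beads as stated", {
  # frac 0 -> no internal beads
  s0 <- simulate_bead_scene(scene_gen_spec(n_cells = 6, frac_phagocytic = 0,
                                           n_external_beads = 5, seed = 1))
  expect_true(all(s0$beads$true_cell == 0L))

  # n_cells = 10, frac = 0.5 -> exactly 5 cells with an internal bead
  s <- simulate_bead_scene(scene_gen_spec(n_cells = 10, frac_phagocytic = 0.5,
                                          beads_per_phagocytic_cell = 1,
                                          n_external_beads = 4, seed = 2))
  expect_equal(length(unique(s$beads$true_cell[s$beads$true_cell > 0])), 5L)

  # containment truth agrees with an independent point-in-mask lookup
  for (k in seq_len(nrow(s$beads))) {
    expect_equal(oracle_bead_cell(s, s$beads$x_um[k], s$beads$y_um[k],
                                  s$beads$z_um[k]),
                 s$beads$true_cell[k])
  }
  expect_error(scene_gen_spec(frac_phagocytic = 1.5), "<= 1")
})

test_that("point pattern generator matches closed-form expectations", {
  # expected count: 100 cells/mm^2 on a 640-um field -> ~41
  n <- vapply(1:300, function(s) {
    length(simulate_point_pattern(pattern_gen_spec(
      "poisson", intensity_per_um2 = 100e-6, seed = s))$x)
  }, numeric(1))
  expect_equal(mean(n), 40.96, tolerance = 0.05)

  # zero jitter -> exact lattice, all NND equal
  lat <- simulate_point_pattern(pattern_gen_spec(
    "jittered_lattice", intensity_per_um2 = 1e-4, fov_um = 600,
    jitter_sd_um = 0, seed = 1))
  d <- nnd_stats(lat)
  expect_equal(d$sd_nnd, 0)
  expect_equal(d$mean_nnd, 100)

  # Poisson mean NND converges to 1/(2 sqrt(lambda)) (toroidal metric)
  lam <- 1e-3
  m <- vapply(1:50, function(s) {
    p <- simulate_point_pattern(pattern_gen_spec(
      "poisson", intensity_per_um2 = lam, fov_um = 1000, seed = s))
    nnd_stats(p, metric = "toroidal")$mean_nnd
  }, numeric(1))
  expect_equal(mean(m), 1 / (2 * sqrt(lam)), tolerance = 0.02)
})

test_that("current trace generator obeys its stated construction", {
  # no events, no noise -> constant at holding
  flat <- simulate_current_trace(ephys_gen_spec(
    duration_s = 2, event_rate_pre_hz = 0, ttx_onset_s = NA,
    noise_sd_pA = 0, holding_pA = -60, seed = 1))
  expect_true(all(flat$trace$samples == -60))

  # rate drop at TTX onset: pre/post ground-truth count ratio ~ 2
  pre_n <- post_n <- 0
  for (s in 1:40) {
    sim <- simulate_current_trace(ephys_gen_spec(
      duration_s = 100, event_rate_pre_hz = 2, event_rate_post_hz = 1,
      ttx_onset_s = 50, noise_sd_pA = 0, seed = s))
    pre_n <- pre_n + sum(sim$truth$time_s < 50)
    post_n <- post_n + sum(sim$truth$time_s >= 50)
  }
  expect_equal(pre_n / post_n, 2, tolerance = 0.1)

  # agonist step: post-onset mean = holding + step
  ag <- simulate_current_trace(ephys_gen_spec(
    duration_s = 40, event_rate_pre_hz = 0, ttx_onset_s = NA,
    noise_sd_pA = 0, holding_pA = -100, agonist_step_pA = -50,
    agonist_onset_s = 20, seed = 1))
  fs <- ag$trace$sample_rate_hz
  expect_equal(mean(ag$trace$samples[1:(20 * fs)]), -100)
  expect_equal(mean(ag$trace$samples[(20 * fs + 1):(40 * fs)]), -150)

  # determinism
  expect_identical(
    simulate_current_trace(ephys_gen_spec(duration_s = 5, seed = 3)),
    simulate_current_trace(ephys_gen_spec(duration_s = 5, seed = 3)))
})
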