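# Synthetic-data generators. Every generator consumes a validated *_gen_spec,
# uses one seeded RNG stream (restoring the caller's RNG state on exit), and
# returns the rendered data together with its ground truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Transient kernel: linear rise over rise_s to `amplitude`, then exponential
# decay with time constant tau. Analytic area = amplitude * (tau + rise/2).
transient_kernel <- function(t_rel, amplitude, rise_s, decay_tau_s) {
  k <- numeric(length(t_rel))
  if (rise_s > 0) {
    up <- t_rel >= 0 & t_rel < rise_s
    k[up] <- amplitude * t_rel[up] / rise_s
  }
  dn <- t_rel >= rise_s
  k[dn] <- amplitude * exp(-(t_rel[dn] - rise_s) / decay_tau_s)
  k
}

#' Simulate a calcium fluorescence trace with known transients
#'
#' Transient onsets are a homogeneous Poisson process at the specified rate;
#' each transient is a linear-rise/exponential-decay kernel scaled to
#' `amplitude_dff`, superposed on optional sinusoidal drift and additive
#' Gaussian noise. The trace is returned in dF/F units.
#'
#' @param spec a [trace_gen_spec()].
#' @return list with `trace` (a [fluor_trace()], `is_dff = TRUE`) and `truth`
#'   (data frame of injected `onset_s`, `amplitude_dff`, `area_dff_s`, where
#'   the area is the analytic kernel integral).
#' @export
simulate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_gen_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$frame_rate_hz)
    t <- (seq_len(n) - 1) / spec$frame_rate_hz
    n_ev <- rpois(1L, spec$transient_rate_per_min / 60 * spec$duration_s)
    onsets <- sort(runif(n_ev, 0, spec$duration_s))
    v <- numeric(n)
    for (o in onsets) {
      v <- v + transient_kernel(t - o, spec$amplitude_dff, spec$rise_s,
                                spec$decay_tau_s)
    }
    if (spec$drift_amplitude_dff != 0) {
      v <- v + spec$drift_amplitude_dff * sin(2 * pi * t / spec$drift_period_s)
    }
    if (spec$noise_sd_dff > 0) v <- v + rnorm(n, 0, spec$noise_sd_dff)
    truth <- data.frame(
      onset_s = onsets,
      amplitude_dff = rep(spec$amplitude_dff, n_ev),
      area_dff_s = rep(spec$amplitude_dff *
                         (spec$decay_tau_s + spec$rise_s / 2), n_ev))
    list(trace = fluor_trace(v, spec$frame_rate_hz, is_dff = TRUE),
         truth = truth)
  })
}

# Add a Gaussian spot (peak `peak`, SD sigma_px pixels) at micron coordinates
# (x_um, y_um) into matrix `img`. Pixel (row i, col j), 1-based, has its
# centre at ((j-1)*px, (i-1)*px): a 0-based pixel-centre convention.
add_spot <- function(img, x_um, y_um, px, sigma_px, peak) {
  cx <- x_um / px + 1
  cy <- y_um / px + 1
  r <- ceiling(3 * sigma_px) + 1L
  jj <- max(1L, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  ii <- max(1L, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  if (!length(jj) || !length(ii)) return(img)
  gx <- exp(-((jj - cx)^2) / (2 * sigma_px^2))
  gy <- exp(-((ii - cy)^2) / (2 * sigma_px^2))
  img[ii, jj] <- img[ii, jj] + peak * outer(gy, gx)
  img
}

#' Simulate a two-channel synaptic puncta field with known colocalisation
#'
#' Colocalised pairs share a centre (the postsynaptic partner is offset by
#' less than a quarter of the punctum diameter, so thresholded masks overlap);
#' lone puncta are placed uniformly. All centres (within and across channels,
#' except within a colocalised pair) keep a hard-core separation of twice the
#' punctum diameter via rejection sampling (up to 100 attempts per punctum,
#' then dropped and flagged), so the ground-truth pairing is exact. Spots are
#' rendered as Gaussians, Gaussian read noise is added, and images are
#' clipped (not wrapped) into the 8-bit range.
#'
#' @param spec a [puncta_gen_spec()].
#' @return list with `pre` and `post` ([channel_image()]s), and `truth`: data
#'   frames `pre`/`post` (`x_um`, `y_um`, `colocalized`), `n_coloc`, and
#'   `placement_failures` (puncta dropped after 100 attempts).
#' @export
simulate_puncta_field <- function(spec) {
  stopifnot(inherits(spec, "puncta_gen_spec"))
  with_seed(spec$seed, {
    a100 <- spec$fov_um^2 / 100
    n_coloc <- rpois(1L, spec$density_coloc_per_100um2 * a100)
    n_pre_only <- rpois(1L, max(0, spec$density_pre_per_100um2 -
                                  spec$density_coloc_per_100um2) * a100)
    n_post_only <- rpois(1L, max(0, spec$density_post_per_100um2 -
                                   spec$density_coloc_per_100um2) * a100)
    sep <- 2 * spec$punctum_diameter_um
    pc <- hardcore_sample(n_coloc, spec$fov_um, sep)
    pr <- hardcore_sample(n_pre_only, spec$fov_um, sep,
                          existing = list(x = pc$x, y = pc$y))
    po <- hardcore_sample(n_post_only, spec$fov_um, sep,
                          existing = list(x = c(pc$x, pr$x),
                                          y = c(pc$y, pr$y)))
    failures <- pc$failures + pr$failures + po$failures
    # postsynaptic partner of each colocalised punctum: small random offset
    n_pc <- length(pc$x)
    th <- runif(n_pc, 0, 2 * pi)
    rr <- runif(n_pc, 0, 0.25 * spec$punctum_diameter_um)
    post_pair_x <- pc$x + rr * cos(th)
    post_pair_y <- pc$y + rr * sin(th)

    npix <- round(spec$fov_um / spec$pixel_size_um)
    sigma_px <- spec$punctum_diameter_um / 2.355 / spec$pixel_size_um
    render <- function(xs, ys) {
      img <- matrix(spec$background_level, npix, npix)
      for (k in seq_along(xs)) {
        img <- add_spot(img, xs[k], ys[k], spec$pixel_size_um, sigma_px,
                        spec$punctum_intensity)
      }
      if (spec$noise_sd > 0) {
        img <- img + matrix(rnorm(npix * npix, 0, spec$noise_sd), npix, npix)
      }
      matrix(as.integer(pmin(pmax(round(img), 0), 255)), npix, npix)
    }
    pre_x <- c(pc$x, pr$x); pre_y <- c(pc$y, pr$y)
    post_x <- c(post_pair_x, po$x); post_y <- c(post_pair_y, po$y)
    truth <- list(
      pre = data.frame(x_um = pre_x, y_um = pre_y,
                       colocalized = c(rep(TRUE, n_pc),
                                       rep(FALSE, length(pr$x)))),
      post = data.frame(x_um = post_x, y_um = post_y,
                        colocalized = c(rep(TRUE, n_pc),
                                        rep(FALSE, length(po$x)))),
      n_coloc = n_pc, placement_failures = failures)
    list(pre = channel_image(render(pre_x, pre_y), spec$pixel_size_um, "pre"),
         post = channel_image(render(post_x, post_y), spec$pixel_size_um,
                              "post"),
         truth = truth)
  })
}

#' Simulate a cell-and-bead phagocytosis scene
#'
#' Microglial somata are rasterised as labelled discs whose radius tapers
#' across neighbouring z-planes; `round(n_cells * frac_phagocytic)` cells
#' receive `beads_per_phagocytic_cell` beads with centroids inside the mask
#' at the cell's central plane, and `n_external_beads` beads are placed
#' outside all masks.
#'
#' @param spec a [scene_gen_spec()].
#' @return a `cell_bead_scene`: list with `masks` (integer array
#'   ny x nx x nz of cell labels, 0 = background), `beads` (data frame
#'   `x_um`, `y_um`, `z_um`, `true_cell`; 0 = external), `pixel_size_um`,
#'   `z_step_um`, `fov_um`, `n_cells`.
#' @export
simulate_bead_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_gen_spec"))
  with_seed(spec$seed, {
    npix <- round(spec$fov_um / spec$pixel_size_um)
    nz <- spec$z_planes
    r <- spec$cell_radius_um
    margin <- r + 2
    # cell centres: hard-core so discs never touch, away from the border
    ctr <- hardcore_sample(spec$n_cells, spec$fov_um - 2 * margin,
                           2 * r + 3, max_attempts = 1000L)
    if (length(ctr$x) < spec$n_cells) {
      stop("could not place all cells; lower n_cells or cell_radius_um")
    }
    cx <- ctr$x + margin
    cy <- ctr$y + margin
    cz <- sample(seq(2L, max(2L, nz - 1L)), spec$n_cells, replace = TRUE)
    taper <- c(0.4, 0.7, 1, 0.7, 0.4) # radius factor at dz = -2..2 planes
    masks <- array(0L, dim = c(npix, npix, nz))
    xs <- ((seq_len(npix)) - 1) * spec$pixel_size_um
    for (cidx in seq_len(spec$n_cells)) {
      for (dz in -2:2) {
        z <- cz[cidx] + dz
        if (z < 1L || z > nz) next
        rad <- r * taper[dz + 3L]
        jj <- which(abs(xs - cx[cidx]) <= rad)
        ii <- which(abs(xs - cy[cidx]) <= rad)
        if (!length(jj) || !length(ii)) next
        d2 <- outer((xs[ii] - cy[cidx])^2, (xs[jj] - cx[cidx])^2, "+")
        sub <- masks[ii, jj, z, drop = FALSE]
        sub[, , 1][d2 <= rad^2] <- cidx
        masks[ii, jj, z] <- sub[, , 1]
      }
    }
    # internal beads: centroid strictly inside the central-plane disc
    n_phago <- round(spec$n_cells * spec$frac_phagocytic)
    phago_cells <- if (n_phago > 0) {
      sample(spec$n_cells, n_phago)
    } else integer(0)
    bead_r <- 1.5 # 3-um beads
    bx <- by <- bz <- numeric(0); bcell <- integer(0)
    for (cidx in phago_cells) {
      for (b in seq_len(spec$beads_per_phagocytic_cell)) {
        th <- runif(1, 0, 2 * pi)
        rho <- runif(1, 0, max(0, r - bead_r - spec$pixel_size_um))
        bx <- c(bx, cx[cidx] + rho * cos(th))
        by <- c(by, cy[cidx] + rho * sin(th))
        bz <- c(bz, (cz[cidx] - 1) * spec$z_step_um +
                  runif(1, -0.3, 0.3) * spec$z_step_um)
        bcell <- c(bcell, cidx)
      }
    }
    # external beads: rejection-sample positions clear of every soma
    n_ext <- 0L
    guard <- 0L
    while (n_ext < spec$n_external_beads && guard < 10000L) {
      guard <- guard + 1L
      x <- runif(1, 0, spec$fov_um); y <- runif(1, 0, spec$fov_um)
      if (all(sqrt((x - cx)^2 + (y - cy)^2) > r + bead_r + 1)) {
        bx <- c(bx, x); by <- c(by, y)
        bz <- c(bz, runif(1, 0, (nz - 1) * spec$z_step_um))
        bcell <- c(bcell, 0L)
        n_ext <- n_ext + 1L
      }
    }
    beads <- data.frame(x_um = bx, y_um = by, z_um = bz, true_cell = bcell)
    structure(list(masks = masks, beads = beads,
                   pixel_size_um = spec$pixel_size_um,
                   z_step_um = spec$z_step_um, fov_um = spec$fov_um,
                   n_cells = spec$n_cells),
              class = "cell_bead_scene")
  })
}

#' Simulate a 2D point pattern of cell somata
#'
#' @param spec a [pattern_gen_spec()].
#' @return a [point_pattern()].
#' @export
simulate_point_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_gen_spec"))
  with_seed(spec$seed, {
    fov <- spec$fov_um
    lambda <- spec$intensity_per_um2
    if (spec$mode == "poisson") {
      n <- rpois(1L, lambda * fov^2)
      x <- runif(n, 0, fov); y <- runif(n, 0, fov)
    } else if (spec$mode == "jittered_lattice") {
      a <- 1 / sqrt(lambda)
      k <- max(1L, floor(fov / a))
      g <- (seq_len(k) - 0.5) * a
      x <- rep(g, each = k); y <- rep(g, times = k)
      if (spec$jitter_sd_um > 0) {
        x <- x + rnorm(length(x), 0, spec$jitter_sd_um)
        y <- y + rnorm(length(y), 0, spec$jitter_sd_um)
        x <- x %% fov; y <- y %% fov # wrap: keeps points in the FOV
      }
    } else { # clustered: Thomas-like process
      mu <- 5
      n_par <- rpois(1L, lambda * fov^2 / mu)
      sdc <- fov / 40
      x <- y <- numeric(0)
      for (p in seq_len(n_par)) {
        pxy <- runif(2, 0, fov)
        n_off <- rpois(1L, mu)
        x <- c(x, (pxy[1] + rnorm(n_off, 0, sdc)) %% fov)
        y <- c(y, (pxy[2] + rnorm(n_off, 0, sdc)) %% fov)
      }
    }
    point_pattern(x, y, fov, fov)
  })
}

# Event times for a piecewise-homogeneous Poisson train (rate switches at
# ttx_onset_s when given), plus truncated-normal amplitudes.
simulate_event_train <- function(spec) {
  seg_times <- function(rate, t0, t1) {
    if (rate <= 0 || t1 <= t0) return(numeric(0))
    sort(runif(rpois(1L, rate * (t1 - t0)), t0, t1))
  }
  if (is.na(spec$ttx_onset_s)) {
    times <- seg_times(spec$event_rate_pre_hz, 0, spec$duration_s)
  } else {
    times <- c(seg_times(spec$event_rate_pre_hz, 0, spec$ttx_onset_s),
               seg_times(spec$event_rate_post_hz, spec$ttx_onset_s,
                         spec$duration_s))
  }
  amps <- abs(rnorm(length(times), spec$amplitude_mean_pA,
                    spec$amplitude_sd_pA))
  amps <- pmax(amps, 1e-3)
  data.frame(time_s = times, amplitude_pA = amps)
}

#' Simulate a voltage-clamp current trace with known synaptic events
#'
#' Double-exponential postsynaptic-current kernels at Poisson event times
#' (rate switching from `event_rate_pre_hz` to `event_rate_post_hz` at
#' `ttx_onset_s`), Gaussian baseline noise around the holding current, and an
#' optional agonist-induced step after `agonist_onset_s`.
#'
#' @param spec an [ephys_gen_spec()].
#' @return list with `trace` (a [current_trace()]) and `truth` (data frame of
#'   event `time_s` and `amplitude_pA`, magnitude convention).
#' @export
simulate_current_trace <- function(spec) {
  stopifnot(inherits(spec, "ephys_gen_spec"))
  with_seed(spec$seed, {
    fs <- spec$sample_rate_hz
    n <- round(spec$duration_s * fs)
    events <- simulate_event_train(spec)
    v <- rnorm(n, 0, spec$noise_sd_pA) + spec$holding_pA
    tau_r <- spec$rise_ms / 1000
    tau_d <- spec$decay_ms / 1000
    t_peak <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
    peak_norm <- exp(-t_peak / tau_d) - exp(-t_peak / tau_r)
    klen <- ceiling(8 * tau_d * fs)
    tk <- (0:klen) / fs
    kern <- (exp(-tk / tau_d) - exp(-tk / tau_r)) / peak_norm
    sgn <- if (spec$polarity == "inward") -1 else 1
    for (k in seq_len(nrow(events))) {
      i0 <- floor(events$time_s[k] * fs) + 1L
      idx <- i0:min(n, i0 + klen)
      if (i0 > n) next
      v[idx] <- v[idx] + sgn * events$amplitude_pA[k] * kern[seq_along(idx)]
    }
    if (!is.na(spec$agonist_onset_s) && spec$agonist_step_pA != 0) {
      i0 <- floor(spec$agonist_onset_s * fs) + 1L
      if (i0 <= n) v[i0:n] <- v[i0:n] + spec$agonist_step_pA
    }
    list(trace = current_trace(v, fs, ttx_onset_s = spec$ttx_onset_s,
                               agonist_onset_s = spec$agonist_onset_s,
                               polarity = spec$polarity),
         truth = events)
  })
}
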