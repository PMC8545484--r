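# Independent oracles used across tests. These deliberately re-derive results
# by brute force so they stay independent of the implementation paths they
# check.

# Brute-force transient boundaries: maximal runs of frames where
# (dff - baseline) > threshold, runs separated by < 2 frames merged, kept iff
# the trapezoidal area exceeds min_area. Plain loop, no rle.
oracle_transient_runs <- function(dff, baseline, threshold, dt = 1,
                                  min_area = 0.15) {
  above <- (dff - baseline) > threshold
  on <- integer(0); off <- integer(0)
  in_run <- FALSE
  for (i in seq_along(above)) {
    if (above[i] && !in_run) { on <- c(on, i); in_run <- TRUE }
    if (!above[i] && in_run) { off <- c(off, i - 1L); in_run <- FALSE }
  }
  if (in_run) off <- c(off, length(above))
  # merge runs separated by a single sub-threshold frame
  k <- 1L
  while (k < length(on)) {
    if (on[k + 1L] - off[k] - 1L < 2L) {
      off[k] <- off[k + 1L]
      on <- on[-(k + 1L)]; off <- off[-(k + 1L)]
    } else k <- k + 1L
  }
  keep <- logical(length(on))
  for (k in seq_along(on)) {
    y <- (dff - baseline)[on[k]:off[k]]
    area <- if (length(y) < 2L) 0 else sum((y[-1] + y[-length(y)]) / 2) * dt
    keep[k] <- area > min_area
  }
  data.frame(onset_frame = on[keep], offset_frame = off[keep])
}

# Arithmetic size-exclusion oracle: retained iff strictly inside the window.
oracle_size_keep <- function(area_um2, min_a = 0.05, max_a = 1.2) {
  area_um2 > min_a & area_um2 < max_a
}

# Point-in-mask oracle for bead containment: nearest z-plane lookup done
# from scratch.
oracle_bead_cell <- function(scene, x, y, z) {
  zq <- round(z / scene$z_step_um) + 1
  zq <- min(dim(scene$masks)[3], max(1, zq))
  i <- min(dim(scene$masks)[1], max(1, round(y / scene$pixel_size_um) + 1))
  j <- min(dim(scene$masks)[2], max(1, round(x / scene$pixel_size_um) + 1))
  scene$masks[i, j, zq]
}

# Numeric integral of the noiseless transient kernel by fine trapezoid.
oracle_kernel_area <- function(amplitude, rise_s, tau_s, dt = 0.001,
                               t_max = 200) {
  t <- seq(0, t_max, by = dt)
  k <- ifelse(t < rise_s, amplitude * t / max(rise_s, dt),
              amplitude * exp(-(t - rise_s) / tau_s))
  sum((k[-1] + k[-length(k)]) / 2) * dt
}

make_dff_trace <- function(values, fr = 1) {
  microquant::fluor_trace(values, fr, is_dff = TRUE)
}

# mirrors the generator transient shape (linear rise then exponential decay)
transient_kernel_for_test <- function(t, onset, amplitude, rise, tau) {
  tr <- t - onset
  k <- numeric(length(t))
  k[tr >= 0 & tr < rise] <- amplitude * tr[tr >= 0 & tr < rise] / rise
  k[tr >= rise] <- amplitude * exp(-(tr[tr >= rise] - rise) / tau)
  k
}
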