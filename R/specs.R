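# Declarative generator specifications. Each constructor validates its
# invariants eagerly so that simulate_*() can assume a well-formed spec.
# Defaults encode the acquisition conditions the analyses assume: 300 frames
# at 1 Hz for calcium movies, 102-um fields at 8 bits for puncta, 2-um
# z-steps with 3-um beads for the phagocytosis assay, 640-um fields for
# density mosaics, and 20-kHz voltage-clamp sampling.

#' Specification for a synthetic calcium fluorescence trace
#'
#' Describes a single-ROI GCaMP recording: sparse Poisson-timed transients
#' (linear rise then exponential decay) riding on an optionally drifting,
#' noisy baseline, sampled at `frame_rate_hz` for `duration_s`.
#'
#' @param duration_s recording length in seconds (default 300, i.e. 5 min).
#' @param frame_rate_hz frames per second (default 1).
#' @param transient_rate_per_min expected transient rate (events/min, >= 0).
#' @param amplitude_dff peak amplitude of each transient in dF/F units.
#' @param decay_tau_s exponential decay time constant (s).
#' @param rise_s linear rise time (s).
#' @param noise_sd_dff SD of additive Gaussian noise (dF/F units, >= 0).
#' @param drift_amplitude_dff amplitude of a sinusoidal baseline drift.
#' @param drift_period_s period of the drift (s).
#' @param seed integer seed; identical seed and spec give identical output.
#' @return a `trace_gen_spec` list.
#' @export
trace_gen_spec <- function(duration_s = 300, frame_rate_hz = 1,
                           transient_rate_per_min = 0.13,
                           amplitude_dff = 0.4, decay_tau_s = 8,
                           rise_s = 1, noise_sd_dff = 0.02,
                           drift_amplitude_dff = 0, drift_period_s = 300,
                           seed = 1L) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  check_scalar(transient_rate_per_min, "transient_rate_per_min", nonneg = TRUE)
  check_scalar(noise_sd_dff, "noise_sd_dff", nonneg = TRUE)
  check_scalar(decay_tau_s, "decay_tau_s", positive = TRUE)
  check_scalar(rise_s, "rise_s", nonneg = TRUE)
  spec <- list(duration_s = duration_s, frame_rate_hz = frame_rate_hz,
               transient_rate_per_min = transient_rate_per_min,
               amplitude_dff = amplitude_dff, decay_tau_s = decay_tau_s,
               rise_s = rise_s, noise_sd_dff = noise_sd_dff,
               drift_amplitude_dff = drift_amplitude_dff,
               drift_period_s = drift_period_s, seed = as.integer(seed))
  structure(spec, class = "trace_gen_spec")
}

#' Specification for a synthetic two-channel puncta field
#'
#' Describes a pair of 8-bit single-plane images (presynaptic and
#' postsynaptic channels) with controlled per-channel punctum densities and a
#' controlled colocalised fraction. Colocalised pairs share a centre (offset
#' below the punctum radius so thresholded masks overlap); all other centres
#' keep a hard-core separation of twice the punctum diameter, so ground-truth
#' pairing is exact: lone puncta cannot colocalise by accident and
#' same-channel puncta cannot merge.
#'
#' @param fov_um field of view side length (um; default 102).
#' @param pixel_size_um pixel size (um/px; default 0.1).
#' @param density_pre_per_100um2 total presynaptic punctum density.
#' @param density_post_per_100um2 total postsynaptic punctum density.
#' @param density_coloc_per_100um2 density of colocalised (paired) puncta;
#'   must not exceed either channel density.
#' @param punctum_diameter_um FWHM of the rendered Gaussian spot (um).
#' @param punctum_intensity peak intensity above background (8-bit).
#' @param background_level constant background (8-bit).
#' @param noise_sd SD of additive Gaussian read noise (8-bit counts).
#' @param seed integer seed.
#' @return a `puncta_gen_spec` list.
#' @export
puncta_gen_spec <- function(fov_um = 102, pixel_size_um = 0.1,
                            density_pre_per_100um2 = 53,
                            density_post_per_100um2 = 42,
                            density_coloc_per_100um2 = 26,
                            punctum_diameter_um = 0.4,
                            punctum_intensity = 120,
                            background_level = 10, noise_sd = 3,
                            seed = 1L) {
  check_scalar(fov_um, "fov_um", positive = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_scalar(density_pre_per_100um2, "density_pre_per_100um2", nonneg = TRUE)
  check_scalar(density_post_per_100um2, "density_post_per_100um2", nonneg = TRUE)
  check_scalar(density_coloc_per_100um2, "density_coloc_per_100um2", nonneg = TRUE)
  if (density_coloc_per_100um2 >
      min(density_pre_per_100um2, density_post_per_100um2) + 1e-12) {
    stop_invalid("density_coloc_per_100um2",
                 "must not exceed min(pre, post) density")
  }
  if (punctum_intensity < 0 || punctum_intensity > 255 ||
      background_level < 0 || background_level > 255) {
    stop_invalid("punctum_intensity/background_level", "must lie in [0, 255]")
  }
  spec <- list(fov_um = fov_um, pixel_size_um = pixel_size_um,
               density_pre_per_100um2 = density_pre_per_100um2,
               density_post_per_100um2 = density_post_per_100um2,
               density_coloc_per_100um2 = density_coloc_per_100um2,
               punctum_diameter_um = punctum_diameter_um,
               punctum_intensity = punctum_intensity,
               background_level = background_level, noise_sd = noise_sd,
               seed = as.integer(seed))
  structure(spec, class = "puncta_gen_spec")
}

#' Specification for a synthetic cell-and-bead phagocytosis scene
#'
#' Describes labelled microglial (Iba1) soma masks across a confocal z-stack
#' plus 3-um bead centroids; a stated fraction of cells receives internal
#' beads, the rest of the beads lie outside all masks.
#'
#' @param n_cells number of cells in the field.
#' @param frac_phagocytic fraction of cells given internal beads (0-1).
#' @param beads_per_phagocytic_cell internal beads per phagocytic cell (>= 1).
#' @param n_external_beads beads placed outside every mask.
#' @param fov_um field side length (um; default 106, the 20x assay field).
#' @param z_planes number of z planes.
#' @param z_step_um z step (um; default 2).
#' @param pixel_size_um raster pixel size for the masks (um/px).
#' @param cell_radius_um soma disc radius at the cell's central plane (um).
#' @param seed integer seed.
#' @return a `scene_gen_spec` list.
#' @export
scene_gen_spec <- function(n_cells = 15, frac_phagocytic = 0.5,
                           beads_per_phagocytic_cell = 1,
                           n_external_beads = 10, fov_um = 106,
                           z_planes = 7, z_step_um = 2,
                           pixel_size_um = 0.5, cell_radius_um = 7,
                           seed = 1L) {
  check_scalar(n_cells, "n_cells", positive = TRUE)
  check_scalar(frac_phagocytic, "frac_phagocytic", nonneg = TRUE)
  if (frac_phagocytic > 1) stop_invalid("frac_phagocytic", "must be <= 1")
  if (beads_per_phagocytic_cell < 1) {
    stop_invalid("beads_per_phagocytic_cell", "must be >= 1")
  }
  check_scalar(n_external_beads, "n_external_beads", nonneg = TRUE)
  check_scalar(z_planes, "z_planes", positive = TRUE)
  spec <- list(n_cells = as.integer(n_cells),
               frac_phagocytic = frac_phagocytic,
               beads_per_phagocytic_cell = as.integer(beads_per_phagocytic_cell),
               n_external_beads = as.integer(n_external_beads),
               fov_um = fov_um, z_planes = as.integer(z_planes),
               z_step_um = z_step_um, pixel_size_um = pixel_size_um,
               cell_radius_um = cell_radius_um, seed = as.integer(seed))
  structure(spec, class = "scene_gen_spec")
}

#' Specification for a synthetic 2D point pattern
#'
#' @param mode one of `"poisson"` (count drawn from a Poisson with mean
#'   intensity x area, points uniform), `"jittered_lattice"` (square lattice
#'   plus isotropic Gaussian jitter) or `"clustered"` (Thomas-like parent/
#'   offspring clusters).
#' @param intensity_per_um2 expected points per square micron (> 0).
#' @param fov_um field side length (um; default 640).
#' @param jitter_sd_um jitter SD for the lattice mode (um).
#' @param seed integer seed.
#' @return a `pattern_gen_spec` list.
#' @export
pattern_gen_spec <- function(mode = c("poisson", "jittered_lattice",
                                      "clustered"),
                             intensity_per_um2 = 1e-4, fov_um = 640,
                             jitter_sd_um = 0, seed = 1L) {
  mode <- match.arg(mode)
  check_scalar(intensity_per_um2, "intensity_per_um2", positive = TRUE)
  check_scalar(fov_um, "fov_um", positive = TRUE)
  check_scalar(jitter_sd_um, "jitter_sd_um", nonneg = TRUE)
  structure(list(mode = mode, intensity_per_um2 = intensity_per_um2,
                 fov_um = fov_um, jitter_sd_um = jitter_sd_um,
                 seed = as.integer(seed)),
            class = "pattern_gen_spec")
}

#' Specification for a synthetic voltage-clamp current trace
#'
#' Postsynaptic-current events (double-exponential kernels at Poisson times)
#' on Gaussian baseline noise around a holding current; the event rate
#' switches at TTX onset and an optional agonist-induced step is added after
#' `agonist_onset_s`.
#'
#' @param duration_s recording length (s).
#' @param sample_rate_hz sampling rate (default 20000).
#' @param event_rate_pre_hz event rate before TTX onset (Hz, >= 0).
#' @param event_rate_post_hz event rate after TTX onset (Hz, >= 0).
#' @param ttx_onset_s time of the TTX switch; `NA` for none.
#' @param amplitude_mean_pA mean event amplitude (pA, magnitude).
#' @param amplitude_sd_pA SD of event amplitudes (pA).
#' @param rise_ms kernel rise time constant (ms).
#' @param decay_ms kernel decay time constant (ms).
#' @param noise_sd_pA baseline noise SD (pA).
#' @param holding_pA holding current (pA).
#' @param agonist_step_pA current step added after `agonist_onset_s` (pA,
#'   signed); 0 for none.
#' @param agonist_onset_s agonist application time; `NA` for none.
#' @param polarity `"inward"` (events deflect negative) or `"outward"`.
#' @param seed integer seed.
#' @return an `ephys_gen_spec` list.
#' @export
ephys_gen_spec <- function(duration_s = 60, sample_rate_hz = 20000,
                           event_rate_pre_hz = 2, event_rate_post_hz = 1,
                           ttx_onset_s = NA_real_,
                           amplitude_mean_pA = 30, amplitude_sd_pA = 8,
                           rise_ms = 0.5, decay_ms = 5,
                           noise_sd_pA = 3, holding_pA = -100,
                           agonist_step_pA = 0, agonist_onset_s = NA_real_,
                           polarity = c("inward", "outward"), seed = 1L) {
  polarity <- match.arg(polarity)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  check_scalar(event_rate_pre_hz, "event_rate_pre_hz", nonneg = TRUE)
  check_scalar(event_rate_post_hz, "event_rate_post_hz", nonneg = TRUE)
  check_scalar(noise_sd_pA, "noise_sd_pA", nonneg = TRUE)
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 event_rate_pre_hz = event_rate_pre_hz,
                 event_rate_post_hz = event_rate_post_hz,
                 ttx_onset_s = ttx_onset_s,
                 amplitude_mean_pA = amplitude_mean_pA,
                 amplitude_sd_pA = amplitude_sd_pA,
                 rise_ms = rise_ms, decay_ms = decay_ms,
                 noise_sd_pA = noise_sd_pA, holding_pA = holding_pA,
                 agonist_step_pA = agonist_step_pA,
                 agonist_onset_s = agonist_onset_s, polarity = polarity,
                 seed = as.integer(seed)),
            class = "ephys_gen_spec")
}
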