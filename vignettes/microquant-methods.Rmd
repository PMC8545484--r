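---
title: "Methods: models, parameters, and design choices in microquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in microquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

microquant packages the quantitative core of a class of microglial
synapse-pruning studies: calcium-transient detection, synaptic-puncta
colocalisation and engulfment, bead-phagocytosis indexing, spatial
statistics of microglial mosaics, and synaptic-current analysis. Every
analysis can be exercised end-to-end on synthetic inputs with exact ground
truth. This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the green test suite does and does
not establish.

## Calcium transients

**Model.** A microglial ROI trace is normalised to
ΔF/F = (F~t~ − F~o~)/F~o~, where F~o~ is the mean raw fluorescence over a
stated baseline window. Spontaneous activity is sparse (of order 0.1
transients/min), so most frames are baseline-like; a slowly varying baseline
is estimated and events are threshold crossings of the residual.

**Baseline.** The trace is cut into consecutive blocks of
`smoothing_frames` (default 100 frames at 1 frame/s). In each block the
anchor is the *median* ΔF/F of frames below the eligibility ceiling
(`baseline_eligibility_dff`, default 0.1), which makes the anchor robust to
transients occupying part of the block; a block with no eligible frame falls
back to the all-frame median and is flagged. A Fritsch–Carlson
shape-preserving cubic Hermite interpolant (`stats::splinefun(method =
"monoH.FC")`, the same family as MATLAB's `pchip`) is drawn through the
anchors and extrapolated as a constant beyond the first/last anchor. Shape
preservation means the curve cannot overshoot the anchor range within an
interval — important because an overshooting spline under a transient would
eat into the event's area.

**Detection.** The threshold is `threshold_multiplier` (default 2.25) times
the SD of the first `n_baseline_points` (default 100) frames, *scanning from
the start of the trace*, whose ΔF/F is below 0.1. We read "the first 100
points in the trace that had ΔF/F < 0.1" as the first 100 qualifying frames,
not "frames among the first 100"; with 300-frame traces and sparse activity
the two agree almost always, but the qualifying-frame reading is the literal
one. The SD is computed on the raw ΔF/F values of those frames by default
(`sd_on = "raw_dff"`); a `baseline_subtracted` switch exists because the
source description is ambiguous on this point. Candidate events are maximal
runs of (ΔF/F − baseline) above threshold; runs separated by a single
sub-threshold frame are merged (noise chatter at 1 frame/s); events are kept
iff the trapezoidal integral of the residual over the event exceeds
`min_area_dff_s` (default 0.15 ΔF/F·s). A single-frame excursion has zero
trapezoidal area and is therefore always rejected, which is the intended
behaviour of an area criterion at 1 Hz sampling. Rates are reported per
300 s and per minute.

**Quality flags instead of manual curation.** The original workflow included
a manual false-positive check. That is not reproducible, so events whose
peak is below 1.5 × threshold, or which touch either end of the trace, are
flagged `needs-review` — they are *reported*, never silently dropped. A
transient spanning the trace end is counted and flagged.

**Evoked responses.** For lesion experiments, F~o~ is the mean raw
fluorescence over the 20 s before the lesion frame and the response is the
maximum ΔF/F over post-lesion frames; fewer than 20 s of pre-lesion data is
an error, not a silent shorter window.

## Synaptic puncta

**Background.** The rolling-ball background is the grayscale opening of the
image with a spherical structuring element (radius in pixels, default 10 —
the radius is printed in pixels in the protocols this follows). The
implementation is exact (erosion then dilation with the ball height profile,
in compiled code). Two details matter:

- The reference interactive tool estimates the background on a 3×3-mean
  pre-smoothed copy and subtracts it from the *original* image. Without
  smoothing, the ball drops into noise minima and the background is biased
  low by roughly 2–3 noise SD, which inflates every punctum and merges
  neighbours. `subtract_background(presmooth = TRUE)` (the default)
  reproduces the smoothed behaviour; the raw opening is available and is
  validated against an independently computed reference background frozen
  into the test fixtures.
- The widely used scikit-image variant returns the ball *apex* (erosion
  plus radius) rather than the full opening; the two agree on smooth
  backgrounds and differ by a bounded curvature term under sharp features.
  The oracle test asserts exactly that relationship.

**Thresholding and particle analysis.** Masks are inclusive fixed ranges
(defaults 15–255 for the presynaptic channel, 30–255 for the postsynaptic
channel, on 8-bit images). Connected components use 8-connectivity by
default (the common particle-analysis convention; 4-connectivity is a
switch). Areas are pixel counts × pixel area; components are retained iff
strictly 0.05 µm² < area < 1.2 µm², with a 10⁻⁹ relative epsilon so that,
e.g., 5 px × (0.1 µm)² compares equal to 0.05 µm² and is excluded. Puncta
touching the image border are retained and flagged. The pixel size is not
derivable from the data and must be set deliberately (`pixel_size_um`,
default 0.1 µm/px for a 63× field).

**Synapses.** A synapse is a retained presynaptic punctum whose pixel set
intersects ≥ 1 pixel of ≥ 1 retained postsynaptic punctum. A presynaptic
punctum overlapping two postsynaptic puncta counts once (pre-anchored
counting; `count = "pairs"` counts distinct pairs). The "colocalised area"
is reported both as the raw pre/post intersection and as the union of all
participating puncta, since either reading is defensible; the intersection
is the primary value.

**Engulfment.** The engulfed presynaptic area per microglial cell is the
summed area of retained presynaptic punctum pixels lying inside each
labelled cell mask.

**Averaging.** `aggregate_hierarchy()` implements the study-shaped
hierarchy: images are averaged into slices, slice means into animal means,
all unweighted; the animal is the terminal statistical unit. Group
statistics (t tests and relatives) are deliberately out of scope — standard
routines exist and nothing here is bespoke.

## Phagocytosis

A bead belongs to a cell iff its centroid pixel lies inside the cell's mask
at the nearest z-plane (2-µm z-steps; the centroid rule, not surface
contact, defines internalisation). The phagocytic index is the percentage of
cells with at least `min_beads` internal beads. The source criterion reads
">1 beads"; the conventional phagocytic-cell definition is ≥ 1 bead, and
that is the default, with `min_beads = 2` one flag away — both readings are
reported when they differ rather than guessed silently. FOV occurrence is
the percentage of fields containing ≥ 1 phagocytic cell. Bead conservation
(assigned + unassigned = total) is a tested invariant.

## Spatial statistics

Density is n/area in cells/mm². Nearest-neighbour distances are plain
Euclidean within the cropped field by default — no edge correction — because
that reproduces the plain computation the source describes; a toroidal
metric is provided for validation, since for a 2D Poisson process the
closed forms (mean NND = 1/(2√λ), regularity index
RI = 1/√(4/π − 1) ≈ 1.913) are exact only without edge effects. The SD in
the RI is the population SD (divide by n) by default, with a sample-SD
switch; at n of a few dozen cells per field the difference is ~1%, but the
convention is explicit. A perfect lattice has zero SD; the RI returns `Inf`
with a warning rather than an error. Border-cell exclusion is not applied
(the source is silent); both metrics being available lets a user quantify
the edge effect directly.

## Electrophysiology

**Event detection.** Traces are low-pass filtered offline at 2 kHz with a
zero-phase frequency-domain Butterworth-magnitude filter (no group delay, so
event times are unbiased), and a running-median baseline (200 ms window) is
subtracted. Events are the maxima of above-threshold excursions of the
event-polarity deflection, with two guards: a refractory gap
(`min_interval_ms`, default 5 ms) and a hysteresis re-arm (the deflection
must fall below threshold/2 between events). The re-arm matters: without
it, noise bumps riding on an event's decay tail re-cross the threshold a
few ms after the peak and are double-counted. The detector's parameters are
explicit configuration because the original analysis used a commercial
detector whose internals are not published. On the stated synthetic
condition (30 ± 8 pA events, 3 pA noise, threshold 5 × noise SD) the
detector reaches ≥ 95% recall with event times within 2 ms and no false
positives; the residual misses are events arriving inside another event's
re-arm window, which no run-based detector can split.

**TTX windows.** Baseline frequency is the event count in the 180 s
immediately before TTX onset ÷ 180; the post-TTX frequency is the count in
the 180-s window starting 100 s after onset (the 100-s gap is wash-in
time). Insufficient coverage is an error naming the missing span.

**Holding currents.** The holding current of a 20-s segment is the centre
of a single Gaussian least-squares fitted to the histogram of all samples
(bin width = half the robust noise SD). Because sparse synaptic events
populate only one tail of the histogram, the fitted mode is robust where
the plain mean is biased — the tests assert exactly this ordering. Fit
divergence falls back to the histogram mode, flagged. Agonist-induced
currents are the difference between the holding current of the 20-s window
(located among post-onset windows by maximal absolute shift of the running
mean, then properly fitted) and the 20-s control window ending at onset.

**Reversal potentials.** E = (RT/zF)·ln([out]/[in]) in mV. Chloride totals
are derived stoichiometrically from named components (KCl → 1 Cl⁻,
CaCl₂/MgCl₂ → 2, gluconate/HEPES/phosphates/nucleotides → 0). The default
temperature is 33 °C, the midpoint of the 32–34 °C bath range; across
32–37 °C the computed E_Cl moves by ~1 mV, which is why the inhibitory
value is quoted as ≈ −85 mV while the computation at 33 °C gives −84.4 mV.
The bath recipe is the standard bicarbonate-buffered aCSF whose chloride
total (132.5 mM) reproduces both printed reversal potentials; activity
coefficients are not applied (concentrations, not activities, as is
conventional for these quick design calculations).

## Synthetic data: what it emulates, and what a green test means

Each generator states a world and attaches exact ground truth:

- **Traces**: homogeneous-Poisson transient onsets; each transient rises
  linearly over `rise_s` (1 s) and decays exponentially with `decay_tau_s`
  (8 s), scaled to `amplitude_dff` (0.4) — a shape chosen for its simple
  analytic area, amplitude × (τ + rise/2); Gaussian noise
  (`noise_sd_dff` = 0.02, i.e. SNR 20 — the source gives no SNR, so it is a
  config value, not a constant); optional sinusoidal drift. 300 frames at
  1 Hz by default.
- **Puncta fields**: colocalised pairs share a centre (partner offset
  < ¼ punctum diameter, guaranteeing mask overlap); all other centres keep
  a hard-core separation of 2 × punctum diameter via rejection sampling
  (100 attempts, then dropped and counted), so ground-truth pairing is
  exact — lone puncta cannot colocalise by accident and same-channel
  puncta cannot touch. Spots are Gaussian (FWHM = `punctum_diameter_um`,
  default 0.4 µm, a realistic synaptic punctum), peak 120 over background
  10, noise SD 3, clipped (never wrapped) into 8 bits. At the densest
  realistic fields (~53/100 µm²) neighbouring spots at the hard-core limit
  occasionally merge at threshold, so recovered counts run ~5% below truth;
  this is a property of the imaging model, not a detection bug, and it is
  why the recovery tolerance is 10%.
- **Bead scenes**: labelled somata as discs whose radius tapers across
  neighbouring z-planes; internal beads strictly inside the central-plane
  disc; external beads clear of every soma. 3-µm beads, 2-µm z-steps.
- **Point patterns**: count-conditioned Poisson, jittered square lattices
  (wrapped on the field torus so the lattice stays regular under the
  toroidal metric), and a Thomas-like clustered mode.
- **Current traces**: double-exponential PSC kernels (rise 0.5 ms, decay
  5 ms) at Poisson times with a rate switch at TTX onset, truncated-normal
  amplitudes, Gaussian baseline noise, and an instantaneous agonist step.

All generators consume a single seeded RNG stream and restore the caller's
RNG state; identical seed and spec give bit-identical output.

What the generators do *not* emulate: optics (no PSF fitting), bleaching,
registration artifacts, z-blur between planes, bursty or non-Poisson event
statistics, slow membrane-current drifts, or the biology itself (channel
gating). A green suite therefore establishes that the *measurement
operators* are correct on data satisfying their stated assumptions — it
does not validate those assumptions on real tissue.

## Numerical choices and degenerate inputs

- Integration is trapezoidal at the native frame interval everywhere.
- F~o~ = 0 in ΔF/F, zero cells in a phagocytic index, n < 2 in NND, empty
  event traces, non-positive Nernst concentrations, and insufficient
  TTX/agonist coverage are errors with named causes, not NaN propagation.
- The strict punctum size window uses a 10⁻⁹ relative epsilon against
  floating-point representation of pixel-count × pixel-area products.
- Images are serialised as CSV matrices and configs as JSON: the deployment
  environment has no TIFF or YAML reader, and the analysis is agnostic to
  the container format. The module boundaries are unchanged, so a TIFF
  reader can be slotted into `read_image_csv`'s place.
- The pipeline materialises every default into the resolved config and
  records it, with input checksums and seeds, in `manifest.json`;
  deterministic stages re-run byte-identically from the same manifest.

## Known limitations

- Recovered punctum counts are biased low by a few percent at dense fields
  (spot merging, above); the bias grows with density and punctum size.
- The transient detector's rate response is linear only in the sparse
  regime (below ~0.3 transients/min for 8-s decays); overlapping transients
  merge into single detected events at higher rates.
- The mean-NND estimator without edge correction is biased upward on
  cropped fields (its documented behaviour); use the toroidal metric for
  closed-form comparisons.
- 3D puncta segmentation, adaptive thresholding, ROI segmentation from
  movies, bead detection from raw fluorescence, spine counting, image
  registration, and access-resistance QC are out of scope by design.
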