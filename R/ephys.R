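# Synaptic-current analysis: event detection on voltage-clamp traces,
# frequency comparison around TTX application, Gaussian-histogram holding
# currents, agonist-induced current shifts, and Nernst reversal potentials
# from pipette/bath solution recipes.

#' Construct a voltage-clamp current trace
#'
#' @param samples current samples in pA.
#' @param sample_rate_hz sampling rate (default 20000).
#' @param ttx_onset_s time of TTX application (s), `NA` if none.
#' @param agonist_onset_s time of agonist application (s), `NA` if none.
#' @param holding_mV holding potential (metadata).
#' @param polarity `"inward"` (events deflect negative) or `"outward"`.
#' @return a `current_trace` object.
#' @export
current_trace <- function(samples, sample_rate_hz = 20000,
                          ttx_onset_s = NA_real_, agonist_onset_s = NA_real_,
                          holding_mV = NA_real_,
                          polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(samples), length(samples) >= 2L, sample_rate_hz > 0)
  dur <- length(samples) / sample_rate_hz
  for (m in c(ttx_onset_s, agonist_onset_s)) {
    if (!is.na(m) && (m < 0 || m > dur)) {
      stop("epoch marker outside the trace duration")
    }
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 ttx_onset_s = ttx_onset_s,
                 agonist_onset_s = agonist_onset_s,
                 holding_mV = holding_mV, polarity = polarity),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %.1f s @ %g kHz (%s events)\n",
              length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz / 1000, x$polarity))
  invisible(x)
}

#' Detect synaptic events in a current trace
#'
#' The trace is low-pass filtered offline (zero-phase, 2 kHz by default), a
#' running-median baseline is subtracted, and events are local extrema of the
#' event-polarity deflection exceeding `threshold_pA`, separated by at least
#' `min_interval_ms` (closer candidates are merged into the larger one).
#' Amplitude is the peak deflection from the local baseline, reported as a
#' magnitude.
#'
#' @param trace a [current_trace()].
#' @param threshold_pA detection threshold (pA); should exceed the noise
#'   floor (e.g. 5 x the baseline SD).
#' @param min_interval_ms refractory interval between events (default 5 ms).
#' @param filter_cutoff_hz offline low-pass cutoff (default 2000).
#' @param baseline_window_ms running-median window (default 200 ms).
#' @return a `synaptic_events` data frame: `time_s` (sorted), `amplitude_pA`
#'   (> 0), with attributes `polarity` and `duration_s`.
#' @export
detect_events <- function(trace, threshold_pA, min_interval_ms = 5,
                          filter_cutoff_hz = 2000,
                          baseline_window_ms = 200) {
  stopifnot(inherits(trace, "current_trace"))
  if (!length(trace$samples)) stop("empty trace")
  fs <- trace$sample_rate_hz
  x <- lowpass_filter(trace$samples, fs, filter_cutoff_hz)
  k <- round(baseline_window_ms / 1000 * fs)
  if (k %% 2 == 0) k <- k + 1L
  base <- runmed(x, k, endrule = "median")
  d <- if (trace$polarity == "inward") base - x else x - base
  n <- length(d)
  # one candidate per above-threshold excursion (the detector re-arms only
  # once the deflection falls back below threshold), then a refractory merge
  r <- rle(d > threshold_pA)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_on <- starts[r$values]
  run_off <- ends[r$values]
  peaks <- vapply(seq_along(run_on), function(k) {
    idx <- run_on[k]:run_off[k]
    idx[which.max(d[idx])]
  }, integer(1))
  min_gap <- round(min_interval_ms / 1000 * fs)
  if (length(peaks) > 1L) {
    merged <- peaks[1]
    for (p in peaks[-1]) {
      last <- merged[length(merged)]
      # hysteresis: a new event requires the deflection to have re-armed
      # below half threshold since the previous peak, plus the refractory gap
      rearmed <- min(d[last:p]) < threshold_pA / 2
      if (p - last < min_gap || !rearmed) {
        if (d[p] > d[last]) merged[length(merged)] <- p
      } else {
        merged <- c(merged, p)
      }
    }
    peaks <- merged
  }
  ev <- data.frame(time_s = (peaks - 1L) / fs, amplitude_pA = d[peaks])
  attr(ev, "polarity") <- trace$polarity
  attr(ev, "duration_s") <- n / fs
  class(ev) <- c("synaptic_events", "data.frame")
  ev
}

#' Compare event frequencies around TTX application
#'
#' Baseline frequency is the event count in the 180 s immediately before TTX
#' onset divided by 180; the post frequency is the count in the 180-s window
#' starting 100 s after onset. Mean amplitudes per window are also reported.
#'
#' @param events a data frame with `time_s` (and optionally `amplitude_pA`),
#'   e.g. from [detect_events()] or a simulated ground-truth train.
#' @param ttx_onset_s TTX application time (s).
#' @param duration_s trace duration; taken from the `duration_s` attribute of
#'   `events` when missing.
#' @param baseline_window_s,post_delay_s,post_window_s window geometry
#'   (defaults 180, 100, 180 s).
#' @return list with `baseline_freq_hz`, `post_freq_hz`, `baseline_n`,
#'   `post_n`, `baseline_mean_amplitude_pA`, `post_mean_amplitude_pA`, and
#'   the window bounds.
#' @export
ttx_comparison <- function(events, ttx_onset_s, duration_s = NULL,
                           baseline_window_s = 180, post_delay_s = 100,
                           post_window_s = 180) {
  if (is.null(duration_s)) duration_s <- attr(events, "duration_s")
  if (is.null(duration_s)) stop("duration_s required")
  t0 <- ttx_onset_s - baseline_window_s
  t1 <- ttx_onset_s + post_delay_s + post_window_s
  if (t0 < 0 || t1 > duration_s) {
    stop(sprintf(
      "insufficient coverage: need [%.0f, %.0f] s but trace spans [0, %.0f] s",
      t0, t1, duration_s))
  }
  tt <- events$time_s
  in_base <- tt >= t0 & tt < ttx_onset_s
  in_post <- tt >= ttx_onset_s + post_delay_s & tt < t1
  amp <- function(sel) {
    if (!is.null(events$amplitude_pA) && any(sel)) {
      mean(events$amplitude_pA[sel])
    } else NA_real_
  }
  list(baseline_freq_hz = sum(in_base) / baseline_window_s,
       post_freq_hz = sum(in_post) / post_window_s,
       baseline_n = sum(in_base), post_n = sum(in_post),
       baseline_mean_amplitude_pA = amp(in_base),
       post_mean_amplitude_pA = amp(in_post),
       baseline_window = c(t0, ttx_onset_s),
       post_window = c(ttx_onset_s + post_delay_s, t1))
}

#' Holding current from a Gaussian fit to the sample histogram
#'
#' Histograms all samples in the segment (bin width = half the robust noise
#' SD by default) and least-squares fits a single Gaussian; the fitted centre
#' is the holding current. Because sparse synaptic events populate only one
#' tail, the fitted mode is more robust than the plain mean. If the fit
#' diverges the histogram mode is returned and flagged.
#'
#' @param samples numeric current samples (pA) of the segment.
#' @param bin_width_pA histogram bin width; default `mad(samples)/2`.
#' @return list with `mean_pA`, `sd_pA`, `method` (`"gaussian_fit"` or
#'   `"histogram_mode"`).
#' @export
holding_current <- function(samples, bin_width_pA = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 10L)
  if (is.null(bin_width_pA)) {
    bw <- mad(samples) / 2
    if (bw <= 0) bw <- max(diff(range(samples)) / 100, 1e-9)
  } else {
    bw <- bin_width_pA
  }
  if (diff(range(samples)) < 1e-12) {
    return(list(mean_pA = samples[1], sd_pA = 0, method = "constant"))
  }
  breaks <- seq(min(samples) - bw, max(samples) + bw, by = bw)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  xs <- h$mids
  ys <- h$counts
  mode0 <- xs[which.max(ys)]
  obj <- function(p) {
    # p = (log amplitude, mean, log sd)
    sum((ys - exp(p[1]) * exp(-(xs - p[2])^2 / (2 * exp(2 * p[3]))))^2)
  }
  fit <- tryCatch(
    optim(c(log(max(ys)), mode0, log(max(mad(samples), bw))), obj,
          method = "BFGS", control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) ||
      abs(fit$par[2] - mode0) > 10 * mad(samples) + 10 * bw) {
    return(list(mean_pA = mode0, sd_pA = mad(samples),
                method = "histogram_mode"))
  }
  list(mean_pA = fit$par[2], sd_pA = exp(fit$par[3]), method = "gaussian_fit")
}

#' Agonist-induced shift in holding current
#'
#' Control current is the Gaussian-histogram holding current of the
#' `segment_s` window ending at agonist onset; the response is the 20-s
#' window after onset maximising the absolute shift of the (running-mean
#' located, then Gaussian-fitted) holding current. The returned shift is
#' response minus control, signed.
#'
#' @param trace a [current_trace()].
#' @param onset_s agonist application time; defaults to the trace marker.
#' @param segment_s analysis window length (default 20 s).
#' @param search_step_s step between candidate response windows (default 5 s).
#' @return list with `shift_pA`, `control_pA`, `response_pA`,
#'   `response_window` (start/end s), and the fit methods used.
#' @export
agonist_current <- function(trace, onset_s = trace$agonist_onset_s,
                            segment_s = 20, search_step_s = 5) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.na(onset_s)) stop("agonist onset time required")
  fs <- trace$sample_rate_hz
  n <- length(trace$samples)
  dur <- n / fs
  if (onset_s < segment_s || dur - onset_s < segment_s) {
    stop(sprintf("need >= %g s both before onset and after it", segment_s))
  }
  seg_idx <- function(t0) {
    i0 <- floor(t0 * fs) + 1L
    i0:min(n, i0 + round(segment_s * fs) - 1L)
  }
  ctrl <- holding_current(trace$samples[seg_idx(onset_s - segment_s)])
  # locate the peak window cheaply with window means, then fit it properly
  starts <- seq(onset_s, dur - segment_s, by = search_step_s)
  means <- vapply(starts, function(t0) mean(trace$samples[seg_idx(t0)]),
                  numeric(1))
  best <- starts[which.max(abs(means - ctrl$mean_pA))]
  resp <- holding_current(trace$samples[seg_idx(best)])
  list(shift_pA = resp$mean_pA - ctrl$mean_pA,
       control_pA = ctrl$mean_pA, response_pA = resp$mean_pA,
       response_window = c(best, best + segment_s),
       control_method = ctrl$method, response_method = resp$method)
}

# ---- Solution recipes and Nernst potentials -------------------------------

# Chloride stoichiometry of common pipette/bath components; everything else
# (gluconate, HEPES, phosphates, nucleotides, sugars) contributes no Cl-.
.cl_stoichiometry <- c(KCl = 1, NaCl = 1, CaCl2 = 2, MgCl2 = 2,
                       CholineCl = 1, CsCl = 1)
.k_stoichiometry <- c(KCl = 1, K_gluconate = 1, KOH = 1, K2HPO4 = 2,
                      KH2PO4 = 1)
.na_stoichiometry <- c(NaCl = 1, NaHCO3 = 1, NaH2PO4 = 1, Na2GTP = 2,
                       Na_ascorbate = 1, Na_pyruvate = 1, NaOH = 1)

#' Construct a solution recipe with derived ionic totals
#'
#' @param components named numeric vector of molarities in mM, e.g.
#'   `c(K_gluconate = 132.3, KCl = 7.7, NaCl = 4, CaCl2 = 0.5)`. Component
#'   names follow the salts as printed (underscores for hyphens).
#' @param name optional label.
#' @return a `solution_recipe` with elements `components`, `name`, and
#'   derived totals `cl_mM`, `k_mM`, `na_mM`.
#' @export
solution_recipe <- function(components, name = "") {
  stopifnot(is.numeric(components), !is.null(names(components)))
  if (any(components < 0)) stop("molarities must be >= 0")
  total <- function(stoich) {
    common <- intersect(names(components), names(stoich))
    sum(components[common] * stoich[common])
  }
  structure(list(components = components, name = name,
                 cl_mM = total(.cl_stoichiometry),
                 k_mM = total(.k_stoichiometry),
                 na_mM = total(.na_stoichiometry)),
            class = "solution_recipe")
}

#' @export
print.solution_recipe <- function(x, ...) {
  cat(sprintf("<solution_recipe> %s: [Cl-] %.1f mM, [K+] %.1f mM, [Na+] %.1f mM\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              x$cl_mM, x$k_mM, x$na_mM))
  invisible(x)
}

#' Built-in solution recipes
#'
#' The pipette internals used for excitatory and inhibitory recordings and
#' the bathing aCSF (the slicing solution, whose chloride total reproduces
#' the stated reversal potentials).
#'
#' @return a [solution_recipe()].
#' @export
#' @rdname recipes
recipe_internal_excitatory <- function() {
  solution_recipe(c(K_gluconate = 132.3, KCl = 7.7, NaCl = 4, CaCl2 = 0.5,
                    HEPES = 10, EGTA = 5, MgATP = 4, Na2GTP = 0.5),
                  "excitatory internal")
}

#' @export
#' @rdname recipes
recipe_internal_inhibitory <- function() {
  solution_recipe(c(K_gluconate = 140, NaCl = 1.4, MgCl2 = 1.5, CaCl2 = 0.5,
                    HEPES = 10, EGTA = 0.2, MgATP = 4, Na2GTP = 0.5),
                  "inhibitory internal")
}

#' @export
#' @rdname recipes
recipe_acsf <- function() {
  solution_recipe(c(NaCl = 124, KCl = 2.5, NaHCO3 = 26, NaH2PO4 = 1,
                    glucose = 10, CaCl2 = 1, MgCl2 = 2),
                  "aCSF")
}

#' Nernst reversal potential
#'
#' E = (R T) / (z F) ln([out]/[in]), in mV.
#'
#' @param valence ionic valence z (e.g. -1 for Cl-).
#' @param conc_in_mM,conc_out_mM intracellular/extracellular concentrations
#'   (mM, > 0).
#' @param temp_C temperature in degrees Celsius (default 33, the midpoint of
#'   the 32--34 degree recording range).
#' @return reversal potential in mV.
#' @export
nernst <- function(valence, conc_in_mM, conc_out_mM, temp_C = 33) {
  if (conc_in_mM <= 0 || conc_out_mM <= 0) {
    stop("concentrations must be positive")
  }
  R <- 8.314462618; FARADAY <- 96485.33212
  TK <- temp_C + 273.15
  1000 * R * TK / (valence * FARADAY) * log(conc_out_mM / conc_in_mM)
}

#' Chloride reversal potential from solution recipes
#'
#' @param internal,external [solution_recipe()]s (pipette and bath).
#' @param temp_C temperature in degrees Celsius.
#' @return E_Cl in mV.
#' @export
e_rev_cl <- function(internal, external = recipe_acsf(), temp_C = 33) {
  stopifnot(inherits(internal, "solution_recipe"),
            inherits(external, "solution_recipe"))
  nernst(-1, internal$cl_mM, external$cl_mM, temp_C)
}
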