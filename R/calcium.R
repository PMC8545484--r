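# Spontaneous calcium-transient detection and lesion-evoked responses from
# ROI fluorescence time series.
#
# Pipeline: dF/F normalisation -> shape-preserving piecewise-cubic baseline
# through block-median anchors -> threshold at 2.25 x the SD of the first 100
# near-baseline points -> integral-area filter (> 0.15 dF/F.s).

#' Construct a fluorescence trace
#'
#' @param values per-frame fluorescence, raw (arbitrary units) or dF/F.
#' @param frame_rate_hz frames per second (default 1).
#' @param is_dff `TRUE` if `values` are already dF/F.
#' @return a `fluor_trace` object.
#' @export
fluor_trace <- function(values, frame_rate_hz = 1, is_dff = FALSE) {
  stopifnot(is.numeric(values), length(values) >= 2L, frame_rate_hz > 0)
  structure(list(values = as.numeric(values),
                 frame_rate_hz = frame_rate_hz, is_dff = isTRUE(is_dff)),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d frames @ %g Hz (%s)\n", length(x$values),
              x$frame_rate_hz, if (x$is_dff) "dF/F" else "raw"))
  invisible(x)
}

#' Detection parameters for calcium transients
#'
#' Defaults are the published analysis settings: 100-frame baseline
#' smoothing blocks, a detection threshold of 2.25 x the SD of the first 100
#' points with dF/F below 0.1, and a minimal transient area of 0.15 dF/F.s.
#'
#' @param smoothing_frames block length for baseline anchors (frames).
#' @param threshold_multiplier multiple of the baseline-noise SD.
#' @param baseline_eligibility_dff dF/F ceiling for a frame to count as
#'   baseline-like (both for anchors and for the SD estimate).
#' @param min_area_dff_s minimal integral of (dF/F - baseline) over an event.
#' @param n_baseline_points number of eligible points used for the SD.
#' @param sd_on one of `"raw_dff"` (SD computed on the dF/F values of the
#'   eligible frames, as published) or `"baseline_subtracted"`.
#' @return a `detection_params` list.
#' @export
detection_params <- function(smoothing_frames = 100L,
                             threshold_multiplier = 2.25,
                             baseline_eligibility_dff = 0.1,
                             min_area_dff_s = 0.15,
                             n_baseline_points = 100L,
                             sd_on = c("raw_dff", "baseline_subtracted")) {
  sd_on <- match.arg(sd_on)
  for (f in c("smoothing_frames", "threshold_multiplier",
              "baseline_eligibility_dff", "min_area_dff_s",
              "n_baseline_points")) {
    check_scalar(get(f), f, positive = TRUE)
  }
  structure(list(smoothing_frames = as.integer(smoothing_frames),
                 threshold_multiplier = threshold_multiplier,
                 baseline_eligibility_dff = baseline_eligibility_dff,
                 min_area_dff_s = min_area_dff_s,
                 n_baseline_points = as.integer(n_baseline_points),
                 sd_on = sd_on),
            class = "detection_params")
}

#' Convert a raw fluorescence trace to dF/F
#'
#' dF/F at frame t is (F_t - F_o) / F_o with F_o the mean raw fluorescence
#' over `baseline_frames`.
#'
#' @param raw a raw [fluor_trace()].
#' @param baseline_frames integer frame indices defining the baseline.
#' @return a [fluor_trace()] with `is_dff = TRUE`.
#' @export
compute_dff <- function(raw, baseline_frames) {
  stopifnot(inherits(raw, "fluor_trace"))
  if (raw$is_dff) stop("trace is already dF/F")
  baseline_frames <- as.integer(baseline_frames)
  if (!length(baseline_frames) ||
      any(baseline_frames < 1L | baseline_frames > length(raw$values))) {
    stop("baseline_frames must be a non-empty range within the trace")
  }
  f0 <- mean(raw$values[baseline_frames])
  if (f0 == 0) stop("degenerate baseline: F_o is zero")
  fluor_trace((raw$values - f0) / f0, raw$frame_rate_hz, is_dff = TRUE)
}

#' Fit a slowly varying baseline to a dF/F trace
#'
#' The trace is cut into consecutive blocks of `smoothing_frames` frames; in
#' each block the anchor is the median dF/F of frames below the eligibility
#' ceiling (a robust estimate unaffected by transients). A shape-preserving
#' piecewise cubic Hermite interpolant (Fritsch--Carlson) is drawn through
#' the anchors and extrapolated as a constant beyond the first/last anchor,
#' so the curve never overshoots the anchor range within an interval.
#'
#' @param trace a dF/F [fluor_trace()].
#' @param params a [detection_params()].
#' @return numeric baseline, one value per frame. Attribute
#'   `fallback_blocks` lists blocks that had no eligible frame (their anchor
#'   fell back to the all-frame median).
#' @export
fit_baseline <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "fluor_trace"), trace$is_dff)
  v <- trace$values
  n <- length(v)
  if (n < params$smoothing_frames) {
    stop("trace shorter than one smoothing block")
  }
  starts <- seq(1L, n, by = params$smoothing_frames)
  fallback <- integer(0)
  anchors_x <- anchors_y <- numeric(length(starts))
  for (b in seq_along(starts)) {
    idx <- starts[b]:min(n, starts[b] + params$smoothing_frames - 1L)
    elig <- idx[v[idx] < params$baseline_eligibility_dff]
    if (length(elig) == 0L) {
      elig <- idx
      fallback <- c(fallback, b)
    }
    anchors_x[b] <- mean(range(idx))
    anchors_y[b] <- median(v[elig])
  }
  base <- if (length(starts) == 1L) {
    rep(anchors_y, n)
  } else if (length(starts) == 2L) {
    # two anchors: linear between, constant outside
    xq <- pmin(pmax(seq_len(n), anchors_x[1]), anchors_x[2])
    anchors_y[1] + (anchors_y[2] - anchors_y[1]) *
      (xq - anchors_x[1]) / (anchors_x[2] - anchors_x[1])
  } else {
    f <- splinefun(anchors_x, anchors_y, method = "monoH.FC")
    f(pmin(pmax(seq_len(n), anchors_x[1]), anchors_x[length(anchors_x)]))
  }
  attr(base, "fallback_blocks") <- fallback
  base
}

#' Detect calcium transients in a dF/F trace
#'
#' The detection threshold is `threshold_multiplier` times the SD of the
#' first `n_baseline_points` frames, scanning from the start of the trace,
#' whose dF/F is below the eligibility ceiling. Candidate events are maximal
#' runs where (dF/F - baseline) exceeds the threshold; runs separated by
#' fewer than 2 frames are merged; events are kept iff their trapezoidal
#' integral of (dF/F - baseline) exceeds `min_area_dff_s`. Events whose peak
#' is within 1.5 x threshold or which touch the trace edges are flagged
#' `needs-review` rather than excluded (machine-readable stand-in for manual
#' confirmation).
#'
#' @param trace a dF/F [fluor_trace()].
#' @param baseline per-frame baseline from [fit_baseline()] (recomputed when
#'   `NULL`).
#' @param params a [detection_params()].
#' @return list with `events` (data frame: `onset_frame`, `offset_frame`,
#'   `onset_s`, `offset_s`, `peak_dff`, `area_dff_s`, `qc_flag`),
#'   `rate_per_300s`, `rate_per_min`, `threshold`, and `sd_flag` (`TRUE` if
#'   fewer than `n_baseline_points` eligible frames were available).
#' @export
detect_transients <- function(trace, baseline = NULL,
                              params = detection_params()) {
  stopifnot(inherits(trace, "fluor_trace"), trace$is_dff)
  v <- trace$values
  n <- length(v)
  if (is.null(baseline)) baseline <- fit_baseline(trace, params)
  stopifnot(length(baseline) == n)

  resid <- v - baseline
  elig_values <- switch(params$sd_on, raw_dff = v, baseline_subtracted = resid)
  elig <- which(v < params$baseline_eligibility_dff)
  sd_flag <- FALSE
  if (length(elig) == 0L) {
    stop("detection impossible: no frames below the baseline-eligibility ",
         "ceiling")
  }
  if (length(elig) < params$n_baseline_points) {
    sd_flag <- TRUE
  } else {
    elig <- elig[seq_len(params$n_baseline_points)]
  }
  threshold <- params$threshold_multiplier * sd(elig_values[elig])

  above <- resid > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  # merge events separated by < 2 frames (a single sub-threshold frame)
  if (length(on) > 1L) {
    merged_on <- c(); merged_off <- c()
    cur_on <- on[1]; cur_off <- off[1]
    for (k in 2:length(on)) {
      if (on[k] - cur_off - 1L < 2L) {
        cur_off <- off[k]
      } else {
        merged_on <- c(merged_on, cur_on); merged_off <- c(merged_off, cur_off)
        cur_on <- on[k]; cur_off <- off[k]
      }
    }
    on <- c(merged_on, cur_on); off <- c(merged_off, cur_off)
  }

  dt <- 1 / trace$frame_rate_hz
  rows <- lapply(seq_along(on), function(k) {
    idx <- on[k]:off[k]
    area <- trapz(resid[idx], dt)
    peak <- max(resid[idx])
    data.frame(onset_frame = on[k], offset_frame = off[k],
               onset_s = (on[k] - 1L) * dt, offset_s = (off[k] - 1L) * dt,
               peak_dff = peak, area_dff_s = area)
  })
  ev <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(onset_frame = integer(0), offset_frame = integer(0),
               onset_s = numeric(0), offset_s = numeric(0),
               peak_dff = numeric(0), area_dff_s = numeric(0))
  }
  ev <- ev[ev$area_dff_s > params$min_area_dff_s, , drop = FALSE]
  ev$qc_flag <- ifelse(
    ev$peak_dff < 1.5 * threshold | ev$onset_frame == 1L |
      ev$offset_frame == n,
    "needs-review", "auto-accepted")
  rownames(ev) <- NULL
  duration_s <- n * dt
  list(events = ev,
       rate_per_300s = nrow(ev) * 300 / duration_s,
       rate_per_min = nrow(ev) * 60 / duration_s,
       threshold = threshold, sd_flag = sd_flag)
}

#' Peak dF/F response evoked by a laser lesion
#'
#' The baseline F_o is the mean raw fluorescence over the `pre_window_s`
#' seconds preceding the lesion frame; the response is the maximum dF/F over
#' the post-lesion frames.
#'
#' @param raw a raw [fluor_trace()].
#' @param lesion_frame 1-based frame index at which the lesion occurred.
#' @param pre_window_s pre-lesion baseline window (default 20 s).
#' @return list with `peak_dff`, `peak_frame`, and the `dff` trace.
#' @export
evoked_response <- function(raw, lesion_frame, pre_window_s = 20) {
  stopifnot(inherits(raw, "fluor_trace"), !raw$is_dff)
  w <- round(pre_window_s * raw$frame_rate_hz)
  if (lesion_frame - w < 1L) {
    stop(sprintf("insufficient baseline: need %g s before the lesion frame",
                 pre_window_s))
  }
  dff <- compute_dff(raw, (lesion_frame - w):(lesion_frame - 1L))
  post <- lesion_frame:length(dff$values)
  peak_idx <- post[which.max(dff$values[post])]
  list(peak_dff = dff$values[peak_idx], peak_frame = peak_idx, dff = dff)
}
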