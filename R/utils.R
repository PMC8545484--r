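# Shared numeric helpers.

#' Trapezoidal integral of a sampled curve
#'
#' @param y numeric samples.
#' @param dx spacing between consecutive samples (constant).
#' @return the trapezoid-rule integral; 0 for fewer than two samples.
#' @keywords internal
trapz <- function(y, dx = 1) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2) * dx
}

#' Zero-phase low-pass filter via the frequency domain
#'
#' Applies a Butterworth-magnitude transfer function |H(f)| =
#' 1 / sqrt(1 + (f/fc)^(2n)) symmetrically in the frequency domain, which is
#' zero-phase by construction (no group delay, suitable for offline event
#' timing).
#'
#' @param x numeric vector of samples.
#' @param sample_rate_hz sampling rate.
#' @param cutoff_hz -3 dB cutoff frequency.
#' @param order filter order (default 4).
#' @return filtered vector, same length.
#' @export
lowpass_filter <- function(x, sample_rate_hz, cutoff_hz, order = 4L) {
  n <- length(x)
  if (n < 2L || cutoff_hz >= sample_rate_hz / 2) return(x)
  f <- seq(0, sample_rate_hz, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, sample_rate_hz - f) # two-sided frequency axis
  H <- 1 / sqrt(1 + (f / cutoff_hz)^(2 * order))
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

# Sequential hard-core (rejection) sampler: uniform points in [0, fov] x
# [0, fov] with pairwise distance >= min_sep, checked against an optional set
# of pre-existing points. Bucketed grid keeps each check local. Points that
# cannot be placed within max_attempts are dropped and counted.
hardcore_sample <- function(n, fov, min_sep, existing = NULL,
                            max_attempts = 100L) {
  if (n <= 0L) {
    return(list(x = numeric(0), y = numeric(0), failures = 0L))
  }
  cell <- max(min_sep, 1e-9)
  ncell <- max(1L, ceiling(fov / cell))
  grid <- vector("list", ncell * ncell)
  gidx <- function(x, y) {
    cx <- pmin(pmax(floor(x / cell), 0), ncell - 1L)
    cy <- pmin(pmax(floor(y / cell), 0), ncell - 1L)
    as.integer(cy * ncell + cx + 1L)
  }
  px <- numeric(0); py <- numeric(0)
  add_pt <- function(x, y) {
    px[length(px) + 1L] <<- x
    py[length(py) + 1L] <<- y
    g <- gidx(x, y)
    grid[[g]] <<- c(grid[[g]], length(px))
  }
  if (!is.null(existing) && length(existing$x) > 0L) {
    for (k in seq_along(existing$x)) add_pt(existing$x[k], existing$y[k])
  }
  n_existing <- length(px)
  clear <- function(x, y) {
    cx <- as.integer(floor(x / cell)); cy <- as.integer(floor(y / cell))
    for (i in max(0L, cy - 1L):min(ncell - 1L, cy + 1L)) {
      for (j in max(0L, cx - 1L):min(ncell - 1L, cx + 1L)) {
        ids <- grid[[i * ncell + j + 1L]]
        if (length(ids) &&
            any((px[ids] - x)^2 + (py[ids] - y)^2 < min_sep^2)) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  failures <- 0L
  for (k in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- runif(1, 0, fov); y <- runif(1, 0, fov)
      if (clear(x, y)) { add_pt(x, y); placed <- TRUE; break }
    }
    if (!placed) failures <- failures + 1L
  }
  keep <- seq.int(n_existing + 1L, length.out = length(px) - n_existing)
  list(x = px[keep], y = py[keep], failures = failures)
}

# Pairwise nearest-neighbour distances, plain Euclidean or on a torus of the
# FOV dimensions (used to test against closed-form Poisson expectations
# without edge bias).
nn_distances <- function(x, y, width = NULL, height = NULL,
                         toroidal = FALSE) {
  n <- length(x)
  stopifnot(n >= 2L)
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  if (toroidal) {
    dx <- pmin(dx, width - dx)
    dy <- pmin(dy, height - dy)
  }
  d <- sqrt(dx^2 + dy^2)
  diag(d) <- Inf
  apply(d, 1L, min)
}

stop_invalid <- function(field, why) {
  stop(sprintf("invalid spec: `%s` %s", field, why), call. = FALSE)
}

check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(field, "must be a finite numeric scalar")
  }
  if (positive && x <= 0) stop_invalid(field, "must be > 0")
  if (nonneg && x < 0) stop_invalid(field, "must be >= 0")
  invisible(x)
}
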