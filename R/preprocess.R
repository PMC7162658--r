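#' Bandpass specification
#'
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr)`.
#' @return A `bandpass_spec` object.
#' @export
bandpass_spec <- function(low_hz, high_hz) {
  low_hz <- check_pos(low_hz, "low_hz")
  high_hz <- check_pos(high_hz, "high_hz")
  if (low_hz >= high_hz) stop_invalid("low_hz", "must be below high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "bandpass_spec")
}

# --- Butterworth bandpass design (analog prototype -> LP-to-BP transform ->
# bilinear). No filter-design package ships with this R stack, so the design
# is done here; the tests check the realised frequency response, not the
# coefficient path.

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

# Coefficients (b, a) of an order-`n` (prototype order) digital Butterworth
# bandpass; `low`/`high` are normalised to the sampling rate fs = 1.
butter_bandpass <- function(n, low, high) {
  fs <- 2  # design at fs = 2 so band edges are in (0, 1) as Nyquist fractions
  warped <- 2 * fs * tan(pi * c(low, high) / fs)
  bw <- warped[2] - warped[1]
  w0 <- sqrt(prod(warped))
  # analog lowpass prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # lowpass -> bandpass: each pole maps to a conjugate-free pair
  disc <- sqrt((bw * p / 2)^2 - w0^2)
  p_bp <- c(bw * p / 2 + disc, bw * p / 2 - disc)
  z_bp <- rep(0 + 0i, n)
  k_bp <- bw^n
  # bilinear transform
  pd <- (2 * fs + p_bp) / (2 * fs - p_bp)
  zd <- (2 * fs + z_bp) / (2 * fs - z_bp)
  kd <- k_bp * Re(prod(2 * fs - z_bp) / prod(2 * fs - p_bp))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# |H(f)| of a digital filter at normalised frequencies f (cycles/sample).
freq_response <- function(b, a, f) {
  ew <- exp(-2i * pi * f)
  hb <- vapply(ew, function(e) sum(b * e^(seq_along(b) - 1)), complex(1))
  ha <- vapply(ew, function(e) sum(a * e^(seq_along(a) - 1)), complex(1))
  abs(hb / ha)
}

# Zero-phase filtering: odd-reflect pad, filter forward and backward.
filtfilt_pad <- function(b, a, x) {
  n <- length(x)
  padlen <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  ext <- c(pre, x, post)
  y <- .iir_filter_cpp(b, a, ext)
  y <- rev(.iir_filter_cpp(b, a, rev(y)))
  y[seq(padlen + 1, padlen + n)]
}

#' Bandpass filter a timeseries
#'
#' Zero-phase (forward-backward) Butterworth bandpass. The forward-backward
#' pass squares the magnitude response, so attenuation one octave beyond a
#' band edge far exceeds 20 dB at the default order; the mean is removed
#' with the DC component. Band edges must lie below Nyquist; the upper edge
#' additionally reflects the constraint that a lowpass period should span
#' at least five volumes of data.
#'
#' @param ts a [region_ts()].
#' @param band a [bandpass_spec()].
#' @param order Butterworth prototype order. The default 4 is the lowest
#'   order whose zero-phase response suppresses a 0.2 Hz physiological
#'   artefact below 10% amplitude under the human band at TR 0.72 s; a
#'   2nd-order variant remains available.
#' @return The filtered [region_ts()].
#' @export
bandpass_filter <- function(ts, band, order = 4L) {
  stopifnot(inherits(ts, "region_ts"), inherits(band, "bandpass_spec"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (band$high_hz >= nyquist)
    stop_invalid("high_hz", sprintf(
      paste0("%.4g Hz is at or above Nyquist (%.4g Hz); the upper edge must",
             " leave a lowpass period of several volumes (rule of thumb:",
             " five volumes of data)"), band$high_hz, nyquist))
  # edges normalised as fractions of Nyquist (the fs = 2 design grid)
  coef <- butter_bandpass(order, band$low_hz / nyquist,
                          band$high_hz / nyquist)
  # demean before filtering (keeps the long highpass transient off short
  # series) and after (the spec of a bandpass: no DC in the output)
  out <- apply(ts$values, 2, function(x)
    filtfilt_pad(coef$b, coef$a, x - mean(x)))
  out <- sweep(out, 2, colMeans(out))
  region_ts(out, ts$tr_seconds, ts$unit_labels)
}

#' Remove a least-squares linear trend from each unit
#'
#' @param ts a [region_ts()] with at least 3 timepoints.
#' @return The detrended [region_ts()] (residuals of a per-unit OLS line;
#'   zero mean, zero residual slope).
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  n <- nrow(ts$values)
  if (n < 3L) stop_invalid("ts", "need n_time >= 3 for detrending")
  t0 <- seq_len(n) - (n + 1) / 2
  X <- cbind(1, t0)
  beta <- solve(crossprod(X), crossprod(X, ts$values))
  region_ts(ts$values - X %*% beta, ts$tr_seconds, ts$unit_labels)
}

#' Replace spikes by a running-median value
#'
#' Per unit, samples deviating from an 11-sample running median by more than
#' `z_mad_threshold` times the MAD of those deviations are replaced by the
#' running-median value; all other samples are untouched. Constant units
#' (MAD 0) are returned unchanged.
#'
#' @param ts a [region_ts()].
#' @param z_mad_threshold positive spike threshold in MAD units (default 5).
#' @param window running-median window, odd (default 11).
#' @return The despiked [region_ts()].
#' @export
despike <- function(ts, z_mad_threshold = 5, window = 11L) {
  stopifnot(inherits(ts, "region_ts"))
  check_pos(z_mad_threshold, "z_mad_threshold")
  out <- apply(ts$values, 2, function(x) {
    w <- min(window, length(x) - (length(x) + 1) %% 2)
    med <- runmed(x, w, endrule = "median")
    dev <- x - med
    s <- mad(dev)
    if (s == 0) return(x)
    ifelse(abs(dev) > z_mad_threshold * s, med, x)
  })
  region_ts(out, ts$tr_seconds, ts$unit_labels)
}

#' Principal eigenvariate of a multi-voxel seed
#'
#' The first left singular vector of the column-centred time-by-voxel matrix,
#' scaled to unit variance, with its sign chosen so that it correlates
#' non-negatively with the seed's mean timeseries. `variance_explained` is
#' the first squared singular value over the total.
#'
#' @param seed_ts a [region_ts()] or time-by-voxel matrix.
#' @param normalise_voxels logical; additionally scale each voxel column to
#'   unit sd before the decomposition (default FALSE, the usual eigenvariate
#'   convention).
#' @return An `eigenvariate`: list with `series` (length n_time, unit
#'   variance) and `variance_explained` in `[0, 1]`.
#' @export
principal_eigenvariate <- function(seed_ts, normalise_voxels = FALSE) {
  X <- if (inherits(seed_ts, "region_ts")) seed_ts$values else as.matrix(seed_ts)
  if (ncol(X) < 1L) stop_invalid("seed_ts", "need at least one voxel")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(Xc == 0)) stop_invalid("seed_ts", "all voxels constant")
  if (normalise_voxels) {
    sds <- apply(Xc, 2, sd)
    Xc <- sweep(Xc, 2, ifelse(sds > 0, sds, 1), `/`)
  }
  sv <- svd(Xc)
  series <- sv$u[, 1]
  m <- rowMeans(Xc)
  if (sd(m) > 0 && cor(series, m) < 0) series <- -series
  series <- series / sd(series)
  structure(list(series = series,
                 variance_explained = sv$d[1]^2 / sum(sv$d^2)),
            class = "eigenvariate")
}

#' Full conditioning pipeline for one timeseries
#'
#' Applies, in order, linear detrending, despiking, and bandpass filtering
#' (the order is configurable; this default keeps spike energy out of the
#' filter).
#'
#' @param ts a [region_ts()].
#' @param band a [bandpass_spec()] or NULL to skip filtering.
#' @param order character vector permutation of
#'   `c("detrend", "despike", "bandpass")`.
#' @param z_mad_threshold despike threshold.
#' @return The conditioned [region_ts()].
#' @export
condition_timeseries <- function(ts, band,
                                 order = c("detrend", "despike", "bandpass"),
                                 z_mad_threshold = 5) {
  stopifnot(all(order %in% c("detrend", "despike", "bandpass")))
  for (step in order) {
    ts <- switch(step,
      detrend = detrend_linear(ts),
      despike = despike(ts, z_mad_threshold),
      bandpass = if (is.null(band)) ts else bandpass_filter(ts, band))
  }
  ts
}
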