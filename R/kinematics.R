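#' Zero-phase low-pass Butterworth filter
#'
#' Filters a uniformly sampled series with a 2nd-order Butterworth low-pass
#' applied forward and backward (zero phase, DC gain 1). Motion and force
#' channels are conventionally filtered at 4 Hz before derivatives are taken;
#' bench torque sweeps use 10 Hz.
#'
#' @param series numeric vector, uniformly sampled.
#' @param fc cutoff frequency in Hz; must be below the Nyquist frequency.
#' @param fs sampling frequency in Hz.
#' @param order filter order before the forward-backward pass (default 2).
#' @return filtered numeric vector, same length as `series`.
#' @export
lowpass_filter <- function(series, fc, fs, order = 2) {
  if (!is.numeric(series)) stop("`series` must be numeric")
  if (fc >= fs / 2) stop("invalid cutoff: fc must be < fs/2 (Nyquist)")
  if (fc <= 0 || fs <= 0) stop("invalid cutoff: fc and fs must be positive")
  warmup <- 3 * (2 * order + 1)
  if (length(series) <= warmup) {
    stop("series too short for filter warm-up (need > ", warmup, " samples)")
  }
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  # odd-reflection padding suppresses forward-backward edge transients
  n <- length(series)
  pad <- min(n - 1, 3L * as.integer(ceiling(fs / fc)))
  left <- 2 * series[1] - series[(pad + 1):2]
  right <- 2 * series[n] - series[(n - 1):(n - pad)]
  out <- as.numeric(signal::filtfilt(bf, c(left, series, right)))
  out[(pad + 1):(pad + n)]
}

#' Interior angle at a vertex between two rays
#'
#' The trunk angle is the interior angle at L5 between the rays L5->C7 and
#' L5->C (C = knee midpoint), in degrees within \[0, 180\].
#'
#' @param c7,l5,c numeric length-3 points (m), or n x 3 matrices for series.
#' @return angle(s) in degrees.
#' @seealso [trunk_flexion_angle()] for the upright-zero convention.
#' @export
trunk_angle <- function(c7, l5, c) {
  c7 <- to_mat3(c7); l5 <- to_mat3(l5); c <- to_mat3(c)
  u <- c7 - l5
  v <- c - l5
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  if (any(nu < 1e-12) || any(nv < 1e-12)) {
    stop("degenerate geometry: L5 coincides with C7 or C")
  }
  cosang <- rowSums(u * v) / (nu * nv)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  if (length(ang) == 1L) as.numeric(ang) else ang
}

#' Trunk flexion angle (upright = 0 degrees)
#'
#' Reports 180 - angle(C7, L5, C) so an upright posture (C7 above L5, knees
#' below) reads approximately 0 degrees and full stoop reads large positive.
#' This convention makes the 0--90 degree bench characterization range and
#' small-angle thresholds directly interpretable; the raw interior angle is
#' available via [trunk_angle()].
#'
#' @inheritParams trunk_angle
#' @return flexion angle(s) in degrees.
#' @export
trunk_flexion_angle <- function(c7, l5, c) {
  180 - trunk_angle(c7, l5, c)
}

#' Midpoint of two markers
#'
#' Used to build the virtual wrist-midpoint D from (D1, D2) and the knee
#' midpoint C from (C1, C2).
#'
#' @param p_left,p_right length-3 points or n x 3 matrices.
#' @return midpoint(s), same shape as input.
#' @export
midpoint_marker <- function(p_left, p_right) {
  (p_left + p_right) / 2
}

#' Central-difference derivative of a uniformly sampled series
#'
#' Second-order central differences at interior points, first-order one-sided
#' differences at the two ends. Trunk angular velocity is the derivative of
#' the trunk angle and angular acceleration the derivative of the velocity;
#' both are taken on the raw (seconds) time base, before time normalization,
#' so units stay deg/s and deg/s^2.
#'
#' @param series numeric vector.
#' @param dt sampling interval in seconds.
#' @return derivative series, same length.
#' @export
differentiate <- function(series, dt) {
  n <- length(series)
  if (n < 3) stop("insufficient data: need at least 3 samples to differentiate")
  d <- numeric(n)
  d[1] <- (series[2] - series[1]) / dt
  d[n] <- (series[n] - series[n - 1]) / dt
  d[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) / (2 * dt)
  d
}

#' Horizontal displacement between wrist midpoint and L5
#'
#' Norm of the wrist-to-L5 offset after removing its component along the
#' up axis (global +Z by default); always non-negative.
#'
#' @param wrist_mid,l5 length-3 points or n x 3 matrices.
#' @param up_axis unit up vector (default c(0, 0, 1)).
#' @return horizontal distance(s) in metres.
#' @export
horizontal_displacement <- function(wrist_mid, l5, up_axis = c(0, 0, 1)) {
  up <- up_axis / sqrt(sum(up_axis^2))
  w <- to_mat3(wrist_mid); l <- to_mat3(l5)
  v <- w - l
  vh <- v - outer(as.numeric(v %*% up), up)
  h <- sqrt(rowSums(vh^2))
  if (length(h) == 1L) as.numeric(h) else h
}

#' Segment a lifting trial into flexion / lifting / laying phases
#'
#' Two methods are provided because published movement studies report phases
#' both ways:
#' \describe{
#'   \item{event}{The box-carry interval is detected from the summed vertical
#'     hand force: onset is the first sample whose absolute summed vertical
#'     force stays above `threshold` for at least `debounce` seconds; offset
#'     is the last sample of the final sustained above-threshold run. The
#'     boundaries are reported as index fractions (i - 1)/(n - 1).}
#'   \item{fixed}{Published phase fractions: (0.30, 0.60) for symmetric
#'     tasks and (0.33, 0.67) for asymmetric tasks.}
#' }
#' If the event method finds no sustained crossing it falls back to the fixed
#' fractions with a warning.
#'
#' @param trial a `motion_trial` (see [motion_trial()]).
#' @param method "event" or "fixed".
#' @param threshold force threshold in N (default 20).
#' @param debounce minimum sustained duration in seconds (default 0.1).
#' @param up_axis unit up vector for the vertical force component.
#' @return object of class `phase_segmentation`: list with `boundaries`
#'   (two fractions in (0,1)), `samples` (1-based onset/offset indices, event
#'   method only) and `method`.
#' @export
segment_phases <- function(trial, method = c("event", "fixed"),
                           threshold = 20, debounce = 0.1,
                           up_axis = c(0, 0, 1)) {
  method <- match.arg(method)
  n <- length(trial$time)
  fixed_boundaries <- function() {
    if (identical(trial$condition$symmetry, "symmetric")) c(0.30, 0.60) else c(0.33, 0.67)
  }
  if (method == "fixed") {
    b <- fixed_boundaries()
    return(structure(list(boundaries = b, samples = NULL, method = "fixed"),
                     class = "phase_segmentation"))
  }
  up <- up_axis / sqrt(sum(up_axis^2))
  fz <- as.numeric(to_mat3(trial$hand_force$left) %*% up +
                   to_mat3(trial$hand_force$right) %*% up)
  above <- abs(fz) > threshold
  dt <- trial$time[2] - trial$time[1]
  min_run <- max(1L, as.integer(ceiling(debounce / dt)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) {
    warning("no sustained hand-force crossing found; falling back to fixed phase fractions")
    b <- fixed_boundaries()
    return(structure(list(boundaries = b, samples = NULL, method = "fixed"),
                     class = "phase_segmentation"))
  }
  onset <- starts[which(keep)[1]]
  offset <- ends[tail(which(keep), 1)]
  b <- c((onset - 1) / (n - 1), (offset - 1) / (n - 1))
  structure(list(boundaries = b, samples = c(onset = onset, offset = offset),
                 method = "event"),
            class = "phase_segmentation")
}

#' Resample a series onto a uniform normalized-time grid
#'
#' Linear interpolation onto `grid_len` equally spaced points spanning the
#' whole trial; the first and last values are preserved exactly. The default
#' grid length of 101 gives the conventional 0--100\% grid in 1\% steps.
#'
#' @param series numeric vector (length >= 2).
#' @param grid_len number of output points (default 101).
#' @return numeric vector of length `grid_len`.
#' @export
time_normalize <- function(series, grid_len = 101) {
  n <- length(series)
  if (n < 2) stop("need at least 2 samples to time-normalize")
  x <- seq(0, 1, length.out = n)
  out <- approx(x, series, xout = seq(0, 1, length.out = grid_len))$y
  out[1] <- series[1]
  out[grid_len] <- series[n]
  out
}

#' Kinematic variables of a lifting trial on the normalized grid
#'
#' Computes the trunk flexion angle theta (deg), angular velocity omega
#' (deg/s), angular acceleration alpha (deg/s^2) and horizontal wrist-lumbar
#' displacement H (m) from the trial markers. Marker series are low-pass
#' filtered first; derivatives are taken on the raw time base and only then
#' resampled onto the normalized grid.
#'
#' @param trial a `motion_trial`.
#' @param cutoff low-pass cutoff in Hz (default 4).
#' @param grid_len normalized grid length (default 101).
#' @param filter apply the low-pass filter to marker series (default TRUE).
#' @return object of class `kinematic_series`: list with `theta`, `omega`,
#'   `alpha_acc`, `H` (each length `grid_len`), `grid` (0--100), and
#'   `theta_raw`/`omega_raw` on the original time base (used by the torque
#'   model, which needs deg and deg/s at each raw sample).
#' @export
compute_kinematics <- function(trial, cutoff = 4, grid_len = 101, filter = TRUE) {
  fs <- 1 / (trial$time[2] - trial$time[1])
  filt <- function(m) {
    if (!filter) return(m)
    apply(m, 2, lowpass_filter, fc = cutoff, fs = fs)
  }
  c7 <- filt(trial$markers$C7)
  l5 <- filt(trial$markers$L5)
  wl <- filt(trial$markers$wrist_L)
  wr <- filt(trial$markers$wrist_R)
  kl <- filt(trial$markers$knee_L)
  kr <- filt(trial$markers$knee_R)
  cmid <- midpoint_marker(kl, kr)
  dmid <- midpoint_marker(wl, wr)
  theta <- trunk_flexion_angle(c7, l5, cmid)
  dt <- 1 / fs
  omega <- differentiate(theta, dt)
  alpha <- differentiate(omega, dt)
  H <- horizontal_displacement(dmid, l5)
  structure(list(
    theta = time_normalize(theta, grid_len),
    omega = time_normalize(omega, grid_len),
    alpha_acc = time_normalize(alpha, grid_len),
    H = time_normalize(H, grid_len),
    grid = seq(0, 100, length.out = grid_len),
    theta_raw = theta, omega_raw = omega
  ), class = "kinematic_series")
}

# coerce a length-3 vector or n x 3 matrix to matrix form
to_mat3 <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    p
  } else {
    stopifnot(length(p) == 3)
    matrix(p, nrow = 1)
  }
}
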