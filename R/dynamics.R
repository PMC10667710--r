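#' Default anthropometric mass-fraction table
#'
#' Winter-style segment mass fractions of total body mass for the nine
#' modelled upper-body segments (lower limbs are not part of the dynamic
#' chain). The trunk fraction is apportioned over shoulder girdle, thoracic
#' spine, lumbar spine and pelvis. Shipped as an editable data.frame so a
#' different literature table can be substituted.
#'
#' @return data.frame with `segment` and `fraction`.
#' @export
default_segment_table <- function() {
  data.frame(
    segment = SEGMENT_NAMES,
    fraction = c(0.016, 0.016,   # forearms (incl. hand)
                 0.028, 0.028,   # upper arms
                 0.081,          # head + neck
                 0.078,          # shoulder girdle
                 0.172,          # thoracic spine
                 0.105,          # lumbar spine
                 0.142)          # pelvis
  )
}

#' Segment masses for a subject
#'
#' Each segment's mass is its table fraction times total body mass. When the
#' exoskeleton is worn its mass (default 3.8 kg) is carried at the lumbar
#' segment COM.
#'
#' @param mass body mass, kg.
#' @param height body height, m (kept for segment-length based extensions).
#' @param exo_on logical; add the exoskeleton mass at the lumbar COM.
#' @param table anthropometric fraction table (see [default_segment_table()]).
#' @param exo_mass exoskeleton mass, kg.
#' @return object of class `segment_params`: data.frame of segment masses
#'   plus `exo_mass` attribute (0 when `exo_on` is FALSE).
#' @export
build_segments <- function(mass, height, exo_on = FALSE,
                           table = default_segment_table(), exo_mass = 3.8) {
  if (mass <= 0 || height <= 0) stop("mass and height must be > 0")
  miss <- setdiff(SEGMENT_NAMES, table$segment)
  if (length(miss)) stop("configuration error: missing segment entries: ",
                         paste(miss, collapse = ", "))
  tab <- table[match(SEGMENT_NAMES, table$segment), ]
  out <- data.frame(segment = tab$segment, fraction = tab$fraction,
                    mass = tab$fraction * mass)
  attr(out, "exo_mass") <- if (exo_on) exo_mass else 0
  attr(out, "body_mass") <- mass
  attr(out, "height") <- height
  class(out) <- c("segment_params", "data.frame")
  out
}

GRAVITY <- c(0, 0, -9.81)

#' Top-down inverse dynamics: gross moment at L5/S1
#'
#' Newton--Euler recursion over the upper-body point-mass chain, from the
#' hands and head down to the lumbosacral joint. Per sample the gross (load)
#' moment about L5/S1 is
#' \deqn{M(t) = \sum_i (r_i - r_{L5}) \times m_i (g - a_i) +
#'       \sum_h (r_h - r_{L5}) \times F_h}
#' where \eqn{r_i, a_i} are segment COM position and acceleration, \eqn{m_i}
#' segment mass (the exoskeleton mass rides on the lumbar COM), \eqn{r_h} the
#' wrist markers and \eqn{F_h} the measured external forces on the hands.
#' Positive sagittal component = flexion load the back must resist. COM
#' accelerations come from double central differencing of (optionally
#' filtered) COM positions; segment rotational inertia is neglected
#' (point-mass model).
#'
#' @param trial a `motion_trial` (series assumed filtered and time-aligned;
#'   see [compute_kinematics()] / [lowpass_filter()]).
#' @param seg `segment_params` from [build_segments()].
#' @param filter_cutoff if not `NULL`, low-pass filter COM and force series at
#'   this cutoff (Hz) before differencing.
#' @return n x 3 matrix of gross moment (N m) at L5/S1; attribute
#'   `upper_load` holds the n x 3 force (N) transmitted from the upper body
#'   to L5/S1 (gravity + inertial + hand loads, typically pointing down).
#' @export
inverse_dynamics_topdown <- function(trial, seg, filter_cutoff = NULL) {
  n <- length(trial$time)
  dt <- trial$time[2] - trial$time[1]
  fs <- 1 / dt
  filt <- function(m) {
    if (is.null(filter_cutoff)) return(m)
    apply(m, 2, lowpass_filter, fc = filter_cutoff, fs = fs)
  }
  l5 <- filt(trial$markers$L5)
  M <- matrix(0, n, 3)
  Fload <- matrix(0, n, 3)
  masses <- seg$mass
  exo_mass <- attr(seg, "exo_mass")
  for (i in seq_along(SEGMENT_NAMES)) {
    nm <- SEGMENT_NAMES[i]
    m_i <- masses[i] + if (nm == "lumbar") exo_mass else 0
    com <- filt(trial$segments[[nm]]$com)
    acc <- apply(com, 2, function(p) differentiate(differentiate(p, dt), dt))
    f_i <- m_i * sweep(-acc, 2, GRAVITY, "+")   # m (g - a)
    M <- M + cross3(com - l5, f_i)
    Fload <- Fload + f_i
  }
  for (h in c("left", "right")) {
    fh <- trial$hand_force[[h]]
    if (is.null(fh)) {
      warning("missing hand-force channel '", h, "'; treated as zero")
      next
    }
    fh <- filt(fh)
    rh <- filt(trial$markers[[if (h == "left") "wrist_L" else "wrist_R"]])
    M <- M + cross3(rh - l5, fh)
    Fload <- Fload + fh
  }
  attr(M, "upper_load") <- Fload
  M
}

# rowwise cross product of n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Net lumbar moment after assistive-torque subtraction
#'
#' The exoskeleton's assistive torque acts only in the trunk flexion plane
#' (the plane through C7, L5 and the knee midpoint C). Per sample the plane
#' normal is computed from the three points, the assistive torque is read
#' from the thin-plate-spline surface at the current trunk angle and angular
#' velocity, and its magnitude is subtracted from the gross-moment component
#' along the (sign-aligned) plane normal. Components of the gross moment
#' outside the flexion plane are unchanged; no clamping is applied, so an
#' assistive torque exceeding the gross flexion moment yields a negative net
#' component (flagged).
#'
#' @param gross n x 3 gross moment matrix from [inverse_dynamics_topdown()].
#' @param theta,omega trunk flexion angle (deg) and velocity (deg/s) per
#'   sample.
#' @param surface a `tps_surface`, or `NULL` for no assistance.
#' @param c7,l5,c n x 3 marker matrices defining the flexion plane.
#' @param exo_on logical; when FALSE assistive torque is 0 and net = gross.
#' @return list with `net` (n x 3), `assist` (length-n N m, >= 0 as fitted),
#'   `gross`, and `overassisted` (logical per sample).
#' @export
net_lumbar_moment <- function(gross, theta, omega, surface, c7, l5, c,
                              exo_on = TRUE) {
  n <- nrow(gross)
  if (!exo_on || is.null(surface)) {
    return(list(net = gross, assist = rep(0, n), gross = gross,
                overassisted = rep(FALSE, n)))
  }
  # negative speeds (trunk extension) fall outside the characterized range and
  # are clamped to its lower edge by evaluate_tps
  assist <- as.numeric(evaluate_tps(surface, theta, omega))
  nrm <- cross3(c7 - l5, c - l5)
  len <- sqrt(rowSums(nrm^2))
  bad <- len < 1e-9
  if (any(bad)) {
    warning("degenerate flexion plane at ", sum(bad), " sample(s); reusing previous plane")
    for (i in which(bad)) {
      j <- if (i > 1) i - 1 else which(!bad)[1]
      nrm[i, ] <- nrm[j, ]; len[i] <- len[j]
    }
  }
  nrm <- nrm / len
  # orient the plane axis along the gross flexion component so the assistive
  # torque always opposes it
  s <- sign(rowSums(gross * nrm)); s[s == 0] <- 1
  axis <- nrm * s
  net <- gross - axis * assist
  over <- rowSums(gross * axis) < assist
  if (any(over)) message("assistive torque exceeds gross flexion moment at ",
                         sum(over), " sample(s); sign preserved")
  list(net = net, assist = assist, gross = gross, overassisted = over)
}

#' Default six-muscle sagittally symmetric trunk model
#'
#' Literature-style geometry in the lumbar frame (x forward, y left,
#' z cranial; origin at L5/S1): an erector spinae pair (extensors), a rectus
#' abdominis pair (flexors) and an internal/external oblique pair (angled
#' lines of action giving lateral-bend and axial-twist capability). Moment
#' arms (m) and PCSA (m^2) are editable defaults, not a reproduction of any
#' specific cadaveric dataset.
#'
#' @return object of class `muscle_model`: data.frame with `name`, unit
#'   line-of-action columns `ux,uy,uz`, moment-arm point `rx,ry,rz` (m),
#'   `pcsa` (m^2) and `max_stress` (Pa).
#' @export
default_muscle_model <- function() {
  u_obl <- c(0, 0.37, 0.93); u_obl <- u_obl / sqrt(sum(u_obl^2))
  m <- data.frame(
    name = c("erector_spinae_L", "erector_spinae_R",
             "rectus_abdominis_L", "rectus_abdominis_R",
             "oblique_L", "oblique_R"),
    ux = c(0, 0, 0, 0, u_obl[1], u_obl[1]),
    uy = c(0, 0, 0, 0, -u_obl[2], u_obl[2]),
    uz = c(1, 1, 1, 1, u_obl[3], u_obl[3]),
    rx = c(-0.055, -0.055, 0.10, 0.10, 0.04, 0.04),
    ry = c(0.030, -0.030, 0.040, -0.040, 0.110, -0.110),
    rz = c(0, 0, 0, 0, 0, 0),
    pcsa = c(15e-4, 15e-4, 6e-4, 6e-4, 10e-4, 10e-4),
    max_stress = rep(0.46e6, 6)
  )
  class(m) <- c("muscle_model", "data.frame")
  m
}

# per-unit-force moment contribution matrix: 3 x n_muscles, column = r x u
muscle_moment_matrix <- function(muscles) {
  t(cross3(as.matrix(muscles[, c("rx", "ry", "rz")]),
           as.matrix(muscles[, c("ux", "uy", "uz")])))
}

#' Distribute the net lumbar moment over trunk muscles
#'
#' Solves \eqn{\min \sum_i (F_i / PCSA_i)^2} subject to moment equilibrium
#' \eqn{\sum_i (r_i \times \hat u_i) F_i = M_{net}} and \eqn{F_i \ge 0}
#' (optionally also \eqn{F_i \le \sigma_{max} PCSA_i}). The objective is
#' strictly convex, so the solution is unique; it is computed by quadratic
#' programming.
#'
#' @param net_moment net moment: length-3 vector (3D equilibrium), or a
#'   scalar sagittal moment with `mode = "sagittal"`.
#' @param muscles a `muscle_model`.
#' @param mode "3d" (sagittal + lateral + axial equilibrium) or "sagittal"
#'   (flexion-axis component only).
#' @param upper_bounds apply \eqn{F_i \le \sigma_{max} PCSA_i} (default FALSE).
#' @return named numeric vector of muscle forces (N).
#' @export
solve_muscle_forces <- function(net_moment, muscles, mode = c("3d", "sagittal"),
                                upper_bounds = FALSE) {
  mode <- match.arg(mode)
  A_full <- muscle_moment_matrix(muscles)
  if (mode == "sagittal") {
    A <- A_full[2, , drop = FALSE]
    b <- if (length(net_moment) == 3) net_moment[2] else net_moment[1]
  } else {
    if (length(net_moment) != 3) stop("3d mode needs a length-3 net moment")
    A <- A_full
    b <- net_moment
  }
  nm <- nrow(muscles)
  # objective scaled by mean PCSA^2 for conditioning; argmin is unchanged
  p0 <- mean(muscles$pcsa)
  Cmat <- diag(2 * (p0 / muscles$pcsa)^2, nm)
  ub <- if (upper_bounds) muscles$max_stress * muscles$pcsa else NULL
  res <- tryCatch(
    pracma::quadprog(Cmat, rep(0, nm), Aeq = A, beq = b,
                     lb = rep(0, nm), ub = ub),
    error = function(e) {
      # name the axis with the largest unmet demand under nonnegative forces
      ax <- c("lateral (x)", "sagittal (y)", "axial (z)")
      fls <- pmax(as.numeric(t(A) %*% solve(A %*% t(A) + 1e-12 * diag(nrow(A)), b)), 0)
      resid <- abs(b - as.numeric(A %*% fls))
      lab <- if (mode == "sagittal") "sagittal (y)" else ax[which.max(resid)]
      stop("muscle force distribution infeasible (axis: ", lab, "): ",
           conditionMessage(e), call. = FALSE)
    })
  f <- pmax(res$xmin, 0)
  names(f) <- muscles$name
  f
}

# vectorized series solver: unconstrained equality solution where all forces
# are nonnegative, per-sample QP elsewhere
solve_muscle_forces_series <- function(B, muscles, mode = "3d") {
  A <- muscle_moment_matrix(muscles)
  if (mode == "sagittal") A <- A[2, , drop = FALSE]
  Dinv <- diag(muscles$pcsa^2)
  Mmap <- Dinv %*% t(A) %*% solve(A %*% Dinv %*% t(A))
  Fm <- Mmap %*% B                      # n_muscles x T
  bad <- which(apply(Fm, 2, function(f) any(f < -1e-9)))
  for (j in bad) {
    Fm[, j] <- solve_muscle_forces(B[, j], muscles,
                                   mode = if (mode == "sagittal") "sagittal" else "3d")
  }
  pmax(Fm, 0)
}

#' Lumbar compression force
#'
#' The compression load Fc is the component, along the lumbar longitudinal
#' axis, of the muscle forces plus the force transmitted from the upper body:
#' \deqn{F_c = \sum_i F_i (\hat u_i \cdot \hat n) - L \cdot \hat n}
#' with \eqn{\hat n} the (cranial) vertebral axis and \eqn{L} the upper-body
#' load vector (gravity + inertial + hand loads, typically pointing down, so
#' its projection subtracts negatively, i.e. adds compression). All muscle
#' lines of action point cranially, so muscle force always compresses.
#'
#' @param muscle_forces numeric vector of muscle forces (N).
#' @param upper_load length-3 force (N) the upper body transmits to L5/S1.
#' @param lumbar_axis unit cranial vertebral axis.
#' @param muscles the `muscle_model` the forces refer to.
#' @return compression force (N), positive in compression.
#' @export
compression_force <- function(muscle_forces, upper_load, lumbar_axis, muscles) {
  nhat <- lumbar_axis / sqrt(sum(lumbar_axis^2))
  U <- as.matrix(muscles[, c("ux", "uy", "uz")])
  sum(muscle_forces * as.numeric(U %*% nhat)) - sum(upper_load * nhat)
}

#' Convert intradiscal pressure to lumbar load
#'
#' Linear conversion `p * factor`; the correction factor (N per MPa) comes
#' from the calibration literature and is configuration, not a fitted value.
#'
#' @param p intradiscal pressure, MPa.
#' @param factor correction factor, N/MPa (> 0).
#' @return lumbar load, N.
#' @export
pressure_to_force <- function(p, factor) {
  if (factor <= 0) stop("correction factor must be > 0")
  p * factor
}

#' One-way random-effects single-measure intraclass correlation, ICC(1,1)
#'
#' Agreement between paired measurements (e.g., model-estimated vs in vivo
#' lumbar loads over a set of postures) from the one-way ANOVA decomposition
#' with targets as groups and k = 2 measurements per target:
#' \deqn{ICC(1,1) = (MS_B - MS_W) / (MS_B + (k-1) MS_W)}
#' The 95\% confidence interval uses the standard F-based bounds.
#'
#' @param x,y paired numeric vectors (length >= 3).
#' @param conf confidence level (default 0.95).
#' @return list with `r` and `ci95` (length-2). Zero between-target variance
#'   returns r <= 0, not an error.
#' @export
icc_1_1 <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need paired vectors of equal length >= 3")
  k <- 2
  m_i <- (x + y) / 2
  grand <- mean(c(x, y))
  msb <- k * sum((m_i - grand)^2) / (n - 1)
  msw <- sum((x - m_i)^2 + (y - m_i)^2) / (n * (k - 1))
  r <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf
  Fobs <- msb / max(msw, .Machine$double.eps)
  FL <- Fobs / qf(1 - alpha / 2, n - 1, n * (k - 1))
  FU <- Fobs * qf(1 - alpha / 2, n * (k - 1), n - 1)
  ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  list(r = r, ci95 = ci)
}

#' Lumbar frame at a sample
#'
#' Right-handed local frame at L5/S1: z cranial along L5->C7, y the flexion
#' plane normal (via the knee midpoint C), x forward. Rows of the returned
#' matrix are the local axes expressed in world coordinates, so `R %*% v`
#' maps a world vector into the lumbar frame.
#'
#' @param c7,l5,c length-3 world points.
#' @return 3 x 3 rotation matrix.
#' @export
lumbar_frame <- function(c7, l5, c) {
  z <- c7 - l5; z <- z / sqrt(sum(z^2))
  # oriented so a forward-flexion load moment has positive local y
  nrm <- pracma::cross(c7 - l5, c - l5)
  if (sqrt(sum(nrm^2)) < 1e-9) stop("degenerate geometry: collinear C7, L5, C")
  y <- nrm / sqrt(sum(nrm^2))
  x <- pracma::cross(y, z)
  rbind(x, y, z)
}

#' Lumbar load series for one trial
#'
#' Full per-trial dynamics: gross moment by top-down inverse dynamics,
#' assistive-torque subtraction in the flexion plane (exo-on trials with a
#' fitted surface), muscle-force distribution by QP in the lumbar frame, and
#' compression force along the vertebral axis — all on the raw time base,
#' then resampled onto the normalized grid.
#'
#' @param trial a `motion_trial`.
#' @param surface a `tps_surface` or `NULL`.
#' @param kin optional precomputed [compute_kinematics()] result.
#' @param muscles muscle model (default [default_muscle_model()]).
#' @param cutoff low-pass cutoff (Hz) for dynamics inputs.
#' @param grid_len normalized grid length.
#' @param exo_mass exoskeleton mass (kg) added at the lumbar COM when worn.
#' @param mode equilibrium dimensionality for the QP ("3d" or "sagittal").
#' @return list with `Fc` (length `grid_len`), `gross`, `assist`, `net`
#'   (sagittal-plane magnitudes on the grid) and the raw-sample series.
#' @export
lumbar_load_series <- function(trial, surface = NULL, kin = NULL,
                               muscles = default_muscle_model(), cutoff = 4,
                               grid_len = 101, exo_mass = 3.8, mode = "3d") {
  exo_on <- identical(trial$condition$exo, "on")
  seg <- build_segments(trial$subject$mass, trial$subject$height,
                        exo_on = exo_on, exo_mass = exo_mass)
  if (is.null(kin)) kin <- compute_kinematics(trial, cutoff = cutoff, grid_len = grid_len)
  gross <- inverse_dynamics_topdown(trial, seg, filter_cutoff = cutoff)
  upper_load <- attr(gross, "upper_load")
  fs <- 1 / (trial$time[2] - trial$time[1])
  c7 <- apply(trial$markers$C7, 2, lowpass_filter, fc = cutoff, fs = fs)
  l5 <- apply(trial$markers$L5, 2, lowpass_filter, fc = cutoff, fs = fs)
  cm <- midpoint_marker(
    apply(trial$markers$knee_L, 2, lowpass_filter, fc = cutoff, fs = fs),
    apply(trial$markers$knee_R, 2, lowpass_filter, fc = cutoff, fs = fs))
  nlm <- net_lumbar_moment(gross, kin$theta_raw, kin$omega_raw, surface,
                           c7, l5, cm, exo_on = exo_on)
  n <- nrow(gross)
  Fc <- numeric(n)
  netloc_mat <- matrix(0, 3, n)
  loadloc_mat <- matrix(0, 3, n)
  Rlist <- vector("list", n)
  for (i in seq_len(n)) {
    R <- lumbar_frame(c7[i, ], l5[i, ], cm[i, ])
    Rlist[[i]] <- R
    netloc_mat[, i] <- R %*% nlm$net[i, ]
    loadloc_mat[, i] <- R %*% upper_load[i, ]
  }
  Fm <- solve_muscle_forces_series(netloc_mat, muscles, mode = mode)
  for (i in seq_len(n)) {
    Fc[i] <- compression_force(Fm[, i], loadloc_mat[, i], c(0, 0, 1), muscles)
  }
  list(Fc = time_normalize(Fc, grid_len),
       gross = time_normalize(gross[, 2], grid_len),
       assist = time_normalize(nlm$assist, grid_len),
       net = time_normalize(nlm$net[, 2], grid_len),
       Fc_raw = Fc, gross_raw = gross, assist_raw = nlm$assist,
       muscle_forces = Fm)
}
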