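#' Specification of a synthetic lifting cohort
#'
#' Encodes the study conditions a generated cohort emulates: 10 subjects
#' (mass 68.1 +/- 8.8 kg, height 1.72 +/- 0.08 m) each performing 5 trials of
#' every symmetric/asymmetric x exoskeleton on/off condition, lifting a 10 kg
#' box (98.1 N) with a 90-degree box-table angle in the asymmetric layout.
#' Exoskeleton effect sizes are the injected ground-truth reductions the
#' pipeline should recover: peak flexion angle (deg), peak angular velocity
#' (deg/s), and wrist-lumbar reach (m). Noise defaults are instrument-grade:
#' 5 mm marker, 1 N force, 2 N m bench torque.
#'
#' @param n_subjects number of subjects (>= 2), default 10.
#' @param trials_per_condition default 5.
#' @param mass,height c(mean, sd) of subject anthropometry.
#' @param phase_durations seconds for flexion / lifting / laying.
#' @param peak_flexion c(mean, sd) of the peak trunk flexion angle, deg.
#' @param exo_effects list: `dtheta` (deg), `domega` (deg/s), `dH` (m)
#'   reductions when the exoskeleton is worn.
#' @param timing_jitter SD of multiplicative phase-duration jitter (fraction).
#' @param noise list: `marker` (m), `force` (N), `torque` (N m) SDs.
#' @param box_mass box mass, kg (default 10).
#' @param exo_mass exoskeleton mass, kg (default 3.8).
#' @param fs sampling rate, Hz (default 60).
#' @param gamma_deg asymmetric box-table angle, deg (default 90).
#' @param seed master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, trials_per_condition = 5,
                        mass = c(68.1, 8.8), height = c(1.72, 0.08),
                        phase_durations = c(1.4, 1.4, 1.4),
                        peak_flexion = c(85, 5),
                        exo_effects = list(dtheta = 5.5, domega = 20, dH = 0.02),
                        timing_jitter = 0.05,
                        noise = list(marker = 0.005, force = 1, torque = 2),
                        box_mass = 10, exo_mass = 3.8, fs = 60,
                        gamma_deg = 90, seed = 1L) {
  stopifnot(n_subjects >= 2, all(phase_durations > 0),
            mass[2] >= 0, height[2] >= 0, timing_jitter >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# deterministic per-(subject, condition, trial) substream below 2^31
substream_seed <- function(seed, subject, sym, exo, trial, salt = 0L) {
  s <- (as.integer(seed) %% 100003L) * 7919L +
    subject * 1009L + (if (sym == "asymmetric") 101L else 0L) +
    (if (exo == "on") 211L else 0L) + trial * 13L + salt
  s %% 2147483629L
}

# minimum-jerk position profile from x0 to x1 over [0, 1]
minjerk <- function(tau, x0, x1) {
  tau <- pmin(pmax(tau, 0), 1)
  x0 + (x1 - x0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

quat_about <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  c(cos(angle_rad / 2), sin(angle_rad / 2) * a)
}

#' Generate one synthetic lifting trial
#'
#' The trunk flexion angle follows minimum-jerk segments through the three
#' phases (stand -> peak flexion; peak -> carry angle while the box load is on
#' the hands; carry -> laying angle). Marker and segment-COM positions are
#' kinematically consistent with the flexion angle over a two-link trunk-arm
#' geometry; the asymmetric condition adds a trunk azimuth ramp toward the
#' 90-degree box position. Hand forces equal the box weight during the carry
#' interval with smooth cosine on/off ramps. The exoskeleton-on condition
#' applies the cohort's configured kinematic reductions (smaller peak flexion, slower
#' movement scaled to the requested peak-velocity reduction, shorter reach).
#' Subject anthropometry is drawn from a subject-only substream so it is
#' identical across that subject's trials and conditions; all randomness is a
#' pure function of (spec, subject, condition, trial index).
#'
#' @param spec a `cohort_spec`.
#' @param subject subject index (1-based).
#' @param condition list with `symmetry` and `exo`.
#' @param trial_idx trial index 1..trials_per_condition.
#' @return a validated `motion_trial`.
#' @export
generate_trial <- function(spec, subject, condition, trial_idx = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  # subject-level draws (identical across conditions/trials)
  set.seed(substream_seed(spec$seed, subject, "symmetric", "off", 0L, salt = 1L))
  mass <- max(40, rnorm(1, spec$mass[1], spec$mass[2]))
  height <- max(1.4, rnorm(1, spec$height[1], spec$height[2]))
  theta_peak_subj <- rnorm(1, spec$peak_flexion[1], spec$peak_flexion[2])

  # trial-level timing stream: shared between exo on/off so that zero effect
  # sizes and zero noise give identical paired trials
  set.seed(substream_seed(spec$seed, subject, condition$symmetry,
                          "off", trial_idx, salt = 2L))
  exo_on <- identical(condition$exo, "on")
  dtheta <- if (exo_on) spec$exo_effects$dtheta else 0
  domega <- if (exo_on) spec$exo_effects$domega else 0
  dH <- if (exo_on) spec$exo_effects$dH else 0

  theta_peak <- max(20, theta_peak_subj - dtheta)
  durs <- spec$phase_durations *
    (1 + if (spec$timing_jitter > 0) rnorm(3, 0, spec$timing_jitter) else rep(0, 3))
  durs <- pmax(durs, 0.4)
  # min-jerk peak velocity over amplitude A and duration d is 1.875 A / d;
  # scale durations so the peak flexion velocity drops by `domega`
  w_off <- 1.875 * theta_peak_subj / durs[1]
  w_on <- max(w_off - domega, w_off * 0.3)
  scale_t <- if (exo_on) (1.875 * theta_peak / durs[1]) / w_on else 1
  durs <- durs * scale_t

  fs <- spec$fs
  n <- round(sum(durs) * fs) + 1
  time <- seq(0, by = 1 / fs, length.out = n)
  tt <- time
  b1 <- durs[1]; b2 <- durs[1] + durs[2]; Tend <- sum(durs)

  theta_carry <- 15
  theta_lay <- 45
  theta <- ifelse(tt <= b1, minjerk(tt / durs[1], 0, theta_peak),
           ifelse(tt <= b2, minjerk((tt - b1) / durs[2], theta_peak, theta_carry),
                  minjerk((tt - b2) / durs[3], theta_carry, theta_lay)))
  # azimuth toward the box (asymmetric layout only)
  gamma <- if (condition$symmetry == "asymmetric") spec$gamma_deg else 0
  psi <- ifelse(tt <= b1, 0,
         ifelse(tt <= b2, minjerk((tt - b1) / durs[2], 0, gamma),
                gamma))
  th <- theta * pi / 180
  ps <- psi * pi / 180

  # L5 stays above the knee midpoint so the marker-derived flexion angle
  # reproduces the constructed profile exactly
  h_l5 <- 0.58 * height
  Lt <- 0.30 * height
  l5 <- cbind(rep(0.05, n), rep(0, n), h_l5 - 0.08 * (1 - cos(th)))
  trunk_dir <- cbind(sin(th) * cos(ps), sin(th) * sin(ps), cos(th))
  c7 <- l5 + Lt * trunk_dir

  knee_h <- 0.28 * height
  knee_L <- cbind(rep(0.05, n), rep(0.12, n), rep(knee_h, n))
  knee_R <- cbind(rep(0.05, n), rep(-0.12, n), rep(knee_h, n))

  # wrist midpoint: reach out and down during flexion, box carried in phase 2,
  # laid toward the table in phase 3
  reach0 <- 0.18
  reach1 <- max(0.46 - dH, 0.2)
  reach <- ifelse(tt <= b1, minjerk(tt / durs[1], reach0, reach1),
           ifelse(tt <= b2, minjerk((tt - b1) / durs[2], reach1, reach1 - 0.05),
                  minjerk((tt - b2) / durs[3], reach1 - 0.05, reach1 - 0.02)))
  z_box <- 0.10; z_carry <- 0.95; z_table <- 0.65
  wz <- ifelse(tt <= b1, minjerk(tt / durs[1], 0.75 * h_l5, z_box),
        ifelse(tt <= b2, minjerk((tt - b1) / durs[2], z_box, z_carry),
               minjerk((tt - b2) / durs[3], z_carry, z_table)))
  wmid <- cbind(reach * cos(ps), reach * sin(ps), wz)
  lat <- cbind(-sin(ps), cos(ps), 0) * 0.15
  wrist_L <- wmid + lat
  wrist_R <- wmid - lat

  shoulder <- c7
  seg_pos <- list(
    pelvis = sweep(l5, 2, c(0, 0, -0.05), "+"),
    lumbar = l5 + 0.18 * Lt * trunk_dir,
    thoracic = l5 + 0.50 * Lt * trunk_dir,
    shoulder = l5 + 0.85 * Lt * trunk_dir,
    head = l5 + 1.15 * Lt * trunk_dir,
    upperarm_L = 0.6 * (shoulder + lat) + 0.4 * wrist_L,
    upperarm_R = 0.6 * (shoulder - lat) + 0.4 * wrist_R,
    forearm_L = 0.25 * (shoulder + lat) + 0.75 * wrist_L,
    forearm_R = 0.25 * (shoulder - lat) + 0.75 * wrist_R
  )
  quats <- t(vapply(seq_len(n), function(i) {
    qz <- quat_about(c(0, 0, 1), ps[i])
    qy <- quat_about(c(0, 1, 0), th[i])
    quat_mult(qz, qy)
  }, numeric(4)))

  # box weight on the hands during the lifting (carry) phase, cosine ramps
  w_box <- spec$box_mass * 9.81
  ramp <- 0.15
  env <- ramp_env(tt, b1, b2, ramp)
  share <- if (condition$symmetry == "asymmetric") c(0.55, 0.45) else c(0.5, 0.5)
  fz <- -w_box * env
  hand_L <- cbind(0 * fz, 0 * fz, fz * share[1])
  hand_R <- cbind(0 * fz, 0 * fz, fz * share[2])

  # measurement-noise stream: independent between exo on/off recordings
  set.seed(substream_seed(spec$seed, subject, condition$symmetry,
                          condition$exo, trial_idx, salt = 3L))
  sdm <- spec$noise$marker
  sdf <- spec$noise$force
  addn <- function(m, sd) if (sd > 0) m + matrix(rnorm(length(m), 0, sd), nrow(m)) else m
  markers <- list(C7 = addn(c7, sdm), L5 = addn(l5, sdm),
                  wrist_L = addn(wrist_L, sdm), wrist_R = addn(wrist_R, sdm),
                  knee_L = addn(knee_L, sdm), knee_R = addn(knee_R, sdm))
  segments <- lapply(SEGMENT_NAMES, function(s)
    list(com = addn(seg_pos[[s]], sdm), quat = quats))
  names(segments) <- SEGMENT_NAMES
  hand_force <- list(left = addn(hand_L, sdf), right = addn(hand_R, sdf))

  motion_trial(time, markers, segments, hand_force,
               subject = list(mass = mass, height = height,
                              id = sprintf("S%02d", subject)),
               condition = list(symmetry = condition$symmetry,
                                exo = condition$exo,
                                gamma_deg = spec$gamma_deg),
               trial_index = as.integer(trial_idx))
}

# smooth 0/1 envelope: cosine ramp up at b1, down ending at b2
ramp_env <- function(t, b1, b2, ramp) {
  up <- pmin(pmax((t - b1) / ramp, 0), 1)
  dn <- pmin(pmax((b2 - t) / ramp, 0), 1)
  (0.5 - 0.5 * cos(pi * up)) * (0.5 - 0.5 * cos(pi * dn))
}

quat_mult <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + pracma::cross(a[2:4], b[2:4]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default bench torque surface used by the generator
#'
#' Saturating rise with angle times a mild linear speed penalty (higher
#' extension speed costs friction torque in a pneumatic artificial muscle):
#' `T(angle, speed) = t_max (1 - exp(-angle / angle_scale)) - speed_slope * speed`.
#'
#' @param angle,speed query points (deg, deg/s).
#' @param params list with `t_max` (N m), `angle_scale` (deg), `speed_slope`
#'   (N m per deg/s).
#' @return torque, N m.
#' @export
bench_true_torque <- function(angle, speed,
                              params = list(t_max = 60, angle_scale = 30,
                                            speed_slope = 0.05)) {
  params$t_max * (1 - exp(-angle / params$angle_scale)) - params$speed_slope * speed
}

#' Generate synthetic bench characterization sweeps
#'
#' Emulates the bench protocol: the exoskeleton is rotated 0 -> 90 degrees at
#' each sweep speed, `n_repeats` times per speed, torque sampled at `fs` Hz
#' from a smooth surface plus iid Gaussian noise.
#'
#' @param params true-surface parameters (see [bench_true_torque()]).
#' @param speeds sweep speeds, deg/s (default the five-speed protocol).
#' @param n_repeats repeats per speed (default 10).
#' @param noise_sd torque noise SD, N m (default 2).
#' @param fs sampling rate, Hz (default 1000; lower for quick tests).
#' @param seed RNG seed.
#' @return data.frame `speed_dps, repeat, angle_deg, torque_Nm` with
#'   attribute `fs`; format matches [read_bench_csv()].
#' @export
generate_bench <- function(params = list(t_max = 60, angle_scale = 30,
                                         speed_slope = 0.05),
                           speeds = c(10, 30, 45, 60, 90), n_repeats = 10,
                           noise_sd = 2, fs = 1000, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed) %% 2147483629L)
  out <- list()
  for (s in speeds) {
    nsamp <- max(20, round(90 / s * fs))
    ang <- seq(0, 90, length.out = nsamp)
    for (r in seq_len(n_repeats)) {
      tq <- bench_true_torque(ang, s, params) +
        if (noise_sd > 0) rnorm(nsamp, 0, noise_sd) else 0
      out[[length(out) + 1]] <- data.frame(speed_dps = s, rep = r,
                                           angle_deg = ang, torque_Nm = tq)
    }
  }
  df <- do.call(rbind, out)
  names(df)[names(df) == "rep"] <- "repeat"
  attr(df, "fs") <- fs
  df
}

#' Flat-top bump effect function
#'
#' Full amplitude over `[from, to]` with short cosine shoulders decaying to
#' zero just outside the interval, so every grid point inside the stated
#' support carries the whole effect (the support of the recovered
#' significance is then directly comparable to `[from, to]`).
#'
#' @param amplitude effect height.
#' @param from,to support bounds on the normalized-time axis.
#' @param ramp shoulder width outside the support (default 3).
#' @return function of t.
#' @export
bump_effect <- function(amplitude, from = 30, to = 60, ramp = 3) {
  force(amplitude); force(from); force(to); force(ramp)
  function(t) {
    up <- pmin(pmax((t - (from - ramp)) / ramp, 0), 1)
    dn <- pmin(pmax(((to + ramp) - t) / ramp, 0), 1)
    amplitude * (0.5 - 0.5 * cos(pi * up)) * (0.5 - 0.5 * cos(pi * dn))
  }
}

#' Generate a two-group curve set with known ground truth
#'
#' Each curve is `base mean + per-curve random offset + smooth Gaussian
#' noise`; the first group additionally receives the effect function. The
#' smooth noise is a stationary squared-exponential Gaussian process, so the
#' pointwise noise SD is constant: `sqrt(offset_sd^2 + gp_sd^2)` (returned as
#' attribute `pointwise_sd`). Offsets are drawn independently for every curve
#' (the two groups are unpaired), which makes the curve values at any fixed
#' time point iid normal under a null effect.
#'
#' @param n_per_group curves per group (>= 2), default 10.
#' @param effect effect function of t added to group 1, or NULL for none.
#' @param noise list: `offset_sd`, `gp_sd`, `gp_scale` (correlation length in
#'   grid units).
#' @param grid evaluation grid (default 0..100, 101 points).
#' @param base base mean function of t (default a unimodal lifting-like
#'   curve).
#' @param seed RNG seed.
#' @return list with `Y` (2n x grid matrix), `groups` (factor, levels
#'   `effect`/`control`, group 1 first), `grid`, `alpha1_true` (ground-truth
#'   group-1 effect function values = effect/2) and attribute `pointwise_sd`.
#' @export
generate_curveset <- function(n_per_group = 10, effect = NULL,
                              noise = list(offset_sd = 3, gp_sd = 2, gp_scale = 10),
                              grid = seq(0, 100, length.out = 101),
                              base = function(t) 40 * exp(-(t - 45)^2 / (2 * 18^2)),
                              seed = 1L) {
  if (n_per_group < 2) stop("need at least 2 curves per group")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed) %% 2147483629L)
  ng <- length(grid)
  n <- 2 * n_per_group
  Kmat <- noise$gp_sd^2 * exp(-outer(grid, grid, "-")^2 / (2 * noise$gp_scale^2))
  L <- chol(Kmat + diag(1e-8, ng))
  gp <- matrix(rnorm(n * ng), n, ng) %*% L
  offsets <- rnorm(n, 0, noise$offset_sd)
  mu <- base(grid)
  eff <- if (is.null(effect)) rep(0, ng) else effect(grid)
  Y <- sweep(gp, 2, mu, "+") + offsets
  Y[seq_len(n_per_group), ] <- sweep(Y[seq_len(n_per_group), , drop = FALSE], 2, eff, "+")
  groups <- factor(rep(c("effect", "control"), each = n_per_group),
                   levels = c("effect", "control"))
  out <- list(Y = Y, groups = groups, grid = grid, alpha1_true = eff / 2)
  attr(out, "pointwise_sd") <- sqrt(noise$offset_sd^2 + noise$gp_sd^2)
  out
}
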