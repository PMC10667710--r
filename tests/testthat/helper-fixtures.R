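# fixtures built in code; nothing is read from disk

# static toy trial: all nine segment COMs at one point, wrists at another,
# everything constant in time; used for closed-form inverse-dynamics checks
static_trial <- function(com = c(0.3, 0, 0.5), wrist = c(0.45, 0, 0.8),
                         hand_fz = -98.1, n = 50, fs = 60,
                         mass = 40, height = 1.7) {
  time <- seq(0, by = 1 / fs, length.out = n)
  const <- function(p) matrix(rep(p, each = n), ncol = 3)
  markers <- list(C7 = const(c(0.1, 0, 0.5)), L5 = const(c(0, 0, 0)),
                  wrist_L = const(wrist), wrist_R = const(wrist),
                  knee_L = const(c(0, 0.1, -0.4)), knee_R = const(c(0, -0.1, -0.4)))
  segments <- lapply(exofanova:::SEGMENT_NAMES, function(s)
    list(com = const(com), quat = NULL))
  names(segments) <- exofanova:::SEGMENT_NAMES
  hand_force <- list(left = const(c(0, 0, hand_fz / 2)),
                     right = const(c(0, 0, hand_fz / 2)))
  motion_trial(time, markers, segments, hand_force,
               subject = list(mass = mass, height = height, id = "toy"),
               condition = list(symmetry = "symmetric", exo = "off"),
               trial_index = 1L)
}

# anthropometric table whose fractions sum to 1 (all body mass in the chain)
unit_fraction_table <- function() {
  tab <- default_segment_table()
  tab$fraction <- tab$fraction / sum(tab$fraction)
  tab
}

# n-muscle sagittal model from moment arms (m) and PCSAs (m^2): muscle i acts
# along +z at lever point (-arm_i, 0, 0), so its sagittal moment per newton
# is +arm_i
sagittal_muscles <- function(arms, pcsas) {
  m <- data.frame(name = paste0("m", seq_along(arms)),
                  ux = 0, uy = 0, uz = 1,
                  rx = -arms, ry = 0, rz = 0,
                  pcsa = pcsas, max_stress = 0.46e6)
  class(m) <- c("muscle_model", "data.frame")
  m
}

# brute-force grid minimizer of sum (F_i/PCSA_i)^2 s.t. sum(arm_i F_i) = b,
# F >= 0, on a 1 N grid; the last force is eliminated through the constraint
grid_qp_oracle <- function(arms, pcsas, b, fmax = 1500, step = 1) {
  k <- length(arms)
  stopifnot(k %in% c(2, 3))
  obj_best <- Inf; f_best <- NULL
  f1s <- seq(0, fmax, by = step)
  if (k == 2) {
    f2 <- (b - arms[1] * f1s) / arms[2]
    ok <- f2 >= 0 & f2 <= fmax * 2
    obj <- (f1s / pcsas[1])^2 + (f2 / pcsas[2])^2
    obj[!ok] <- Inf
    j <- which.min(obj)
    return(list(forces = c(f1s[j], f2[j]), objective = obj[j]))
  }
  for (f1 in f1s) {
    f2 <- f1s
    f3 <- (b - arms[1] * f1 - arms[2] * f2) / arms[3]
    ok <- f3 >= 0 & f3 <= fmax * 2
    if (!any(ok)) next
    obj <- (f1 / pcsas[1])^2 + (f2 / pcsas[2])^2 + (f3 / pcsas[3])^2
    obj[!ok] <- Inf
    j <- which.min(obj)
    if (obj[j] < obj_best) {
      obj_best <- obj[j]; f_best <- c(f1, f2[j], f3[j])
    }
  }
  list(forces = f_best, objective = obj_best)
}

stress_sq_objective <- function(forces, pcsas) sum((forces / pcsas)^2)

# quick cohort spec for tests
tiny_spec <- function(...) {
  cohort_spec(n_subjects = 2, trials_per_condition = 1, seed = 42L, ...)
}
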