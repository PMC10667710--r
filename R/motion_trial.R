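SEGMENT_NAMES <- c("forearm_L", "forearm_R", "upperarm_L", "upperarm_R",
                   "head", "shoulder", "thoracic", "lumbar", "pelvis")
MARKER_NAMES <- c("C7", "L5", "wrist_L", "wrist_R", "knee_L", "knee_R")

#' Construct and validate a motion trial
#'
#' A `motion_trial` holds one lifting trial: uniformly sampled time (nominal
#' 60 Hz), six joint-centre / virtual-marker 3D trajectories (C7, L5, left and
#' right wrist, left and right knee), nine upper-body segments (forearms,
#' upper arms, head, shoulder, thoracic spine, lumbar spine, pelvis) each with
#' a COM trajectory and orientation quaternion series, per-hand external force
#' series, subject anthropometry, and condition labels.
#'
#' @param time numeric vector of sample times (s), strictly increasing and
#'   uniform.
#' @param markers named list of n x 3 matrices, names
#'   `r paste(MARKER_NAMES, collapse = ", ")`.
#' @param segments named list (names `r paste(SEGMENT_NAMES, collapse = ", ")`)
#'   of lists with `com` (n x 3) and `quat` (n x 4, w-first).
#' @param hand_force list with `left` and `right` n x 3 force matrices (N),
#'   forces applied to the hands.
#' @param subject list with `mass` (kg), `height` (m), `id`.
#' @param condition list with `symmetry` ("symmetric"/"asymmetric") and
#'   `exo` ("on"/"off"); the box-table setup angle gamma (90 deg for the
#'   asymmetric layout) may be carried as `condition$gamma_deg`.
#' @param trial_index integer 1-5.
#' @return object of class `motion_trial`.
#' @export
motion_trial <- function(time, markers, segments, hand_force, subject,
                         condition, trial_index = 1L) {
  x <- structure(list(time = time, markers = markers, segments = segments,
                      hand_force = hand_force, subject = subject,
                      condition = condition, trial_index = trial_index),
                 class = "motion_trial")
  validate_motion_trial(x)
  x
}

#' Validate a motion trial's invariants
#'
#' Checks: strictly increasing, uniform time base (within 1e-9 s); all series
#' share the time length; positive mass and height; required marker and
#' segment entries present. The same validator runs on files read from disk
#' and on synthetic trials.
#'
#' @param x a `motion_trial`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_motion_trial <- function(x) {
  n <- length(x$time)
  if (n < 2) stop("motion_trial: need at least 2 samples")
  dt <- diff(x$time)
  if (any(dt <= 0)) stop("motion_trial: time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9) stop("motion_trial: time must be uniformly sampled (within 1e-9 s)")
  miss <- setdiff(MARKER_NAMES, names(x$markers))
  if (length(miss)) stop("motion_trial: missing markers: ", paste(miss, collapse = ", "))
  for (m in MARKER_NAMES) {
    if (!is.matrix(x$markers[[m]]) || nrow(x$markers[[m]]) != n || ncol(x$markers[[m]]) != 3)
      stop("motion_trial: marker ", m, " must be an n x 3 matrix matching time length")
  }
  miss <- setdiff(SEGMENT_NAMES, names(x$segments))
  if (length(miss)) stop("motion_trial: missing segments: ", paste(miss, collapse = ", "))
  for (s in SEGMENT_NAMES) {
    seg <- x$segments[[s]]
    if (!is.matrix(seg$com) || nrow(seg$com) != n || ncol(seg$com) != 3)
      stop("motion_trial: segment ", s, " COM must be an n x 3 matrix")
    if (!is.null(seg$quat) && (nrow(seg$quat) != n || ncol(seg$quat) != 4))
      stop("motion_trial: segment ", s, " quaternion series must be n x 4")
  }
  for (h in c("left", "right")) {
    f <- x$hand_force[[h]]
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop("motion_trial: hand_force$", h, " must be an n x 3 matrix")
  }
  if (!is.numeric(x$subject$mass) || x$subject$mass <= 0) stop("motion_trial: subject mass must be > 0")
  if (!is.numeric(x$subject$height) || x$subject$height <= 0) stop("motion_trial: subject height must be > 0")
  if (!x$condition$symmetry %in% c("symmetric", "asymmetric"))
    stop("motion_trial: condition$symmetry must be 'symmetric' or 'asymmetric'")
  if (!x$condition$exo %in% c("on", "off"))
    stop("motion_trial: condition$exo must be 'on' or 'off'")
  invisible(x)
}

#' @export
print.motion_trial <- function(x, ...) {
  cat(sprintf("<motion_trial> %d samples @ %.1f Hz | subject %s (%.1f kg, %.2f m) | %s, exo %s, trial %d\n",
              length(x$time), 1 / (x$time[2] - x$time[1]),
              as.character(x$subject$id), x$subject$mass, x$subject$height,
              x$condition$symmetry, x$condition$exo, x$trial_index))
  invisible(x)
}

#' Write a motion trial to CSV with a JSON metadata sidecar
#'
#' One row per sample with columns `time`, `<marker>_{x,y,z}`,
#' `<segment>_{comx,comy,comz,qw,qx,qy,qz}`, `handL_{fx,fy,fz}`,
#' `handR_{fx,fy,fz}`. Subject and condition metadata go to `<path>.json`.
#'
#' @param trial a `motion_trial`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  df <- data.frame(time = trial$time)
  for (m in MARKER_NAMES) {
    mm <- trial$markers[[m]]
    df[[paste0(m, "_x")]] <- mm[, 1]; df[[paste0(m, "_y")]] <- mm[, 2]; df[[paste0(m, "_z")]] <- mm[, 3]
  }
  for (s in SEGMENT_NAMES) {
    seg <- trial$segments[[s]]
    df[[paste0(s, "_comx")]] <- seg$com[, 1]; df[[paste0(s, "_comy")]] <- seg$com[, 2]; df[[paste0(s, "_comz")]] <- seg$com[, 3]
    q <- if (is.null(seg$quat)) matrix(rep(c(1, 0, 0, 0), each = length(trial$time)), ncol = 4) else seg$quat
    df[[paste0(s, "_qw")]] <- q[, 1]; df[[paste0(s, "_qx")]] <- q[, 2]; df[[paste0(s, "_qy")]] <- q[, 3]; df[[paste0(s, "_qz")]] <- q[, 4]
  }
  df$handL_fx <- trial$hand_force$left[, 1]; df$handL_fy <- trial$hand_force$left[, 2]; df$handL_fz <- trial$hand_force$left[, 3]
  df$handR_fx <- trial$hand_force$right[, 1]; df$handR_fy <- trial$hand_force$right[, 2]; df$handR_fz <- trial$hand_force$right[, 3]
  write.csv(df, path, row.names = FALSE)
  meta <- list(subject = trial$subject, condition = trial$condition,
               trial_index = trial$trial_index)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a motion trial written by [write_trial_csv()]
#'
#' @param path CSV path; `<path>.json` must hold the metadata sidecar.
#' @return a validated `motion_trial`.
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  markers <- lapply(MARKER_NAMES, function(m)
    as.matrix(df[, paste0(m, c("_x", "_y", "_z"))]))
  names(markers) <- MARKER_NAMES
  segments <- lapply(SEGMENT_NAMES, function(s) {
    list(com = unname(as.matrix(df[, paste0(s, c("_comx", "_comy", "_comz"))])),
         quat = unname(as.matrix(df[, paste0(s, c("_qw", "_qx", "_qy", "_qz"))])))
  })
  names(segments) <- SEGMENT_NAMES
  markers <- lapply(markers, unname)
  hand_force <- list(left = unname(as.matrix(df[, c("handL_fx", "handL_fy", "handL_fz")])),
                     right = unname(as.matrix(df[, c("handR_fx", "handR_fy", "handR_fz")])))
  motion_trial(df$time, markers, segments, hand_force,
               subject = as.list(meta$subject), condition = as.list(meta$condition),
               trial_index = meta$trial_index)
}
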