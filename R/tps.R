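#' Thin-plate spline model of exoskeleton assistive torque
#'
#' Fits the classic thin-plate spline (kernel r^2 log r, affine part
#' 1 + angle + speed) to bench characterization records of assistive torque
#' measured over trunk-angle sweeps at several angular speeds. Angle and
#' speed are each scaled to \[0, 1\] before kernel evaluation because the two
#' axes carry incommensurate units; the scaling constants are stored with the
#' surface. With `regularization = 0` the surface interpolates the data
#' exactly; positive values add a ridge term on the kernel block and trade
#' fidelity for smoothness.
#'
#' @param data data.frame with columns `angle` (deg), `speed` (deg/s),
#'   `torque` (N m) — see [read_bench_csv()] / [average_characterization()].
#' @param regularization smoothing scalar lambda >= 0, or `"auto"` to select
#'   by leave-one-speed-out cross-validation via [select_tps_reg()].
#' @return object of class `tps_surface`: centers (scaled), kernel weights,
#'   affine coefficients (constant, angle, speed on the scaled axes),
#'   regularization, and per-axis scaling constants.
#' @export
fit_tps <- function(data, regularization = 0) {
  stopifnot(all(c("angle", "speed", "torque") %in% names(data)))
  if (identical(regularization, "auto")) {
    regularization <- select_tps_reg(data)
  }
  if (regularization < 0) stop("regularization must be >= 0")
  sites <- unique_sites(data)
  ang <- sites$angle; spd <- sites$speed; y <- sites$torque
  n <- length(y)
  if (n < 3) stop("need at least 3 distinct (angle, speed) sites")
  sc <- list(angle_min = min(ang), angle_range = max(max(ang) - min(ang), 1e-12),
             speed_min = min(spd), speed_range = max(max(spd) - min(spd), 1e-12))
  x1 <- (ang - sc$angle_min) / sc$angle_range
  x2 <- (spd - sc$speed_min) / sc$speed_range
  P <- cbind(1, x1, x2)
  qrP <- qr(P)
  if (qrP$rank < 3) {
    ax <- if (stats::sd(x1) < 1e-12) "angle" else if (stats::sd(x2) < 1e-12) "speed" else "angle-speed line"
    stop("rank deficiency: characterization sites are collinear along the ", ax, " axis")
  }
  K <- tps_kernel_matrix(cbind(x1, x2), cbind(x1, x2))
  A <- rbind(cbind(K + diag(regularization, n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(y, rep(0, 3))
  sol <- solve(A, rhs)
  structure(list(centers = cbind(angle = x1, speed = x2),
                 weights = sol[1:n],
                 affine = sol[(n + 1):(n + 3)],
                 regularization = regularization,
                 scaling = sc,
                 hull = grDevices::chull(x1, x2)),
            class = "tps_surface")
}

# average duplicated (angle, speed) sites so the kernel matrix is nonsingular
unique_sites <- function(data) {
  key <- paste(signif(data$angle, 12), signif(data$speed, 12))
  if (!anyDuplicated(key)) return(data[, c("angle", "speed", "torque")])
  agg <- stats::aggregate(torque ~ angle + speed, data = data, FUN = mean)
  agg
}

tps_kernel_matrix <- function(x, centers) {
  d2 <- outer(x[, 1], centers[, 1], "-")^2 + outer(x[, 2], centers[, 2], "-")^2
  k <- 0.5 * d2 * log(pmax(d2, 1e-300))  # r^2 log r = d2 log(sqrt(d2))
  k[d2 == 0] <- 0
  k
}

#' Evaluate a thin-plate spline torque surface
#'
#' @param surface a `tps_surface` from [fit_tps()].
#' @param angle trunk angle(s), deg.
#' @param speed trunk angular speed(s), deg/s. The bench characterizes
#'   positive speeds only; by default speed queries are clamped to the fitted
#'   speed range (angle is never clamped) and flagged as extrapolation.
#' @param clamp clamp speed queries to the fitted range (default TRUE).
#' @return numeric torque (N m) with attribute `extrapolated` (logical vector:
#'   query outside the convex hull of the training sites).
#' @export
evaluate_tps <- function(surface, angle, speed, clamp = TRUE) {
  sc <- surface$scaling
  x1 <- (angle - sc$angle_min) / sc$angle_range
  x2 <- (speed - sc$speed_min) / sc$speed_range
  extra <- !in_hull(surface, x1, x2)
  if (clamp) {
    x2 <- pmin(1, pmax(0, x2))
  }
  K <- tps_kernel_matrix(cbind(x1, x2), surface$centers)
  val <- as.numeric(K %*% surface$weights +
                    cbind(1, x1, x2) %*% surface$affine)
  attr(val, "extrapolated") <- extra
  val
}

# point-in-convex-hull test on the scaled training sites
in_hull <- function(surface, x1, x2) {
  idx <- surface$hull
  hx <- surface$centers[idx, 1]; hy <- surface$centers[idx, 2]
  m <- length(idx)
  inside <- rep(TRUE, length(x1))
  cx <- mean(hx); cy <- mean(hy)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    s_c <- ex * (cy - hy[i]) - ey * (cx - hx[i])
    s_p <- ex * (x2 - hy[i]) - ey * (x1 - hx[i])
    inside <- inside & (s_p * sign(s_c) >= -1e-9)
  }
  inside
}

#' Goodness of fit of a torque surface against characterization records
#'
#' @param surface a `tps_surface`.
#' @param data data.frame with `angle`, `speed`, `torque`.
#' @return list with `r2` (1 - SS_res/SS_tot) and `rmse` (N m).
#' @export
goodness_of_fit <- function(surface, data) {
  if (!nrow(data)) stop("no characterization records")
  if (stats::var(data$torque) < 1e-300) stop("R^2 undefined: zero-variance torque")
  pred <- evaluate_tps(surface, data$angle, data$speed)
  res <- data$torque - pred
  list(r2 = 1 - sum(res^2) / sum((data$torque - mean(data$torque))^2),
       rmse = sqrt(mean(res^2)))
}

#' Select TPS regularization by leave-one-speed-out cross-validation
#'
#' For each lambda on a log grid, each sweep speed is held out in turn, the
#' surface is fitted to the remaining speeds and scored on the held-out
#' records; the lambda with smallest mean squared prediction error wins.
#'
#' @param data characterization data.frame (`angle`, `speed`, `torque`).
#' @param grid candidate lambdas (default `10^seq(-5, 0)`).
#' @return the selected lambda.
#' @export
select_tps_reg <- function(data, grid = 10^seq(-5, 0, by = 1)) {
  speeds <- sort(unique(data$speed))
  if (length(speeds) < 3) return(grid[1])
  err <- sapply(grid, function(lam) {
    se <- 0
    for (s in speeds[-c(1, length(speeds))]) {  # hold out interior speeds only
      fitd <- data[data$speed != s, ]
      test <- data[data$speed == s, ]
      surf <- fit_tps(fitd, lam)
      se <- se + mean((test$torque - evaluate_tps(surf, test$angle, test$speed))^2)
    }
    se
  })
  grid[which.min(err)]
}

#' Filter and average repeated bench sweeps onto a common angle grid
#'
#' Bench protocol: the exoskeleton is driven from 0 to 90 degrees at each
#' sweep speed, repeated `n_repeats` times, torque recorded at `fs` Hz. Each
#' repeat's torque trace is low-pass filtered (default 10 Hz), resampled onto
#' a common angle grid per speed, and averaged over repeats.
#'
#' @param raw data.frame with columns `speed_dps`, `repeat`, `angle_deg`,
#'   `torque_Nm` and attribute or argument `fs` (sampling rate, Hz).
#' @param fs sampling rate in Hz (default taken from `attr(raw, "fs")`, else
#'   1000).
#' @param fc filter cutoff in Hz (default 10).
#' @param grid_len points of the common angle grid per speed (default 181).
#' @return data.frame with columns `angle`, `speed`, `torque` (one averaged
#'   sweep per speed), ready for [fit_tps()].
#' @export
average_characterization <- function(raw, fs = NULL, fc = 10, grid_len = 181) {
  stopifnot(all(c("speed_dps", "repeat", "angle_deg", "torque_Nm") %in% names(raw)))
  if (is.null(fs)) fs <- attr(raw, "fs") %||% 1000
  out <- list()
  for (s in sort(unique(raw$speed_dps))) {
    d <- raw[raw$speed_dps == s, ]
    agrid <- seq(min(d$angle_deg), max(d$angle_deg), length.out = grid_len)
    reps <- sort(unique(d[["repeat"]]))
    acc <- matrix(NA_real_, length(reps), grid_len)
    lens <- table(d[["repeat"]])
    if (length(unique(lens)) > 1)
      message("average_characterization: sweep lengths differ at speed ", s,
              "; resampling to a common angle grid")
    for (i in seq_along(reps)) {
      di <- d[d[["repeat"]] == reps[i], ]
      di <- di[order(di$angle_deg), ]
      tq <- if (fc < fs / 2 && nrow(di) > 3 * 5) lowpass_filter(di$torque_Nm, fc, fs) else di$torque_Nm
      acc[i, ] <- approx(di$angle_deg, tq, xout = agrid, rule = 2)$y
    }
    out[[length(out) + 1]] <- data.frame(angle = agrid, speed = s,
                                         torque = colMeans(acc))
  }
  do.call(rbind, out)
}

#' Serialize a fitted torque surface to JSON
#' @param surface a `tps_surface`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_json <- function(surface, path) {
  obj <- list(centers = unname(apply(surface$centers, 1, as.numeric, simplify = FALSE)),
              weights = surface$weights, affine = surface$affine,
              regularization = surface$regularization,
              scaling = surface$scaling, hull = surface$hull)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a torque surface serialized by [write_surface_json()]
#' @param path JSON path.
#' @return a `tps_surface`.
#' @export
read_surface_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- if (is.list(obj$centers)) do.call(rbind, obj$centers) else obj$centers
  colnames(centers) <- c("angle", "speed")
  structure(list(centers = centers, weights = obj$weights, affine = obj$affine,
                 regularization = obj$regularization,
                 scaling = as.list(obj$scaling), hull = obj$hull),
            class = "tps_surface")
}

#' Read / write bench characterization CSV
#'
#' Columns: `speed_dps`, `repeat`, `angle_deg`, `torque_Nm`; the sampling
#' rate travels as an `fs` column (constant) if present, else defaults apply.
#'
#' @param path CSV path.
#' @return data.frame with attribute `fs`.
#' @export
read_bench_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if ("fs" %in% names(df)) {
    attr(df, "fs") <- df$fs[1]
    df$fs <- NULL
  }
  df
}

#' @rdname read_bench_csv
#' @param raw characterization data.frame (with optional `fs` attribute).
#' @export
write_bench_csv <- function(raw, path) {
  df <- raw
  if (!is.null(attr(raw, "fs"))) df$fs <- attr(raw, "fs")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
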