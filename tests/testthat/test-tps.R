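test_that("TPS with zero regularization interpolates and reproduces affine surfaces", {
  set.seed(2)
  ang <- runif(25, 0, 90); spd <- runif(25, 10, 90)
  # affine torque surface: TPS must reproduce it exactly with zero weights
  tq <- 2 + 0.5 * ang - 0.1 * spd
  d <- data.frame(angle = ang, speed = spd, torque = tq)
  surf <- fit_tps(d, 0)
  expect_lt(max(abs(surf$weights)), 1e-6)
  qa <- runif(30, 0, 90); qs <- runif(30, 10, 90)
  expect_equal(as.numeric(evaluate_tps(surf, qa, qs, clamp = FALSE)),
               2 + 0.5 * qa - 0.1 * qs, tolerance = 1e-8)

  # generic data: exact interpolation at training sites
  d2 <- data.frame(angle = ang, speed = spd,
                   torque = bench_true_torque(ang, spd) + rnorm(25))
  s2 <- fit_tps(d2, 0)
  expect_lt(max(abs(as.numeric(evaluate_tps(s2, ang, spd)) - d2$torque)), 1e-6)
})

test_that("TPS side conditions hold and the fit ignores record order", {
  set.seed(3)
  d <- data.frame(angle = runif(20, 0, 90), speed = runif(20, 10, 90))
  d$torque <- bench_true_torque(d$angle, d$speed) + rnorm(20, 0, 2)
  s <- fit_tps(d, 1e-3)
  expect_lt(abs(sum(s$weights)), 1e-8)
  expect_lt(abs(sum(s$weights * s$centers[, 1])), 1e-8)
  expect_lt(abs(sum(s$weights * s$centers[, 2])), 1e-8)
  sh <- fit_tps(d[sample(nrow(d)), ], 1e-3)
  q <- cbind(runif(15, 0, 90), runif(15, 10, 90))
  expect_equal(as.numeric(evaluate_tps(s, q[, 1], q[, 2])),
               as.numeric(evaluate_tps(sh, q[, 1], q[, 2])), tolerance = 1e-6)
})

test_that("TPS surface is continuous and constant surfaces evaluate constant", {
  ang <- rep(seq(0, 90, by = 15), 3)
  spd <- rep(c(10, 45, 90), each = 7)
  s <- fit_tps(data.frame(angle = ang, speed = spd, torque = 30), 0)
  expect_equal(as.numeric(evaluate_tps(s, c(5, 44, 71), c(12, 33, 88))),
               rep(30, 3), tolerance = 1e-8)
  # continuity: 1e-6 apart in inputs -> < 1e-3 N m apart in torque
  d <- data.frame(angle = ang, speed = spd,
                  torque = bench_true_torque(ang, spd))
  s2 <- fit_tps(d, 0)
  v1 <- as.numeric(evaluate_tps(s2, 40, 50))
  v2 <- as.numeric(evaluate_tps(s2, 40 + 1e-6, 50 + 1e-6))
  expect_lt(abs(v1 - v2), 1e-3)
})

test_that("collinear characterization sites are rejected with the degenerate axis named", {
  d <- data.frame(angle = seq(0, 90, by = 10), speed = 45, torque = 1:10)
  expect_error(fit_tps(d, 0), "speed")
  d2 <- data.frame(angle = 30, speed = seq(10, 90, by = 10), torque = 1:9)
  expect_error(fit_tps(d2, 0), "angle")
})

test_that("increasing regularization never increases training R^2", {
  set.seed(4)
  bench <- generate_bench(fs = 100, n_repeats = 3, seed = 9)
  avg <- average_characterization(bench, fs = 100, grid_len = 25)
  r2s <- sapply(c(0, 1e-4, 1e-2, 1, 100), function(lam)
    goodness_of_fit(fit_tps(avg, lam), avg)$r2)
  expect_true(all(diff(r2s) <= 1e-9))
})

test_that("goodness of fit matches its definitions", {
  ang <- runif(12, 0, 90); spd <- runif(12, 10, 90)
  d <- data.frame(angle = ang, speed = spd, torque = 1 + 0.3 * ang + 0.05 * spd)
  s <- fit_tps(d, 0)
  g <- goodness_of_fit(s, d)
  expect_equal(g$r2, 1, tolerance = 1e-9)
  expect_equal(g$rmse, 0, tolerance = 1e-6)
  # residuals all +2 -> rmse 2; surface == mean -> r2 = 0
  d_shift <- d; d_shift$torque <- d_shift$torque + 2
  expect_equal(goodness_of_fit(s, d_shift)$rmse, 2, tolerance = 1e-6)
  d_const <- d; d_const$torque <- rep(5, 12)
  expect_error(goodness_of_fit(s, d_const[0, ]), "no characterization")
  expect_error(goodness_of_fit(s, d_const), "zero-variance")
  # r2 = 0 when predictions equal the mean torque
  s_mean <- fit_tps(data.frame(angle = c(0, 45, 90, 45), speed = c(10, 50, 90, 10),
                               torque = mean(d$torque)), 0)
  expect_equal(goodness_of_fit(s_mean, d)$r2,
               1 - sum((d$torque - mean(d$torque))^2) /
                 sum((d$torque - mean(d$torque))^2), tolerance = 1e-9)
})

test_that("averaging repeats: identical repeats pass through, f and -f cancel, noise shrinks", {
  ang <- seq(0, 90, length.out = 120)
  tq <- bench_true_torque(ang, 45)
  mk <- function(r, torque) data.frame(speed_dps = 45, "repeat" = r,
                                       angle_deg = ang, torque_Nm = torque,
                                       check.names = FALSE)
  raw_id <- rbind(mk(1, tq), mk(2, tq))
  avg <- average_characterization(raw_id, fs = 100, fc = 0.4 * 100 / 2, grid_len = 120)
  expect_equal(avg$torque, tq, tolerance = 0.05)
  raw_pm <- rbind(mk(1, tq), mk(2, -tq))
  avg_pm <- average_characterization(raw_pm, fs = 100, grid_len = 120)
  expect_equal(avg_pm$torque, rep(0, 120), tolerance = 1e-9)
  # mean of 10 noisy repeats within 3 sd/sqrt(10) pointwise (away from edges)
  set.seed(6)
  raw_n <- do.call(rbind, lapply(1:10, function(r) mk(r, tq + rnorm(120, 0, 2))))
  avg_n <- average_characterization(raw_n, fs = 100, fc = 45, grid_len = 120)
  inner <- 10:110
  expect_true(all(abs(avg_n$torque - tq)[inner] < 3 * 2 / sqrt(10)))
})

test_that("bench CSV and surface JSON round-trip", {
  bench <- generate_bench(fs = 60, n_repeats = 2, seed = 3)
  p <- tempfile(fileext = ".csv")
  write_bench_csv(bench, p)
  back <- read_bench_csv(p)
  expect_equal(attr(back, "fs"), 60)
  expect_equal(back$torque_Nm, bench$torque_Nm, tolerance = 1e-12)
  avg <- average_characterization(bench, fs = 60, grid_len = 30)
  s <- fit_tps(avg, 1e-4)
  pj <- tempfile(fileext = ".json")
  write_surface_json(s, pj)
  s2 <- read_surface_json(pj)
  q <- cbind(runif(10, 0, 90), runif(10, 10, 90))
  expect_equal(as.numeric(evaluate_tps(s2, q[, 1], q[, 2])),
               as.numeric(evaluate_tps(s, q[, 1], q[, 2])), tolerance = 1e-10)
})

test_that("queries outside the characterized region are flagged as extrapolation", {
  bench <- generate_bench(fs = 60, n_repeats = 2, noise_sd = 0, seed = 3)
  avg <- average_characterization(bench, fs = 60, grid_len = 30)
  s <- fit_tps(avg, 0)
  v <- evaluate_tps(s, c(45, 45), c(50, 500))
  expect_identical(attr(v, "extrapolated"), c(FALSE, TRUE))
  # negative sweep speed is outside the bench range: clamped and flagged
  v2 <- evaluate_tps(s, 45, -20)
  expect_true(attr(v2, "extrapolated"))
  expect_equal(as.numeric(v2), as.numeric(evaluate_tps(s, 45, 10)), tolerance = 1e-9)
})
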