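test_that("segment masses are proportional to body mass; exo mass rides the lumbar COM", {
  seg <- build_segments(100, 1.8)
  expect_equal(seg$mass[seg$segment == "forearm_L"], 1.6)
  expect_equal(attr(seg, "exo_mass"), 0)
  seg_on <- build_segments(100, 1.8, exo_on = TRUE, exo_mass = 3.8)
  expect_equal(attr(seg_on, "exo_mass"), 3.8)
  # conservation: fractions x mass (+ exo mass) = modelled upper-body mass
  expect_equal(sum(seg_on$mass) + attr(seg_on, "exo_mass"),
               sum(default_segment_table()$fraction) * 100 + 3.8)
  expect_error(build_segments(-1, 1.8), "> 0")
  bad <- default_segment_table()[-3, ]
  expect_error(build_segments(80, 1.8, table = bad), "missing segment")
})

test_that("static stoop toy reproduces the closed-form sagittal moment", {
  # 40 kg upper body at 0.3 m + 10 kg hand load at 0.45 m:
  # (40*0.3 + 10*0.45) * 9.81 = 161.865 N m
  tr <- static_trial(com = c(0.3, 0, 0.5), wrist = c(0.45, 0, 0.8),
                     hand_fz = -10 * 9.81, mass = 40)
  seg <- build_segments(40, 1.7, table = unit_fraction_table())
  M <- inverse_dynamics_topdown(tr, seg)
  expected <- (40 * 0.3 + 10 * 0.45) * 9.81
  expect_lt(max(abs(M[, 2] - expected)) / expected, 1e-6)
  expect_lt(max(abs(M[, c(1, 3)])), 1e-9)
})

test_that("upright static posture with no hand load gives zero moment", {
  tr <- static_trial(com = c(0, 0, 0.4), wrist = c(0, 0, 0.8), hand_fz = 0)
  seg <- build_segments(40, 1.7, table = unit_fraction_table())
  M <- inverse_dynamics_topdown(tr, seg)
  expect_lt(max(abs(M)), 1e-9)
})

test_that("uniform acceleration adds the m*a*h inertial moment", {
  # single effective point mass at height h above L5 accelerating horizontally:
  # sagittal moment gains -m*a*h relative to static (inertial reaction)
  n <- 121; fs <- 60; a <- 2; h <- 0.5; mass <- 40
  t <- seq(0, by = 1 / fs, length.out = n)
  xpos <- 0.5 * a * t^2
  tr <- static_trial(com = c(0, 0, h), wrist = c(0, 0, h), hand_fz = 0,
                     n = n, mass = mass)
  for (s in exofanova:::SEGMENT_NAMES) {
    tr$segments[[s]]$com <- cbind(xpos, 0, h)
  }
  seg <- build_segments(mass, 1.7, table = unit_fraction_table())
  M <- inverse_dynamics_topdown(tr, seg)
  interior <- 5:(n - 5)
  # moment of m(g - a) at r = (x, 0, h): y-component = m*(9.81*x - (-a)*... )
  expected <- mass * (9.81 * xpos[interior] - a * h)
  expect_equal(M[interior, 2], expected, tolerance = 1e-6)
})

test_that("missing hand-force channel is treated as zero with a warning", {
  tr <- static_trial(com = c(0.2, 0, 0.5), wrist = c(0.3, 0, 0.8), hand_fz = -50)
  tr2 <- tr
  tr2$hand_force$right <- NULL
  seg <- build_segments(40, 1.7, table = unit_fraction_table())
  expect_warning(M2 <- inverse_dynamics_topdown(tr2, seg), "missing hand-force")
  M <- inverse_dynamics_topdown(tr, seg)
  # right hand carried half the load
  expect_equal(M2[1, 2], M[1, 2] - 0.3 * 25, tolerance = 1e-9)
})

test_that("assistive torque is subtracted in the flexion plane only", {
  n <- 10
  gross <- matrix(rep(c(5, 150, 2), each = n), ncol = 3)
  c7 <- matrix(rep(c(0.3, 0, 0.9), each = n), ncol = 3)
  l5 <- matrix(0, n, 3)
  cm <- matrix(rep(c(0, 0, -0.4), each = n), ncol = 3)
  # exo off: net = gross
  off <- net_lumbar_moment(gross, rep(40, n), rep(10, n), NULL, c7, l5, cm,
                           exo_on = FALSE)
  expect_identical(off$net, gross)
  expect_identical(off$assist, rep(0, n))
  # constant surface of 40 N m: sagittal component drops by 40
  d <- data.frame(angle = c(0, 45, 90, 45), speed = c(10, 50, 90, 10), torque = 40)
  s40 <- fit_tps(d, 0)
  on <- net_lumbar_moment(gross, rep(40, n), rep(50, n), s40, c7, l5, cm)
  # flexion plane here is the x-z plane of the markers -> normal along y
  expect_equal(on$net[, 2], rep(110, n), tolerance = 1e-6)
  expect_equal(on$net[, 1], gross[, 1], tolerance = 1e-9)
  expect_equal(on$net[, 3], gross[, 3], tolerance = 1e-9)
  expect_false(any(on$overassisted))
  # over-assistance: sign preserved, no clamping
  gross_small <- matrix(rep(c(0, 10, 0), each = n), ncol = 3)
  suppressMessages(
    on2 <- net_lumbar_moment(gross_small, rep(40, n), rep(50, n), s40, c7, l5, cm))
  expect_equal(on2$net[, 2], rep(-30, n), tolerance = 1e-6)
  expect_true(all(on2$overassisted))
})

test_that("degenerate flexion plane reuses the previous sample's plane", {
  n <- 4
  gross <- matrix(rep(c(0, 100, 0), each = n), ncol = 3)
  c7 <- matrix(rep(c(0.3, 0, 0.9), each = n), ncol = 3)
  l5 <- matrix(0, n, 3)
  cm <- matrix(rep(c(0, 0, -0.4), each = n), ncol = 3)
  cm[3, ] <- c7[3, ] * 0.5  # collinear with C7 and L5 at sample 3
  d <- data.frame(angle = c(0, 45, 90, 45), speed = c(10, 50, 90, 10), torque = 20)
  s <- fit_tps(d, 0)
  expect_warning(out <- net_lumbar_moment(gross, rep(40, n), rep(50, n), s,
                                          c7, l5, cm), "degenerate")
  expect_equal(out$net[3, 2], 80, tolerance = 1e-6)
})

test_that("QP muscle forces match the worked two-muscle example and KKT symmetry", {
  # extensor arm +0.05 m, flexor arm -0.03 m, equal PCSA, net 100 N m
  mus <- sagittal_muscles(arms = c(0.05, -0.03), pcsas = c(0.001, 0.001))
  f <- solve_muscle_forces(100, mus, mode = "sagittal")
  expect_equal(unname(f), c(2000, 0), tolerance = 1e-6)
  # zero moment -> all forces zero
  f0 <- solve_muscle_forces(0, mus, mode = "sagittal")
  expect_equal(unname(f0), c(0, 0), tolerance = 1e-9)
  # two identical parallel extensors split the load symmetrically
  mus2 <- sagittal_muscles(arms = c(0.05, 0.05), pcsas = c(0.001, 0.001))
  f2 <- solve_muscle_forces(100, mus2, mode = "sagittal")
  expect_equal(unname(f2), c(1000, 1000), tolerance = 1e-6)
})

test_that("QP solution matches the brute-force grid oracle on 2- and 3-muscle problems", {
  cases <- list(
    list(arms = c(0.05, -0.03), pcsas = c(0.001, 0.001), b = 50),
    list(arms = c(0.06, 0.04, -0.03), pcsas = c(0.0015, 0.001, 0.0006), b = 40),
    list(arms = c(0.05, 0.05, 0.02), pcsas = c(0.0015, 0.0008, 0.0010), b = 30)
  )
  for (cs in cases) {
    mus <- sagittal_muscles(cs$arms, cs$pcsas)
    f_qp <- unname(solve_muscle_forces(cs$b, mus, mode = "sagittal"))
    oracle <- grid_qp_oracle(cs$arms, cs$pcsas, cs$b, fmax = 1500, step = 1)
    # a 1 N grid step on the free forces moves the eliminated force by
    # sum(|other arms|)/|last arm| newtons; that is the grid's resolution
    k <- length(cs$arms)
    res_bound <- 1 + sum(abs(cs$arms[-k])) / abs(cs$arms[k])
    expect_lt(max(abs(f_qp - oracle$forces)), res_bound)
    obj_qp <- stress_sq_objective(f_qp, cs$pcsas)
    # grid objective can only be >= the continuum optimum, within grid slack
    expect_gte(oracle$objective, obj_qp - 1e-6 * obj_qp)
    hess_scale <- max(2 / cs$pcsas^2)
    expect_lte(oracle$objective - obj_qp, hess_scale * length(cs$arms) * 1^2)
  }
})

test_that("QP objective beats 1000 random feasible alternatives", {
  mus <- sagittal_muscles(arms = c(0.06, 0.04, -0.03), pcsas = c(0.0015, 0.001, 0.0006))
  b <- 40
  f_qp <- unname(solve_muscle_forces(b, mus, mode = "sagittal"))
  obj_qp <- stress_sq_objective(f_qp, mus$pcsa)
  set.seed(99)
  n_ok <- 0
  while (n_ok < 1000) {
    f23 <- runif(2, 0, 2000)
    f1 <- (b - 0.04 * f23[1] - (-0.03) * f23[2]) / 0.06
    if (f1 < 0) next
    n_ok <- n_ok + 1
    expect_gte(stress_sq_objective(c(f1, f23), mus$pcsa), obj_qp - 1e-9)
  }
})

test_that("infeasible equilibrium errors and names the unbalanced axis", {
  # two extensors only: negative (extension-demand) moment is unreachable
  mus <- sagittal_muscles(arms = c(0.05, 0.04), pcsas = c(0.001, 0.001))
  expect_error(solve_muscle_forces(-50, mus, mode = "sagittal"),
               "infeasible.*sagittal")
})

test_that("compression force projects muscles and upper-body load onto the lumbar axis", {
  mus1 <- sagittal_muscles(arms = 0.05, pcsas = 0.001)  # acts along +z
  # vertical axis, vertical 2000 N muscle, 400 N hanging upper body -> 2400 N
  expect_equal(compression_force(2000, c(0, 0, -400), c(0, 0, 1), mus1), 2400)
  # load perpendicular to the axis contributes nothing
  expect_equal(compression_force(0, c(300, 0, 0), c(0, 0, 1), mus1), 0)
  # muscle at 60 degrees to the axis: cosine projection
  mus60 <- data.frame(name = "m", ux = sin(pi / 3), uy = 0, uz = cos(pi / 3),
                      rx = -0.05, ry = 0, rz = 0, pcsa = 0.001, max_stress = 0.46e6)
  expect_equal(compression_force(1000, c(0, 0, 0), c(0, 0, 1), mus60), 500,
               tolerance = 1e-9)
})

test_that("pressure-to-force conversion is the stated linear map", {
  expect_equal(pressure_to_force(0.5, 1000), 500)
  expect_equal(pressure_to_force(0, 1234), 0)
  expect_equal(pressure_to_force(2 * 0.37, 900), 2 * pressure_to_force(0.37, 900))
  expect_error(pressure_to_force(0.5, -1), "> 0")
})

test_that("ICC(1,1) equals the one-way ANOVA oracle and hits r = 1 for y = x", {
  x <- c(3, 7, 1, 9, 4, 6, 8, 2, 5, 10, 11, 12)
  expect_equal(icc_1_1(x, x)$r, 1, tolerance = 1e-12)

  # independent oracle: ICC from aov() mean squares on the long-format table
  set.seed(21)
  y <- x + rnorm(12, 0, 2)
  icc <- icc_1_1(x, y)
  long <- data.frame(target = factor(rep(1:12, 2)), value = c(x, y))
  ms <- summary(stats::aov(value ~ target, data = long))[[1]]$`Mean Sq`
  r_oracle <- (ms[1] - ms[2]) / (ms[1] + ms[2])
  expect_equal(icc$r, r_oracle, tolerance = 1e-10)

  # y an uncorrelated permutation of x: r near 0 (same oracle route)
  set.seed(8)
  yp <- sample(x)
  icc_p <- icc_1_1(x, yp)
  long_p <- data.frame(target = factor(rep(1:12, 2)), value = c(x, yp))
  ms_p <- summary(stats::aov(value ~ target, data = long_p))[[1]]$`Mean Sq`
  expect_equal(icc_p$r, (ms_p[1] - ms_p[2]) / (ms_p[1] + ms_p[2]), tolerance = 1e-10)
  expect_lt(abs(icc_p$r), 0.45)

  # zero between-target variance: r <= 0, no error
  expect_lte(icc_1_1(rep(5, 6) + c(1, -1, 1, -1, 1, -1) * 0.5,
                     rep(5, 6) - c(1, -1, 1, -1, 1, -1) * 0.5)$r, 0)
})

test_that("ICC recovers a rho = 0.93 generating model within its confidence interval", {
  # 12 posture pairs per repeat: shared target value + independent errors with
  # variance ratio set so the population ICC is 0.93
  rho <- 0.93
  sb <- 1; sw <- sqrt(sb^2 * (1 - rho) / rho)
  set.seed(31)
  rs <- replicate(60, {
    tgt <- rnorm(12, 10, sb)
    icc_1_1(tgt + rnorm(12, 0, sw), tgt + rnorm(12, 0, sw))
  }, simplify = FALSE)
  covered <- vapply(rs, function(ic) ic$ci95[1] <= rho && rho <= ic$ci95[2],
                    logical(1))
  expect_gte(mean(covered), 0.85)  # 95% nominal coverage, Monte-Carlo slack
  expect_equal(mean(vapply(rs, `[[`, numeric(1), "r")), rho, tolerance = 0.04)
})

test_that("with zero assistive torque the exo-on pipeline reproduces exo-off Fc bit for bit (apart from exo mass)", {
  spec <- tiny_spec()
  spec$noise$marker <- 0; spec$noise$force <- 0
  spec$exo_effects <- list(dtheta = 0, domega = 0, dH = 0)
  tr_off <- generate_trial(spec, 1, list(symmetry = "symmetric", exo = "off"), 1)
  tr_on <- generate_trial(spec, 1, list(symmetry = "symmetric", exo = "on"), 1)
  dyn_off <- lumbar_load_series(tr_off, surface = NULL)
  # exo on, no surface -> assist 0; exo_mass = 0 removes the only other difference
  dyn_on <- lumbar_load_series(tr_on, surface = NULL, exo_mass = 0)
  expect_identical(dyn_on$Fc, dyn_off$Fc)
})

test_that("Fc is monotone non-decreasing in hand-load mass for a fixed static posture", {
  fcs <- sapply(c(0, 5, 10, 15, 20), function(kg) {
    tr <- static_trial(com = c(0.25, 0, 0.45), wrist = c(0.4, 0, 0.3),
                       hand_fz = -kg * 9.81)
    max(lumbar_load_series(tr, surface = NULL)$Fc)
  })
  expect_true(all(diff(fcs) > 0))
})
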