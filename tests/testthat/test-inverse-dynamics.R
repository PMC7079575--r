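test_that("a driven pendulum matches the closed-form equation of motion", {
  m <- pendulum_model(mass = 2, com_mm = -150, izz = 0.004)
  tt <- seq(0, 2, by = 0.002)
  th <- 25 * sin(2 * pi * tt)
  qw <- tibble::tibble(time = tt, base_tx = 0, base_ty = 0, base_tz = 0,
                       base_rz = 0, base_rx = 0, base_ry = 0, hinge_rz = th)
  id <- inverse_dynamics(qw, m)
  mom <- id$moments$moment_nm[id$moments$coord == "hinge_rz"]
  lc <- 0.15; Ij <- 0.004 + 2 * lc^2
  thr <- caninegait:::deg2rad(th)
  thdd <- -(2 * pi)^2 * caninegait:::deg2rad(25) * sin(2 * pi * tt)
  closed <- Ij * thdd + 2 * 9.81 * lc * sin(thr)
  inner <- 5:(length(tt) - 5)
  expect_lt(max(abs(mom[inner] - closed[inner])) / max(abs(closed)), 0.01)
})

test_that("no gravity, no motion, no load gives zero moments", {
  m <- chain3_model()
  tt <- seq(0, 0.1, by = 0.01)
  qw <- tibble::tibble(time = tt, base_tx = 0, base_ty = 0, base_tz = 0,
                       base_rz = 0, base_rx = 0, base_ry = 0,
                       j1_rz = 20, j2_rz = -35, j3_rz = 10)
  id <- inverse_dynamics(qw, m, gravity = c(0, 0, 0))
  expect_lt(max(abs(id$moments$moment_nm)), 1e-9)
  expect_lt(max(abs(as.matrix(id$residuals[, -1]))), 1e-9)
})

test_that("static joint moments equal the closed-form gravity moments", {
  m <- chain3_model()
  tt <- seq(0, 0.1, by = 0.01)
  pose <- c(base_tx = 0, base_ty = 500, base_tz = 0, base_rz = 0,
            base_rx = 0, base_ry = 0, j1_rz = 30, j2_rz = -45, j3_rz = 15)
  qw <- dplyr::bind_cols(tibble::tibble(time = tt),
                         tibble::as_tibble(as.list(pose)))
  id <- inverse_dynamics(qw, m)
  fk <- forward_kinematics(m, pose)
  segs <- m$segments
  com_x <- vapply(seq_len(nrow(segs)), function(s) {
    (fk$p[segs$name[s], ] + fk$R[[segs$name[s]]] %*%
       c(segs$cx[s], segs$cy[s], segs$cz[s]))[1] / 1000
  }, numeric(1))
  names(com_x) <- segs$name
  jx <- fk$p[, 1] / 1000
  g <- 9.81
  # applied moment at a hinge supports the weight of everything distal:
  # tau = sum_distal m g (x_com - x_joint)
  expected <- c(
    j1 = unname(sum(segs$mass_kg[2:4] * g * (com_x[2:4] - jx["link1"]))),
    j2 = unname(sum(segs$mass_kg[3:4] * g * (com_x[3:4] - jx["link2"]))),
    j3 = unname(segs$mass_kg[4] * g * (com_x[4] - jx["link3"]))
  )
  got <- id$moments[id$moments$time == tt[5], ]
  expect_equal(got$moment_nm[got$coord == "j1_rz"], expected[["j1"]],
               tolerance = 1e-8)
  expect_equal(got$moment_nm[got$coord == "j2_rz"], expected[["j2"]],
               tolerance = 1e-8)
  expect_equal(got$moment_nm[got$coord == "j3_rz"], expected[["j3"]],
               tolerance = 1e-8)
  # the root carries the full weight as residual force
  expect_equal(id$residuals$fy_n[5], sum(segs$mass_kg) * g,
               tolerance = 1e-8)
})

test_that("a matching ground reaction cancels the static residuals", {
  m <- chain3_model()
  tt <- seq(0, 0.2, by = 0.01)
  pose <- c(base_tx = 0, base_ty = 500, base_tz = 0, base_rz = 0,
            base_rx = 0, base_ry = 0, j1_rz = 0, j2_rz = 0, j3_rz = 0)
  qw <- dplyr::bind_cols(tibble::tibble(time = tt),
                         tibble::as_tibble(as.list(pose)))
  segs <- m$segments
  W <- sum(segs$mass_kg) * 9.81
  # straight-down chain: every COM is on the root vertical, so a
  # vertical force of the total weight applied on that line balances
  # the system exactly
  grf <- tibble::tibble(time = tt, fx = 0, fy = W, fz = 0, tv = 0,
                        copx = 0, copy = 0, copz = 0)
  id <- inverse_dynamics(qw, m, grf, grf_segment = "link3")
  expect_lt(max(abs(id$residuals$fx_n)), 1e-6)
  expect_lt(max(abs(id$residuals$fy_n)), 1e-6)
  expect_lt(max(abs(id$residuals$fz_n)), 1e-6)
  expect_lt(max(abs(id$residuals$mz_nm)), 1e-6)
})

test_that("residuals scale linearly with an injected force-plate bias", {
  trial <- cached_trial(seed = 1, noise_sd_mm = 0)
  id0 <- inverse_dynamics(trial$truth_coords, trial$model, trial$grf)
  b1 <- corrupt_trial(trial, grf_bias = c(fy = 2))
  id1 <- inverse_dynamics(b1$truth_coords, b1$model, b1$grf)
  b2 <- corrupt_trial(trial, grf_bias = c(fy = 4))
  id2 <- inverse_dynamics(b2$truth_coords, b2$model, b2$grf)
  d1 <- id1$residuals$fy_n - id0$residuals$fy_n
  d2 <- id2$residuals$fy_n - id0$residuals$fy_n
  # doubling the bias doubles the residual change, frame by frame,
  # over solidly loaded frames (at the contact edges the bias can flip
  # a frame across the loaded/unloaded threshold)
  tt <- id0$residuals$time
  inner <- tt >= 0.05 & tt <= 0.35
  expect_equal(d2[inner], 2 * d1[inner], tolerance = 1e-8)
  expect_equal(mean(abs(d1[inner])), 2, tolerance = 0.01)
})

test_that("joint power is the moment-velocity product in SI units", {
  mom <- tibble::tibble(cycle_pct = c(0, 50, 100), joint = "hip",
                        moment_nm = c(1, 2, -1))
  vel <- tibble::tibble(cycle_pct = c(0, 50, 100), joint = "hip",
                        velocity_dps = c(180 / pi, 0, 180 / pi))
  p <- joint_power(mom, vel)
  expect_equal(p$power_w, c(1, 0, -1), tolerance = 1e-12)
  # extensor moment during flexion absorbs energy (negative power)
  expect_lt(p$power_w[3], 0)
  expect_error(joint_power(mom, vel[1:2, ]),
               class = "caninegait_invalid_input")
})

test_that("summed joint power integrates to the mechanical energy change", {
  m <- pendulum_model(mass = 2, com_mm = -150, izz = 0.004)
  tt <- seq(0, 0.5, by = 0.001)
  th <- 20 + 40 * sin(2 * pi * tt)
  qw <- tibble::tibble(time = tt, base_tx = 0, base_ty = 0, base_tz = 0,
                       base_rz = 0, base_rx = 0, base_ry = 0, hinge_rz = th)
  id <- inverse_dynamics(qw, m)
  mom <- id$moments$moment_nm[id$moments$coord == "hinge_rz"]
  thd <- caninegait:::finite_diff(th, 0.001)
  P <- mom * caninegait:::deg2rad(thd)
  lc <- 0.15; Ij <- 0.004 + 2 * lc^2
  energy <- function(i) {
    w <- caninegait:::deg2rad(thd[i])
    0.5 * Ij * w^2 + 2 * 9.81 * (-lc * cos(caninegait:::deg2rad(th[i])))
  }
  i0 <- 5; i1 <- length(tt) - 5
  work <- sum((P[i0:(i1 - 1)] + P[(i0 + 1):i1]) / 2) * 0.001
  dE <- energy(i1) - energy(i0)
  expect_lt(abs(work - dE) / abs(dE), 0.02)
})

test_that("misaligned or incomplete inputs are rejected", {
  m <- pendulum_model()
  qw <- tibble::tibble(time = c(0, 0.01, 0.03), base_tx = 0, base_ty = 0,
                       base_tz = 0, base_rz = 0, base_rx = 0, base_ry = 0,
                       hinge_rz = 0)
  expect_error(inverse_dynamics(qw, m), class = "caninegait_invalid_input")
  qw2 <- tibble::tibble(time = seq(0, 0.05, by = 0.01), base_tx = 0,
                        base_ty = 0, base_tz = 0, base_rz = 0, base_rx = 0,
                        base_ry = 0, hinge_rz = 0)
  grf_nocop <- tibble::tibble(time = qw2$time, fx = 0, fy = 10, fz = 0)
  expect_error(inverse_dynamics(qw2, m, grf_nocop, grf_segment = "rod"),
               class = "caninegait_invalid_input")
})
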