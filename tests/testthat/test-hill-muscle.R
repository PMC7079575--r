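test_that("Hill characteristic curves satisfy their defining anchors", {
  cv <- hill_curves()
  expect_equal(cv$fl(1), 1)
  expect_lt(cv$fl(0.5), cv$fl(1))
  expect_equal(cv$fp(0.9), 0)
  expect_equal(cv$fp(1), 0)
  expect_equal(cv$fp(1.6), 1, tolerance = 1e-12)  # strain 0.6 at one F_iso
  expect_equal(cv$fv(0), 1)
  expect_equal(cv$fv(1), 0)                       # max shortening velocity
  expect_true(all(cv$fv(seq(-5, 1, by = 0.1)) >= 0))
  expect_true(all(cv$fv(seq(-5, 0, by = 0.1)) <= 1.4))  # eccentric plateau
  expect_gt(cv$fv(-0.5), 1)
})

test_that("musculotendon length is the polyline through the path points", {
  m <- twolink_muscle_model()
  # straight segment-local two-point path: pose-invariant Euclidean length
  segs_1 <- m$segments
  paths1 <- tibble::tibble(muscle = "onseg", point = 1:2,
                           segment = "upper", x = c(0, 10),
                           y = c(-20, -120), z = c(0, 5))
  m1 <- msk_model(segs_1, paths = paths1)
  L0 <- musculotendon_length(m1, c(shoulder_rz = 0))$mtu_cm
  L1 <- musculotendon_length(m1, c(shoulder_rz = 57, elbow_rz = -30))$mtu_cm
  expect_equal(L0, sqrt(10^2 + 100^2 + 5^2) / 10, tolerance = 1e-12)
  expect_equal(L1, L0, tolerance = 1e-12)

  # planar two-link flexor: L = 50 sqrt(2 + 2 cos(theta)) mm
  for (th in c(0, 10, 35, -20)) {
    L <- musculotendon_length(m, c(elbow_rz = th), "flexor")$mtu_cm
    expect_equal(L, 50 * sqrt(2 + 2 * cos(caninegait:::deg2rad(th))) / 10,
                 tolerance = 1e-9)
  }

  # adding a collinear via point changes nothing
  pv <- dplyr::bind_rows(
    tibble::tibble(muscle = "flexor", point = 1, segment = "upper",
                   x = 0, y = -100, z = 0),
    tibble::tibble(muscle = "flexor", point = 2, segment = "upper",
                   x = 0, y = -125, z = 0),
    tibble::tibble(muscle = "flexor", point = 3, segment = "lower",
                   x = 0, y = -50, z = 0)
  )
  mv <- msk_model(m$segments, paths = pv, muscles = m$muscles)
  expect_equal(musculotendon_length(mv, c(elbow_rz = 0))$mtu_cm,
               musculotendon_length(m, c(elbow_rz = 0))$mtu_cm,
               tolerance = 1e-12)
})

test_that("tendon-excursion moment arms match pulley geometry", {
  R <- 20
  m <- pulley_model(R_mm = R)
  # at the neutral pose the line of action is vertical at x = -R
  arm0 <- moment_arm(m, c(hinge_rz = 0), coord = "hinge_rz")$arm_cm
  expect_equal(abs(arm0), R / 10, tolerance = 1e-3)

  # excursion arm equals the geometric perpendicular distance to the
  # line of action across random poses
  set.seed(9)
  for (th in runif(20, -40, 40)) {
    arm <- moment_arm(m, c(hinge_rz = th), coord = "hinge_rz")$arm_cm
    fk <- forward_kinematics(m, c(hinge_rz = th))
    p1 <- fk$p["base", ] + fk$R[["base"]] %*% c(-R, -20, 0)
    p2 <- fk$p["arm", ] + fk$R[["arm"]] %*% c(-R, -10, 0)
    joint <- fk$p["arm", ]
    d <- unname(perp_distance_z(as.numeric(joint)[1:2], as.numeric(p1),
                                as.numeric(p2))) / 10
    expect_equal(abs(arm), d, tolerance = 0.005 * d)
  }

  # mirrored antagonist path flips the arm sign
  paths_m <- m$paths; paths_m$x <- -paths_m$x
  mm <- msk_model(m$segments, paths = paths_m, muscles = m$muscles)
  arm_m <- moment_arm(mm, c(hinge_rz = 0), coord = "hinge_rz")$arm_cm
  expect_equal(arm_m, -arm0, tolerance = 1e-6)

  # a muscle that does not span the joint has zero arm
  m2 <- twolink_muscle_model()
  paths_up <- tibble::tibble(muscle = "mono", point = 1:2,
                             segment = "upper", x = c(0, 5),
                             y = c(-10, -100), z = 0)
  m3 <- msk_model(m2$segments, paths = paths_up)
  expect_equal(moment_arm(m3, coord = "elbow_rz")$arm_cm, 0,
               tolerance = 1e-9)
})

test_that("rigid-tendon force follows the activation-scaled envelope", {
  cv <- hill_curves()
  expect_equal(tendon_force(1, 1, 0, f_iso_n = 120, pennation_deg = 0,
                            curves = cv), 120)
  expect_equal(tendon_force(0, 0.9, 0, 120, 0, cv), 0)
  expect_equal(tendon_force(0.5, 1, 0, 120, 0, cv), 60)
  # pennation projects the force
  expect_equal(tendon_force(1, 1, 0, 120, 60, cv), 120 * cos(pi / 3),
               tolerance = 1e-12)
  # passive force adds on beyond optimal length even at zero activation
  expect_gt(tendon_force(0, 1.3, 0, 120, 0, cv), 0)
  expect_warning(tendon_force(1.4, 1, 0, 120, 0, cv), "clamping")
})
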