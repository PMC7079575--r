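test_that("identical specs generate bit-identical trials", {
  model <- cached_morphology()$model
  t1 <- generate_trial(gait_spec(seed = 5), model)
  t2 <- generate_trial(gait_spec(seed = 5), model)
  expect_identical(t1$markers, t2$markers)
  expect_identical(t1$grf, t2$grf)
  t3 <- generate_trial(gait_spec(seed = 6), model)
  expect_false(identical(t1$markers$x, t3$markers$x))
})

test_that("morphology closes the torso mass rule exactly", {
  morph <- cached_morphology()
  m <- morph$model
  expect_equal(sum(m$segments$mass_kg), m$body_mass_kg / 2,
               tolerance = 1e-9)
  seg_sum <- sum(m$segments$mass_kg[m$segments$name != "torso"])
  expect_equal(morph$torso_mass_kg,
               compute_torso_mass(m$body_mass_kg, seg_sum))
  # the full roster rides along with its paths
  expect_equal(nrow(m$muscles), 33)
  expect_true(all(m$paths$segment %in% m$segments$name))
})

test_that("segment masses scale linearly with body mass", {
  m1 <- generate_morphology(gait_spec(body_mass_kg = 5.4))$model
  m2 <- generate_morphology(gait_spec(body_mass_kg = 10.8))$model
  ratio <- m2$segments$mass_kg / m1$segments$mass_kg
  bony <- m1$segments$name != "torso"
  expect_equal(ratio[bony], rep(2, sum(bony)), tolerance = 0.005)
})

test_that("the vertical GRF hits its designed first peak and phases", {
  trial <- cached_trial(seed = 1, noise_sd_mm = 0)
  spec <- trial$spec
  g <- trial$grf
  bw <- spec$body_mass_kg * 9.81
  Tc <- spec$cycle_duration_s
  expect_true(all(g$fy >= 0))
  # zero through swing of the first cycle
  swing <- g$time > spec$stance_fraction * Tc & g$time < Tc
  expect_true(all(g$fy[swing] == 0))
  # first peak: 51% BW at 16% of the cycle (grid resolution 1 ms)
  early <- g$time < Tc / 3
  ipk <- which(early)[which.max(g$fy[early])]
  expect_equal(g$fy[ipk] / bw, spec$grf_peak1_bw, tolerance = 0.005)
  expect_equal(g$time[ipk] / Tc, spec$grf_peak1_pct / 100,
               tolerance = 0.005)
  # braking for the first third of stance, propulsion after
  phi_s <- g$time / (spec$stance_fraction * Tc)
  brake <- phi_s > 0.02 & phi_s < 0.31
  prop <- phi_s > 0.36 & phi_s < 0.98
  expect_true(all(g$fx[brake] <= 0))
  expect_true(all(g$fx[prop] >= 0))
  # mediolateral force stays small
  expect_lt(max(abs(g$fz)) / bw, spec$ml_amp_bw + 1e-9)
})

test_that("markers are forward kinematics of the truth plus seeded noise", {
  clean <- cached_trial(seed = 1, noise_sd_mm = 0)
  noisy <- generate_trial(gait_spec(seed = 1, noise_sd_mm = 2),
                          cached_morphology()$model)
  expect_equal(noisy$markers_clean$x, clean$markers$x, tolerance = 1e-12)
  resid <- noisy$markers$x - noisy$markers_clean$x
  expect_equal(sd(resid), 2, tolerance = 0.15)
  expect_equal(mean(resid), 0, tolerance = 0.15)
})

test_that("trial corruption injects recoverable, bounded defects", {
  trial <- cached_trial(seed = 2, noise_sd_mm = 0)
  # 4-frame gap is quintic-recoverable on the smooth truth
  bad <- corrupt_trial(trial, gaps = tibble::tibble(
    marker = "tibial_crest_L", start_frame = 30, length = 4))
  expect_equal(sum(!bad$markers$visible), 4)
  filled <- fill_gaps_quintic(bad$markers)
  expect_true(attr(filled, "trial_valid"))
  i <- filled$marker == "tibial_crest_L"
  j <- trial$markers$marker == "tibial_crest_L"
  expect_lt(max(abs(filled$x[i] - trial$markers$x[j])), 0.5)

  # 6-frame gap flags the trial unsuccessful
  bad6 <- corrupt_trial(trial, gaps = tibble::tibble(
    marker = "tibial_crest_L", start_frame = 30, length = 6))
  filled6 <- fill_gaps_quintic(bad6$markers)
  expect_false(attr(filled6, "trial_valid"))

  expect_error(corrupt_trial(trial, gaps = tibble::tibble(
    marker = "tibial_crest_L", start_frame = 70, length = 10)),
    class = "caninegait_invalid_input")

  biased <- corrupt_trial(trial, grf_bias = c(fx = 1.5))
  expect_equal(biased$grf$fx, trial$grf$fx + 1.5)
  off <- corrupt_trial(trial, torso_offset_mm = 10)
  i <- match("torso", off$model$segments$name)
  expect_equal(off$model$segments$cx[i],
               trial$model$segments$cx[i] + 10)
})

test_that("the full pipeline closes on a noise-free trial", {
  trial <- cached_trial(seed = 1, noise_sd_mm = 0)
  ik <- inverse_kinematics(trial$markers, trial$model)
  qw <- ik_coords_wide(ik)
  # recovered angles match truth essentially exactly
  for (j in c("hip", "stifle", "tarsus")) {
    cc <- paste0(j, "_L_rz")
    est <- resample_cycle(qw[, c("time", cc)], 100)[[cc]]
    tru <- trial$truth_angles$angle_deg[trial$truth_angles$joint == j]
    expect_gt(correlation_coefficient(est, tru), 0.999)
  }
  # moments recomputed from the IK coordinates match the generator truth
  id <- inverse_dynamics(qw, trial$model, trial$grf)
  for (cc in c("hip_L_rz", "stifle_L_rz", "tarsus_L_rz")) {
    tru <- trial$truth_moments$moments$moment_nm[
      trial$truth_moments$moments$coord == cc]
    est <- id$moments$moment_nm[id$moments$coord == cc]
    expect_lt(sqrt(mean((est - tru)^2)) / max(abs(tru)), 0.01)
  }
})
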