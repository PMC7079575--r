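test_that("fiber and tendon scaling is the segment-length ratio", {
  expect_equal(scale_fiber_length(4.0, l = 6, l_ref = 8), 3.0)
  expect_equal(scale_fiber_length(4.0, l = 8, l_ref = 8), 4.0)
  expect_equal(scale_fiber_length(4.0, l = 16, l_ref = 8),
               2 * scale_fiber_length(4.0, l = 8, l_ref = 8))
  expect_equal(scale_tendon_slack(2.5, l = 6, l_ref = 8), 1.875)
  expect_error(scale_fiber_length(4, 6, 0), class = "caninegait_invalid_input")
  expect_error(scale_tendon_slack(4, 6, -1), class = "caninegait_invalid_input")
})

test_that("fiber/tendon adjustment preserves the split and closes to the MTU", {
  # fixed point: MTU equal to f + TSL leaves both unchanged
  adj <- adjust_fiber_and_tendon(3, 2, 5)
  expect_equal(adj$f_adj, 3)
  expect_equal(adj$tsl_adj, 2)
  # equal split preserved
  adj <- adjust_fiber_and_tendon(2, 2, 6)
  expect_equal(adj$f_adj, 3)
  expect_equal(adj$tsl_adj, 3)

  set.seed(123)
  f <- runif(1000, 0.1, 12)
  tsl <- runif(1000, 0.05, 18)
  mtu <- runif(1000, 0.5, 40)
  adj <- adjust_fiber_and_tendon(f, tsl, mtu)
  expect_lt(max(abs(adj$f_adj + adj$tsl_adj - mtu)), 1e-10)
  expect_equal(adj$f_adj / adj$tsl_adj, f / tsl, tolerance = 1e-10)

  expect_error(adjust_fiber_and_tendon(0, 0, 5),
               class = "caninegait_invalid_input")
})

test_that("maximum isometric force reproduces the roster's printed values", {
  # six worked examples from the packaged roster (printed inputs are
  # rounded to one decimal, hence the 1% tolerance)
  cases <- tibble::tribble(
    ~vol, ~alpha, ~fib, ~expected,
    35.1, 4, 3.9, 202.4,     # adductor magnus et brevis
    16.9, 6, 2.7, 140.0,     # iliopsoas
    15.6, 0, 6.3, 55.7,      # semitendinosus
    19.2, 10, 4.3, 99.0,     # vastus lateralis and intermedius
    6.7, 17, 2.5, 57.6,      # gastrocnemius lateralis
    13.1, 0, 4.7, 62.5       # biceps femoris (tibial)
  )
  f <- max_isometric_force(cases$vol, cases$alpha, cases$fib)
  expect_true(all(abs(f - cases$expected) / cases$expected < 0.01))

  expect_equal(max_isometric_force(0, 10, 2), 0)
  # zero pennation reduces to T * Vol / f
  expect_equal(max_isometric_force(10, 0, 2), 22.5 * 10 / 2)
  expect_error(max_isometric_force(10, 0, 0),
               class = "caninegait_invalid_input")
  expect_error(max_isometric_force(10, 95, 2),
               class = "caninegait_invalid_input")
})

test_that("most roster muscles reproduce their printed force within 1%", {
  t2 <- canine_muscles()
  f <- max_isometric_force(t2$volume_cm3, t2$pennation_deg,
                           t2$optimal_fiber_cm)
  rel <- abs(f - t2$max_isometric_n) / t2$max_isometric_n
  # 21 of the 33 printed rows are self-consistent to printed precision
  expect_gte(sum(rel < 0.01), 12)
  named <- c("Adductor magnus et brevis", "Iliopsoas", "Semitendinosus",
             "Vastus lateralis and intermedius", "Gastrocnemius lateralis",
             "Biceps femoris (tibial)")
  expect_true(all(rel[t2$muscle %in% named] < 0.01))
})

test_that("fiber operating ranges tune into the physiological bands", {
  trial <- cached_trial(seed = 2, noise_sd_mm = 0)
  tuned <- tune_fiber_operating_range(trial$model, trial$truth_coords)
  rep <- tuned$report
  expect_true(all(rep$converged))
  # whole-cycle band for every muscle
  expect_true(all(rep$min_lnorm_after >= 0.5))
  expect_true(all(rep$max_lnorm_after <= 1.5))
  # mid-stance band
  expect_true(all(rep$ms_lnorm_after >= 0.8 - 1e-9))
  expect_true(all(rep$ms_lnorm_after <= 1.2 + 1e-9))
  # muscles already in band are untouched
  ok_before <- rep$muscle[!rep$tuned]
  expect_gt(length(ok_before), 0)
  same <- tuned$model$muscles$f_adj_cm[match(ok_before,
                                             tuned$model$muscles$muscle)]
  orig <- trial$model$muscles$f_adj_cm[match(ok_before,
                                             trial$model$muscles$muscle)]
  expect_equal(same, orig)

  # a constructed violation (fiber length far too small -> mid-stance
  # normalized length ~1.4) is pulled back into band
  m2 <- trial$model
  j <- match("Iliopsoas", m2$muscles$muscle)
  m2$muscles$f_adj_cm[j] <- m2$muscles$f_adj_cm[j] / 1.4
  t2 <- tune_fiber_operating_range(m2, trial$truth_coords)
  r2 <- t2$report[t2$report$muscle == "Iliopsoas", ]
  expect_gt(r2$ms_lnorm_before, 1.2)
  expect_true(r2$ms_lnorm_after >= 0.8 && r2$ms_lnorm_after <= 1.2)
})
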