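test_that("age adjustment is the identity at the reference age and monotone", {
  fixture <- system.file("extdata", "vpatient_network.json",
                         package = "willisim")
  raw <- load_network(fixture)
  at40 <- build_virtual_patient(age = 40, fixture = fixture)
  expect_equal(at40$segments$E_dyn_cm2, raw$segments$E_dyn_cm2)
  at70 <- build_virtual_patient(age = 70, fixture = fixture)
  expect_true(all(at70$segments$E_dyn_cm2 > at40$segments$E_dyn_cm2))
  expect_equal(at70$segments$E_dyn_cm2 / raw$segments$E_dyn_cm2,
               rep(1.1^3, nrow(raw$segments)))
  # radii untouched; result passes validation; sex is a no-op
  expect_equal(at70$segments$r_prox_cm, raw$segments$r_prox_cm)
  expect_silent(validate_network(at70))
  female <- build_virtual_patient(age = 70, sex = "female",
                                  fixture = fixture)
  expect_equal(female$segments, at70$segments)
  expect_error(build_virtual_patient(fixture = "/nowhere.json"),
               "not found")
})

test_that("perturbed patients are deterministic, bounded, and valid", {
  net <- build_virtual_patient(age = 70)
  expect_equal(perturb_patient(net, seed = 1, cv = 0), net)
  a <- perturb_patient(net, seed = 7, cv = 0.1)
  b <- perturb_patient(net, seed = 7, cv = 0.1)
  expect_equal(a, b)
  c <- perturb_patient(net, seed = 8, cv = 0.1)
  expect_false(isTRUE(all.equal(a$segments$r_prox_cm,
                                c$segments$r_prox_cm)))
  for (s in 1:20) {
    expect_silent(validate_network(perturb_patient(net, seed = s,
                                                   cv = 0.1)))
  }
  expect_error(perturb_patient(net, 1, cv = 0.5))
})

test_that("calibration reaches the target mean pressure monotonically", {
  cal <- cached_calibration()
  expect_gte(cal$achieved_map_mmhg, 89)
  expect_lte(cal$achieved_map_mmhg, 91)
  expect_gt(cal$scale, 0.2)
  expect_lt(cal$scale, 5)
  # idempotence: recalibrating the calibrated patient to its own
  # achieved pressure moves the scale by less than 1%
  cal2 <- calibrate_map(cal$net, target_map_mmhg = cal$achieved_map_mmhg)
  expect_lt(abs(cal2$scale - 1), 0.01)
})

test_that("the calibrated baseline operates inside the autoregulation plateau", {
  base <- cached_baseline()
  plateau <- attr(load_autoregulation_curve(), "plateau")
  expect_true(base$converged)
  expect_true(all(base$beds$P_mean_mmhg >= plateau[1]))
  expect_true(all(base$beds$P_mean_mmhg <= plateau[2]))
  # every bed delivers its baseline flow within 2%
  expect_equal(base$beds$Q_mean_ml_min,
               to_ml_min(base$beds$q0), tolerance = 0.02)
})
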