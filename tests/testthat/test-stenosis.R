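host <- list(r_prox_cm = 0.25, r_dist_cm = 0.25, length_cm = 5,
             h_cm = 0.05, E_dyn_cm2 = 8e6)
spec07 <- list(segment = "h", start_offset_mm = 10, length_mm = 10,
               ratio = 0.7)

test_that("no flow, no pressure drop", {
  expect_equal(stenosis_pressure_drop(0, 0, spec07, host), 0)
})

test_that("three-term drop matches an independent hand evaluation", {
  # D0 = 0.5 cm, Ls = 1.0 cm, r = 0.7 (diameter), steady Q = 4 cm^3/s
  rho <- 1.06; mu <- 0.04; Q <- 4
  A0s <- pi * 0.25^2
  As <- A0s * (1 - 0.7)^2
  Kv <- 32 * (1 / 0.5) * (A0s / As)^2
  expected <- Kv * mu / (A0s * 0.5) * Q +
    (1.52 * rho / (2 * A0s^2)) * ((A0s / As) - 1)^2 * Q * abs(Q)
  expect_equal(stenosis_pressure_drop(Q, 0, spec07, host), expected)
  # the drop is tens of mmHg, dominated by the turbulent term
  expect_gt(to_mmhg(expected), 10)
  turb <- (1.52 * rho / (2 * A0s^2)) * ((A0s / As) - 1)^2 * Q^2
  expect_gt(turb / expected, 0.5)
  # inertial term adds Ku rho Ls / A0s * dQdt
  dQdt <- 50
  expect_equal(stenosis_pressure_drop(Q, dQdt, spec07, host),
               expected + 1.2 * rho * 1.0 / A0s * dQdt)
})

test_that("at ratio zero the turbulent term vanishes identically", {
  spec0 <- modifyList(spec07, list(ratio = 0))
  k <- stenosis_coefficients(spec0, host)
  expect_equal(k$b, 0)
  # viscous + inertial survive: Kv = 32 Ls / D0 at As = A0s
  A0s <- pi * 0.25^2
  expect_equal(k$a, 32 * (1 / 0.5) * 0.04 / (A0s * 0.5))
  expect_equal(stenosis_pressure_drop(2, 0, spec0, host), k$a * 2)
})

test_that("steady drop has odd symmetry and increases with severity", {
  Q <- seq(0.5, 6, by = 0.5)
  expect_equal(stenosis_pressure_drop(-Q, 0, spec07, host),
               -stenosis_pressure_drop(Q, 0, spec07, host))
  drops <- vapply(seq(0, 0.9, by = 0.1), function(r) {
    stenosis_pressure_drop(3, 0, modifyList(spec07, list(ratio = r)), host)
  }, 0)
  expect_true(all(diff(drops) > 0))
})

test_that("geometry uses the taper at the lesion site and rejects occlusion", {
  tapered <- modifyList(host, list(r_prox_cm = 0.4, r_dist_cm = 0.2,
                                   length_cm = 10))
  g <- stenosis_geometry(list(segment = "h", start_offset_mm = 20,
                              length_mm = 10, ratio = 0.5), tapered)
  expect_equal(g$D0, 2 * (0.4 - 0.2 * 2 / 10))
  expect_equal(g$As, g$A0s * 0.25)
  expect_equal(g$Ls, 1)
  expect_error(stenosis_pressure_drop(1, 0,
                                      modifyList(spec07, list(ratio = 1)),
                                      host),
               "occlusion")
})
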