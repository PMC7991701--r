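seg_example <- list(r_prox_cm = 0.3, r_dist_cm = 0.3, h_cm = 0.05,
                    E_dyn_cm2 = 4e6)

test_that("tube law returns the reference pressure at the reference area", {
  A0 <- segment_area0(seg_example)
  expect_equal(tube_law(A0, seg_example), 0)
  expect_equal(tube_law(A0, seg_example, p_ext = 1234), 1234)
})

test_that("tube law matches direct formula evaluation and is monotone", {
  A0 <- segment_area0(seg_example)
  beta_hand <- sqrt(pi) * 4e6 * 0.05 / ((1 - 0.25) * A0)
  expect_equal(tube_law(1.1 * A0, seg_example),
               beta_hand * (sqrt(1.1 * A0) - sqrt(A0)))
  set.seed(42)
  for (i in 1:20) {
    seg <- list(r_prox_cm = runif(1, 0.05, 1), h_cm = runif(1, 0.01, 0.1),
                E_dyn_cm2 = runif(1, 1e6, 2e7))
    seg$r_dist_cm <- seg$r_prox_cm
    A <- sort(runif(2, 0.3, 3) * segment_area0(seg))
    expect_lt(tube_law(A[1], seg), tube_law(A[2], seg))
  }
  expect_error(tube_law(-1, seg_example), "positive")
})

test_that("wave speed is consistent with the pressure-area derivative", {
  # c^2 = (A / rho) dP/dA, checked against a centred finite difference
  set.seed(7)
  rho <- 1.06
  for (i in 1:100) {
    seg <- list(r_prox_cm = runif(1, 0.05, 1), h_cm = runif(1, 0.01, 0.1),
                E_dyn_cm2 = runif(1, 1e6, 2e7))
    seg$r_dist_cm <- seg$r_prox_cm
    A <- runif(1, 0.5, 2) * segment_area0(seg)
    h <- A * 1e-6
    dPdA <- (tube_law(A + h, seg) - tube_law(A - h, seg)) / (2 * h)
    expect_equal(wave_speed(A, seg, rho), sqrt(A / rho * dPdA),
                 tolerance = 1e-7)
  }
})

test_that("reference wave speed has its closed form and grows with stiffness", {
  A0 <- segment_area0(seg_example)
  beta <- segment_beta(seg_example)
  expect_equal(wave_speed(A0, seg_example),
               sqrt(beta * sqrt(A0) / (2 * 1.06)))
  stiffer <- seg_example
  stiffer$E_dyn_cm2 <- 2 * seg_example$E_dyn_cm2
  expect_gt(wave_speed(A0, stiffer), wave_speed(A0, seg_example))
})
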