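grid <- seq(0, 1, by = 0.1)

test_that("onset detection honours direction, threshold, and the baseline", {
  flat <- rep(100, 11)
  expect_true(is.na(detect_onset(grid, flat, "flow_decrease")))
  # 2% of a 100-unit baseline: first excursion beyond 2 units counts
  dec <- 100 - c(0, 0.5, 1, 1.5, 1.9, 2.5, 8, 20, 40, 70, 100)
  expect_equal(detect_onset(grid, dec, "flow_decrease"), 0.5)
  expect_true(is.na(detect_onset(grid, dec, "flow_increase")))
  inc <- 200 - dec
  expect_equal(detect_onset(grid, inc, "flow_increase"), 0.5)
  p <- c(80, 80, 79.5, 79.2, 79.05, 78.9, 78.2, 76, 73, 70, 69)
  expect_equal(detect_onset(grid, p, "pressure_decline"), 0.5)
  expect_equal(detect_onset(grid, p, "pressure_decline",
                            pressure_tol_mmhg = 2), 0.7)
  expect_error(detect_onset(grid[-1], dec[-1], "flow_decrease"), "baseline")
})

test_that("zero detection uses the grid point past the crossing", {
  s <- c(100, 90, 70, 50, 30, 15, 6, 2, 0.5, -0.2, -0.1)
  expect_equal(detect_zero(grid, s), 0.8)
  expect_true(is.na(detect_zero(grid, rep(5, 11))))
  expect_error(detect_zero(grid, c(0, s[-1])), "baseline")
})

test_that("inversion detection is invariant to the sign convention", {
  s <- c(-30, -28, -25, -20, -12, -5, -1, 2, 20, 60, 90)
  expect_equal(detect_inversion(grid, s), 0.7)
  expect_equal(detect_inversion(grid, -s), 0.7)
  expect_true(is.na(detect_inversion(grid, abs(s) + 1)))
  expect_error(detect_inversion(grid, c(0, s[-1])), "undefined")
})

test_that("duplex grading follows the four-category precedence", {
  expect_identical(classify_ica_stenosis(300, 4.5, TRUE), "severe")
  expect_identical(classify_ica_stenosis(100, 1.2, TRUE), "no_stenosis")
  expect_identical(classify_ica_stenosis(0, 0, FALSE), "occlusion")
  expect_identical(classify_ica_stenosis(130, 2, TRUE), "moderate")
  # occlusion > severe > moderate
  expect_identical(classify_ica_stenosis(300, 5, FALSE), "occlusion")
  expect_identical(classify_ica_stenosis(124, 4, TRUE), "severe")
})

test_that("the shunt rule uses a strict 40 mmHg cutoff", {
  expect_true(shunt_decision(33))
  expect_false(shunt_decision(46))
  expect_false(shunt_decision(40))
  expect_true(shunt_decision(39.9))
  expect_error(shunt_decision(-1))
})

test_that("sweep thresholds summarise a synthetic sweep coherently", {
  sw <- data.frame(
    ratio = grid,
    q_acom_ml_min = c(130, 129.5, 129.2, 129, 128.5, 126, 118, 95, 55, 1, 0),
    q_pcom_ipsi_ml_min = c(115, 115.3, 115.6, 116, 117, 120, 128, 150, 185,
                           225, 235),
    q_a1_ipsi_ml_min = c(-30, -29, -29, -28, -27, -25, -20, -5, 30, 80, 95),
    p_mca_ipsi_mmhg = c(71, 71, 70.9, 70.9, 70.8, 70.6, 69.9, 68, 65, 62, 61))
  th <- sweep_thresholds(sw)
  expect_equal(th$acom_decrease_onset, 0.5)
  expect_equal(th$pcom_ipsi_increase_onset, 0.5)
  expect_equal(th$mca_pressure_decline_onset, 0.6)
  expect_equal(th$acom_zero, 0.9)
  expect_equal(th$a1_inversion, 0.8)
  expect_equal(th$a1_last_upright, 0.7)
  expect_equal(nrow(th$sensitivity), 11)
})
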