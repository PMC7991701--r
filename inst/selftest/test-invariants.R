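# Fast invariant suite for the command-line `selftest` subcommand.
# Self-contained (no fixtures beyond the installed package data).

library(willisim)

simple_net <- function(co_ml_min, Pv = 0) {
  segs <- data.frame(id = "v", name = "v", length_cm = 20,
                     r_prox_cm = 0.5, r_dist_cm = 0.5, h_cm = 0.05,
                     E_dyn_cm2 = 4e6, alpha = 1,
                     K_R = 22 * pi * 0.04 / 1.06)
  structure(list(fixture_version = "selftest", reference_age = 40,
                 blood = list(rho = 1.06, mu = 0.04),
                 inflow = list(segment = "v",
                               cardiac_output_ml_min = co_ml_min,
                               period_s = 0.9, systole_s = 0.3),
                 segments = segs, junctions = list(),
                 terminals = data.frame(segment = "v", kind = "windkessel",
                                        R1 = 100, R2 = 1000, C = 1e-4,
                                        Pv = Pv, q0_ml_min = NA_real_),
                 stenoses = data.frame(segment = character(),
                                       start_offset_mm = numeric(),
                                       length_mm = numeric(),
                                       ratio = numeric()),
                 clamps = data.frame(segment = character(),
                                     position_mm = numeric())),
            class = "arterial_network")
}

test_that("rest state is preserved", {
  model <- discretise_network(simple_net(0), solver_config(ramp_cycles = 0))
  st <- advance_cycle(NULL, model)
  expect_lt(max(abs(st$A - init_state(model)$A)), 1e-10)
  expect_lt(max(abs(st$Q)), 1e-10)
})

test_that("tube law and wave speed are mutually consistent", {
  seg <- list(r_prox_cm = 0.3, r_dist_cm = 0.3, h_cm = 0.05,
              E_dyn_cm2 = 4e6)
  A <- 1.2 * segment_area0(seg)
  h <- A * 1e-6
  dPdA <- (tube_law(A + h, seg) - tube_law(A - h, seg)) / (2 * h)
  expect_equal(wave_speed(A, seg), sqrt(A / 1.06 * dPdA),
               tolerance = 1e-7)
})

test_that("stenosis element has odd symmetry and severity monotonicity", {
  host <- list(r_prox_cm = 0.25, r_dist_cm = 0.25, length_cm = 5,
               h_cm = 0.05, E_dyn_cm2 = 8e6)
  spec <- list(segment = "h", start_offset_mm = 10, length_mm = 10,
               ratio = 0.6)
  expect_equal(stenosis_pressure_drop(-3, 0, spec, host),
               -stenosis_pressure_drop(3, 0, spec, host))
  d <- vapply(seq(0, 0.9, 0.1), function(r)
    stenosis_pressure_drop(3, 0, modifyList(spec, list(ratio = r)), host),
    0)
  expect_true(all(diff(d) > 0))
})

test_that("windkessel terminal relaxes to its analytic level", {
  st <- list(Pc = 0)
  for (i in 1:20000) st <- windkessel_step(st, 2, 1e-3, 50, 800, 2e-4,
                                           0)$state
  expect_equal(st$Pc, 800 * 2, tolerance = 1e-6)
})

test_that("autoregulation curve fixture keeps its plateau", {
  curve <- load_autoregulation_curve()
  plateau <- attr(curve, "plateau")
  p <- seq(plateau[1], plateau[2], by = 1)
  expect_true(all(abs(curve(p) - 1) < 0.02))
  expect_true(all(diff(curve(seq(0, 200, 1))) >= -1e-12))
})

test_that("decision rules match their definitions", {
  expect_identical(classify_ica_stenosis(300, 4.5, TRUE), "severe")
  expect_identical(classify_ica_stenosis(100, 1.2, TRUE), "no_stenosis")
  expect_identical(classify_ica_stenosis(0, 0, FALSE), "occlusion")
  expect_false(shunt_decision(40))
  expect_true(shunt_decision(39))
})
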