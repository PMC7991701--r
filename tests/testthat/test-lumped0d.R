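test_that("inflow waveform is periodic, nonnegative, and mean-preserving", {
  t <- seq(0, 0.9, length.out = 20001)[-20001]
  q <- inflow_waveform(t)
  expect_true(all(q >= 0))
  # cycle mean equals the configured cardiac output (5 L/min)
  expect_equal(mean(q), from_ml_min(5000), tolerance = 1e-8)
  expect_equal(inflow_waveform(c(0.1, 0.4)),
               inflow_waveform(c(0.1, 0.4) + 0.9))
  # diastole carries zero flow for the half-sine systolic shape
  expect_true(all(inflow_waveform(seq(0.31, 0.89, by = 0.01)) == 0))
})

test_that("windkessel terminal reaches its analytic steady state", {
  R1 <- 100; R2 <- 2000; C <- 1e-4; Pv <- 5000
  Q <- 3
  st <- list(Pc = Pv)
  for (i in 1:40000) {
    out <- windkessel_step(st, Q, 1e-3, R1, R2, C, Pv)
    st <- out$state
  }
  expect_equal(out$pressure, Pv + (R1 + R2) * Q, tolerance = 1e-6)
  # at rest with the compliance at venous pressure nothing moves
  out0 <- windkessel_step(list(Pc = Pv), 0, 1e-3, R1, R2, C, Pv)
  expect_equal(out0$pressure, Pv)
})

test_that("windkessel relaxation follows the closed-form R2*C decay", {
  R1 <- 0; R2 <- 1500; C <- 2e-4; Pv <- 0
  P0 <- 1e5
  st <- list(Pc = P0)
  dt <- 1e-4
  n <- 3000
  for (i in seq_len(n)) st <- windkessel_step(st, 0, dt, R1, R2, C, Pv)$state
  # backward-Euler decay matches exp(-t / (R2 C)) as dt -> 0
  expect_equal(st$Pc, P0 * exp(-n * dt / (R2 * C)), tolerance = 1e-3)
})

test_that("autoregulation curve satisfies its shape invariants", {
  curve <- load_autoregulation_curve()
  plateau <- attr(curve, "plateau")
  expect_equal(curve(0), 0)
  p_in <- seq(plateau[1], plateau[2], by = 1)
  expect_true(all(abs(curve(p_in) - 1) < 0.02))
  p <- seq(0, 200, by = 1)
  expect_true(all(diff(curve(p)) >= -1e-12))
  expect_equal(autoregulation_target(90, curve, q0 = 2.5), 2.5,
               tolerance = 0.02)
  expect_equal(autoregulation_target(0, curve, q0 = 2.5), 0)
})

test_that("resistance adaptation recognises its fixed point", {
  curve <- load_autoregulation_curve()
  Pv <- from_mmhg(5)
  P <- from_mmhg(90)                      # inside the plateau
  q0 <- 2.5
  beds <- data.frame(terminal = "bed", R = (P - Pv) / q0, Pv = Pv, q0 = q0)
  m <- data.frame(terminal = "bed", P_mean = P, Q_mean = q0)
  ad <- adapt_resistances(m, beds, curve)
  expect_true(ad$converged)
  expect_equal(ad$beds$R, beds$R, tolerance = 1e-9)
  # off the fixed point the update moves toward it; kappa = 0 freezes
  beds2 <- beds; beds2$R <- beds$R * 2
  ad2 <- adapt_resistances(m, beds2, curve, kappa = 0.5)
  expect_false(ad2$converged)
  expect_lt(ad2$beds$R, beds2$R)
  ad0 <- adapt_resistances(m, beds2, curve, kappa = 0)
  expect_equal(ad0$beds$R, beds2$R)
  expect_false(ad0$converged)
})

test_that("beds whose target flow vanishes are flagged, not divided by", {
  # a pathological curve that is exactly zero below 50 mmHg
  dead_zone <- function(p) ifelse(p < 50, 0, 1)
  beds <- data.frame(terminal = "bed", R = 1e4, Pv = 0, q0 = 2)
  m <- data.frame(terminal = "bed", P_mean = from_mmhg(20), Q_mean = 0)
  ad <- adapt_resistances(m, beds, dead_zone)
  expect_identical(ad$non_autoregulable, "bed")
  expect_equal(ad$beds$R, beds$R)
})
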