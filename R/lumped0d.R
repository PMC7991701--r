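#' Cardiac inflow waveform
#'
#' Open-loop prescribed aortic-root inflow: a half-sine systolic pulse
#' of duration `systole_s` followed by zero diastolic flow, normalised
#' so the cycle mean equals the configured cardiac output.  The heart
#' itself is not modelled; the mean-pressure calibration absorbs the
#' difference from a closed-loop source.
#'
#' @param t time in s (vectorised), t >= 0
#' @param cardiac_output_ml_min cycle-mean flow, mL/min
#' @param period_s cardiac period T, s
#' @param systole_s systolic (nonzero-flow) duration, s
#' @return inflow in cm^3/s, T-periodic and nonnegative
#' @export
inflow_waveform <- function(t, cardiac_output_ml_min = 5000,
                            period_s = 0.9, systole_s = 0.3) {
  stopifnot(all(t >= 0), period_s > 0, systole_s > 0, systole_s < period_s)
  q_mean <- from_ml_min(cardiac_output_ml_min)
  q_peak <- q_mean * period_s * pi / (2 * systole_s)
  tau <- t %% period_s
  ifelse(tau < systole_s, q_peak * sin(pi * tau / systole_s), 0)
}

#' Advance an RCR Windkessel terminal one time step
#'
#' Three-element Windkessel: proximal resistance R1 in series with a
#' parallel compliance C and distal resistance R2 draining to venous
#' pressure Pv.  The compliance pressure Pc obeys
#' dPc/dt = (Q - (Pc - Pv)/R2) / C and is advanced implicitly
#' (backward Euler); the boundary pressure seen by the 1D domain is
#' Pc + R1 Q.
#'
#' This is the reference (pure R) implementation used for testing; the
#' time stepper applies the same update inside the compiled solver.
#'
#' @param state list with element `Pc` (compliance pressure, dyn/cm^2)
#' @param Q_in inflow into the terminal, cm^3/s
#' @param dt time step, s (> 0)
#' @param R1,R2 resistances, dyn s/cm^5
#' @param C compliance, cm^5/dyn
#' @param Pv venous pressure, dyn/cm^2
#' @return list with `state` (updated) and `pressure` (boundary
#'   pressure, dyn/cm^2)
#' @export
windkessel_step <- function(state, Q_in, dt, R1, R2, C, Pv) {
  stopifnot(dt > 0, C > 0, R2 > 0)
  Pc <- (state$Pc + (dt / C) * (Q_in + Pv / R2)) / (1 + dt / (R2 * C))
  list(state = list(Pc = Pc), pressure = Pc + R1 * Q_in)
}

#' Load the cerebral autoregulation curve fixture
#'
#' The flow rate--pressure relationship of the cerebral beds is stored
#' as tabular anchor points (pressure in mmHg, flow as a fraction of
#' the bed baseline) and interpolated by a monotone Hermite spline, so
#' the curve is smooth, nondecreasing, exactly 1 on the plateau and 0
#' at zero pressure (classic Lassen shape).
#'
#' @param path CSV file with columns `pressure_mmhg`, `flow_fraction`;
#'   defaults to the fixture shipped with the package
#' @return object of class `autoregulation_curve`: a function
#'   q_fraction(P_mmhg) with the anchor table and plateau range
#'   attached as attributes
#' @export
load_autoregulation_curve <- function(path = system.file(
                                        "extdata", "autoregulation_curve.csv",
                                        package = "willisim")) {
  anchors <- utils::read.csv(path)
  stopifnot(all(c("pressure_mmhg", "flow_fraction") %in% names(anchors)))
  if (is.unsorted(anchors$pressure_mmhg, strictly = TRUE)) {
    stop("autoregulation anchors must have strictly increasing pressure")
  }
  if (is.unsorted(anchors$flow_fraction)) {
    stop("autoregulation anchors must be nondecreasing in flow")
  }
  f <- stats::splinefun(anchors$pressure_mmhg, anchors$flow_fraction,
                        method = "monoH.FC")
  pmax_anchor <- max(anchors$pressure_mmhg)
  fmax <- max(anchors$flow_fraction)
  slope_end <- f(pmax_anchor, deriv = 1)
  curve <- function(p_mmhg) {
    p <- pmin(pmax(p_mmhg, 0), pmax_anchor)
    out <- f(p)
    # linear continuation above the last anchor keeps monotonicity
    over <- p_mmhg > pmax_anchor
    out[over] <- fmax + slope_end * (p_mmhg[over] - pmax_anchor)
    pmax(out, 0)
  }
  plateau <- range(anchors$pressure_mmhg[abs(anchors$flow_fraction - 1) < 1e-9])
  structure(curve,
            class = c("autoregulation_curve", "function"),
            anchors = anchors, plateau = plateau)
}

#' Target cerebral bed flow at a given perfusion pressure
#'
#' Evaluates the autoregulation target q_target(P) = q0 * f(P) for a
#' bed with baseline flow q0, where f is the normalised curve.
#'
#' @param P_mean mean perfusion pressure at the bed inlet, mmHg (>= 0)
#' @param curve an [load_autoregulation_curve()] object
#' @param q0 baseline bed flow (any flow unit; the result has the same
#'   unit)
#' @return target flow at `P_mean`
#' @export
autoregulation_target <- function(P_mean, curve, q0 = 1) {
  stopifnot(all(P_mean >= 0))
  q0 * curve(P_mean)
}

#' One autoregulation resistance update
#'
#' Relaxed fixed-point update of the cerebral bed resistances toward
#' the resistance that would deliver the autoregulation target flow at
#' the currently observed bed pressure:
#' R <- R (1 - kappa) + kappa (P_mean - Pv) / q_target(P_mean).
#' The outer loop ([run_autoregulated()]) alternates this update with
#' periodic re-solves of the 1D network until the resistances settle.
#'
#' @param metrics data.frame with one row per bed: columns `terminal`
#'   (segment id), `P_mean` (dyn/cm^2, cycle-mean bed-inlet pressure),
#'   `Q_mean` (cm^3/s, cycle-mean bed flow)
#' @param beds data.frame of bed definitions: columns `terminal`, `R`
#'   (current total resistance, dyn s/cm^5), `Pv` (dyn/cm^2), `q0`
#'   (cm^3/s)
#' @param curve normalised autoregulation curve
#' @param kappa relaxation factor in (0, 1]
#' @param tol relative fixed-point residual below which the beds are
#'   considered converged
#' @return list: `beds` (with updated `R`), `converged` (logical: the
#'   fixed-point residual max |R* - R| / R was below `tol` before the
#'   update, so it holds irrespective of `kappa`), `max_rel_change`,
#'   and `non_autoregulable` (character vector of bed ids whose target
#'   flow vanished at positive pressure)
#' @export
adapt_resistances <- function(metrics, beds, curve, kappa = 0.5, tol = 1e-3) {
  stopifnot(kappa >= 0, kappa <= 1)
  m <- metrics[match(beds$terminal, metrics$terminal), , drop = FALSE]
  if (any(is.na(m$P_mean))) {
    stop("adapt_resistances: metrics missing for some beds")
  }
  p_mmhg <- to_mmhg(m$P_mean)
  q_tgt <- autoregulation_target(pmax(p_mmhg, 0), curve, beds$q0)
  bad <- q_tgt <= 0 & p_mmhg > 0
  R_star <- beds$R
  ok <- !bad & q_tgt > 0
  R_star[ok] <- (m$P_mean[ok] - beds$Pv[ok]) / q_tgt[ok]
  # cap: beds whose target flow vanished keep (capped) resistance
  R_star[bad] <- beds$R[bad]
  residual <- abs(R_star - beds$R) / beds$R
  beds$R <- beds$R * (1 - kappa) + kappa * R_star
  list(beds = beds,
       converged = max(residual) < tol,
       max_rel_change = kappa * max(residual),
       non_autoregulable = beds$terminal[bad])
}
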