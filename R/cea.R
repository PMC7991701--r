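#' Carotid stump pressure
#'
#' Cycle-mean pressure at the grid node immediately distal to the
#' clamp on the ICA stump side.  Errors if the run carries no clamp.
#'
#' @param state converged `solver_state`
#' @param model the `solver_model` of the run
#' @param segment id of the clamped segment; defaults to the single
#'   clamped segment of the model
#' @return mean stump pressure in mmHg
#' @export
measure_csp <- function(state, model, segment = NULL) {
  is_clamp <- vapply(model$couplings, function(cc)
    cc$type == 2L && identical(cc$meta, "clamp"), TRUE)
  if (!any(is_clamp)) stop("measure_csp: no clamp installed in this run")
  cl <- model$couplings[is_clamp]
  if (!is.null(segment)) {
    cl <- Filter(function(cc) cc$parent == segment, cl)
    if (!length(cl)) stop("measure_csp: no clamp on segment ", segment)
  }
  # distal face of the clamp = proximal node of the second piece
  node <- model$offset[cl[[1]]$seg[2]]
  to_mmhg(attr(state, "mean_P")[node])
}

#' Clamp + contralateral stenosis sweep
#'
#' The carotid endarterectomy protocol: clamp the ipsilateral ICA,
#' install a stenosis on the contralateral ICA (by default a 10 mm
#' lesion starting 10 mm above the carotid bifurcation), and for each
#' requested stenosis ratio run the autoregulation-converged periodic
#' solve and extract the stump pressure, communicating-artery flows
#' and cerebral bed pressures.
#'
#' Sign conventions of the reported flows (recorded in the result's
#' metadata): Acom positive = contralateral to ipsilateral; Pcom
#' positive = posterior to anterior; A1 positive = from the carotid
#' terminus toward the Acom junction.
#'
#' @param patient a calibrated `arterial_network`
#' @param side clamp (= operated) side, "left" or "right"; the
#'   stenosis goes on the opposite ICA
#' @param ratios stenosis ratios to simulate (diameter-based lumen
#'   reduction, in `[0, 1]`)
#' @param config a [solver_config()]
#' @param areg an [autoregulation_config()]
#' @param curve autoregulation curve fixture
#' @param clamp_position_mm clamp position above the bifurcation
#' @param stenosis_start_mm,stenosis_length_mm lesion geometry
#' @param warm_start reuse each ratio's converged bed resistances to
#'   start the next ratio (the converged fixed point is unaffected)
#' @param verbose print per-ratio progress to stderr
#' @return a `data.frame` of class `sweep_result`, one row per ratio:
#'   `ratio`, `csp_mmhg`, `q_acom_ml_min`, `q_pcom_ipsi_ml_min`,
#'   `q_pcom_contra_ml_min`, `q_a1_ipsi_ml_min`, `p_aca_ipsi_mmhg`,
#'   `p_mca_ipsi_mmhg`, `p_pca_ipsi_mmhg`, `converged`,
#'   `autoreg_converged`; metadata in `attr(, "meta")`
#' @export
run_cea_sweep <- function(patient, side = c("left", "right"),
                          ratios = seq(0, 1, by = 0.1),
                          config = solver_config(),
                          areg = autoregulation_config(),
                          curve = load_autoregulation_curve(),
                          clamp_position_mm = 10,
                          stenosis_start_mm = 10,
                          stenosis_length_mm = 10,
                          warm_start = TRUE,
                          verbose = FALSE) {
  side <- match.arg(side)
  stopifnot(all(ratios >= 0), all(ratios <= 1))
  ratios <- sort(unique(ratios))
  ipsi <- if (side == "left") "L" else "R"
  contra <- if (side == "left") "R" else "L"
  seg_ipsi_ica <- paste0(ipsi, "_ICA")
  seg_contra_ica <- paste0(contra, "_ICA")
  # stored orientations: Acom runs R -> L; Pcom runs posterior ->
  # anterior; A1 runs carotid terminus -> Acom junction
  acom_sign <- if (contra == "R") 1 else -1
  clamped <- apply_clamp(patient, list(segment = seg_ipsi_ica,
                                       position_mm = clamp_position_mm))
  rows <- vector("list", length(ratios))
  bed_R <- NULL
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    net_r <- apply_stenosis(clamped,
                            list(segment = seg_contra_ica,
                                 start_offset_mm = stenosis_start_mm,
                                 length_mm = stenosis_length_mm,
                                 ratio = r))
    run <- run_autoregulated(net_r, config, areg, curve, bed_R = bed_R)
    if (warm_start) bed_R <- stats::setNames(run$beds$R, run$beds$terminal)
    st <- run$state; mdl <- run$model
    rows[[i]] <- data.frame(
      ratio = r,
      csp_mmhg = measure_csp(st, mdl, seg_ipsi_ica),
      q_acom_ml_min = acom_sign * mean_flow_at(st, mdl, "Acom"),
      q_pcom_ipsi_ml_min = mean_flow_at(st, mdl, paste0(ipsi, "_Pcom")),
      q_pcom_contra_ml_min = mean_flow_at(st, mdl, paste0(contra, "_Pcom")),
      q_a1_ipsi_ml_min = mean_flow_at(st, mdl, paste0(ipsi, "_ACA_A1")),
      p_aca_ipsi_mmhg = mean_pressure_at(st, mdl, paste0(ipsi, "_ACA_A2"),
                                         "distal"),
      p_mca_ipsi_mmhg = mean_pressure_at(st, mdl, paste0(ipsi, "_MCA"),
                                         "distal"),
      p_pca_ipsi_mmhg = mean_pressure_at(st, mdl, paste0(ipsi, "_PCA_P2"),
                                         "distal"),
      converged = run$periodic_converged,
      autoreg_converged = run$converged)
    if (verbose) {
      message(sprintf("ratio %.0f%%: CSP %.1f mmHg (autoreg %s in %d iters)",
                      100 * r, rows[[i]]$csp_mmhg,
                      if (run$converged) "converged" else "NOT converged",
                      run$outer_iters))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- list(
    side = side,
    stenosis_basis = "diameter",
    clamp_position_mm = clamp_position_mm,
    stenosis_start_mm = stenosis_start_mm,
    stenosis_length_mm = stenosis_length_mm,
    fixture_version = patient$fixture_version,
    sign_conventions = c(
      acom = "positive = contralateral to ipsilateral",
      pcom = "positive = posterior to anterior",
      a1 = "positive = carotid terminus toward Acom junction"))
  class(out) <- c("sweep_result", "data.frame")
  out
}

# common checks for the series detectors
.check_series <- function(ratios, values) {
  stopifnot(length(ratios) == length(values))
  o <- order(ratios)
  ratios <- ratios[o]; values <- values[o]
  if (abs(ratios[1]) > 1e-12) {
    stop("series must include the 0% stenosis baseline")
  }
  list(ratios = ratios, values = values)
}

#' Onset of a deviation from the unstenosed baseline
#'
#' Smallest grid ratio at which the metric deviates from its
#' 0%-stenosis baseline beyond the operational threshold, in the
#' stated direction: flows by more than `flow_tol` (fraction of the
#' baseline magnitude), pressures by more than `pressure_tol_mmhg`.
#' These thresholds stand in for a visual "begins to change" reading
#' of a plotted curve and are reported alongside results.
#'
#' @param ratios stenosis ratios of the series (must include 0)
#' @param values metric values (flow in any fixed unit for the flow
#'   kinds; mmHg for `pressure_decline`)
#' @param kind "flow_decrease", "flow_increase" or "pressure_decline"
#' @param flow_tol relative flow threshold (default 0.02)
#' @param pressure_tol_mmhg absolute pressure threshold (default 1)
#' @return the detected grid ratio, or NA if the metric never deviates
#' @export
detect_onset <- function(ratios, values,
                         kind = c("flow_decrease", "flow_increase",
                                  "pressure_decline"),
                         flow_tol = 0.02, pressure_tol_mmhg = 1) {
  kind <- match.arg(kind)
  s <- .check_series(ratios, values)
  base <- s$values[1]
  hit <- switch(kind,
    flow_decrease = s$values < base - flow_tol * abs(base),
    flow_increase = s$values > base + flow_tol * abs(base),
    pressure_decline = s$values < base - pressure_tol_mmhg)
  if (!any(hit)) return(NA_real_)
  s$ratios[which(hit)[1]]
}

#' First ratio at which a flow has vanished
#'
#' Smallest grid ratio where the flow magnitude falls below
#' `tol` times the 0%-baseline magnitude.
#'
#' @inheritParams detect_onset
#' @param tol relative magnitude threshold (default 0.01)
#' @return the detected grid ratio, or NA if the flow never vanishes
#' @export
detect_zero <- function(ratios, values, tol = 0.01) {
  s <- .check_series(ratios, values)
  base <- abs(s$values[1])
  if (base == 0) stop("detect_zero: zero baseline flow")
  hit <- abs(s$values) < tol * base
  if (!any(hit)) return(NA_real_)
  s$ratios[which(hit)[1]]
}

#' First ratio at which a signed flow has inverted
#'
#' Smallest grid ratio whose flow sign is opposite to the 0%-baseline
#' sign.  Invariant under flipping the sign convention of the series.
#'
#' @inheritParams detect_onset
#' @param tol minimum baseline magnitude for the direction to be
#'   defined (same unit as `values`)
#' @return the detected grid ratio, or NA if the flow never inverts
#' @export
detect_inversion <- function(ratios, values, tol = 1e-6) {
  s <- .check_series(ratios, values)
  if (abs(s$values[1]) < tol) {
    stop("detect_inversion: baseline flow direction undefined")
  }
  s0 <- sign(s$values[1])
  hit <- s$values * s0 < 0
  if (!any(hit)) return(NA_real_)
  s$ratios[which(hit)[1]]
}

#' Detected thresholds of a sweep
#'
#' Applies the operational detectors to a [run_cea_sweep()] result:
#' Acom flow-decrease onset, ipsilateral Pcom flow-increase onset,
#' ipsilateral MCA bed pressure-decline onset, Acom flow vanishing,
#' and ipsilateral A1 flow inversion (with the last grid ratio that
#' retains the baseline direction).
#'
#' @param sweep a `sweep_result`
#' @param flow_tol,pressure_tol_mmhg,zero_tol detector thresholds, see
#'   [detect_onset()] and [detect_zero()]
#' @return named list of grid ratios (NA where never detected), the
#'   detector criteria used, and a one-grid-step `sensitivity` table
#'   (each criterion statistic normalised by its threshold at every
#'   grid ratio, for transparency about detection margins)
#' @export
sweep_thresholds <- function(sweep, flow_tol = 0.02, pressure_tol_mmhg = 1,
                             zero_tol = 0.01) {
  r <- sweep$ratio
  inv <- detect_inversion(r, sweep$q_a1_ipsi_ml_min)
  last_upright <- if (is.na(inv)) max(r) else max(r[r < inv])
  # one-grid-step sensitivity: each criterion statistic, normalised by
  # its threshold, on the two grid points either side of the detection
  stat <- function(values, base, thr) (values - base) / thr
  acom_dev <- stat(abs(sweep$q_acom_ml_min[1]) - abs(sweep$q_acom_ml_min),
                   0, flow_tol * abs(sweep$q_acom_ml_min[1]))
  pcom_dev <- stat(sweep$q_pcom_ipsi_ml_min, sweep$q_pcom_ipsi_ml_min[1],
                   flow_tol * abs(sweep$q_pcom_ipsi_ml_min[1]))
  mca_dev <- stat(sweep$p_mca_ipsi_mmhg[1] - sweep$p_mca_ipsi_mmhg,
                  0, pressure_tol_mmhg)
  sens <- data.frame(ratio = r, acom_decrease = acom_dev,
                     pcom_increase = pcom_dev, mca_decline = mca_dev)
  list(
    acom_decrease_onset = detect_onset(r, abs(sweep$q_acom_ml_min),
                                       "flow_decrease", flow_tol),
    pcom_ipsi_increase_onset = detect_onset(r, sweep$q_pcom_ipsi_ml_min,
                                            "flow_increase", flow_tol),
    mca_pressure_decline_onset = detect_onset(r, sweep$p_mca_ipsi_mmhg,
                                              "pressure_decline",
                                              pressure_tol_mmhg =
                                                pressure_tol_mmhg),
    acom_zero = detect_zero(r, sweep$q_acom_ml_min, zero_tol),
    a1_inversion = inv,
    a1_last_upright = last_upright,
    criteria = list(flow_tol = flow_tol,
                    pressure_tol_mmhg = pressure_tol_mmhg,
                    zero_tol = zero_tol),
    sensitivity = sens)
}

#' Duplex ultrasound grading of ICA stenosis
#'
#' Four-category carotid duplex classification: "occlusion" when the
#' ICA shows no flow; otherwise "severe" (70--99%) when the ICA/CCA
#' peak-systolic-velocity ratio is 4 or higher; otherwise "moderate"
#' (50--69%) when the ICA PSV is 125 cm/s or higher; otherwise
#' "no_stenosis".
#'
#' @param psv_ica ICA peak systolic velocity, cm/s
#' @param psv_ratio_ica_cca ICA/CCA PSV ratio
#' @param flow_present logical: any flow in the ICA
#' @return one of "no_stenosis", "moderate", "severe", "occlusion"
#' @export
classify_ica_stenosis <- function(psv_ica, psv_ratio_ica_cca,
                                  flow_present = TRUE) {
  stopifnot(psv_ica >= 0, psv_ratio_ica_cca >= 0)
  if (!flow_present) return("occlusion")
  if (psv_ratio_ica_cca >= 4) return("severe")
  if (psv_ica >= 125) return("moderate")
  "no_stenosis"
}

#' Intraoperative shunt decision rule
#'
#' A carotid shunt is indicated when the mean stump pressure is below
#' 40 mmHg (strict inequality: exactly 40 mmHg does not shunt).
#'
#' @param mean_csp_mmhg mean carotid stump pressure, mmHg (>= 0)
#' @param threshold_mmhg decision threshold (default 40)
#' @return logical: TRUE if a shunt is indicated
#' @export
shunt_decision <- function(mean_csp_mmhg, threshold_mmhg = 40) {
  stopifnot(all(mean_csp_mmhg >= 0))
  mean_csp_mmhg < threshold_mmhg
}
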