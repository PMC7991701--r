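#' Construct the virtual patient network
#'
#' Loads the shipped population-average arterial network fixture and
#' applies the age adjustment: vessel stiffness (Young's modulus) is
#' scaled by `(1 + stiffening_per_decade)^((age - reference_age)/10)`
#' relative to the fixture's reference age; radii are untouched.  The
#' `sex` argument is accepted for interface completeness but is a
#' no-op on the default fixture (which is not sex-stratified).
#'
#' @param age patient age in years (default 70)
#' @param sex "male" or "female"; no effect on the default fixture
#' @param fixture path to the network JSON (defaults to the shipped
#'   fixture)
#' @param stiffening_per_decade fractional stiffness increase per
#'   decade of age above the reference (default 0.10)
#' @return an `arterial_network` (uncalibrated)
#' @export
build_virtual_patient <- function(age = 70, sex = c("male", "female"),
                                  fixture = system.file(
                                    "extdata", "vpatient_network.json",
                                    package = "willisim"),
                                  stiffening_per_decade = 0.10) {
  sex <- match.arg(sex)
  if (!nzchar(fixture) || !file.exists(fixture)) {
    stop("network fixture not found: ", fixture)
  }
  net <- load_network(fixture)
  decades <- (age - net$reference_age) / 10
  net$segments$E_dyn_cm2 <- net$segments$E_dyn_cm2 *
    (1 + stiffening_per_decade)^decades
  net$age <- age
  net$sex <- sex
  validate_network(net)
  net
}

#' Converged mean arterial pressure at the aortic root
#'
#' Convenience wrapper: runs the (Windkessel-terminated) network to a
#' periodic regime and reports the cycle-mean pressure at the aortic
#' root (proximal node of the inflow segment).
#'
#' @param net an `arterial_network`
#' @param config a [solver_config()]
#' @param resistance_scale global terminal resistance multiplier
#' @param state optional warm-start `solver_state`
#' @return list: `map_mmhg`, `state`, `model`, `report`
#' @export
converged_map <- function(net, config = solver_config(),
                          resistance_scale = 1, state = NULL) {
  model <- discretise_network(net, config, resistance_scale)
  run <- run_to_periodic(state, model, config)
  map <- mean_pressure_at(run$state, model, net$inflow$segment, "proximal")
  list(map_mmhg = map, state = run$state, model = model,
       report = run$report)
}

#' Calibrate terminal resistances to a target mean arterial pressure
#'
#' Finds a single global scale factor, applied jointly to R1 and R2 of
#' every terminal, such that the converged cycle-mean aortic-root
#' pressure matches the target.  The mean pressure is strictly
#' increasing in the scale factor (at fixed cardiac output the mean
#' level is resistance-determined), so a bracketing secant/bisection
#' search on scale in `[0.2, 5]` converges in a handful of periodic
#' runs, each warm-started from the previous one.
#'
#' @param net an `arterial_network` with no clamp installed
#' @param target_map_mmhg calibration target, mmHg (default 90)
#' @param tolerance_mmhg acceptable |achieved - target| (default 1)
#' @param config a [solver_config()]
#' @param max_iter maximum scale updates
#' @return list: `net` (with scaled terminal R1, R2), `scale`,
#'   `achieved_map_mmhg`, `n_runs`
#' @export
calibrate_map <- function(net, target_map_mmhg = 90, tolerance_mmhg = 1,
                          config = solver_config(), max_iter = 12) {
  if (nrow(net$clamps) > 0) {
    stop("calibrate_map: network must not carry a clamp")
  }
  lo <- 0.2; hi <- 5
  state <- NULL
  s <- 1
  evals <- list()
  map_at <- function(scale, warm) {
    r <- converged_map(net, config, scale, warm)
    r
  }
  r <- map_at(s, state); state <- r$state
  n_runs <- 1
  repeat {
    err <- r$map_mmhg - target_map_mmhg
    evals[[length(evals) + 1L]] <- c(s, r$map_mmhg)
    if (abs(err) <= tolerance_mmhg * 0.5 || n_runs >= max_iter) break
    if (err > 0) hi <- min(hi, s) else lo <- max(lo, s)
    if (length(evals) >= 2) {
      e2 <- evals[[length(evals)]]; e1 <- evals[[length(evals) - 1L]]
      slope <- (e2[2] - e1[2]) / (e2[1] - e1[1])
      s_new <- if (is.finite(slope) && slope > 0) {
        s - err / slope
      } else {
        (lo + hi) / 2
      }
    } else {
      # first correction: mean pressure roughly proportional to scale
      s_new <- s * target_map_mmhg / r$map_mmhg
    }
    if (s_new <= lo || s_new >= hi) s_new <- (lo + hi) / 2
    s <- s_new
    r <- map_at(s, state); state <- r$state
    n_runs <- n_runs + 1
  }
  if (abs(r$map_mmhg - target_map_mmhg) > tolerance_mmhg) {
    stop(sprintf(paste0("calibration failed: achieved %.2f mmHg for target ",
                        "%.2f mmHg within scale bracket [0.2, 5]"),
                 r$map_mmhg, target_map_mmhg))
  }
  net$terminals$R1 <- net$terminals$R1 * s
  net$terminals$R2 <- net$terminals$R2 * s
  net$calibration <- list(scale = s, achieved_map_mmhg = r$map_mmhg,
                          target_map_mmhg = target_map_mmhg)
  list(net = net, scale = s, achieved_map_mmhg = r$map_mmhg,
       n_runs = n_runs)
}

#' Randomly perturbed virtual patient
#'
#' Multiplies radii, stiffness and terminal resistances by independent
#' lognormal factors with coefficient of variation `cv`.  Deterministic
#' given `seed`; `cv = 0` returns the input unchanged.  Used for
#' robustness testing of the protocol, not by the default analyses.
#'
#' @param net an `arterial_network`
#' @param seed integer RNG seed
#' @param cv coefficient of variation in `[0, 0.3]`
#' @return a perturbed `arterial_network`
#' @export
perturb_patient <- function(net, seed, cv = 0.1) {
  stopifnot(cv >= 0, cv <= 0.3)
  if (cv == 0) return(net)
  sdlog <- sqrt(log(1 + cv^2))
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) saved <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", saved, envir = globalenv()))
  set.seed(seed)
  draw <- function(n) exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  ns <- nrow(net$segments)
  f_r <- draw(ns)
  net$segments$r_prox_cm <- net$segments$r_prox_cm * f_r
  net$segments$r_dist_cm <- net$segments$r_dist_cm * f_r
  net$segments$E_dyn_cm2 <- net$segments$E_dyn_cm2 * draw(ns)
  nt <- nrow(net$terminals)
  f_R <- draw(nt)
  net$terminals$R1 <- net$terminals$R1 * f_R
  net$terminals$R2 <- net$terminals$R2 * f_R
  validate_network(net)
  net
}

#' Autoregulation outer-loop configuration
#'
#' @param kappa relaxation factor of the resistance update, in (0, 1]
#' @param tol relative resistance change below which the loop stops
#' @param max_iter maximum outer iterations
#' @return list of class `autoregulation_config`
#' @export
autoregulation_config <- function(kappa = 0.5, tol = 1e-3, max_iter = 20) {
  stopifnot(kappa >= 0, kappa <= 1, tol > 0, max_iter >= 1)
  structure(list(kappa = kappa, tol = tol, max_iter = max_iter),
            class = "autoregulation_config")
}

#' Periodic solve with autoregulating cerebral beds
#'
#' Alternates periodic 1D solves with relaxed updates of the cerebral
#' bed resistances toward the autoregulation target flow at the
#' observed bed-inlet pressure (see [adapt_resistances()]), until the
#' resistances settle or `max_iter` outer iterations are spent.  Each
#' re-solve warm-starts from the previous periodic state.
#'
#' @param net an `arterial_network` (beds are the terminals with kind
#'   `autoregulating_bed`)
#' @param config a [solver_config()]
#' @param areg an [autoregulation_config()]
#' @param curve autoregulation curve; defaults to the shipped fixture
#' @param state,model optional warm start (model must match `net`'s
#'   discretisation)
#' @param bed_R optional named vector of starting total bed
#'   resistances (dyn s/cm^5), e.g. carried over from a neighbouring
#'   run
#' @return list: `state`, `model`, `beds` (converged resistances and
#'   observed flows/pressures), `converged` (autoregulation),
#'   `periodic_converged`, `outer_iters`, `report` (last periodic
#'   report)
#' @export
run_autoregulated <- function(net, config = solver_config(),
                              areg = autoregulation_config(),
                              curve = load_autoregulation_curve(),
                              state = NULL, model = NULL,
                              bed_R = NULL) {
  if (is.null(model)) model <- discretise_network(net, config)
  tt <- model$terminals
  is_bed <- tt$kind == "autoregulating_bed"
  beds <- data.frame(terminal = tt$segment[is_bed],
                     R = tt$R1[is_bed] + tt$R2[is_bed],
                     R1 = tt$R1[is_bed],
                     Pv = tt$Pv[is_bed],
                     q0 = from_ml_min(tt$q0_ml_min[is_bed]))
  # terminal resistances in the model carry the calibration scale
  for (b in seq_len(nrow(beds))) {
    par <- model$couplings[[tt$coupling[is_bed][b]]]$par
    beds$R[b] <- par[1] + par[2]
    beds$R1[b] <- par[1]
  }
  if (!is.null(bed_R)) {
    hit <- match(beds$terminal, names(bed_R))
    beds$R[!is.na(hit)] <- bed_R[hit[!is.na(hit)]]
  }
  set_bed_R <- function(model, beds) {
    for (b in seq_len(nrow(beds))) {
      k <- tt$coupling[is_bed][b]
      model$couplings[[k]]$par[2] <- beds$R[b] - beds$R1[b]
    }
    model
  }
  model <- set_bed_R(model, beds)
  converged <- FALSE
  it <- 0
  metrics <- NULL
  repeat {
    it <- it + 1
    run <- run_to_periodic(state, model, config)
    state <- run$state
    metrics <- data.frame(
      terminal = beds$terminal,
      P_mean = vapply(beds$terminal, function(sg)
        mean_pressure_at(state, model, sg, "distal", units = "cgs"), 0),
      Q_mean = vapply(beds$terminal, function(sg)
        mean_flow_at(state, model, sg, "distal", units = "cgs"), 0))
    ad <- adapt_resistances(metrics, beds[c("terminal", "R", "Pv", "q0")],
                            curve, kappa = areg$kappa, tol = areg$tol)
    beds$R <- ad$beds$R
    model <- set_bed_R(model, beds)
    if (ad$converged) { converged <- TRUE; break }
    if (it >= areg$max_iter) break
  }
  beds$P_mean_mmhg <- to_mmhg(metrics$P_mean)
  beds$Q_mean_ml_min <- to_ml_min(metrics$Q_mean)
  list(state = state, model = model, beds = beds,
       converged = converged,
       periodic_converged = run$report$converged,
       outer_iters = it, report = run$report)
}
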