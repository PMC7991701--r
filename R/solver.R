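#' Solver configuration
#'
#' @param dx_target target grid spacing, cm (every sub-segment gets at
#'   least 5 nodes regardless)
#' @param cfl Courant number in (0, 1)
#' @param max_cycles maximum cardiac cycles for periodic convergence
#' @param cycle_tolerance relative change of segment cycle means
#'   between consecutive cycles below which the run is periodic
#' @param ramp_cycles inflow is ramped linearly over this many initial
#'   cycles to soften the cold-start transient
#' @return object of class `solver_config`
#' @export
solver_config <- function(dx_target = 0.25, cfl = 0.9, max_cycles = 30,
                          cycle_tolerance = 1e-3, ramp_cycles = 1) {
  stopifnot(dx_target > 0, cfl > 0, cfl < 1, max_cycles >= 2,
            cycle_tolerance > 0)
  structure(list(dx_target = dx_target, cfl = cfl, max_cycles = max_cycles,
                 cycle_tolerance = cycle_tolerance,
                 ramp_cycles = ramp_cycles),
            class = "solver_config")
}

#' Discretise an arterial network for the pulse-wave solver
#'
#' Splits each segment at its interventions (clamp positions; stenosis
#' extents, whose lumen is carried by the lumped element rather than
#' the grid), lays a uniform grid of at least 5 nodes on every piece,
#' and assembles the boundary couplings (inflow, junctions, RCR
#' terminals, clamp and stenosis interfaces) consumed by the compiled
#' time stepper.
#'
#' @param net an `arterial_network`
#' @param config a [solver_config()]
#' @param resistance_scale global multiplier applied jointly to R1 and
#'   R2 of every terminal (the mean-pressure calibration knob)
#' @return a `solver_model` list
#' @export
discretise_network <- function(net, config = solver_config(),
                               resistance_scale = 1) {
  segs <- net$segments
  rho <- net$blood$rho
  # interventions per parent segment: ordered cut list
  cuts <- list()
  add_cut <- function(seg, x0, x1, type, par, meta) {
    cuts[[length(cuts) + 1L]] <<- list(segment = seg, x0 = x0, x1 = x1,
                                       type = type, par = par, meta = meta)
  }
  for (i in seq_len(nrow(net$clamps))) {
    cl <- net$clamps[i, ]
    add_cut(cl$segment, cl$position_mm / 10, cl$position_mm / 10, 2L,
            numeric(3), "clamp")
  }
  for (i in seq_len(nrow(net$stenoses))) {
    st <- as.list(net$stenoses[i, ])
    seg <- as.list(segs[match(st$segment, segs$id), ])
    spec <- list(segment = st$segment, start_offset_mm = st$start_offset_mm,
                 length_mm = st$length_mm, ratio = st$ratio)
    x0 <- st$start_offset_mm / 10
    x1 <- x0 + st$length_mm / 10
    if (st$ratio >= 1) {
      add_cut(st$segment, x0, x1, 2L, numeric(3), "occlusion")
    } else {
      k <- stenosis_coefficients(spec, seg, rho = rho, mu = net$blood$mu)
      add_cut(st$segment, x0, x1, 3L, c(k$a, k$b, k$e), "stenosis")
    }
  }

  pieces <- list()      # per sub-segment geometry
  piece_of <- list()    # parent id -> integer vector of piece indices
  interfaces <- list()  # intra-segment couplings
  for (i in seq_len(nrow(segs))) {
    s <- as.list(segs[i, ])
    own <- Filter(function(ct) ct$segment == s$id, cuts)
    own <- own[order(vapply(own, `[[`, 0, "x0"))]
    bounds <- c(0, unlist(lapply(own, function(ct) c(ct$x0, ct$x1))),
                s$length_cm)
    if (is.unsorted(bounds, strictly = FALSE)) {
      stop("overlapping interventions on segment ", s$id)
    }
    idx <- integer()
    for (p in seq_len(length(bounds) / 2)) {
      x0 <- bounds[2 * p - 1]; x1 <- bounds[2 * p]
      len <- x1 - x0
      if (len <= 0) stop("intervention at the edge of segment ", s$id,
                         " leaves a zero-length piece")
      n <- max(5L, as.integer(round(len / config$dx_target)) + 1L)
      # each piece is uniform at the parent's reference radius evaluated
      # at the piece midpoint (linear taper between the end radii)
      xm <- (x0 + x1) / 2
      rm <- s$r_prox_cm + (s$r_dist_cm - s$r_prox_cm) * xm / s$length_cm
      sp <- s; sp$r_prox_cm <- rm; sp$r_dist_cm <- rm
      pieces[[length(pieces) + 1L]] <-
        list(parent = s$id, x0 = x0, len = len, n = n, dx = len / (n - 1),
             A0 = segment_area0(sp), beta = segment_beta(sp),
             alpha = s$alpha, K_R = s$K_R)
      idx <- c(idx, length(pieces))
    }
    piece_of[[s$id]] <- idx
    for (p in seq_along(own)) {
      interfaces[[length(interfaces) + 1L]] <-
        list(type = own[[p]]$type, seg = c(idx[p], idx[p + 1]),
             side = c(1L, 0L), par = own[[p]]$par, state_idx = 1L,
             parent = s$id, meta = own[[p]]$meta)
    }
  }

  off <- cumsum(c(1L, vapply(pieces, `[[`, 0L, "n")))[seq_along(pieces)]
  first_piece <- function(id) piece_of[[id]][1]
  last_piece <- function(id) piece_of[[id]][length(piece_of[[id]])]

  couplings <- list()
  for (j in net$junctions) {
    seg_idx <- integer(); side <- integer()
    for (a in j$attached) {
      if (a$end == "proximal") {
        seg_idx <- c(seg_idx, first_piece(a$segment)); side <- c(side, 0L)
      } else {
        seg_idx <- c(seg_idx, last_piece(a$segment)); side <- c(side, 1L)
      }
    }
    couplings[[length(couplings) + 1L]] <-
      list(type = 0L, seg = seg_idx, side = side, par = numeric(3),
           state_idx = 1L, parent = j$node_id, meta = "junction")
  }
  term_info <- net$terminals
  term_info$coupling <- NA_integer_
  n_term <- 0L
  for (i in seq_len(nrow(net$terminals))) {
    tm <- as.list(net$terminals[i, ])
    n_term <- n_term + 1L
    couplings[[length(couplings) + 1L]] <-
      list(type = 1L, seg = last_piece(tm$segment), side = 1L,
           par = c(tm$R1 * resistance_scale, tm$R2 * resistance_scale,
                   tm$C, tm$Pv),
           state_idx = n_term, parent = tm$segment, meta = tm$kind)
    term_info$coupling[i] <- length(couplings)
  }
  n_sten <- 0L
  for (k in seq_along(interfaces)) {
    if (interfaces[[k]]$type == 3L) {
      n_sten <- n_sten + 1L
      interfaces[[k]]$state_idx <- n_sten
    }
    couplings[[length(couplings) + 1L]] <- interfaces[[k]]
  }

  subsegs <- data.frame(
    parent = vapply(pieces, `[[`, "", "parent"),
    x0 = vapply(pieces, `[[`, 0, "x0"),
    len = vapply(pieces, `[[`, 0, "len"),
    n = vapply(pieces, `[[`, 0L, "n"),
    dx = vapply(pieces, `[[`, 0, "dx"),
    A0 = vapply(pieces, `[[`, 0, "A0"),
    beta = vapply(pieces, `[[`, 0, "beta"),
    alpha = vapply(pieces, `[[`, 0, "alpha"),
    K_R = vapply(pieces, `[[`, 0, "K_R"),
    offset = off)

  structure(list(
    subsegs = subsegs,
    couplings = couplings,
    offset = as.integer(off),
    n_nodes = as.integer(subsegs$n),
    dx = subsegs$dx, A0 = subsegs$A0, beta = subsegs$beta,
    alpha = subsegs$alpha, K_R = subsegs$K_R,
    rho = rho, cfl = config$cfl,
    q_mean = from_ml_min(net$inflow$cardiac_output_ml_min),
    period = net$inflow$period_s,
    systole = net$inflow$systole_s,
    ramp_cycles = config$ramp_cycles,
    inflow_seg = first_piece(net$inflow$segment),
    terminals = term_info,
    n_state_sten = n_sten,
    config = config
  ), class = "solver_model")
}

#' Initial solver state (reproducible cold start)
#'
#' Every node at reference area with zero flow; terminal compliances
#' at venous pressure.
#'
#' @param model a `solver_model`
#' @return object of class `solver_state`
#' @export
init_state <- function(model) {
  N <- sum(model$n_nodes)
  A <- numeric(N)
  for (i in seq_len(nrow(model$subsegs))) {
    off <- model$offset[i]
    A[off:(off + model$n_nodes[i] - 1)] <- model$A0[i]
  }
  structure(list(A = A, Q = numeric(N),
                 Pc = model$terminals$Pv,
                 Qprev = numeric(max(1L, model$n_state_sten)),
                 t = 0),
            class = "solver_state")
}

#' Advance the solution by whole cardiac cycles
#'
#' Runs the compiled Lax-Wendroff stepper for `n_cycles` periods.  The
#' time step is chosen globally each step from the CFL condition.  The
#' returned state carries the last cycle's per-node time-mean pressure
#' and flow, the audited maximum junction mass defect and the time
#' step range as attributes.
#'
#' @param state a `solver_state` (or NULL for a cold start)
#' @param model a `solver_model`
#' @param n_cycles number of cardiac periods to advance
#' @return updated `solver_state` with attributes `mean_P`, `mean_Q`,
#'   `mass_defect_max`, `dt_range`, `n_steps`
#' @export
advance_cycle <- function(state, model, n_cycles = 1) {
  if (is.null(state)) state <- init_state(model)
  out <- .cpp_run_cycles(model, state, as.integer(n_cycles))
  structure(list(A = out$A, Q = out$Q, Pc = out$Pc, Qprev = out$Qprev,
                 t = out$t),
            class = "solver_state",
            mean_P = out$mean_P, mean_Q = out$mean_Q,
            mass_defect_max = out$mass_defect_max,
            dt_range = c(out$dt_min, out$dt_max),
            n_steps = out$n_steps)
}

# cycle- and space-averaged P and Q per sub-segment
.cycle_means <- function(state, model) {
  mp <- attr(state, "mean_P"); mq <- attr(state, "mean_Q")
  ns <- nrow(model$subsegs)
  P <- numeric(ns); Q <- numeric(ns)
  for (i in seq_len(ns)) {
    idx <- model$offset[i]:(model$offset[i] + model$n_nodes[i] - 1)
    P[i] <- mean(mp[idx]); Q[i] <- mean(mq[idx])
  }
  list(P = P, Q = Q)
}

#' Run the solver to a periodic regime
#'
#' Advances cycle by cycle until the maximum relative change, across
#' all sub-segments, of the cycle-averaged pressure and flow between
#' consecutive cycles drops below `config$cycle_tolerance`, or
#' `max_cycles` is reached.  Relative flow changes are measured
#' against a floor of 1% of the mean root inflow so that vessels
#' carrying (near-)zero mean flow do not stall convergence.
#'
#' @param state starting `solver_state`, or NULL for a cold start
#' @param model a `solver_model`
#' @param config a [solver_config()]; defaults to the configuration
#'   the model was built with
#' @return list with `state` (periodic) and `report` (class
#'   `convergence_report`: `converged`, `n_cycles`, per-cycle
#'   `residuals`, `mass_defect_max`)
#' @export
run_to_periodic <- function(state = NULL, model, config = model$config) {
  q_floor <- 0.01 * model$q_mean
  p_floor <- from_mmhg(0.1)
  prev <- NULL
  residuals <- numeric()
  mass_max <- 0
  converged <- FALSE
  for (cyc in seq_len(config$max_cycles)) {
    state <- advance_cycle(state, model, 1)
    mass_max <- max(mass_max, attr(state, "mass_defect_max"))
    cur <- .cycle_means(state, model)
    if (!is.null(prev)) {
      resP <- max(abs(cur$P - prev$P) / pmax(abs(prev$P), p_floor))
      resQ <- max(abs(cur$Q - prev$Q) / pmax(abs(prev$Q), q_floor))
      residuals <- c(residuals, max(resP, resQ))
      if (cyc > config$ramp_cycles + 1 &&
          residuals[length(residuals)] < config$cycle_tolerance) {
        converged <- TRUE
        break
      }
    }
    prev <- cur
  }
  report <- structure(list(converged = converged, n_cycles = cyc,
                           residuals = residuals,
                           mass_defect_max = mass_max),
                      class = "convergence_report")
  list(state = state, report = report)
}

# --- measurement helpers -------------------------------------------------

# node index for a position along a parent segment; where is
# "proximal", "mid", "distal" or a numeric position in cm
.node_at <- function(model, segment, where = "mid") {
  rows <- which(model$subsegs$parent == segment)
  if (!length(rows)) stop("unknown segment in model: ", segment)
  sub <- model$subsegs[rows, , drop = FALSE]
  total <- sub$x0[nrow(sub)] + sub$len[nrow(sub)]
  x <- if (is.numeric(where)) where else {
    switch(where, proximal = 0, mid = total / 2, distal = total,
           stop("bad position: ", where))
  }
  # pick the piece containing x (pieces may not tile the parent where a
  # stenosis lumen was removed: snap into the nearest piece)
  di <- vapply(seq_len(nrow(sub)), function(i) {
    if (x < sub$x0[i]) sub$x0[i] - x
    else if (x > sub$x0[i] + sub$len[i]) x - (sub$x0[i] + sub$len[i])
    else 0
  }, 0)
  i <- which.min(di)
  loc <- min(max(x - sub$x0[i], 0), sub$len[i])
  model$offset[rows[i]] + as.integer(round(loc / sub$dx[i]))
}

#' Cycle-mean pressure at a point of a segment
#'
#' @param state converged `solver_state` (with cycle means attached)
#' @param model the `solver_model` it was produced with
#' @param segment segment id
#' @param where "proximal", "mid", "distal", or a position in cm from
#'   the proximal end
#' @param units "mmHg" (default) or "cgs"
#' @return cycle-mean pressure
#' @export
mean_pressure_at <- function(state, model, segment, where = "mid",
                             units = "mmHg") {
  p <- attr(state, "mean_P")[.node_at(model, segment, where)]
  if (units == "mmHg") to_mmhg(p) else p
}

#' Cycle-mean flow through a point of a segment
#'
#' Sign convention: positive in the proximal-to-distal direction of
#' the segment's stored orientation.
#'
#' @inheritParams mean_pressure_at
#' @param units "mL/min" (default) or "cgs"
#' @return cycle-mean flow
#' @export
mean_flow_at <- function(state, model, segment, where = "mid",
                         units = "mL/min") {
  q <- attr(state, "mean_Q")[.node_at(model, segment, where)]
  if (units == "mL/min") to_ml_min(q) else q
}
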