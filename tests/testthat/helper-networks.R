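# Small hand-built networks for solver unit tests.  These bypass
# load_network()/validate_network() (which require the full CoW) and
# are consumed directly by discretise_network().

make_segments <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r$id, name = r$id, length_cm = r$L,
               r_prox_cm = r$r, r_dist_cm = if (is.null(r$rd)) r$r else r$rd,
               h_cm = r$h, E_dyn_cm2 = r$E, alpha = 1.0,
               K_R = if (is.null(r$K_R)) 22 * pi * 0.04 / 1.06 else r$K_R)
  }))
}

make_junction <- function(node_id, ...) {
  list(node_id = node_id,
       attached = lapply(list(...), function(a)
         list(segment = a[1], end = a[2])))
}

make_terminal <- function(segment, R1, R2, C, Pv = 0,
                          kind = "windkessel", q0 = NA_real_) {
  data.frame(segment = segment, kind = kind, R1 = R1, R2 = R2, C = C,
             Pv = Pv, q0_ml_min = q0)
}

make_test_net <- function(segments, junctions, terminals,
                          root, co_ml_min = 5000, period = 0.9,
                          systole = 0.3) {
  structure(list(
    fixture_version = "test",
    reference_age = 40,
    blood = list(rho = 1.06, mu = 0.04),
    inflow = list(segment = root, cardiac_output_ml_min = co_ml_min,
                  period_s = period, systole_s = systole),
    segments = segments,
    junctions = junctions,
    terminals = terminals,
    stenoses = data.frame(segment = character(), start_offset_mm = numeric(),
                          length_mm = numeric(), ratio = numeric()),
    clamps = data.frame(segment = character(), position_mm = numeric())
  ), class = "arterial_network")
}

# single vessel with an RCR outlet
single_vessel_net <- function(co_ml_min = 5000, L = 20, r = 0.5,
                              Pv = 0) {
  segs <- make_segments(list(id = "v", L = L, r = r, h = 0.05, E = 4e6))
  make_test_net(segs, list(),
                make_terminal("v", 100, 1000, 1e-4, Pv = Pv),
                root = "v", co_ml_min = co_ml_min)
}

# symmetric Y bifurcation: parent -> two identical daughters, with an
# optional bridging vessel between the daughter midnodes' junctions
symmetric_tree_net <- function(bridge = FALSE, co_ml_min = 3000) {
  rows <- list(
    list(id = "parent", L = 10, r = 0.4, h = 0.05, E = 4e6),
    list(id = "d_left1", L = 6, r = 0.25, h = 0.04, E = 4e6),
    list(id = "d_right1", L = 6, r = 0.25, h = 0.04, E = 4e6),
    list(id = "d_left2", L = 6, r = 0.22, h = 0.04, E = 4e6),
    list(id = "d_right2", L = 6, r = 0.22, h = 0.04, E = 4e6))
  juncs <- list(
    make_junction("j0", c("parent", "distal"), c("d_left1", "proximal"),
                  c("d_right1", "proximal")))
  if (bridge) {
    rows <- c(rows, list(list(id = "bridge", L = 2, r = 0.1, h = 0.02,
                              E = 4e6)))
    juncs <- c(juncs, list(
      make_junction("jl", c("d_left1", "distal"), c("d_left2", "proximal"),
                    c("bridge", "proximal")),
      make_junction("jr", c("d_right1", "distal"), c("d_right2", "proximal"),
                    c("bridge", "distal"))))
  } else {
    juncs <- c(juncs, list(
      make_junction("jl", c("d_left1", "distal"), c("d_left2", "proximal")),
      make_junction("jr", c("d_right1", "distal"), c("d_right2", "proximal"))))
  }
  terms <- rbind(make_terminal("d_left2", 200, 2000, 5e-5),
                 make_terminal("d_right2", 200, 2000, 5e-5))
  make_test_net(do.call(make_segments, rows), juncs, terms,
                root = "parent", co_ml_min = co_ml_min)
}
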