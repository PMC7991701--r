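test_that("a quiescent vessel stays exactly at rest", {
  net <- single_vessel_net(co_ml_min = 0, Pv = 0)
  model <- discretise_network(net, solver_config(ramp_cycles = 0))
  st <- advance_cycle(NULL, model)
  expect_lt(max(abs(st$A - init_state(model)$A)), 1e-10)
  expect_lt(max(abs(st$Q)), 1e-10)
})

test_that("identical daughters of a symmetric bifurcation split evenly", {
  net <- symmetric_tree_net(bridge = FALSE)
  model <- discretise_network(net, solver_config())
  st <- NULL
  for (i in 1:4) st <- advance_cycle(st, model)
  sub <- model$subsegs
  qL <- attr(st, "mean_Q")[model$offset[sub$parent == "d_left2"]]
  qR <- attr(st, "mean_Q")[model$offset[sub$parent == "d_right2"]]
  expect_equal(qL, qR, tolerance = 1e-8)
  # the end states themselves are mirror images
  iL <- which(sub$parent %in% c("d_left1", "d_left2"))
  iR <- which(sub$parent %in% c("d_right1", "d_right2"))
  idx <- function(i) unlist(lapply(i, function(k)
    model$offset[k]:(model$offset[k] + model$n_nodes[k] - 1)))
  expect_equal(st$A[idx(iL)], st$A[idx(iR)], tolerance = 1e-8)
})

test_that("a bridge between mirror-image branches carries no mean flow", {
  net <- symmetric_tree_net(bridge = TRUE)
  model <- discretise_network(net, solver_config())
  run <- run_to_periodic(NULL, model)
  q_bridge <- mean_flow_at(run$state, model, "bridge", units = "cgs")
  expect_lt(abs(q_bridge), 1e-6 * model$q_mean)
})

test_that("junction mass defects stay below the audit threshold", {
  net <- symmetric_tree_net(bridge = TRUE)
  model <- discretise_network(net, solver_config())
  run <- run_to_periodic(NULL, model)
  q_peak <- model$q_mean * model$period * pi / (2 * model$systole)
  expect_lt(run$report$mass_defect_max, 1e-6 * q_peak)
})

test_that("an infinite cycle tolerance returns after the minimum 2 cycles", {
  net <- single_vessel_net()
  cfg <- solver_config(cycle_tolerance = Inf, ramp_cycles = 0)
  model <- discretise_network(net, cfg)
  run <- run_to_periodic(NULL, model, cfg)
  expect_true(run$report$converged)
  expect_identical(run$report$n_cycles, 2L)
})

test_that("a small pulse propagates at the analytic reference wave speed", {
  # short low-amplitude systolic pulse on a long uniform vessel; after
  # one cycle the area peak sits where c(A0) predicts
  net <- single_vessel_net(co_ml_min = 50, L = 110, r = 0.5)
  net$inflow$period_s <- 0.2
  net$inflow$systole_s <- 0.04
  model <- discretise_network(net, solver_config(ramp_cycles = 0))
  st <- advance_cycle(NULL, model)
  dx <- model$subsegs$dx[1]
  x_peak <- (which.max(st$A - model$A0[1]) - 1) * dx
  c0 <- sqrt(model$beta[1] * sqrt(model$A0[1]) / (2 * model$rho))
  measured <- x_peak / (0.2 - 0.02)      # pulse centroid leaves at t = Ts/2
  expect_equal(measured, c0, tolerance = 0.02)
})

test_that("a clamped branch carries no flow while its stump stays observable", {
  net <- symmetric_tree_net(bridge = FALSE)
  net <- apply_clamp(net, list(segment = "d_left1", position_mm = 20))
  model <- discretise_network(net, solver_config())
  run <- run_to_periodic(NULL, model)
  mq <- attr(run$state, "mean_Q")
  stump <- which(model$subsegs$parent == "d_left1" & model$subsegs$x0 > 0)
  nodes <- model$offset[stump]:(model$offset[stump] +
                                  model$n_nodes[stump] - 1)
  expect_lt(max(abs(mq[nodes])), 1e-8)
  csp <- measure_csp(run$state, model, "d_left1")
  expect_true(is.finite(csp) && csp > 0)
  # the sibling branch now takes the whole cardiac output
  q_sib <- mean_flow_at(run$state, model, "d_right2", "distal",
                        units = "cgs")
  expect_equal(q_sib, model$q_mean, tolerance = 5e-3)
  expect_error(measure_csp(run$state, model, "d_right1"), "clamp")
})

test_that("a transparent (ratio ~ 0) stenosis interface matches a plain junction", {
  # reference: the host vessel split at the same spot by an ordinary
  # junction, so that only the interface physics (not the grid split)
  # is compared
  rows <- list(
    list(id = "parent", L = 10, r = 0.4, h = 0.05, E = 4e6),
    list(id = "d_a", L = 2, r = 0.25, h = 0.04, E = 4e6),
    list(id = "d_b", L = 4, r = 0.25, h = 0.04, E = 4e6),
    list(id = "sib", L = 6, r = 0.25, h = 0.04, E = 4e6))
  juncs <- list(
    make_junction("j0", c("parent", "distal"), c("d_a", "proximal"),
                  c("sib", "proximal")),
    make_junction("js", c("d_a", "distal"), c("d_b", "proximal")))
  terms <- rbind(make_terminal("d_b", 200, 2000, 5e-5),
                 make_terminal("sib", 200, 2000, 5e-5))
  ref <- make_test_net(do.call(make_segments, rows), juncs, terms,
                       root = "parent", co_ml_min = 3000)
  mref <- discretise_network(ref, solver_config())
  rref <- run_to_periodic(NULL, mref)

  rows2 <- list(rows[[1]],
                list(id = "d", L = 6, r = 0.25, h = 0.04, E = 4e6),
                rows[[4]])
  juncs2 <- list(make_junction("j0", c("parent", "distal"),
                               c("d", "proximal"), c("sib", "proximal")))
  terms2 <- rbind(make_terminal("d", 200, 2000, 5e-5),
                  make_terminal("sib", 200, 2000, 5e-5))
  net <- make_test_net(do.call(make_segments, rows2), juncs2, terms2,
                       root = "parent", co_ml_min = 3000)
  net <- apply_stenosis(net, list(segment = "d", start_offset_mm = 20,
                                  length_mm = 1e-6, ratio = 1e-9))
  m1 <- discretise_network(net, solver_config())
  r1 <- run_to_periodic(NULL, m1)
  q_ref <- mean_flow_at(rref$state, mref, "d_b", "distal", units = "cgs")
  q1 <- mean_flow_at(r1$state, m1, "d", "distal", units = "cgs")
  expect_equal(q1, q_ref, tolerance = 1e-6)
})

test_that("mean flow through a stenosed branch decreases strictly with severity", {
  flows <- vapply(c(0, 0.3, 0.6, 0.9), function(r) {
    net <- symmetric_tree_net(bridge = FALSE)
    if (r > 0) {
      net <- apply_stenosis(net, list(segment = "d_left1",
                                      start_offset_mm = 20,
                                      length_mm = 10, ratio = r))
    }
    model <- discretise_network(net, solver_config())
    run <- run_to_periodic(NULL, model)
    mean_flow_at(run$state, model, "d_left2", "distal", units = "cgs")
  }, 0)
  expect_true(all(diff(flows) < 0))
})
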