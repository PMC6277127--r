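# Biphasic solver: pressure/flow, hematocrit advection, coupled iteration.

test_that("a two-segment series acts as an equal-resistance divider", {
  nodes <- data.frame(id = 1:3, x = c(0, 100, 200), y = 0, z = -200,
                      role = c("arterial_inlet", "interior", "venous_outlet"))
  segs <- data.frame(id = 1:2, tail = 1:2, head = 2:3, diameter = 8,
                     length = 100, compartment = "CAP")
  net <- vascular_network(nodes, segs)
  pf <- solve_pressure_flow(net, c(0.35, 0.35))
  expect_equal(pf$p[2] / 133.322, 62.5, tolerance = 1e-10)
})

test_that("a single segment carries Q = dp / R", {
  net <- make_fixture("single_segment")
  f <- solve_biphasic(net)
  R <- segment_resistance(10, 100, f$h[1])
  expect_equal(f$Q[1], (120 - 5) * 133.322 / R, tolerance = 1e-10)
  expect_equal(f$h[1], 0.35)
})

test_that("identical daughters split the parent flow exactly in half", {
  net <- make_fixture("single_bifurcation")
  f <- solve_biphasic(net)
  expect_lt(abs(f$Q[2] - f$Q[1] / 2), 1e-12 * abs(f$Q[1]))
  expect_lt(abs(f$Q[3] - f$Q[2]), 1e-12 * abs(f$Q[1]))
  expect_equal(f$h, rep(0.35, 3), tolerance = 1e-12)
})

test_that("sparse solve matches a dense first-principles oracle", {
  for (fix in list(make_fixture("honeycomb_lattice", rows = 4, cols = 5),
                   make_fixture("two_layer_toy"))) {
    h <- rep(0.35, nrow(fix$segments))
    pf <- solve_pressure_flow(fix, h)
    p_or <- dense_pressure_oracle(fix, h)
    expect_lt(max(abs(pf$p - p_or)) / max(abs(p_or)), 1e-9)
  }
})

test_that("without skimming the hematocrit field is uniformly the inlet value", {
  hc <- make_fixture("honeycomb_lattice", rows = 4, cols = 4)
  cfg <- solver_config(rheology = rheology_params(m = Inf))
  f <- solve_biphasic(hc, boundary_conditions(), cfg)
  expect_equal(f$h, rep(0.35, length(f$h)), tolerance = 1e-9)
})

test_that("hematocrit is constant along a single path", {
  nodes <- data.frame(id = 1:4, x = c(0, 100, 200, 300), y = 0, z = -300,
                      role = c("arterial_inlet", "interior", "interior",
                               "venous_outlet"))
  segs <- data.frame(id = 1:3, tail = 1:3, head = 2:4,
                     diameter = c(9, 5, 7), length = 100, compartment = "CAP")
  net <- vascular_network(nodes, segs)
  f <- solve_biphasic(net)
  expect_equal(f$h, rep(0.35, 3), tolerance = 1e-12)
})

test_that("asymmetric junction hematocrits match the junction-local kernel", {
  y <- make_fixture("y_tree")
  f <- solve_biphasic(y)
  pr <- rheology_params()
  daughters <- c(2L, 3L)
  hk <- kpsm_split(abs(f$Q[daughters]),
                   inflow_flux = abs(f$Q[1]) * f$h[1], params = pr)
  expect_equal(f$h[daughters], hk, tolerance = 1e-9)
  # RBC conservation at the junction
  expect_lt(abs(sum(abs(f$Q[daughters]) * f$h[daughters]) -
                abs(f$Q[1]) * f$h[1]),
            1e-12 * abs(f$Q[1]) * f$h[1])
})

test_that("the converged field is independent of hematocrit initialization", {
  hc <- make_fixture("honeycomb_lattice", rows = 4, cols = 4)
  f1 <- solve_biphasic(hc, h_init = 0.35)
  f2 <- solve_biphasic(hc, h_init = 0.10)
  expect_lt(max(abs(f1$h - f2$h)), 1e-6)
  expect_lt(max(abs(f1$Q - f2$Q)) / max(abs(f1$Q)), 1e-6)
})

test_that("global bulk and RBC balances close on converged solutions", {
  for (fix in list(make_fixture("two_layer_toy"),
                   make_fixture("honeycomb_lattice", rows = 4, cols = 4))) {
    f <- solve_biphasic(fix)
    it <- match(fix$segments$tail, fix$nodes$id)
    ih <- match(fix$segments$head, fix$nodes$id)
    inl <- which(fix$nodes$role == "arterial_inlet")
    out <- which(fix$nodes$role == "venous_outlet")
    qin <- sum(f$Q[it %in% inl]) - sum(f$Q[ih %in% inl])
    qout <- sum(f$Q[ih %in% out]) - sum(f$Q[it %in% out])
    expect_lt(abs(qin - qout), 1e-9 * abs(qin))
    # RBC phase: outflow flux = inlet h times bulk inflow
    rbc_out <- sum((abs(f$Q) * f$h)[ih %in% out | it %in% out])
    expect_lt(abs(rbc_out - 0.35 * qin), 1e-9 * abs(0.35 * qin))
  }
})

test_that("perfusion is linear in the driving pressure at fixed hematocrit", {
  hc <- make_fixture("honeycomb_lattice", rows = 4, cols = 4)
  h <- rep(0.35, nrow(hc$segments))
  pf1 <- solve_pressure_flow(hc, h, boundary_conditions(120, 5))
  pf2 <- solve_pressure_flow(hc, h, boundary_conditions(235, 5))
  expect_equal(max(abs(pf2$Q)) / max(abs(pf1$Q)), 2, tolerance = 1e-9)
})

test_that("non-convergence raises an informative error", {
  tl <- make_fixture("two_layer_toy")
  expect_error(solve_biphasic(tl, config = solver_config(max_iter = 1L)),
               "did not converge")
})

test_that("RBC flux is |Q| h segment-wise", {
  y <- make_fixture("y_tree")
  f <- solve_biphasic(y)
  expect_equal(rbc_flux(f), abs(f$Q) * f$h)
  f0 <- f; f0$h <- rep(0, 3)
  expect_equal(rbc_flux(f0), rep(0, 3))
})

test_that("isolated subnetworks without boundary nodes are reported", {
  nodes <- data.frame(id = 1:2, x = c(0, 100), y = 0, z = 0,
                      role = c("arterial_inlet", "venous_outlet"))
  segs <- data.frame(id = 1L, tail = 1L, head = 2L, diameter = 5,
                     length = 100, compartment = "CAP")
  net <- vascular_network(nodes, segs)
  # boundary conditions with reversed ordering are rejected up front
  expect_error(boundary_conditions(5, 120), "exceed")
})
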