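# Graph data model, validation, incidence operators, file round trips.

test_that("fixtures have the documented shapes", {
  y <- make_fixture("y_tree")
  expect_equal(nrow(y$segments), 3L)
  expect_equal(nrow(y$nodes), 4L)
  expect_equal(sum(y$nodes$role == "arterial_inlet"), 1L)
  expect_equal(sum(y$nodes$role == "venous_outlet"), 2L)
  d <- validate_network(y)
  expect_equal(d$n_bifurcations, 1L)
  expect_error(make_fixture("moebius_lattice"), "unknown fixture")
})

test_that("incidence matrices have the contract structure", {
  s1 <- make_fixture("single_segment")
  inc <- build_incidence(s1)
  expect_equal(dim(inc$C1), c(1L, 2L))
  expect_equal(as.numeric(inc$C1), c(1, -1))
  expect_equal(nrow(inc$C2), 0L)  # no interior nodes
  y <- make_fixture("y_tree")
  incy <- build_incidence(y)
  expect_equal(dim(incy$C2), c(1L, 3L))
  expect_equal(as.numeric(incy$C2), c(1, -1, -1))
  # every C1 row: exactly two nonzeros summing to zero
  hc <- make_fixture("honeycomb_lattice", rows = 4, cols = 4)
  C1 <- build_incidence(hc)$C1
  expect_true(all(Matrix::rowSums(C1 != 0) == 2))
  expect_true(all(abs(Matrix::rowSums(C1)) == 0))
})

test_that("flow conservation holds through the C2 operator", {
  hc <- make_fixture("honeycomb_lattice", rows = 4, cols = 4)
  f <- solve_biphasic(hc)
  C2 <- build_incidence(hc)$C2
  resid <- as.numeric(C2 %*% f$Q)
  expect_lt(max(abs(resid)), 1e-10 * max(abs(f$Q)))
})

test_that("network validation catches structural defects", {
  nodes <- data.frame(id = 1:2, x = c(0, 100), y = 0, z = 0,
                      role = c("arterial_inlet", "venous_outlet"))
  segs <- data.frame(id = 1L, tail = 1L, head = 999L, diameter = 5,
                     length = 100, compartment = "CAP")
  expect_error(vascular_network(nodes, segs), "999")
  segs2 <- data.frame(id = 1L, tail = 1L, head = 2L, diameter = NaN,
                      length = 100, compartment = "CAP")
  expect_error(vascular_network(nodes, segs2), "diameter")
  # disconnected graph reports its components
  nodes3 <- data.frame(id = 1:4, x = c(0, 100, 500, 600), y = 0, z = 0,
                       role = c("arterial_inlet", "interior", "interior",
                                "venous_outlet"))
  segs3 <- data.frame(id = 1:2, tail = c(1L, 3L), head = c(2L, 4L),
                      diameter = 5, length = 100, compartment = "CAP")
  expect_error(vascular_network(nodes3, segs3), "disconnected")
})

test_that("multifurcation counting distinguishes junction degrees", {
  hc <- make_fixture("honeycomb_lattice", rows = 3, cols = 3)
  expect_equal(validate_network(hc)$n_multifurcations, 0L)
  # star with one 4-way junction
  nodes <- data.frame(id = 1:5, x = c(0, 100, 200, 100, 100),
                      y = c(0, 0, 0, 100, -100), z = 0,
                      role = c("arterial_inlet", "interior", "venous_outlet",
                               "venous_outlet", "venous_outlet"))
  segs <- data.frame(id = 1:4, tail = c(1L, 2L, 2L, 2L),
                     head = c(2L, 3L, 4L, 5L), diameter = 5, length = 120,
                     compartment = "CAP")
  star <- vascular_network(nodes, segs)
  expect_equal(validate_network(star)$n_multifurcations, 1L)
})

test_that("JSON and CSV round trips are lossless", {
  net <- make_fixture("two_layer_toy")
  set.seed(5)
  net <- apply_tortuosity(net, list(mean = 1.15, sd = 0.05))
  for (fmt in c("json", "csv_pair")) {
    path <- if (fmt == "json") tempfile(fileext = ".json") else
      file.path(tempdir(), paste0("rt_", fmt))
    write_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_equal(back$nodes$id, net$nodes$id)
    expect_equal(back$nodes$role, net$nodes$role)
    expect_equal(back$nodes$x, net$nodes$x, tolerance = 1e-12)
    expect_equal(back$segments$tail, net$segments$tail)
    expect_equal(back$segments$compartment, net$segments$compartment)
    expect_equal(back$segments$diameter, net$segments$diameter,
                 tolerance = 1e-12)
    expect_equal(back$segments$length, net$segments$length, tolerance = 1e-12)
    has_cp <- !vapply(net$segments$cp, is.null, logical(1))
    expect_equal(!vapply(back$segments$cp, is.null, logical(1)), has_cp)
    i <- which(has_cp)[1]
    expect_equal(back$segments$cp[[i]], net$segments$cp[[i]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("CSV pair writes one row per node and segment", {
  net <- make_fixture("single_bifurcation")
  stem <- file.path(tempdir(), "bif")
  write_network(net, stem, "csv_pair")
  expect_equal(nrow(utils::read.csv(paste0(stem, "_nodes.csv"))), 4L)
  expect_equal(nrow(utils::read.csv(paste0(stem, "_segments.csv"))), 3L)
})

test_that("VTK export writes polylines with the advertised arrays", {
  y <- make_fixture("y_tree")
  f <- solve_biphasic(y)
  path <- tempfile(fileext = ".vtp")
  export_vtk(y, f, path)
  txt <- readLines(path)
  expect_true(any(grepl('NumberOfLines="3"', txt)))
  for (arr in c("diameter", "compartment", "pressure", "flow", "hematocrit")) {
    expect_true(any(grepl(paste0('Name="', arr, '"'), txt)))
  }
  path2 <- tempfile(fileext = ".vtp")
  export_vtk(y, NULL, path2)
  txt2 <- readLines(path2)
  expect_true(any(grepl('Name="compartment"', txt2)))
  expect_false(any(grepl('Name="pressure"', txt2)))
  # dimension mismatch refused
  f_bad <- f; f_bad$Q <- f$Q[-1]
  expect_error(export_vtk(y, f_bad, tempfile(fileext = ".vtp")), "dimension")
})

test_that("tortuosity never falls below one", {
  net <- small_sample()
  chord <- net$segments$length / pmax(vasonet:::segment_chord(net), 1e-9)
  expect_true(all(chord >= 1 - 1e-6))
})
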