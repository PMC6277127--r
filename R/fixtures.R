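#' Deterministic test networks
#'
#' Small, hand-constructed networks used as solver and analysis test
#' surfaces:
#' \describe{
#'   \item{single_segment}{one vessel from inlet to outlet.}
#'   \item{single_bifurcation}{a symmetric parent + two identical daughters.}
#'   \item{y_tree}{an asymmetric bifurcation (unequal daughter diameters and
#'     lengths), the minimal plasma-skimming testbed.}
#'   \item{honeycomb_lattice}{a meshed capillary plane (brick-wall/honeycomb
#'     pattern) between one inlet and one outlet; contains flow-directed
#'     cycle candidates, exercising the non-acyclic hematocrit solve.}
#'   \item{two_layer_toy}{one shallow and one deep arterio-venous route of
#'     unequal path length branching off a penetrating trunk: the minimal
#'     instance of the depth-dependent hematocrit effect.}
#' }
#'
#' @param name Fixture name (see above).
#' @param rows,cols Lattice extents for `honeycomb_lattice`.
#' @return A `vascular_network`.
#' @export
make_fixture <- function(name = c("single_segment", "single_bifurcation",
                                  "y_tree", "honeycomb_lattice",
                                  "two_layer_toy"),
                         rows = 3L, cols = 3L) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown fixture '", name[1], "'; available: single_segment, ",
         "single_bifurcation, y_tree, honeycomb_lattice, two_layer_toy")
  })
  dom <- domain_descriptor(x = c(-100, 1200), y = c(-100, 1200), depth = 1000)
  straight <- function(nodes, segs) {
    it <- match(segs$tail, nodes$id); ih <- match(segs$head, nodes$id)
    segs$length <- sqrt((nodes$x[it] - nodes$x[ih])^2 +
                        (nodes$y[it] - nodes$y[ih])^2 +
                        (nodes$z[it] - nodes$z[ih])^2)
    vascular_network(nodes, segs, dom)
  }
  switch(name,
    single_segment = {
      nodes <- data.frame(id = 1:2, x = c(0, 100), y = 0, z = -200,
                          role = c("arterial_inlet", "venous_outlet"))
      segs <- data.frame(id = 1L, tail = 1L, head = 2L, diameter = 10,
                         length = NA_real_, compartment = "CAP")
      straight(nodes, segs)
    },
    single_bifurcation = {
      nodes <- data.frame(id = 1:4,
                          x = c(0, 100, 200, 200), y = c(0, 0, 60, -60),
                          z = -200,
                          role = c("arterial_inlet", "interior",
                                   "venous_outlet", "venous_outlet"))
      dp <- 6 * 2^(1 / 3)
      segs <- data.frame(id = 1:3, tail = c(1L, 2L, 2L), head = c(2L, 3L, 4L),
                         diameter = c(dp, 6, 6), length = NA_real_,
                         compartment = c("PEA", "CAP", "CAP"))
      straight(nodes, segs)
    },
    y_tree = {
      nodes <- data.frame(id = 1:4,
                          x = c(0, 100, 260, 180), y = c(0, 0, 60, -90),
                          z = -200,
                          role = c("arterial_inlet", "interior",
                                   "venous_outlet", "venous_outlet"))
      dp <- (8^3 + 5^3)^(1 / 3)
      segs <- data.frame(id = 1:3, tail = c(1L, 2L, 2L), head = c(2L, 3L, 4L),
                         diameter = c(dp, 8, 5), length = NA_real_,
                         compartment = c("PEA", "CAP", "CAP"))
      straight(nodes, segs)
    },
    honeycomb_lattice = {
      stopifnot(rows >= 2L, cols >= 2L)
      sp <- 50
      idx <- function(r, c) (r - 1L) * cols + c
      grid <- expand.grid(c = seq_len(cols), r = seq_len(rows))
      n_grid <- nrow(grid)
      nodes <- data.frame(id = seq_len(n_grid),
                          x = (grid$c - 1) * sp, y = (grid$r - 1) * sp,
                          z = -200, role = "interior")
      segs <- NULL
      for (r in seq_len(rows)) for (c in seq_len(cols - 1L)) {
        segs <- rbind(segs, c(idx(r, c), idx(r, c + 1L)))
      }
      # brick pattern: vertical rung only where (r + c) is even
      for (r in seq_len(rows - 1L)) for (c in seq_len(cols)) {
        if ((r + c) %% 2L == 0L) segs <- rbind(segs, c(idx(r, c), idx(r + 1L, c)))
      }
      inlet_id <- n_grid + 1L; outlet_id <- n_grid + 2L
      nodes <- rbind(nodes,
                     data.frame(id = inlet_id, x = -sp, y = 0, z = -200,
                                role = "arterial_inlet"),
                     data.frame(id = outlet_id, x = cols * sp,
                                y = (rows - 1) * sp, z = -200,
                                role = "venous_outlet"))
      segs <- rbind(segs, c(inlet_id, idx(1L, 1L)), c(idx(rows, cols), outlet_id))
      segs <- data.frame(id = seq_len(nrow(segs)), tail = segs[, 1],
                         head = segs[, 2], diameter = 5, length = NA_real_,
                         compartment = "CAP")
      segs$diameter[segs$tail == inlet_id | segs$head == outlet_id] <- 9
      straight(nodes, segs)
    },
    two_layer_toy = {
      nodes <- data.frame(
        id = 1:10,
        x = c(-50, 0,    0,    0,  200,  200, 400,  400, 400, 450),
        y = 0,
        z = c(0,  0, -100, -700, -100, -700,  -100, -700, 0, 0),
        role = c("arterial_inlet", rep("interior", 8), "venous_outlet"))
      segs <- data.frame(
        id = 1:10,
        tail = c(1L, 2L, 3L, 3L, 4L, 6L, 5L, 8L, 7L, 9L),
        head = c(2L, 3L, 5L, 4L, 6L, 8L, 7L, 7L, 9L, 10L),
        diameter = c(12, 10, 4.5, 9, 6, 4, 4, 8, 9, 12),
        length = NA_real_,
        compartment = c("PIA", "PEA", "CAP", "PEA", "PEC", "CAP", "CAP",
                        "AV", "AV", "PV"))
      straight(nodes, segs)
    })
}
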