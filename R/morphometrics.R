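#' Morphometric summary of a network
#'
#' Topological and geometric summary statistics. Splined segments are
#' counted between branching points: chains through degree-2 nodes are
#' merged before counting, making the tally independent of how segments are
#' sub-partitioned. Bifurcations are interior junctions of degree 3,
#' multifurcations of degree >= 4 (both the junction count and the fraction
#' of adjacent segments are reported). The blood-brain-barrier ratio is the
#' summed endothelial (lateral) surface area of the capillary bed divided by
#' the domain tissue volume.
#'
#' @param net A `vascular_network`.
#' @param bbb_compartment Compartment(s) forming the capillary bed for the
#'   BBB ratio (default `"CAP"`).
#' @return An object of class `morphometric_summary`.
#' @export
morphometry <- function(net, bbb_compartment = "CAP") {
  segs <- net$segments
  deg <- node_degree(net)
  interior <- net$nodes$role == "interior"
  n_deg2 <- sum(deg == 2L & interior)
  n_spline <- nrow(segs) - n_deg2
  L <- segs$length            # um
  d <- segs$diameter          # um
  vsa_um2 <- pi * d * L
  vol_um3 <- pi * d^2 / 4 * L
  iscap <- segs$compartment %in% bbb_compartment
  tv <- tissue_volume(net)    # mm^3
  xy <- cbind(net$nodes$x, net$nodes$y)
  hull <- grDevices::chull(xy)
  hx <- xy[hull, 1]; hy <- xy[hull, 2]
  coverage_mm2 <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2 * 1e-6
  it <- match(segs$tail, net$nodes$id); ih <- match(segs$head, net$nodes$id)
  multi <- interior & deg >= 4L
  chord <- segment_chord(net)
  structure(list(
    n_segments_raw = nrow(segs),
    n_segments = n_spline,
    segments_per_mm2 = n_spline / coverage_mm2,
    n_bifurcations = sum(interior & deg == 3L),
    n_multifurcations = sum(multi),
    multifurcation_segment_fraction = mean(multi[it] | multi[ih]),
    total_length_m = sum(L) * 1e-6,
    volume_nl = sum(vol_um3) * 1e-6,
    vsa_mm2 = sum(vsa_um2) * 1e-6,
    capillary_surface_mm2 = sum(vsa_um2[iscap]) * 1e-6,
    bbb_ratio = sum(vsa_um2[iscap]) * 1e-6 / tv,
    coverage_mm2 = coverage_mm2,
    tissue_volume_mm3 = tv,
    mean_tortuosity = mean(L / pmax(chord, 1e-9)),
    diameter_um = unname(stats::quantile(d, c(.05, .5, .95)))
  ), class = "morphometric_summary")
}

#' @export
print.morphometric_summary <- function(x, ...) {
  cat("Morphometric summary\n")
  cat(sprintf("  splined segments (merged): %d (raw %d)\n",
              x$n_segments, x$n_segments_raw))
  cat(sprintf("  segments per mm^2 pial surface: %.0f\n", x$segments_per_mm2))
  cat(sprintf("  bifurcations: %d   multifurcations: %d (%.1f%% of segments)\n",
              x$n_bifurcations, x$n_multifurcations,
              100 * x$multifurcation_segment_fraction))
  cat(sprintf("  total length: %.3f m   volume: %.1f nL   surface: %.1f mm^2\n",
              x$total_length_m, x$volume_nl, x$vsa_mm2))
  cat(sprintf("  BBB surface/tissue volume: %.2f mm^2/mm^3 (tissue %.2f mm^3)\n",
              x$bbb_ratio, x$tissue_volume_mm3))
  cat(sprintf("  pial coverage: %.2f mm^2   mean tortuosity: %.3f\n",
              x$coverage_mm2, x$mean_tortuosity))
  invisible(x)
}

#' Probability density histogram of a segment metric
#'
#' @param net A `vascular_network`.
#' @param metric `"diameter"`, `"length"` or `"tortuosity"`.
#' @param bins Number of bins or break vector.
#' @return data.frame with `mid`, `density`, `counts`; densities integrate
#'   to 1 over the binned range.
#' @export
vessel_distributions <- function(net, metric = c("diameter", "length",
                                                 "tortuosity"),
                                 bins = 30) {
  metric <- match.arg(metric)
  if (nrow(net$segments) == 0L) stop("empty network")
  v <- switch(metric,
              diameter = net$segments$diameter,
              length = net$segments$length,
              tortuosity = net$segments$length / pmax(segment_chord(net), 1e-9))
  br <- if (length(bins) == 1L) {
    r <- range(v)
    if (diff(r) <= 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1L)
  } else sort(bins)
  hh <- graphics::hist(v, breaks = br, plot = FALSE, include.lowest = TRUE)
  data.frame(mid = hh$mids, density = hh$density, counts = hh$counts)
}

#' Compare two network ensembles metric by metric
#'
#' One-way ANOVA of each shared scalar morphometric between two ensembles of
#' summaries; equivalence is flagged at p > 0.05 (the convention for calling
#' ensembles statistically similar).
#'
#' @param a,b Lists of [morphometry()] summaries (>= 2 members each).
#' @param metrics Metric names to compare.
#' @return data.frame with per-metric `F`, `p` and `equivalent`.
#' @export
compare_ensembles <- function(a, b,
                              metrics = c("n_segments", "total_length_m",
                                          "vsa_mm2", "volume_nl")) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each ensemble needs at least two members")
  }
  res <- do.call(rbind, lapply(metrics, function(mname) {
    va <- vapply(a, function(s) as.numeric(s[[mname]]), numeric(1))
    vb <- vapply(b, function(s) as.numeric(s[[mname]]), numeric(1))
    an <- anova_oneway(list(va, vb))
    data.frame(metric = mname, F = an$F, p = an$p, equivalent = an$p > 0.05)
  }))
  res
}

#' Deterministic reference ensemble from printed summary statistics
#'
#' Builds a synthetic stand-in ensemble of `n = 4` pseudo-measurements per
#' metric reproducing a printed mean and standard deviation exactly
#' (offsets -1, -1/sqrt(2), +1/sqrt(2), +1 times the SD). Used to test
#' statistical equivalence against published ensemble statistics when the
#' underlying specimens are not distributable.
#'
#' @param means Named list/vector of printed means.
#' @param sds Matching printed standard deviations.
#' @return List of `n` pseudo-summaries usable with [compare_ensembles()].
#' @export
synthetic_reference_ensemble <- function(means, sds) {
  offs <- c(-1, -1 / sqrt(2), 1 / sqrt(2), 1)
  lapply(offs, function(o) {
    s <- lapply(seq_along(means), function(i) means[[i]] + o * sds[[i]])
    names(s) <- names(means)
    s
  })
}
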