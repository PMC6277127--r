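#' Trace arterial-to-venous flow paths
#'
#' Follows the converged flow field from arterial inlets downstream through
#' the capillary bed to a venous outlet. In `flux_weighted_sampling` mode
#' (the default), `n_paths` random walks start at inlets (chosen with
#' probability proportional to inlet flow) and at every diverging node pick
#' an outflow branch with probability proportional to its flow; duplicate
#' paths are removed. `exhaustive_capped` mode enumerates all flow-directed
#' paths depth-first up to a cap (small networks only). Each path gets a
#' depth label equal to the cortical depth of its deepest segment and the
#' corresponding layer.
#'
#' @param net A `vascular_network`.
#' @param field A converged `vnet_solution`.
#' @param n_paths Number of sampled walks (before deduplication), or the
#'   enumeration cap.
#' @param mode `"flux_weighted_sampling"` or `"exhaustive_capped"`.
#' @param layer_boundaries Passed to [assign_layers()].
#' @return A list of class `flow_paths`: per-path segment index vectors,
#'   depth labels, layers, lengths, and the per-path hemodynamic traces.
#' @export
trace_paths <- function(net, field, n_paths = 2000L,
                        mode = c("flux_weighted_sampling", "exhaustive_capped"),
                        layer_boundaries = default_layer_boundaries()) {
  mode <- match.arg(mode)
  stopifnot(n_paths >= 1)
  ns <- nrow(net$segments)
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  up <- ifelse(field$Q >= 0, it, ih)
  dn <- ifelse(field$Q >= 0, ih, it)
  aQ <- abs(field$Q)
  active <- !field$stagnant
  out_of <- split(which(active), up[active])
  role <- net$nodes$role
  inlets <- which(role == "arterial_inlet")
  inlet_w <- vapply(inlets, function(n) {
    s <- out_of[[as.character(n)]]
    if (is.null(s)) 0 else sum(aQ[s])
  }, numeric(1))
  if (all(inlet_w <= 0)) stop("no flow leaves any inlet")
  paths <- list()
  discarded <- 0L
  if (mode == "flux_weighted_sampling") {
    keyset <- new.env(hash = TRUE, parent = emptyenv())
    for (w in seq_len(n_paths)) {
      node <- inlets[sample.int(length(inlets), 1L, prob = inlet_w)]
      segp <- integer(0)
      ok <- FALSE
      for (step in seq_len(ns)) {
        outs <- out_of[[as.character(node)]]
        if (is.null(outs) || !length(outs)) break
        s <- if (length(outs) == 1L) outs else
          outs[sample.int(length(outs), 1L, prob = aQ[outs])]
        segp <- c(segp, s)
        node <- dn[s]
        if (role[node] == "venous_outlet") { ok <- TRUE; break }
      }
      if (!ok) { discarded <- discarded + 1L; next }
      key <- paste(segp, collapse = ",")
      if (is.null(keyset[[key]])) {
        keyset[[key]] <- TRUE
        paths[[length(paths) + 1L]] <- segp
      }
    }
  } else {
    stack <- lapply(which(up %in% inlets & active), function(s) s)
    while (length(stack) && length(paths) < n_paths) {
      segp <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      node <- dn[segp[length(segp)]]
      if (role[node] == "venous_outlet") {
        paths[[length(paths) + 1L]] <- segp
        next
      }
      outs <- out_of[[as.character(node)]]
      if (is.null(outs)) { discarded <- discarded + 1L; next }
      for (s in outs) {
        if (!(s %in% segp)) stack[[length(stack) + 1L]] <- c(segp, s)
      }
    }
  }
  sdep <- segment_depth(net)
  depth_label <- vapply(paths, function(p) max(sdep[p]), numeric(1))
  layers <- assign_layers(depth_label, layer_boundaries)
  lens <- vapply(paths, function(p) sum(net$segments$length[p]), numeric(1))
  structure(list(segments = paths, depth_label = depth_label, layer = layers,
                 length = lens, net = net, field = field,
                 n_discarded = discarded,
                 layer_boundaries = layer_boundaries),
            class = "flow_paths")
}

#' @export
print.flow_paths <- function(x, ...) {
  cat("flow_paths:", length(x$segments), "distinct inlet->outlet paths",
      sprintf("(%d dead-end walks discarded)\n", x$n_discarded))
  if (length(x$segments)) {
    cat("  depth labels (um): ",
        paste(round(stats::quantile(x$depth_label, c(0, .5, 1))), collapse = " / "),
        " (min/median/max)\n")
    print(table(x$layer))
  }
  invisible(x)
}

#' Default cortical layer boundaries
#'
#' Depth boundaries (um below the pial surface) of the layer bins
#' I, II/III, IV, V, VI used to group segments and paths. Depths at or
#' beyond the last boundary map to layer VI.
#'
#' @return Named numeric vector of lower bin edges.
#' @export
default_layer_boundaries <- function() {
  c(I = 0, `II/III` = 100, IV = 420, V = 590, VI = 890)
}

#' Assign cortical layers to depth labels
#'
#' Half-open binning `[b_k, b_{k+1})`; a depth exactly on a boundary goes to
#' the deeper layer, and depths at or beyond the last boundary go to the
#' deepest layer.
#'
#' @param depth Depths, um below the pia (must be non-negative).
#' @param boundaries Strictly increasing lower bin edges, named by layer.
#' @return Factor of layer labels (ordered shallow to deep).
#' @export
assign_layers <- function(depth, boundaries = default_layer_boundaries()) {
  if (any(depth < 0)) stop("negative cortical depth")
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("layer boundaries must be strictly increasing")
  }
  lab <- names(boundaries)
  if (is.null(lab)) lab <- as.character(seq_along(boundaries))
  idx <- findInterval(depth, boundaries, left.open = FALSE)
  idx[idx < 1L] <- 1L
  factor(lab[idx], levels = lab, ordered = TRUE)
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA F statistic and p value (F distribution with
#' k-1 and N-k degrees of freedom) across groups. Degenerate input with
#' zero between-group variance returns F = 0, p = 1 (the skimming-free
#' uniform-hematocrit case).
#'
#' @param groups List of numeric vectors (>= 2 non-empty groups).
#' @return List with `F`, `p`, and the degrees of freedom.
#' @export
anova_oneway <- function(groups) {
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least two non-empty groups")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups); N <- length(vals)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - mean(vals))^2)
  df1 <- k - 1L; df2 <- N - k
  # degenerate guard: between-group spread at numerical-noise scale
  scale <- mean(abs(vals)) + 1e-300
  if (sqrt(ssb / N) < 1e-9 * scale || df2 < 1L) {
    return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  }
  ot <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  list(F = unname(ot$statistic), p = unname(ot$p.value),
       df1 = df1, df2 = df2)
}

#' Layer-wise statistics of a converged solution
#'
#' Segment-based grouping: every segment is assigned to a cortical layer by
#' its midpoint depth, and per-layer medians/quartiles of discharge
#' hematocrit, bulk flow and RBC flux are computed, together with the
#' per-layer variance of capillary RBC flux (`VarRBCFlux`) and the one-way
#' ANOVA of hematocrit across layers. Empty layers are reported as missing.
#'
#' @param net A `vascular_network`.
#' @param field A converged `vnet_solution`.
#' @param boundaries Layer boundaries, see [assign_layers()].
#' @param flux_compartment Compartment(s) over which `VarRBCFlux` is
#'   computed (default `"CAP"`, the capillary bed).
#' @return A list of class `layer_stats` with a per-layer `table`
#'   (data.frame) and the ANOVA results.
#' @export
layer_statistics <- function(net, field,
                             boundaries = default_layer_boundaries(),
                             flux_compartment = "CAP") {
  dep <- segment_depth(net)
  lay <- assign_layers(dep, boundaries)
  h <- field$h
  Qn <- abs(field$Q) * 1e12            # nL/s
  flux <- Qn * h
  iscap <- net$segments$compartment %in% flux_compartment
  lev <- levels(lay)
  qs <- function(v) stats::quantile(v, c(.25, .5, .75), names = FALSE)
  tab <- do.call(rbind, lapply(lev, function(L) {
    sel <- lay == L
    if (!any(sel)) {
      return(data.frame(layer = L, n = 0L, h_q25 = NA, h_median = NA,
                        h_q75 = NA, q_median = NA, rbc_median = NA,
                        var_rbc_flux = NA))
    }
    hq <- qs(h[sel])
    selc <- sel & iscap
    data.frame(layer = L, n = sum(sel), h_q25 = hq[1], h_median = hq[2],
               h_q75 = hq[3], q_median = stats::median(Qn[sel]),
               rbc_median = stats::median(flux[sel]),
               var_rbc_flux = if (any(selc)) stats::var(flux[selc]) else NA)
  }))
  groups <- split(h, lay)
  groups <- groups[lengths(groups) > 0]
  aov_h <- if (length(groups) >= 2L) anova_oneway(groups) else
    list(F = NA_real_, p = NA_real_, df1 = NA_integer_, df2 = NA_integer_)
  structure(list(table = tab, anova_h = aov_h, boundaries = boundaries,
                 n_segments = nrow(net$segments)),
            class = "layer_stats")
}

#' @export
print.layer_stats <- function(x, ...) {
  cat("Layer-wise hemodynamics (segment-based,", x$n_segments, "segments)\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (is.na(x$anova_h$F)) {
    cat("one-way ANOVA of h across layers: not defined (single layer)\n")
  } else {
    cat(sprintf("one-way ANOVA of h across layers: F = %.4g, p = %.3g\n",
                x$anova_h$F, x$anova_h$p))
  }
  invisible(x)
}

#' Pressure profiles along flow paths
#'
#' Long-format table of blood pressure against vessel diameter and
#' cumulative path length for every traced path, with the across-path
#' envelope (min/max pressure per diameter and length bin).
#'
#' @param paths A `flow_paths` object.
#' @return A list with `trace` (long data.frame: path, step, diameter_um,
#'   cum_length_um, pressure_mmHg, hematocrit, flow_nl_s) and `envelope`.
#' @export
pressure_profiles <- function(paths) {
  if (!length(paths$segments)) stop("no paths")
  net <- paths$net; field <- paths$field
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  up <- ifelse(field$Q >= 0, it, ih)
  trace <- do.call(rbind, lapply(seq_along(paths$segments), function(i) {
    p <- paths$segments[[i]]
    data.frame(path = i, step = seq_along(p),
               diameter_um = net$segments$diameter[p],
               cum_length_um = cumsum(net$segments$length[p]),
               pressure_mmHg = field$p[up[p]] / 133.322,
               hematocrit = field$h[p],
               flow_nl_s = abs(field$Q[p]) * 1e12)
  }))
  env_by <- function(key) {
    br <- pretty(trace[[key]], 30)
    bin <- cut(trace[[key]], br, include.lowest = TRUE)
    agg <- stats::aggregate(trace$pressure_mmHg, list(bin = bin),
                            function(v) c(min = min(v), max = max(v)))
    data.frame(bin = agg$bin, p_min = agg$x[, "min"], p_max = agg$x[, "max"])
  }
  list(trace = trace,
       envelope = list(by_diameter = env_by("diameter_um"),
                       by_length = env_by("cum_length_um")))
}

#' Hematocrit dispersion across the diameter spectrum
#'
#' Bins segments by diameter and reports per-bin counts, median and
#' interquartile range of discharge hematocrit (the variability measure).
#' Empty bins are reported as missing.
#'
#' @param net A `vascular_network`.
#' @param field A converged `vnet_solution`.
#' @param bins Number of diameter bins, or a vector of breaks (um).
#' @return data.frame with columns `d_lo`, `d_hi`, `n`, `h_median`,
#'   `h_q25`, `h_q75`, `h_iqr`.
#' @export
hematocrit_vs_diameter <- function(net, field, bins = 12) {
  d <- net$segments$diameter
  br <- if (length(bins) == 1L) seq(min(d), max(d), length.out = bins + 1L)
        else sort(bins)
  idx <- findInterval(d, br, rightmost.closed = TRUE, all.inside = TRUE)
  out <- do.call(rbind, lapply(seq_len(length(br) - 1L), function(b) {
    sel <- idx == b
    if (!any(sel)) {
      return(data.frame(d_lo = br[b], d_hi = br[b + 1L], n = 0L,
                        h_median = NA, h_q25 = NA, h_q75 = NA, h_iqr = NA))
    }
    q <- stats::quantile(field$h[sel], c(.25, .5, .75), names = FALSE)
    data.frame(d_lo = br[b], d_hi = br[b + 1L], n = sum(sel),
               h_median = q[2], h_q25 = q[1], h_q75 = q[3],
               h_iqr = q[3] - q[1])
  }))
  out
}
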