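#' Synthesis configuration
#'
#' Morphometric targets and structural parameters of the network generator.
#' Defaults encode the study conditions for a ~1.2 x 1.2 x 1.0 mm cortical
#' slab: penetrating vessels at 13 per mm^2 of pial surface, pre-capillary
#' terminal diameters around 4 um (which, with roughly 20 capillary-bed
#' entry points per penetrating vessel, gives ~12 um penetrating trunks
#' under Murray's law with exponent 3), a meshed capillary bed of ~11,000
#' nodes per mm^3 with degree-3 junctions and sub-6-um diameters, and a
#' Bezier tortuosity distribution with mean 1.12.
#'
#' @param domain A [domain_descriptor()].
#' @param pa_density,av_density Penetrating arteriole / ascending venule
#'   surface density, vessels per mm^2 of pial surface.
#' @param entry_density Capillary-bed entry points (pre/post-capillary
#'   terminals) per mm^3, per side.
#' @param terminal_diameter,terminal_diameter_sd Pre/post-capillary terminal
#'   diameter distribution, micrometers.
#' @param cap_node_density Capillary junction density, nodes per mm^3.
#' @param cap_diameter,cap_diameter_sd,cap_diameter_range Capillary segment
#'   diameter distribution (truncated normal), micrometers; upper bound must
#'   stay below the 6 um capillary/venule cutoff.
#' @param cap_degree Target capillary junction degree (3 = bifurcating bed).
#' @param mesh_reach Neighbour search radius for capillary wiring, as a
#'   multiple of the mean capillary node spacing.
#' @param murray_exponent Murray exponent `gamma` in `[2, 4]`.
#' @param root_diameter Optional prescribed feeding-root diameter (um); when
#'   set, a feeding conduit of this caliber is prepended to the pial root
#'   (e.g. 142 um for the MCA M1).
#' @param tortuosity List `(mean, sd)` of the per-segment tortuosity
#'   distribution (arc length / chord, >= 1).
#' @param min_terminal_separation Poisson-disc minimum distance between
#'   sampled terminal sites, micrometers.
#' @param k_candidates Candidate segments evaluated per CCO insertion.
#' @param pial_caliber_factor Over-capacity factor applied to pial-tree
#'   terminal calibers relative to the penetrating trunks they feed. Pial
#'   distribution vessels are sized beyond sample-local Murray continuity
#'   (they also supply adjacent territory), which keeps pressures along
#'   pial paths near the inlet value, as seen in path-analysis profiles.
#' @param balance_outflow Apply the post-growth hydraulic balancing pass
#'   that equalizes terminal outflows? Off by default: cortical penetrating
#'   trunks under-compensate for path length, which is what produces the
#'   depth-declining bulk flow of the converged solutions (see the methods
#'   vignette); equal outflow remains the growth constraint shaping
#'   attachment order and diameters.
#' @param rheology A [rheology_params()] object (used by flow balancing).
#' @return An object of class `synthesis_config`.
#' @export
synthesis_config <- function(domain = domain_descriptor(),
                             pa_density = 13, av_density = 13,
                             entry_density = 300,
                             terminal_diameter = 4.15,
                             terminal_diameter_sd = 0.3,
                             cap_node_density = 11000,
                             cap_diameter = 4.5, cap_diameter_sd = 0.55,
                             cap_diameter_range = c(2.8, 5.9),
                             cap_degree = 3L, mesh_reach = 1.9,
                             murray_exponent = 3,
                             root_diameter = NULL,
                             tortuosity = list(mean = 1.12, sd = 0.08),
                             min_terminal_separation = 25,
                             k_candidates = 20L,
                             pial_caliber_factor = 1.3,
                             balance_outflow = FALSE,
                             rheology = rheology_params()) {
  stopifnot(pa_density > 0, av_density > 0, entry_density > 0,
            cap_node_density > 0, terminal_diameter > 0,
            murray_exponent >= 2, murray_exponent <= 4,
            cap_diameter_range[1] > 0, cap_diameter_range[2] < 6,
            tortuosity$mean >= 1, min_terminal_separation >= 0)
  structure(as.list(environment()), class = "synthesis_config")
}

#' Poisson-disc terminal site sampling
#'
#' Draws `n` points uniformly inside the domain (slab interior, or the pial
#' surface when `surface = TRUE`) with all pairwise distances >= `min_sep`,
#' by grid-hashed dart throwing. Deterministic given the RNG state.
#'
#' @param domain A [domain_descriptor()].
#' @param n Number of sites.
#' @param min_sep Minimum pairwise separation, micrometers.
#' @param surface Sample on the pial plane `z = 0`?
#' @param depth_range Depth interval (um below pia) for interior sampling.
#' @param margin Lateral inset from the domain boundary, micrometers.
#' @return An `n x 3` matrix of positions.
#' @export
sample_terminal_sites <- function(domain, n, min_sep = 25, surface = FALSE,
                                  depth_range = c(60, domain$depth - 40),
                                  margin = 0) {
  stopifnot(n >= 1, min_sep >= 0)
  lo <- c(domain$x[1] + margin, domain$y[1] + margin,
          if (surface) 0 else -depth_range[2])
  hi <- c(domain$x[2] - margin, domain$y[2] - margin,
          if (surface) 0 else -depth_range[1])
  span <- pmax(hi - lo, 0)
  cell <- max(min_sep / sqrt(if (surface) 2 else 3), 1e-6)
  pts <- matrix(NA_real_, n, 3)
  grid <- new.env(hash = TRUE, parent = emptyenv())
  accepted <- 0L
  attempts <- 0L
  max_attempts <- 60L * n + 1000L
  while (accepted < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    p <- lo + stats::runif(3) * span
    if (surface) p[3] <- 0
    ci <- floor(p / cell)
    ok <- TRUE
    if (min_sep > 0) {
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        key <- paste(ci[1] + dx, ci[2] + dy, ci[3] + dz)
        idx <- grid[[key]]
        if (!is.null(idx)) {
          d2 <- colSums((t(pts[idx, , drop = FALSE]) - p)^2)
          if (any(d2 < min_sep^2)) { ok <- FALSE; break }
        }
      }
    }
    if (ok) {
      accepted <- accepted + 1L
      pts[accepted, ] <- p
      key <- paste(ci[1], ci[2], ci[3])
      grid[[key]] <- c(grid[[key]], accepted)
    }
  }
  if (accepted < n) {
    stop("could not place ", n, " sites with min_sep = ", min_sep,
         " um; try a smaller separation or a larger domain")
  }
  pts
}

# truncated-normal diameter draws
.rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  for (i in seq_len(50)) {
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  pmin(pmax(x, lo), hi)
}

# ---------------------------------------------------------------------------
# Capillary bed closure

# Wire capillary nodes into a connected, degree-capped mesh. Returns an edge
# list (pairs of node indices into `pos`).
.mesh_edges <- function(pos, degree_cap = 3L, reach) {
  K <- nrow(pos)
  if (K < 2L) return(matrix(integer(0), 0, 2))
  cellsz <- reach
  ci <- floor(pos / cellsz)
  key <- paste(ci[, 1], ci[, 2], ci[, 3])
  cellmap <- split(seq_len(K), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ii <- jj <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nk <- paste(ci[, 1] + offs[r, 1], ci[, 2] + offs[r, 2], ci[, 3] + offs[r, 3])
    hit <- cellmap[nk]
    len <- lengths(hit)
    if (sum(len) == 0L) next
    i0 <- rep.int(seq_len(K), len)
    j0 <- unlist(hit, use.names = FALSE)
    keep <- i0 < j0
    ii <- c(ii, i0[keep]); jj <- c(jj, j0[keep])
  }
  if (!length(ii)) return(matrix(integer(0), 0, 2))
  dup <- duplicated(ii * (K + 1) + jj)
  ii <- ii[!dup]; jj <- jj[!dup]
  d2 <- rowSums((pos[ii, , drop = FALSE] - pos[jj, , drop = FALSE])^2)
  keep <- d2 <= reach^2
  ii <- ii[keep]; jj <- jj[keep]; d2 <- d2[keep]
  ord <- order(d2)
  deg <- integer(K)
  sel <- logical(length(ord))
  for (k in ord) {
    a <- ii[k]; b <- jj[k]
    if (deg[a] < degree_cap && deg[b] < degree_cap) {
      sel[k] <- TRUE
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    }
  }
  edges <- cbind(ii[sel], jj[sel])
  # bridge disconnected components (prefer low-degree endpoints)
  for (pass in seq_len(200L)) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < K) g <- igraph::add_vertices(g, K - igraph::vcount(g))
    comp <- igraph::components(g)
    if (comp$no <= 1L) break
    giant <- which.max(comp$csize)
    small <- which(comp$membership != giant)
    main <- which(comp$membership == giant)
    sm_comp <- comp$membership[small[1]]
    sm <- which(comp$membership == sm_comp)
    # prefer degree-deficient endpoints so bridges do not create
    # multifurcations
    main_ok <- main[deg[main] < degree_cap]
    if (length(main_ok)) main <- main_ok
    sm_ok <- sm[deg[sm] < degree_cap]
    if (length(sm_ok)) sm <- sm_ok
    best <- c(NA, NA); bestd <- Inf
    for (v in sm) {
      d2v <- rowSums((pos[main, , drop = FALSE] -
                      matrix(pos[v, ], length(main), 3, byrow = TRUE))^2)
      w <- which.min(d2v)
      if (d2v[w] < bestd) { bestd <- d2v[w]; best <- c(v, main[w]) }
    }
    edges <- rbind(edges, best)
    deg[best] <- deg[best] + 1L
  }
  edges
}

#' Close the capillary bed between arterial and venous trees
#'
#' Joins two tree fragments through a synthetic capillary mesh: capillary
#' junction nodes are scattered through the slab at the configured density,
#' wired to their nearest neighbours into a connected mesh with junction
#' degree capped at `cap_degree`, pruned of dangling chains, and every
#' dangling tree terminal (pre/post-capillary entry point) is connected to a
#' nearby degree-deficient capillary node. Capillary diameters are drawn
#' below the 6 um capillary cutoff. No segment is clipped at the domain
#' boundary, and the closed network passes validation with zero dangling
#' interior nodes. Degenerate domains without room for capillary nodes fall
#' back to direct terminal-to-terminal capillary chains.
#'
#' @param arterial,venous Tree fragments from [cco_as_network()] (sharing
#'   one domain); their dangling interior nodes are the entry terminals.
#' @param config A [synthesis_config()].
#' @return A validated, closed `vascular_network`.
#' @export
close_capillary_bed <- function(arterial, venous, config = synthesis_config()) {
  dom <- arterial$domain
  vol_mm3 <- diff(dom$x) * diff(dom$y) * dom$depth * 1e-9
  K <- round(config$cap_node_density * vol_mm3)
  # merge fragments with id offsets
  off_n <- max(arterial$nodes$id)
  ven_nodes <- venous$nodes; ven_nodes$id <- ven_nodes$id + off_n
  ven_segs <- venous$segments
  ven_segs$id <- ven_segs$id + max(arterial$segments$id)
  ven_segs$tail <- ven_segs$tail + off_n
  ven_segs$head <- ven_segs$head + off_n
  nodes <- rbind(arterial$nodes, ven_nodes)
  segs <- rbind(arterial$segments, ven_segs)
  deg <- tabulate(c(match(segs$tail, nodes$id), match(segs$head, nodes$id)),
                  nbins = nrow(nodes))
  dang_a <- arterial$nodes$id[deg[seq_len(off_n)] == 1L &
                              arterial$nodes$role == "interior"]
  dang_v <- ven_nodes$id[deg[-seq_len(off_n)] == 1L &
                         ven_nodes$role == "interior"]
  if (!length(dang_a) || !length(dang_v)) {
    stop("no dangling entry terminals to close")
  }
  ent_pos <- function(ids) {
    i <- match(ids, nodes$id)
    cbind(nodes$x[i], nodes$y[i], nodes$z[i])
  }
  pa <- ent_pos(dang_a); pv <- ent_pos(dang_v)
  # entry diameters: continue the incident terminal segment's caliber
  ent_d <- function(ids) {
    vapply(ids, function(id) {
      d <- segs$diameter[segs$tail == id | segs$head == id]
      min(max(d[1], config$cap_diameter_range[1]), 5.9)
    }, numeric(1))
  }
  da <- ent_d(dang_a); dv <- ent_d(dang_v)
  next_nid <- max(nodes$id) + 1L
  next_sid <- max(segs$id) + 1L
  add_seg <- function(tail, head, d, len, comp) {
    data.frame(id = NA_integer_, tail = tail, head = head, diameter = d,
               length = len, compartment = comp)
  }
  new_nodes <- NULL; new_segs <- NULL
  spacing <- (vol_mm3 * 1e9 / max(K, 1))^(1 / 3)
  if (K >= 4L) {
    cap_pos <- sample_terminal_sites(dom, K, min_sep = 0.55 * spacing,
                                     depth_range = c(40, dom$depth - 20),
                                     margin = 10)
    edges <- .mesh_edges(cap_pos, config$cap_degree,
                         reach = config$mesh_reach * spacing)
    # prune dangling capillary chains (keep the mesh 2-core)
    repeat {
      degm <- tabulate(c(edges[, 1], edges[, 2]), nbins = K)
      drop <- degm <= 1L
      if (!any(drop[edges[, 1]] | drop[edges[, 2]])) break
      edges <- edges[!(drop[edges[, 1]] | drop[edges[, 2]]), , drop = FALSE]
      if (!nrow(edges)) break
    }
    keep_nodes <- sort(unique(as.vector(edges)))
    if (length(keep_nodes) >= 2L && nrow(edges) > 0) {
      remap <- integer(K); remap[keep_nodes] <- seq_along(keep_nodes)
      cap_pos <- cap_pos[keep_nodes, , drop = FALSE]
      edges <- cbind(remap[edges[, 1]], remap[edges[, 2]])
      ed <- .rtnorm(nrow(edges), config$cap_diameter, config$cap_diameter_sd,
                    config$cap_diameter_range[1], config$cap_diameter_range[2])
      # Attach each entry terminal by splitting its nearest capillary edge:
      # the inserted junction has degree 3, so closure never creates a
      # multifurcation. Entry order is interleaved arterial/venous.
      ne_a <- length(dang_a); ne_v <- length(dang_v)
      ent_all <- rbind(pa, pv)
      eids_all <- c(dang_a, dang_v)
      ediam_all <- c(da, dv)
      ecomp_all <- rep(c("PEC", "POC"), c(ne_a, ne_v))
      ord_ent <- order(rep(seq_len(max(ne_a, ne_v)), 2)[seq_len(ne_a + ne_v)])
      entry_rows <- NULL
      mids <- (cap_pos[edges[, 1], , drop = FALSE] +
               cap_pos[edges[, 2], , drop = FALSE]) / 2
      for (i in seq_len(ne_a + ne_v)) {
        ii <- ord_ent[i]
        d2 <- (mids[, 1] - ent_all[ii, 1])^2 + (mids[, 2] - ent_all[ii, 2])^2 +
          (mids[, 3] - ent_all[ii, 3])^2
        eidx <- which.min(d2)
        u <- edges[eidx, 1]; v <- edges[eidx, 2]
        w_pos <- mids[eidx, ]
        cap_pos <- rbind(cap_pos, w_pos)
        w <- nrow(cap_pos)
        # replace (u,v) by (u,w); append (w,v); both keep the old diameter
        edges[eidx, ] <- c(u, w)
        edges <- rbind(edges, c(w, v))
        ed <- c(ed, ed[eidx])
        mids[eidx, ] <- (cap_pos[u, ] + w_pos) / 2
        mids <- rbind(mids, (w_pos + cap_pos[v, ]) / 2)
        entry_rows <- rbind(entry_rows, data.frame(
          eid = eids_all[ii], w = w, d = ediam_all[ii],
          len = max(sqrt(d2[eidx]), 1), comp = ecomp_all[ii]))
      }
      Kk <- nrow(cap_pos)
      cap_ids <- next_nid + seq_len(Kk) - 1L
      next_nid <- next_nid + Kk
      new_nodes <- data.frame(id = cap_ids, x = cap_pos[, 1], y = cap_pos[, 2],
                              z = cap_pos[, 3], role = "interior")
      elen <- sqrt(rowSums((cap_pos[edges[, 1], , drop = FALSE] -
                            cap_pos[edges[, 2], , drop = FALSE])^2))
      new_segs <- rbind(
        add_seg(cap_ids[edges[, 1]], cap_ids[edges[, 2]], ed,
                pmax(elen, 1), "CAP"),
        add_seg(entry_rows$eid, cap_ids[entry_rows$w], entry_rows$d,
                entry_rows$len, entry_rows$comp))
    } else K <- 0L
  }
  if (K < 4L) {
    # degenerate fallback: direct capillary chains between nearest entries
    for (i in seq_along(dang_a)) {
      d2 <- rowSums((pv - matrix(pa[i, ], nrow(pv), 3, byrow = TRUE))^2)
      j <- which.min(d2)
      mid <- (pa[i, ] + pv[j, ]) / 2
      mid_id <- next_nid; next_nid <- next_nid + 1L
      new_nodes <- rbind(new_nodes,
                         data.frame(id = mid_id, x = mid[1], y = mid[2],
                                    z = mid[3], role = "interior"))
      dcap <- .rtnorm(1, config$cap_diameter, config$cap_diameter_sd,
                      config$cap_diameter_range[1], config$cap_diameter_range[2])
      halfl <- max(sqrt(d2[j]) / 2, 1)
      new_segs <- rbind(new_segs,
                        add_seg(dang_a[i], mid_id, dcap, halfl, "CAP"),
                        add_seg(mid_id, dang_v[j], dcap, halfl, "CAP"))
    }
  }
  new_segs$id <- next_sid + seq_len(nrow(new_segs)) - 1L
  nodes <- rbind(nodes, new_nodes)
  segs$cp <- NULL; new_segs$cp <- NULL
  segs <- rbind(segs, new_segs)
  segs$cp <- vector("list", nrow(segs))
  vascular_network(nodes, segs, dom)
}

# ---------------------------------------------------------------------------
# Tortuosity

# arc/chord ratio of a symmetric quadratic Bezier as a function of the
# relative control-point offset q = e / chord (lazy lookup table)
.tort_env <- new.env(parent = emptyenv())
.tort_table <- function() {
  if (is.null(.tort_env$tab)) {
    q <- seq(0, 3, by = 0.01)
    f <- vapply(q, function(qi) {
      cp <- rbind(c(0, 0, 0), c(0.5, qi, 0), c(1, 0, 0))
      bezier_arclength(cp, n = 200L)
    }, numeric(1))
    .tort_env$tab <- list(q = q, f = f)
  }
  .tort_env$tab
}

#' Impose Bezier tortuosity on a network
#'
#' Replaces straight segments by symmetric quadratic Bezier splines whose
#' middle control point is offset perpendicular to the chord so that the
#' achieved arc/chord ratio matches a draw from the tortuosity distribution.
#' Endpoints are unchanged; arc lengths are updated. Segments incident to a
#' boundary node (root conduits) are left straight.
#'
#' @param net A `vascular_network` with straight segments.
#' @param tortuosity List `(mean, sd)`; a point mass (`sd = 0`) at 1 leaves
#'   the network unchanged. Support below 1 is a configuration error.
#' @return The network with curved splines and updated lengths.
#' @export
apply_tortuosity <- function(net, tortuosity = list(mean = 1.12, sd = 0.08)) {
  m <- tortuosity$mean; s <- tortuosity$sd
  if (m < 1) stop("tortuosity distribution must have support >= 1")
  ns <- nrow(net$segments)
  tau <- if (s <= 0) rep(m, ns) else {
    shape <- ((m - 1) / s)^2
    rate <- (m - 1) / s^2
    if (m - 1 <= 0) rep(1, ns) else 1 + stats::rgamma(ns, shape, rate)
  }
  tau <- pmin(tau, 2.2)
  tab <- .tort_table()
  qv <- stats::approx(tab$f, tab$q, xout = pmin(tau, max(tab$f)), rule = 2)$y
  fv <- stats::approx(tab$q, tab$f, xout = qv, rule = 2)$y
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  bnd <- net$nodes$role != "interior"
  skip <- bnd[it] | bnd[ih] | qv < 1e-4
  A <- cbind(net$nodes$x[it], net$nodes$y[it], net$nodes$z[it])
  B <- cbind(net$nodes$x[ih], net$nodes$y[ih], net$nodes$z[ih])
  U <- B - A
  chord <- sqrt(rowSums(U^2))
  # random perpendicular directions
  Rv <- matrix(stats::rnorm(3 * ns), ns, 3)
  dotp <- rowSums(Rv * U) / pmax(chord^2, 1e-12)
  P <- Rv - U * dotp
  Pn <- sqrt(rowSums(P^2))
  degen <- Pn < 1e-9
  P[degen, ] <- matrix(rep(c(1, 0, 0), sum(degen)), ncol = 3, byrow = TRUE)
  Pn[degen] <- 1
  P <- P / Pn
  cps <- net$segments$cp
  Mid <- (A + B) / 2 + P * (qv * chord)
  for (i in which(!skip)) {
    cps[[i]] <- rbind(A[i, ], Mid[i, ], B[i, ])
  }
  len <- net$segments$length
  len[!skip] <- (chord * fv)[!skip]
  net$segments$cp <- cps
  net$segments$length <- len
  net
}

# ---------------------------------------------------------------------------
# High-level generators

# splice `sub` (a cco_tree) onto leaf segment `leaf_seg` of `main`;
# sub's root node must coincide with the leaf's terminal node.
.cco_splice <- function(main, leaf_seg, sub) {
  off_n <- main$n_nodes
  off_s <- length(main$tail)
  term_node <- main$head[leaf_seg]
  # sub node 1 -> term_node; others appended
  map <- c(term_node, off_n + seq_len(sub$n_nodes - 1L))
  main$pos <- rbind(main$pos, sub$pos[-1, , drop = FALSE])
  main$n_nodes <- main$n_nodes + sub$n_nodes - 1L
  idx <- seq_along(sub$tail)
  main$tail[off_s + idx] <- map[sub$tail]
  main$head[off_s + idx] <- map[sub$head]
  main$s[off_s + idx] <- sub$s
  main$nterm[off_s + idx] <- sub$nterm
  main$is_leaf[off_s + idx] <- sub$is_leaf
  main$tier[off_s + idx] <- "penetrating"
  main$parent[off_s + idx] <- ifelse(sub$parent == 0L, leaf_seg,
                                     sub$parent + off_s)
  for (i in idx) {
    main$children[[off_s + i]] <- sub$children[[i]] + off_s
  }
  subroots <- off_s + which(sub$parent == 0L)
  main$children[[leaf_seg]] <- c(main$children[[leaf_seg]], subroots)
  main$is_leaf[leaf_seg] <- FALSE
  # terminal-count correction up the pial path
  extra <- sum(sub$nterm[sub$parent == 0L]) - 1L
  anc <- leaf_seg
  while (anc != 0L) {
    main$nterm[anc] <- main$nterm[anc] + extra
    anc <- main$parent[anc]
  }
  main
}

# grow one side (pial tree + penetrating subtrees), return cco_tree with tier
# labels and balanced flows
.grow_side <- function(config, side, pial_sites, entries, root_pos) {
  dom <- config$domain
  gamma <- config$murray_exponent
  n_p <- nrow(pial_sites)
  # assign entries to the nearest pial site
  asg <- apply(entries, 1L, function(p) {
    which.min((pial_sites[, 1] - p[1])^2 + (pial_sites[, 2] - p[2])^2)
  })
  subtrees <- vector("list", n_p)
  trunk_d <- numeric(n_p)
  for (i in seq_len(n_p)) {
    pts <- entries[asg == i, , drop = FALSE]
    if (nrow(pts) == 0L) {
      # guarantee at least one entry per penetrating vessel
      pts <- matrix(c(pial_sites[i, 1], pial_sites[i, 2],
                      -stats::runif(1, 200, dom$depth - 100)), 1)
    }
    dts <- .rtnorm(nrow(pts), config$terminal_diameter,
                   config$terminal_diameter_sd,
                   config$terminal_diameter - 3 * config$terminal_diameter_sd,
                   config$terminal_diameter + 3 * config$terminal_diameter_sd)
    st <- grow_tree(c(pial_sites[i, 1], pial_sites[i, 2], 0), pts, dts,
                    gamma = gamma, domain = dom, k = config$k_candidates,
                    balance = FALSE)
    subtrees[[i]] <- st
    trunk_d[i] <- max(cco_diameters(st)[st$parent == 0L])
  }
  # pial tree over the penetrating sites; pial calibers carry an
  # over-capacity factor relative to the trunks they feed
  pial <- grow_tree(root_pos, pial_sites,
                    trunk_d * config$pial_caliber_factor, gamma = gamma,
                    domain = dom, k = config$k_candidates, balance = FALSE)
  pial$tier <- rep("pial", length(pial$tail))
  for (i in seq_len(n_p)) {
    pial <- .cco_splice(pial, pial$term_segs[i], subtrees[[i]])
  }
  if (isTRUE(config$balance_outflow)) {
    pial <- cco_balance(pial, config$rheology)
  }
  class(pial) <- "cco_tree"
  pial
}

# materialize a grown side with tier-aware compartments
.side_as_network <- function(tree, side, config) {
  net <- cco_as_network(tree, side, domain = config$domain)
  comp <- if (side == "arterial") {
    ifelse(tree$tier == "pial", "PIA", ifelse(tree$is_leaf, "PEC", "PEA"))
  } else {
    ifelse(tree$tier == "pial", "PV", ifelse(tree$is_leaf, "POC", "AV"))
  }
  net$segments$compartment <- comp
  net
}

#' Synthesize a cortical microvascular sample
#'
#' End-to-end constructive synthesis over a cortical slab: penetrating
#' arteriole and ascending venule sites are scattered over the pial surface
#' at the configured densities; capillary-bed entry points are scattered
#' through the slab and connected to their penetrating vessel by CCO growth
#' (volume-minimizing attachment, Murray diameters, equal-outflow
#' balancing); a pial arterial tree and a reverse-grown pial venous tree
#' collect the penetrating vessels to a single inlet and outlet; the
#' capillary bed is closed as a connected degree-3 mesh; and Bezier
#' tortuosity is imposed on all interior segments.
#'
#' @param config A [synthesis_config()].
#' @param seed Integer RNG seed (identical seed + config gives an identical
#'   network).
#' @return A validated `vascular_network` with compartments
#'   PIA/PEA/PEC/CAP/POC/AV/PV.
#' @export
synthesize_cortical_sample <- function(config = synthesis_config(),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dom <- config$domain
  area_mm2 <- diff(dom$x) * diff(dom$y) * 1e-6
  vol_mm3 <- area_mm2 * dom$depth * 1e-3
  n_pa <- max(1L, round(config$pa_density * area_mm2))
  n_av <- max(1L, round(config$av_density * area_mm2))
  spacing <- sqrt(area_mm2 * 1e6 / (n_pa + n_av))
  pial <- sample_terminal_sites(dom, n_pa + n_av, min_sep = 0.55 * spacing,
                                surface = TRUE, margin = 60)
  pick <- sample.int(n_pa + n_av, n_pa)
  pa_sites <- pial[pick, , drop = FALSE]
  av_sites <- pial[-pick, , drop = FALSE]
  n_ent <- max(n_pa, round(config$entry_density * vol_mm3))
  ent_a <- sample_terminal_sites(dom, n_ent, config$min_terminal_separation,
                                 margin = 30)
  ent_v <- sample_terminal_sites(dom, n_ent, config$min_terminal_separation,
                                 margin = 30)
  ymid <- mean(dom$y)
  art <- .grow_side(config, "arterial", pa_sites, ent_a,
                    c(dom$x[1] + 20, ymid, 0))
  ven <- .grow_side(config, "venous", av_sites, ent_v,
                    c(dom$x[2] - 20, ymid, 0))
  art_net <- .side_as_network(art, "arterial", config)
  ven_net <- .side_as_network(ven, "venous", config)
  net <- close_capillary_bed(art_net, ven_net, config)
  if (!is.null(config$root_diameter)) {
    net <- .add_feed_both(net, config$root_diameter)
  }
  net <- apply_tortuosity(net, config$tortuosity)
  attr(net, "synthesis") <- list(seed = seed, n_pa = n_pa, n_av = n_av,
                                 n_entries = n_ent)
  net
}

# feed conduits for both the inlet (prescribed caliber) and outlet side
.add_feed_both <- function(net, root_diameter) {
  rid_in <- which(net$nodes$role == "arterial_inlet")
  rid_out <- which(net$nodes$role == "venous_outlet")
  stopifnot(length(rid_in) == 1L, length(rid_out) == 1L)
  add_one <- function(net, rid, d, comp) {
    root <- net$nodes[rid, ]
    newid <- max(net$nodes$id) + 1L
    dir <- if (root$y <= mean(net$domain$y)) 1 else -1
    fl <- 400
    feed <- data.frame(id = newid, x = root$x, y = root$y + dir * fl, z = 0,
                       role = root$role)
    arterial <- root$role == "arterial_inlet"
    net$nodes$role[rid] <- "interior"
    seg <- data.frame(id = max(net$segments$id) + 1L,
                      tail = if (arterial) newid else root$id,
                      head = if (arterial) root$id else newid,
                      diameter = d, length = fl, compartment = comp)
    seg$cp <- list(NULL)
    net$nodes <- rbind(net$nodes, feed)
    net$segments <- rbind(net$segments, seg)
    net
  }
  net <- add_one(net, rid_in, root_diameter, "PIA")
  net <- add_one(net, which(net$nodes$role == "venous_outlet"),
                 root_diameter * 1.2, "PV")
  net
}

#' Synthesize a middle-cerebral-artery territory at reduced scale
#'
#' Grows an MCA-like territory over a pial surface patch: the feeding M1
#' conduit (prescribed 142 um caliber) supplies a pial arterial tree whose
#' terminals are penetrating arterioles at 13 per mm^2 with microcirculatory
#' growth to ~1 mm depth, closed through the capillary mesh and drained by a
#' reverse-grown venous side. At `scale = 1` the construction targets the
#' full ~40 mm^2 territory (~10^6 segments); at reduced scale all densities
#' and diameters (intensive properties) are preserved.
#'
#' @param config A [synthesis_config()]; `root_diameter` defaults to 142 um.
#' @param scale Fraction of the full territory surface area, in (0, 1].
#' @param seed Integer RNG seed.
#' @param full_area_mm2 Full MCA territory pial area, mm^2.
#' @return A validated `vascular_network`.
#' @export
synthesize_mca_territory <- function(config = NULL, scale = 0.05, seed = NULL,
                                     full_area_mm2 = 39.5) {
  stopifnot(scale > 0, scale <= 1)
  area <- scale * full_area_mm2
  if (area < 1) stop("scaled territory below 1 mm^2; increase scale")
  side_um <- sqrt(area) * 1000
  dom <- domain_descriptor(x = c(0, side_um), y = c(0, side_um), depth = 1000)
  if (is.null(config)) {
    # a territory is self-contained: its pial tree supplies exactly the
    # territory, so no sample-style pial over-capacity factor
    config <- synthesis_config(domain = dom, root_diameter = 142,
                               pial_caliber_factor = 1)
  } else {
    config$domain <- dom
    if (is.null(config$root_diameter)) config$root_diameter <- 142
  }
  net <- synthesize_cortical_sample(config, seed)
  attr(net, "synthesis")$scale <- scale
  net
}
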