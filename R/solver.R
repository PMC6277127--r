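#' Boundary conditions for the biphasic solve
#'
#' Defaults are the standard microcirculatory conditions: arterial inlet
#' pressure 120 mmHg, venous outlet pressure 5 mmHg, inlet discharge
#' hematocrit 0.35. Outlet hematocrit is fully developed (zero gradient,
#' automatic in the advection solve); closed boundaries carry zero flux by
#' construction (no segment crosses the domain boundary).
#'
#' @param inlet_pressure Arterial inlet pressure(s), mmHg. Either a scalar
#'   applied to every inlet or a named vector keyed by inlet node id.
#' @param outlet_pressure Venous outlet pressure(s), mmHg.
#' @param inlet_hematocrit Discharge hematocrit entering at every inlet.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(inlet_pressure = 120, outlet_pressure = 5,
                                inlet_hematocrit = 0.35) {
  if (any(inlet_pressure <= outlet_pressure)) {
    stop("inlet pressure must exceed outlet pressure")
  }
  if (inlet_hematocrit <= 0 || inlet_hematocrit >= 1) {
    stop("inlet hematocrit must lie in (0, 1)")
  }
  structure(list(inlet_pressure = inlet_pressure,
                 outlet_pressure = outlet_pressure,
                 inlet_hematocrit = inlet_hematocrit),
            class = "boundary_conditions")
}

#' Solver configuration
#'
#' @param relax Under-relaxation factor for the hematocrit update in the
#'   Picard alternation, in (0, 1].
#' @param tol Convergence tolerance on the relative L-infinity change of both
#'   the hematocrit and flow fields between iterations.
#' @param max_iter Maximum Picard iterations.
#' @param zero_flow_tol Segments with `|Q|` below this fraction of the median
#'   nonzero `|Q|` are treated as stagnant: they carry no RBC flux and
#'   inherit the mixed hematocrit of their higher-pressure endpoint.
#' @param rheology A [rheology_params()] object.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(relax = 0.5, tol = 1e-6, max_iter = 200L,
                          zero_flow_tol = 1e-9,
                          rheology = rheology_params()) {
  stopifnot(relax > 0, relax <= 1, tol > 0, max_iter >= 1)
  structure(list(relax = relax, tol = tol, max_iter = as.integer(max_iter),
                 zero_flow_tol = zero_flow_tol, rheology = rheology),
            class = "solver_config")
}

# mmHg <-> Pa
mmHg_to_Pa <- function(p) p * 133.322

# Dirichlet pressure vector (Pa) over boundary nodes, from bc spec
.bc_pressures <- function(net, bc) {
  role <- net$nodes$role
  p <- rep(NA_real_, nrow(net$nodes))
  pick <- function(spec, ids) {
    if (!is.null(names(spec))) {
      out <- spec[as.character(ids)]
      if (any(is.na(out))) stop("missing boundary pressure for node(s) ",
                                paste(ids[is.na(out)], collapse = ", "))
      as.numeric(out)
    } else rep(spec[1], length(ids))
  }
  inl <- which(role == "arterial_inlet"); out <- which(role == "venous_outlet")
  p[inl] <- mmHg_to_Pa(pick(bc$inlet_pressure, net$nodes$id[inl]))
  p[out] <- mmHg_to_Pa(pick(bc$outlet_pressure, net$nodes$id[out]))
  p
}

#' Solve the linear pressure/flow problem at fixed hematocrit
#'
#' Eliminates the per-segment flows from the Poiseuille and conservation
#' relations, leaving the sparse symmetric positive-definite nodal system
#' for the pressures. Flows follow segment-wise from the pressure
#' differences. Dirichlet pressures are applied at inlets and outlets;
#' interior conservation holds to linear-solver accuracy.
#'
#' @param net A `vascular_network`.
#' @param h Per-segment discharge hematocrit.
#' @param bc A [boundary_conditions()] object.
#' @param params A [rheology_params()] object.
#' @return List with `p` (Pa, per node), `Q` (m^3/s, signed, per segment)
#'   and `R` (Pa*s/m^3, per segment).
#' @export
solve_pressure_flow <- function(net, h, bc = boundary_conditions(),
                                params = rheology_params()) {
  ns <- nrow(net$segments); nn <- nrow(net$nodes)
  stopifnot(length(h) == ns)
  R <- segment_resistance(net$segments$diameter, net$segments$length, h, params)
  g <- 1 / R
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  # weighted graph Laplacian
  L <- Matrix::sparseMatrix(i = c(it, ih, it, ih), j = c(it, ih, ih, it),
                            x = c(g, g, -g, -g), dims = c(nn, nn))
  pb <- .bc_pressures(net, bc)
  fixed <- !is.na(pb)
  if (!any(fixed)) stop("no boundary nodes with prescribed pressure")
  free <- which(!fixed)
  p <- pb
  if (length(free)) {
    Lff <- L[free, free, drop = FALSE]
    rhs <- -L[free, fixed, drop = FALSE] %*% pb[fixed]
    # SPD provided every component touches a boundary node
    sol <- tryCatch(
      Matrix::solve(Matrix::forceSymmetric(Lff), rhs),
      error = function(e) {
        g2 <- network_igraph(net)
        comps <- igraph::components(g2)
        nob <- which(!tapply(fixed, comps$membership, any))
        stop("singular pressure system; component(s) without boundary node: ",
             paste(nob, collapse = ", "))
      })
    p[free] <- as.numeric(sol)
  }
  Q <- g * (p[it] - p[ih])
  list(p = p, Q = Q, R = R)
}

# Flow-orientation bookkeeping: for each segment the upstream/downstream node
# index given the sign of Q; stagnant segments flagged.
.orient_flows <- function(net, Q, zero_flow_tol) {
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  aQ <- abs(Q)
  medQ <- stats::median(aQ[aQ > 0])
  if (!is.finite(medQ) || medQ <= 0) medQ <- max(aQ, 1e-30)
  stagnant <- aQ <= zero_flow_tol * medQ
  up <- ifelse(Q >= 0, it, ih)
  dn <- ifelse(Q >= 0, ih, it)
  list(up = up, dn = dn, aQ = aQ, stagnant = stagnant)
}

#' Solve the hematocrit advection problem at fixed flow
#'
#' Assembles the junction-local advection operator over the flow-directed
#' graph — converging nodes mix flux-weighted ([junction_mix()]), diverging
#' nodes split by the kinetic plasma-skimming rule ([kpsm_split()]'s linear
#' kernel), inlets carry the boundary hematocrit, outlets inherit upstream
#' values — and solves the resulting sparse linear system. Meshed capillary
#' beds with flow-directed cycles are handled by the sparse solve directly.
#' Stagnant segments are excluded and inherit the mixed hematocrit of their
#' higher-pressure endpoint.
#'
#' @param net A `vascular_network`.
#' @param Q Signed per-segment flows (m^3/s), conservative at interior nodes.
#' @param p Per-node pressures (Pa), used only to orient stagnant segments.
#' @param bc A [boundary_conditions()] object.
#' @param params A [rheology_params()] object.
#' @param zero_flow_tol See [solver_config()].
#' @return List with `h` (per segment, clamped to `[0, h_max]`) and
#'   `stagnant` (logical flags).
#' @export
solve_hematocrit <- function(net, Q, p = NULL, bc = boundary_conditions(),
                             params = rheology_params(),
                             zero_flow_tol = 1e-9) {
  ns <- nrow(net$segments); nn <- nrow(net$nodes)
  ori <- .orient_flows(net, Q, zero_flow_tol)
  act <- which(!ori$stagnant)
  role <- net$nodes$role
  e <- if (is.infinite(params$m)) 1 else (params$m + 1) / params$m
  # Linear system A h = b over segments: h_s - sum_j c_sj h_j = b_s where j
  # runs over the active inflow segments of s's upstream node. Assembly is
  # vectorized over segments grouped by upstream node.
  b <- numeric(ns)
  u_out <- ori$up[act]                  # upstream node of each active segment
  u_in <- ori$dn[act]                   # node each active segment feeds
  # split-kernel flux fractions per upstream node
  w <- ori$aQ[act]^e
  sw <- numeric(nn)
  agg <- rowsum(w, u_out)
  sw[as.integer(rownames(agg))] <- agg[, 1]
  coef <- (w / sw[u_out]) / ori$aQ[act] # h_out = coef * sum(|Q_in| h_in)
  # inflow lists grouped by node
  o_in <- order(u_in)
  ins_sorted <- act[o_in]
  cnt_in <- tabulate(u_in, nbins = nn)
  start_in <- cumsum(c(0L, cnt_in))
  from_inlet <- role[u_out] == "arterial_inlet"
  orphan <- cnt_in[u_out] == 0L & !from_inlet
  b[act[from_inlet | orphan]] <- bc$inlet_hematocrit
  couple <- which(!from_inlet & !orphan)
  ni <- cnt_in[u_out[couple]]
  rows <- rep(act[couple], times = ni)
  col_idx <- sequence(ni) + rep(start_in[u_out[couple]], times = ni)
  cols <- ins_sorted[col_idx]
  vals <- rep(coef[couple], times = ni) * ori$aQ[cols]
  diag_i <- seq_len(ns)
  A <- Matrix::sparseMatrix(i = c(rows, diag_i), j = c(cols, diag_i),
                            x = c(-vals, rep(1, ns)), dims = c(ns, ns))
  stag <- which(ori$stagnant)
  h <- as.numeric(Matrix::solve(A, b))
  h <- pmin(pmax(h, 0), params$h_max)
  if (length(stag)) {
    # stagnant: mixed hematocrit of the higher-pressure endpoint
    it <- match(net$segments$tail, net$nodes$id)
    ih <- match(net$segments$head, net$nodes$id)
    for (s in stag) {
      nd <- if (!is.null(p) && p[ih[s]] > p[it[s]]) ih[s] else it[s]
      sel <- if (cnt_in[nd] > 0L) {
        ins_sorted[start_in[nd] + seq_len(cnt_in[nd])]
      } else integer(0)
      h[s] <- if (length(sel)) junction_mix(ori$aQ[sel], h[sel])
              else bc$inlet_hematocrit
    }
  }
  list(h = h, stagnant = ori$stagnant)
}

#' Solve the coupled biphasic network flow problem
#'
#' Picard alternation between the linear pressure/flow solve at fixed
#' hematocrit and the linear hematocrit advection solve at fixed flow, with
#' under-relaxation of the hematocrit update. Flow-direction changes between
#' iterations are honored by re-assembling the advection operator each pass.
#'
#' @param net A `vascular_network`.
#' @param bc A [boundary_conditions()] object.
#' @param config A [solver_config()] object.
#' @param h_init Optional initial hematocrit field (default: the inlet
#'   hematocrit everywhere); the converged solution is insensitive to it.
#' @return An object of class `vnet_solution`: per-node pressures `p` (Pa),
#'   signed per-segment flows `Q` (m^3/s), per-segment discharge hematocrits
#'   `h`, iteration history, and convergence flag.
#' @export
solve_biphasic <- function(net, bc = boundary_conditions(),
                           config = solver_config(), h_init = NULL) {
  assert_valid_network(net)
  params <- config$rheology
  ns <- nrow(net$segments)
  h <- if (is.null(h_init)) rep(bc$inlet_hematocrit, ns)
       else rep_len(h_init, ns)
  Q_old <- NULL
  hist <- data.frame(iter = integer(0), dh = numeric(0), dQ = numeric(0))
  converged <- FALSE
  for (iter in seq_len(config$max_iter)) {
    pf <- solve_pressure_flow(net, h, bc, params)
    hs <- solve_hematocrit(net, pf$Q, pf$p, bc, params, config$zero_flow_tol)
    h_new <- (1 - config$relax) * h + config$relax * hs$h
    # stagnant segments carry no RBC flux and are decoupled from the
    # advection system; their placeholder h is excluded from the norm
    act <- !hs$stagnant
    dh <- max(abs(h_new - h)[act]) / max(max(abs(h[act])), 1e-12)
    dQ <- if (is.null(Q_old)) Inf else
      max(abs(pf$Q - Q_old)) / max(max(abs(pf$Q)), 1e-30)
    hist <- rbind(hist, data.frame(iter = iter, dh = dh, dQ = dQ))
    h <- h_new
    Q_old <- pf$Q
    if (dh < config$tol && dQ < config$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("biphasic solve did not converge in ", config$max_iter,
         " iterations (last dh = ", signif(hist$dh[nrow(hist)], 3),
         ", dQ = ", signif(hist$dQ[nrow(hist)], 3), ")")
  }
  # final consistent fields at the converged hematocrit
  pf <- solve_pressure_flow(net, h, bc, params)
  hs <- solve_hematocrit(net, pf$Q, pf$p, bc, params, config$zero_flow_tol)
  structure(list(p = pf$p, Q = pf$Q, h = hs$h, R = pf$R,
                 stagnant = hs$stagnant, iterations = iter,
                 history = hist, converged = TRUE,
                 bc = bc, config = config),
            class = "vnet_solution")
}

#' @export
print.vnet_solution <- function(x, ...) {
  cat("vnet_solution:", length(x$Q), "segments,", length(x$p), "nodes\n")
  cat("  converged in", x$iterations, "iterations\n")
  cat("  pressure range:", signif(min(x$p) / 133.322, 4), "-",
      signif(max(x$p) / 133.322, 4), "mmHg\n")
  cat("  hematocrit range:", signif(min(x$h), 3), "-", signif(max(x$h), 3),
      "\n")
  invisible(x)
}

#' @export
summary.vnet_solution <- function(object, ...) {
  print(object)
  cat("  |Q| median:", signif(stats::median(abs(object$Q)) * 1e12, 4),
      "nL/s; stagnant segments:", sum(object$stagnant), "\n")
  invisible(object)
}

#' Total arterial inflow of a converged solution, m^3/s
#' @param net A `vascular_network`.
#' @param field A `vnet_solution` for `net`.
#' @return Total volumetric inflow across arterial inlets (m^3/s).
#' @export
total_inflow <- function(net, field) {
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  inl <- which(net$nodes$role == "arterial_inlet")
  sum(vapply(inl, function(n) {
    sum(field$Q[it == n]) - sum(field$Q[ih == n])
  }, numeric(1)))
}

#' Tissue perfusion of a converged solution
#'
#' Perfusion = total arterial inflow / (tissue volume x tissue density),
#' reported in the conventional ml/100g/min together with the SI m^3/kg/s.
#'
#' @param net A `vascular_network`.
#' @param field A `vnet_solution`.
#' @param tissue_density Tissue density, g/ml (default 1.0).
#' @return List with `ml_100g_min`, `m3_kg_s` and `inflow_nl_s`.
#' @export
compute_perfusion <- function(net, field, tissue_density = 1.0) {
  vol_mm3 <- tissue_volume(net)
  if (vol_mm3 <= 0) stop("zero tissue volume")
  Qin <- total_inflow(net, field)                 # m^3/s
  mass_kg <- vol_mm3 * 1e-3 * tissue_density      # mm^3 * g/ml -> g, /1000 -> kg
  mass_kg <- mass_kg * 1e-3
  m3_kg_s <- Qin / mass_kg
  list(ml_100g_min = m3_kg_s * 6e6, m3_kg_s = m3_kg_s,
       inflow_nl_s = Qin * 1e12)
}

#' Per-segment RBC volumetric flux
#'
#' The volumetric flow rate of the red-blood-cell phase, `|Q| * h`.
#'
#' @param field A `vnet_solution`.
#' @return Numeric vector (m^3/s) over segments.
#' @export
rbc_flux <- function(field) abs(field$Q) * field$h
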