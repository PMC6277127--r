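#' Rheology parameters
#'
#' Bundles the constitutive constants of the biphasic blood model: plasma
#' viscosity, the kinetic plasma-skimming coefficient `m`, the hematocrit
#' ceiling used when clamping junction splits, and the choice of
#' diameter/hematocrit-dependent relative viscosity law.
#'
#' @param plasma_viscosity Plasma dynamic viscosity in Pa*s.
#' @param m Skimming coefficient of the kinetic plasma-skimming split rule.
#'   Larger `m` means weaker skimming; `m = Inf` disables skimming entirely
#'   (proportional RBC split). Default 8, the value used for all
#'   microcirculatory runs.
#' @param h_max Upper clamp for discharge hematocrit, in (0, 1).
#' @param viscosity_law `"in_vivo"` (the in-vivo apparent-viscosity core
#'   curve, the default), `"in_vivo_esl"` (adds the \eqn{(d/(d-1.1))^2}
#'   endothelial-surface-layer wall factor), or `"in_vitro"` (the glass-tube
#'   law, whose viscosity minimum below 20 um is the classical
#'   Fåhræus–Lindqvist dip). All three share the same shape exponent `C(d)`.
#' @return An object of class `rheology_params`.
#' @export
rheology_params <- function(plasma_viscosity = 1.2e-3, m = 8, h_max = 0.95,
                            viscosity_law = c("in_vivo", "in_vivo_esl",
                                              "in_vitro")) {
  viscosity_law <- match.arg(viscosity_law)
  stopifnot(plasma_viscosity > 0, m > 0, h_max > 0, h_max < 1)
  structure(list(plasma_viscosity = plasma_viscosity, m = m, h_max = h_max,
                 viscosity_law = viscosity_law),
            class = "rheology_params")
}

# Shape exponent C(d) shared by both viscosity laws (d in micrometers).
.visc_shape_C <- function(d) {
  t <- 1 / (1 + 1e-11 * d^12)
  (0.8 + exp(-0.075 * d)) * (-1 + t) + t
}

# Core relative viscosity at h = 0.45 (d in micrometers).
.visc_mu45 <- function(d, law) {
  if (law == "in_vitro") {
    220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  } else {
    6 * exp(-0.085 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  }
}

.law_has_wall_factor <- function(law) law == "in_vivo_esl"

#' Relative apparent blood viscosity
#'
#' Diameter- and hematocrit-dependent relative apparent viscosity of blood
#' (the Fåhræus–Lindqvist effect). The in-vitro law is the glass-tube
#' parameterization; the in-vivo law uses the in-vivo core curve, optionally
#' (`in_vivo_esl`) with a \eqn{(d/(d-1.1))^2} wall factor accounting for the
#' endothelial surface layer. Absolute blood viscosity is
#' `plasma_viscosity * relative_viscosity(...)`.
#'
#' @param d Vessel luminal diameter, micrometers (> 0). Vectorized.
#' @param h Discharge hematocrit in `[0, 1)`. Vectorized.
#' @param params A [rheology_params()] object (selects the law).
#' @return Dimensionless relative viscosity, same length as the broadcast of
#'   `d` and `h`.
#' @export
relative_viscosity <- function(d, h, params = rheology_params()) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("diameter must be positive and finite")
  if (any(!is.finite(h)) || any(h < 0) || any(h >= 1)) {
    stop("hematocrit must lie in [0, 1)")
  }
  law <- params$viscosity_law
  # wall-layer factor is singular at d = 1.1 um; clamp the factor below the
  # smallest physiological lumen rather than extrapolating
  dw <- pmax(d, 2.4)
  C <- .visc_shape_C(d)
  mu45 <- .visc_mu45(d, law)
  frac <- ((1 - h)^C - 1) / ((1 - 0.45)^C - 1)
  if (.law_has_wall_factor(law)) {
    W2 <- (dw / (dw - 1.1))^2
    (1 + (mu45 - 1) * frac * W2) * W2
  } else {
    1 + (mu45 - 1) * frac
  }
}

#' Poiseuille segment resistance
#'
#' Hydraulic resistance \eqn{R = 128 \mu(d,h) L / (\pi d^4)} of a cylindrical
#' segment, in SI units (Pa*s/m^3). Geometric arguments are given in the
#' package's micrometer convention and converted internally.
#'
#' @param d Diameter, micrometers (> 0).
#' @param L Arc length, micrometers (> 0).
#' @param h Discharge hematocrit in `[0, 1)`.
#' @param params A [rheology_params()] object.
#' @return Resistance in Pa*s/m^3 (vectorized).
#' @export
segment_resistance <- function(d, L, h, params = rheology_params()) {
  if (any(!is.finite(d)) || any(d <= 0) || any(!is.finite(L)) || any(L <= 0)) {
    stop("segment geometry must be positive and finite")
  }
  mu <- params$plasma_viscosity * relative_viscosity(d, h, params)
  d_m <- d * 1e-6
  L_m <- L * 1e-6
  128 * mu * L_m / (pi * d_m^4)
}

#' Kinetic plasma-skimming split at a diverging junction
#'
#' Distributes the red-blood-cell flux entering a junction among its outflow
#' branches. The RBC flux fraction routed to daughter `i` is
#' \eqn{\phi_i = Q_i^{(m+1)/m} / \sum_j Q_j^{(m+1)/m}}, so daughters with a
#' larger flow fraction are enriched (RBCs concentrate in the
#' stronger branch) while weak side branches skim cell-poor plasma. The rule
#' handles any number of daughters, is linear in the upstream hematocrits,
#' conserves RBC flux exactly, and reduces to a proportional (skimming-free)
#' split as `m -> Inf`. Daughter hematocrits are clamped to
#' `[0, h_max]`; any clamped excess flux is redistributed conservatively over
#' the remaining daughters.
#'
#' @param Q Outflow rates of the daughters (all > 0), any consistent unit.
#' @param d Daughter diameters, micrometers (carried for interface
#'   compatibility; the kernel depends on diameter only through `Q`).
#' @param inflow_flux Total RBC flux entering the junction,
#'   \eqn{\sum Q_{in} h_{in}}, in the same flow unit as `Q`.
#' @param params A [rheology_params()] object (supplies `m` and `h_max`).
#' @return Daughter discharge hematocrits, one per outflow.
#' @export
kpsm_split <- function(Q, d = NULL, inflow_flux, params = rheology_params()) {
  if (length(Q) < 1L) stop("at least one outflow required")
  if (any(!is.finite(Q)) || any(Q <= 0)) {
    stop("degenerate junction: outflows must be positive")
  }
  phi <- kpsm_phi(Q, params$m)
  h <- pmax(phi * inflow_flux / Q, 0)
  # clamp with conservative redistribution of the clamped excess RBC flux
  hmax <- params$h_max
  for (.pass in seq_len(length(Q))) {
    over <- h > hmax
    if (!any(over)) break
    excess <- sum((h[over] - hmax) * Q[over])
    h[over] <- hmax
    free <- which(h < hmax)
    if (length(free) == 0L || excess <= 0) break
    w <- kpsm_phi(Q[free], params$m)
    h[free] <- h[free] + excess * w / Q[free]
  }
  h
}

# RBC flux fractions of the split kernel (exponent (m+1)/m; m = Inf -> Q-proportional)
kpsm_phi <- function(Q, m) {
  e <- if (is.infinite(m)) 1 else (m + 1) / m
  w <- Q^e
  w / sum(w)
}

#' Flux-weighted mixing at a converging junction
#'
#' Mixed discharge hematocrit leaving a node where several flows merge:
#' \eqn{h_{mix} = \sum Q_j h_j / \sum Q_j}. Always lies between the extreme
#' inflow hematocrits.
#'
#' @param Q Inflow rates (sum must be > 0).
#' @param h Inflow discharge hematocrits.
#' @return The mixed hematocrit (scalar).
#' @export
junction_mix <- function(Q, h) {
  if (length(Q) != length(h)) stop("Q and h must have equal length")
  tot <- sum(Q)
  if (!is.finite(tot) || tot <= 0) stop("degenerate junction: zero total inflow")
  sum(Q * h) / tot
}
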