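# Shared fixtures and lazily cached study-scale objects. Expensive objects
# (full-size synthetic samples and their solutions) are built once per test
# session and reused across test files.

.vasonet_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.vasonet_cache[[name]])) .vasonet_cache[[name]] <- force(expr)
  .vasonet_cache[[name]]
}

# a reduced slab for fast unit tests (~2-3k segments)
small_config <- function(...) {
  synthesis_config(domain = domain_descriptor(x = c(0, 500), y = c(0, 500),
                                              depth = 800), ...)
}

small_sample <- function(seed = 11) {
  cached(paste0("small_", seed), synthesize_cortical_sample(small_config(),
                                                            seed = seed))
}

small_solution <- function(seed = 11) {
  cached(paste0("smallsol_", seed), solve_biphasic(small_sample(seed)))
}

# full study-scale ensemble used by the acceptance tests
study_sample <- function(seed) {
  cached(paste0("study_", seed),
         synthesize_cortical_sample(synthesis_config(), seed = seed))
}

study_solution <- function(seed) {
  cached(paste0("studysol_", seed), solve_biphasic(study_sample(seed)))
}

# Murray-law residual: max relative violation of d_p^gamma = sum d_c^gamma
# over bifurcations of a rooted tree network (independent recheck working
# from the materialized segment table).
murray_violation <- function(net, gamma = 3) {
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  g <- igraph::graph_from_edgelist(cbind(it, ih), directed = FALSE)
  root <- which(net$nodes$role != "interior")[1]
  bfs <- igraph::bfs(g, root = root, father = TRUE)
  father <- as.integer(bfs$father)
  key <- paste(pmin(it, ih), pmax(it, ih))
  seg_between <- function(a, b) match(paste(min(a, b), max(a, b)), key)
  worst <- 0
  for (v in seq_len(nrow(net$nodes))) {
    kids <- which(father == v)
    if (length(kids) < 2L) next
    f <- father[v]
    if (is.na(f) || f == 0) next
    dp <- net$segments$diameter[seg_between(v, f)]
    dc <- net$segments$diameter[vapply(kids, seg_between, numeric(1), a = v)]
    worst <- max(worst, abs(dp^gamma - sum(dc^gamma)) / dp^gamma)
  }
  worst
}

# independent dense solve of the pressure problem from first principles
dense_pressure_oracle <- function(net, h, bc = boundary_conditions(),
                                  params = rheology_params()) {
  segs <- net$segments
  mu <- params$plasma_viscosity * relative_viscosity(segs$diameter, h, params)
  R <- 128 * mu * (segs$length * 1e-6) / (pi * (segs$diameter * 1e-6)^4)
  g <- 1 / R
  nn <- nrow(net$nodes)
  it <- match(segs$tail, net$nodes$id)
  ih <- match(segs$head, net$nodes$id)
  L <- matrix(0, nn, nn)
  for (s in seq_along(g)) {
    L[it[s], it[s]] <- L[it[s], it[s]] + g[s]
    L[ih[s], ih[s]] <- L[ih[s], ih[s]] + g[s]
    L[it[s], ih[s]] <- L[it[s], ih[s]] - g[s]
    L[ih[s], it[s]] <- L[ih[s], it[s]] - g[s]
  }
  pb <- rep(NA_real_, nn)
  pb[net$nodes$role == "arterial_inlet"] <- bc$inlet_pressure * 133.322
  pb[net$nodes$role == "venous_outlet"] <- bc$outlet_pressure * 133.322
  free <- which(is.na(pb)); fixed <- which(!is.na(pb))
  p <- pb
  p[free] <- solve(L[free, free], -L[free, fixed, drop = FALSE] %*% pb[fixed])
  p
}
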