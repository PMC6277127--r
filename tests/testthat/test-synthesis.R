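# Constructive synthesis: site sampling, CCO growth, Murray closure,
# capillary-bed closure, tortuosity, end-to-end generation.

test_that("Poisson-disc sampling honors separation and determinism", {
  dom <- domain_descriptor(x = c(0, 1000), y = c(0, 1000), depth = 1000)
  set.seed(1)
  one <- sample_terminal_sites(dom, 1, min_sep = 20)
  expect_true(one[1] >= 0 && one[1] <= 1000 && one[3] <= 0)
  set.seed(2)
  pts <- sample_terminal_sites(dom, 100, min_sep = 20)
  expect_gte(min(stats::dist(pts)), 20)
  set.seed(7); a <- sample_terminal_sites(dom, 50, min_sep = 25)
  set.seed(7); b <- sample_terminal_sites(dom, 50, min_sep = 25)
  expect_identical(a, b)
  expect_error(sample_terminal_sites(
    domain_descriptor(x = c(0, 60), y = c(0, 60), depth = 60), 500,
    min_sep = 30), "min_sep|separation")
})

test_that("Murray recomputation matches closed forms", {
  # parent of two identical 6-um children, gamma = 3
  nodes <- data.frame(id = 1:4, x = c(0, 100, 200, 200),
                      y = c(0, 0, 50, -50), z = -100,
                      role = c("arterial_inlet", "interior", "interior",
                               "interior"))
  segs <- data.frame(id = 1:3, tail = c(1L, 2L, 2L), head = c(2L, 3L, 4L),
                     diameter = c(1, 6, 6), length = 100, compartment = "PEA")
  net <- vascular_network(nodes, segs, check = FALSE)
  out <- recompute_diameters(net, gamma = 3)
  expect_equal(out$segments$diameter[1], 7.55952629937, tolerance = 1e-10)
  # a chain keeps a constant diameter
  nodes2 <- data.frame(id = 1:3, x = c(0, 100, 200), y = 0, z = -100,
                       role = c("arterial_inlet", "interior", "interior"))
  segs2 <- data.frame(id = 1:2, tail = 1:2, head = 2:3,
                      diameter = c(9, 5), length = 100, compartment = "PEA")
  out2 <- recompute_diameters(vascular_network(nodes2, segs2, check = FALSE))
  expect_equal(out2$segments$diameter, c(5, 5))
  # cycles are rejected
  hc <- make_fixture("honeycomb_lattice")
  expect_error(recompute_diameters(hc), "cycle|tree")
})

test_that("CCO growth meets its count, determinism and Murray contracts", {
  dom <- domain_descriptor(x = c(0, 600), y = c(0, 600), depth = 600)
  set.seed(31)
  term <- sample_terminal_sites(dom, 200, min_sep = 20)
  set.seed(32)
  tr <- grow_tree(c(300, 300, 0), term, 4, domain = dom, balance = FALSE)
  expect_equal(sum(tr$is_leaf), 200L)
  net <- cco_as_network(tr, "arterial", domain = dom)
  expect_lt(murray_violation(net, 3), 1e-9)
  # balancing preserves Murray closure
  set.seed(32)
  trb <- grow_tree(c(300, 300, 0), term, 4, domain = dom, balance = TRUE)
  netb <- cco_as_network(trb, "arterial", domain = dom)
  expect_lt(murray_violation(netb, 3), 1e-9)
  # determinism: same seed, same tree
  set.seed(32)
  tr2 <- grow_tree(c(300, 300, 0), term, 4, domain = dom, balance = FALSE)
  expect_identical(tr$tail, tr2$tail)
  expect_equal(tr$pos, tr2$pos)
  expect_equal(tr$s, tr2$s)
})

test_that("balanced trees deliver equal terminal outflows within 5%", {
  dom <- domain_descriptor(x = c(0, 600), y = c(0, 600), depth = 600)
  set.seed(41)
  term <- sample_terminal_sites(dom, 60, min_sep = 30)
  tr <- grow_tree(c(300, 300, 0), term, 4.2, domain = dom, balance = TRUE)
  net <- cco_as_network(tr, "arterial", domain = dom)
  # open the terminals at equal pressure and solve single-phase flow
  leaves <- which(vasonet:::node_degree(net) == 1L &
                  net$nodes$role == "interior")
  net$nodes$role[leaves] <- "venous_outlet"
  pf <- solve_pressure_flow(net, rep(0.35, nrow(net$segments)))
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  qterm <- abs(pf$Q[ih %in% leaves | it %in% leaves])
  expect_lt((max(qterm) - min(qterm)) / stats::median(qterm), 0.05)
})

test_that("bifurcation optimization beats random candidate placements", {
  dom <- domain_descriptor(x = c(0, 400), y = c(0, 400), depth = 400)
  tree <- vasonet:::cco_new(c(200, 200, 0), gamma = 3)
  tree <- vasonet:::cco_insert(tree, c(200, 260, -200), 5, dom)
  # mirror-symmetric configuration (root on the daughters' mirror plane,
  # equal daughter flows and calibers): the optimal bifurcation lies on
  # the perpendicular bisector plane of the two daughters
  t_sym <- c(200, 140, -200)
  opt <- optimize_bifurcation(tree, 1L, t_sym, 5, dom)
  a <- tree$pos[1, ]; b <- tree$pos[2, ]
  expect_lt(abs(opt$position[2] - 200), 1.0)
  expect_lt(abs(sqrt(sum((opt$position - b)^2)) -
                sqrt(sum((opt$position - t_sym)^2))), 1.0)
  expect_gt(opt$dvolume, 0)
  # brute-force sweep: no random in-domain point does better
  g2 <- 2 / 3
  w <- c((tree$s[1] + 125)^g2, tree$s[1]^g2, 125^g2)
  vol_at <- function(x) {
    w[1] * sqrt(sum((x - a)^2)) + w[2] * sqrt(sum((x - b)^2)) +
      w[3] * sqrt(sum((x - t_sym)^2))
  }
  set.seed(9)
  rand <- replicate(20, c(stats::runif(2, 0, 400), -stats::runif(1, 0, 400)))
  best_rand <- min(apply(rand, 2, vol_at))
  expect_lte(vol_at(opt$position), best_rand + 1e-9)
})

test_that("degenerate collinear geometry falls back to the midpoint", {
  dom <- domain_descriptor(x = c(0, 400), y = c(0, 400), depth = 400)
  tree <- vasonet:::cco_new(c(0, 200, -200), gamma = 3)
  tree <- vasonet:::cco_insert(tree, c(300, 200, -200), 5, dom)
  expect_warning(
    opt <- optimize_bifurcation(tree, 1L, c(150, 200, -200), 5, dom),
    "collinear")
  expect_equal(opt$position, c(150, 200, -200), tolerance = 1e-9)
})

test_that("volume strictly increases at every growth step", {
  dom <- domain_descriptor(x = c(0, 500), y = c(0, 500), depth = 500)
  set.seed(13)
  term <- sample_terminal_sites(dom, 40, min_sep = 30)
  tree <- vasonet:::cco_new(c(250, 250, 0), gamma = 3)
  vol_prev <- 0
  for (i in seq_len(nrow(term))) {
    tree <- vasonet:::cco_insert(tree, term[i, ], 4, dom)
    vol <- vasonet:::cco_volume(tree)
    expect_gt(vol, vol_prev)
    vol_prev <- vol
  }
})

test_that("capillary closure joins all terminals without defects", {
  net <- small_sample()
  diag <- validate_network(net)
  expect_true(diag$connected)
  expect_equal(diag$n_dangling_interior, 0L)
  cap <- net$segments$compartment == "CAP"
  expect_true(any(cap))
  expect_true(all(net$segments$diameter[cap] < 6))
  # no segment pokes outside the domain (no clipping at the bounds)
  expect_true(all(net$nodes$x >= net$domain$x[1] - 1e-9 &
                  net$nodes$x <= net$domain$x[2] + 1e-9))
  expect_true(all(-net$nodes$z <= net$domain$depth + 1e-9))
})

test_that("closure of one arterial and one venous terminal makes one chain", {
  dom <- domain_descriptor(x = c(0, 120), y = c(0, 120), depth = 120)
  mk <- function(side) {
    arterial <- side == "arterial"
    nodes <- data.frame(id = 1:2,
                        x = if (arterial) c(10, 40) else c(110, 80),
                        y = 60, z = c(0, -60),
                        role = c(if (arterial) "arterial_inlet" else
                                 "venous_outlet", "interior"))
    segs <- data.frame(id = 1L, tail = if (arterial) 1L else 2L,
                       head = if (arterial) 2L else 1L, diameter = 5,
                       length = 80, compartment = if (arterial) "PEC" else "POC")
    vascular_network(nodes, segs, dom, check = FALSE)
  }
  cfg <- synthesis_config(domain = dom)
  set.seed(4)
  closed <- close_capillary_bed(mk("arterial"), mk("venous"), cfg)
  expect_equal(sum(closed$nodes$role == "arterial_inlet"), 1L)
  expect_equal(sum(closed$nodes$role == "venous_outlet"), 1L)
  expect_true(validate_network(closed)$connected)
  expect_true(all(closed$segments$diameter[closed$segments$compartment ==
                                           "CAP"] < 6))
})

test_that("tortuosity imposition hits its targets and fixes endpoints", {
  net <- make_fixture("honeycomb_lattice", rows = 4, cols = 4)
  before <- net
  set.seed(21)
  same <- apply_tortuosity(net, list(mean = 1, sd = 0))
  expect_equal(same$segments$length, before$segments$length)
  set.seed(22)
  curved <- apply_tortuosity(net, list(mean = 1.2, sd = 0))
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  bnd <- net$nodes$role != "interior"
  inner <- which(!(bnd[it] | bnd[ih]))
  chord <- vasonet:::segment_chord(net)
  for (i in inner[1:10]) {
    cp <- curved$segments$cp[[i]]
    arc <- vasonet:::bezier_arclength(cp, n = 400)
    expect_gte(arc / chord[i], 1.18)
    expect_lte(arc / chord[i], 1.22)
    expect_lt(max(abs(cp[1, ] - c(net$nodes$x[it[i]], net$nodes$y[it[i]],
                                  net$nodes$z[it[i]]))), 1e-9)
    expect_lt(max(abs(cp[nrow(cp), ] - c(net$nodes$x[ih[i]],
                                         net$nodes$y[ih[i]],
                                         net$nodes$z[ih[i]]))), 1e-9)
  }
  expect_error(apply_tortuosity(net, list(mean = 0.8, sd = 0)), "support")
})

test_that("sample synthesis is deterministic and fully labeled", {
  net <- small_sample()
  net2 <- synthesize_cortical_sample(small_config(), seed = 11)
  expect_equal(net$segments$diameter, net2$segments$diameter)
  expect_equal(net$nodes$x, net2$nodes$x)
  expect_true(all(net$segments$compartment %in%
                  c("PIA", "PEA", "PEC", "CAP", "POC", "AV", "PV")))
  expect_setequal(unique(net$segments$compartment),
                  c("PIA", "PEA", "PEC", "CAP", "POC", "AV", "PV"))
})

test_that("territory synthesis preserves intensive properties at scale", {
  net <- cached("mca_small", synthesize_mca_territory(scale = 0.04, seed = 3))
  inlet <- net$nodes$id[net$nodes$role == "arterial_inlet"]
  rootseg <- net$segments[net$segments$tail == inlet, ]
  expect_equal(rootseg$diameter, 142)
  area <- diff(net$domain$x) * diff(net$domain$y) * 1e-6
  pa_density <- attr(net, "synthesis")$n_pa / area
  expect_gte(pa_density, 10); expect_lte(pa_density, 16)
  expect_error(synthesize_mca_territory(scale = 0.01), "1 mm")
})
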