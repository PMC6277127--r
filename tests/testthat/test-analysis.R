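# Path tracing, layer assignment, layer statistics, ANOVA, profiles.

test_that("exhaustive tracing enumerates both routes of a y-tree", {
  y <- make_fixture("y_tree")
  f <- solve_biphasic(y)
  set.seed(1)
  ps <- trace_paths(y, f, n_paths = 10, mode = "exhaustive_capped")
  expect_equal(length(ps$segments), 2L)
  expect_true(all(vapply(ps$segments, function(p) p[1] == 1L, logical(1))))
})

test_that("every traced path is flow-directed and pressure-monotone", {
  net <- small_sample()
  f <- small_solution()
  set.seed(8)
  ps <- trace_paths(net, f, n_paths = 300)
  expect_gt(length(ps$segments), 0)
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  up <- ifelse(f$Q >= 0, it, ih); dn <- ifelse(f$Q >= 0, ih, it)
  for (p in ps$segments) {
    expect_equal(net$nodes$role[up[p[1]]], "arterial_inlet")
    expect_equal(net$nodes$role[dn[p[length(p)]]], "venous_outlet")
    expect_true(all(dn[p[-length(p)]] == up[p[-1]]))       # contiguity
    pr <- c(f$p[up[p]], f$p[dn[p[length(p)]]])
    expect_true(all(diff(pr) < 1e-9))                      # monotone
  }
  # determinism given the seed
  set.seed(8)
  ps2 <- trace_paths(net, f, n_paths = 300)
  expect_identical(ps$segments, ps2$segments)
})

test_that("layer assignment follows the half-open convention", {
  expect_equal(as.character(assign_layers(50)), "I")
  expect_equal(as.character(assign_layers(100)), "II/III") # boundary: deeper
  expect_equal(as.character(assign_layers(1500)), "VI")
  d <- sort(stats::runif(50, 0, 1200))
  lay <- assign_layers(d)
  expect_true(!is.unsorted(as.integer(lay)))               # monotone
  expect_error(assign_layers(-5), "negative")
  expect_error(assign_layers(10, c(0, 100, 50)), "increasing")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  res0 <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res0$F, 0); expect_equal(res0$p, 1)
  res <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$F, 1.5, tolerance = 1e-12)
  expect_equal(res$p, 0.2878641347, tolerance = 1e-9)
  # random case against an explicit sum-of-squares computation
  set.seed(12)
  gr <- list(stats::rnorm(7), stats::rnorm(5, 0.5), stats::rnorm(9, -0.3))
  res2 <- anova_oneway(gr)
  v <- unlist(gr); n <- lengths(gr); m <- vapply(gr, mean, numeric(1))
  ssb <- sum(n * (m - mean(v))^2)
  ssw <- sum(unlist(lapply(gr, function(g) (g - mean(g))^2)))
  Fh <- (ssb / 2) / (ssw / (length(v) - 3))
  expect_equal(res2$F, Fh, tolerance = 1e-10)
  expect_error(anova_oneway(list(1:3)), "two")
})

test_that("skimming-free solutions have no layer effect", {
  tl <- make_fixture("two_layer_toy")
  cfg <- solver_config(rheology = rheology_params(m = Inf))
  f <- solve_biphasic(tl, boundary_conditions(), cfg)
  ls <- layer_statistics(tl, f)
  expect_equal(ls$anova_h$F, 0)
  expect_equal(ls$anova_h$p, 1)
  expect_true(all(abs(f$h - 0.35) < 1e-9))
})

test_that("the two-layer toy shows the depth effect at m = 8", {
  tl <- make_fixture("two_layer_toy")
  f <- solve_biphasic(tl)
  # deep capillary (segment 6) vs shallow capillary (segment 7)
  expect_gt(f$h[6], f$h[7])
  # the deep route is the stronger branch at the dividing junction
  expect_gt(abs(f$Q[4]), abs(f$Q[3]))
})

test_that("layer statistics group by segment midpoint depth", {
  net <- small_sample()
  f <- small_solution()
  ls <- layer_statistics(net, f)
  tab <- ls$table
  expect_equal(sum(tab$n), nrow(net$segments))
  expect_true(all(tab$h_q25 <= tab$h_median & tab$h_median <= tab$h_q75,
                  na.rm = TRUE))
  expect_true(all(tab$var_rbc_flux >= 0, na.rm = TRUE))
  # depth effect: deepest populated layer exceeds layer I in median h
  pop <- tab[tab$n > 50, ]
  expect_gt(pop$h_median[nrow(pop)], pop$h_median[1])
  expect_lt(ls$anova_h$p, 0.01)
})

test_that("pressure profiles are linear on a single vessel and enveloped", {
  s1 <- make_fixture("single_segment")
  f1 <- solve_biphasic(s1)
  ps1 <- trace_paths(s1, f1, n_paths = 3, mode = "exhaustive_capped")
  pr <- pressure_profiles(ps1)
  expect_equal(nrow(pr$trace), 1L)
  net <- small_sample(); f <- small_solution()
  set.seed(2)
  ps <- trace_paths(net, f, n_paths = 100)
  prof <- pressure_profiles(ps)
  expect_true(all(prof$trace$pressure_mmHg <= 120 + 1e-9))
  expect_true(all(prof$trace$pressure_mmHg >= 5 - 1e-9))
  env <- prof$envelope$by_length
  expect_true(all(env$p_min <= env$p_max))
})

test_that("hematocrit-by-diameter bins cover the spectrum", {
  net <- small_sample(); f <- small_solution()
  hb <- hematocrit_vs_diameter(net, f, bins = 10)
  expect_equal(sum(hb$n), nrow(net$segments))
  expect_lte(min(hb$d_lo), min(net$segments$diameter))
  expect_gte(max(hb$d_hi), max(net$segments$diameter))
  # capillary bins show genuine dispersion under skimming
  capbins <- hb[hb$d_hi < 6 & hb$n > 30, ]
  expect_true(any(capbins$h_iqr > 0))
  # uniform field: zero IQR everywhere
  f0 <- f; f0$h <- rep(0.35, length(f$h))
  hb0 <- hematocrit_vs_diameter(net, f0, bins = 10)
  expect_true(all(hb0$h_iqr[hb0$n > 0] == 0))
})
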