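test_that("random-walk subgraphs honour their size and connectivity contract", {
  g <- gen_small_world(80, 4, 0.2, seed = 1)
  for (i in 1:20) {
    sub <- random_walk_subgraph(g, 25, seed = i)
    expect_equal(igraph::vcount(sub), 25)
    expect_true(igraph::is_connected(sub))
  }
  # n_sub = n returns the whole graph
  whole <- random_walk_subgraph(g_c5, 5, seed = 3)
  expect_true(igraph::isomorphic(whole, g_c5))
  expect_error(random_walk_subgraph(g_c5, 9), class = "netdiv_size_error")
})

test_that("walk sampling is seed-deterministic and mostly stays in a clique", {
  g <- two_clique_graph(20)
  s1 <- sample_subgraphs(g, 10, 5, seed = 11)
  s2 <- sample_subgraphs(g, 10, 5, seed = 11)
  expect_true(all(mapply(igraph::identical_graphs, s1, s2)))
  expect_length(sample_subgraphs(g, 10, 1, seed = 1), 1)
  # most draws stay within one K20: density near the clique's
  dens <- replicate(200, igraph::edge_density(
    random_walk_subgraph(g, 10, seed = NULL)))
  expect_gte(mean(dens > 0.9), 0.8)
})

test_that("measure histograms fluctuate where structure varies and not otherwise", {
  vals <- measure_histogram(function() ring_lattice(40, 4),
                            measures = c("zagreb", "wiener"),
                            replicates = 5, seed = 1)
  expect_equal(apply(vals, 2, stats::sd), c(zagreb = 0, wiener = 0))
  # fixed-edge-count generation pins the (n, e)-determined measure
  vals2 <- measure_histogram(function() gen_erdos_renyi_m(30, 60),
                             measures = c("nEdgeComplexity", "zagreb"),
                             replicates = 30, seed = 2)
  expect_equal(stats::sd(vals2[, "nEdgeComplexity"]), 0)
  expect_gt(stats::sd(vals2[, "zagreb"]), 0)
})

test_that("parameter sweeps report means, sds and undefined sd at 1 replicate", {
  sw <- parameter_sweep(function(p) gen_erdos_renyi(25, p),
                        grid = c(0.1, 0.3), measures = c("zagreb"),
                        replicates = 5, seed = 3)
  expect_equal(nrow(sw), 2)
  expect_true(all(is.finite(sw$sd)))
  expect_lt(sw$mean[1], sw$mean[2])
  sw1 <- parameter_sweep(function(p) gen_erdos_renyi(25, p),
                         grid = 0.2, measures = "zagreb",
                         replicates = 1, seed = 4)
  expect_true(is.na(sw1$sd))
})

test_that("empirical CDFs and kernel densities behave as distributions", {
  x <- c(rnorm(50), rnorm(30, 4))
  F <- empirical_cdf(x)
  expect_equal(F(max(x)), 1)
  grid <- seq(min(x), max(x), length.out = 100)
  expect_true(all(diff(F(grid)) >= 0))
  d <- score_density(x)
  expect_equal(sum(d$y) * diff(d$x[1:2]), 1, tolerance = 0.01)
  expect_error(empirical_cdf(numeric(0)), class = "netdiv_input_error")
})

test_that("the interval classifier scores disjoint, identical and swapped classes", {
  set.seed(5)
  # three disjoint ranges: perfect accuracy
  v <- c(runif(10, 0, 1), runif(10, 2, 3), runif(10, 4, 5))
  lab <- rep(c("a", "b", "c"), each = 10)
  rep1 <- separation_score(v, lab)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$assignment, c("a", "b", "c"))
  # identical distributions: accuracy near 1/3 (plus small-sample slack)
  v2 <- rep(stats::qnorm(seq(0.01, 0.99, length.out = 30)), 3)
  lab2 <- rep(c("a", "b", "c"), times = 30)
  rep2 <- separation_score(v2, lab2)
  expect_lt(rep2$accuracy, 0.55)
  # label permutation leaves the best accuracy unchanged
  swap <- c(a = "b", b = "a", c = "c")[lab]
  expect_equal(separation_score(v, swap)$accuracy, 1)
  expect_error(separation_score(v[1:12], lab[1:12]),
               class = "netdiv_input_error")
  # overlap coefficients: disjoint classes have (near) zero overlap
  expect_lt(max(rep1$overlap[upper.tri(rep1$overlap)]), 0.05)
})

test_that("two-class separation works with a single threshold", {
  v <- c(rnorm(20, 0), rnorm(20, 10))
  lab <- rep(c("lo", "hi"), each = 20)
  rep2 <- separation_score(v, lab)
  expect_equal(rep2$accuracy, 1)
  expect_length(rep2$thresholds, 1)
})

test_that("evaluate_separation reproduces the population experiment end to end", {
  spec <- benchmark_spec(counts = c(ordered = 12, random = 12, complex = 12),
                         n = 60)
  pop <- benchmark_population(spec, seed = 15)
  out <- evaluate_separation(pop, sample_size = 5, n_estimates = 6, seed = 1)
  expect_s3_class(out$report, "separation_report")
  expect_length(out$estimates, 18)
  expect_gte(out$report$accuracy, 1 / 3)
  # deterministic under the same seed
  out2 <- evaluate_separation(pop, sample_size = 5, n_estimates = 6, seed = 1)
  expect_equal(out$estimates, out2$estimates)
})
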