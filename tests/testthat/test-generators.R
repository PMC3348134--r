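test_that("Erdos-Renyi generators hit their parameter edge cases", {
  expect_equal(igraph::ecount(gen_erdos_renyi(6, 1, seed = 1)), 15)
  expect_equal(igraph::ecount(gen_erdos_renyi(6, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(gen_erdos_renyi_m(10, 17, seed = 1)), 17)
  expect_error(gen_erdos_renyi(5, 1.5), class = "netdiv_input_error")
  expect_error(gen_erdos_renyi_m(4, 7), class = "netdiv_input_error")
})

test_that("G(n,p) edge counts match the binomial expectation", {
  set.seed(17)
  es <- replicate(2000, igraph::ecount(gen_erdos_renyi(20, 0.3)))
  expected <- 0.3 * choose(20, 2)
  se <- sqrt(choose(20, 2) * 0.3 * 0.7 / 2000)
  expect_lt(abs(mean(es) - expected), 3 * se)
  # dispersion is binomial too (variance ratio near 1)
  expect_lt(abs(var(es) / (choose(20, 2) * 0.3 * 0.7) - 1), 0.2)
})

test_that("preferential attachment produces trees, uniform limits and hubs", {
  g1 <- gen_preferential_attachment(50, 1, 1, seed = 4)
  expect_equal(igraph::ecount(g1), 49)
  expect_true(igraph::is_connected(g1))
  g0 <- gen_preferential_attachment(200, 0, 2, seed = 4)
  expect_true(igraph::is_connected(g0))
  # power = 1 produces a heavy-tailed degree distribution: the maximum hub
  # degree dwarfs the uniform-attachment one on average
  set.seed(31)
  hub_pa <- mean(replicate(10, max(igraph::degree(
    gen_preferential_attachment(500, 1, 2)))))
  hub_unif <- mean(replicate(10, max(igraph::degree(
    gen_preferential_attachment(500, 0, 2)))))
  expect_gt(hub_pa, 1.5 * hub_unif)
})

test_that("small-world graphs preserve edge counts and regularity at p = 0", {
  g <- gen_small_world(100, 4, 0, seed = 1)
  expect_equal(igraph::ecount(g), 200)
  expect_true(all(igraph::degree(g) == 4))
  for (p in c(0.1, 0.5, 1)) {
    h <- gen_small_world(100, 4, p, seed = 2)
    expect_equal(igraph::ecount(h), 200)
    expect_true(igraph::is_simple(h))
  }
  expect_error(gen_small_world(10, 3, 0.1), class = "netdiv_input_error")
})

test_that("ordered-class graphs have the stated structure and symmetry", {
  rl <- ring_lattice(100, 4)
  expect_true(all(igraph::degree(rl) == 4))
  expect_equal(topological_information_content(rl), 0)
  expect_equal(offdiagonal_complexity(rl), 0)
  expect_true(igraph::isomorphic(ring_lattice(8, 2), igraph::make_ring(8)))
  t55 <- grid_2d(5, 5, periodic = TRUE)
  expect_true(all(igraph::degree(t55) == 4))
  sw0 <- gen_small_world(60, 4, 0, seed = 9)
  expect_equal(topological_information_content(sw0), 0)
  expect_equal(offdiagonal_complexity(sw0), 0)
})

test_that("planted partitions are connected with aligned labels", {
  pp <- planted_partition(60, 3, 0.5, 0.03, seed = 6)
  expect_true(igraph::is_connected(pp$graph))
  expect_equal(length(pp$labels), 60)
  expect_equal(as.numeric(table(pp$labels)), rep(20, 3))
  # p_out = 0 without the connectivity requirement: blocks are components
  pp0 <- planted_partition(20, 2, 1, 1e-9, seed = 1, connected = FALSE)
  expect_equal(igraph::components(pp0$graph)$no, 2)
})

test_that("benchmark populations honour composition, connectivity and seeds", {
  spec <- benchmark_spec(counts = c(ordered = 10, random = 12, complex = 14),
                         n = 60)
  pop <- benchmark_population(spec, seed = 42)
  expect_equal(as.numeric(table(pop$labels)[c("ordered", "random", "complex")]),
               c(10, 12, 14))
  expect_true(all(vapply(pop$networks, igraph::is_connected, logical(1))))
  expect_true(all(vapply(pop$networks, igraph::is_simple, logical(1))))
  # determinism: same seed, bit-identical population
  pop2 <- benchmark_population(spec, seed = 42)
  same <- mapply(function(a, b) igraph::identical_graphs(a, b),
                 pop$networks, pop2$networks)
  expect_true(all(same))
  # the full-scale default mirrors the 200/600/700 composition
  full <- benchmark_spec()
  expect_equal(sum(full$count), 1500)
  expect_equal(sum(full$count[full$class == "ordered"]), 200)
  expect_equal(sum(full$count[full$class == "random"]), 600)
  expect_equal(sum(full$count[full$class == "complex"]), 700)
})

test_that("benchmark classes are calibrated to about 200 edges at n = 100", {
  spec <- benchmark_spec(counts = c(ordered = 6, random = 9, complex = 9),
                         n = 100)
  pop <- benchmark_population(spec, seed = 7)
  med <- tapply(pop$provenance$e, pop$provenance$class, stats::median)
  expect_true(all(abs(med - 200) <= 20))
})
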