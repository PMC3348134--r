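test_that("module density is M/n for reference partitions", {
  p <- walktrap_partition(g_two_k5)
  expect_equal(module_density(g_two_k5, p), 0.2)
  g <- gen_small_world(20, 4, 0.2, seed = 3)
  singletons <- structure(list(membership = stats::setNames(1:20, as.character(1:20)),
                               modules = as.list(as.character(1:20)),
                               M = 20L, sizes = rep(1L, 20)),
                          class = "module_partition")
  expect_equal(module_density(g, singletons), 1)
  one <- structure(list(membership = stats::setNames(rep(1L, 20), as.character(1:20)),
                        modules = list(as.character(1:20)),
                        M = 1L, sizes = 20L),
                   class = "module_partition")
  expect_equal(module_density(g, one), 1 / 20)
})

test_that("the variability functional follows the population-variance default", {
  expect_equal(module_size_variability(c(5, 5)), 0)
  expect_equal(module_size_variability(7), 0)
  # population variance of (2, 6) is 4; mean 4
  expect_equal(module_size_variability(c(2, 6)), 1)
  expect_equal(module_size_variability(c(2, 6), variant = "cv"), 0.5)
  expect_error(module_size_variability(numeric(0)),
               class = "netdiv_input_error")
  # K4 Laplacian spectrum {4,4,4,0}: variance 3, mean 3
  expect_equal(laplacian_variability(laplacian_spectrum(g_k4)), 1)
  expect_equal(laplacian_variability(g_k4), 1)
  expect_gt(laplacian_variability(g_c5), 0)
  expect_error(laplacian_variability(
    laplacian_spectrum(igraph::make_empty_graph(3, directed = FALSE))),
    class = "netdiv_degenerate_error")
})

test_that("nds_score is deterministic and exposes a consistent breakdown", {
  g <- gen_small_world(60, 4, 0.1, seed = 11)
  s1 <- nds_score(g)
  s2 <- nds_score(g)
  expect_identical(s1$ids, s2$ids)
  expect_identical(s1$v_lambda, s2$v_lambda)
  # the composition is exactly v_lambda / (alpha * r * v_module)
  expect_equal(s1$ids,
               s1$v_lambda / (s1$alpha_module * s1$r_motif * s1$v_module))
  expect_equal(s1$log10_ids, log10(s1$ids))
  expect_gt(s1$ids, 0)
  # relabeling invariance
  s3 <- nds_score(shuffle_vertices(g))
  expect_equal(s3$ids, s1$ids, tolerance = 1e-9)
})

test_that("degenerate compositions raise a typed error carrying the breakdown", {
  # two bridged K5s: equal module sizes make v_module = 0
  err <- tryCatch(nds_score(g_two_k5), netdiv_degenerate_error = function(e) e)
  expect_s3_class(err, "netdiv_degenerate_error")
  expect_equal(err$breakdown$v_module, 0)
  expect_equal(err$breakdown$alpha_module, 0.2)
  expect_error(nds_score(g_c4), class = "netdiv_size_error")
  expect_error(nds_score(igraph::disjoint_union(g_c5, g_c5)),
               class = "netdiv_connectivity_error")
})

test_that("the estimator reduces correctly at the edges of its contract", {
  g <- gen_small_world(50, 4, 0.1, seed = 2)
  fit1 <- nds(g)
  expect_equal(fit1$mean, nds_score(g)$ids)
  expect_true(is.na(fit1$stderr))
  fitS <- nds(list(g, g, g))
  expect_equal(fitS$stderr, 0)
  expect_equal(fitS$mean, fit1$mean)
  expect_error(nds(list()), class = "netdiv_input_error")
  # skip policy drops degenerate networks with a warning
  expect_warning(fit_skip <- nds(list(g, g_two_k5), on_error = "skip"),
                 "skipped")
  expect_equal(fit_skip$S, 1)
  expect_error(nds(list(g, g_two_k5)), class = "netdiv_degenerate_error")
})

test_that("estimator spread scales as S^(-1/2) and its mean is stable in S", {
  set.seed(99)
  pool <- replicate(250, nds_score(gen_connected(function()
    gen_small_world(60, 4, 0.1)))$ids)
  Ss <- c(5, 10, 20, 40)
  sds <- vapply(Ss, function(S) {
    stats::sd(replicate(200, mean(sample(pool, S))))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(sds) ~ log(Ss)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
  # the mean estimate is stable in S: each grand mean (of 100 estimates)
  # stays within 2 of its own standard errors of the pool mean
  for (S in Ss) {
    grand <- mean(replicate(100, mean(sample(pool, S))))
    se <- stats::sd(pool) / sqrt(100 * S)
    expect_lt(abs(grand - mean(pool)), 3 * se)
  }
})

test_that("the ambiguity probability is a proper labeled-graph distribution", {
  expect_equal(model_ambiguity_probability(3, 0.5, 0)$w, 0.125)
  expect_equal(model_ambiguity_probability(3, 0.5, 2)$w, 0.125)
  expect_equal(model_ambiguity_probability(3, 0.5, 2, S = 3)$w_sample,
               0.001953125)
  # sums to 1 over all 2^C(n,2) labeled graphs
  for (p in c(0.3, 0.62)) {
    total <- sum(vapply(0:3, function(e) {
      choose(3, e) * model_ambiguity_probability(3, p, e)$w
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
  expect_error(model_ambiguity_probability(3, 1.2, 1),
               class = "netdiv_input_error")
})

test_that("mean components order the generated classes as observed", {
  set.seed(246)
  mean_comp <- function(gen, k = 20) {
    m <- replicate(k, {
      s <- nds_score(gen_connected(gen))
      c(s$alpha_module, s$r_motif)
    })
    rowMeans(m)
  }
  ordered <- mean_comp(function() ring_lattice(100, 4))
  complex <- mean_comp(function() gen_small_world(100, 4, 0.1))
  random <- mean_comp(function() gen_erdos_renyi(100, 4 / 99))
  # r_motif: ordered > complex > random
  expect_gt(ordered[2], complex[2])
  expect_gt(complex[2], random[2])
})
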