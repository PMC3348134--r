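test_that("vertex orbits match expectations on canonical graphs", {
  expect_equal(vertex_orbits(g_c6)$sizes, 6L)
  expect_equal(sort(vertex_orbits(g_p3)$sizes), c(1L, 2L))
  expect_equal(sort(vertex_orbits(g_star3)$sizes), c(1L, 3L))
})

test_that("vertex orbits agree with full permutation search on random graphs", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(3:7, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.2, 0.8))
    expect_equal(sort(vertex_orbits(g)$sizes), oracle_orbits(g))
  }
})

test_that("topological information content is the orbit entropy in bits", {
  expect_equal(topological_information_content(g_k5), 0)
  expect_equal(topological_information_content(g_p3),
               -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3))
  expect_equal(topological_information_content(g_star3),
               -(3 / 4) * log2(3 / 4) - (1 / 4) * log2(1 / 4))
  # vanishes on vertex-transitive graphs; relabeling-invariant
  expect_equal(topological_information_content(ring_lattice(12, 4)), 0)
  set.seed(12)
  g <- igraph::sample_gnp(9, 0.4)
  expect_equal(topological_information_content(shuffle_vertices(g)),
               topological_information_content(g))
})

test_that("Bertz index is the total information of the orbit partition", {
  expect_equal(bertz_index(g_c5), 0)
  expect_equal(bertz_index(g_c6), 0)
  expect_equal(bertz_index(g_p3), 3 * log2(3) - 2 * log2(2))
  # fully resolved partition of 4 elements
  expect_equal(bertz_index(g_c4, invariant = function(g) rep(1, 4)), 8)
  expect_error(bertz_index(g_c4, invariant = function(g) numeric(0)),
               class = "netdiv_input_error")
})

test_that("Bonchev-Trinajstic index follows the distance-magnitude form", {
  expect_equal(bonchev_trinajstic(g_k3), 3 * log2(3))
  expect_equal(bonchev_trinajstic(g_p3), 6)     # 8 - 2
  expect_equal(bonchev_trinajstic(g_c4), 20)    # 24 - 4
  expect_error(bonchev_trinajstic(igraph::disjoint_union(g_k3, g_k3)),
               class = "netdiv_connectivity_error")
})

test_that("information-functional entropy honours scaling and symmetry", {
  expect_equal(information_functional_entropy(g_c5, functional_constant),
               log2(5))
  expect_equal(information_functional_entropy(g_c4, functional_constant,
                                              scale = 2), 4)
  # equal weights by symmetry on vertex-transitive graphs
  expect_equal(information_functional_entropy(g_c6), log2(6))
  expect_equal(information_functional_entropy(g_k4), log2(4))
  expect_error(
    information_functional_entropy(g_p3, functional = function(g) c(1, 0, 1)),
    class = "netdiv_functional_error"
  )
})

test_that("offdiagonal complexity is zero exactly for degree-homogeneous bands", {
  expect_equal(offdiagonal_complexity(g_c5), 0)
  expect_equal(offdiagonal_complexity(g_k4), 0)
  expect_equal(offdiagonal_complexity(ring_lattice(10, 4)), 0)
  expect_equal(offdiagonal_complexity(g_star3), 0)  # single (1,3) band
  expect_gt(offdiagonal_complexity(g_p4), 0)
  # every k-regular graph collapses to one band
  set.seed(77)
  for (k in c(2, 3, 4)) {
    g <- igraph::sample_k_regular(10, k)
    expect_equal(offdiagonal_complexity(g), 0)
  }
  expect_error(offdiagonal_complexity(igraph::make_empty_graph(3, directed = FALSE)),
               class = "netdiv_input_error")
})

test_that("spanning-tree sensitivities match the per-edge Matrix-Tree oracle", {
  s_c4 <- spanning_tree_sensitivity(g_c4)
  expect_equal(s_c4$sensitivities, rep(3, 4))
  expect_equal(s_c4$distinct_values, 3)
  s_k4 <- spanning_tree_sensitivity(g_k4)
  expect_equal(s_k4$sensitivities, rep(8, 6))
  s_tp <- spanning_tree_sensitivity(g_triangle_pendant)
  expect_equal(sort(s_tp$sensitivities), c(2, 2, 2, 3))
  expect_equal(s_tp$distinct_values, c(2, 3))
  # random graphs: s_e = tau(G) - tau(G - e) edge by edge
  set.seed(21)
  for (i in 1:15) {
    g <- random_connected_gnp(sample(4:7, 1), 0.6)
    sts <- spanning_tree_sensitivity(g)
    tau <- spanning_tree_count(g)
    for (eidx in seq_len(igraph::ecount(g))) {
      expect_equal(sts$sensitivities[eidx],
                   tau - spanning_tree_count(igraph::delete_edges(g, eidx)))
    }
  }
})

test_that("bridges lose every spanning tree", {
  set.seed(33)
  for (i in 1:10) {
    # a random connected graph with a pendant vertex: its edge is a bridge
    g <- random_connected_gnp(6, 0.5)
    g <- igraph::add_vertices(g, 1)
    g <- igraph::add_edges(g, c(1, 7))
    sts <- spanning_tree_sensitivity(g)
    tau <- spanning_tree_count(g)
    bridge_idx <- igraph::ecount(g)   # the pendant edge added last
    expect_equal(sts$sensitivities[bridge_idx], tau)
  }
})
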