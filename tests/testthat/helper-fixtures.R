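# Shared fixtures: small named graphs used across the suite.

g_p2 <- igraph::make_graph(~ a - b)
g_p3 <- igraph::make_graph(~ a - b, b - c)
g_p4 <- igraph::make_graph(~ a - b, b - c, c - d)
g_c4 <- igraph::make_ring(4)
g_c5 <- igraph::make_ring(5)
g_c6 <- igraph::make_ring(6)
g_k3 <- igraph::make_full_graph(3)
g_k4 <- igraph::make_full_graph(4)
g_k5 <- igraph::make_full_graph(5)
g_star3 <- igraph::make_star(4, mode = "undirected")
g_triangle_pendant <- igraph::make_graph(~ 1 - 2, 2 - 3, 3 - 1, 3 - 4)
g_two_k5 <- two_clique_graph(5)

# a connected ER graph, regenerating until connected
gen_connected <- function(gen, max_tries = 300) {
  for (i in seq_len(max_tries)) {
    g <- gen()
    if (igraph::is_connected(g)) return(g)
  }
  stop("no connected draw")
}

random_connected_gnp <- function(n, p) {
  gen_connected(function() igraph::sample_gnp(n, p))
}
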