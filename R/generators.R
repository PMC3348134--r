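# Seeded generators for the ordered / random / complex network classes and
# the labeled benchmark population used in the separation experiments.

#' Erdos--Renyi random graphs
#'
#' `gen_erdos_renyi()` draws `G(n, p)` (each vertex pair connected
#' independently with probability `p`); `gen_erdos_renyi_m()` draws `G(n, m)`
#' (uniform over the graphs with exactly `e` edges).
#'
#' @param n number of vertices.
#' @param p connection probability in `[0, 1]`.
#' @param e number of edges, `0 <= e <= choose(n, 2)`.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return an undirected simple igraph.
#' @export
gen_erdos_renyi <- function(n, p, seed = NULL) {
  if (!is_count(n) || n < 1) {
    stop_netdiv("`n` must be a positive integer", "netdiv_input_error")
  }
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
    stop_netdiv("`p` must be in [0, 1]", "netdiv_input_error")
  }
  with_seed(seed, igraph::sample_gnp(n, p))
}

#' @rdname gen_erdos_renyi
#' @export
gen_erdos_renyi_m <- function(n, e, seed = NULL) {
  if (!is_count(n) || n < 1) {
    stop_netdiv("`n` must be a positive integer", "netdiv_input_error")
  }
  if (!is_count(e) || e < 0 || e > choose(n, 2)) {
    stop_netdiv("`e` must be between 0 and choose(n, 2)", "netdiv_input_error")
  }
  with_seed(seed, igraph::sample_gnm(n, e))
}

#' Preferential-attachment (scale-free) graphs
#'
#' Growth model: each new vertex attaches `edges_per_step` edges to existing
#' vertices with probability proportional to `degree^power`.  `power = 1` is
#' the Barabasi--Albert model; `power = 0` is uniform attachment.  The
#' result is connected by construction, and a tree when
#' `edges_per_step = 1`.
#'
#' @param n number of vertices (`>= 3`).
#' @param power attachment exponent (`>= 0`).
#' @param edges_per_step edges added per new vertex (`>= 1`).
#' @inheritParams gen_erdos_renyi
#' @return an undirected simple igraph.
#' @export
gen_preferential_attachment <- function(n, power = 1, edges_per_step = 1,
                                        seed = NULL) {
  if (!is_count(n) || n < 3) {
    stop_netdiv("`n` must be an integer >= 3", "netdiv_input_error")
  }
  if (!is.numeric(power) || length(power) != 1L || power < 0) {
    stop_netdiv("`power` must be >= 0", "netdiv_input_error")
  }
  if (!is_count(edges_per_step) || edges_per_step < 1) {
    stop_netdiv("`edges_per_step` must be a positive integer",
                "netdiv_input_error")
  }
  with_seed(seed, igraph::sample_pa(n, power = power, m = edges_per_step,
                                    directed = FALSE))
}

#' Watts--Strogatz small-world graphs
#'
#' A ring lattice with `k_neighbors` neighbors per vertex whose edges are
#' rewired independently with probability `p_rewire`, avoiding self-loops
#' and duplicate edges; rewiring moves edges, so the edge count `n k / 2` is
#' preserved.  `p_rewire = 0` returns the exact ring lattice (ordered
#' class); `p_rewire = 1` a fully randomized graph (random class);
#' intermediate values the small-world (complex) regime.
#'
#' @param n number of vertices (`> k_neighbors`).
#' @param k_neighbors even lattice degree (`>= 2`).
#' @param p_rewire rewiring probability in `[0, 1]`.
#' @inheritParams gen_erdos_renyi
#' @return an undirected simple igraph.
#' @export
gen_small_world <- function(n, k_neighbors, p_rewire, seed = NULL) {
  if (!is_count(k_neighbors) || k_neighbors < 2 || k_neighbors %% 2 != 0) {
    stop_netdiv("`k_neighbors` must be an even integer >= 2",
                "netdiv_input_error")
  }
  if (!is_count(n) || n <= k_neighbors) {
    stop_netdiv("`n` must exceed `k_neighbors`", "netdiv_input_error")
  }
  if (!is.numeric(p_rewire) || length(p_rewire) != 1L ||
      p_rewire < 0 || p_rewire > 1) {
    stop_netdiv("`p_rewire` must be in [0, 1]", "netdiv_input_error")
  }
  with_seed(seed, igraph::sample_smallworld(1, n, k_neighbors / 2, p_rewire,
                                            loops = FALSE, multiple = FALSE))
}

#' Deterministic ordered-class graphs
#'
#' `ring_lattice(n, k)` is the circulant lattice where each vertex is
#' joined to its `k/2` nearest neighbors on each side (`k = 2` gives the
#' cycle `C_n`); `grid_2d(rows, cols, periodic)` the rectangular lattice,
#' 4-regular when periodic.
#'
#' @param n,k ring size and (even) degree, `n > k`.
#' @param rows,cols grid dimensions (each `>= 3` when periodic, to stay
#'   simple).
#' @param periodic wrap around (torus)? Default `FALSE`.
#' @return an undirected simple igraph.
#' @export
ring_lattice <- function(n, k) {
  if (!is_count(k) || k < 2 || k %% 2 != 0) {
    stop_netdiv("`k` must be an even integer >= 2", "netdiv_input_error")
  }
  if (!is_count(n) || n <= k) {
    stop_netdiv("`n` must exceed `k`", "netdiv_input_error")
  }
  igraph::make_lattice(n, nei = k / 2, periodic = TRUE)
}

#' @rdname ring_lattice
#' @export
grid_2d <- function(rows, cols, periodic = FALSE) {
  min_dim <- if (periodic) 3 else 1
  if (!is_count(rows) || !is_count(cols) || rows < min_dim || cols < min_dim) {
    stop_netdiv(sprintf("grid dimensions must be integers >= %d", min_dim),
                "netdiv_input_error")
  }
  igraph::make_lattice(c(rows, cols), periodic = periodic)
}

#' Two cliques joined by a single edge
#'
#' A standard community-detection fixture: two `K_k` cliques bridged by one
#' edge.
#'
#' @param k clique size.
#' @return an undirected simple igraph with `2k` vertices.
#' @export
two_clique_graph <- function(k) {
  if (!is_count(k) || k < 2) {
    stop_netdiv("`k` must be an integer >= 2", "netdiv_input_error")
  }
  g <- igraph::disjoint_union(igraph::make_full_graph(k),
                              igraph::make_full_graph(k))
  igraph::add_edges(g, c(1, k + 1))
}

#' Planted-partition (stochastic block) graphs
#'
#' `modules` equally sized blocks with within-block connection probability
#' `p_in` and between-block probability `p_out`; the known block labels are
#' returned alongside.  By default the graph is regenerated until connected
#' (bounded retries).
#'
#' @param n number of vertices (a multiple of `modules`).
#' @param modules number of planted blocks.
#' @param p_in,p_out connection probabilities, `p_in > p_out`.
#' @param connected regenerate until connected? Default `TRUE`.
#' @param max_tries retry bound (default 100).
#' @inheritParams gen_erdos_renyi
#' @return a list with `graph` and integer `labels`.
#' @export
planted_partition <- function(n, modules, p_in, p_out, seed = NULL,
                              connected = TRUE, max_tries = 100) {
  if (!is_count(n) || !is_count(modules) || n %% modules != 0) {
    stop_netdiv("`n` must be a positive multiple of `modules`",
                "netdiv_input_error")
  }
  if (!is.numeric(p_in) || !is.numeric(p_out) || p_in <= p_out) {
    stop_netdiv("`p_in` must exceed `p_out`", "netdiv_input_error")
  }
  sizes <- rep(n / modules, modules)
  P <- matrix(p_out, modules, modules)
  diag(P) <- p_in
  labels <- rep(seq_len(modules), times = sizes)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      g <- igraph::sample_sbm(n, pref.matrix = P, block.sizes = sizes)
      if (!connected || igraph::is_connected(g)) {
        return(list(graph = g, labels = labels))
      }
    }
    stop_netdiv(sprintf("no connected graph in %d tries; lower `modules` or raise `p_in`/`p_out`",
                        max_tries), "netdiv_generation_error")
  })
}

# ---------------------------------------------------------------------------
# Benchmark population

#' Default benchmark specification
#'
#' Builds the per-class generator blocks for a labeled benchmark of ordered,
#' random and complex networks of common size `n`, calibrated to mean degree
#' about 4 (about 200 edges at `n = 100` for every class).  Subtypes:
#' ordered = ring lattices (degree 4) and periodic grids; random =
#' `G(n, p)` at mean degrees 3.5--5 plus fully rewired small-world graphs;
#' complex = preferential attachment at powers 0.5, 1, 1.5 (2 edges per
#' step) plus small-world graphs at rewiring probability 0.1.
#'
#' @param counts named or positional counts for the three classes, default
#'   `c(ordered = 200, random = 600, complex = 700)` (the full-scale
#'   composition); use e.g. `c(60, 60, 60)` for a balanced scaled benchmark.
#' @param n network size (default 100).
#' @return a data frame with one row per block: `class`, `generator`,
#'   `args` (list-column), `count`.
#' @export
benchmark_spec <- function(counts = c(ordered = 200, random = 600,
                                      complex = 700),
                           n = 100) {
  if (length(counts) != 3L) {
    stop_netdiv("`counts` must give three class counts", "netdiv_input_error")
  }
  if (is.null(names(counts)) || !all(nzchar(names(counts)))) {
    names(counts) <- c("ordered", "random", "complex")
  }
  rows <- function(cls, gen, args, count) {
    data.frame(class = cls, generator = gen,
               args = I(list(args)), count = count)
  }
  split_count <- function(total, k) {
    base <- total %/% k
    extra <- total %% k
    base + as.integer(seq_len(k) <= extra)
  }
  # ordered: half ring lattices, half periodic grids
  no <- split_count(counts[["ordered"]], 2)
  grid_rows <- max(3, round(sqrt(n)))
  while (n %% grid_rows != 0) grid_rows <- grid_rows - 1
  spec <- rbind(
    rows("ordered", "ring_lattice", list(n = n, k = 4), no[1]),
    rows("ordered", "grid_2d",
         list(rows = grid_rows, cols = n / grid_rows, periodic = TRUE), no[2])
  )
  # random: ER at mean degrees 3.5-5, plus fully rewired small world
  deg <- c(3.5, 4, 4.5, 5)
  nr <- split_count(counts[["random"]], 5)
  for (i in seq_along(deg)) {
    spec <- rbind(spec, rows("random", "gen_erdos_renyi",
                             list(n = n, p = deg[i] / (n - 1)), nr[i]))
  }
  spec <- rbind(spec, rows("random", "gen_small_world",
                           list(n = n, k_neighbors = 4, p_rewire = 1), nr[5]))
  # complex: preferential attachment (three powers), plus small world
  nc_pa <- split_count(ceiling(counts[["complex"]] / 2), 3)
  for (i in seq_along(c(0.5, 1, 1.5))) {
    spec <- rbind(spec, rows("complex", "gen_preferential_attachment",
                             list(n = n, power = c(0.5, 1, 1.5)[i],
                                  edges_per_step = 2), nc_pa[i]))
  }
  spec <- rbind(spec, rows("complex", "gen_small_world",
                           list(n = n, k_neighbors = 4, p_rewire = 0.1),
                           counts[["complex"]] - sum(nc_pa)))
  spec[spec$count > 0, , drop = FALSE]
}

#' Generate a labeled benchmark population
#'
#' Instantiates every block of a [benchmark_spec()], regenerating each
#' stochastic network until it is connected (bounded retries, retry counts
#' recorded), so every network in the population is simple and connected.
#' Each network gets its own seed derived from the master seed, making the
#' population bit-reproducible and the provenance sufficient to regenerate
#' any single network.
#'
#' @param spec a benchmark specification data frame (default
#'   [benchmark_spec()]).
#' @param seed master integer seed.
#' @param max_tries per-network connectivity retry bound (default 100).
#' @return a list of class `labeled_population`: `networks` (list of
#'   igraphs), `labels` (character), and `provenance` (data frame: index,
#'   class, generator, args, seed, tries, n, e).
#' @export
benchmark_population <- function(spec = benchmark_spec(), seed = NULL,
                                 max_tries = 100) {
  if (!is.data.frame(spec) ||
      !all(c("class", "generator", "args", "count") %in% names(spec))) {
    stop_netdiv("`spec` must be a benchmark specification data frame",
                "netdiv_input_error")
  }
  total <- sum(spec$count)
  seeds <- derive_seeds(seed, total)
  networks <- vector("list", total)
  labels <- character(total)
  prov <- vector("list", total)
  idx <- 0L
  for (b in seq_len(nrow(spec))) {
    gen <- get(spec$generator[b], mode = "function")
    args <- spec$args[[b]]
    deterministic <- spec$generator[b] %in% c("ring_lattice", "grid_2d")
    for (j in seq_len(spec$count[b])) {
      idx <- idx + 1L
      tries <- 1L
      g <- with_seed(seeds[[idx]], {
        g <- do.call(gen, args)
        while (!igraph::is_connected(g) && tries < max_tries) {
          tries <- tries + 1L
          g <- do.call(gen, args)
        }
        g
      })
      if (!igraph::is_connected(g)) {
        stop_netdiv(sprintf("block %d: no connected network in %d tries",
                            b, max_tries), "netdiv_generation_error")
      }
      networks[[idx]] <- g
      labels[idx] <- spec$class[b]
      prov[[idx]] <- data.frame(
        index = idx, class = spec$class[b], generator = spec$generator[b],
        args = paste(names(args), unlist(args), sep = "=", collapse = ","),
        seed = if (deterministic || is.null(seeds[[idx]])) NA_real_
               else seeds[[idx]],
        tries = tries, n = igraph::vcount(g), e = igraph::ecount(g)
      )
    }
  }
  structure(list(networks = networks, labels = labels,
                 provenance = do.call(rbind, prov)),
            class = "labeled_population")
}

#' @export
print.labeled_population <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Labeled population: %d networks (%s)\n", length(x$networks),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  med <- stats::aggregate(e ~ class, data = x$provenance, FUN = stats::median)
  cat("median edges per class:",
      paste(med$class, med$e, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}
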