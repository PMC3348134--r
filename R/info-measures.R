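# Information-theoretic complexity measures.  All entropies are in bits
# (base-2 logarithms) and 0 log 0 := 0, package-wide.

#' Vertex orbits of the automorphism group
#'
#' Partitions the vertex set into orbits of the automorphism group.  The
#' group generators are obtained exactly (BLISS backend) and the orbits are
#' the connected components of the union of all generator mappings.
#'
#' @param g an undirected simple igraph.
#' @return a list of class `orbit_partition`: `classes` (list of vertex-label
#'   vectors), `sizes`, and `k` (number of orbits).
#' @examples
#' vertex_orbits(igraph::make_star(4, mode = "undirected"))$sizes
#' @export
vertex_orbits <- function(g) {
  check_graph(g)
  n <- igraph::vcount(g)
  lab <- vertex_labels(g)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (igraph::ecount(g) > 0L || n > 1L) {
    gens <- igraph::automorphism_group(g)
    for (p in gens) {
      p <- as.integer(p)
      for (i in seq_len(n)) {
        ri <- find(i); rj <- find(p[i])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  classes <- split(lab, roots)
  classes <- classes[order(vapply(classes, min, ""))]
  names(classes) <- NULL
  structure(list(classes = classes,
                 sizes = vapply(classes, length, integer(1)),
                 k = length(classes)),
            class = "orbit_partition")
}

#' @export
print.orbit_partition <- function(x, ...) {
  cat(sprintf("Orbit partition: %d orbit(s), sizes %s\n", x$k,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Topological information content
#'
#' Shannon entropy (bits) of the orbit-size proportions: it vanishes for
#' vertex-transitive graphs and is bounded by `log2(n)`.
#'
#' @inheritParams vertex_orbits
#' @return a number in `[0, log2(n)]`.
#' @export
topological_information_content <- function(g) {
  orb <- vertex_orbits(g)
  entropy_bits(orb$sizes / sum(orb$sizes))
}

#' Bertz total information index
#'
#' Total structural information of a partition of a graph-element set `X`:
#' `|X| log2 |X| - sum |X_i| log2 |X_i|`.  By default the partition is the
#' vertex-orbit partition, recovering the classical special case.
#'
#' @inheritParams vertex_orbits
#' @param invariant a function mapping the graph to a vector of partition
#'   class sizes; defaults to the orbit partition sizes.
#' @return a nonnegative number (0 when the partition has one class).
#' @export
bertz_index <- function(g, invariant = NULL) {
  check_graph(g)
  sizes <- if (is.null(invariant)) vertex_orbits(g)$sizes else invariant(g)
  sizes <- as.numeric(sizes[sizes > 0])
  if (length(sizes) == 0L) {
    stop_netdiv("invariant produced an empty partition", "netdiv_input_error")
  }
  N <- sum(sizes)
  N * log2(N) - sum(sizes * log2(sizes))
}

#' Bonchev--Trinajstic distance-magnitude information index
#'
#' Built from the Wiener index `W`, the diameter and the counts `k_i` of
#' vertex pairs at distance `i`: `W log2 W - sum_i k_i * i * log2(i)`.
#'
#' @param g a connected undirected simple igraph.
#' @return a number.
#' @export
bonchev_trinajstic <- function(g) {
  check_graph(g)
  check_connected(g, "the Bonchev-Trinajstic index")
  dm <- distance_matrix(g)
  k <- as.numeric(dm$counts)
  i <- seq_along(k)
  W <- sum(k * i)
  if (W == 0) return(0)
  W * log2(W) - sum(k * i * log2(i))
}

#' Information-functional graph entropy
#'
#' Entropy (bits) of the vertex distribution `p(v) = f(v) / sum_u f(u)`
#' induced by a strictly positive vertex weighting `f`, scaled by a constant.
#' Two functionals ship with the package: [functional_degree_association()]
#' (the default; the weight of a vertex is the total degree of its
#' neighborhood, a degree-degree association) and [functional_constant()]
#' (uniform weights, giving `log2 n`; useful for testing).
#'
#' @param g an undirected simple igraph.
#' @param functional a function `g -> positive numeric vector` over vertices.
#' @param scale positive scaling constant (default 1).
#' @return `scale * H(p)` in bits, at most `scale * log2(n)`.
#' @export
information_functional_entropy <- function(g,
                                           functional = functional_degree_association,
                                           scale = 1) {
  check_graph(g)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop_netdiv("`scale` must be a positive number", "netdiv_input_error")
  }
  f <- functional(g)
  if (length(f) != igraph::vcount(g) || any(!is.finite(f)) || any(f <= 0)) {
    stop_netdiv("the information functional must assign a strictly positive weight to every vertex",
                "netdiv_functional_error")
  }
  scale * entropy_bits(f / sum(f))
}

#' @rdname information_functional_entropy
#' @export
functional_degree_association <- function(g) {
  d <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  vapply(adj, function(nb) sum(d[as.integer(nb)]), numeric(1))
}

#' @rdname information_functional_entropy
#' @export
functional_constant <- function(g) {
  rep(1, igraph::vcount(g))
}

#' Link-correlation matrix of a graph
#'
#' `c[i, j]` counts, over all vertices of degree `i`, their neighbors of
#' degree `j`, restricted to the upper band `j >= i` (so an edge between
#' vertices of unequal degree contributes once, from its lower-degree
#' endpoint).
#'
#' @inheritParams vertex_orbits
#' @return an integer matrix `max_degree x max_degree`.
#' @export
link_correlation_matrix <- function(g) {
  check_graph(g)
  d <- igraph::degree(g)
  dmax <- max(d)
  C <- matrix(0L, dmax, dmax)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(el))) {
    di <- d[el[r, 1]]; dj <- d[el[r, 2]]
    lo <- min(di, dj); hi <- max(di, dj)
    if (lo == hi) {
      C[lo, hi] <- C[lo, hi] + 2L   # both endpoints see a same-degree neighbor
    } else {
      C[lo, hi] <- C[lo, hi] + 1L
    }
  }
  C
}

#' Offdiagonal complexity
#'
#' Entropy (bits) of the normalized off-diagonal band sums of the
#' link-correlation matrix: with `a_k = sum_i c[i, i+k]` and
#' `b_k = a_k / sum(a)`, the measure is `-sum b_k log2 b_k`.  It is 0 for
#' every regular graph (a single populated band).
#'
#' @param g an undirected simple igraph with at least one edge.
#' @return a nonnegative number.
#' @export
offdiagonal_complexity <- function(g) {
  check_graph(g)
  if (igraph::ecount(g) == 0L) {
    stop_netdiv("offdiagonal complexity requires at least one edge",
                "netdiv_input_error")
  }
  C <- link_correlation_matrix(g)
  dmax <- nrow(C)
  a <- vapply(0:(dmax - 1L), function(k) {
    i <- seq_len(dmax - k)
    sum(C[cbind(i, i + k)])
  }, numeric(1))
  entropy_bits(a / sum(a))
}

#' Spanning-tree sensitivity spectrum and summary measures
#'
#' For every edge `e`, the sensitivity `s_e = tau(G) - tau(G - e)` is the
#' number of spanning trees destroyed by deleting `e`; a bridge has
#' `s_e = tau(G)`.  The per-edge values are computed in one pass from the
#' effective resistances `R_e` of the Laplacian pseudoinverse, using
#' `tau(G - e) = tau(G) (1 - R_e)`, and are exact integers whenever `tau`
#' is exactly representable.  With `C_1 < ... < C_k` the distinct
#' sensitivities, the summary pair is
#' `STS = k / e` (distinct sensitivity values per edge) and
#' `STSD = u / C(k, 2)` where `u` is the number of unique pairwise
#' differences `C_j - C_i` (`STSD = 0` when `k = 1`).
#'
#' @param g a connected undirected simple igraph with `n >= 3`.
#' @return a list of class `sts_spectrum`: `sts`, `stsd`, `sensitivities`
#'   (per edge, ordered as `igraph::E(g)`), `distinct_values`,
#'   `unique_differences`, and `tau`.
#' @export
spanning_tree_sensitivity <- function(g) {
  check_graph(g)
  check_connected(g, "spanning-tree sensitivity")
  n <- igraph::vcount(g)
  if (n < 3L) {
    stop_netdiv("spanning-tree sensitivity requires at least 3 vertices",
                "netdiv_input_error")
  }
  tau <- spanning_tree_count(g)
  L <- igraph::laplacian_matrix(g, sparse = FALSE)
  eg <- eigen(L, symmetric = TRUE)
  nz <- seq_len(n - 1L)
  V <- eg$vectors[, nz, drop = FALSE]
  Lp <- V %*% (t(V) / eg$values[nz])           # Moore-Penrose pseudoinverse
  el <- igraph::as_edgelist(g, names = FALSE)
  R <- Lp[cbind(el[, 1], el[, 1])] + Lp[cbind(el[, 2], el[, 2])] -
    2 * Lp[cbind(el[, 1], el[, 2])]
  s <- tau * R
  if (tau < 2^53) s <- round(s)
  m <- length(s)
  # distinct values under a relative tolerance (guards floating-point noise
  # when tau overflows exact integer range)
  tol <- max(1e-9 * max(abs(s)), 1e-12)
  sv <- sort(s)
  distinct <- sv[c(TRUE, diff(sv) > tol)]
  k <- length(distinct)
  diffs <- if (k >= 2L) {
    dd <- sort(as.numeric(stats::dist(matrix(distinct))))
    dd[c(TRUE, diff(dd) > tol)]
  } else numeric(0)
  structure(list(
    sts = k / m,
    stsd = if (k >= 2L) length(diffs) / (k * (k - 1) / 2) else 0,
    sensitivities = as.numeric(s),
    distinct_values = as.numeric(distinct),
    unique_differences = as.numeric(diffs),
    tau = tau
  ), class = "sts_spectrum")
}

#' @export
print.sts_spectrum <- function(x, ...) {
  cat(sprintf("Spanning-tree sensitivity: STS = %.4g, STSD = %.4g (%d distinct value(s) over %d edges, tau = %.6g)\n",
              x$sts, x$stsd, length(x$distinct_values),
              length(x$sensitivities), x$tau))
  invisible(x)
}
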