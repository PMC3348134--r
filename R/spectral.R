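# Eigenvalue machinery: adjacency and Laplacian spectra, the two energy
# measures, and spanning-tree counting via the Matrix-Tree theorem.

#' Adjacency spectrum
#'
#' All `n` real eigenvalues of the symmetric 0/1 adjacency matrix, in
#' descending order.
#'
#' @param g an undirected simple igraph.
#' @return a numeric vector of class `netdiv_spectrum` with attribute
#'   `source = "adjacency"`.
#' @export
adjacency_spectrum <- function(g) {
  check_graph(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  structure(sort(ev, decreasing = TRUE), source = "adjacency",
            class = "netdiv_spectrum")
}

#' Laplacian spectrum
#'
#' Eigenvalues of `L = D - A`, descending.  The multiplicity of the
#' eigenvalue 0 equals the number of connected components.
#'
#' @inheritParams adjacency_spectrum
#' @return a numeric vector of class `netdiv_spectrum` with attribute
#'   `source = "laplacian"`.
#' @export
laplacian_spectrum <- function(g) {
  check_graph(g)
  L <- igraph::laplacian_matrix(g, sparse = FALSE)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  ev[abs(ev) < 1e-9] <- 0
  structure(sort(ev, decreasing = TRUE), source = "laplacian",
            class = "netdiv_spectrum")
}

#' @export
print.netdiv_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum (%d values):\n", attr(x, "source"), length(x)))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Graph energy
#'
#' `E(G) = sum |lambda_i|` over the adjacency eigenvalues; zero exactly for
#' the edgeless graph.
#'
#' @inheritParams adjacency_spectrum
#' @return a nonnegative number.
#' @export
graph_energy <- function(g) {
  sum(abs(adjacency_spectrum(g)))
}

#' Laplacian energy
#'
#' The Gutman--Zhou form `LE(G) = sum |mu_i - 2e/n|`, i.e. the total
#' deviation of the Laplacian eigenvalues from the mean degree.
#'
#' @inheritParams adjacency_spectrum
#' @return a nonnegative number, with attribute `variant = "gutman-zhou"`
#'   recording the definition in use.
#' @export
laplacian_energy <- function(g) {
  check_graph(g)
  mu <- as.numeric(laplacian_spectrum(g))
  dbar <- 2 * igraph::ecount(g) / igraph::vcount(g)
  structure(sum(abs(mu - dbar)), variant = "gutman-zhou")
}

#' Number of spanning trees
#'
#' Counts spanning trees by the Matrix-Tree theorem: `tau(G)` equals any
#' cofactor of the Laplacian, computed here as the product of the nonzero
#' Laplacian eigenvalues divided by `n`.  The count is rounded to the nearest
#' integer while it is exactly representable in double precision; beyond
#' 2^53 the returned floating-point value carries the usual precision caveat.
#'
#' @param g an undirected simple igraph with at least 2 vertices.
#' @return a nonnegative number; 0 exactly when `g` is disconnected.
#' @export
spanning_tree_count <- function(g) {
  check_graph(g)
  n <- igraph::vcount(g)
  if (n < 2L) {
    stop_netdiv("spanning trees require at least 2 vertices",
                "netdiv_input_error")
  }
  if (!igraph::is_connected(g)) return(0)
  mu <- as.numeric(laplacian_spectrum(g))
  mu <- mu[seq_len(n - 1L)]          # drop the single zero eigenvalue
  log_tau <- sum(log(mu)) - log(n)
  tau <- exp(log_tau)
  if (tau < 2^53) round(tau) else tau
}
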