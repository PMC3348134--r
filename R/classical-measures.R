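# Non-information-theoretic complexity measures and the registry of all 16
# descriptors under their conventional short labels.

#' Wiener index
#'
#' `W(G)`: sum of shortest-path distances over all unordered vertex pairs
#' (the half-sum convention, so `sum_v sigma(v) = 2 W`).
#'
#' @param g a connected undirected simple igraph.
#' @return a number.
#' @export
wiener_index <- function(g) {
  check_graph(g)
  check_connected(g, "the Wiener index")
  D <- igraph::distances(g)
  sum(D[upper.tri(D)])
}

#' First Zagreb index
#'
#' `M1 = sum_v deg(v)^2`.
#'
#' @param g an undirected simple igraph.
#' @return a number.
#' @export
zagreb_index <- function(g) {
  check_graph(g)
  sum(igraph::degree(g)^2)
}

#' Randic connectivity index
#'
#' `R = sum over edges (deg u * deg v)^(-1/2)`; the classical branching
#' index.
#'
#' @param g an undirected simple igraph.
#' @return a number (0 for the edgeless graph).
#' @export
randic_index <- function(g) {
  check_graph(g)
  d <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) return(0)
  sum(1 / sqrt(d[el[, 1]] * d[el[, 2]]))
}

#' Balaban J index
#'
#' `J = e / (gamma + 1) * sum over edges (sigma(u) sigma(v))^(-1/2)` with
#' `sigma` the per-vertex distance sums and `gamma` the cyclomatic number.
#'
#' @param g a connected undirected simple igraph.
#' @return a number.
#' @export
balaban_j <- function(g) {
  check_graph(g)
  check_connected(g, "the Balaban J index")
  D <- igraph::distances(g)
  sig <- rowSums(D)
  el <- igraph::as_edgelist(g, names = FALSE)
  e <- nrow(el)
  if (e == 0L) return(0)
  gam <- e - igraph::vcount(g) + 1L
  (e / (gam + 1)) * sum(1 / sqrt(sig[el[, 1]] * sig[el[, 2]]))
}

#' Bonchev complexity index B
#'
#' `B = sum_v deg(v) / sigma(v)`, the total degree-to-distance-sum ratio.
#'
#' @param g a connected undirected simple igraph.
#' @return a number.
#' @export
complexity_index_b <- function(g) {
  check_graph(g)
  check_connected(g, "the complexity index B")
  if (igraph::vcount(g) == 1L) return(0)
  sig <- rowSums(igraph::distances(g))
  sum(igraph::degree(g) / sig)
}

#' Efficiency complexity
#'
#' The arithmetic mean of all inverse path lengths over ordered vertex
#' pairs, with `1/Inf := 0` for unreachable pairs, normalized by the
#' efficiency of the ideal (complete) graph, which is 1 for unweighted
#' graphs.  Consequently `E(K_n) = 1` and `E = 0` for the edgeless graph,
#' and disconnected input is handled rather than rejected.
#'
#' @param g an undirected simple igraph with `n >= 2`.
#' @return a number in `[0, 1]`.
#' @export
efficiency_complexity <- function(g) {
  check_graph(g)
  n <- igraph::vcount(g)
  if (n < 2L) {
    stop_netdiv("efficiency requires at least 2 vertices", "netdiv_input_error")
  }
  D <- igraph::distances(g)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean distance deviation
#'
#' `(1/n) sum_v |sigma(v) - mean(sigma)|`: the mean absolute deviation of
#' the per-vertex distance sums.  Zero on vertex-transitive graphs.
#'
#' @param g a connected undirected simple igraph.
#' @return a nonnegative number.
#' @export
mean_distance_deviation <- function(g) {
  check_graph(g)
  check_connected(g, "the mean distance deviation")
  sig <- rowSums(igraph::distances(g))
  mean(abs(sig - mean(sig)))
}

#' Normalized edge complexity
#'
#' The adjacency-sum normalization `sum_ij a_ij / n^2 = 2e / n^2`, in
#' `[0, 1)`.
#'
#' @param g an undirected simple igraph.
#' @return a number.
#' @export
normalized_edge_complexity <- function(g) {
  check_graph(g)
  2 * igraph::ecount(g) / igraph::vcount(g)^2
}

# ---------------------------------------------------------------------------
# Measure registry

measure_defs <- list(
  balabanJ        = list(fn = function(g) balaban_j(g),               connected = TRUE),
  bertz           = list(fn = function(g) bertz_index(g),             connected = FALSE),
  bonchev2        = list(fn = function(g) bonchev_trinajstic(g),      connected = TRUE),
  complexityIndexB = list(fn = function(g) complexity_index_b(g),     connected = TRUE),
  efficiency      = list(fn = function(g) efficiency_complexity(g),   connected = FALSE),
  energy          = list(fn = function(g) graph_energy(g),            connected = FALSE),
  # the degree-association functional needs every vertex to have a positive
  # neighborhood degree sum, so isolated vertices are inadmissible
  InfoTheoGCM     = list(fn = function(g) information_functional_entropy(g), connected = TRUE),
  lapEnergy       = list(fn = function(g) as.numeric(laplacian_energy(g)), connected = FALSE),
  mDistDev        = list(fn = function(g) mean_distance_deviation(g), connected = TRUE),
  nEdgeComplexity = list(fn = function(g) normalized_edge_complexity(g), connected = FALSE),
  offdiagonal     = list(fn = function(g) offdiagonal_complexity(g),  connected = FALSE),
  randic          = list(fn = function(g) randic_index(g),            connected = FALSE),
  sTreeSens       = list(fn = function(g) spanning_tree_sensitivity(g)$sts, connected = TRUE),
  tInfoContent    = list(fn = function(g) topological_information_content(g), connected = FALSE),
  wiener          = list(fn = function(g) wiener_index(g),            connected = TRUE),
  zagreb          = list(fn = function(g) zagreb_index(g),            connected = FALSE)
)

#' Registry of the 16 complexity measures
#'
#' Returns the label -> function mapping for the sixteen single-network
#' complexity descriptors bundled with the package.  Labels marked as
#' distance-based (`connected = TRUE`) refuse disconnected input; all others
#' accept any simple undirected graph.
#'
#' @return a data frame with columns `label` and `connected`.
#' @export
measure_registry <- function() {
  data.frame(
    label = names(measure_defs),
    connected = vapply(measure_defs, `[[`, logical(1), "connected"),
    row.names = NULL
  )
}

#' Compute a registered complexity measure by label
#'
#' Dispatches to one of the 16 measures in [measure_registry()].  With
#' `giant = TRUE`, measures that require connectivity are evaluated on the
#' largest connected component (the convention used throughout the
#' population harness); with `giant = FALSE` they raise a connectivity error
#' on disconnected input.
#'
#' @param g an undirected simple igraph.
#' @param label a registry label, e.g. `"wiener"`.
#' @param giant evaluate connectivity-requiring measures on the giant
#'   component? Default `FALSE`.
#' @return a number with attributes `label` and `log_base`.
#' @examples
#' compute_measure(igraph::make_ring(5), "zagreb")
#' @export
compute_measure <- function(g, label, giant = FALSE) {
  if (!is.character(label) || length(label) != 1L ||
      !(label %in% names(measure_defs))) {
    stop_netdiv(sprintf("unknown measure label: %s",
                        paste(label, collapse = ", ")),
                "netdiv_lookup_error")
  }
  def <- measure_defs[[label]]
  if (giant && def$connected) g <- giant_component(g)
  structure(as.numeric(def$fn(g)), label = label, log_base = 2)
}
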