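# Graph representation, file I/O and elementary invariants.  The universal
# graph object is a simple undirected igraph with character vertex names.

#' Read a network from a file
#'
#' Reads a simple undirected graph from a plain edge list, GML, or GraphML
#' file.  Multi-edges are collapsed and self-loops dropped with a warning;
#' original vertex labels are preserved.  The edge-list dialect is one edge
#' per line as two whitespace-separated endpoint labels, with `#` starting a
#' comment.
#'
#' @param path path to an existing file.
#' @param format one of `"edgelist"`, `"gml"`, `"graphml"`.
#' @return an undirected simple [igraph::igraph] with vertex names.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c"), f)
#' g <- read_network(f, "edgelist")
#' igraph::vcount(g)
#' @export
read_network <- function(path, format = c("edgelist", "gml", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_netdiv(sprintf("file not found: %s", path), "netdiv_format_error")
  }
  g <- switch(format,
    edgelist = read_edgelist_file(path),
    gml = try_read(path, "gml"),
    graphml = try_read(path, "graphml")
  )
  if (igraph::is_directed(g)) {
    stop_netdiv("directed input is rejected; provide an undirected graph",
                "netdiv_format_error")
  }
  if (igraph::vcount(g) < 1L) {
    stop_netdiv("input graph has an empty vertex set", "netdiv_input_error")
  }
  if (is.null(igraph::V(g)$name)) {
    # GML/GraphML may carry labels in "id" or "label"; fall back to indices.
    attrs <- igraph::vertex_attr_names(g)
    lab <- if ("label" %in% attrs) igraph::vertex_attr(g, "label")
           else if ("id" %in% attrs) igraph::vertex_attr(g, "id")
           else seq_len(igraph::vcount(g))
    igraph::V(g)$name <- as.character(lab)
  }
  n_loops <- sum(igraph::which_loop(g))
  if (n_loops > 0L) {
    warning(sprintf("dropped %d self-loop(s) from %s", n_loops, path))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' @noRd
try_read <- function(path, fmt) {
  g <- tryCatch(igraph::read_graph(path, format = fmt),
                error = function(e) {
    stop_netdiv(sprintf("cannot parse %s as %s: %s", path, fmt,
                        conditionMessage(e)), "netdiv_format_error")
  })
  g
}

#' @noRd
read_edgelist_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop_netdiv("edge list contains no edges", "netdiv_input_error")
  }
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(toks, function(t) length(t) != 2L, logical(1))
  if (any(bad)) {
    stop_netdiv(sprintf("malformed edge-list line: '%s'",
                        lines[which(bad)[1]]), "netdiv_format_error")
  }
  el <- do.call(rbind, toks)
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Write a network to a file
#'
#' Writers emit a deterministic vertex ordering (sorted labels), so the same
#' graph always produces the same file.
#'
#' @param g an undirected simple igraph.
#' @param path output file path.
#' @inheritParams read_network
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, format = c("edgelist", "gml", "graphml")) {
  format <- match.arg(format)
  check_graph(g)
  g <- sort_vertices(g)
  for (a in igraph::graph_attr_names(g)) g <- igraph::delete_graph_attr(g, a)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g)
    if (nrow(el) > 0L) {
      swap <- el[, 1] > el[, 2]
      el[swap, ] <- el[swap, c(2, 1)]
      el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    }
    writeLines(paste(el[, 1], el[, 2]), path)
  } else {
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' @noRd
sort_vertices <- function(g) {
  lab <- vertex_labels(g)
  igraph::V(g)$name <- lab
  igraph::permute(g, order(order(lab)))
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected vertex set.  Ties in
#' component size are broken toward the component containing the smallest
#' vertex label (lexicographically), so the result is deterministic.
#'
#' @param g an undirected simple igraph.
#' @return an igraph; the input itself when it is connected.
#' @export
giant_component <- function(g) {
  check_graph(g)
  if (igraph::is_connected(g)) return(g)
  comp <- igraph::components(g)
  lab <- vertex_labels(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    min_lab <- vapply(best, function(k) min(lab[comp$membership == k]), "")
    best <- best[order(min_lab)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == best[1]))
}

#' All-pairs shortest-path structure of a connected graph
#'
#' BFS all-pairs distances together with the diameter `rho` and the counts
#' `k_i` of unordered vertex pairs at distance `i` (so `sum(k) = n(n-1)/2`).
#'
#' @param g a connected undirected simple igraph.
#' @return a list of class `netdiv_distmat` with elements `D` (the labeled
#'   distance matrix), `diameter`, and `counts` (named vector, distance ->
#'   number of unordered pairs).
#' @export
distance_matrix <- function(g) {
  check_graph(g)
  check_connected(g, "the distance matrix")
  D <- igraph::distances(g)
  rho <- max(D)
  counts <- if (rho >= 1) {
    du <- D[upper.tri(D)]
    stats::setNames(tabulate(du, nbins = rho), seq_len(rho))
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(list(D = D, diameter = rho, counts = counts),
            class = "netdiv_distmat")
}

#' @export
print.netdiv_distmat <- function(x, ...) {
  cat(sprintf("Distance structure: %d vertices, diameter %d\n",
              nrow(x$D), x$diameter))
  cat("pairs per distance:", paste(names(x$counts), x$counts, sep = ":",
                                   collapse = " "), "\n")
  invisible(x)
}

#' Distance sum of a vertex
#'
#' `sigma(v) = sum_u d(v, u)`, the transmission of `v`.
#'
#' @param g a connected undirected simple igraph.
#' @param v a vertex label (or index).
#' @return a number.
#' @export
distance_sum <- function(g, v) {
  check_graph(g)
  check_connected(g, "the distance sum")
  lab <- vertex_labels(g)
  idx <- if (is.character(v)) match(v, lab) else as.integer(v)
  if (is.na(idx) || idx < 1L || idx > igraph::vcount(g)) {
    stop_netdiv(sprintf("unknown vertex: %s", as.character(v)),
                "netdiv_lookup_error")
  }
  sum(igraph::distances(g, v = idx))
}

#' Cyclomatic number of a connected graph
#'
#' `gamma = e - n + 1`, the number of independent cycles.
#'
#' @param g a connected undirected simple igraph.
#' @return a nonnegative integer.
#' @export
cyclomatic_number <- function(g) {
  check_graph(g)
  check_connected(g, "the cyclomatic number")
  igraph::ecount(g) - igraph::vcount(g) + 1L
}
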