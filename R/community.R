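# Walktrap module detection: supplies the module count M and the
# module-size vector m that the diversity score builds on.

#' Walktrap module partition
#'
#' Deterministic agglomerative community detection using t-step random-walk
#' probability distances (Pons--Latapy): starting from singletons, the pair
#' of adjacent modules whose merge least increases the mean squared walk
#' distance to module centers is merged repeatedly, and the merge tree is cut
#' at maximum modularity, with ties broken toward fewer modules.
#' Disconnected input is partitioned per component and the modules
#' concatenated, so modules never span components; isolated vertices become
#' singleton modules.
#'
#' @param g an undirected simple igraph.
#' @param walk_length random-walk length `t` (default 4).
#' @return a list of class `module_partition`: `membership` (integer vector
#'   named by vertex label), `modules` (list of vertex-label vectors), `M`
#'   (module count), and `sizes`.
#' @examples
#' g <- two_clique_graph(5)
#' walktrap_partition(g)$sizes
#' @export
walktrap_partition <- function(g, walk_length = 4) {
  check_graph(g)
  if (!is_count(walk_length) || walk_length < 1) {
    stop_netdiv("`walk_length` must be a positive integer", "netdiv_input_error")
  }
  n <- igraph::vcount(g)
  lab <- vertex_labels(g)
  comp <- igraph::components(g)
  membership <- integer(n)
  next_id <- 0L
  for (k in seq_len(comp$no)) {
    idx <- which(comp$membership == k)
    if (length(idx) == 1L) {
      membership[idx] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    sub <- igraph::induced_subgraph(g, idx)
    cw <- igraph::cluster_walktrap(sub, steps = walk_length)
    qv <- cw$modularity
    # cut at max modularity; ties toward fewer modules (later merge step)
    best_step <- max(which(qv >= max(qv) - 1e-12))
    mem <- igraph::cut_at(cw, steps = best_step - 1L)
    membership[idx] <- next_id + as.integer(mem)
    next_id <- next_id + max(mem)
  }
  # renumber modules in order of first appearance
  membership <- match(membership, unique(membership))
  names(membership) <- lab
  modules <- split(lab, membership)
  names(modules) <- NULL
  structure(list(membership = membership,
                 modules = modules,
                 M = length(modules),
                 sizes = vapply(modules, length, integer(1))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: M = %d module(s), sizes %s\n", x$M,
              paste(sort(x$sizes, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Newman--Girvan modularity of a partition
#'
#' Standard modularity `Q` in `[-1/2, 1)`; 0 for the one-module partition.
#'
#' @param g an undirected simple igraph.
#' @param partition a `module_partition`, or a membership vector over the
#'   vertices of `g`.
#' @return a number.
#' @export
partition_modularity <- function(g, partition) {
  check_graph(g)
  mem <- if (inherits(partition, "module_partition")) partition$membership
         else partition
  if (length(mem) != igraph::vcount(g)) {
    stop_netdiv("partition does not cover the vertex set of `g`",
                "netdiv_input_error")
  }
  if (!is.null(names(mem))) {
    lab <- vertex_labels(g)
    if (!setequal(names(mem), lab)) {
      stop_netdiv("partition vertex labels do not match `g`",
                  "netdiv_input_error")
    }
    mem <- mem[lab]
  }
  igraph::modularity(g, as.integer(as.factor(mem)))
}
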