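# Independent oracles: brute-force or closed-form reference implementations
# kept deliberately separate from the package's computation paths.

# All-pairs shortest paths by Floyd-Warshall on the adjacency matrix.
oracle_floyd_warshall <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Spanning-tree count by exhaustive enumeration of (n-1)-edge subsets.
oracle_spanning_trees <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  if (m < n - 1) return(0)
  if (n == 1) return(1)
  subsets <- utils::combn(m, n - 1)
  count <- 0L
  for (s in seq_len(ncol(subsets))) {
    sel <- el[subsets[, s], , drop = FALSE]
    # union-find connectivity over exactly n-1 edges => spanning tree iff
    # no cycle (equivalently: connects all n vertices)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (r in seq_len(nrow(sel))) {
      a <- find(sel[r, 1]); b <- find(sel[r, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) count <- count + 1L
  }
  count
}

# Connected induced subgraph census by exhaustive subset enumeration,
# classified by (edge count, degree sequence); exact for k in {3, 4}.
oracle_motif_census <- function(g, k) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- nrow(A)
  subsets <- utils::combn(n, k)
  if (k == 3) {
    counts <- c(path = 0, triangle = 0)
    for (s in seq_len(ncol(subsets))) {
      v <- subsets[, s]
      e <- A[v[1], v[2]] + A[v[1], v[3]] + A[v[2], v[3]]
      if (e == 3) counts["triangle"] <- counts["triangle"] + 1
      else if (e == 2) counts["path"] <- counts["path"] + 1
    }
    return(counts)
  }
  counts <- c(star = 0, path = 0, tadpole = 0, cycle = 0, diamond = 0,
              complete = 0)
  for (s in seq_len(ncol(subsets))) {
    v <- subsets[, s]
    B <- A[v, v]
    e <- sum(B) / 2
    deg <- rowSums(B)
    if (e < 3 || min(deg) == 0) next          # disconnected
    key <- paste(sort(deg), collapse = "")
    cls <- switch(as.character(e),
      "3" = if (key == "1113") "star" else "path",
      "4" = if (key == "2222") "cycle" else "tadpole",
      "5" = "diamond",
      "6" = "complete")
    counts[cls] <- counts[cls] + 1
  }
  counts
}

# Vertex orbits by enumerating all n! permutations and keeping the
# automorphisms; orbits are the classes of mutual reachability.
oracle_orbits <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- nrow(A)
  perms <- all_permutations(n)
  reach <- diag(TRUE, n)
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (all(A[p, p] == A)) {
      reach[cbind(seq_len(n), p)] <- TRUE
    }
  }
  # transitive closure (orbits are small; a few squarings suffice)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  membership <- apply(reach, 1, function(row) min(which(row)))
  sort(as.integer(table(membership)))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Maximum-modularity partition by exhaustive enumeration of all set
# partitions (restricted growth strings).  Feasible up to n ~ 10.
oracle_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  best <- list(q = -Inf, membership = NULL)
  rgs <- integer(n)
  recurse <- function(i, maxval) {
    if (i > n) {
      q <- igraph::modularity(g, rgs + 1L)
      if (q > best$q + 1e-12) best <<- list(q = q, membership = rgs + 1L)
      return(invisible())
    }
    for (v in 0:(maxval + 1L)) {
      rgs[i] <<- v
      recurse(i + 1L, max(maxval, v))
    }
  }
  recurse(2L, 0L)   # vertex 1 fixed in block 0
  best
}

# Adjusted Rand index between two labelings (closed form on the
# contingency table).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(length(a), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Random relabeling of a graph's vertices (for invariance checks).
shuffle_vertices <- function(g) {
  igraph::permute(g, sample(igraph::vcount(g)))
}
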