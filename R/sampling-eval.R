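# Random-walk subnetwork sampling and the statistical evaluation harness:
# histograms, parameter sweeps, empirical CDFs / densities, and the
# interval-threshold separation score.

#' Random-walk induced subnetwork
#'
#' Runs a simple random walk (uniform neighbor choice, no teleportation)
#' from a uniformly chosen start vertex and returns the induced subgraph on
#' the first `n_sub` distinct vertices visited.  On a connected graph the
#' walk reaches any number of distinct vertices almost surely; a generous
#' step cap (10^6) guards pathological inputs.  The output has exactly
#' `n_sub` vertices and is connected.  This turns a single large network
#' into a sample of fixed-size subnetworks, so the population estimator
#' [nds()] can be applied to one network.
#'
#' @param g a connected undirected simple igraph.
#' @param n_sub number of vertices to collect, `<= vcount(g)`.
#' @param seed optional integer seed.
#' @return an induced subgraph with `n_sub` vertices.
#' @export
random_walk_subgraph <- function(g, n_sub, seed = NULL) {
  check_graph(g)
  check_connected(g, "random-walk subnetwork sampling")
  n <- igraph::vcount(g)
  if (!is_count(n_sub) || n_sub < 1 || n_sub > n) {
    stop_netdiv("`n_sub` must be an integer between 1 and vcount(g)",
                "netdiv_size_error")
  }
  with_seed(seed, {
    adj <- igraph::as_adj_list(g)
    seen <- logical(n)
    order_seen <- integer(n_sub)
    cur <- sample.int(n, 1)
    seen[cur] <- TRUE
    order_seen[1] <- cur
    found <- 1L
    steps <- 0L
    while (found < n_sub) {
      steps <- steps + 1L
      if (steps > 1e6) {
        stop_netdiv("random walk exceeded the step cap", "netdiv_input_error")
      }
      nb <- as.integer(adj[[cur]])
      cur <- nb[sample.int(length(nb), 1)]
      if (!seen[cur]) {
        seen[cur] <- TRUE
        found <- found + 1L
        order_seen[found] <- cur
      }
    }
    igraph::induced_subgraph(g, order_seen)
  })
}

#' Sample of random-walk subnetworks
#'
#' `S` independent draws of [random_walk_subgraph()], ready to feed into
#' [nds()].
#'
#' @inheritParams random_walk_subgraph
#' @param S number of subnetworks.
#' @return a list of `S` igraphs.
#' @export
sample_subgraphs <- function(g, n_sub, S, seed = NULL) {
  if (!is_count(S) || S < 1) {
    stop_netdiv("`S` must be a positive integer", "netdiv_input_error")
  }
  seeds <- derive_seeds(seed, S)
  lapply(seq_len(S), function(i) random_walk_subgraph(g, n_sub, seeds[[i]]))
}

#' Replicate measure values for one generator setting
#'
#' Draws `replicates` networks from a generator and evaluates the requested
#' registry measures on each, for histogram / density rendering.  Measures
#' that need connectivity are evaluated on the giant component (the harness
#' convention).
#'
#' @param gen a zero-argument function returning an igraph.
#' @param measures character vector of registry labels (default: all 16).
#' @param replicates number of draws (`>= 2`).
#' @param seed optional integer seed.
#' @return a numeric matrix `replicates x measures`.
#' @export
measure_histogram <- function(gen, measures = measure_registry()$label,
                              replicates = 100, seed = NULL) {
  if (!is.function(gen)) {
    stop_netdiv("`gen` must be a zero-argument generator function",
                "netdiv_input_error")
  }
  if (!is_count(replicates) || replicates < 2) {
    stop_netdiv("`replicates` must be an integer >= 2", "netdiv_input_error")
  }
  with_seed(seed, {
    out <- matrix(NA_real_, replicates, length(measures),
                  dimnames = list(NULL, measures))
    for (r in seq_len(replicates)) {
      g <- gen()
      for (m in measures) {
        out[r, m] <- compute_measure(g, m, giant = TRUE)
      }
    }
    out
  })
}

#' Parameter sweep of complexity measures over a generator grid
#'
#' For each grid value, draws `replicates` networks and records the mean and
#' standard deviation of every requested measure (evaluated on the giant
#' component where connectivity is required).  Supports the Erdos--Renyi
#' `p` sweep, the small-world rewiring sweep, and size sweeps, via a
#' one-argument generator factory.
#'
#' @param gen_at a function of one argument (the grid value) returning an
#'   igraph.
#' @param grid numeric vector of parameter values (nonempty).
#' @param measures registry labels.
#' @param replicates draws per grid point; with 1 replicate the sd column is
#'   `NA`.
#' @param seed optional integer seed.
#' @return a data frame (`SweepTable`) with columns `param`, `measure`,
#'   `replicates`, `mean`, `sd`.
#' @export
parameter_sweep <- function(gen_at, grid, measures = measure_registry()$label,
                            replicates = 30, seed = NULL) {
  if (length(grid) == 0L) {
    stop_netdiv("`grid` must be nonempty", "netdiv_input_error")
  }
  with_seed(seed, {
    rows <- list()
    for (v in grid) {
      vals <- matrix(NA_real_, replicates, length(measures),
                     dimnames = list(NULL, measures))
      for (r in seq_len(replicates)) {
        g <- gen_at(v)
        for (m in measures) vals[r, m] <- compute_measure(g, m, giant = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        param = v, measure = measures, replicates = replicates,
        mean = colMeans(vals),
        sd = if (replicates > 1) apply(vals, 2, stats::sd) else NA_real_,
        row.names = NULL
      )
    }
    do.call(rbind, rows)
  })
}

#' Empirical CDF and kernel density of score samples
#'
#' `empirical_cdf()` is the right-continuous empirical distribution
#' function; `score_density()` a Gaussian-kernel density estimate with
#' Silverman's rule-of-thumb bandwidth.  Densities are for reporting; the
#' separation accuracy is always computed on the raw samples.
#'
#' @param values nonempty numeric vector.
#' @return `empirical_cdf()`: a function (class `ecdf`); `score_density()`:
#'   a `density` object.
#' @export
empirical_cdf <- function(values) {
  if (length(values) == 0L || any(!is.finite(values))) {
    stop_netdiv("`values` must be nonempty and finite", "netdiv_input_error")
  }
  stats::ecdf(values)
}

#' @rdname empirical_cdf
#' @param bandwidth bandwidth rule or value passed to [stats::density()]
#'   (default Silverman's `"nrd0"`).
#' @export
score_density <- function(values, bandwidth = "nrd0") {
  if (length(values) < 2L || any(!is.finite(values))) {
    stop_netdiv("`values` must hold at least 2 finite samples",
                "netdiv_input_error")
  }
  stats::density(values, bw = bandwidth)
}

#' Interval-threshold separation score
#'
#' Scores how well labeled score samples separate into contiguous intervals
#' of the score axis: for three classes, two thresholds are fitted by
#' exhaustive search over midpoints between sorted sample values (and over
#' all assignments of classes to intervals), maximizing classification
#' accuracy; for two classes a single threshold.  The class-interval model
#' reflects the premise that each network type occupies one continuous
#' region of score values.  Pairwise overlap coefficients
#' (`int min(f_a, f_b)` of the kernel densities) are reported alongside.
#'
#' @param values numeric score samples.
#' @param labels class labels aligned with `values`; 2 or 3 classes, each
#'   with at least 5 samples.
#' @return a list of class `separation_report`: `accuracy`, `thresholds`,
#'   `assignment` (interval -> class), `overlap` (pairwise matrix), and the
#'   per-class sample list.
#' @export
separation_score <- function(values, labels) {
  if (length(values) != length(labels)) {
    stop_netdiv("`values` and `labels` must be aligned", "netdiv_input_error")
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L || length(classes) > 3L) {
    stop_netdiv("separation scoring supports 2 or 3 classes",
                "netdiv_input_error")
  }
  tab <- table(labels)
  if (any(tab < 5L)) {
    stop_netdiv("every class needs at least 5 samples", "netdiv_input_error")
  }
  o <- order(values)
  v <- values[o]
  lab <- labels[o]
  nv <- length(v)
  cuts <- c(-Inf, (v[-1] + v[-nv]) / 2, Inf)
  # cumulative class counts at each cut: counts[c, t] = #{class c <= cut t}
  counts <- vapply(cuts, function(ct) {
    vapply(classes, function(cl) sum(lab == cl & v <= ct), numeric(1))
  }, numeric(length(classes)))
  counts <- matrix(counts, nrow = length(classes),
                   dimnames = list(classes, NULL))
  totals <- vapply(classes, function(cl) sum(lab == cl), numeric(1))
  best <- list(accuracy = -1)
  if (length(classes) == 2L) {
    perms <- rbind(1:2, 2:1)
    for (p in seq_len(nrow(perms))) {
      pa <- perms[p, ]
      acc <- (counts[pa[1], ] + totals[pa[2]] - counts[pa[2], ]) / nv
      i <- which.max(acc)
      if (acc[i] > best$accuracy) {
        best <- list(accuracy = acc[i], thresholds = cuts[i],
                     assignment = classes[pa])
      }
    }
  } else {
    perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    for (p in seq_len(nrow(perms))) {
      pa <- perms[p, ]
      # accuracy(i, j) = a_i + b_j + const, maximized with i <= j via cummax
      a <- counts[pa[1], ] - counts[pa[2], ]
      b <- counts[pa[2], ] - counts[pa[3], ]
      amax <- cummax(a)
      tot <- (amax + b + totals[pa[3]]) / nv
      j <- which.max(tot)
      i <- which(a == amax[j])[1]
      if (tot[j] > best$accuracy) {
        best <- list(accuracy = tot[j], thresholds = c(cuts[i], cuts[j]),
                     assignment = classes[pa])
      }
    }
  }
  ov <- overlap_matrix(values, labels, classes)
  structure(c(best, list(overlap = ov,
                         samples = split(values, labels))),
            class = "separation_report")
}

#' @noRd
overlap_matrix <- function(values, labels, classes) {
  k <- length(classes)
  ov <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  diag(ov) <- 1
  rng <- range(values)
  pad <- diff(rng) * 0.25 + 1e-9
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = 512)
  dens <- lapply(classes, function(cl) {
    x <- values[labels == cl]
    if (length(unique(x)) < 2L) {
      # degenerate (constant) sample: point mass approximated by a spike
      d <- numeric(length(grid))
      d[which.min(abs(grid - x[1]))] <- 1 / diff(grid[1:2])
      d
    } else {
      stats::approx(stats::density(x), xout = grid, yleft = 0,
                    yright = 0)$y
    }
  })
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ov[i, j] <- ov[j, i] <-
      sum(pmin(dens[[i]], dens[[j]])) * diff(grid[1:2])
  }
  ov
}

#' @export
print.separation_report <- function(x, digits = 3, ...) {
  cat(sprintf("Separation report: accuracy %.*f\n", digits, x$accuracy))
  cat("  interval assignment (low to high):",
      paste(x$assignment, collapse = " < "), "\n")
  cat("  thresholds:", paste(signif(x$thresholds, digits), collapse = ", "),
      "\n")
  invisible(x)
}

#' Class-separation of the diversity-score estimator on a benchmark
#'
#' The population experiment behind the score: for each class of a labeled
#' benchmark, `n_estimates` samples of `sample_size` networks are drawn
#' (without replacement within a draw) and fitted with [nds()]; the
#' resulting estimates are scored with [separation_score()].
#'
#' @param population a `labeled_population` from [benchmark_population()].
#' @param sample_size `S`, networks per estimate.
#' @param n_estimates estimates per class (default 30).
#' @param seed optional integer seed for the draws.
#' @param ... passed to [nds()].
#' @return a list: `report` (a `separation_report`), `estimates`, `labels`.
#' @export
evaluate_separation <- function(population, sample_size, n_estimates = 30,
                                seed = NULL, ...) {
  if (!inherits(population, "labeled_population")) {
    stop_netdiv("`population` must be a labeled_population",
                "netdiv_input_error")
  }
  with_seed(seed, {
    classes <- unique(population$labels)
    est <- c()
    lab <- c()
    # score every network once, then resample the per-network scores
    ids_all <- vapply(population$networks,
                      function(g) nds_score(g, ...)$ids, numeric(1))
    for (cl in classes) {
      pool <- ids_all[population$labels == cl]
      if (length(pool) < sample_size) {
        stop_netdiv(sprintf("class %s has fewer than S = %d networks",
                            cl, sample_size), "netdiv_input_error")
      }
      for (b in seq_len(n_estimates)) {
        est <- c(est, mean(sample(pool, sample_size)))
        lab <- c(lab, cl)
      }
    }
    list(report = separation_score(est, lab), estimates = est, labels = lab)
  })
}
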