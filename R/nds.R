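# The network diversity score: four component variables, the individual
# (per-network) score, the population estimator, and the model-ambiguity
# probability that motivates scoring populations rather than single
# networks.

#' Module density
#'
#' `alpha_module = M / n`: modules found per vertex.  1 for the
#' all-singleton partition, `1/n` for a single module.
#'
#' @param g an undirected simple igraph.
#' @param partition a `module_partition` of `g` (default: Walktrap).
#' @return a number in `(0, 1]`.
#' @export
module_density <- function(g, partition = walktrap_partition(g)) {
  check_graph(g)
  if (!inherits(partition, "module_partition")) {
    stop_netdiv("`partition` must be a module_partition", "netdiv_input_error")
  }
  if (sum(partition$sizes) != igraph::vcount(g)) {
    stop_netdiv("partition does not cover the vertex set of `g`",
                "netdiv_input_error")
  }
  partition$M / igraph::vcount(g)
}

# The shared variability functional of the score: population variance over
# mean by default, or the true coefficient of variation (sd / mean).
#' @noRd
variability <- function(x, variant) {
  switch(variant,
    var_mean = pop_var(x) / mean(x),
    cv = sqrt(pop_var(x)) / mean(x),
    stop_netdiv(sprintf("unknown variability variant: %s", variant),
                "netdiv_input_error")
  )
}

#' Module-size variability
#'
#' Variability of the module sizes `m` relative to the mean module size:
#' population variance over mean by default (`variant = "var_mean"`), or the
#' coefficient of variation sd/mean (`variant = "cv"`).  Zero when all
#' modules have equal size.
#'
#' @param m integer vector of module sizes (all `>= 1`), or a
#'   `module_partition`.
#' @param variant `"var_mean"` (default) or `"cv"`.
#' @return a nonnegative number.
#' @export
module_size_variability <- function(m, variant = c("var_mean", "cv")) {
  variant <- match.arg(variant)
  if (inherits(m, "module_partition")) m <- m$sizes
  m <- as.numeric(m)
  if (length(m) == 0L || any(!is.finite(m)) || any(m < 1)) {
    stop_netdiv("`m` must be a nonempty vector of module sizes >= 1",
                "netdiv_input_error")
  }
  variability(m, variant)
}

#' Laplacian-eigenvalue variability
#'
#' The same variability functional as [module_size_variability()], applied
#' to the Laplacian spectrum.  Strictly positive on every connected graph
#' with at least one edge (the spectrum then contains both a 0 and positive
#' values); the zero-mean spectrum of an edgeless graph is degenerate.
#'
#' @param spectrum a `netdiv_spectrum` from [laplacian_spectrum()], a
#'   numeric vector of eigenvalues, or an igraph (its Laplacian spectrum is
#'   computed).
#' @inheritParams module_size_variability
#' @return a nonnegative number.
#' @export
laplacian_variability <- function(spectrum, variant = c("var_mean", "cv")) {
  variant <- match.arg(variant)
  if (igraph::is_igraph(spectrum)) spectrum <- laplacian_spectrum(spectrum)
  mu <- as.numeric(spectrum)
  if (length(mu) == 0L || mean(mu) == 0) {
    stop_netdiv("Laplacian variability is degenerate: zero-mean spectrum (edgeless graph)",
                "netdiv_degenerate_error")
  }
  variability(mu, variant)
}

#' Individual diversity score of a single network
#'
#' Computes the four component variables and composes them multiplicatively
#' into the individual diversity score
#' \deqn{ids(G) = \frac{v_\lambda}{\alpha_{module} \; r_{motif} \; v_{module}}}
#' where `alpha_module = M/n` is the module density, `r_motif =
#' n_motif(3)/n_motif(4)` the motif growth rate, `v_module` the module-size
#' variability and `v_lambda` the Laplacian-eigenvalue variability.  The
#' score is high when the eigenvalue spectrum is heterogeneous relative to
#' how fragmented and locally tree-like the network is; empirically random
#' networks score lowest, ordered (lattice) networks intermediate and
#' complex (scale-free / small-world) networks highest.
#'
#' A partition into equal-size modules makes `v_module = 0`, a zero
#' denominator: this raises a `netdiv_degenerate_error` carrying the full
#' component breakdown, rather than returning `Inf`.
#'
#' @param g a connected undirected simple igraph with `n >= 5` (so the
#'   size-4 motif census exists and is nonempty).
#' @param walk_length Walktrap random-walk length (default 4).
#' @param variant variability functional, `"var_mean"` (default) or `"cv"`.
#' @param motif_orientation `"3/4"` (default) or `"4/3"`, see [motif_rate()].
#' @param motif_semantics `"occurrences"` (default) or `"distinct"`.
#' @return a list of class `nds_score`: `ids`, `log10_ids`, the four
#'   components (`alpha_module`, `r_motif`, `v_module`, `v_lambda`),
#'   `diagnostics` (n, e, M, module sizes, motif totals, spectrum summary)
#'   and `config` (all variant flags).
#' @examples
#' g <- gen_small_world(50, 4, 0.1, seed = 1)
#' nds_score(g)
#' @export
nds_score <- function(g, walk_length = 4,
                      variant = c("var_mean", "cv"),
                      motif_orientation = c("3/4", "4/3"),
                      motif_semantics = c("occurrences", "distinct")) {
  variant <- match.arg(variant)
  motif_orientation <- match.arg(motif_orientation)
  motif_semantics <- match.arg(motif_semantics)
  check_graph(g)
  check_connected(g, "the individual diversity score")
  if (igraph::vcount(g) < 5L) {
    stop_netdiv("the diversity score requires n >= 5 (size-4 motif census)",
                "netdiv_size_error")
  }
  part <- walktrap_partition(g, walk_length = walk_length)
  alpha <- module_density(g, part)
  r <- as.numeric(motif_rate(g, orientation = motif_orientation,
                             semantics = motif_semantics))
  v_mod <- module_size_variability(part$sizes, variant = variant)
  spec <- laplacian_spectrum(g)
  v_lam <- laplacian_variability(spec, variant = variant)
  config <- list(walk_length = walk_length, variant = variant,
                 motif_orientation = motif_orientation,
                 motif_semantics = motif_semantics,
                 log_base = 2)
  diagnostics <- list(
    n = igraph::vcount(g), e = igraph::ecount(g),
    M = part$M, module_sizes = part$sizes,
    n_motif3 = motif_census(g, 3)$total, n_motif4 = motif_census(g, 4)$total,
    spectrum_mean = mean(spec), spectrum_max = max(spec)
  )
  breakdown <- list(alpha_module = alpha, r_motif = r,
                    v_module = v_mod, v_lambda = v_lam,
                    diagnostics = diagnostics, config = config)
  denom <- alpha * r * v_mod
  if (denom == 0) {
    stop_netdiv(
      "degenerate diversity score: zero denominator in the composition (all module sizes equal)",
      "netdiv_degenerate_error", breakdown = breakdown
    )
  }
  ids <- v_lam / denom
  structure(c(list(ids = ids, log10_ids = log10(ids)), breakdown),
            class = "nds_score")
}

#' @export
print.nds_score <- function(x, digits = 4, ...) {
  cat("Individual diversity score\n")
  cat(sprintf("  ids = %.*g   (log10: %.*g)\n", digits, x$ids, digits,
              x$log10_ids))
  cat(sprintf("  components: alpha_module = %.*g, r_motif = %.*g, v_module = %.*g, v_lambda = %.*g\n",
              digits, x$alpha_module, digits, x$r_motif,
              digits, x$v_module, digits, x$v_lambda))
  cat(sprintf("  network: n = %d, e = %d, M = %d modules\n",
              x$diagnostics$n, x$diagnostics$e, x$diagnostics$M))
  invisible(x)
}

#' Network diversity score of a sample of networks
#'
#' Fits the population-level diversity score from a sample of `S` networks:
#' the estimate is the sample mean of the individual scores and its standard
#' error is `sd(ids) / sqrt(S)` by the central limit theorem (reported as
#' `NA` at `S = 1`).  Networks whose individual score fails (degenerate
#' composition, disconnected input, too small) abort the fit by default;
#' with `on_error = "skip"` they are dropped with a warning and reported in
#' the `failures` field.
#'
#' @param graphs a list of undirected simple igraphs (or a single igraph).
#' @param ... passed on to [nds_score()] (variant flags, walk length).
#' @param on_error `"fail"` (default) or `"skip"`.
#' @return an object of class `nds`: `mean`, `stderr`, `log10_mean`, `S`,
#'   `scores` (the per-network `nds_score` breakdowns), `ids` (numeric
#'   vector), `failures`, and `config`.
#' @examples
#' pop <- replicate(5, gen_small_world(50, 4, 0.1), simplify = FALSE)
#' fit <- nds(pop)
#' summary(fit)
#' @export
nds <- function(graphs, ..., on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  if (!is.list(graphs) || length(graphs) == 0L) {
    stop_netdiv("`graphs` must be a nonempty list of igraph objects",
                "netdiv_input_error")
  }
  scores <- vector("list", length(graphs))
  failures <- list()
  for (i in seq_along(graphs)) {
    res <- tryCatch(nds_score(graphs[[i]], ...), netdiv_error = function(e) e)
    if (inherits(res, "netdiv_error")) {
      if (on_error == "fail") stop(res)
      failures[[length(failures) + 1L]] <-
        list(index = i, message = conditionMessage(res))
    } else {
      scores[[i]] <- res
    }
  }
  scores <- scores[!vapply(scores, is.null, logical(1))]
  if (length(failures) > 0L) {
    warning(sprintf("skipped %d network(s) with degenerate or invalid scores",
                    length(failures)))
  }
  if (length(scores) == 0L) {
    stop_netdiv("no network in the sample could be scored", "netdiv_input_error")
  }
  ids <- vapply(scores, `[[`, numeric(1), "ids")
  S <- length(ids)
  est <- mean(ids)
  stderr <- if (S > 1L) stats::sd(ids) / sqrt(S) else NA_real_
  structure(list(mean = est, stderr = stderr, log10_mean = log10(est),
                 S = S, ids = ids, scores = scores, failures = failures,
                 config = scores[[1]]$config),
            class = "nds")
}

#' @export
print.nds <- function(x, digits = 4, ...) {
  cat(sprintf("Network diversity score (sample of S = %d network(s))\n", x$S))
  cat(sprintf("  estimate: %.*g  (log10: %.*g)\n", digits, x$mean, digits,
              x$log10_mean))
  if (is.na(x$stderr)) {
    cat("  std. error: undefined at S = 1\n")
  } else {
    cat(sprintf("  std. error: %.*g\n", digits, x$stderr))
  }
  if (length(x$failures) > 0L) {
    cat(sprintf("  (%d network(s) skipped)\n", length(x$failures)))
  }
  invisible(x)
}

#' @export
summary.nds <- function(object, ...) {
  comp <- sapply(object$scores, function(s)
    c(alpha_module = s$alpha_module, r_motif = s$r_motif,
      v_module = s$v_module, v_lambda = s$v_lambda, ids = s$ids))
  out <- list(mean = object$mean, stderr = object$stderr, S = object$S,
              log10_mean = object$log10_mean,
              component_means = rowMeans(comp),
              ids_range = range(object$ids),
              config = object$config)
  class(out) <- "summary.nds"
  out
}

#' @export
print.summary.nds <- function(x, digits = 4, ...) {
  cat(sprintf("Network diversity score: %.*g +/- %.*g (S = %d)\n",
              digits, x$mean, digits, x$stderr, x$S))
  cat("Mean components:\n")
  print(round(x$component_means, digits))
  cat(sprintf("ids range: [%.*g, %.*g]\n", digits, x$ids_range[1],
              digits, x$ids_range[2]))
  cat(sprintf("Flags: variability = %s, motif orientation = %s (%s), walk length = %d, log base = %d\n",
              x$config$variant, x$config$motif_orientation,
              x$config$motif_semantics, x$config$walk_length,
              x$config$log_base))
  invisible(x)
}

#' @export
coef.nds <- function(object, ...) {
  comp <- sapply(object$scores, function(s)
    c(alpha_module = s$alpha_module, r_motif = s$r_motif,
      v_module = s$v_module, v_lambda = s$v_lambda))
  c(rowMeans(comp), ids = object$mean)
}

#' Confidence interval for a diversity-score estimate
#'
#' Normal-approximation interval `mean +/- z * stderr` from the CLT standard
#' error.
#'
#' @param object an `nds` fit.
#' @param parm ignored (a single estimate).
#' @param level confidence level (default 0.95).
#' @param ... ignored.
#' @return a 1 x 2 matrix as for other `confint` methods.
#' @export
confint.nds <- function(object, parm, level = 0.95, ...) {
  if (is.na(object$stderr)) {
    stop_netdiv("standard error undefined at S = 1", "netdiv_input_error")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- object$mean + c(-1, 1) * z * object$stderr
  m <- matrix(ci, nrow = 1,
              dimnames = list("nds", sprintf("%.1f %%",
                                             100 * c((1 - level) / 2,
                                                     1 - (1 - level) / 2))))
  m
}

#' @export
plot.nds <- function(x, ...) {
  if (x$S < 2L) {
    stop_netdiv("plotting the score distribution requires S >= 2",
                "netdiv_input_error")
  }
  graphics::hist(log10(x$ids), breaks = "FD",
                 main = "Individual diversity scores",
                 xlab = "log10(ids)", ...)
  graphics::abline(v = x$log10_mean, lwd = 2)
  invisible(x)
}

#' Model-ambiguity probability of a single network
#'
#' The probability that the Erdos--Renyi model `G(n, p)` emits one specific
#' labeled graph with `e` edges: `w = p^e (1-p)^(C(n,2)-e)`.  For an
#' independent sample of `S` networks the corresponding misattribution
#' factor is `w^S`, which is the quantitative reason the diversity score is
#' defined over network populations rather than single networks.
#'
#' @param n vertex count.
#' @param p connection probability, strictly inside `(0, 1)`.
#' @param e edge count of the target graph, `0 <= e <= C(n,2)`.
#' @param S sample size (default 1).
#' @return a list with `w` and `w_sample = w^S`.
#' @examples
#' model_ambiguity_probability(3, 0.5, 2, S = 3)
#' @export
model_ambiguity_probability <- function(n, p, e, S = 1) {
  if (!is_count(n) || n < 1) {
    stop_netdiv("`n` must be a positive integer", "netdiv_input_error")
  }
  npairs <- choose(n, 2)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop_netdiv("`p` must be strictly between 0 and 1", "netdiv_input_error")
  }
  if (!is_count(e) || e < 0 || e > npairs) {
    stop_netdiv("`e` must be between 0 and choose(n, 2)", "netdiv_input_error")
  }
  if (!is_count(S) || S < 1) {
    stop_netdiv("`S` must be a positive integer", "netdiv_input_error")
  }
  w <- p^e * (1 - p)^(npairs - e)
  list(w = w, w_sample = w^S)
}
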