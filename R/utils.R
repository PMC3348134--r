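# Internal helpers shared across modules.

#' @noRd
stop_netdiv <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "netdiv_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

# Shannon entropy in bits of a probability vector; 0 log 0 := 0.
#' @noRd
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Population variance (divides by n, not n - 1).
#' @noRd
pop_var <- function(x) mean((x - mean(x))^2)

# Run `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's state afterwards.  A NULL seed leaves the RNG alone.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is_count(seed)) {
    stop_netdiv("`seed` must be a single integer", "netdiv_input_error")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of per-item seeds from one master seed, staying inside the
# 32-bit integer range.
#' @noRd
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647)
}

#' @noRd
check_graph <- function(g, arg = "g") {
  if (!igraph::is_igraph(g)) {
    stop_netdiv(sprintf("`%s` must be an igraph object", arg),
                "netdiv_input_error")
  }
  if (igraph::is_directed(g)) {
    stop_netdiv("directed graphs are not supported", "netdiv_input_error")
  }
  if (igraph::vcount(g) < 1L) {
    stop_netdiv("graph has an empty vertex set", "netdiv_input_error")
  }
  if (igraph::any_multiple(g) || igraph::any_loop(g)) {
    stop_netdiv("graph must be simple (no multi-edges, no self-loops)",
                "netdiv_input_error")
  }
  invisible(g)
}

#' @noRd
check_connected <- function(g, what = "this measure") {
  if (!igraph::is_connected(g)) {
    stop_netdiv(
      sprintf("%s is defined on connected graphs; see giant_component()", what),
      "netdiv_connectivity_error"
    )
  }
  invisible(g)
}

#' @noRd
vertex_labels <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(g))) else as.character(nm)
}
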