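#' Query-counted general-graph-model oracle
#'
#' Wraps a network behind the three query types of the general graph model:
#' degree, l-th neighbour, and vertex-pair (adjacency entry) queries, each
#' costing exactly one unit. The oracle is the instrument with which the
#' samplers' query complexity is measured: every call increments exactly one
#' counter by one, repeats included — caching answers is the caller's
#' business, never the oracle's.
#'
#' @param network a [network()] object.
#' @return An environment of class `ggm_oracle` holding the network and the
#'   three counters (`degree_queries`, `neighbour_queries`, `pair_queries`).
#' @examples
#' o <- ggm_oracle(network(rbind(c(0, 1), c(1, 2))))
#' oracle_degree(o, 1)
#' query_counts(o)
#' @export
ggm_oracle <- function(network) {
  stopifnot(inherits(network, "walk_network"))
  e <- new.env(parent = emptyenv())
  e$network <- network
  e$degree_queries <- 0
  e$neighbour_queries <- 0
  e$pair_queries <- 0
  class(e) <- "ggm_oracle"
  e
}

check_node <- function(oracle, v) {
  if (any(v < 0L | v >= oracle$network$n)) {
    stop("node id out of range [0, ", oracle$network$n - 1L, "]")
  }
}

#' Degree query
#' @param oracle a [ggm_oracle()].
#' @param v node id (0-based).
#' @return The degree `k_v`; `degree_queries` is incremented by 1.
#' @export
oracle_degree <- function(oracle, v) {
  check_node(oracle, v)
  oracle$degree_queries <- oracle$degree_queries + 1
  oracle$network$deg[v + 1L]
}

#' Neighbour query
#'
#' Returns the `l`-th neighbour of `v` in ascending node order (`l` is
#' 1-based) when `l <= k_v`, and the not-present sentinel `NA` otherwise.
#'
#' @param oracle a [ggm_oracle()].
#' @param v node id (0-based).
#' @param l neighbour index, `l >= 1`.
#' @return Node id of the neighbour, or `NA_integer_`; `neighbour_queries`
#'   is incremented by 1.
#' @export
oracle_neighbour <- function(oracle, v, l) {
  check_node(oracle, v)
  if (l < 1L) stop("neighbour index l must be >= 1")
  oracle$neighbour_queries <- oracle$neighbour_queries + 1
  nb <- oracle$network$nbr[[v + 1L]]
  if (l <= length(nb)) nb[l] else NA_integer_
}

#' Vertex-pair query
#' @param oracle a [ggm_oracle()].
#' @param u,v node ids (0-based).
#' @return The adjacency entry `A_uv` (0 or 1); `pair_queries` is
#'   incremented by 1.
#' @export
oracle_pair <- function(oracle, u, v) {
  check_node(oracle, u)
  check_node(oracle, v)
  oracle$pair_queries <- oracle$pair_queries + 1
  oracle$network$adj[u + 1L, v + 1L]
}

#' Snapshot of the oracle's query counters
#' @param oracle a [ggm_oracle()].
#' @return Named numeric vector with components `degree`, `neighbour`,
#'   `pair`, `total`.
#' @export
query_counts <- function(oracle) {
  stopifnot(inherits(oracle, "ggm_oracle"))
  c(
    degree = oracle$degree_queries,
    neighbour = oracle$neighbour_queries,
    pair = oracle$pair_queries,
    total = oracle$degree_queries + oracle$neighbour_queries + oracle$pair_queries
  )
}

#' @export
print.ggm_oracle <- function(x, ...) {
  q <- query_counts(x)
  cat(sprintf(
    "ggm_oracle on N = %d: %g degree, %g neighbour, %g pair queries\n",
    x$network$n, q[["degree"]], q[["neighbour"]], q[["pair"]]
  ))
  invisible(x)
}

# bulk counter bump used by vectorized sampling paths; each unit corresponds
# to one oracle call of the named type
bump_queries <- function(oracle, degree = 0, neighbour = 0, pair = 0) {
  oracle$degree_queries <- oracle$degree_queries + degree
  oracle$neighbour_queries <- oracle$neighbour_queries + neighbour
  oracle$pair_queries <- oracle$pair_queries + pair
  invisible(oracle)
}
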