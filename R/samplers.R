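#' Exact path-count score distribution
#'
#' The ground-truth sampling law for the classical samplers: the probability
#' of drawing the ordered pair `(i, j)` is the number of length-`n` paths
#' between them, normalized by the `L_{1,1}` norm of `A^n`,
#' `P_ij = (A^n)_ij / sum(A^n)`. Entries of `A^n` are nonnegative, so the
#' absolute value in the general score law is vacuous here.
#'
#' @param network a [network()] object with at least one edge.
#' @param n path length, 2 or 3.
#' @return Object of class `score_distribution`: list with the probability
#'   matrix `P`, the score label `source` ("A2" or "A3") and the norm
#'   exponent `q = 1`.
#' @examples
#' p3 <- network(rbind(c(0, 1), c(1, 2)))
#' exact_power_distribution(p3, 2)$P  # (0,2) entry is 1/6
#' @export
exact_power_distribution <- function(network, n) {
  stopifnot(inherits(network, "walk_network"), n %in% c(2L, 3L))
  a <- network$adj
  storage.mode(a) <- "double"
  an <- if (n == 2L) a %*% a else a %*% a %*% a
  z <- sum(an)
  if (z == 0) stop("A^", n, " is identically zero; no distribution to sample")
  structure(
    list(P = an / z, source = paste0("A", n), q = 1),
    class = "score_distribution"
  )
}

#' Preprocess the A^2 sampler
#'
#' Queries the degree of every node (exactly `N` degree queries) and builds
#' the node distribution `p_v = k_v^2 / sum_w k_w^2` with its cumulative
#' array for bisection sampling. The identity
#' `sum_v k_v^2 = ||A^2||_{1,1}` makes the induced pair marginal equal the
#' exact `A^2` score distribution.
#'
#' @param oracle a [ggm_oracle()].
#' @return Object of class `a2_sampler`: node probabilities `p_v`,
#'   cumulative array `cum`, cached degrees `deg`, and
#'   `preprocessing_queries` (named vector).
#' @export
build_a2 <- function(oracle) {
  stopifnot(inherits(oracle, "ggm_oracle"))
  n <- oracle$network$n
  before <- query_counts(oracle)
  deg <- vapply(seq_len(n) - 1L, function(v) oracle_degree(oracle, v), numeric(1))
  z <- sum(deg^2)
  if (z == 0) stop("all degrees zero; A^2 distribution undefined")
  p_v <- deg^2 / z
  structure(
    list(
      p_v = p_v, cum = cumsum(p_v), deg = as.integer(deg),
      preprocessing_queries = query_counts(oracle) - before
    ),
    class = "a2_sampler"
  )
}

#' Draw link samples from the A^2 sampler
#'
#' Each draw bisects the cumulative node array to pick `v` (no queries),
#' picks neighbour indices `l, l'` uniformly and independently on
#' `1..k_v` (two neighbour queries to learn `i` and `j`; `i = j` is possible
#' and counts as a bad sample), and spends one vertex-pair query on the
#' usefulness check, for exactly 3 input queries per draw. The marginal law
#' of `(i, j)` is [exact_power_distribution()] with `n = 2`. Each draw
#' consumes exactly three uniform variates from R's RNG.
#'
#' @param sampler an [build_a2()] result built on the same network as
#'   `oracle`.
#' @param oracle the [ggm_oracle()]; its neighbour/pair counters advance by
#'   `2 * n_draws` and `n_draws`.
#' @param n_draws number of samples.
#' @return Data frame with columns `i`, `j`, `useful` (logical:
#'   `A_ij = 0` and `i != j`), `parity` ("none") and `queries_spent` (3).
#' @export
draw_a2 <- function(sampler, oracle, n_draws = 1L) {
  stopifnot(inherits(sampler, "a2_sampler"), inherits(oracle, "ggm_oracle"))
  net <- oracle$network
  v <- findInterval(stats::runif(n_draws), sampler$cum) + 1L  # 1-based node
  kv <- sampler$deg[v]
  l1 <- 1L + as.integer(floor(stats::runif(n_draws) * kv))
  l2 <- 1L + as.integer(floor(stats::runif(n_draws) * kv))
  flat <- unlist(net$nbr, use.names = FALSE)
  offs <- cumsum(c(0L, lengths(net$nbr)))
  i <- flat[offs[v] + l1]
  j <- flat[offs[v] + l2]
  bump_queries(oracle, neighbour = 2 * n_draws, pair = n_draws)
  useful <- net$adj[cbind(i + 1L, j + 1L)] == 0L & i != j
  data.frame(i = i, j = j, useful = useful, parity = "none",
             queries_spent = 3L)
}

#' Preprocess the A^3 sampler
#'
#' Queries the degree and full neighbour list of every node (exactly `N`
#' degree queries plus `sum_v k_v = 2|E|` neighbour queries — the whole
#' input), and builds the distribution over ordered adjacent pairs
#' `p_uv = k_u k_v / Z` with `Z = sum over ordered edges of k_u k_v`, which
#' equals `||A^3||_{1,1}`. Everything the draws need (neighbour lists,
#' adjacency) is cached here, so draws cost zero further queries.
#'
#' @param oracle a [ggm_oracle()].
#' @return Object of class `a3_sampler` with the ordered pair list `pairs`,
#'   their probabilities `p_uv`, cumulative array `cum`, cached `deg` and
#'   neighbour lists `nbr`, and `preprocessing_queries`.
#' @export
build_a3 <- function(oracle) {
  stopifnot(inherits(oracle, "ggm_oracle"))
  n <- oracle$network$n
  before <- query_counts(oracle)
  deg <- integer(n)
  nbr <- vector("list", n)
  for (v in seq_len(n) - 1L) {
    deg[v + 1L] <- oracle_degree(oracle, v)
    nbr[[v + 1L]] <- vapply(
      seq_len(deg[v + 1L]),
      function(l) oracle_neighbour(oracle, v, l),
      integer(1)
    )
  }
  if (sum(deg) == 0L) stop("edgeless network; A^3 distribution undefined")
  u <- rep.int(seq_len(n) - 1L, deg)        # ordered pairs (u, v): A_uv = 1
  v <- unlist(nbr, use.names = FALSE)
  w <- deg[u + 1L] * deg[v + 1L]
  p_uv <- w / sum(w)
  structure(
    list(
      pairs = cbind(u = u, v = v), p_uv = p_uv, cum = cumsum(p_uv),
      deg = deg, nbr = nbr,
      edge_keys = as.numeric(u) * n + v,  # cached adjacency as hashed ordered pairs
      preprocessing_queries = query_counts(oracle) - before
    ),
    class = "a3_sampler"
  )
}

#' Draw link samples from the A^3 sampler
#'
#' Each draw bisects the cumulative array over ordered adjacent pairs to
#' pick `(u, v)`, then picks `i` uniformly from the cached neighbours of `u`
#' and `j` uniformly from the cached neighbours of `v`; usefulness comes
#' from the cached adjacency. No input queries are spent — the whole graph
#' was read during preprocessing. The marginal law of `(i, j)` is
#' [exact_power_distribution()] with `n = 3`. Each draw consumes exactly
#' three uniform variates.
#'
#' @param sampler a [build_a3()] result.
#' @param n_draws number of samples.
#' @return Data frame as in [draw_a2()], with `queries_spent = 0`.
#' @export
draw_a3 <- function(sampler, n_draws = 1L) {
  stopifnot(inherits(sampler, "a3_sampler"))
  idx <- findInterval(stats::runif(n_draws), sampler$cum) + 1L
  u <- sampler$pairs[idx, "u"]
  v <- sampler$pairs[idx, "v"]
  ku <- sampler$deg[u + 1L]
  kv <- sampler$deg[v + 1L]
  l1 <- 1L + as.integer(floor(stats::runif(n_draws) * ku))
  l2 <- 1L + as.integer(floor(stats::runif(n_draws) * kv))
  flat <- unlist(sampler$nbr, use.names = FALSE)
  offs <- cumsum(c(0L, lengths(sampler$nbr)))
  i <- flat[offs[u + 1L] + l1]
  j <- flat[offs[v + 1L] + l2]
  # adjacency reconstructed from the cached neighbour lists, not the oracle
  useful <- !((as.numeric(i) * length(sampler$deg) + j) %in% sampler$edge_keys) &
    i != j
  data.frame(i = i, j = j, useful = useful, parity = "none",
             queries_spent = 0L)
}

#' Query-cost report for a sampling run
#'
#' Tabulates preprocessing versus per-sample input queries by query type,
#' and reports the empirical `n_draws` to `n_useful` ratio, the measured
#' counterpart of the `1 / p_G` rejection overhead in the samplers' query
#' complexity (`O(N + n_s / p_G)` for the A^2 sampler, `O(|E|)` for A^3).
#'
#' @param sampler an `a2_sampler` or `a3_sampler`.
#' @param oracle the oracle the run used.
#' @param n_draws total draws taken.
#' @param n_useful useful samples among them.
#' @return Data frame with columns `phase`, `degree`, `neighbour`, `pair`,
#'   `total`; attributes `p_hat_G` (empirical useful fraction) and
#'   `overhead` (`n_draws / n_useful`, `Inf` when no useful sample).
#' @export
query_cost_report <- function(sampler, oracle, n_draws, n_useful) {
  pre <- sampler$preprocessing_queries
  tot <- query_counts(oracle)
  samp <- tot - pre
  out <- data.frame(
    phase = c("preprocessing", "sampling", "total"),
    degree = c(pre[["degree"]], samp[["degree"]], tot[["degree"]]),
    neighbour = c(pre[["neighbour"]], samp[["neighbour"]], tot[["neighbour"]]),
    pair = c(pre[["pair"]], samp[["pair"]], tot[["pair"]]),
    total = c(pre[["total"]], samp[["total"]], tot[["total"]])
  )
  attr(out, "p_hat_G") <- if (n_draws > 0) n_useful / n_draws else NA_real_
  attr(out, "overhead") <- if (n_useful > 0) n_draws / n_useful else Inf
  out
}
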