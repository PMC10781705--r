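#' Sample an i.i.d. discrete power-law degree sequence
#'
#' Degrees are drawn from `P(k) proportional to k^(-gamma)` on the truncated
#' support `k_min..k_max` (default `k_max = N - 1`, the largest degree a
#' simple graph admits), and the sum is forced even by incrementing one
#' uniformly chosen node, so the sequence can seed a configuration model.
#'
#' @param n number of nodes.
#' @param gamma power-law exponent, `gamma > 2`.
#' @param k_min minimum degree, `>= 1`.
#' @param k_max maximum degree; defaults to `n - 1`.
#' @return Integer vector of `n` degrees with an even sum.
#' @export
powerlaw_degrees <- function(n, gamma, k_min = 1L, k_max = n - 1L) {
  stopifnot(n >= 2L, gamma > 2, k_min >= 1L, k_max >= k_min)
  ks <- k_min:k_max
  deg <- sample(ks, n, replace = TRUE, prob = ks^(-gamma))
  if (sum(deg) %% 2L == 1L) {
    i <- sample.int(n, 1L)
    deg[i] <- deg[i] + 1L
  }
  as.integer(deg)
}

#' Generate a scale-free network (configuration model)
#'
#' Draws a power-law degree sequence with [powerlaw_degrees()] and realizes
#' it as a simple graph with the configuration model, removing self-loops
#' and multi-edges by degree-preserving edge switching
#' (igraph's `edge.switching.simple` method). If a sampled sequence is not
#' graphical the sequence is resampled, up to `max_tries` times. The
#' largest hub of such networks grows as `k_max = O(N^(1/(gamma-1)))`.
#'
#' @param n number of nodes, `>= 10`.
#' @param gamma power-law exponent, `gamma > 2` (real networks typically
#'   have `2 < gamma <= 4`).
#' @param k_min minimum degree of the sampled sequence.
#' @param seed integer seed; the same seed reproduces the same edge set.
#' @param max_tries resampling attempts before giving up.
#' @return A [network()] object.
#' @examples
#' g <- generate_scale_free(200, gamma = 2.5, k_min = 2, seed = 1)
#' g$k_max
#' @export
generate_scale_free <- function(n, gamma, k_min = 1L, seed = 1L, max_tries = 25L) {
  stopifnot(n >= 10L, gamma > 2)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    deg <- powerlaw_degrees(n, gamma, k_min)
    g <- tryCatch(
      igraph::sample_degseq(deg, method = "edge.switching.simple"),
      error = function(e) NULL
    )
    if (!is.null(g)) {
      el <- igraph::as_edgelist(g, names = FALSE) - 1L
      return(network(el, n = n))
    }
  }
  stop("could not realize a graphical power-law degree sequence after ",
       max_tries, " attempts")
}

#' Generate an Erdos-Renyi G(N, p) network
#'
#' Control model with `p = k_av / (N - 1)` so the expected mean degree is
#' `k_av`.
#'
#' @param n number of nodes.
#' @param k_av target average degree, `0 < k_av < n - 1`.
#' @param seed integer seed.
#' @return A [network()] object.
#' @export
generate_er <- function(n, k_av, seed = 1L) {
  stopifnot(n >= 2L, k_av > 0, k_av < n - 1)
  set.seed(seed)
  g <- igraph::sample_gnp(n, k_av / (n - 1))
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  network(el, n = n)
}

#' Link-removal cross-validation folds
#'
#' Each fold independently removes a uniform random subset of
#' `round(fraction * |E|)` links from the network (folds are independent
#' resamples, not a partition). The removed links become the held-out truth
#' matrix `A'` against which precision is scored; the remaining links form
#' the training network.
#'
#' @param network a [network()] object.
#' @param fraction fraction of links to hold out per fold, in (0, 1);
#'   0.1 reproduces the usual 10%-removal protocol.
#' @param folds number of folds.
#' @param seed master seed; per-fold sub-seeds are derived from it so each
#'   fold is individually reproducible.
#' @return List of `folds` objects of class `cv_fold`, each with fields
#'   `train` (a `walk_network`), `aprime` (0/1 matrix marking held-out links,
#'   both orientations), `fold` and `seed`.
#' @export
cv_split <- function(network, fraction = 0.1, folds = 10L, seed = 1L) {
  stopifnot(inherits(network, "walk_network"), fraction > 0, fraction < 1,
            folds >= 1L)
  m <- nrow(network$edges)
  n_out <- round(fraction * m)
  if (n_out < 1L) stop("fraction * |E| < 1: nothing to hold out")
  if (m - n_out < 1L) stop("holding out ", n_out, " links would empty the network")

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, folds)
  lapply(seq_len(folds), function(f) {
    set.seed(sub_seeds[f])
    out <- sample.int(m, n_out)
    train <- network(network$edges[-out, , drop = FALSE], n = network$n)
    held <- network$edges[out, , drop = FALSE]
    aprime <- matrix(0L, network$n, network$n)
    aprime[cbind(held[, 1L] + 1L, held[, 2L] + 1L)] <- 1L
    aprime[cbind(held[, 2L] + 1L, held[, 1L] + 1L)] <- 1L
    structure(
      list(train = train, aprime = aprime, fold = f, seed = sub_seeds[f]),
      class = "cv_fold"
    )
  })
}

#' Empirical scaling exponent of the largest hub
#'
#' Generates `reps` scale-free networks at each size, records the mean
#' largest degree, and returns the least-squares slope of
#' `log(mean k_max)` against `log(N)`. For a power-law exponent `gamma` the
#' expected slope is `1 / (gamma - 1)`.
#'
#' @param gamma power-law exponent.
#' @param sizes at least 3 distinct network sizes.
#' @param reps networks per size, `>= 5`.
#' @param k_min minimum degree passed to the generator.
#' @param seed master seed.
#' @return The fitted slope (a single number) with the per-size mean `k_max`
#'   table attached as attribute `"ensemble"`.
#' @export
kmax_scaling_exponent <- function(gamma, sizes, reps = 10L, k_min = 2L, seed = 1L) {
  sizes <- sort(unique(as.integer(sizes)))
  stopifnot(length(sizes) >= 3L, reps >= 5L)
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max, length(sizes) * reps),
                      nrow = length(sizes))
  mean_kmax <- vapply(seq_along(sizes), function(s) {
    mean(vapply(seq_len(reps), function(r) {
      generate_scale_free(sizes[s], gamma, k_min = k_min,
                          seed = run_seeds[s, r])$k_max
    }, numeric(1)))
  }, numeric(1))
  if (length(unique(mean_kmax)) == 1L) {
    stop("degenerate ensemble: mean k_max identical across sizes")
  }
  fit <- stats::lm(log(mean_kmax) ~ log(sizes))
  slope <- unname(stats::coef(fit)[2L])
  attr(slope, "ensemble") <- data.frame(n = sizes, mean_kmax = mean_kmax)
  slope
}
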