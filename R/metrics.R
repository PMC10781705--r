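# Masked quadratic mass of cos(At)/sin(At) from one eigendecomposition.
# For a set of ordered pairs (i, j) and a vector of times, returns the
# per-time sums over the pairs of cos(At)_ij^2 and sin(At)_ij^2, each
# divided by N. C_ij = sum_k Q_ik f(lambda_k t) Q_jk, so the masked mass
# costs O(M N) per time instead of a dense N^3 matrix function.
spectral_mask_mass <- function(es, i1, j1, t) {
  n <- nrow(es$vectors)
  w <- es$vectors[i1, , drop = FALSE] * es$vectors[j1, , drop = FALSE]
  lt <- outer(es$values, t)
  list(
    even = colSums((w %*% cos(lt))^2) / n,
    odd = colSums((w %*% sin(lt))^2) / n,
    frob_even = colSums(cos(lt)^2) / n,   # total even mass, all pairs
    frob_odd = colSums(sin(lt)^2) / n
  )
}

bad_pair_indices <- function(network) {
  # ordered pairs with (A + I)_ij = 1: the diagonal plus both edge orientations
  list(
    i1 = c(seq_len(network$n), network$edges[, 1L] + 1L, network$edges[, 2L] + 1L),
    j1 = c(seq_len(network$n), network$edges[, 2L] + 1L, network$edges[, 1L] + 1L)
  )
}

#' Probability of a bad (useless) sample under a score distribution
#'
#' Mass of the distribution on existing links and the diagonal,
#' `sum_ij (A + I)_ij P_ij`. Complements [p_good()]: the two always sum
#' to one.
#'
#' @param dist a [exact_power_distribution()] or [qlp_distribution()] (the
#'   latter uses the stacked even + odd matrix).
#' @param network the generating [network()].
#' @return A probability in \[0, 1\].
#' @export
p_bad <- function(dist, network) {
  stopifnot(inherits(network, "walk_network"))
  p <- stacked_probability(dist)
  if (!all(dim(p) == network$n)) stop("distribution/network shape mismatch")
  sum((network$adj + diag(network$n)) * p)
}

#' Probability of a good (useful) sample under a score distribution
#'
#' Mass of the distribution on the good-link mask `G = J - (A + I)`:
#' unconnected, distinct node pairs — the only samples that constitute link
#' predictions.
#'
#' @inheritParams p_bad
#' @return A probability in \[0, 1\].
#' @examples
#' p3 <- network(rbind(c(0, 1), c(1, 2)))
#' p_good(exact_power_distribution(p3, 2), p3)  # 1/3
#' @export
p_good <- function(dist, network) {
  stopifnot(inherits(network, "walk_network"))
  p <- stacked_probability(dist)
  if (!all(dim(p) == network$n)) stop("distribution/network shape mismatch")
  sum(good_link_matrix(network) * p)
}

stacked_probability <- function(dist) {
  if (inherits(dist, "qlp_distribution")) {
    dist$p_even + dist$p_odd
  } else if (inherits(dist, "score_distribution")) {
    dist$P
  } else {
    stop("dist must be a score_distribution or qlp_distribution")
  }
}

#' Useful-sample probability of the QLP walk over time
#'
#' `p_G(t) = (1/N) sum_ij G_ij (cos(At)_ij^2 + sin(At)_ij^2)`, split into
#' its even and odd parity components. Computed spectrally: the total mass
#' of each parity is a function of the eigenvalues alone, and the bad-pair
#' mass only touches the `N + 2|E|` diagonal and edge entries, so a whole
#' time grid costs one eigendecomposition.
#'
#' @param network a [network()] object.
#' @param t vector of walk times.
#' @return Data frame with columns `t`, `p_G`, `p_G_even`, `p_G_odd`.
#' @examples
#' p3 <- network(rbind(c(0, 1), c(1, 2)))
#' p_good_qlp(p3, pi / sqrt(2))$p_G  # 2/3, the maximum for this graph
#' @export
p_good_qlp <- function(network, t) {
  stopifnot(inherits(network, "walk_network"))
  es <- eigen(network$adj, symmetric = TRUE)
  bad <- bad_pair_indices(network)
  m <- spectral_mask_mass(es, bad$i1, bad$j1, t)
  p_even <- pmax(m$frob_even - m$even, 0)
  p_odd <- pmax(m$frob_odd - m$odd, 0)
  # t = 0 is the identity walk: all mass diagonal, so p_G is exactly zero
  p_even[t == 0] <- 0
  p_odd[t == 0] <- 0
  data.frame(t = t, p_G = p_even + p_odd, p_G_even = p_even, p_G_odd = p_odd)
}

#' Correct-sample probability of the QLP walk over time
#'
#' Mass of the even/odd walk distributions on the held-out truth matrix:
#' `p_C_even(t) = (1/N) sum_ij A'_ij cos(At)_ij^2`, and the sine analogue.
#' `A'` marks links removed from the training network, so it must not
#' overlap the training adjacency or the diagonal.
#'
#' @param train the training [network()] (held-out links removed).
#' @param aprime 0/1 matrix marking held-out links (both orientations).
#' @param t vector of walk times.
#' @return Data frame with columns `t`, `p_C_even`, `p_C_odd`.
#' @export
p_correct_qlp <- function(train, aprime, t) {
  stopifnot(inherits(train, "walk_network"))
  aprime <- as.matrix(aprime)
  validate_truth_mask(train, aprime)
  idx <- which(aprime == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(t = t, p_C_even = 0, p_C_odd = 0))
  }
  es <- eigen(train$adj, symmetric = TRUE)
  m <- spectral_mask_mass(es, idx[, 1L], idx[, 2L], t)
  data.frame(t = t, p_C_even = m$even, p_C_odd = m$odd)
}

validate_truth_mask <- function(train, aprime) {
  if (!all(dim(aprime) == train$n)) stop("truth matrix shape mismatch")
  if (!all(aprime %in% c(0, 1))) stop("truth matrix entries must be 0/1")
  if (any(aprime == 1 & (train$adj == 1 | diag(train$n) == 1))) {
    stop("truth matrix overlaps training links or the diagonal")
  }
  invisible(TRUE)
}

#' Sampling-conditional precision p_C / p_G
#'
#' Probability that a sample is a correct prediction given that it was
#' useful. Below the stability `floor` on `p_G` the division is numerically
#' meaningless (the small-t regime) and `NA` is returned instead.
#'
#' @param p_C correct-sample probability (vector ok).
#' @param p_G useful-sample probability, `>= p_C` componentwise.
#' @param floor smallest trustworthy `p_G`.
#' @return `p_C / p_G`, with `NA` where `p_G < floor`.
#' @export
precision_given_good <- function(p_C, p_G, floor = 1e-8) {
  if (any(p_C > p_G + 1e-12)) stop("p_C exceeds p_G: masks are inconsistent")
  out <- ifelse(p_G >= floor, p_C / p_G, NA_real_)
  unname(out)
}

#' Classical A^n sampling precision on a held-out split
#'
#' The `p_C|G` of the exact `A^2` or `A^3` score distribution on a training
#' network: held-out mass divided by good mass. `NA` when the distribution
#' has no good mass at all (e.g. `A^3` on a path or star, whose odd paths
#' only connect existing links).
#'
#' @param train training [network()].
#' @param aprime held-out 0/1 truth matrix.
#' @param n path length, 2 or 3.
#' @return A probability, or `NA` when undefined.
#' @export
classical_precision <- function(train, aprime, n) {
  aprime <- as.matrix(aprime)
  validate_truth_mask(train, aprime)
  dist <- exact_power_distribution(train, n)
  den <- p_good(dist, train)
  if (den == 0) return(NA_real_)
  sum(aprime * dist$P) / den
}

#' Useful-sample saturation curves across networks
#'
#' Computes the `p_G(t)` curve of the QLP walk for each network in a list
#' and its saturation value (maximum over the grid) — the evidence that the
#' rejection overhead `1 / p_G` stays an N-independent constant.
#'
#' @param networks list of [network()] objects (named or not).
#' @param t_grid walk-time grid, e.g. `seq(0, 5, length.out = 50)`.
#' @return List with `curves` (long data frame: `network`, `n`, `k_av`,
#'   `t`, `p_G`, `p_G_even`, `p_G_odd`) and `saturation` (one row per
#'   network with `p_G_max`).
#' @export
fig2_experiment <- function(networks, t_grid = seq(0, 5, length.out = 50L)) {
  stopifnot(is.list(networks), length(networks) >= 1L)
  labels <- names(networks)
  if (is.null(labels)) labels <- paste0("network_", seq_along(networks))
  curves <- do.call(rbind, lapply(seq_along(networks), function(k) {
    g <- networks[[k]]
    cbind(
      data.frame(network = labels[k], n = g$n, k_av = g$k_av),
      p_good_qlp(g, t_grid)
    )
  }))
  saturation <- do.call(rbind, lapply(split(curves, curves$network), function(d) {
    data.frame(network = d$network[1L], n = d$n[1L], k_av = d$k_av[1L],
               p_G_max = max(d$p_G))
  }))
  rownames(saturation) <- NULL
  list(curves = curves, saturation = saturation)
}

#' Cross-validated precision curves (QLP vs classical samplers)
#'
#' Runs the link-removal cross-validation protocol: for each fold a random
#' `fraction` of links is removed, the walk and the exact `A^2`/`A^3`
#' distributions are computed on the remaining network, and the
#' conditional precisions `p_C|G` are evaluated against the removed links.
#' Results are arithmetic means over folds; time points where a parity's
#' `p_G` sits below `floor` are excluded from that parity's average, with
#' the exclusion count reported.
#'
#' @param network the full [network()].
#' @param fraction held-out link fraction per fold (default 0.1).
#' @param folds number of independent folds (default 10).
#' @param t_grid walk-time grid; start it around 0.1 to stay clear of the
#'   small-`p_G` instability near `t = 0`.
#' @param seed master seed for the folds.
#' @param floor stability floor for the precision divisions.
#' @return Object of class `precision_curve`: list with `curve` (data frame
#'   over `t`: fold-averaged `p_G_even/odd`, `p_C_even/odd`,
#'   `p_CG_even/odd`, their standard deviations `sd_even`/`sd_odd`, and
#'   missing-fold counts `n_missing_even/odd`), scalars `p_CG_A2`,
#'   `p_CG_A3` (fold means; `NA` folds dropped), and `folds`.
#' @export
fig3_experiment <- function(network, fraction = 0.1, folds = 10L,
                            t_grid = seq(0.1, 5, length.out = 50L),
                            seed = 1L, floor = 1e-8) {
  fold_list <- cv_split(network, fraction, folds, seed)
  per_fold <- lapply(fold_list, function(fd) {
    g <- p_good_qlp(fd$train, t_grid)
    cc <- p_correct_qlp(fd$train, fd$aprime, t_grid)
    list(
      p_G_even = g$p_G_even, p_G_odd = g$p_G_odd,
      p_C_even = cc$p_C_even, p_C_odd = cc$p_C_odd,
      p_CG_even = precision_given_good(cc$p_C_even, g$p_G_even, floor),
      p_CG_odd = precision_given_good(cc$p_C_odd, g$p_G_odd, floor),
      a2 = classical_precision(fd$train, fd$aprime, 2L),
      a3 = classical_precision(fd$train, fd$aprime, 3L)
    )
  })
  get_mat <- function(fld) do.call(cbind, lapply(per_fold, `[[`, fld))
  mean_na <- function(m) rowMeans(m, na.rm = TRUE)
  sd_na <- function(m) apply(m, 1L, stats::sd, na.rm = TRUE)
  ce <- get_mat("p_CG_even")
  co <- get_mat("p_CG_odd")
  curve <- data.frame(
    t = t_grid,
    p_G_even = mean_na(get_mat("p_G_even")),
    p_G_odd = mean_na(get_mat("p_G_odd")),
    p_C_even = mean_na(get_mat("p_C_even")),
    p_C_odd = mean_na(get_mat("p_C_odd")),
    p_CG_even = mean_na(ce), sd_even = sd_na(ce),
    p_CG_odd = mean_na(co), sd_odd = sd_na(co),
    n_missing_even = rowSums(is.na(ce)),
    n_missing_odd = rowSums(is.na(co))
  )
  a2 <- vapply(per_fold, `[[`, numeric(1), "a2")
  a3 <- vapply(per_fold, `[[`, numeric(1), "a3")
  structure(
    list(curve = curve,
         p_CG_A2 = mean(a2, na.rm = TRUE), p_CG_A3 = mean(a3, na.rm = TRUE),
         sd_A2 = stats::sd(a2, na.rm = TRUE), sd_A3 = stats::sd(a3, na.rm = TRUE),
         folds = folds),
    class = "precision_curve"
  )
}

#' Total variation distance between two distributions over pairs
#' @param empirical,exact nonnegative matrices (or vectors) of matching
#'   shape, each summing to ~1.
#' @return Half the entrywise absolute difference, in \[0, 1\].
#' @export
tv_distance <- function(empirical, exact) {
  if (!all(dim(as.matrix(empirical)) == dim(as.matrix(exact)))) {
    stop("shape mismatch between empirical and exact distributions")
  }
  sum(abs(empirical - exact)) / 2
}

#' Empirical pair-frequency matrix from drawn samples
#' @param draws data frame with 0-based `i`, `j` columns, as returned by the
#'   samplers.
#' @param n_nodes network size.
#' @return `n x n` matrix of relative frequencies summing to 1.
#' @export
sample_frequency_matrix <- function(draws, n_nodes) {
  tab <- table(factor(draws$i * n_nodes + draws$j,
                      levels = 0:(n_nodes * n_nodes - 1)))
  # keys are row-major (i * n + j); fill the matrix to match
  matrix(as.numeric(tab), n_nodes, n_nodes, byrow = TRUE) / nrow(draws)
}
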