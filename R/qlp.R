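#' Cosine and sine of the adjacency matrix at walk time t
#'
#' The continuous-time quantum walk `exp(-iAt)` splits into real matrix
#' functions `cos(At)` and `sin(At)`, whose power series contain the even
#' and odd powers of `A` — the direct-similarity and neighbour-similarity
#' path scores, weighted by `t`. Both are computed exactly (to floating
#' point) from the symmetric eigendecomposition `A = Q L Q'`:
#' `cos(At) = Q cos(Lt) Q'`, `sin(At) = Q sin(Lt) Q'`. No complex
#' exponential is ever formed and no quantum state is simulated; the
#' measurement statistics are all that is needed.
#'
#' @param network a [network()] object with `N` at most `dense_cap`.
#' @param t walk time (dimensionless), `t >= 0`.
#' @param dense_cap guard on the dense eigendecomposition size.
#' @return Object of class `walk_matrices`: list with symmetric matrices
#'   `C` (= cos(At)) and `S` (= sin(At)) and the time `t`. They satisfy
#'   `C^2 + S^2 = I`.
#' @examples
#' wm <- walk_matrices(network(rbind(c(0, 1))), t = pi / 2)
#' round(wm$S, 12)  # sin(t) * A
#' @export
walk_matrices <- function(network, t, dense_cap = 5000L) {
  stopifnot(inherits(network, "walk_network"), t >= 0)
  if (network$n > dense_cap) {
    stop("N = ", network$n, " exceeds the dense eigendecomposition cap (",
         dense_cap, "); raise dense_cap deliberately if you have the memory")
  }
  es <- eigen(network$adj, symmetric = TRUE)
  cc <- es$vectors %*% (cos(es$values * t) * t(es$vectors))
  ss <- es$vectors %*% (sin(es$values * t) * t(es$vectors))
  structure(
    list(C = (cc + t(cc)) / 2, S = (ss + t(ss)) / 2, t = t),
    class = "walk_matrices"
  )
}

#' QLP measurement distribution at walk time t
#'
#' The full outcome distribution of measuring the walk circuit: an even
#' (ancilla 0) and an odd (ancilla 1) component over ordered node pairs,
#' `p_ij_even = |cos(At)_ij|^2 / N` and `p_ij_odd = |sin(At)_ij|^2 / N`.
#' Unitarity makes the two totals sum to one, which is asserted.
#'
#' @inheritParams walk_matrices
#' @return Object of class `qlp_distribution`: matrices `p_even`, `p_odd`,
#'   scalars `p_even_total`, `p_odd_total`, the time `t` and the generating
#'   `network`.
#' @export
qlp_distribution <- function(network, t, dense_cap = 5000L) {
  wm <- walk_matrices(network, t, dense_cap)
  n <- network$n
  p_even <- wm$C^2 / n
  p_odd <- wm$S^2 / n
  tot_e <- sum(p_even)
  tot_o <- sum(p_odd)
  if (abs(tot_e + tot_o - 1) > 1e-6) {
    stop("parity totals sum to ", tot_e + tot_o, ", not 1; eigendecomposition ",
         "must have failed numerically")
  }
  structure(
    list(p_even = p_even, p_odd = p_odd,
         p_even_total = tot_e, p_odd_total = tot_o,
         t = t, network = network),
    class = "qlp_distribution"
  )
}

#' Draw parity-labelled link samples from a QLP distribution
#'
#' Emulates measuring the circuit: each draw first selects the ancilla
#' parity with probability `(p_even_total, p_odd_total)`, then a pair
#' `(i, j)` from the normalized parity-conditional matrix — jointly one
#' categorical draw over the `2 N^2` outcomes. The usefulness flag
#' (`A_ij = 0`, `i != j`) is evaluated on the generating network, mirroring
#' post-selection on the measured ancilla and registers.
#'
#' @param dist a [qlp_distribution()].
#' @param n_draws number of samples.
#' @return Data frame with columns `i`, `j`, `useful`, `parity`
#'   ("even"/"odd") and `queries_spent` (0: no classical oracle is
#'   involved).
#' @export
sample_qlp <- function(dist, n_draws = 1L) {
  stopifnot(inherits(dist, "qlp_distribution"))
  n <- dist$network$n
  even <- stats::runif(n_draws) < dist$p_even_total
  idx <- integer(n_draws)
  if (any(even)) {
    idx[even] <- sample.int(n * n, sum(even), replace = TRUE,
                            prob = as.vector(dist$p_even))
  }
  if (any(!even)) {
    idx[!even] <- sample.int(n * n, sum(!even), replace = TRUE,
                             prob = as.vector(dist$p_odd))
  }
  i <- (idx - 1L) %% n           # row, 0-based (column-major layout)
  j <- (idx - 1L) %/% n          # column, 0-based
  useful <- dist$network$adj[cbind(i + 1L, j + 1L)] == 0L & i != j
  data.frame(i = i, j = j, useful = useful,
             parity = ifelse(even, "even", "odd"), queries_spent = 0L)
}

#' Gate and qubit counts of the QLP circuit
#'
#' The circuit holds two node registers of `ceiling(log2(N))` qubits plus a
#' single ancilla; apart from the controlled walk it uses `n + 2` Hadamard
#' and `n` CNOT gates, `n = ceiling(log2(N))`. Non-power-of-two `N` pads
#' the registers; padded basis states carry zero amplitude.
#'
#' @param n_nodes network size, `>= 2`.
#' @return Named integer vector `c(hadamards, cnots, qubits)`.
#' @examples
#' circuit_gate_counts(8)  # 5 Hadamards, 3 CNOTs, 7 qubits
#' @export
circuit_gate_counts <- function(n_nodes) {
  if (n_nodes < 2L) stop("need at least 2 nodes for a walk register")
  nq <- as.integer(ceiling(log2(n_nodes)))
  c(hadamards = nq + 2L, cnots = nq, qubits = 2L * nq + 1L)
}

#' Query estimate for QLP under d-sparse walk simulation
#'
#' Cost of producing `n_s` useful samples when each run of the circuit
#' simulates `exp(-iAt)` with the d-sparse algorithm at `d = k_max` and
#' `max|A_ij| = 1`: `n_s * k_max * t / p_G` input queries, with the
#' constants and polylog(1/epsilon) factors of the asymptotic statement set
#' to one — a comparator across parameter settings, not an absolute gate
#' count. When `C_queries` (queries per walk call under an arbitrary
#' simulation algorithm) is supplied, the generic estimate
#' `n_s * C_queries / p_G` is attached as attribute `"generic"`.
#'
#' @param n_s target number of useful samples.
#' @param p_G probability of a useful sample, `> 0`.
#' @param k_max largest degree.
#' @param t walk time.
#' @param C_queries optional queries per `exp(-iAt)` application.
#' @return The d-sparse query estimate (a single number).
#' @examples
#' dsparse_query_estimate(n_s = 1, p_G = 0.5, k_max = 10, t = 1)  # 20
#' @export
dsparse_query_estimate <- function(n_s, p_G, k_max, t, C_queries = NULL) {
  if (p_G <= 0) stop("p_G must be positive (the estimate diverges at p_G = 0)")
  est <- n_s * k_max * t / p_G
  if (!is.null(C_queries)) attr(est, "generic") <- n_s * C_queries / p_G
  est
}

#' Does the sample budget admit a quantum query speedup?
#'
#' On scale-free networks the largest hub grows as `k_max = O(N^(1/(gamma-1)))`,
#' so QLP's per-sample cost beats the classical samplers' linear-in-N input
#' reads only while the number of useful samples stays below
#' `N^((gamma-2)/(gamma-1))` (strict inequality).
#'
#' @param n_nodes network size.
#' @param gamma power-law exponent, `> 2`.
#' @param n_s number of useful samples.
#' @return Logical.
#' @examples
#' speedup_condition(1e6, 3, 999)   # TRUE  (threshold N^0.5 = 1000)
#' speedup_condition(1e6, 3, 1000)  # FALSE (boundary excluded)
#' @export
speedup_condition <- function(n_nodes, gamma, n_s) {
  if (gamma <= 2) stop("gamma must exceed 2; the threshold degenerates to N^0")
  n_s < n_nodes^((gamma - 2) / (gamma - 1))
}
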