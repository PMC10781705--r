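test_that("walk matrices reproduce the small-graph closed forms", {
  # t = 0: identity walk
  wm0 <- walk_matrices(er30_graph(), 0)
  expect_equal(wm0$C, diag(30), tolerance = 1e-12)
  expect_equal(max(abs(wm0$S)), 0, tolerance = 1e-12)

  # single edge: eigenvalues +/-1 give C = cos(t) I, S = sin(t) A
  g2 <- single_edge_graph()
  for (t in c(0.3, 1, pi / 2, 3)) {
    wm <- walk_matrices(g2, t)
    expect_equal(wm$C, cos(t) * diag(2), tolerance = 1e-12)
    expect_equal(wm$S, sin(t) * (matrix(1, 2, 2) - diag(2)), tolerance = 1e-12)
  }

  # P3: C_02 = (cos(sqrt(2) t) - 1)/2, S_02 = 0
  p3 <- p3_graph()
  for (t in c(0.5, 1.3, 2.7)) {
    wm <- walk_matrices(p3, t)
    expect_equal(wm$C[1, 3], (cos(sqrt(2) * t) - 1) / 2, tolerance = 1e-10)
    expect_equal(wm$S[1, 3], 0, tolerance = 1e-10)
  }

  expect_error(walk_matrices(er30_graph(), 1, dense_cap = 10), "cap")
})

test_that("C^2 + S^2 = I on random graphs (unitarity of the walk)", {
  for (seed in 1:20) {
    g <- random_graph(sample(5:25, 1), p = 0.3, seed = seed)
    for (t in c(0.3, 1, 3)) {
      wm <- walk_matrices(g, t)
      expect_lt(max(abs(wm$C %*% wm$C + wm$S %*% wm$S - diag(g$n))), 1e-9)
      expect_equal(wm$C, t(wm$C))
      expect_equal(wm$S, t(wm$S))
    }
  }
})

test_that("measurement distribution normalizes and splits by parity", {
  # t = 0: all mass even and diagonal
  g <- er30_graph()
  d0 <- qlp_distribution(g, 0)
  expect_equal(d0$p_even_total, 1, tolerance = 1e-12)
  expect_equal(diag(d0$p_even), rep(1 / 30, 30), tolerance = 1e-12)
  expect_equal(sum(d0$p_even) - sum(diag(d0$p_even)), 0, tolerance = 1e-12)

  # single edge at t = pi/2: all mass odd, on the two edge orientations
  dpi <- qlp_distribution(single_edge_graph(), pi / 2)
  expect_equal(dpi$p_odd_total, 1, tolerance = 1e-12)
  expect_equal(dpi$p_odd[1, 2], 1 / 2, tolerance = 1e-12)
  expect_equal(dpi$p_odd[2, 1], 1 / 2, tolerance = 1e-12)

  for (seed in 1:5) {
    d <- qlp_distribution(random_graph(15, p = 0.3, seed = seed), runif(1) * 4)
    expect_equal(d$p_even_total + d$p_odd_total, 1, tolerance = 1e-9)
    expect_true(all(d$p_even >= 0) && all(d$p_odd >= 0))
  }
})

test_that("odd mass respects bipartite parity of path lengths", {
  # on bipartite graphs sin(At) vanishes within parts, cos(At) across
  # odd-distance pairs; check the distributions directly
  for (gf in list(p3_graph, c4_graph, star4_graph)) {
    g <- gf()
    ig <- as_igraph(g)
    dmat <- igraph::distances(ig)
    d <- qlp_distribution(g, 1.3)
    odd_pairs <- (dmat %% 2) == 1
    expect_lt(max(d$p_odd[!odd_pairs]), 1e-18)
    expect_lt(max(d$p_even[odd_pairs]), 1e-18)
  }
})

test_that("short-time expansion recovers the leading path contributions", {
  # sin(At) ~ At and the off-diagonal of cos(At) - I ~ -(t^2/2) A^2
  p3 <- p3_graph()
  t <- 0.05
  d <- qlp_distribution(p3, t)
  a <- p3$adj
  storage.mode(a) <- "double"
  expect_equal(d$p_odd[1, 2], t^2 * a[1, 2]^2 / 3, tolerance = 0.1)
  a2 <- a %*% a
  expect_equal(d$p_even[1, 3], (t^2 / 2)^2 * a2[1, 3]^2 / 3, tolerance = 0.1)
})

test_that("sampling the distribution matches it empirically", {
  g <- er30_graph()
  d <- qlp_distribution(g, 0.3)
  set.seed(33)
  n_draws <- 1e5
  dr <- sample_qlp(d, n_draws)

  # parity fractions within binomial 3 sigma
  se <- sqrt(d$p_even_total * (1 - d$p_even_total) / n_draws)
  expect_lt(abs(mean(dr$parity == "even") - d$p_even_total), 3 * se)

  emp <- sample_frequency_matrix(dr, g$n)
  expect_lt(tv_distance(emp, d$p_even + d$p_odd), 0.02)

  # P3 at t = pi/sqrt(2): useful fraction concentrates at 2/3
  set.seed(34)
  drp <- sample_qlp(qlp_distribution(p3_graph(), pi / sqrt(2)), 1e5)
  expect_lt(abs(mean(drp$useful) - 2 / 3), 3 * sqrt(2 / 9 / 1e5))

  # t = 0 samples are diagonal, even, and never useful
  set.seed(35)
  dr0 <- sample_qlp(qlp_distribution(g, 0), 1000)
  expect_true(all(dr0$i == dr0$j))
  expect_true(all(dr0$parity == "even"))
  expect_false(any(dr0$useful))
})

test_that("circuit sizes follow the padded register arithmetic", {
  expect_equal(unname(circuit_gate_counts(8)), c(5L, 3L, 7L))
  expect_equal(unname(circuit_gate_counts(2)), c(3L, 1L, 3L))
  expect_equal(unname(circuit_gate_counts(1000)), c(12L, 10L, 21L))
  expect_error(circuit_gate_counts(1))
})

test_that("resource estimate and speedup bound do the advertised arithmetic", {
  expect_equal(dsparse_query_estimate(n_s = 1, p_G = 0.5, k_max = 10, t = 1), 20)
  e1 <- dsparse_query_estimate(2, 0.5, 10, 1)
  expect_equal(unclass(e1), 2 * dsparse_query_estimate(1, 0.5, 10, 1))
  est <- dsparse_query_estimate(1, 0.5, 10, 1, C_queries = 7)
  expect_equal(attr(est, "generic"), 14)
  expect_error(dsparse_query_estimate(1, 0, 10, 1), "positive")

  expect_true(speedup_condition(1e6, 3, 999))
  expect_false(speedup_condition(1e6, 3, 1000))  # strict inequality
  # the threshold shrinks toward N^0 = 1 as gamma approaches 2 from above
  expect_false(speedup_condition(1e6, 2.1, 5))
  expect_error(speedup_condition(1e6, 2, 10), "gamma")
})
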