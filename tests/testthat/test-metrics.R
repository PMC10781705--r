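test_that("good and bad sample probabilities complement exactly", {
  p3 <- p3_graph()
  d2 <- exact_power_distribution(p3, 2)
  expect_equal(p_bad(d2, p3), 4 / 6)
  expect_equal(p_good(d2, p3), 2 / 6)
  expect_equal(p_good(exact_power_distribution(p3, 3), p3), 0)
  expect_equal(p_good(exact_power_distribution(star4_graph(), 3), star4_graph()), 0)
  expect_equal(p_bad(exact_power_distribution(k3_graph(), 2), k3_graph()), 1)

  for (seed in 1:10) {
    g <- random_graph(20, p = 0.25, seed = seed)
    for (n in 2:3) {
      d <- exact_power_distribution(g, n)
      expect_equal(p_bad(d, g) + p_good(d, g), 1, tolerance = 1e-12)
    }
    d <- qlp_distribution(g, runif(1) * 4)
    expect_equal(p_bad(d, g) + p_good(d, g), 1, tolerance = 1e-9)
  }
})

test_that("spectral p_G(t) agrees with the dense distribution route", {
  for (seed in 1:5) {
    g <- random_graph(18, p = 0.25, seed = seed)
    for (t in c(0.4, 1.1, 2.9)) {
      fast <- p_good_qlp(g, t)
      d <- qlp_distribution(g, t)
      gm <- good_link_matrix(g)
      expect_equal(fast$p_G_even, sum(gm * d$p_even), tolerance = 1e-12)
      expect_equal(fast$p_G_odd, sum(gm * d$p_odd), tolerance = 1e-12)
      expect_equal(fast$p_G, p_good(d, g), tolerance = 1e-12)
    }
  }
})

test_that("P3 usefulness curve matches its analytic closed form", {
  p3 <- p3_graph()
  ts <- seq(0, 6, length.out = 100)
  curve <- p_good_qlp(p3, ts)
  expect_equal(curve$p_G, (cos(sqrt(2) * ts) - 1)^2 / 6, tolerance = 1e-9)
  expect_equal(max(abs(curve$p_G_odd)), 0, tolerance = 1e-12)
  expect_equal(p_good_qlp(p3, 0)$p_G, 0)
  expect_equal(p_good_qlp(p3, pi / sqrt(2))$p_G, 2 / 3, tolerance = 1e-9)
  # complete graph has no good pairs at any time
  expect_equal(max(p_good_qlp(k3_graph(), ts)$p_G), 0, tolerance = 1e-12)
})

test_that("correctness mass respects its mask and bounds", {
  p3 <- p3_graph()
  aprime <- matrix(0L, 3, 3)
  aprime[1, 3] <- aprime[3, 1] <- 1L
  ts <- c(0.5, 1.5, 2.5)
  pc <- p_correct_qlp(p3, aprime, ts)
  pg <- p_good_qlp(p3, ts)
  # for P3 the held-out mask equals the whole good mask
  expect_equal(pc$p_C_even, pg$p_G_even, tolerance = 1e-12)
  expect_equal(pc$p_C_odd, pg$p_G_odd, tolerance = 1e-12)

  expect_equal(p_correct_qlp(p3, matrix(0L, 3, 3), ts)$p_C_even, rep(0, 3))

  bad_mask <- matrix(0L, 3, 3)
  bad_mask[1, 2] <- 1L  # overlaps a training edge
  expect_error(p_correct_qlp(p3, bad_mask, 1), "overlap")

  # monotone masks: held-out subset of good implies p_C <= p_G
  g <- generate_er(40, k_av = 5, seed = 6)
  for (fd in cv_split(g, 0.1, 3, seed = 2)) {
    pcf <- p_correct_qlp(fd$train, fd$aprime, ts)
    pgf <- p_good_qlp(fd$train, ts)
    expect_true(all(pcf$p_C_even <= pgf$p_G_even + 1e-12))
    expect_true(all(pcf$p_C_odd <= pgf$p_G_odd + 1e-12))
  }
})

test_that("conditional precision divides safely above the stability floor", {
  expect_equal(precision_given_good(0.1, 0.2), 0.5)
  expect_true(is.na(precision_given_good(0, 1e-12)))
  expect_equal(precision_given_good(0.3, 0.3), 1)
  expect_equal(precision_given_good(c(0.1, 0), c(0.2, 1e-12)), c(0.5, NA))
  expect_error(precision_given_good(0.3, 0.2), "exceeds")
})

test_that("classical precision reduces to the masked A^n mass ratio", {
  p3 <- p3_graph()
  aprime <- matrix(0L, 3, 3)
  aprime[1, 3] <- aprime[3, 1] <- 1L
  expect_equal(classical_precision(p3, aprime, 2), 1)
  expect_true(is.na(classical_precision(p3, aprime, 3)))  # A^3 has no good mass
  expect_equal(classical_precision(p3, matrix(0L, 3, 3), 2), 0)
})

test_that("saturation curves report per-network maxima over the grid", {
  nets <- list(sf = generate_scale_free(150, 2.5, k_min = 2, seed = 1),
               k3 = k3_graph())
  res <- fig2_experiment(nets, seq(0, 5, length.out = 25))
  expect_equal(nrow(res$curves), 2 * 25)
  expect_equal(res$curves$p_G[res$curves$t == 0], c(0, 0))
  sat <- res$saturation
  expect_equal(sat$p_G_max[sat$network == "k3"], 0)
  expect_gte(sat$p_G_max[sat$network == "sf"], 0.1)
})

test_that("cross-validated precision pipeline averages folds deterministically", {
  g <- generate_er(50, k_av = 6, seed = 12)
  ts <- seq(0.1, 3, length.out = 10)
  res <- fig3_experiment(g, fraction = 0.1, folds = 3, t_grid = ts, seed = 5)
  expect_s3_class(res, "precision_curve")
  expect_equal(nrow(res$curve), 10)
  # away from t ~ 0 on a connected-ish graph nothing goes missing
  expect_true(all(res$curve$n_missing_even == 0))
  expect_true(all(res$curve$p_CG_even >= 0 & res$curve$p_CG_even <= 1,
                  na.rm = TRUE))
  expect_true(res$p_CG_A2 >= 0 && res$p_CG_A2 <= 1)

  res2 <- fig3_experiment(g, fraction = 0.1, folds = 3, t_grid = ts, seed = 5)
  expect_identical(res$curve, res2$curve)
})

test_that("total variation distance is the half L1 difference", {
  m <- matrix(c(0.5, 0.5, 0, 0), 2)
  expect_equal(tv_distance(m, m), 0)
  expect_equal(tv_distance(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), 1)
  expect_equal(tv_distance(c(0.6, 0.4), c(0.5, 0.5)), 0.1)
  expect_error(tv_distance(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})
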