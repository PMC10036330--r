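test_that("quadratic degree law evaluates and fits flag-complex data", {
  expect_equal(expected_k2(1, 0.7), 0)
  expect_equal(expected_k2(20, 0.1), 19)

  # regression of k2 on k1(k1-1)/2 through the origin recovers p within 10%
  xs <- ys <- numeric(0)
  for (s in 1:5) {
    d <- flag_degrees(er_graph(300, 0.3, seed = 500 + s))
    xs <- c(xs, d$k1 * (d$k1 - 1) / 2)
    ys <- c(ys, d$k2)
  }
  slope <- sum(xs * ys) / sum(xs * xs)
  expect_lt(abs(slope - 0.3) / 0.3, 0.1)
})

test_that("heterogeneity ratio matches hand enumeration and is label-free", {
  all_tri <- hypergraph(5, edges = t(combn(5, 2)), triangles = t(combn(5, 3)))
  expect_equal(heterogeneity_ratio(all_tri), 1)

  expect_equal(heterogeneity_ratio(k4_two_tri()), 2)

  no_min <- hypergraph(4, edges = rbind(c(1, 2)), triangles = rbind(c(1, 2, 3)))
  expect_error(heterogeneity_ratio(no_min), "undefined")

  H <- flag_complex(er_graph(60, 0.4, seed = 77))
  perm <- sample(60)
  Hp <- hypergraph(60, edges = matrix(perm[H$edges], ncol = 2),
                   triangles = matrix(perm[H$triangles], ncol = 3))
  expect_equal(heterogeneity_ratio(Hp), heterogeneity_ratio(H))
})

test_that("flag complexes of ER graphs are rich-get-richer (r > 1, decreasing in p)", {
  mean_r <- vapply(c(0.2, 0.5, 0.8), function(p) {
    rs <- vapply(1:10, function(s) {
      heterogeneity_ratio(flag_degrees(er_graph(300, p, seed = round(1e4 * p) + s)))
    }, numeric(1))
    expect_true(all(rs > 1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})

test_that("Gumbel extreme estimate obeys its limits and the order-statistics oracle", {
  expect_equal(gumbel_extreme_estimate(1000, 1), 1000)
  expect_equal(gumbel_extreme_estimate(1000, 0), 0)
  # f(m, y) -> 1, but only logarithmically: check the limit and monotone approach
  f_gap <- abs(triadsync:::gumbel_correction(10^c(3, 6, 12, 40), -log(log(2))) - 1)
  expect_true(all(diff(f_gap) < 0))
  expect_lt(f_gap[4], 0.02)

  est <- gumbel_extreme_estimate(500, 0.1)
  oracle <- exact_max_binomial_median(500, 0.1, 500)
  expect_lt(abs(est - oracle) / oracle, 0.05)

  # min side is the mirror image of the max side around p * m
  lo <- gumbel_extreme_estimate(500, 0.1, side = "min")
  expect_equal((est + lo) / 2, 0.1 * 500)
})

test_that("theoretical heterogeneity-index ratio exceeds sqrt(n)/2", {
  hi <- heterogeneity_indexes(400, 1)
  expect_equal(hi$h1, 0)
  expect_equal(hi$h2, 0)

  for (n in c(50, 100, 200, 500, 1000)) {
    th <- heterogeneity_indexes(n, 0.1)
    expect_gt(th$ratio_asymptotic, sqrt(n) / 2)
    # finite-size corrections perturb the ratio only a few percent
    expect_lt(abs(th$ratio - th$ratio_asymptotic) / th$ratio_asymptotic, 0.07)
  }
})

test_that("empirical heterogeneity indexes average maxima over the ensemble", {
  emp <- empirical_hetero_indexes(100, 0.1, 0.1, n_samples = 30, seed = 9)
  expect_gt(emp$h1, emp$h2)
  expect_gte(emp$ratio, sqrt(100) / 2)
  # theoretical Gumbel estimate tracks the empirical h1 reasonably
  th <- heterogeneity_indexes(100, 0.1)
  expect_lt(abs(emp$h1 - th$h1) / th$h1, 0.35)
})

test_that("cross-order degree correlation separates representations", {
  perfect <- hypergraph(4, edges = rbind(c(1, 2), c(2, 3), c(3, 4)),
                        triangles = rbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(degrees(perfect)$k1, c(1, 2, 2, 1))
  expect_equal(degrees(perfect)$k2, c(1, 2, 2, 1))
  expect_equal(cross_order_degree_correlation(perfect), 1)

  all_tri <- hypergraph(5, edges = t(combn(5, 2)), triangles = t(combn(5, 3)))
  expect_error(cross_order_degree_correlation(all_tri), "constant")

  expect_gt(cross_order_degree_correlation(flag_complex(er_graph(300, 0.3, seed = 5))), 0.5)

  dcs <- vapply(1:10, function(s) {
    cross_order_degree_correlation(random_hypergraph(100, 0.1, 0.1, seed = 800 + s))
  }, numeric(1))
  expect_lt(abs(mean(dcs)), 0.1)
})

test_that("membership swaps lower DC but never the heterogeneity ratio", {
  H0 <- flag_complex(er_graph(100, 0.3, seed = 13))
  H <- swap_memberships(H0, 10)
  expect_lt(cross_order_degree_correlation(H), cross_order_degree_correlation(H0))
  expect_equal(heterogeneity_ratio(H), heterogeneity_ratio(H0))
})

test_that("exact max-binomial median agrees with Monte Carlo", {
  expect_equal(exact_max_binomial_median(100, 0.3, 1), qbinom(0.5, 100, 0.3))
  expect_equal(exact_max_binomial_median(77, 1, 10), 77)

  mc <- withr::with_seed(99, {
    stats::median(replicate(1e4, max(rbinom(500, 500, 0.1))))
  })
  expect_lte(abs(exact_max_binomial_median(500, 0.1, 500) - mc), 1)
  expect_error(exact_max_binomial_median(1e8, 0.5, 10), "too large")
})
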