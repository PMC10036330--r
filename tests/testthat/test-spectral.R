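test_that("order-1 and order-2 Laplacians have the defining structure", {
  H <- k3_tri()
  L2 <- laplacian_second(H)
  expect_equal(diag(L2), rep(1, 3))
  expect_equal(L2[upper.tri(L2)], rep(-0.5, 3))

  expect_equal(laplacian_second(hypergraph(4, edges = rbind(c(1, 2)))),
               matrix(0, 4, 4))

  for (seed in 1:4) {
    Hr <- random_hypergraph(25, 0.2, 0.1, seed = seed)
    expect_equal(rowSums(laplacian_first(Hr)), rep(0, 25))
    expect_equal(rowSums(laplacian_second(Hr)), rep(0, 25))
  }
})

test_that("multiorder Laplacian interpolates between normalized orders", {
  H <- random_hypergraph(30, 0.3, 0.1, seed = 8)
  d <- degrees(H)
  expect_equal(multiorder_laplacian(H, 0), laplacian_first(H) / d$mean_k1)
  expect_equal(multiorder_laplacian(H, 1), laplacian_second(H) / d$mean_k2)

  # K3 + one 2-simplex: both normalized layers coincide, spectrum alpha-free
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    expect_equal(sort(eigen(multiorder_laplacian(k3_tri(), a),
                            symmetric = TRUE, only.values = TRUE)$values),
                 c(0, 1.5, 1.5))
  }

  no_tri <- hypergraph(5, edges = rbind(c(1, 2), c(2, 3)))
  expect_error(multiorder_laplacian(no_tri, 0.5), "normalization undefined")
  expect_silent(multiorder_laplacian(no_tri, 0))
})

test_that("multiorder Laplacian is PSD with the uniform kernel at every alpha", {
  for (seed in 1:5) {
    H <- random_hypergraph(40, 0.2, 0.1, seed = 40 + seed)
    for (a in c(0, 0.33, 0.71, 1)) {
      L <- multiorder_laplacian(H, a)
      expect_equal(L, t(L))
      expect_equal(as.numeric(L %*% rep(1, 40)), rep(0, 40))
      ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-9 * max(ev))
    }
  }
})

test_that("lambda2 distinguishes connected from disconnected supports", {
  two_k3 <- hypergraph(6, edges = rbind(c(1, 2), c(1, 3), c(2, 3),
                                        c(4, 5), c(4, 6), c(5, 6)))
  expect_identical(lambda2(two_k3, 0)$lambda2, 0)

  for (a in c(0, 0.5, 1)) {
    expect_equal(lambda2(k3_tri(), a)$lambda2, -1.5)
  }

  H <- random_hypergraph(100, 0.1, 0.1, seed = 17)
  expect_true(connected_support(H, 0.5))
  expect_lt(lambda2(H, 0.5)$lambda2, 0)
})

test_that("lambda2 is continuous along the alpha pencil", {
  H <- random_hypergraph(60, 0.3, 0.1, seed = 23)
  alphas <- seq(0, 1, by = 0.02)
  l2 <- vapply(alphas, function(a) lambda2(H, a)$lambda2, numeric(1))
  expect_lt(max(abs(diff(l2))), 0.1 * max(abs(l2)))
  expect_true(all(l2 < 0))
})

test_that("degree bounds bracket the extreme eigenvalues", {
  # K3, pairwise only: kmul = 1, |lambda_n| = 3/2 <= 2
  b <- degree_bounds(hypergraph(3, edges = rbind(c(1, 2), c(1, 3), c(2, 3))), 0)
  expect_equal(b$kmax, 1)
  expect_equal(b$abs_lambdan, 1.5)
  expect_equal(b$lambdan_upper, 2)
  expect_true(all(b$holds))

  # complete graph: n/(n-1) * kmin is exactly tight
  for (n in c(10, 25)) {
    Hc <- hypergraph(n, edges = t(combn(n, 2)))
    bc <- degree_bounds(Hc, 0)
    expect_equal(bc$abs_lambda2, bc$lambda2_upper)
  }

  for (seed in 1:20) {
    H <- random_hypergraph(60, 0.15, 0.1, seed = 60 + seed)
    for (a in c(0, 0.5, 1)) {
      expect_true(all(degree_bounds(H, a)$holds))
    }
  }
})

test_that("alpha sweeps are deterministic with zero SD for one realization", {
  spec <- generator_spec("random_hypergraph", n = 40, p = 0.3, p_tri = 0.1)
  sw1 <- alpha_sweep(spec, alphas = c(0, 0.5, 1), n_realizations = 1, seed = 4)
  expect_equal(sw1$lambda2_sd, rep(0, 3))

  sw2 <- alpha_sweep(spec, alphas = c(0, 0.5, 1), n_realizations = 5, seed = 4)
  sw3 <- alpha_sweep(spec, alphas = c(0, 0.5, 1), n_realizations = 5, seed = 4)
  expect_equal(sw2, sw3)
  expect_true(all(sw2$lambda2_sd >= 0))
})
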