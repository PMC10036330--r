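test_that("random hypergraph hits its limiting cases and binomial counts", {
  expect_equal(nrow(random_hypergraph(10, 0, 0)$edges), 0)
  expect_equal(nrow(random_hypergraph(10, 0, 0)$triangles), 0)

  full <- random_hypergraph(8, 1, 1)
  expect_equal(nrow(full$edges), choose(8, 2))
  expect_equal(nrow(full$triangles), choose(8, 3))

  counts <- vapply(1:200, function(s) {
    nrow(random_hypergraph(200, 0.1, 0, seed = s)$edges)
  }, numeric(1))
  mu <- 0.1 * choose(200, 2)
  mc_se <- sqrt(choose(200, 2) * 0.1 * 0.9 / 200)
  expect_lt(abs(mean(counts) - mu), 3 * mc_se)
})

test_that("generators are deterministic given a seed", {
  expect_identical(random_hypergraph(40, 0.2, 0.1, seed = 9),
                   random_hypergraph(40, 0.2, 0.1, seed = 9))
  spec <- generator_spec("flag_complex_er", n = 50, p = 0.3)
  expect_identical(generate(spec, seed = 3), generate(spec, seed = 3))
})

test_that("flag complex fills exactly the 3-cliques", {
  tree <- igraph::make_tree(20, 2, mode = "undirected")
  expect_equal(nrow(flag_complex(tree)$triangles), 0)

  expect_equal(nrow(flag_complex(igraph::make_full_graph(4))$triangles), 4)

  g <- er_graph(60, 0.3, seed = 12)
  H <- flag_complex(g)
  expect_true(is_simplicial_complex(H))
  expect_equal(nrow(H$edges), igraph::ecount(g))
  expect_equal(nrow(H$triangles), oracle_triangle_count(g))
})

test_that("probabilistic triangle filling interpolates to the flag complex", {
  g <- er_graph(30, 0.4, seed = 7)
  expect_equal(nrow(fill_triangles(g, 0)$triangles), 0)
  expect_identical(fill_triangles(g, 1), flag_complex(g))

  k5 <- igraph::make_full_graph(5)
  counts <- vapply(1:500, function(s) {
    nrow(fill_triangles(k5, 0.5, seed = s)$triangles)
  }, numeric(1))
  mu <- 0.5 * choose(5, 3)
  mc_se <- sqrt(choose(5, 3) * 0.25 / 500)
  expect_lt(abs(mean(counts) - mu), 3 * mc_se)
})

test_that("fixed-budget sampling is exact and validates its budget", {
  H0 <- fixed_budget_hypergraph(10, 0, 0)
  expect_equal(nrow(H0$edges) + nrow(H0$triangles), 0)

  Hfull <- fixed_budget_hypergraph(7, choose(7, 2), choose(7, 3), seed = 1)
  expect_equal(nrow(Hfull$edges), choose(7, 2))
  expect_equal(nrow(Hfull$triangles), choose(7, 3))

  for (s in 1:5) {
    H <- fixed_budget_hypergraph(20, 37, 51, seed = s)
    expect_equal(nrow(H$edges), 37)
    expect_equal(nrow(H$triangles), 51)
  }
  expect_error(fixed_budget_hypergraph(5, 11, 0), "budget")
  expect_error(fixed_budget_hypergraph(5, 0, 11), "budget")
})

test_that("simplex shuffling conserves the triangle count and the edges", {
  H0 <- flag_complex(er_graph(50, 0.3, seed = 21))
  expect_identical(shuffle_simplices(H0, 0, seed = 1), H0)

  for (ps in c(0.3, 1)) {
    H <- shuffle_simplices(H0, ps, seed = 22)
    expect_identical(H$edges, H0$edges)
    expect_equal(nrow(H$triangles), nrow(H0$triangles))
    # canonical constructor guarantees no duplicates/degenerates survived
    expect_false(anyDuplicated(triadsync:::rank_triples(H$triangles)) > 0)
  }
})

test_that("full shuffling pushes cross-order degree correlation toward zero", {
  dc0 <- dc1 <- numeric(15)
  for (s in 1:15) {
    H0 <- flag_complex(er_graph(60, 0.4, seed = 300 + s))
    dc0[s] <- cross_order_degree_correlation(H0)
    dc1[s] <- cross_order_degree_correlation(shuffle_simplices(H0, 1, seed = s))
  }
  expect_gt(mean(dc0), 0.5)          # inclusion condition: strongly positive
  expect_lt(abs(mean(dc1)), 0.15)    # shuffled: near zero
  expect_lt(mean(abs(dc1)), mean(dc0) / 2)
})

test_that("membership swaps preserve degree sequences and the order-2 spectrum", {
  H0 <- flag_complex(er_graph(100, 0.3, seed = 31))
  expect_identical(swap_memberships(H0, 0), H0)

  H <- swap_memberships(H0, 15)
  d0 <- degrees(H0); d <- degrees(H)
  expect_identical(d$k1, d0$k1)
  expect_identical(sort(d$k2), sort(d0$k2))
  expect_lt(cross_order_degree_correlation(H),
            cross_order_degree_correlation(H0))
  ev0 <- eigen(laplacian_second(H0), symmetric = TRUE, only.values = TRUE)$values
  ev <- eigen(laplacian_second(H), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, ev0, tolerance = 1e-9)

  # swapped pair exchanges its k2 values
  k2 <- d0$k2
  ord <- order(k2, seq_along(k2))
  i <- ord[1]; j <- ord[length(k2)]
  H1 <- swap_memberships(H0, 1)
  expect_equal(degrees(H1)$k2[c(i, j)], k2[c(j, i)])

  expect_error(swap_memberships(H0, 51), "overlapping")
  expect_error(swap_memberships(H0, -1), "non-negative")
})

test_that("pairwise substrates have their family-defining structure", {
  expect_equal(igraph::ecount(er_graph(10, 1)), choose(10, 2))

  ring <- smallworld_graph(30, 2, 0, seed = 1)
  expect_true(all(igraph::degree(ring) == 4))

  sf <- scalefree_graph(100, 2, seed = 2)
  expect_equal(sum(igraph::degree(sf)) %% 2, 0)
  expect_equal(igraph::ecount(sf), 2 * (100 - 2) + 1)
  expect_gt(max(igraph::degree(sf)), 3 * mean(igraph::degree(sf)))
})

test_that("generator specs round-trip through flat key-value files", {
  spec <- generator_spec("random_hypergraph", n = 80, p = 0.25, p_tri = 0.1)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_generator_spec(spec, path)
  spec2 <- read_generator_spec(path)
  expect_identical(spec2$family, spec$family)
  expect_equal(spec2$n, spec$n)
  expect_equal(spec2$p, spec$p)
  expect_identical(generate(spec, seed = 5), generate(spec2, seed = 5))
})
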