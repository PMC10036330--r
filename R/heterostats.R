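# Degree-heterogeneity theory: quadratic degree law, heterogeneity ratio and
# indexes, Gumbel extreme-value estimates, cross-order degree correlation.

#' Expected generalized degree in a flag complex of an ER graph
#'
#' In the flag complex of `G(n, p)`, a node of first-order degree `k1` has
#' `choose(k1, 2)` candidate 2-simplices among its neighbors, each filled
#' independently with probability `p`, so
#' `E[k2 | k1] = p * k1 * (k1 - 1) / 2`.
#' This quadratic dependence is the rich-get-richer mechanism that amplifies
#' degree heterogeneity at the triadic order.
#'
#' @param k1 first-order degree(s).
#' @param p pairwise wiring probability.
#' @return expected second-order degree(s).
#' @export
expected_k2 <- function(k1, p) {
  stopifnot(all(k1 >= 0))
  stop_if_not_prob(p, "p")
  p * k1 * (k1 - 1) / 2
}

#' Heterogeneity ratio between triadic and pairwise degrees
#'
#' `r = (max(k2) / min(k2)) / (max(k1) / min(k1))`. Values above 1 mean the
#' triadic coupling structure is more degree-heterogeneous than the pairwise
#' one, which degrades synchronization stability as coupling shifts to the
#' triadic order. On flag complexes of ER graphs, `r ~ max(k1) / min(k1) >= 1`.
#' Invariant under node relabeling.
#'
#' @param x a [hypergraph()] or a `degree_summary` from [degrees()].
#' @return the ratio `r`.
#' @export
heterogeneity_ratio <- function(x) {
  d <- if (is_hypergraph(x)) degrees(x) else x
  stopifnot(inherits(d, "degree_summary"))
  if (min(d$k1) == 0 || min(d$k2) == 0) {
    stop("a minimum degree is zero: heterogeneity ratio undefined", call. = FALSE)
  }
  (max(d$k2) / min(d$k2)) / (max(d$k1) / min(d$k1))
}

# Gumbel finite-size correction factor f(m, y).
gumbel_correction <- function(m, y) {
  lm <- log(m)
  1 - log(lm) / (4 * lm) - log(sqrt(2 * pi)) / (2 * lm) + y / (2 * lm)
}

#' Gumbel estimate of the extreme degree of a binomial ensemble
#'
#' For the maximum of many weakly-correlated degrees drawn from
#' `Binomial(m, p)`, extreme-value asymptotics give the quantile estimate
#' `p * m + sqrt(2 p q m log m) * f(m, y0)` with `q = 1 - p` and the
#' finite-size correction
#' `f(m, y) = 1 - log(log m)/(4 log m) - log(sqrt(2 pi))/(2 log m) + y/(2 log m)`.
#' By symmetry the minimum-degree estimate subtracts the same fluctuation
#' term. The default `y0 = -log(log 2)` makes the estimate the median of the
#' limiting Gumbel law (the median is used to approximate the expectation).
#' All logarithms are natural.
#'
#' @param m sample-space size (number of potential hyperedges per node).
#' @param p wiring probability.
#' @param y0 Gumbel quantile parameter.
#' @param side `"max"` or `"min"`.
#' @return the estimated extreme degree.
#' @export
gumbel_extreme_estimate <- function(m, p, y0 = -log(log(2)),
                                    side = c("max", "min")) {
  side <- match.arg(side)
  stopifnot(m >= 3)
  stop_if_not_prob(p, "p")
  if (p == 0 || p == 1) return(p * m)  # degenerate: no fluctuation
  q <- 1 - p
  fluct <- sqrt(2 * p * q * m * log(m)) * gumbel_correction(m, y0)
  p * m + if (side == "max") fluct else -fluct
}

#' Theoretical and empirical heterogeneity indexes
#'
#' The heterogeneity index at order `l` is
#' `h(l) = (E[kmax(l)] - E[mean k(l)]) / E[mean k(l)]`, with
#' `E[mean k1] = p n` and `E[mean k2] = p N`, `N = (n - 1)(n - 2) / 2` being
#' the per-node triple capacity. `heterogeneity_indexes()` evaluates the
#' Gumbel estimates ([gumbel_extreme_estimate()]); for large `n` the ratio
#' obeys `h1 / h2 > sqrt(n) / 2`, which is why triadic coupling in random
#' hypergraphs is much more degree-homogeneous (hence more synchronizable)
#' than pairwise coupling. `empirical_hetero_indexes()` measures the same
#' indexes on an ensemble of random hypergraphs, averaging maxima and means
#' across realizations before forming each index.
#'
#' @param n number of nodes (>= 3).
#' @param p wiring probability.
#' @param y0 Gumbel quantile parameter.
#' @return a list with `h1`, `h2`, `ratio = h1 / h2`, and the bound
#'   `sqrt(n) / 2`.
#' @export
heterogeneity_indexes <- function(n, p, y0 = -log(log(2))) {
  stopifnot(n >= 3)
  stop_if_not_prob(p, "p")
  if (p == 0) stop("p = 0: mean degree is zero, indexes undefined", call. = FALSE)
  N <- (n - 1) * (n - 2) / 2
  h1 <- (gumbel_extreme_estimate(n, p, y0) - p * n) / (p * n)
  h2 <- (gumbel_extreme_estimate(N, p, y0) - p * N) / (p * N)
  # large-n form of the ratio (finite-size corrections f dropped); this is
  # the quantity the sqrt(n)/2 bound refers to
  ratio_asym <- sqrt((log(n) / n) / (log(N) / N))
  list(h1 = h1, h2 = h2, ratio = h1 / h2, ratio_asymptotic = ratio_asym,
       bound = sqrt(n) / 2)
}

#' @rdname heterogeneity_indexes
#' @param p_tri triadic wiring probability of the sampled random hypergraphs.
#' @param n_samples ensemble size.
#' @param seed master seed.
#' @export
empirical_hetero_indexes <- function(n, p, p_tri = p, n_samples = 100,
                                     seed = NULL) {
  stopifnot(n >= 3, n_samples >= 1)
  stop_if_not_prob(p, "p")
  stop_if_not_prob(p_tri, "p_tri")
  seeds <- if (is.null(seed)) rep(list(NULL), n_samples)
           else as.list(child_seeds(seed, n_samples))
  max1 <- mean1 <- max2 <- mean2 <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    deg <- with_optional_seed(seeds[[s]], sample_rh_degrees(n, p, p_tri))
    max1[s] <- max(deg$k1); mean1[s] <- mean(deg$k1)
    max2[s] <- max(deg$k2); mean2[s] <- mean(deg$k2)
  }
  h1 <- (mean(max1) - mean(mean1)) / mean(mean1)
  h2 <- (mean(max2) - mean(mean2)) / mean(mean2)
  list(h1 = h1, h2 = h2, ratio = h1 / h2, bound = sqrt(n) / 2,
       n_samples = n_samples)
}

# Degree vectors of a random hypergraph without materializing the hyperedge
# matrices. Uses the same sampling scheme (and hence, under the same seed, the
# same RNG stream and hyperedge set) as random_hypergraph().
sample_rh_degrees <- function(n, p, p_tri) {
  er <- sample_rank_subset(choose2(n), p)
  tr <- sample_rank_subset(choose3(n), p_tri)
  k1 <- pair_incidence_counts_cpp(er, n)
  k2 <- triple_incidence_counts_cpp(tr, n)
  list(k1 = k1, k2 = k2)
}

#' Degrees of a flag complex without materializing its 2-simplices
#'
#' For a pairwise graph `g`, the flag complex has `k1 = degree(g)` and
#' `k2 = ` the number of 3-cliques each node belongs to. This degrees-only
#' fast path makes large heterogeneity ensembles cheap; it agrees exactly
#' with `degrees(flag_complex(g))`.
#'
#' @param g an igraph undirected simple graph.
#' @return a `degree_summary` (see [degrees()]).
#' @export
flag_degrees <- function(g) {
  stopifnot(igraph::is_igraph(g))
  k1 <- as.integer(igraph::degree(g))
  k2 <- as.integer(igraph::count_triangles(g))
  structure(list(k1 = k1, k2 = k2, mean_k1 = mean(k1), mean_k2 = mean(k2)),
            class = "degree_summary")
}

#' Cross-order degree correlation
#'
#' Pearson product-moment correlation across nodes between the first- and
#' second-order degree vectors, `DC = cor(k1, k2)`. Large and positive in
#' simplicial complexes (the inclusion condition ties triadic memberships to
#' pairwise neighborhoods), close to zero in random hypergraphs. Negative DC
#' lets the heterogeneity of the two orders compensate at intermediate
#' coupling mixtures, improving synchronization stability.
#'
#' @param x a [hypergraph()] or a `degree_summary` from [degrees()].
#' @return the correlation in `[-1, 1]`.
#' @export
cross_order_degree_correlation <- function(x) {
  d <- if (is_hypergraph(x)) degrees(x) else x
  stopifnot(inherits(d, "degree_summary"))
  if (stats::sd(d$k1) == 0 || stats::sd(d$k2) == 0) {
    stop("a degree vector is constant: correlation undefined", call. = FALSE)
  }
  stats::cor(d$k1, d$k2)
}

#' Exact median of the maximum of iid binomial draws
#'
#' Order-statistics oracle for the Gumbel estimate: the CDF of the maximum of
#' `n_draws` iid `Binomial(m, p)` variables is `F(k)^n_draws`, so the median
#' is the smallest `k` with `F(k) >= (1/2)^(1/n_draws)`.
#'
#' @param m binomial size.
#' @param p success probability.
#' @param n_draws number of iid draws.
#' @return integer median of the maximum.
#' @export
exact_max_binomial_median <- function(m, p, n_draws) {
  stopifnot(m >= 1, n_draws >= 1)
  stop_if_not_prob(p, "p")
  if (m > 1e7) stop("m too large for dense CDF evaluation; use gumbel_extreme_estimate()", call. = FALSE)
  stats::qbinom(0.5^(1 / n_draws), m, p)
}

#' Full heterogeneity report of a hypergraph
#'
#' Convenience bundle of the statistics used throughout the degree-based
#' analysis of synchronization stability.
#'
#' @param H a [hypergraph()].
#' @param y0 Gumbel quantile parameter.
#' @return an object of class `"hetero_report"`: list with `r`
#'   (heterogeneity ratio, `NA` if a minimum degree is zero), `dc`
#'   (cross-order degree correlation, `NA` if a degree vector is constant),
#'   per-node triple capacity `N`, and `y0`.
#' @export
hetero_report <- function(H, y0 = -log(log(2))) {
  stopifnot(is_hypergraph(H))
  d <- degrees(H)
  r <- tryCatch(heterogeneity_ratio(d), error = function(e) NA_real_)
  dc <- tryCatch(cross_order_degree_correlation(d), error = function(e) NA_real_)
  structure(list(r = r, dc = dc, N = (H$n - 1) * (H$n - 2) / 2, y0 = y0,
                 mean_k1 = d$mean_k1, mean_k2 = d$mean_k2),
            class = "hetero_report")
}

#' @export
print.hetero_report <- function(x, ...) {
  cat(sprintf("heterogeneity report: r = %s, DC = %s, <k1> = %.3f, <k2> = %.3f\n",
              format(x$r, digits = 4), format(x$dc, digits = 4),
              x$mean_k1, x$mean_k2))
  invisible(x)
}
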