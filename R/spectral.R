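# Multiorder Laplacian stability machinery.

#' Order-1 and order-2 Laplacians
#'
#' `laplacian_first()` is the ordinary graph Laplacian
#' `L1 = diag(k1) - A`. `laplacian_second()` generalizes it to triadic
#' interactions: `L2 = diag(k2) - A2 / 2`, where `A2` counts, for each node
#' pair, the 2-simplices containing both nodes. Both are symmetric with zero
#' row sums and positive semidefinite.
#'
#' @param H a [hypergraph()].
#' @return an `n x n` numeric matrix.
#' @export
laplacian_first <- function(H) {
  d <- degrees(H)
  diag(d$k1, H$n) - pairwise_adjacency(H)
}

#' @rdname laplacian_first
#' @export
laplacian_second <- function(H) {
  d <- degrees(H)
  diag(d$k2, H$n) - second_order_adjacency(H) / 2
}

#' Multiorder Laplacian at mixing parameter alpha
#'
#' The linearization of the triadic Kuramoto model around full synchrony is
#' governed by
#' `Lmul = (1 - alpha) / mean(k1) * L1 + alpha / mean(k2) * L2`,
#' with each order's coupling normalized by its mean degree so that the total
#' coupling budget is conserved as `alpha` moves from purely pairwise (0) to
#' purely triadic (1). The diagonal of `Lmul` is the multiorder degree vector.
#'
#' @param H a [hypergraph()].
#' @param alpha mixing parameter in `[0, 1]`.
#' @return an `n x n` numeric matrix.
#' @export
multiorder_laplacian <- function(H, alpha) {
  stopifnot(is_hypergraph(H))
  stop_if_not_prob(alpha, "alpha")
  d <- degrees(H)
  L <- matrix(0, H$n, H$n)
  if (alpha < 1) {
    if (d$mean_k1 == 0) stop("mean first-order degree is zero: normalization undefined for alpha < 1", call. = FALSE)
    L <- L + (1 - alpha) / d$mean_k1 * laplacian_first(H)
  }
  if (alpha > 0) {
    if (d$mean_k2 == 0) stop("mean second-order degree is zero: normalization undefined for alpha > 0", call. = FALSE)
    L <- L + alpha / d$mean_k2 * laplacian_second(H)
  }
  L
}

#' Second Lyapunov exponent of the synchronized state
#'
#' Computes the full spectrum of the multiorder Laplacian with a dense
#' symmetric eigensolver, sorts it ascending `0 = Lambda_n <= ... <= Lambda_1`,
#' and returns `lambda2 = -Lambda_{n-1}` (minus the second-smallest
#' eigenvalue). `lambda2 < 0` means full synchronization is linearly stable,
#' with larger magnitudes indicating faster recovery from perturbations;
#' `lambda2 = 0` signals a disconnected coupling support. Eigenvalues below
#' `tol` times the spectral radius are treated as exact zeros.
#'
#' @param H a [hypergraph()].
#' @param alpha mixing parameter in `[0, 1]`.
#' @param tol relative zero tolerance for eigenvalues.
#' @return an object of class `"spectral_result"`: list with `alpha`,
#'   `eigenvalues` (ascending) and `lambda2`.
#' @export
lambda2 <- function(H, alpha, tol = 1e-9) {
  L <- multiorder_laplacian(H, alpha)
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  scale <- max(ev[length(ev)], .Machine$double.eps)
  ev[abs(ev) < tol * scale] <- 0
  structure(list(alpha = alpha, eigenvalues = ev, lambda2 = -ev[2]),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("spectral result: n = %d, alpha = %.3f, lambda2 = %.6f (%s)\n",
              length(x$eigenvalues), x$alpha, x$lambda2,
              if (x$lambda2 < 0) "stable sync" else "marginal / disconnected"))
  invisible(x)
}

#' Degree-based bounds on the extreme Laplacian eigenvalues
#'
#' For a Laplacian with (multiorder) degrees `k`, the second-smallest and
#' largest eigenvalues are bracketed by the extreme degrees:
#' `2 kmin - n + 2 <= |lambda2| <= n / (n - 1) * kmin` and
#' `n / (n - 1) * kmax <= |lambda_n| <= 2 kmax`.
#' The upper bound on `|lambda2|` explains the non-monotone (U-shaped)
#' stability curves of random hypergraphs: the mixing `alpha` that maximizes
#' the minimum multiorder degree optimizes synchronization.
#'
#' @param H a [hypergraph()].
#' @param alpha mixing parameter in `[0, 1]`.
#' @return a list with the four bounds, the measured `|lambda2|` and
#'   `|lambda_n|`, and logical flags for each inequality.
#' @export
degree_bounds <- function(H, alpha) {
  d <- degrees(H, alpha = alpha)
  sr <- lambda2(H, alpha)
  n <- H$n
  ev <- sr$eigenvalues
  abs_l2 <- ev[2]
  abs_ln <- ev[n]
  kmin <- min(d$kmul)
  kmax <- max(d$kmul)
  out <- list(
    alpha = alpha,
    kmin = kmin, kmax = kmax,
    lambda2_lower = 2 * kmin - n + 2,
    lambda2_upper = n / (n - 1) * kmin,
    lambdan_lower = n / (n - 1) * kmax,
    lambdan_upper = 2 * kmax,
    abs_lambda2 = abs_l2,
    abs_lambdan = abs_ln
  )
  out$holds <- c(
    lambda2_lower = out$lambda2_lower <= abs_l2,
    lambda2_upper = abs_l2 <= out$lambda2_upper,
    lambdan_lower = out$lambdan_lower <= abs_ln,
    lambdan_upper = abs_ln <= out$lambdan_upper
  )
  out
}

#' Ensemble sweep of lambda2 over the coupling-budget parameter
#'
#' Generates `n_realizations` structures from `spec` (child seeds spawned from
#' `seed` by [child_seeds()]) and computes `lambda2` at every `alpha` in the
#' grid, together with the degree-bound prediction
#' `-n / (n - 1) * min(kmul)`. Disconnected supports enter as `lambda2 = 0`
#' (with a warning). Means and sample standard deviations are reported per
#' alpha.
#'
#' @param spec a [generator_spec()].
#' @param alphas grid of mixing parameters in `[0, 1]`.
#' @param n_realizations ensemble size (>= 1).
#' @param seed master seed.
#' @return an object of class `"sweep_result"`: a data.frame with columns
#'   `alpha`, `lambda2_mean`, `lambda2_sd`, `bound_mean`, `n_realizations`,
#'   carrying the generator spec and master seed as attributes.
#' @export
alpha_sweep <- function(spec, alphas = seq(0, 1, length.out = 21),
                        n_realizations = 10, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"), n_realizations >= 1,
            all(alphas >= 0 & alphas <= 1))
  seeds <- if (is.null(seed)) rep(list(NULL), n_realizations)
           else as.list(child_seeds(seed, n_realizations))
  vals <- matrix(NA_real_, n_realizations, length(alphas))
  bnds <- matrix(NA_real_, n_realizations, length(alphas))
  n_disc <- 0L
  for (r in seq_len(n_realizations)) {
    H <- generate(spec, seed = seeds[[r]])
    d <- degrees(H)
    for (a in seq_along(alphas)) {
      sr <- lambda2(H, alphas[a])
      vals[r, a] <- sr$lambda2
      if (sr$lambda2 == 0) n_disc <- n_disc + 1L
      km <- multiorder_degree(d, alphas[a])
      bnds[r, a] <- -H$n / (H$n - 1) * min(km)
    }
  }
  if (n_disc > 0) {
    warning(sprintf("%d realization/alpha combinations had a disconnected support (lambda2 = 0 retained)", n_disc))
  }
  out <- data.frame(
    alpha = alphas,
    lambda2_mean = colMeans(vals),
    lambda2_sd = if (n_realizations > 1) apply(vals, 2, stats::sd) else 0,
    bound_mean = colMeans(bnds),
    n_realizations = n_realizations
  )
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  attr(out, "lambda2_matrix") <- vals
  class(out) <- c("sweep_result", "data.frame")
  out
}
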