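#' Construct a hypergraph with pairwise and triadic hyperedges
#'
#' The central container of the package: `n` nodes (1-based integer IDs
#' `1..n`), a set of unordered pairs (1-hyperedges, "edges") and a set of
#' unordered triples (2-hyperedges, "triangles" / 2-simplices). All
#' interactions are unweighted and undirected. Triangles need *not* have their
#' three boundary edges present; the simplicial-complex special case can be
#' checked with [is_simplicial_complex()] or enforced with
#' [simplicial_closure()].
#'
#' Hyperedges are stored canonically: node IDs ascending within each row, rows
#' in lexicographic order, no duplicates. The symmetric triadic adjacency
#' tensor is never materialized; the triangle set is the source of truth and
#' derived quantities (generalized degrees, second-order adjacency) apply the
#' tensor's factor-of-two normalization that avoids double counting a
#' 2-simplex.
#'
#' @param n number of nodes (>= 1).
#' @param edges two-column integer matrix (or NULL) of node pairs.
#' @param triangles three-column integer matrix (or NULL) of node triples.
#' @return an object of class `"hypergraph"` with elements `n`, `edges`,
#'   `triangles`.
#' @examples
#' H <- hypergraph(3, edges = rbind(c(1, 2), c(1, 3), c(2, 3)),
#'                 triangles = rbind(c(1, 2, 3)))
#' degrees(H)$k1
#' @export
hypergraph <- function(n, edges = NULL, triangles = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  edges <- canonicalize_hyperedges(edges, n, 2L)
  triangles <- canonicalize_hyperedges(triangles, n, 3L)
  structure(list(n = n, edges = edges, triangles = triangles),
            class = "hypergraph")
}

canonicalize_hyperedges <- function(x, n, width) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0)) {
    return(matrix(integer(0), ncol = width))
  }
  if (is.vector(x) && length(x) == width) x <- matrix(x, ncol = width)
  if (!is.matrix(x) || ncol(x) != width) {
    stop(sprintf("hyperedges of order %d must form a %d-column matrix",
                 width - 1L, width), call. = FALSE)
  }
  storage.mode(x) <- "integer"
  if (anyNA(x) || any(x < 1L) || any(x > n)) {
    stop("node IDs must lie in 1..n", call. = FALSE)
  }
  x <- sort_within_rows(x)
  if (any(x[, -1, drop = FALSE] == x[, -width, drop = FALSE])) {
    stop("degenerate hyperedge: repeated node within a hyperedge", call. = FALSE)
  }
  r <- if (width == 2L) rank_pairs(x) else rank_triples(x)
  if (anyDuplicated(r)) stop("duplicate hyperedges are not allowed", call. = FALSE)
  x[order(r), , drop = FALSE]
}

# Vectorized ascending sort within the rows of a 2- or 3-column matrix.
sort_within_rows <- function(x) {
  if (ncol(x) == 2) {
    cbind(pmin(x[, 1], x[, 2]), pmax(x[, 1], x[, 2]))
  } else {
    lo <- pmin(x[, 1], x[, 2], x[, 3])
    hi <- pmax(x[, 1], x[, 2], x[, 3])
    cbind(lo, x[, 1] + x[, 2] + x[, 3] - lo - hi, hi)
  }
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("hypergraph: %d nodes, %d edges, %d triangles (%s)\n",
              x$n, nrow(x$edges), nrow(x$triangles),
              if (is_simplicial_complex(x)) "simplicial complex" else "not simplicial"))
  invisible(x)
}

is_hypergraph <- function(x) inherits(x, "hypergraph")

#' Generalized degrees of a hypergraph
#'
#' First-order degree `k1[i]` counts edges containing node `i`; second-order
#' (generalized) degree `k2[i]` counts 2-simplices containing node `i`,
#' equivalently half the row-slice sum of the symmetric triadic tensor. With a
#' coupling-budget parameter `alpha`, the multiorder degree
#' `kmul = (1 - alpha) k1 / mean(k1) + alpha k2 / mean(k2)` is also returned;
#' it equals the diagonal of the multiorder Laplacian.
#'
#' @param H a [hypergraph()].
#' @param alpha optional mixing parameter in `[0, 1]` for the multiorder degree.
#' @return an object of class `"degree_summary"`: list with `k1`, `k2`,
#'   `mean_k1`, `mean_k2`, and (if `alpha` given) `alpha` and `kmul`.
#' @export
degrees <- function(H, alpha = NULL) {
  stopifnot(is_hypergraph(H))
  k1 <- tabulate(H$edges, nbins = H$n)
  k2 <- tabulate(H$triangles, nbins = H$n)
  out <- list(k1 = k1, k2 = k2, mean_k1 = mean(k1), mean_k2 = mean(k2))
  if (!is.null(alpha)) {
    out$alpha <- alpha
    out$kmul <- multiorder_degree(out, alpha)
  }
  class(out) <- "degree_summary"
  out
}

multiorder_degree <- function(d, alpha) {
  stop_if_not_prob(alpha, "alpha")
  km <- numeric(length(d$k1))
  if (alpha < 1) {
    if (d$mean_k1 == 0) stop("mean first-order degree is zero: multiorder normalization undefined for alpha < 1", call. = FALSE)
    km <- km + (1 - alpha) * d$k1 / d$mean_k1
  }
  if (alpha > 0) {
    if (d$mean_k2 == 0) stop("mean second-order degree is zero: multiorder normalization undefined for alpha > 0", call. = FALSE)
    km <- km + alpha * d$k2 / d$mean_k2
  }
  km
}

#' @export
print.degree_summary <- function(x, ...) {
  cat(sprintf("degree summary: n = %d, <k1> = %.3f, <k2> = %.3f\n",
              length(x$k1), x$mean_k1, x$mean_k2))
  if (!is.null(x$kmul)) {
    cat(sprintf("  multiorder degrees at alpha = %.3f: min %.4f, max %.4f\n",
                x$alpha, min(x$kmul), max(x$kmul)))
  }
  invisible(x)
}

#' Pairwise and second-order adjacency matrices
#'
#' `pairwise_adjacency()` returns the symmetric 0/1 matrix `A`.
#' `second_order_adjacency()` returns `A2` with `A2[i, j]` = number of
#' 2-simplices containing both `i` and `j` (the contraction of the symmetric
#' triadic tensor over its third index). Both have zero diagonal; row sums of
#' `A2` equal `2 * k2`.
#'
#' @param H a [hypergraph()].
#' @return an `n x n` numeric matrix.
#' @export
pairwise_adjacency <- function(H) {
  stopifnot(is_hypergraph(H))
  n <- H$n
  A <- matrix(0, n, n)
  if (nrow(H$edges) > 0) {
    A[H$edges] <- 1
    A[H$edges[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' @rdname pairwise_adjacency
#' @export
second_order_adjacency <- function(H) {
  stopifnot(is_hypergraph(H))
  n <- H$n
  t <- H$triangles
  if (nrow(t) == 0) return(matrix(0, n, n))
  i <- c(t[, 1], t[, 1], t[, 2])
  j <- c(t[, 2], t[, 3], t[, 3])
  lin <- c((j - 1) * n + i, (i - 1) * n + j)  # both orientations
  counts <- tabulate(lin, nbins = n * n)
  matrix(counts, n, n)
}

#' Test the simplicial-complex inclusion condition
#'
#' A hypergraph is a simplicial complex (here, up to order two) when every
#' triangle's three boundary pairs are present as edges.
#'
#' @param H a [hypergraph()].
#' @return TRUE/FALSE.
#' @export
is_simplicial_complex <- function(H) {
  stopifnot(is_hypergraph(H))
  if (nrow(H$triangles) == 0) return(TRUE)
  all(boundary_pair_ranks(H$triangles) %in% rank_pairs(H$edges))
}

boundary_pair_ranks <- function(t) {
  rank_pairs(rbind(t[, c(1, 2), drop = FALSE],
                   t[, c(1, 3), drop = FALSE],
                   t[, c(2, 3), drop = FALSE]))
}

#' Close a hypergraph into a simplicial complex
#'
#' Adds the three boundary edges of every triangle; the triangle set is
#' unchanged. Idempotent; the result always satisfies
#' [is_simplicial_complex()].
#'
#' @param H a [hypergraph()].
#' @return a [hypergraph()].
#' @export
simplicial_closure <- function(H) {
  stopifnot(is_hypergraph(H))
  if (nrow(H$triangles) == 0) return(H)
  r <- unique(c(rank_pairs(H$edges), boundary_pair_ranks(H$triangles)))
  hypergraph(H$n, edges = unrank_pairs(r, H$n), triangles = H$triangles)
}

#' Connectedness of the multiorder coupling support
#'
#' The multiorder Laplacian at mixing parameter `alpha` couples nodes through
#' the pairwise adjacency (weight `1 - alpha`) and the second-order adjacency
#' (weight `alpha`). Its second Lyapunov exponent is zero exactly when the
#' union support is disconnected. At `alpha = 0` only the pairwise support
#' counts; at `alpha = 1` only the triadic support; in between, their union.
#' Isolated nodes make the structure disconnected.
#'
#' @param H a [hypergraph()].
#' @param alpha mixing parameter in `[0, 1]`.
#' @return TRUE if the weighted support is connected.
#' @export
connected_support <- function(H, alpha) {
  stopifnot(is_hypergraph(H))
  stop_if_not_prob(alpha, "alpha")
  el <- matrix(integer(0), ncol = 2)
  if (alpha < 1) el <- rbind(el, H$edges)
  if (alpha > 0 && nrow(H$triangles) > 0) {
    t <- H$triangles
    el <- rbind(el, t[, c(1, 2), drop = FALSE], t[, c(1, 3), drop = FALSE],
                t[, c(2, 3), drop = FALSE])
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, H$n - igraph::vcount(g)))
  igraph::components(g)$no == 1
}
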