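# Synthetic higher-order structure generators and rewiring procedures.

#' Random hypergraph with independent hyperedge placement
#'
#' Every one of the `choose(n, 2)` node pairs is included as an edge
#' independently with probability `p`, and every one of the `choose(n, 3)`
#' node triples is included as a 2-simplex independently with probability
#' `p_tri`. No inclusion condition links the two orders.
#'
#' @param n number of nodes (>= 3).
#' @param p pairwise wiring probability.
#' @param p_tri triadic wiring probability.
#' @param seed optional integer seed (scoped; session RNG untouched).
#' @return a [hypergraph()].
#' @export
random_hypergraph <- function(n, p, p_tri, seed = NULL) {
  stopifnot(n >= 3)
  stop_if_not_prob(p, "p")
  stop_if_not_prob(p_tri, "p_tri")
  with_optional_seed(seed, {
    er <- sample_rank_subset(choose2(n), p)
    tr <- sample_rank_subset(choose3(n), p_tri)
    hypergraph(n,
               edges = if (length(er)) unrank_pairs(er, n) else NULL,
               triangles = if (length(tr)) unrank_triples(tr, n) else NULL)
  })
}

# Subset of 1..total where each element is kept independently with
# probability p, generated by scanning with geometric gaps (the spacing
# between successive successes of a Bernoulli(p) process is Geometric(p) + 1).
# Exact, O(total * p), and returns the ranks already sorted.
sample_rank_subset <- function(total, p) {
  if (p <= 0 || total == 0) return(double(0))
  if (p >= 1) return(seq_len(total))
  bernoulli_ranks_cpp(total, p)
}

#' Flag (clique) complex of a pairwise graph
#'
#' Attaches a 2-simplex to every 3-clique of `g`; the edge set is that of `g`.
#' The result is always a simplicial complex.
#'
#' @param g an igraph undirected simple graph.
#' @return a [hypergraph()].
#' @export
flag_complex <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  tri <- as.integer(igraph::triangles(g))
  tri <- if (length(tri)) matrix(tri, ncol = 3, byrow = TRUE) else NULL
  hypergraph(n, edges = if (nrow(el)) el else NULL, triangles = tri)
}

#' Probabilistic triangle filling
#'
#' Like [flag_complex()], but each 3-clique of `g` receives a 2-simplex
#' independently with probability `p_fill`; `p_fill = 1` reduces to the flag
#' complex, `p_fill = 0` yields a purely pairwise structure.
#'
#' @param g an igraph undirected simple graph.
#' @param p_fill filling probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return a [hypergraph()].
#' @export
fill_triangles <- function(g, p_fill, seed = NULL) {
  stop_if_not_prob(p_fill, "p_fill")
  H <- flag_complex(g)
  m <- nrow(H$triangles)
  if (m == 0 || p_fill >= 1) return(H)
  with_optional_seed(seed, {
    keep <- stats::runif(m) < p_fill
    hypergraph(H$n, edges = H$edges,
               triangles = if (any(keep)) H$triangles[keep, , drop = FALSE] else NULL)
  })
}

#' Hypergraph with a fixed connection budget
#'
#' Samples exactly `m_edges` pairs and `m_triangles` triples uniformly without
#' replacement, so structures of different families can be compared at equal
#' numbers of connections.
#'
#' @param n number of nodes.
#' @param m_edges number of edges (<= `choose(n, 2)`).
#' @param m_triangles number of triangles (<= `choose(n, 3)`).
#' @param seed optional integer seed.
#' @return a [hypergraph()].
#' @export
fixed_budget_hypergraph <- function(n, m_edges, m_triangles, seed = NULL) {
  stopifnot(n >= 3, m_edges >= 0, m_triangles >= 0)
  if (m_edges > choose2(n)) stop("edge budget exceeds choose(n, 2)", call. = FALSE)
  if (m_triangles > choose3(n)) stop("triangle budget exceeds choose(n, 3)", call. = FALSE)
  with_optional_seed(seed, {
    er <- if (m_edges > 0) sort(as.double(sample.int(as.integer(choose2(n)), m_edges))) else double(0)
    tr <- if (m_triangles > 0) sort(as.double(sample.int(as.integer(choose3(n)), m_triangles))) else double(0)
    hypergraph(n,
               edges = if (length(er)) unrank_pairs(er, n) else NULL,
               triangles = if (length(tr)) unrank_triples(tr, n) else NULL)
  })
}

#' Shuffle 2-simplices to random locations
#'
#' Each triangle is, independently with probability `p_s`, removed and
#' re-inserted at a triple chosen uniformly among the currently unoccupied
#' `choose(n, 3)` locations (rejection-resampled against occupancy, including
#' triangles already moved in this pass). Edges are untouched and the triangle
#' count is conserved exactly. With `p_s = 1` a simplicial complex loses its
#' inclusion structure and approaches a random hypergraph with the same
#' number of hyperedges at each order.
#'
#' @param H a [hypergraph()].
#' @param p_s shuffling probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return a [hypergraph()].
#' @export
shuffle_simplices <- function(H, p_s, seed = NULL) {
  stopifnot(is_hypergraph(H))
  stop_if_not_prob(p_s, "p_s")
  m <- nrow(H$triangles)
  if (m == 0 || p_s == 0) return(H)
  total <- choose3(H$n)
  if (m >= total) stop("all candidate triples are occupied: relocation impossible", call. = FALSE)
  with_optional_seed(seed, {
    ranks <- rank_triples(H$triangles)
    occ <- new.env(hash = TRUE, size = 2L * m)
    keys <- sprintf("%.0f", ranks)
    for (k in keys) assign(k, TRUE, envir = occ)
    move <- which(stats::runif(m) < p_s)
    for (idx in move) {
      rm(list = keys[idx], envir = occ)
      repeat {
        cand <- floor(stats::runif(1) * total) + 1
        ck <- sprintf("%.0f", cand)
        if (!exists(ck, envir = occ, inherits = FALSE)) {
          assign(ck, TRUE, envir = occ)
          ranks[idx] <- cand
          keys[idx] <- ck
          break
        }
      }
    }
    hypergraph(H$n, edges = H$edges, triangles = unrank_triples(sort(ranks), H$n))
  })
}

#' Degree-preserving hyperedge membership swaps
#'
#' Lowers the cross-order degree correlation while leaving both degree
#' sequences (as multisets) intact. Nodes are ranked by second-order degree
#' `k2` (ties broken by ascending node ID); the m-th lowest is paired with the
#' m-th highest for `m = 1..n_pairs`, and each pair `(i, j)` is applied as the
#' transposition `i <-> j` to the triangle set only. Consequently `k1` is
#' unchanged per node, the multiset of `k2` is unchanged with `k2[i]` and
#' `k2[j]` exchanged, and the second-order Laplacian spectrum is invariant
#' (the order-2 layer is merely relabeled), so the stability endpoints at
#' `alpha = 0` and `alpha = 1` are unaffected.
#'
#' @param H a [hypergraph()].
#' @param n_pairs number of (lowest, highest) node pairs to swap;
#'   `2 * n_pairs <= n`.
#' @return a [hypergraph()].
#' @export
swap_memberships <- function(H, n_pairs) {
  stopifnot(is_hypergraph(H))
  if (!is.numeric(n_pairs) || length(n_pairs) != 1 || n_pairs < 0 || n_pairs != floor(n_pairs)) {
    stop("`n_pairs` must be a single non-negative integer", call. = FALSE)
  }
  if (2 * n_pairs > H$n) stop("overlapping pairs: 2 * n_pairs exceeds n", call. = FALSE)
  if (n_pairs == 0 || nrow(H$triangles) == 0) return(H)
  k2 <- tabulate(H$triangles, nbins = H$n)
  ord <- order(k2, seq_len(H$n))  # ascending k2, ties by node ID
  perm <- seq_len(H$n)
  for (m in seq_len(n_pairs)) {
    i <- ord[m]
    j <- ord[H$n + 1 - m]
    perm[c(i, j)] <- c(j, i)
  }
  tri <- matrix(perm[H$triangles], ncol = 3)
  hypergraph(H$n, edges = H$edges, triangles = tri)
}

#' Pairwise substrate graphs
#'
#' Standard random-graph families used as pairwise substrates for flag
#' complexes: Erdős–Rényi `G(n, p)`, the small-world rewiring model on a ring
#' lattice, and linear preferential attachment.
#'
#' @param n number of nodes.
#' @param p wiring probability (ER).
#' @param seed optional integer seed.
#' @return an igraph undirected simple graph.
#' @export
er_graph <- function(n, p, seed = NULL) {
  stop_if_not_prob(p, "p")
  with_optional_seed(seed, igraph::sample_gnp(n, p))
}

#' @rdname er_graph
#' @param nei neighborhood radius of the ring lattice (each node starts with
#'   `2 * nei` neighbors).
#' @param p_rewire rewiring probability.
#' @export
smallworld_graph <- function(n, nei, p_rewire, seed = NULL) {
  stop_if_not_prob(p_rewire, "p_rewire")
  with_optional_seed(seed, igraph::simplify(igraph::sample_smallworld(1, n, nei, p_rewire)))
}

#' @rdname er_graph
#' @param m edges attached by each incoming node (preferential attachment).
#' @export
scalefree_graph <- function(n, m, seed = NULL) {
  stopifnot(m >= 1)
  with_optional_seed(seed, igraph::sample_pa(n, m = m, directed = FALSE))
}

#' Declarative generator specification
#'
#' Bundles a structure family and its parameters so that ensemble routines
#' ([alpha_sweep()], [run_experiment()]) can regenerate structures from a
#' master seed. Families: `random_hypergraph`, `flag_complex_er`,
#' `flag_complex_smallworld`, `flag_complex_scalefree`, `filled_triangles`
#' (ER substrate filled with probability `p_fill`), `fixed_budget`.
#'
#' @param family family name (see above).
#' @param n node count.
#' @param p pairwise wiring probability (ER-based families).
#' @param p_tri triadic wiring probability (`random_hypergraph`).
#' @param p_fill triangle-filling probability (`filled_triangles`).
#' @param nei,p_rewire small-world parameters.
#' @param m_attach preferential-attachment edge count.
#' @param m_edges,m_triangles fixed-budget hyperedge counts.
#' @return an object of class `"generator_spec"`.
#' @export
generator_spec <- function(family = c("random_hypergraph", "flag_complex_er",
                                      "flag_complex_smallworld",
                                      "flag_complex_scalefree",
                                      "filled_triangles", "fixed_budget"),
                           n, p = NULL, p_tri = NULL, p_fill = NULL,
                           nei = NULL, p_rewire = NULL, m_attach = NULL,
                           m_edges = NULL, m_triangles = NULL) {
  family <- match.arg(family)
  stopifnot(n >= 3)
  spec <- list(family = family, n = as.integer(n), p = p, p_tri = p_tri,
               p_fill = p_fill, nei = nei, p_rewire = p_rewire,
               m_attach = m_attach, m_edges = m_edges, m_triangles = m_triangles)
  structure(spec[!vapply(spec, is.null, logical(1))], class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf("generator spec: %s (%s)\n", x$family,
              paste(names(pars), unlist(pars), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Generate a hypergraph from a specification
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer seed.
#' @return a [hypergraph()].
#' @export
generate <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  switch(spec$family,
    random_hypergraph = random_hypergraph(spec$n, spec$p, spec$p_tri, seed = seed),
    flag_complex_er = flag_complex(er_graph(spec$n, spec$p, seed = seed)),
    flag_complex_smallworld = flag_complex(
      smallworld_graph(spec$n, spec$nei, spec$p_rewire, seed = seed)),
    flag_complex_scalefree = flag_complex(
      scalefree_graph(spec$n, spec$m_attach, seed = seed)),
    filled_triangles = with_optional_seed(seed, {
      fill_triangles(er_graph(spec$n, spec$p), spec$p_fill)
    }),
    fixed_budget = fixed_budget_hypergraph(spec$n, spec$m_edges,
                                           spec$m_triangles, seed = seed)
  )
}

#' Read and write generator specifications as flat key-value files
#'
#' One `key = value` pair per line; `#` starts a comment.
#'
#' @param spec a [generator_spec()].
#' @param path file path.
#' @return `read_generator_spec()` returns a [generator_spec()];
#'   `write_generator_spec()` returns `path` invisibly.
#' @export
write_generator_spec <- function(spec, path) {
  stopifnot(inherits(spec, "generator_spec"))
  vals <- vapply(spec, function(v) format(v, scientific = FALSE), character(1))
  writeLines(paste(names(spec), vals, sep = " = "), path)
  invisible(path)
}

#' @rdname write_generator_spec
#' @export
read_generator_spec <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop(sprintf("malformed spec line(s): %s",
                             paste(which(bad), collapse = ", ")), call. = FALSE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  args <- as.list(vals)
  names(args) <- keys
  num <- setdiff(keys, "family")
  args[num] <- lapply(args[num], as.numeric)
  do.call(generator_spec, args)
}
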