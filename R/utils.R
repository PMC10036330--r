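# Internal combinatorics and seeding helpers.
#
# Pairs and triples of node IDs are ranked in the colexicographic (combinadic)
# order so that hyperedge sets can be manipulated as flat double vectors: with
# 0-based node values x1 < x2 < x3,
#   rank(pair)   = C(x2,2) + x1          in 0..C(n,2)-1
#   rank(triple) = C(x3,3) + C(x2,2) + x1 in 0..C(n,3)-1
# Ranks are kept as doubles (exact up to 2^53, far beyond any n used here).

choose2 <- function(x) x * (x - 1) / 2
choose3 <- function(x) x * (x - 1) * (x - 2) / 6

# pairs: m x 2 matrix of 1-based node IDs, sorted within rows
rank_pairs <- function(pairs) {
  x1 <- pairs[, 1] - 1
  x2 <- pairs[, 2] - 1
  choose2(x2) + x1 + 1
}

unrank_pairs <- function(r, n) {
  r0 <- r - 1
  tab <- choose2(0:(n - 1))
  x2 <- findInterval(r0, tab) - 1
  x1 <- r0 - choose2(x2)
  cbind(x1, x2) + 1L
}

rank_triples <- function(triples) {
  x1 <- triples[, 1] - 1
  x2 <- triples[, 2] - 1
  x3 <- triples[, 3] - 1
  choose3(x3) + choose2(x2) + x1 + 1
}

unrank_triples <- function(r, n) {
  r0 <- r - 1
  tab3 <- choose3(0:(n - 1))
  x3 <- findInterval(r0, tab3) - 1
  r1 <- r0 - choose3(x3)
  tab2 <- choose2(0:(n - 1))
  x2 <- findInterval(r1, tab2) - 1
  x1 <- r1 - choose2(x2)
  cbind(x1, x2, x3) + 1L
}

# Evaluate `expr` under a scoped seed; seed = NULL uses the session RNG as-is.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Derive per-realization child seeds from a master seed
#'
#' Ensemble routines spawn one child seed per realization with the fixed rule
#' `(master + 1000003 * i) mod (2^31 - 1)`, so ensembles are reproducible and
#' individual realizations can be regenerated in isolation.
#'
#' @param master integer master seed.
#' @param k number of child seeds.
#' @return integer vector of length `k`.
#' @export
child_seeds <- function(master, k) {
  stopifnot(k >= 0)
  as.integer((as.double(master) %% 2147483647 + 1000003 * seq_len(k)) %% 2147483647)
}

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
}
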