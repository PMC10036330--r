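# Shared fixtures and independent brute-force oracles.

# K3 with its single filled triangle: the exactly solvable toy structure
# (multiorder eigenvalues {0, 3/2, 3/2} at every alpha).
k3_tri <- function() {
  hypergraph(3, edges = rbind(c(1, 2), c(1, 3), c(2, 3)),
             triangles = rbind(c(1, 2, 3)))
}

# K4 with triangles {1,2,3} and {1,2,4}: k2 = (2, 2, 1, 1).
k4_two_tri <- function() {
  hypergraph(4, edges = t(combn(4, 2)), triangles = rbind(c(1, 2, 3), c(1, 2, 4)))
}

# Dense symmetric triadic tensor B from the triangle set (small n only).
dense_triadic_tensor <- function(H) {
  B <- array(0, dim = rep(H$n, 3))
  t <- H$triangles
  for (r in seq_len(nrow(t))) {
    for (perm in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
      B[t[r, perm[1]], t[r, perm[2]], t[r, perm[3]]] <- 1
    }
  }
  B
}

# Second-order adjacency by brute-force tensor contraction A2_ij = sum_k B_ijk.
oracle_second_order_adjacency <- function(H) {
  B <- dense_triadic_tensor(H)
  apply(B, c(1, 2), sum)
}

# Triadic Kuramoto velocities from the ordered-sum form of the model:
# omega + (1-a)/<k1> sum_j A_ij sin(th_j - th_i)
#       + a/<k2> sum_{j,k} (1/2) B_ijk (1/2) sin(th_j + th_k - 2 th_i).
oracle_kuramoto_rhs <- function(theta, H, alpha, omega = 0) {
  d <- degrees(H)
  A <- pairwise_adjacency(H)
  B <- dense_triadic_tensor(H)
  n <- H$n
  v <- rep(omega, n)
  for (i in seq_len(n)) {
    if (alpha < 1) {
      v[i] <- v[i] + (1 - alpha) / d$mean_k1 *
        sum(A[i, ] * sin(theta - theta[i]))
    }
    if (alpha > 0 && d$mean_k2 > 0) {
      acc <- 0
      for (j in seq_len(n)) {
        for (k in seq_len(n)) {
          acc <- acc + 0.25 * B[i, j, k] * sin(theta[j] + theta[k] - 2 * theta[i])
        }
      }
      v[i] <- v[i] + alpha / d$mean_k2 * acc
    }
  }
  v
}

# Brute-force 3-clique count by looping over all node triples.
oracle_triangle_count <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  cnt <- 0L
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (A[i, j] && A[i, k] && A[j, k]) cnt <- cnt + 1L
  }
  cnt
}
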