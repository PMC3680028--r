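# Independent reference implementations used as oracles. They work on plain
# dense adjacency matrices so they share no code path with the package.

random_network <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# one synchronous PE update on dense matrices: for every adjacent pair (u,v),
# multiply the "no support" terms over all vertices l adjacent to both
naive_pe_step <- function(A, P) {
  n <- nrow(A)
  newP <- matrix(0, n, n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u >= v || A[u, v] == 0) next
      prod_term <- 1
      for (l in seq_len(n)) {
        if (A[u, l] == 1 && A[v, l] == 1) {
          prod_term <- prod_term * (1 - P[u, l] * P[v, l])
        }
      }
      newP[u, v] <- newP[v, u] <- 1 - prod_term
    }
  }
  newP
}

# number of triangles through vertex v = edges among its neighbors
naive_triangles_through <- function(A, v) {
  nb <- which(A[v, ] == 1)
  if (length(nb) < 2) return(0L)
  sum(A[nb, nb]) / 2
}

# iterated degree-adjusted common-neighbor weighting by direct summation
naive_adjstcd_iterate <- function(A, k) {
  n <- nrow(A)
  W <- A
  for (s in seq_len(k)) {
    inc <- rowSums(W)
    w_avg <- sum(W) / n
    newW <- matrix(0, n, n)
    for (u in seq_len(n)) {
      for (v in seq_len(n)) {
        if (u >= v || A[u, v] == 0) next
        num <- 0
        for (x in seq_len(n)) {
          if (A[x, u] == 1 && A[x, v] == 1) num <- num + W[x, u] + W[x, v]
        }
        den <- max(inc[u], w_avg) + max(inc[v], w_avg)
        if (den > 0) newW[u, v] <- newW[v, u] <- num / den
      }
    }
    W <- newW
  }
  W
}

# maximum-total-weight one-to-one assignment by exhaustive branching
brute_mmr <- function(M) {
  n <- nrow(M)
  m <- ncol(M)
  best <- 0
  recurse <- function(i, used, acc) {
    if (i > n) {
      best <<- max(best, acc)
      return(invisible())
    }
    recurse(i + 1, used, acc)
    for (j in seq_len(m)) {
      if (!used[j] && M[i, j] > 0) {
        used[j] <- TRUE
        recurse(i + 1, used, acc + M[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, logical(m), 0)
  best / n
}

random_catalog <- function(n_complexes, universe, seed) {
  set.seed(seed)
  complex_set(lapply(seq_len(n_complexes), function(i) {
    sample(universe, sample(3:6, 1))
  }))
}
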