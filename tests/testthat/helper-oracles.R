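# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately naive and share no code with the package internals.

# Betweenness by geodesic counting from adjacency-matrix powers:
# sigma[s, t] = (A^d)[s, t] where d = dist(s, t) (walks of minimal length
# are exactly the shortest paths), and a path s..t passes through v iff
# dist(s, v) + dist(v, t) = dist(s, t), contributing
# sigma[s, v] * sigma[v, t] / sigma[s, t].
bf_betweenness <- function(A, normalized = TRUE) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- diag(n)
  P <- diag(n)
  for (d in seq_len(n)) {
    P <- P %*% A
    newly <- is.infinite(D) & P > 0
    D[newly] <- d
    S[newly] <- P[newly]
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (is.infinite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t])
          bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  if (normalized) {
    bc <- if (n >= 3) bc * 2 / ((n - 1) * (n - 2)) else rep(0, n)
  }
  bc
}

# highest k-core of a graph by naive iterated peeling on the adjacency
# matrix; returns the maximum k and the density of that core
peel_highest_core <- function(A) {
  stopifnot(isSymmetric(A))
  best_k <- 0; best_density <- 0
  for (k in seq_len(nrow(A))) {
    keep <- seq_len(nrow(A))
    M <- A
    repeat {
      deg <- rowSums(M)
      drop <- which(deg < k)
      if (length(drop) == 0 || length(keep) == 0) break
      keep <- keep[-drop]
      M <- M[-drop, -drop, drop = FALSE]
    }
    if (length(keep) > 0) {
      nn <- length(keep)
      mm <- sum(M) / 2
      best_k <- k
      best_density <- if (nn < 2) 0 else 2 * mm / (nn * (nn - 1))
    } else break
  }
  list(k = best_k, density = best_density)
}

# hypergeometric upper tail by exhaustive enumeration of all draws
bf_hyper_tail <- function(overlap, term_size, module_size, universe_size) {
  universe <- seq_len(universe_size)
  term <- seq_len(term_size)
  draws <- utils::combn(universe, module_size)
  hits <- apply(draws, 2, function(d) sum(d %in% term) >= overlap)
  mean(hits)
}

# Holm correction straight from its definition
holm_direct <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[ord[i]]))
    adj[ord[i]] <- running
  }
  adj
}

# Cohen's kappa from the explicit 2x2 contingency table
kappa_2x2 <- function(x, y) {
  tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (identical(as.logical(x), as.logical(y))) return(1)
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

# Erdos-Renyi style random test graph as a ppiscreen network
random_test_graph <- function(n, p = 0.3, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(labels, 2))
  keep <- stats::runif(nrow(pairs)) < p
  ppi_network(edges = pairs[keep, , drop = FALSE], nodes = labels)
}

adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

path_graph <- function(labels) {
  n <- length(labels)
  ppi_network(edges = cbind(labels[-n], labels[-1]))
}

complete_graph <- function(labels) {
  ppi_network(edges = t(utils::combn(labels, 2)))
}

star_graph <- function(center, leaves) {
  ppi_network(edges = cbind(center, leaves))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
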