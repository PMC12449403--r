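# Independent metric oracles used to validate the package's from-scratch
# implementations.  Distances come from Floyd-Warshall on a dense matrix;
# shortest-path counts from adjacency-matrix powers (walks of minimal
# length are exactly the shortest paths); the eigenvector oracle is the
# projection of the all-ones vector onto the dominant eigenspace of a
# dense symmetric eigendecomposition.  None of these share code with the
# BFS/Brandes/power-iteration implementations they check.

# unweighted undirected 0/1 adjacency matrix
adj_matrix <- function(graph) {
  ids <- graph$nodes$provider_id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  pr <- undirected_projection(graph)
  if (nrow(pr$edges)) {
    i <- match(pr$edges$a, ids); j <- match(pr$edges$b, ids)
    A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
  }
  A
}

# weighted undirected adjacency
wadj_matrix <- function(graph) {
  ids <- graph$nodes$provider_id
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  pr <- undirected_projection(graph)
  if (nrow(pr$edges)) {
    i <- match(pr$edges$a, ids); j <- match(pr$edges$b, ids)
    W[cbind(i, j)] <- pr$edges$weight; W[cbind(j, i)] <- pr$edges$weight
  }
  W
}

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  if (n) diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

oracle_betweenness <- function(graph) {
  A <- adj_matrix(graph)
  n <- nrow(A)
  bc <- stats::setNames(numeric(n), rownames(A))
  if (n < 3L) return(bc)
  D <- oracle_distances(A)
  pow <- vector("list", n + 1L)
  pow[[1L]] <- diag(n)
  for (k in seq_len(n)) pow[[k + 1L]] <- pow[[k]] %*% A
  sig <- function(s, t) pow[[D[s, t] + 1L]][s, t]
  for (s in 1:(n - 1L)) for (t in (s + 1L):n) {
    if (!is.finite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        bc[v] <- bc[v] + sig(s, v) * sig(v, t) / sig(s, t)
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(graph) {
  A <- adj_matrix(graph)
  n <- nrow(A)
  out <- stats::setNames(numeric(n), rownames(A))
  if (n < 2L) return(out)
  D <- oracle_distances(A)
  for (v in seq_len(n)) {
    d <- D[v, -v]
    r <- sum(is.finite(d))
    if (r > 0L) out[v] <- (r / (n - 1)) * (r / sum(d[is.finite(d)]))
  }
  out
}

oracle_eigenvector <- function(graph) {
  W <- wadj_matrix(graph)
  n <- nrow(W)
  out <- stats::setNames(numeric(n), rownames(W))
  if (n == 0L || all(W == 0)) return(out)
  eg <- eigen(W, symmetric = TRUE)
  lam1 <- eg$values[1L]
  dom <- which(eg$values > lam1 - 1e-9 * max(1, abs(lam1)))
  V <- eg$vectors[, dom, drop = FALSE]
  v <- as.numeric(V %*% crossprod(V, rep(1, n)))
  stats::setNames(v / max(v), rownames(W))
}

oracle_summary <- function(graph) {
  A <- adj_matrix(graph)
  n <- nrow(A)
  m <- nrow(graph$edges)
  D <- oracle_distances(A)
  ecc <- if (n) vapply(seq_len(n), function(v) {
    d <- D[v, ]
    max(0, d[is.finite(d)])
  }, numeric(1)) else numeric(0)
  deg <- rowSums(A)
  triples <- sum(deg * (deg - 1) / 2)
  tri <- sum(diag(A %*% A %*% A)) / 6
  list(density = if (n >= 2L) m / (n * (n - 1)) else 0,
       diameter = if (n) max(ecc) else 0,
       radius = if (n) min(ecc) else 0,
       clustering = if (triples > 0) 3 * tri / triples else 0,
       eccentricities = stats::setNames(ecc, rownames(A)))
}
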