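# Network measures, implemented from first principles.
#
# Conventions (all declared, since fragmented small graphs make them
# consequential): distance-based measures (betweenness, closeness,
# eccentricity/diameter/radius) run on the UNWEIGHTED UNDIRECTED
# projection by default; eigenvector centrality runs on the WEIGHTED
# undirected projection; density counts DIRECTED edges.  Distances exist
# within components only -- unreachable pairs contribute nothing, and no
# infinite placeholder is ever used.

# integer adjacency lists; undirected collapses (a,b)/(b,a)
graph_adjacency <- function(graph, directed = FALSE) {
  ids <- graph$nodes$provider_id
  n <- length(ids)
  if (!directed) {
    proj <- undirected_projection(graph)
    a <- match(proj$edges$a, ids)
    b <- match(proj$edges$b, ids)
    adj <- vector("list", n)
    for (i in seq_len(n)) adj[[i]] <- integer(0)
    for (k in seq_along(a)) {
      adj[[a[k]]] <- c(adj[[a[k]]], b[k])
      adj[[b[k]]] <- c(adj[[b[k]]], a[k])
    }
    list(n = n, ids = ids, adj = lapply(adj, sort),
         w_a = a, w_b = b, w = proj$edges$weight)
  } else {
    fr <- match(graph$edges$from, ids)
    to <- match(graph$edges$to, ids)
    adj <- vector("list", n)
    for (i in seq_len(n)) adj[[i]] <- integer(0)
    for (k in seq_along(fr)) adj[[fr[k]]] <- c(adj[[fr[k]]], to[k])
    list(n = n, ids = ids, adj = lapply(adj, sort))
  }
}

bfs_distances <- function(adj, s, n) {
  dist <- rep(-1L, n)
  dist[s] <- 0L
  queue <- integer(n)
  queue[1L] <- s
  qh <- 1L; qt <- 1L
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        qt <- qt + 1L
        queue[qt] <- w
      }
    }
  }
  dist
}

#' Normalized betweenness centrality
#'
#' Brandes-style pair-dependency accumulation on the unweighted
#' projection.  The raw score of `v` sums, over pairs `s != t != v`, the
#' fraction of shortest `s`-`t` paths passing through `v`; normalization
#' divides by `(n-1)(n-2)/2` (undirected; `(n-1)(n-2)` ordered pairs when
#' `directed = TRUE`).  Graphs with fewer than three nodes score all
#' zeros; unreachable pairs contribute nothing.
#'
#' @param graph A [provider_graph()].
#' @param directed Use directed shortest paths (default `FALSE`, the
#'   package convention).
#' @return Named numeric vector in `[0, 1]` over nodes.
#' @export
betweenness_centrality <- function(graph, directed = FALSE) {
  g <- graph_adjacency(graph, directed = directed)
  n <- g$n
  bc <- numeric(n)
  if (n >= 3L) {
    for (s in seq_len(n)) {
      dist <- rep(-1L, n); dist[s] <- 0L
      sigma <- numeric(n); sigma[s] <- 1
      preds <- vector("list", n)
      queue <- integer(n); queue[1L] <- s
      qh <- 1L; qt <- 1L
      while (qh <= qt) {
        v <- queue[qh]; qh <- qh + 1L
        for (w in g$adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            qt <- qt + 1L
            queue[qt] <- w
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      delta <- numeric(n)
      for (idx in rev(seq_len(qt))) {
        v <- queue[idx]
        coef <- (1 + delta[v]) / sigma[v]
        for (p in preds[[v]]) delta[p] <- delta[p] + sigma[p] * coef
        if (v != s) bc[v] <- bc[v] + delta[v]
      }
    }
    # undirected accumulation visits each unordered pair from both ends,
    # so dividing the doubled raw score by (n-1)(n-2) equals halving and
    # then normalizing by (n-1)(n-2)/2; directed raw scores normalize by
    # the (n-1)(n-2) ordered pairs directly
    bc <- bc / ((n - 1) * (n - 2))
  }
  stats::setNames(bc, g$ids)
}

#' Normalized closeness centrality
#'
#' Reachable-set-adjusted (Wasserman-Faust) closeness on the unweighted
#' projection: with `R(v)` the set of nodes reachable from `v` (excluding
#' `v`), `C(v) = (|R|/(n-1)) * (|R| / sum of distances to R)`.  Isolated
#' nodes and singleton graphs score 0.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(graph, directed = FALSE) {
  g <- graph_adjacency(graph, directed = directed)
  n <- g$n
  out <- numeric(n)
  if (n >= 2L) {
    for (v in seq_len(n)) {
      dist <- bfs_distances(g$adj, v, n)
      reach <- dist > 0L
      r <- sum(reach)
      if (r > 0L)
        out[v] <- (r / (n - 1)) * (r / sum(dist[reach]))
    }
  }
  stats::setNames(out, g$ids)
}

#' Normalized eigenvector centrality
#'
#' Leading eigenvector of the weighted undirected projection's adjacency
#' matrix, computed by shifted power iteration (`x <- x + A x`, which
#' preserves the leading eigenvector while guaranteeing convergence on
#' bipartite components) from the all-ones vector, max-normalized each
#' step; convergence when the successive max-norm difference drops below
#' `tol` (default 1e-10), capped at `max_iter` iterations.  The result is
#' scaled so its maximum entry is 1; nodes in non-dominant components
#' carry the (near-zero) converged values; an edgeless graph scores all
#' zeros.
#'
#' @param graph A [provider_graph()].
#' @param tol Convergence tolerance on successive iterates.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return Named numeric vector in `[0, 1]` with maximum 1 (or all 0).
#' @export
eigenvector_centrality <- function(graph, tol = 1e-10, max_iter = 10000L) {
  g <- graph_adjacency(graph, directed = FALSE)
  n <- g$n
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  if (length(g$w) == 0L) return(stats::setNames(numeric(n), g$ids))
  A <- Matrix::sparseMatrix(i = c(g$w_a, g$w_b), j = c(g$w_b, g$w_a),
                            x = rep(as.numeric(g$w), 2L),
                            dims = c(n, n))
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    y <- x + as.numeric(A %*% x)
    y <- y / max(y)
    if (max(abs(y - x)) < tol) {
      return(stats::setNames(y / max(y), g$ids))
    }
    x <- y
  }
  stop(sprintf(
    "eigenvector centrality did not converge in %d iterations (residual %.3e)",
    max_iter, max(abs(y - x))), call. = FALSE)
}

#' Network topology summary
#'
#' Density over directed edges (`m / (n (n-1))`); eccentricity of a node
#' is its maximum distance to the nodes reachable from it on the
#' undirected projection (per component); diameter and radius are the
#' maximum and minimum eccentricity; the global clustering coefficient is
#' the transitivity `3 * triangles / connected triples` (0 when there are
#' no triples).  A single-node graph reports density, diameter, radius
#' and clustering all 0.
#'
#' @param graph A [provider_graph()].
#' @param clustering `"transitivity"` (default) or `"average_local"`
#'   (mean local clustering, isolated and degree-1 nodes counted as 0).
#' @return List of class `"network_summary"` with fields `network_id`,
#'   `n_nodes`, `n_edges`, `density`, `diameter`, `radius`, `clustering`,
#'   `eccentricities` (named integer vector).
#' @export
network_summary <- function(graph,
                            clustering = c("transitivity",
                                           "average_local")) {
  clustering <- match.arg(clustering)
  g <- graph_adjacency(graph, directed = FALSE)
  n <- g$n
  m <- nrow(graph$edges)
  density <- if (n >= 2L) m / (n * (n - 1)) else 0
  ecc <- integer(n)
  for (v in seq_len(n)) {
    dist <- bfs_distances(g$adj, v, n)
    ecc[v] <- max(0L, dist)
  }
  deg <- lengths(g$adj)
  n_tri2 <- 0        # sum over edges of |N(a) inter N(b)| = 3 * triangles
  if (length(g$w_a)) {
    for (k in seq_along(g$w_a))
      n_tri2 <- n_tri2 +
        length(intersect(g$adj[[g$w_a[k]]], g$adj[[g$w_b[k]]]))
  }
  triples <- sum(deg * (deg - 1) / 2)
  cc <- if (clustering == "transitivity") {
    if (triples > 0) n_tri2 / triples else 0
  } else {
    if (n == 0L) 0 else {
      local <- vapply(seq_len(n), function(v) {
        if (deg[v] < 2L) return(0)
        nb <- g$adj[[v]]
        links <- 0L
        for (j in seq_along(nb))
          links <- links + sum(g$adj[[nb[j]]] %in% nb[-seq_len(j)])
        links / (deg[v] * (deg[v] - 1) / 2)
      }, numeric(1))
      mean(local)
    }
  }
  structure(list(network_id = graph$network_id,
                 n_nodes = n, n_edges = m,
                 density = density,
                 diameter = if (n) max(ecc) else 0L,
                 radius = if (n) min(ecc) else 0L,
                 clustering = cc,
                 eccentricities = stats::setNames(ecc, g$ids)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<network_summary '%s'> %d nodes, %d edges, density %.4f,\n",
    "  diameter %d, radius %d, clustering %.4f\n"),
    x$network_id, x$n_nodes, x$n_edges, x$density, x$diameter, x$radius,
    x$clustering))
  invisible(x)
}

#' Node degrees and the degree-frequency table
#'
#' Degree counts distinct in-neighbours plus distinct out-neighbours
#' (edge weights ignored; a mutual pair contributes 2 to each endpoint).
#'
#' @param graph A [provider_graph()].
#' @return For [node_degrees()], a named integer vector; for
#'   [degree_frequency()], a data.frame `degree`, `n_nodes` whose counts
#'   sum to the node count.
#' @export
node_degrees <- function(graph) {
  ids <- graph$nodes$provider_id
  indeg <- table(factor(graph$edges$to, levels = ids))
  outdeg <- table(factor(graph$edges$from, levels = ids))
  stats::setNames(as.integer(indeg) + as.integer(outdeg), ids)
}

#' @rdname node_degrees
#' @export
degree_frequency <- function(graph) {
  deg <- node_degrees(graph)
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)), n_nodes = as.integer(tab))
}

#' Per-node centrality table for a network
#'
#' One row per node with degree and the three normalized centralities,
#' tagged with the network id and the node's role.
#'
#' @param graph A [provider_graph()].
#' @return data.frame with columns `network_id`, `provider_id`, `role`,
#'   `degree`, `betweenness`, `closeness`, `eigenvector`.
#' @export
centrality_table <- function(graph) {
  ids <- graph$nodes$provider_id
  data.frame(network_id = rep(graph$network_id, length(ids)),
             provider_id = ids,
             role = graph$nodes$role,
             degree = as.integer(node_degrees(graph)[ids]),
             betweenness = as.numeric(betweenness_centrality(graph)[ids]),
             closeness = as.numeric(closeness_centrality(graph)[ids]),
             eigenvector = as.numeric(eigenvector_centrality(graph)[ids]),
             stringsAsFactors = FALSE)
}
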