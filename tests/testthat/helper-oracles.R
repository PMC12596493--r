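# Brute-force graph oracles, independent of igraph: adjacency-matrix BFS
# for distances and shortest-path counts, exhaustive subset enumeration for
# maximal cliques. Intended for graphs of at most ~12 nodes.

# random simple undirected graph as a 0/1 adjacency matrix
random_adjacency <- function(n, p = 0.35) {
  adj <- matrix(0L, n, n)
  upper <- which(upper.tri(adj))
  adj[upper] <- as.integer(stats::runif(length(upper)) < p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  dimnames(adj) <- list(code_pool(n), code_pool(n))
  adj
}

adjacency_to_network <- function(adj) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  make_network(rownames(adj)[idx[, 1]], colnames(adj)[idx[, 2]],
               nodes = rownames(adj))
}

# BFS from s: distances and number of shortest paths to every node
bf_bfs <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n); nsp <- rep(0, n)
  dist[s] <- 0; nsp[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) nsp[w] <- nsp[w] + nsp[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, nsp = nsp)
}

bf_distances <- function(adj) {
  n <- nrow(adj)
  t(vapply(seq_len(n), function(s) bf_bfs(adj, s)$dist, numeric(n)))
}

bf_degree <- function(adj) rowSums(adj)

# within-component closeness scaled by (reachable)/(n-1)
bf_closeness <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  vapply(seq_len(n), function(v) {
    dv <- d[v, -v]; dv <- dv[is.finite(dv)]
    if (length(dv) == 0) return(0)
    (length(dv) / sum(dv)) * (length(dv) / (n - 1))
  }, numeric(1))
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / 2 / choose(k, 2)
  }, numeric(1))
}

# pair-dependency betweenness over connected (s, t) pairs only
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  nsp <- t(vapply(seq_len(n), function(s) bf_bfs(adj, s)$nsp, numeric(n)))
  bc <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    if (!is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        bc[v] <- bc[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
      }
    }
  }
  bc
}

# exhaustive maximal-clique enumeration; MCC(v) = sum (|C| - 1)!
bf_mcc <- function(adj) {
  n <- nrow(adj)
  is_clique <- function(S) {
    if (length(S) <= 1) return(TRUE)
    all(adj[S, S][upper.tri(diag(length(S)))] == 1)
  }
  mcc <- rep(0, n)
  for (mask in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) == 0 || !is_clique(S)) next
    extendable <- any(vapply(setdiff(seq_len(n), S), function(w) {
      all(adj[w, S] == 1)
    }, logical(1)))
    if (!extendable) mcc[S] <- mcc[S] + factorial(length(S) - 1)
  }
  mcc
}
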