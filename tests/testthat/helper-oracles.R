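# Independent brute-force oracles, deliberately written with naive
# algorithms so they share no code path with the package implementations.

# textbook Pearson correlation, written out longhand
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2)) * sqrt(sum((b - mb)^2))
  num / den
}

# exhaustive max over an explicit permutation loop
oracle_max_rot <- function(a, b, rots) {
  best <- -Inf
  for (p in rots) {
    r <- oracle_pearson(a[p], b)
    if (r > best) best <- r
  }
  best
}

# adjacency matrix of a seeded Erdos-Renyi graph
random_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) a[i, j] <- a[j, i] <- 1L
    }
  }
  a
}

# triangle-counting local clustering
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) links <- links + adj[nb[a], nb[b]]
    }
    2 * links / (k * (k - 1))
  })
}

# Floyd-Warshall all-pairs distances
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1L] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# betweenness by explicit shortest-path counting: sigma via dynamic
# programming over the BFS level structure, accumulated pair by pair
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  # number of shortest paths between every pair
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  ord <- order(as.vector(d))
  for (idx in ord) {
    i <- (idx - 1) %% n + 1
    j <- (idx - 1) %/% n + 1
    if (i == j || !is.finite(d[i, j])) next
    if (d[i, j] == 1) {
      sigma[i, j] <- 1
    } else {
      pred <- which(adj[, j] == 1L & d[i, ] == d[i, j] - 1)
      sigma[i, j] <- sum(sigma[i, pred])
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bc
}

# small all-positive random volume whose cubes all pass the mask rule
toy_volume <- function(dim3 = c(9, 9, 9), seed = 1) {
  set.seed(seed)
  gm_volume(array(stats::runif(prod(dim3), 0.1, 1), dim = dim3))
}

adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(if (inherits(g, "gm_graph"))
    g$graph else g))
}
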