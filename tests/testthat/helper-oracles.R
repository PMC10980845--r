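# Independent brute-force oracles for the graph metrics, kept deliberately
# naive (explicit loops, BFS by hand) so they share no code path with the
# package implementations.

# BFS shortest-path lengths from node s; Inf for unreachable.
bf_bfs <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in which(adj[v, ] != 0)) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

bf_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  total <- 0
  for (i in seq_len(n)) {
    d <- bf_bfs(adj, i)
    for (j in seq_len(n)) {
      if (j != i && is.finite(d[j])) total <- total + 1 / d[j]
    }
  }
  total / (n * (n - 1))
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) { vals[i] <- 0; next }
    vals[i] <- bf_global_efficiency(adj[nb, nb, drop = FALSE])
  }
  mean(vals)
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) { vals[i] <- 0; next }
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && adj[nb[a], nb[b]] != 0) links <- links + 1
    }
    vals[i] <- 2 * links / (k * (k - 1))
  }
  vals
}

bf_participation <- function(adj, modules) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(adj[i, ])
    if (ki == 0) { vals[i] <- 0; next }
    acc <- 0
    for (m in unique(modules)) {
      kis <- sum(adj[i, modules == m])
      acc <- acc + (kis / ki)^2
    }
    vals[i] <- 1 - acc
  }
  vals
}

bf_wmz <- function(adj, modules) {
  n <- nrow(adj)
  wd <- numeric(n)
  for (i in seq_len(n)) wd[i] <- sum(adj[i, modules == modules[i]])
  z <- numeric(n)
  for (m in unique(modules)) {
    idx <- which(modules == m)
    mu <- mean(wd[idx])
    sdev <- sqrt(mean((wd[idx] - mu)^2))
    z[idx] <- if (sdev == 0) 0 else (wd[idx] - mu) / sdev
  }
  z
}

# Newman-Girvan modularity with resolution, evaluated from the definition.
bf_modularity <- function(adj, modules, gamma = 1) {
  m2 <- sum(adj)           # 2m for binary symmetric adjacency
  if (m2 == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (modules[i] == modules[j])
      q <- q + adj[i, j] - gamma * deg[i] * deg[j] / m2
  }
  q / m2
}

# Symmetric 0/1 adjacency from a seeded Erdos-Renyi draw.
rand_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# All 0/1 graphs on n nodes (n small!), as a list of adjacency matrices.
all_graphs <- function(n) {
  npairs <- n * (n - 1) / 2
  lapply(0:(2^npairs - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(npairs)]
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- bits
    a + t(a)
  })
}

# Block-diagonal planted-clique adjacency (cliques of the given sizes,
# optionally with single bridge edges chaining them into a ring).
planted_cliques <- function(sizes, bridges = FALSE) {
  n <- sum(sizes)
  a <- matrix(0L, n, n)
  start <- 1
  bounds <- list()
  for (s in sizes) {
    idx <- start:(start + s - 1)
    a[idx, idx] <- 1L
    bounds[[length(bounds) + 1]] <- idx
    start <- start + s
  }
  diag(a) <- 0L
  if (bridges) {
    k <- length(bounds)
    for (i in seq_len(k)) {
      j <- if (i == k) 1 else i + 1
      a[bounds[[i]][1], bounds[[j]][1]] <- 1L
      a[bounds[[j]][1], bounds[[i]][1]] <- 1L
    }
  }
  a
}

planted_labels <- function(sizes) rep(seq_along(sizes), sizes)
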