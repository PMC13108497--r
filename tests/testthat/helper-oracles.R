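# Independent oracles and small fixture builders. Everything here is coded
# from first principles, on purpose *not* reusing the package's internals,
# so implementation-vs-oracle comparisons stay dual-route.

# ---- graphs ---------------------------------------------------------------

# decode a Prufer sequence (length n - 2, values in 1..n) to tree edges
prufer_to_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  k <- 0L
  for (s in seq) {
    leaf <- which.max(degree == 1L)  # smallest degree-1 node
    k <- k + 1L
    edges[k, ] <- c(leaf, s)
    degree[leaf] <- 0L
    degree[s] <- degree[s] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

# brute-force maximum spanning tree weight of a complete graph, by
# enumerating all n^(n-2) labelled trees (Cayley) via Prufer sequences
brute_force_mst_weight <- function(W) {
  n <- nrow(W)
  stopifnot(n >= 3, n <= 6)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_to_edges(seqs[r, ], n)
    w <- sum(W[e])
    if (w > best) best <- w
  }
  best
}

# random labelled tree adjacency via a random Prufer sequence
random_tree_adjacency <- function(n) {
  adj <- matrix(0L, n, n)
  if (n == 2) {
    adj[1, 2] <- adj[2, 1] <- 1L
    return(adj)
  }
  e <- prufer_to_edges(sample.int(n, n - 2L, replace = TRUE), n)
  adj[e] <- 1L
  adj[e[, 2:1]] <- 1L
  adj
}

# simple reachability check (breadth-first, self-contained)
oracle_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[1] <- TRUE
  queue <- 1L
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    nb <- which(adj[i, ] != 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# random connected Erdos-Renyi graph (binary, symmetric)
random_connected_graph <- function(n, p = 0.3, max_tries = 200) {
  for (t in seq_len(max_tries)) {
    adj <- matrix(0L, n, n)
    ut <- which(upper.tri(adj))
    on <- ut[stats::runif(length(ut)) < p]
    adj[on] <- 1L
    adj <- adj + t(adj)
    if (oracle_connected(adj)) return(adj)
  }
  stop("could not draw a connected graph")
}

# all-pairs shortest path lengths by Floyd-Warshall
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj != 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# leading eigenvector by plain power iteration (shifted by +I), independent
# of the package's solver path
oracle_leading_eigenvector <- function(adj, iters = 20000, tol = 1e-13) {
  n <- nrow(adj)
  v <- stats::runif(n, 0.5, 1)
  v <- v / sqrt(sum(v^2))
  M <- adj + diag(1, n)
  for (i in seq_len(iters)) {
    v2 <- as.vector(M %*% v)
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < tol) break
    v <- v2
  }
  if (sum(v2) < 0) v2 <- -v2
  v2
}

# ---- statistics -----------------------------------------------------------

# OLS by explicit normal equations
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  yhat <- X1 %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(beta = as.vector(beta), r2 = r2)
}

# Levene W statistic evaluated directly from its definition
oracle_levene_w <- function(x, g) {
  g <- as.character(g)
  z <- abs(x - tapply(x, g, mean)[g])
  k <- length(unique(g))
  N <- length(x)
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ng <- tapply(z, g, length)
  num <- sum(ng * (zg - zbar)^2) / (k - 1)
  den <- sum((z - zg[g])^2) / (N - k)
  num / den
}

# ---- fixtures -------------------------------------------------------------

tiny_parcellation <- function(n = 10) {
  nets <- c(rep("frontoparietal", 3), rep("dorsal_attention", 2),
            rep("default_mode", n - 7), rep("subcortical", 2))
  parcellation(paste0("r", seq_len(n)), nets, name = "tiny")
}

# dense symmetric matrix with distinct positive off-diagonal weights
random_dense_weights <- function(n) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  W[ut] <- sample(seq_along(ut)) + stats::runif(length(ut), 0.1, 0.9)
  W + t(W)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "mplexnet", mustWork = TRUE)
}
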