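# Spanning-tree layers and the two-layer multiplex.
#
# Each layer is the binarized maximum spanning tree of one weighted
# connectivity matrix: links are ranked strongest-first and added greedily
# without forming cycles (Kruskal), yielding a connected acyclic backbone of
# N - 1 links. Using a tree per layer sidesteps density and strength
# differences across modalities and subjects. Layers are coupled into a
# multiplex by unit-weight interlayer links between replicas of the same
# region. Note: the neuroimaging literature often calls this backbone the
# "MST" even though, ranked strongest-first, it is a *maximum* spanning tree.

# -- internal: BFS distances over an adjacency list -------------------------
adjacency_list <- function(adj) {
  lapply(seq_len(nrow(adj)), function(i) which(adj[i, ] != 0))
}

bfs_distances <- function(nbrs, start) {
  n <- length(nbrs)
  dist <- rep.int(-1L, n)
  dist[start] <- 0L
  frontier <- start
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
    nxt <- nxt[dist[nxt] < 0L]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# frontier-expansion reachability without materializing an adjacency list
is_connected_adjacency <- function(adj) {
  n <- nrow(adj)
  if (n == 1) return(TRUE)
  visited <- logical(n)
  visited[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nb <- if (length(frontier) == 1L) adj[frontier, ] != 0
          else colSums(adj[frontier, , drop = FALSE] != 0) > 0
    new <- which(nb & !visited)
    visited[new] <- TRUE
    frontier <- new
  }
  all(visited)
}

#' Maximum spanning tree of a weighted connectivity matrix
#'
#' Kruskal's algorithm on links ranked in descending weight order: the
#' strongest links are added one by one, skipping any that would close a
#' cycle, until all N nodes are connected by N - 1 links. The result is the
#' spanning tree of maximal total weight, unique when weights are distinct.
#' Ties are broken deterministically by (weight descending, smaller node
#' index, larger node index).
#'
#' @param x A transformed [connectivity_matrix] or a nonnegative symmetric
#'   weight matrix; entries equal to 0 are absent links.
#' @param layer_name Name recorded on the layer (defaults to the modality
#'   when `x` is a connectivity matrix).
#' @return A `spanning_tree_layer`: list with `layer_name`, `n_nodes`,
#'   `edges` (an (N-1) x 2 matrix of node pairs, smaller index first) and
#'   binary `adjacency`.
#' @export
maximum_spanning_tree <- function(x, layer_name = NULL) {
  if (inherits(x, "connectivity_matrix")) {
    if (is.null(layer_name)) layer_name <- x$modality
    W <- x$weights
  } else {
    if (is.null(layer_name)) layer_name <- "layer"
    W <- as.matrix(x)
    stopifnot(nrow(W) == ncol(W))
  }
  n <- nrow(W)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  idx <- which(upper.tri(W) & W > 0)
  if (length(idx) == 0) {
    stop("no positive-weight links in matrix", call. = FALSE)
  }
  ii <- ((idx - 1L) %% n) + 1L
  jj <- ((idx - 1L) %/% n) + 1L
  w <- W[idx]
  ord <- order(-w, ii, jj)
  ii <- ii[ord]; jj <- jj[ord]; w <- w[ord]

  # union-find with path halving; `find` closes over `parent`
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  total <- 0
  k <- 0L
  for (e in seq_along(w)) {
    ri <- find(ii[e])
    rj <- find(jj[e])
    if (ri != rj) {
      parent[ri] <- rj
      k <- k + 1L
      edges[k, ] <- c(ii[e], jj[e])
      total <- total + w[e]
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) {
    roots <- vapply(seq_len(n), find, integer(1))
    comps <- split(seq_len(n), roots)
    reps <- vapply(comps, `[`, integer(1), 1L)
    stop(sprintf(paste0("positive-weight graph is disconnected: %d ",
                        "components (representative nodes: %s)"),
                 length(comps), paste(reps, collapse = ", ")),
         call. = FALSE)
  }
  adj <- matrix(0L, n, n)
  adj[edges] <- 1L
  adj[edges[, 2:1, drop = FALSE]] <- 1L
  structure(
    list(layer_name = layer_name, n_nodes = n, edges = edges,
         adjacency = adj, total_weight = total),
    class = "spanning_tree_layer"
  )
}

#' @export
print.spanning_tree_layer <- function(x, ...) {
  cat(sprintf("SpanningTreeLayer '%s': %d nodes, %d links, weight %.4f\n",
              x$layer_name, x$n_nodes, nrow(x$edges), x$total_weight))
  invisible(x)
}

#' Assemble spanning-tree layers into a multiplex network
#'
#' All layers must share the same node count and node ordering. Interlayer
#' links of weight 1 connect each node to its own replica in every other
#' layer; for the canonical two-layer (structural + functional) case this
#' gives exactly N interlayer links.
#'
#' @param layers List of [maximum_spanning_tree] layers (length >= 1).
#' @return A `multiplex_network`: list with `layers`, `n_nodes`,
#'   `n_layers`, `interlayer_weight = 1`.
#' @export
build_multiplex <- function(layers) {
  if (inherits(layers, "spanning_tree_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1)
  for (l in layers) stopifnot(inherits(l, "spanning_tree_layer"))
  ns <- vapply(layers, function(l) l$n_nodes, integer(1))
  if (length(unique(ns)) != 1) {
    bad <- which(ns != ns[1])[1]
    stop(sprintf("node count mismatch: layer '%s' has %d nodes, '%s' has %d",
                 layers[[1]]$layer_name, ns[1],
                 layers[[bad]]$layer_name, ns[bad]), call. = FALSE)
  }
  structure(
    list(layers = layers, n_nodes = ns[1], n_layers = length(layers),
         interlayer_weight = 1),
    class = "multiplex_network"
  )
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("MultiplexNetwork: L = %d layers (%s), N = %d nodes\n",
              x$n_layers,
              paste(vapply(x$layers, function(l) l$layer_name,
                           character(1)), collapse = ", "),
              x$n_nodes))
  invisible(x)
}

#' Supra-adjacency matrix of a multiplex
#'
#' The (L*N) x (L*N) block matrix: diagonal N x N blocks hold each layer's
#' adjacency, off-diagonal blocks are N x N identity matrices encoding the
#' unit interlayer links between same-node replicas. Supra-node
#' `(layer l, node i)` sits at row `(l - 1) * N + i`.
#'
#' @param mplex A [build_multiplex] result.
#' @return Symmetric binary `(L*N) x (L*N)` matrix.
#' @export
supra_adjacency <- function(mplex) {
  stopifnot(inherits(mplex, "multiplex_network"))
  n <- mplex$n_nodes
  L <- mplex$n_layers
  S <- matrix(0L, L * n, L * n)
  eye <- diag(1L, n)
  for (a in seq_len(L)) {
    ra <- ((a - 1L) * n + 1L):(a * n)
    S[ra, ra] <- mplex$layers[[a]]$adjacency
    if (a < L) for (b in (a + 1L):L) {
      rb <- ((b - 1L) * n + 1L):(b * n)
      S[ra, rb] <- eye
      S[rb, ra] <- eye
    }
  }
  S
}

#' Export a multiplex as an edge list
#'
#' Writes one row per link with 0-free 1-based node indices and layer
#' indices: intralayer rows have `layer_i == layer_j`, interlayer rows
#' connect replicas of the same node.
#'
#' @param mplex A [build_multiplex] result.
#' @param path Output TSV path (columns node_i, node_j, layer_i, layer_j).
#' @return `path`, invisibly.
#' @export
write_multiplex_edges <- function(mplex, path) {
  rows <- list()
  for (l in seq_len(mplex$n_layers)) {
    e <- mplex$layers[[l]]$edges
    rows[[length(rows) + 1L]] <-
      data.frame(node_i = e[, 1], node_j = e[, 2],
                 layer_i = l, layer_j = l)
  }
  if (mplex$n_layers > 1) {
    for (a in seq_len(mplex$n_layers - 1L)) for (b in (a + 1L):mplex$n_layers) {
      rows[[length(rows) + 1L]] <-
        data.frame(node_i = seq_len(mplex$n_nodes),
                   node_j = seq_len(mplex$n_nodes),
                   layer_i = a, layer_j = b)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
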