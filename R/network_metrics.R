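# Nodal network metrics: eigenvector centrality and eccentricity, on single
# layers and on the multiplex supra-adjacency, plus subnetwork summaries.

#' Eigenvector centrality of a connected graph
#'
#' The leading eigenvector of the adjacency matrix: a node's centrality is
#' proportional to the sum of its neighbours' centralities. For a connected
#' graph with nonnegative weights the Perron-Frobenius theorem guarantees a
#' simple leading eigenvalue with a strictly positive eigenvector, reported
#' here with unit Euclidean norm and positive sign.
#'
#' Below 500 nodes a dense symmetric eigendecomposition is used directly;
#' above that, power iteration (tolerance 1e-12 on the iterate difference,
#' on the diagonally shifted matrix A + I to speed convergence) with a
#' residual check. The contract is the eigenpair, not the algorithm.
#'
#' @param adj Symmetric nonnegative adjacency matrix of a connected graph
#'   (binary in the spanning-tree pipeline), or a `spanning_tree_layer`.
#' @param tol Residual tolerance for the verification `||Av - lambda v||`.
#' @return Numeric vector of per-node centralities (unit Euclidean norm),
#'   with the leading eigenvalue as attribute `"eigenvalue"`.
#' @export
eigenvector_centrality <- function(adj, tol = 1e-8) {
  if (inherits(adj, "spanning_tree_layer")) adj <- adj$adjacency
  n <- nrow(adj)
  stopifnot(n == ncol(adj))
  if (max(abs(adj - t(adj))) > 1e-10) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (!is_connected_adjacency(adj != 0)) {
    stop("graph is disconnected; eigenvector centrality undefined",
         call. = FALSE)
  }
  if (n < 500) {
    e <- eigen(adj, symmetric = TRUE)
    v <- e$vectors[, 1]
    lambda <- e$values[1]
  } else {
    v <- rep(1 / sqrt(n), n)
    shifted <- adj + diag(1, n)
    lambda <- NA_real_
    converged <- FALSE
    for (it in seq_len(100000L)) {
      v_new <- as.vector(shifted %*% v)
      v_new <- v_new / sqrt(sum(v_new^2))
      if (max(abs(v_new - v)) < 1e-12) {
        v <- v_new
        converged <- TRUE
        break
      }
      v <- v_new
    }
    if (!converged) {
      stop(sprintf("power iteration did not converge; last residual %.3g",
                   max(abs(as.vector(adj %*% v) -
                             sum(v * (adj %*% v)) * v))), call. = FALSE)
    }
    lambda <- sum(v * (adj %*% v))
  }
  if (sum(v) < 0) v <- -v
  resid <- max(abs(as.vector(adj %*% v) - lambda * v))
  if (resid > tol) {
    stop(sprintf("eigenpair residual %.3g exceeds tolerance %g",
                 resid, tol), call. = FALSE)
  }
  if (min(v) < -1e-9) {
    stop("leading eigenvector has negative entries; graph not irreducible?",
         call. = FALSE)
  }
  v <- pmax(v, 0)
  attr(v, "eigenvalue") <- lambda
  v
}

#' Multilayer nodal eigenvector centrality
#'
#' Eigenvector centrality of the (L*N) x (L*N) supra-adjacency matrix,
#' collapsed to one value per brain region as the arithmetic mean of the
#' region's L replica entries, renormalized to unit Euclidean norm so the
#' scale is comparable to single-layer centrality. For L identical layers
#' the supra eigenvector is the single-layer eigenvector repeated, so the
#' collapsed values then equal single-layer centrality exactly.
#'
#' @param mplex A [build_multiplex] result with connected layers.
#' @return Numeric vector of length N (per-region multilayer centrality);
#'   the full unit-norm supra eigenvector is attached as attribute
#'   `"supra_values"`.
#' @export
multilayer_nodal_ec <- function(mplex) {
  stopifnot(inherits(mplex, "multiplex_network"))
  S <- supra_adjacency(mplex)
  v <- eigenvector_centrality(S)
  m <- matrix(v, nrow = mplex$n_nodes, ncol = mplex$n_layers)
  out <- rowMeans(m)
  out <- out / sqrt(sum(out^2))
  attr(out, "supra_values") <- as.numeric(v)
  attr(out, "eigenvalue") <- attr(v, "eigenvalue")
  out
}

#' Eccentricity of every node in a connected graph
#'
#' A node's eccentricity is its longest shortest-path distance to any other
#' node; the mean over nodes is a global measure of how far information has
#' to travel. Computed by breadth-first search from every node (hop counts;
#' the spanning-tree pipeline only ever sees binary graphs).
#'
#' @param adj Symmetric binary adjacency matrix of a connected graph, a
#'   `spanning_tree_layer`, or a `multiplex_network` (in which case the
#'   supra-adjacency is used and the mean runs over all L*N supra-nodes).
#' @return List with `values` (integer per-node eccentricities), `mean`,
#'   `radius`, `diameter`, and for multiplex input `region_values` (mean of
#'   each region's replica eccentricities).
#' @export
eccentricity <- function(adj) {
  region_collapse <- NULL
  if (inherits(adj, "spanning_tree_layer")) adj <- adj$adjacency
  if (inherits(adj, "multiplex_network")) {
    region_collapse <- c(adj$n_nodes, adj$n_layers)
    adj <- supra_adjacency(adj)
  }
  n <- nrow(adj)
  nbrs <- adjacency_list(adj != 0)
  ecc <- integer(n)
  for (i in seq_len(n)) {
    d <- bfs_distances(nbrs, i)
    if (any(d < 0L)) {
      stop("graph is disconnected; eccentricity undefined", call. = FALSE)
    }
    ecc[i] <- max(d)
  }
  out <- list(values = ecc, mean = mean(ecc),
              radius = min(ecc), diameter = max(ecc))
  if (!is.null(region_collapse)) {
    out$region_values <- rowMeans(matrix(ecc, nrow = region_collapse[1],
                                         ncol = region_collapse[2]))
  }
  out
}

#' Mean of a nodal metric over one canonical subnetwork
#'
#' E.g. ECfpn: eigenvector centrality averaged over the regions labelled
#' `frontoparietal`, one value per subject.
#'
#' @param values Numeric per-region vector (length = regions in `parc`).
#' @param parc A [parcellation].
#' @param network One of [RSN_NETWORKS].
#' @return Scalar mean with attribute `"n_regions"` (member count).
#' @export
subnetwork_mean <- function(values, parc, network) {
  if (length(values) != n_regions(parc)) {
    stop("length(values) must equal the parcellation's region count",
         call. = FALSE)
  }
  members <- network_members(parc, network)
  if (length(members) == 0) {
    stop("no regions labelled '", network, "' in parcellation", call. = FALSE)
  }
  out <- mean(values[members])
  attr(out, "n_regions") <- length(members)
  out
}
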