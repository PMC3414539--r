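#' Social network container
#'
#' An undirected simple graph over `n_agents` agents, stored as a dense
#' logical adjacency matrix (the model targets desk-scale populations of a
#' few hundred agents, where dense storage is both fastest and simplest).
#' Self-loops are dropped and the matrix is symmetrised on construction.
#'
#' @param n_agents number of agents.
#' @param edges two-column integer matrix/data.frame of 1-based agent index
#'   pairs, or `NULL` for an empty graph.
#' @return object of class `social_network`: list with `n_agents` and the
#'   logical adjacency matrix `adj`.
#' @export
social_network <- function(n_agents, edges = NULL) {
  n_agents <- as.integer(n_agents)
  stopifnot(n_agents >= 1L)
  adj <- matrix(FALSE, n_agents, n_agents)
  if (!is.null(edges) && NROW(edges) > 0L) {
    e <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(e) <- "integer"
    if (any(e < 1L | e > n_agents)) {
      stop("edge endpoint out of range", call. = FALSE)
    }
    keep <- e[, 1L] != e[, 2L]
    e <- e[keep, , drop = FALSE]
    adj[e] <- TRUE
    adj[e[, 2:1, drop = FALSE]] <- TRUE
  }
  structure(list(n_agents = n_agents, adj = adj), class = "social_network")
}

sn_from_adj <- function(adj) {
  structure(list(n_agents = nrow(adj), adj = adj), class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("social_network: %d agents, %d edges\n",
              x$n_agents, n_edges(x)))
  invisible(x)
}

#' Number of edges
#' @param net a [social_network()].
#' @return integer edge count.
#' @export
n_edges <- function(net) sum(net$adj) / 2L

#' Edge list
#' @param net a [social_network()].
#' @return two-column integer matrix of 1-based pairs with `from < to`.
#' @export
edge_list <- function(net) {
  idx <- which(net$adj & upper.tri(net$adj), arr.ind = TRUE)
  colnames(idx) <- c("from", "to")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Neighbours of an agent
#' @param net a [social_network()].
#' @param i agent index.
#' @return integer vector of neighbour indices.
#' @export
neighbours_of <- function(net, i) which(net$adj[i, ])

#' Degrees
#' @param net a [social_network()].
#' @return integer vector of degrees.
#' @export
degrees <- function(net) as.integer(rowSums(net$adj))

#' Convert to an igraph object
#' @param net a [social_network()].
#' @return an `igraph` graph with `n_agents` vertices.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adj * 1L, mode = "undirected")
}

#' Geodesic distance matrix
#'
#' @param net a [social_network()].
#' @return numeric matrix of shortest-path lengths (`Inf` where disconnected).
#' @export
geodesic_distances <- function(net) {
  igraph::distances(as_igraph(net))
}

#' Shell of agents exactly n steps from agent i
#'
#' Shells `S_1(i), S_2(i), ...` partition the agents reachable from `i`
#' (excluding `i` itself).
#'
#' @param net a [social_network()].
#' @param i agent index.
#' @param n shell index `>= 1`.
#' @param dist optional precomputed distance matrix from
#'   [geodesic_distances()].
#' @return integer vector of agent indices at distance exactly `n`.
#' @export
shell <- function(net, i, n, dist = NULL) {
  if (is.null(dist)) {
    d <- igraph::distances(as_igraph(net), v = i)[1L, ]
  } else {
    d <- dist[i, ]
  }
  which(d == n)
}

#' Maximum shell index of an agent
#'
#' @inheritParams shell
#' @return the largest finite geodesic distance from `i` (0 for an isolated
#'   agent).
#' @export
max_shell_index <- function(net, i, dist = NULL) {
  if (is.null(dist)) {
    d <- igraph::distances(as_igraph(net), v = i)[1L, ]
  } else {
    d <- dist[i, ]
  }
  d <- d[is.finite(d)]
  if (length(d) == 0L) return(0L)
  as.integer(max(d))
}

# Normalised (or raw) shell-weight matrix used by the long-range term:
# W[i, j] = w_{d(i,j)} for finite d >= 2, else 0; rows divided by their sum
# when normalise is TRUE (rows with no shell beyond n = 1 stay all-zero).
long_range_weight_matrix <- function(net, shell_decay = 2, normalise = TRUE,
                                     coupling = 1) {
  d <- geodesic_distances(net)
  w <- matrix(0, net$n_agents, net$n_agents)
  sel <- is.finite(d) & d >= 2
  w[sel] <- shell_weight(d[sel], shell_decay)
  if (normalise) {
    rs <- rowSums(w)
    pos <- rs > 0
    w[pos, ] <- coupling * w[pos, , drop = FALSE] / rs[pos]
  }
  w
}
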