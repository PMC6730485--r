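# Binary brain-network metrics: degree, nodal/global/local efficiency,
# clustering, characteristic path length and small-worldness, plus the
# proportional-sparsity sweep. All networks are undirected, unweighted,
# without self-loops. Conventions for disconnected graphs: 1/Inf = 0 in the
# efficiency sums; the characteristic path length is computed on the largest
# connected component; clustering is 0 for nodes of degree < 2.

as_adjacency <- function(net) {
  a <- unclass(net)
  if (!is.matrix(a)) stop("adjacency matrix required", call. = FALSE)
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  if (max(abs(a - t(a))) > 0) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(a) != 0)) stop("self-loops are not allowed", call. = FALSE)
  if (!all(a %in% c(0, 1))) stop("adjacency must be binary", call. = FALSE)
  storage.mode(a) <- "double"
  a
}

#' Shortest path lengths of a binary network
#'
#' All-pairs shortest path lengths by breadth-first search from every node;
#' unreachable pairs are `Inf`, the diagonal is 0.
#'
#' @param net binary adjacency matrix (symmetric, zero diagonal), e.g. an
#'   `fnirs_fc` of kind `"binary"`.
#' @return N x N matrix of hop distances.
#' @export
shortest_path_lengths <- function(net) {
  a <- as_adjacency(net)
  n <- nrow(a)
  nbr <- lapply(seq_len(n), function(i) which(a[i, ] == 1))
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  dimnames(D) <- dimnames(net)
  D
}

#' Degree centrality
#'
#' Number of edges attached to each node: `D(i) = sum_j a(i, j)`.
#'
#' @inheritParams shortest_path_lengths
#' @return Numeric vector of node degrees.
#' @export
degree_centrality <- function(net) {
  rowSums(as_adjacency(net))
}

#' Nodal efficiency
#'
#' Capacity of each node to communicate with the rest of the network:
#' `E_nodal(i) = (1/(N-1)) sum_{j != i} 1 / D(i, j)`, with `1/Inf = 0` for
#' unreachable pairs.
#'
#' @inheritParams shortest_path_lengths
#' @return Numeric vector in \[0, 1\].
#' @export
nodal_efficiency <- function(net) {
  D <- shortest_path_lengths(net)
  n <- nrow(D)
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Clustering coefficient
#'
#' Local interconnectivity: `C(i) = 2 L_i / (Z_i (Z_i - 1))` where `Z_i` is
#' the number of neighbours of node i and `L_i` the number of edges among
#' them; `C(i) = 0` when `Z_i < 2`.
#'
#' @inheritParams shortest_path_lengths
#' @return Numeric vector in \[0, 1\]; the network mean `K` is `mean()` of it.
#' @export
clustering_coefficient <- function(net) {
  a <- as_adjacency(net)
  z <- rowSums(a)
  # edges among neighbours of i = (A^3)_{ii} / 2
  tri2 <- diag(a %*% a %*% a) # 2 * L_i
  cc <- ifelse(z >= 2, tri2 / (z * (z - 1)), 0)
  as.numeric(cc)
}

#' Global efficiency
#'
#' Information-transfer ability of the whole network:
#' `E_glob = (1/(N(N-1))) sum_{i != j} 1 / D(i, j)`; equals the mean nodal
#' efficiency.
#'
#' @inheritParams shortest_path_lengths
#' @return A single number in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  mean(nodal_efficiency(net))
}

#' Local efficiency
#'
#' Mean, over nodes, of the global efficiency of each node's neighbourhood
#' subgraph (the node itself excluded); subgraphs with fewer than two nodes
#' contribute 0.
#'
#' @inheritParams shortest_path_lengths
#' @return A single number in \[0, 1\].
#' @export
local_efficiency <- function(net) {
  a <- as_adjacency(net)
  n <- nrow(a)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2L) next
    vals[i] <- global_efficiency(a[nb, nb, drop = FALSE])
  }
  mean(vals)
}

#' Characteristic path length
#'
#' Mean shortest path length over node pairs of the largest connected
#' component (the graph may be disconnected under heavy thresholding).
#'
#' @inheritParams shortest_path_lengths
#' @return A single number (`NA` if the largest component has < 2 nodes).
#' @export
characteristic_path_length <- function(net) {
  a <- as_adjacency(net)
  comp <- largest_component(a)
  if (length(comp) < 2L) return(NA_real_)
  D <- shortest_path_lengths(a[comp, comp, drop = FALSE])
  mean(D[upper.tri(D)])
}

largest_component <- function(a) {
  n <- nrow(a)
  D <- shortest_path_lengths(a)
  seen <- rep(FALSE, n)
  best <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- which(is.finite(D[s, ]))
    seen[comp] <- TRUE
    if (length(comp) > length(best)) best <- comp
  }
  best
}

#' Degree-preserving random rewiring (Maslov-Sneppen)
#'
#' Produces a randomized network with exactly the same degree sequence by
#' repeated double-edge swaps: two edges (a, b), (c, d) are replaced by
#' (a, d), (c, b) when neither new edge exists already and no self-loop is
#' created. `10 * n_edges` swap attempts are made.
#'
#' @inheritParams shortest_path_lengths
#' @return Rewired binary adjacency matrix.
#' @keywords internal
rewire_preserving_degree <- function(net) {
  a <- as_adjacency(net)
  ut <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2L) return(a)
  edges <- ut
  attempts <- 10L * m
  for (k in seq_len(attempts)) {
    pick <- sample.int(m, 2L)
    e1 <- edges[pick[1], ]; e2 <- edges[pick[2], ]
    a1 <- e1[1]; b1 <- e1[2]; a2 <- e2[1]; b2 <- e2[2]
    # randomly choose which endpoints to exchange
    if (runif(1) < 0.5) { tmp <- a2; a2 <- b2; b2 <- tmp }
    if (a1 == a2 || a1 == b2 || b1 == a2 || b1 == b2) next
    if (a[a1, b2] == 1 || a[a2, b1] == 1) next
    a[a1, b1] <- a[b1, a1] <- 0
    a[a2, b2] <- a[b2, a2] <- 0
    a[a1, b2] <- a[b2, a1] <- 1
    a[a2, b1] <- a[b1, a2] <- 1
    edges[pick[1], ] <- sort(c(a1, b2))
    edges[pick[2], ] <- sort(c(a2, b1))
  }
  a
}

#' Small-worldness index
#'
#' Compares the network's mean clustering `K` and characteristic path length
#' `L` with the means of `n_nulls` degree-preserving rewired random
#' networks: `sigma = (K / C_rand) / (L / L_rand)`. A small-world network
#' has `sigma > 1` (more clustered than random at a comparable path length).
#' A normalized variant `sigma / (1 + sigma)` in \[0, 1\] is also returned.
#'
#' @inheritParams shortest_path_lengths
#' @param n_nulls number of rewired null networks (>= 10).
#' @param seed RNG seed for the null ensemble.
#' @return List with `sw`, `sw_norm`, `K`, `L`, `C_rand`, `L_rand`,
#'   `n_nulls`, `seed`, and `defined` (FALSE when the degree sequence cannot
#'   be rewired or clustering of the nulls is zero).
#' @export
small_worldness <- function(net, n_nulls = 100, seed = 1) {
  a <- as_adjacency(net)
  if (n_nulls < 10) stop("`n_nulls` must be at least 10", call. = FALSE)
  K <- mean(clustering_coefficient(a))
  L <- characteristic_path_length(a)
  res <- list(sw = NA_real_, sw_norm = NA_real_, K = K, L = L,
              C_rand = NA_real_, L_rand = NA_real_, n_nulls = n_nulls,
              seed = seed, defined = FALSE)
  if (sum(a) / 2 < 2 || !is.finite(L)) return(res)
  nulls <- with_seed(seed, {
    lapply(seq_len(n_nulls), function(i) rewire_preserving_degree(a))
  })
  C_rand <- mean(vapply(nulls, function(g) mean(clustering_coefficient(g)), 1))
  L_rand <- mean(vapply(nulls, characteristic_path_length, 1))
  res$C_rand <- C_rand
  res$L_rand <- L_rand
  if (is.finite(C_rand) && C_rand > 0 && is.finite(L_rand) && L_rand > 0 &&
      is.finite(L) && L > 0 && K > 0) {
    res$sw <- (K / C_rand) / (L / L_rand)
    res$sw_norm <- res$sw / (1 + res$sw)
    res$defined <- TRUE
  }
  res
}

#' Full graph-metric set of a binary network
#'
#' Computes the six study metrics on one binary network: per-node degree,
#' nodal efficiency and clustering, and network-level global efficiency,
#' local efficiency, mean clustering `K`, characteristic path length and
#' (optionally) small-worldness against degree-preserving nulls.
#'
#' @inheritParams small_worldness
#' @param small_world logical; compute the null-model small-worldness.
#' @return An object of class `fnirs_graph_metrics`: list with `nodal`
#'   (data frame: channel, degree, efficiency, clustering) and `network`
#'   (named list of scalars).
#' @export
graph_metrics <- function(net, small_world = TRUE, n_nulls = 100, seed = 1) {
  a <- as_adjacency(net)
  deg <- degree_centrality(a)
  en <- nodal_efficiency(a)
  cc <- clustering_coefficient(a)
  network <- list(
    global_efficiency = mean(en),
    local_efficiency = local_efficiency(a),
    mean_clustering = mean(cc),
    char_path_length = characteristic_path_length(a),
    small_worldness = NA_real_,
    small_worldness_norm = NA_real_
  )
  if (small_world) {
    sw <- small_worldness(a, n_nulls = n_nulls, seed = seed)
    network$small_worldness <- sw$sw
    network$small_worldness_norm <- sw$sw_norm
    network$C_rand <- sw$C_rand
    network$L_rand <- sw$L_rand
  }
  structure(list(
    nodal = data.frame(channel = seq_len(nrow(a)), degree = deg,
                       efficiency = en, clustering = cc),
    network = network,
    threshold = attr(net, "threshold")),
    class = "fnirs_graph_metrics")
}

#' @export
print.fnirs_graph_metrics <- function(x, ...) {
  nw <- x$network
  cat(sprintf(
    "Graph metrics: E_glob = %.3f, E_loc = %.3f, K = %.3f, L = %.3g, Sw = %.3g\n",
    nw$global_efficiency, nw$local_efficiency, nw$mean_clustering,
    nw$char_path_length, nw$small_worldness))
  invisible(x)
}

#' Graph metrics over a proportional-sparsity sweep
#'
#' Binarizes an r-kind connectivity matrix at every sparsity level of the
#' grid (default 0.5 to 0.9 in steps of 0.05), computes the full metric set
#' at each level, and summarizes each network metric as mean +/- SD across
#' the grid.
#'
#' @param m an `fnirs_fc` of kind `"r"`.
#' @param grid strictly increasing sparsity levels within (0, 1\].
#' @inheritParams graph_metrics
#' @return An object of class `fnirs_sweep`: list with `grid`, `levels`
#'   (one `fnirs_graph_metrics` per level), `network` (data frame: one row
#'   per level) and `summary` (mean and SD per network metric).
#' @export
sparsity_sweep <- function(m, grid = seq(0.5, 0.9, by = 0.05),
                           small_world = TRUE, n_nulls = 100, seed = 1) {
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid > 1)) {
    stop("`grid` must be strictly increasing within (0, 1]", call. = FALSE)
  }
  levels <- lapply(seq_along(grid), function(i) {
    net <- binarize_sparsity(m, grid[i])
    graph_metrics(net, small_world = small_world, n_nulls = n_nulls,
                  seed = seed + i)
  })
  nw <- do.call(rbind, lapply(seq_along(levels), function(i) {
    data.frame(sparsity = grid[i],
               global_efficiency = levels[[i]]$network$global_efficiency,
               local_efficiency = levels[[i]]$network$local_efficiency,
               mean_clustering = levels[[i]]$network$mean_clustering,
               char_path_length = levels[[i]]$network$char_path_length,
               small_worldness = levels[[i]]$network$small_worldness,
               small_worldness_norm = levels[[i]]$network$small_worldness_norm)
  }))
  metrics <- setdiff(names(nw), "sparsity")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(k) mean(nw[[k]], na.rm = TRUE), 1),
    sd = vapply(metrics, function(k) sd(nw[[k]], na.rm = TRUE), 1),
    row.names = NULL)
  structure(list(grid = grid, levels = levels, network = nw, summary = summ),
            class = "fnirs_sweep")
}

#' @export
print.fnirs_sweep <- function(x, ...) {
  cat(sprintf("Sparsity sweep over %d levels (%g-%g):\n", length(x$grid),
              min(x$grid), max(x$grid)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
plot.fnirs_sweep <- function(x, metrics = c("global_efficiency",
                                            "local_efficiency",
                                            "mean_clustering"), ...) {
  matplot(x$network$sparsity, as.matrix(x$network[, metrics, drop = FALSE]),
          type = "b", pch = 19, lty = 1, xlab = "sparsity", ylab = "value",
          main = "network metrics vs sparsity", ...)
  legend("bottomright", legend = metrics, col = seq_along(metrics), lty = 1,
         pch = 19, cex = 0.8)
  invisible(x)
}
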