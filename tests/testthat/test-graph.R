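complete_graph <- function(n) matrix(1, n, n) - diag(n)

path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

star_graph <- function(n) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

cycle_graph <- function(n) {
  a <- path_graph(n)
  a[1, n] <- a[n, 1] <- 1
  a
}

test_that("analytic graph values are exact", {
  k20 <- complete_graph(20)
  expect_equal(degree_centrality(k20), rep(19, 20))
  expect_equal(nodal_efficiency(k20), rep(1, 20), tolerance = 1e-12)
  expect_equal(global_efficiency(k20), 1, tolerance = 1e-12)
  expect_equal(clustering_coefficient(k20), rep(1, 20), tolerance = 1e-12)

  # 4-cycle: per-node efficiency (1 + 1 + 1/2)/3
  c4 <- cycle_graph(4)
  expect_equal(global_efficiency(c4), (1 + 1 + 0.5) / 3, tolerance = 1e-12)

  # star on 5 nodes: centre 1.0, leaves (1 + 3 * 0.5)/4
  s5 <- star_graph(5)
  en <- nodal_efficiency(s5)
  expect_equal(en[1], 1, tolerance = 1e-12)
  expect_equal(en[2:5], rep(0.625, 4), tolerance = 1e-12)
  expect_equal(local_efficiency(s5), 0, tolerance = 1e-12)
  expect_equal(clustering_coefficient(s5), rep(0, 5))
  expect_equal(degree_centrality(star_graph(6)), c(5, rep(1, 5)))

  # triangle: full clustering and local efficiency 1
  k3 <- complete_graph(3)
  expect_equal(local_efficiency(k3), 1, tolerance = 1e-12)
  expect_equal(clustering_coefficient(k3), rep(1, 3))

  # empty graph conventions
  e5 <- matrix(0, 5, 5)
  expect_equal(degree_centrality(e5), rep(0, 5))
  expect_equal(nodal_efficiency(e5), rep(0, 5))
  expect_equal(local_efficiency(e5), 0)

  # path graph distances
  expect_equal(shortest_path_lengths(path_graph(4))[1, 4], 3)
  expect_equal(shortest_path_lengths(complete_graph(5))[1, 2:5], rep(1, 4),
               ignore_attr = TRUE)
})

test_that("isolated nodes follow the 1/Inf = 0 convention", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  en <- nodal_efficiency(a)
  expect_equal(en[3], 0)
  expect_equal(en[1], 1 / 3)
  D <- shortest_path_lengths(a)
  expect_true(is.infinite(D[1, 3]))
  # characteristic path length uses the largest component
  expect_equal(characteristic_path_length(a), 1)
})

test_that("distances, clustering and top-k edges match independent oracles", {
  for (k in 1:50) {
    n <- sample(5:12, 1)
    a <- random_graph(n, runif(1, 0.2, 0.7), seed = 3000 + k)
    expect_equal(shortest_path_lengths(a), floyd_warshall(a),
                 label = sprintf("distances, graph %d", k))
    expect_equal(clustering_coefficient(a), brute_clustering(a),
                 label = sprintf("clustering, graph %d", k))
  }
})

test_that("graph metrics agree with igraph on random instances", {
  skip_if_not_installed("igraph")
  for (k in 1:10) {
    a <- random_graph(10, 0.4, seed = 4000 + k)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(degree_centrality(a), as.numeric(igraph::degree(g)))
    expect_equal(global_efficiency(a),
                 igraph::global_efficiency(g), tolerance = 1e-12)
    expect_equal(clustering_coefficient(a),
                 ifelse(is.nan(igraph::transitivity(g, type = "local")), 0,
                        igraph::transitivity(g, type = "local")),
                 tolerance = 1e-12)
  }
})

test_that("global efficiency equals mean nodal efficiency", {
  for (k in 1:50) {
    a <- random_graph(sample(5:12, 1), runif(1, 0.1, 0.9), seed = 5000 + k)
    expect_equal(global_efficiency(a), mean(nodal_efficiency(a)),
                 tolerance = 1e-12)
  }
})

test_that("metric bounds hold on many random graphs", {
  for (k in 1:200) {
    n <- sample(4:15, 1)
    a <- random_graph(n, runif(1), seed = 6000 + k)
    en <- nodal_efficiency(a); cc <- clustering_coefficient(a)
    dg <- degree_centrality(a)
    expect_true(all(en >= 0 & en <= 1))
    expect_true(all(cc >= 0 & cc <= 1))
    expect_true(all(dg >= 0 & dg <= n - 1))
    expect_true(global_efficiency(a) >= 0 && global_efficiency(a) <= 1)
    expect_true(local_efficiency(a) >= 0 && local_efficiency(a) <= 1)
  }
})

test_that("degree-preserving rewiring keeps every node degree", {
  for (k in 1:10) {
    a <- random_graph(15, 0.3, seed = 7000 + k)
    set.seed(k)
    b <- fnirsnet:::rewire_preserving_degree(a)
    expect_equal(degree_centrality(b), degree_centrality(a))
    expect_equal(diag(b), rep(0, 15))
    expect_equal(b, t(b))
    expect_true(all(b %in% c(0, 1)))
  }
})

test_that("small-worldness is ~1 for dense random graphs and > 1 for lattices", {
  # null self-consistency: a dense random graph is its own null model
  a <- random_graph(30, 0.5, seed = 99)
  sw <- small_worldness(a, n_nulls = 20, seed = 5)
  expect_true(sw$defined)
  expect_gt(sw$sw, 0.8)
  expect_lt(sw$sw, 1.2)
  # ring lattice with shortcuts: high clustering, short paths after nulls
  rl <- ring_lattice(100, 4, p_shortcut = 0.05, seed = 3)
  sw2 <- small_worldness(rl, n_nulls = 10, seed = 5)
  expect_gt(sw2$sw, 1)
  expect_equal(sw2$sw_norm, sw2$sw / (1 + sw2$sw))
  expect_true(sw2$sw_norm > 0 && sw2$sw_norm < 1)
})

test_that("small-worldness flags degenerate inputs", {
  a <- matrix(0, 5, 5); a[1, 2] <- a[2, 1] <- 1
  sw <- small_worldness(a, n_nulls = 10, seed = 1)
  expect_false(sw$defined)
  expect_error(small_worldness(random_graph(10, 0.5, 1), n_nulls = 5), "10")
})

test_that("sparsity sweep is consistent with single-level calls", {
  m <- random_r_matrix(20, seed = 71)
  sw <- sparsity_sweep(m, small_world = FALSE)
  expect_equal(sw$grid, seq(0.5, 0.9, by = 0.05))
  expect_length(sw$levels, 9)
  for (i in c(1, 5, 9)) {
    net <- binarize_sparsity(m, sw$grid[i])
    gm <- graph_metrics(net, small_world = FALSE)
    expect_equal(sw$network$global_efficiency[i],
                 gm$network$global_efficiency)
    expect_equal(sw$network$mean_clustering[i], gm$network$mean_clustering)
  }
  # adding edges never lengthens shortest paths
  expect_true(all(diff(sw$network$global_efficiency) >= 0))
  # summary matches the level table
  expect_equal(sw$summary$mean[sw$summary$metric == "global_efficiency"],
               mean(sw$network$global_efficiency))
  expect_error(sparsity_sweep(m, grid = c(0.5, 0.4)), "increasing")
})

test_that("adjacency validation rejects malformed networks", {
  expect_error(shortest_path_lengths(matrix(1, 3, 3)), "self-loops")
  b <- matrix(0, 3, 3); b[1, 2] <- 1
  expect_error(shortest_path_lengths(b), "symmetric")
  expect_error(shortest_path_lengths(matrix(0.5, 2, 2) - 0.5 * diag(2)),
               "binary")
})
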