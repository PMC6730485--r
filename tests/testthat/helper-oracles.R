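# Independent oracles used to cross-check the package implementations.

# Floyd-Warshall all-pairs shortest paths on a binary adjacency matrix.
floyd_warshall <- function(a) {
  n <- nrow(a)
  D <- matrix(Inf, n, n)
  D[a == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Brute-force clustering coefficient: count edges among neighbour pairs.
brute_clustering <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    z <- length(nb)
    if (z < 2) return(0)
    links <- 0
    for (u in seq_len(z - 1)) {
      for (v in seq(u + 1, z)) {
        links <- links + a[nb[u], nb[v]]
      }
    }
    2 * links / (z * (z - 1))
  })
}

# Seeded Erdos-Renyi adjacency matrix.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# Seeded symmetric correlation-like matrix with unit diagonal.
random_r_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, -0.9, 0.9), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  fnirsnet:::new_fc(m, kind = "r")
}

# Ring lattice of even degree k with optional random shortcuts.
ring_lattice <- function(n, k, p_shortcut = 0, seed = 1) {
  a <- matrix(0, n, n)
  for (d in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      a[i, j] <- a[j, i] <- 1
    }
  }
  if (p_shortcut > 0) {
    set.seed(seed)
    ut <- which(upper.tri(a) & a == 0)
    add <- ut[runif(length(ut)) < p_shortcut]
    a[add] <- 1
    a <- pmax(a, t(a))
  }
  a
}

# Quiet zero-signal profile for degenerate-case tests.
null_profile <- function(label = "null") {
  group_profile(label, activation_amplitude = 0, background_sd = 0,
                amplitude_sd = 0, noise = fnirsnet:::zero_noise_spec())
}

# Small noiseless profile with a known amplitude.
clean_profile <- function(amp, label = "clean") {
  group_profile(label, activation_amplitude = amp, background_sd = 0,
                amplitude_sd = 0, noise = fnirsnet:::zero_noise_spec())
}
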