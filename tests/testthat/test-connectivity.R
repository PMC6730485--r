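test_that("fc_matrix matches direct correlation and handles exact cases", {
  set.seed(2)
  x <- matrix(rnorm(2000), 100, 20)
  m <- fc_matrix(x)
  expect_equal(unclass(m), cor(x), ignore_attr = TRUE)
  expect_lt(max(abs(unclass(m) - t(unclass(m)))), 1e-12)
  expect_equal(diag(unclass(m)), rep(1, 20), ignore_attr = TRUE)
  # duplicated channels -> r = 1; sign-flipped pair -> r = -1
  y <- cbind(x[, 1], x[, 1], -x[, 1])
  m2 <- fc_matrix(y)
  expect_equal(m2[1, 2], 1)
  expect_equal(m2[1, 3], -1)
})

test_that("fc_matrix zeroes zero-variance channels with a warning", {
  set.seed(4)
  x <- cbind(rnorm(50), rep(2, 50), rnorm(50))
  expect_warning(m <- fc_matrix(x), "zero-variance")
  expect_equal(unclass(m)[2, c(1, 3)], c(0, 0), ignore_attr = TRUE)
  expect_equal(unclass(m)[2, 2], 1)
})

test_that("fc_matrix enforces segment and channel preconditions", {
  expect_error(fc_matrix(matrix(rnorm(40), 20, 2)), "30")
  expect_error(fc_matrix(matrix(rnorm(40), 40, 1)), "channels")
})

test_that("fc_matrix is invariant to per-channel affine rescaling", {
  set.seed(6)
  x <- matrix(rnorm(600), 60, 10)
  a <- runif(10, 0.5, 3); b <- rnorm(10)
  y <- sweep(sweep(x, 2, a, "*"), 2, b, "+")
  expect_equal(unclass(fc_matrix(y)), unclass(fc_matrix(x)),
               tolerance = 1e-12)
})

test_that("fisher transform matches atanh and is monotone", {
  m <- random_r_matrix(8, seed = 10)
  z <- fisher_z(m)
  expect_equal(z[1, 2], atanh(m[1, 2]))
  expect_equal(z[3, 7], 0.5 * log((1 + m[3, 7]) / (1 - m[3, 7])))
  expect_equal(diag(unclass(z)), rep(0, 8), ignore_attr = TRUE)
  # r = 0.8 -> z ~ 1.0986
  m2 <- fnirsnet:::new_fc(matrix(c(1, 0.8, 0.8, 1), 2), kind = "r")
  expect_equal(fisher_z(m2)[1, 2], 1.0986, tolerance = 1e-4)
  # monotone in r
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(atanh(rs)) > 0))
  # r = +/-1 handled by clipping, stays finite
  m3 <- fnirsnet:::new_fc(matrix(c(1, 1, 1, 1), 2), kind = "r")
  expect_true(is.finite(fisher_z(m3)[1, 2]))
})

test_that("fixed-threshold binarization implements r > threshold", {
  n <- 20
  hi <- fnirsnet:::new_fc(matrix(0.9, n, n) + 0.1 * diag(n), kind = "r")
  lo <- fnirsnet:::new_fc(matrix(0.5, n, n) + 0.5 * diag(n), kind = "r")
  bh <- binarize_fixed(hi, 0.8)
  bl <- binarize_fixed(lo, 0.8)
  expect_equal(sum(bh) / 2, n * (n - 1) / 2) # complete graph, 190 edges
  expect_equal(sum(bl), 0)
  expect_equal(diag(unclass(bh)), rep(0, n), ignore_attr = TRUE)
  expect_equal(formals(binarize_fixed)$threshold, 0.8)
  expect_error(binarize_fixed(hi, 1.5), "threshold")
})

test_that("sparsity binarization keeps the exact top-k edge set", {
  m <- random_r_matrix(20, seed = 17)
  # edge-count formula: s = 0.5 on 20 nodes -> 95 edges; s = 1 -> complete
  expect_equal(sum(binarize_sparsity(m, 0.5)) / 2, 95)
  expect_equal(sum(binarize_sparsity(m, 1)) / 2, 190)
  # top-k set equals an independent full sort of the upper triangle
  for (s in c(0.3, 0.5, 0.7)) {
    b <- binarize_sparsity(m, s)
    k <- round(s * 190)
    ut <- which(upper.tri(m), arr.ind = TRUE)
    vals <- unclass(m)[ut]
    top <- ut[order(vals, decreasing = TRUE)[seq_len(k)], , drop = FALSE]
    expect_equal(sum(unclass(b)[top]), k)
    expect_equal(sum(b) / 2, k)
  }
})

test_that("sparsity edge sets are nested across levels", {
  m <- random_r_matrix(15, seed = 23)
  grid <- seq(0.2, 0.9, by = 0.1)
  prev <- NULL
  for (s in grid) {
    cur <- unclass(binarize_sparsity(m, s))
    if (!is.null(prev)) expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }
})

test_that("group averaging works on the Fisher-z scale", {
  m1 <- random_r_matrix(10, seed = 31)
  # idempotence
  avg <- fc_group_average(list(m1, m1, m1))
  expect_equal(unclass(avg), unclass(m1), tolerance = 1e-10)
  # +z / -z cancel to r = 0
  z <- matrix(0.6, 10, 10); diag(z) <- 0
  ra <- fnirsnet:::new_fc(tanh(z) + diag(10) * (1 - tanh(0)), kind = "r")
  rb <- fnirsnet:::new_fc(tanh(-z) + diag(10), kind = "r")
  avg2 <- fc_group_average(list(ra, rb))
  expect_equal(unclass(avg2)[1, 2], 0, tolerance = 1e-10)
  # random matrices vs direct atanh/mean/tanh oracle
  ms <- lapply(1:4, function(k) random_r_matrix(10, seed = 40 + k))
  avg3 <- fc_group_average(ms)
  zbar <- Reduce(`+`, lapply(ms, function(m) atanh(pmin(pmax(
    unclass(m), -(1 - 1e-7)), 1 - 1e-7)))) / 4
  oracle <- tanh(zbar); diag(oracle) <- 1
  expect_equal(unclass(avg3), oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(fc_group_average(list()), "empty")
})

test_that("mean_fisher_z equals the direct upper-triangle average", {
  m <- random_r_matrix(12, seed = 55)
  r <- unclass(m)
  oracle <- mean(atanh(r[upper.tri(r)]))
  expect_equal(mean_fisher_z(m), oracle, tolerance = 1e-12)
})

test_that("group-averaged matrices converge to the latent connectivity", {
  # long-duration cohort: resting state extended to 10x the session scale
  p <- group_profile("conv", 0.2,
                     latent_connectivity = block_connectivity(between = 0.4))
  long_sched <- build_schedule(rest = 2400, n_trials = 9)
  mats <- lapply(1:4, function(i) {
    sim <- simulate_subject(p, schedule = long_sched, seed = 600 + i)
    h <- hemoglobin_series(sim$recording)
    fc_matrix(h, "resting")
  })
  avg <- fc_group_average(mats)
  L <- p$latent_connectivity
  err <- mean(abs(avg[upper.tri(avg)] - L[upper.tri(L)]))
  expect_lte(err, 0.05)
})
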