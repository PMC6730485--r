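fs <- 7.81

test_that("dHRF impulse response peaks at the configured time-to-peak", {
  # evaluate the closed-form kernel on the sample grid: mode of the
  # unit-rate gamma lobe sits at `peak` seconds
  tg <- seq(0, 30, by = 1 / fs)
  h <- canonical_hrf(tg)
  expect_equal(tg[which.max(h)], 6, tolerance = 1 / fs + 1e-9)
  h10 <- canonical_hrf(tg, peak = 10)
  expect_equal(tg[which.max(h10)], 10, tolerance = 1 / fs + 1e-9)
  # undershoot exists and is below zero
  expect_lt(min(h), 0)
})

test_that("dHRF regressor is a shift-invariant unit-peak block response", {
  s <- make_default_schedule()
  d <- build_dhrf(s, fs)
  expect_equal(max(d$dhrf), 1)
  expect_equal(length(d$dhrf), round(612 * fs))
  # zero before the first task onset
  expect_true(all(abs(d$dhrf[d$time < 240]) < 1e-12))
  # two identical non-overlapping blocks: second response is a shifted copy
  s2 <- build_schedule(rest = 100, n_trials = 2, trial_rest = 76,
                       post_rest = 50)
  d2 <- build_dhrf(s2, fs)
  shift <- round(attr(s2, "trial_length") * fs)
  on1 <- round(100 * fs)
  seg1 <- d2$dhrf[(on1 + 1):(on1 + 200)]
  seg2 <- d2$dhrf[(on1 + shift + 1):(on1 + shift + 200)]
  expect_equal(seg1, seg2, tolerance = 1e-8)
})

test_that("dHRF requires task blocks", {
  s <- make_default_schedule()
  s_notask <- s[s$condition == "rest", ]
  attr(s_notask, "class") <- class(s)
  expect_error(build_dhrf(s_notask, fs), "task")
})

test_that("robust GLM recovers exact and contaminated slopes", {
  d <- build_dhrf(make_default_schedule(), fs)
  x <- d$dhrf
  # noiseless: exact slope, zero residuals
  f <- robust_glm(2 * x, x)
  expect_equal(unname(coef(f)["slope"]), 2, tolerance = 1e-10)
  expect_equal(unname(coef(f)["intercept"]), 0, tolerance = 1e-10)
  # amplitude recovery for y = A * dhrf
  fA <- robust_glm(0.37 * x, x)
  expect_equal(unname(coef(fA)["slope"]), 0.37, tolerance = 1e-6 * 0.37)
  # heavy outliers: robust slope beats ordinary least squares
  set.seed(42)
  y <- x + rnorm(length(x), 0, 0.1)
  bad <- sample(length(x), round(0.05 * length(x)))
  y[bad] <- y[bad] + 5
  fr <- robust_glm(y, x)
  ols <- unname(coef(lm(y ~ x))[2])
  expect_lt(abs(coef(fr)["slope"] - 1), abs(ols - 1))
})

test_that("robust GLM agrees with an independent bisquare implementation", {
  skip_if_not_installed("MASS")
  set.seed(7)
  x <- sin(seq(0, 20, length.out = 500))
  y <- 1.5 * x + rnorm(500, 0, 0.3)
  y[1:10] <- y[1:10] + 4
  f <- robust_glm(y, x)
  m <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 50)
  expect_equal(unname(coef(f)["slope"]), unname(coef(m)[2]),
               tolerance = 1e-3)
  expect_equal(unname(f$se["slope"]), sqrt(diag(vcov(m)))[2],
               tolerance = 0.15, ignore_attr = TRUE)
})

test_that("robust GLM rejects degenerate inputs", {
  expect_error(robust_glm(rnorm(100), rep(1, 100)), "variance")
  expect_error(robust_glm(rnorm(10), rnorm(10)), "short")
  expect_error(robust_glm(rnorm(50), rnorm(51)), "aligned")
})

test_that("t is invariant to joint positive rescaling of y and x", {
  set.seed(9)
  x <- rnorm(300); y <- 0.5 * x + rnorm(300)
  f1 <- robust_glm(y, x)
  f2 <- robust_glm(7.3 * y, 7.3 * x)
  expect_equal(unname(f1$t["slope"]), unname(f2$t["slope"]),
               tolerance = 1e-6)
})

test_that("null t-values stay below the 0.99 null quantile", {
  # white noise orthogonalized against the regressor: |t| should look like
  # a central t draw; check 200 seeded replicates
  d <- build_dhrf(make_default_schedule(), fs)
  x <- d$dhrf[d$time >= 240]
  n <- length(x)
  crit <- qt(0.995, n - 2) # 0.99 two-sided quantile of the null
  hits <- 0
  for (k in 1:200) {
    set.seed(1000 + k)
    e <- rnorm(n)
    e <- residuals(lm(e ~ x))
    e <- e + rnorm(n, 0, 1e-8) # break exact orthogonality degeneracy
    f <- robust_glm(e, x)
    if (abs(f$t["slope"]) < crit) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("block average replicates identical trials and matches a direct loop", {
  s <- make_default_schedule()
  # strictly 38-s-periodic series on a sample-aligned grid (fs = 8 Hz so a
  # trial is exactly 304 samples) -> identical epochs, SD 0
  fs8 <- 8
  tvec8 <- (seq_len(612 * fs8) - 1) / fs8
  y_per <- sin(2 * pi * (tvec8 - 240) / 38)
  ba <- block_average(y_per, s, fs8)
  expect_equal(ba$n_trials, 9)
  expect_lt(max(ba$sd), 1e-10)
  expect_equal(ba$mean, ba$epochs[1, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  # default window is the 38-s trial (plus the 2-s pre-onset baseline)
  expect_equal(length(ba$mean), round(38 * fs8) + round(2 * fs8))
  # noisy series vs an independently coded epoching loop
  set.seed(5)
  y <- rnorm(round(612 * fs))
  ba2 <- block_average(y, s, fs, window = 30, baseline = 2)
  nb <- round(2 * fs); nw <- round(30 * fs)
  eps <- t(sapply(task_onsets(s), function(t0) {
    i0 <- round(t0 * fs) + 1
    ep <- y[(i0 - nb):(i0 + nw - 1)]
    ep - mean(ep[1:nb])
  }))
  expect_equal(ba2$mean, colMeans(eps))
  expect_equal(ba2$sd, apply(eps, 2, sd))
})

test_that("single-epoch block average flags undefined SD", {
  s1 <- build_schedule(rest = 60, n_trials = 1, post_rest = 60)
  y <- rnorm(round(attr(s1, "total") * fs))
  ba <- block_average(y, s1, fs)
  expect_false(ba$sd_defined)
  expect_true(all(is.na(ba$sd)))
})

test_that("t-map normalizes to [0, 1] and preserves node ranks", {
  m <- default_montage()
  # single hot channel attains 1.0 at its node
  tv <- rep(0, 20); tv[7] <- 10
  tm <- t_map(tv, m)
  expect_equal(max(tm$node_values), 1)
  expect_equal(which.max(tm$node_values), 7)
  expect_true(all(tm$map >= 0 & tm$map <= 1))
  # flat input -> all-zero map by convention
  tm0 <- t_map(rep(3, 20), m)
  expect_true(all(tm0$map == 0))
  expect_true(all(tm0$node_values == 0))
  # rank order of node values matches input t ranks
  set.seed(13)
  tv2 <- rnorm(20)
  tm2 <- t_map(tv2, m)
  expect_equal(order(tm2$node_values), order(tv2))
})

test_that("active channels in simulated subjects outrank inactive ones", {
  p <- group_profile("act", 0.5, active_channels = 6:13,
                     amplitude_sd = 0)
  sim <- simulate_subject(p, seed = 31)
  h <- hemoglobin_series(sim$recording)
  d <- build_dhrf(make_default_schedule(), fs)
  act <- channel_activation(h, d)
  expect_gt(min(act$t[6:13]), max(act$t[setdiff(1:20, 6:13)]))
  expect_true(all(act$active[6:13]))
})
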