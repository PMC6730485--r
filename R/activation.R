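#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; peak) - ratio * g(t; undershoot)` where `g(.; m)` is a gamma
#' density with unit rate and mode `m` seconds, so the positive lobe peaks at
#' exactly `peak` seconds.
#'
#' @param t time, seconds (vector).
#' @param peak time to peak of the positive lobe, s.
#' @param undershoot time to trough of the undershoot, s.
#' @param ratio undershoot amplitude relative to the peak lobe.
#' @return `h(t)`, arbitrary units.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  dgamma(t, shape = peak + 1, rate = 1) -
    ratio * dgamma(t, shape = undershoot + 1, rate = 1)
}

#' Designed hemodynamic response regressor (dHRF) for a block paradigm
#'
#' Builds the predicted hemodynamic response by convolving the canonical
#' double-gamma HRF with a unit boxcar spanning each task period
#' (encoding + retention + probe, 24 s by default) of the schedule, sampled
#' at `fs`. The regressor is scaled to unit peak so a regression slope is in
#' the units of the data (micromolar per unit response).
#'
#' @param schedule an `fnirs_schedule` with at least one task block.
#' @param fs sampling rate, Hz.
#' @param n_samples regressor length; defaults to the full schedule duration.
#' @param peak,undershoot,ratio double-gamma parameters, see
#'   [canonical_hrf()].
#' @return An object of class `fnirs_dhrf`: list with `time`, `dhrf` (unit
#'   peak), `boxcar`, `hrf_params`, `fs`.
#' @export
build_dhrf <- function(schedule, fs, n_samples = NULL, peak = 6,
                       undershoot = 16, ratio = 1 / 6) {
  stopifnot_scalar_pos(fs, "fs")
  onsets <- task_onsets(schedule)
  if (length(onsets) == 0L) {
    stop("schedule contains no task blocks", call. = FALSE)
  }
  if (is.null(n_samples)) n_samples <- round(attr(schedule, "total") * fs)
  time <- (seq_len(n_samples) - 1) / fs
  block_len <- attr(schedule, "task_duration")
  boxcar <- numeric(n_samples)
  for (t0 in onsets) {
    boxcar[time >= t0 & time < t0 + block_len] <- 1
  }
  kern_t <- seq(0, 40, by = 1 / fs)
  kern <- canonical_hrf(kern_t, peak, undershoot, ratio)
  conv <- stats::convolve(boxcar, rev(kern), type = "open")[seq_len(n_samples)]
  conv <- conv / fs # Riemann-sum convolution
  mx <- max(abs(conv))
  if (mx > 0) conv <- conv / mx
  structure(list(time = time, dhrf = conv, boxcar = boxcar,
                 hrf_params = list(peak = peak, undershoot = undershoot,
                                   ratio = ratio),
                 fs = fs),
            class = "fnirs_dhrf")
}

#' Robust regression of a channel time series on the dHRF
#'
#' Fits `y = b0 + b1 * x` by iteratively reweighted least squares with
#' bisquare (Tukey biweight) weights, the standard robust-fit scheme for
#' activation detection. Scale is re-estimated each iteration from the
#' median absolute residual (leverage-adjusted); iteration stops when the
#' coefficient change is below `tol` or after `max_iter` iterations. The
#' slope standard error is the M-estimation asymptotic (psi-based) estimate,
#' which reduces to the ordinary least-squares formula when all weights are
#' one; `t = b1 / se`.
#'
#' @param y response series (e.g. a channel's filtered dHbO).
#' @param x regressor; an `fnirs_dhrf` or a numeric vector.
#' @param tune bisquare tuning constant (default 4.685, 95% Gaussian
#'   efficiency).
#' @param max_iter,tol IRLS stopping rule.
#' @return An object of class `fnirs_rfit`: list with `coefficients`
#'   (intercept, slope), `se`, `t`, `df`, `weights`, `iterations`,
#'   `converged`.
#' @examples
#' x <- sin(seq(0, 10, length.out = 200))
#' fit <- robust_glm(2 * x, x)
#' coef(fit)["slope"]
#' @export
robust_glm <- function(y, x, tune = 4.685, max_iter = 50, tol = 1e-8) {
  if (inherits(x, "fnirs_dhrf")) x <- x$dhrf
  y <- as.numeric(y); x <- as.numeric(x)
  if (length(y) != length(x)) stop("`y` and `x` must be aligned", call. = FALSE)
  n <- length(y)
  if (n < 20L) stop("series too short for a stable two-term fit", call. = FALSE)
  if (sd(x) == 0) {
    stop("regressor has zero variance; slope undefined", call. = FALSE)
  }
  X <- cbind(1, x)
  p <- 2L
  # leverage of the two-column design, for residual adjustment
  XtX_inv <- solve(crossprod(X))
  h <- rowSums((X %*% XtX_inv) * X)
  h <- pmin(h, 0.9999)
  beta <- XtX_inv %*% crossprod(X, y) # OLS start
  w <- rep(1, n)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    r <- as.numeric(y - X %*% beta)
    radj <- r / sqrt(1 - h)
    s <- median(abs(radj)) / 0.6745
    if (s <= .Machine$double.eps * max(abs(y), 1)) {
      # residuals numerically zero: perfect fit
      w <- rep(1, n); converged <- TRUE
      break
    }
    u <- radj / (tune * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    WX <- X * w
    beta_new <- tryCatch(solve(crossprod(WX, X), crossprod(WX, y)),
                         error = function(e) beta)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  r <- as.numeric(y - X %*% beta)
  s <- median(abs(r / sqrt(1 - h))) / 0.6745
  if (s <= .Machine$double.eps * max(abs(y), 1)) {
    se <- c(0, 0)
  } else {
    u <- r / (tune * s)
    psi <- ifelse(abs(u) < 1, r * (1 - u^2)^2, 0)
    dpsi <- ifelse(abs(u) < 1, (1 - u^2) * (1 - 5 * u^2), 0)
    denom <- sum(dpsi)
    if (denom <= 0) {
      se <- c(NA_real_, NA_real_)
    } else {
      scale2 <- (n / (n - p)) * n * sum(psi^2) / denom^2
      se <- sqrt(scale2 * diag(XtX_inv))
    }
  }
  se <- unname(se)
  tval <- ifelse(se > 0, as.numeric(beta) / se, NA_real_)
  structure(list(coefficients = c(intercept = beta[1], slope = beta[2]),
                 se = c(intercept = se[1], slope = se[2]),
                 t = c(intercept = tval[1], slope = tval[2]),
                 df = n - p, weights = w, iterations = iter,
                 converged = converged),
            class = "fnirs_rfit")
}

#' @export
print.fnirs_rfit <- function(x, ...) {
  cat(sprintf(
    "Robust fit (bisquare IRLS, %d iter%s): slope = %.4g (se %.3g, t = %.3g, df = %d)\n",
    x$iterations, if (x$converged) "" else ", not converged",
    x$coefficients["slope"], x$se["slope"], x$t["slope"], x$df))
  invisible(x)
}

#' @export
coef.fnirs_rfit <- function(object, ...) object$coefficients

#' Per-channel activation statistics
#'
#' Runs [robust_glm()] of every channel's dHbO series on the designed
#' hemodynamic response and flags channels whose t-value exceeds the critical
#' value of the t distribution at level `alpha` (one-sided, activation =
#' positive response).
#'
#' @param hemo an `fnirs_hemo`.
#' @param dhrf an `fnirs_dhrf`, aligned with `hemo` (built from the same
#'   schedule and sampling rate).
#' @param alpha significance level for the active-channel cutoff.
#' @param segment `"session"` (default; task session plus post-rest) or
#'   `"all"`: samples used in the regression.
#' @return An object of class `fnirs_activation`: data frame with columns
#'   `channel`, `beta`, `se`, `t`, `active`, plus attributes `alpha`, `df`,
#'   `t_crit`.
#' @export
channel_activation <- function(hemo, dhrf, alpha = 0.01,
                               segment = c("session", "all")) {
  stopifnot(inherits(hemo, "fnirs_hemo"), inherits(dhrf, "fnirs_dhrf"))
  segment <- match.arg(segment)
  idx <- seq_len(nrow(hemo$hbo))
  if (segment == "session") {
    idx <- which(hemo$time >= attr(hemo$schedule, "task_start"))
  }
  if (length(dhrf$dhrf) < max(idx)) {
    stop("dHRF regressor shorter than the recording", call. = FALSE)
  }
  x <- dhrf$dhrf[idx]
  nch <- ncol(hemo$hbo)
  res <- data.frame(channel = seq_len(nch), beta = NA_real_, se = NA_real_,
                    t = NA_real_, active = FALSE)
  df <- length(idx) - 2L
  for (ch in seq_len(nch)) {
    fit <- robust_glm(hemo$hbo[idx, ch], x)
    res$beta[ch] <- fit$coefficients["slope"]
    res$se[ch] <- fit$se["slope"]
    res$t[ch] <- fit$t["slope"]
    df <- fit$df
  }
  t_crit <- qt(1 - alpha, df)
  res$active <- !is.na(res$t) & res$t > t_crit
  structure(res, alpha = alpha, df = df, t_crit = t_crit,
            class = c("fnirs_activation", "data.frame"))
}

#' @export
print.fnirs_activation <- function(x, ...) {
  cat(sprintf(
    "Channel activation (robust GLM on dHRF): %d/%d active at alpha = %g (t > %.3g, df = %d)\n",
    sum(x$active), nrow(x), attr(x, "alpha"), attr(x, "t_crit"), attr(x, "df")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' @export
summary.fnirs_activation <- function(object, ...) {
  cat(sprintf("Active channels: %s\n",
              paste(object$channel[object$active], collapse = ", ")))
  cat(sprintf("t range: [%.3g, %.3g], critical value %.3g\n",
              min(object$t, na.rm = TRUE), max(object$t, na.rm = TRUE),
              attr(object, "t_crit")))
  invisible(object)
}

#' Trial-locked block average of a channel series
#'
#' Epochs the series around every task onset over `[-baseline, window]`
#' seconds, subtracts each epoch's pre-onset mean, and returns the
#' point-wise mean and standard deviation across trials.
#'
#' @param y numeric vector (one channel) sampled at `fs`.
#' @param schedule an `fnirs_schedule`.
#' @param fs sampling rate, Hz.
#' @param window seconds after onset (default the 38-s trial length).
#' @param baseline seconds before onset used for the epoch baseline.
#' @return An object of class `fnirs_block_average`: list with `time`
#'   (relative to onset), `mean`, `sd`, `n_trials`, `epochs` (trials x time).
#'   With fewer than two epochs the SD is `NA` and `sd_defined` is `FALSE`.
#' @export
block_average <- function(y, schedule, fs, window = NULL, baseline = 2) {
  stopifnot_scalar_pos(fs, "fs")
  if (is.null(window)) window <- attr(schedule, "trial_length")
  onsets <- task_onsets(schedule)
  if (length(onsets) == 0L) stop("schedule contains no task blocks", call. = FALSE)
  nb <- round(baseline * fs)
  nw <- round(window * fs)
  rel <- (seq_len(nb + nw) - nb - 1) / fs
  epochs <- NULL
  for (t0 in onsets) {
    i0 <- round(t0 * fs) + 1L
    idx <- (i0 - nb):(i0 + nw - 1L)
    if (min(idx) < 1L || max(idx) > length(y)) next
    ep <- y[idx]
    if (nb > 0) ep <- ep - mean(ep[seq_len(nb)])
    epochs <- rbind(epochs, ep)
  }
  if (is.null(epochs)) stop("no complete epochs within the series", call. = FALSE)
  sd_defined <- nrow(epochs) >= 2L
  structure(list(time = rel, mean = colMeans(epochs),
                 sd = if (sd_defined) apply(epochs, 2, sd) else
                   rep(NA_real_, ncol(epochs)),
                 n_trials = nrow(epochs), epochs = unname(epochs),
                 sd_defined = sd_defined),
            class = "fnirs_block_average")
}

#' @export
plot.fnirs_block_average <- function(x, ...) {
  plot(x$time, x$mean, type = "l", lwd = 2, xlab = "time from onset (s)",
       ylab = expression(Delta * "HbO (" * mu * "M)"), ...)
  if (x$sd_defined) {
    lines(x$time, x$mean + x$sd, lty = 3)
    lines(x$time, x$mean - x$sd, lty = 3)
  }
  abline(v = 0, col = "grey")
  invisible(x)
}

#' Normalized spatial t-map over the montage plane
#'
#' Interpolates per-channel t-values over the 2-D montage plane with
#' inverse-distance weighting (exact at the channel positions) and min-max
#' normalizes the map to \[0, 1\]. When all t-values are equal the map is
#' defined as all zeros.
#'
#' @param t_values numeric vector, one t per channel.
#' @param montage an `fnirs_montage`.
#' @param resolution grid points per axis.
#' @param power inverse-distance weighting exponent.
#' @return An object of class `fnirs_tmap`: list with grid vectors `x`, `y`,
#'   matrix `map` in \[0, 1\], `node_values` (normalized values at the
#'   channel positions) and the channel coordinates.
#' @export
t_map <- function(t_values, montage = default_montage(), resolution = 60,
                  power = 2) {
  ch <- montage$channels
  if (length(t_values) != nrow(ch)) {
    stop("one t-value per montage channel required", call. = FALSE)
  }
  rng <- max(t_values) - min(t_values)
  norm <- function(v) if (rng > 0) (v - min(t_values)) / rng else rep(0, length(v))
  gx <- seq(min(ch$x) - 1, max(ch$x) + 1, length.out = resolution)
  gy <- seq(min(ch$y) - 1, max(ch$y) + 1, length.out = resolution)
  map <- matrix(0, resolution, resolution)
  if (rng > 0) {
    for (i in seq_along(gx)) {
      dx2 <- (ch$x - gx[i])^2
      for (j in seq_along(gy)) {
        d <- sqrt(dx2 + (ch$y - gy[j])^2)
        if (any(d < 1e-9)) {
          map[i, j] <- t_values[which.min(d)]
        } else {
          w <- 1 / d^power
          map[i, j] <- sum(w * t_values) / sum(w)
        }
      }
    }
    map <- (map - min(t_values)) / rng
    map[map < 0] <- 0; map[map > 1] <- 1
  }
  structure(list(x = gx, y = gy, map = map, node_values = norm(t_values),
                 channels = ch),
            class = "fnirs_tmap")
}

#' @export
plot.fnirs_tmap <- function(x, ...) {
  pal <- colorRampPalette(c("navy", "white", "firebrick"))(64)
  image(x$x, x$y, x$map, col = pal, zlim = c(0, 1), asp = 1,
        xlab = "x (cm)", ylab = "y (cm)", main = "normalized t-map", ...)
  points(x$channels$x, x$channels$y, pch = 21, bg = "white")
  text(x$channels$x, x$channels$y, x$channels$channel, cex = 0.6, pos = 3)
  invisible(x)
}
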