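#' Default optical geometry for the modified Beer-Lambert law
#'
#' Bundles the constants of the modified Beer-Lambert law (MBLL): molar
#' extinction coefficients of oxy- and deoxyhemoglobin at the two acquisition
#' wavelengths (760 and 850 nm), the differential pathlength factor (DPF) and
#' the emitter-detector separation per channel. Extinction defaults are the
#' widely used compiled in-vivo tabulation (values in cm^-1 per micromolar):
#' at 760 nm HbO 5.86e-4, HbR 1.54852e-3; at 850 nm HbO 1.058e-3, HbR
#' 6.9132e-4. The DPF defaults to 6.0 at both wavelengths. Absolute
#' micromolar scaling is therefore convention-dependent (no partial-volume
#' correction is applied); all constants are overridable.
#'
#' @param separation emitter-detector distance(s), cm; either one value or
#'   one per channel. Must lie in \[2.5, 5\] (larger separations give noisy,
#'   unstable signals and are rejected).
#' @param dpf differential pathlength factor, one value per wavelength.
#' @param wavelengths acquisition wavelengths, nm.
#' @param extinction 2x2 matrix of extinction coefficients, rows =
#'   wavelengths, columns = c("HbO", "HbR"), in cm^-1/uM.
#' @return An object of class `fnirs_geometry`.
#' @examples
#' g <- default_geometry()
#' g$extinction
#' @export
default_geometry <- function(separation = 3.0,
                             dpf = c(6.0, 6.0),
                             wavelengths = c(760, 850),
                             extinction = NULL) {
  if (is.null(extinction)) {
    extinction <- matrix(c(586e-6, 1548.52e-6,
                           1058e-6, 691.32e-6),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(paste0("w", wavelengths),
                                         c("HbO", "HbR")))
  }
  if (any(separation < 2.5 | separation > 5.0)) {
    stop("emitter-detector separation must lie in [2.5, 5] cm", call. = FALSE)
  }
  if (length(dpf) != 2L || any(dpf <= 0)) {
    stop("`dpf` must be two positive values (one per wavelength)", call. = FALSE)
  }
  if (!is.matrix(extinction) || any(dim(extinction) != 2L) ||
      !is.finite(rcond_2x2(extinction)) || rcond_2x2(extinction) < 1e-12) {
    stop("`extinction` must be an invertible 2x2 matrix", call. = FALSE)
  }
  structure(list(separation = separation, dpf = dpf,
                 wavelengths = wavelengths, extinction = extinction),
            class = "fnirs_geometry")
}

# Reciprocal condition number of a 2x2 matrix (0 when singular).
rcond_2x2 <- function(m) {
  s <- svd(m)$d
  if (s[1] == 0) 0 else s[2] / s[1]
}

#' Optical density change relative to a baseline window
#'
#' Converts light-intensity time series to optical-density changes,
#' `dOD(t) = -log10(I(t) / I0)`, with `I0` the mean intensity over the
#' baseline window, so the mean dOD over that window is approximately zero.
#'
#' @param intensity numeric vector or matrix (time x channels) of strictly
#'   positive intensities.
#' @param baseline integer vector of sample indices defining the baseline
#'   window; defaults to the full series.
#' @return dOD with the same dimensions as `intensity`.
#' @examples
#' optical_density(c(1, 1, 0.1), baseline = 1:2)
#' @export
optical_density <- function(intensity, baseline = NULL) {
  x <- as.matrix(intensity)
  if (is.null(baseline)) baseline <- seq_len(nrow(x))
  if (any(!is.finite(x[baseline, , drop = FALSE])) ||
      any(x[baseline, , drop = FALSE] <= 0)) {
    bad <- which(apply(x[baseline, , drop = FALSE] <= 0, 2, any))
    stop(sprintf("non-positive intensity on the baseline window in channel(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(x <= 0)) {
    stop(sprintf("non-positive intensity in channel(s): %s",
                 paste(which(apply(x <= 0, 2, any)), collapse = ", ")),
         call. = FALSE)
  }
  i0 <- colMeans(x[baseline, , drop = FALSE])
  od <- -log10(sweep(x, 2, i0, "/"))
  if (is.null(dim(intensity))) od <- drop(od)
  od
}

#' Modified Beer-Lambert conversion of optical densities to hemoglobin
#'
#' Solves, per channel and time point, the 2x2 MBLL system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF(lambda)`
#' for the oxy-/deoxyhemoglobin concentration changes (micromolar).
#'
#' @param od_lo,od_hi optical-density matrices (time x channels) at the lower
#'   (760 nm) and higher (850 nm) wavelength.
#' @param geometry an [default_geometry()] object; `separation` may be a
#'   single value or one per channel.
#' @return List with matrices `hbo` and `hbr` (micromolar).
#' @seealso [mbll_forward()] for the forward model.
#' @export
mbll_convert <- function(od_lo, od_hi, geometry = default_geometry()) {
  od_lo <- as.matrix(od_lo); od_hi <- as.matrix(od_hi)
  if (!all(dim(od_lo) == dim(od_hi))) {
    stop("optical-density series at the two wavelengths must be aligned",
         call. = FALSE)
  }
  nc <- ncol(od_lo)
  sep <- rep_len(geometry$separation, nc)
  E <- geometry$extinction
  hbo <- hbr <- matrix(0, nrow(od_lo), nc, dimnames = dimnames(od_lo))
  for (ch in seq_len(nc)) {
    A <- E * (sep[ch] * geometry$dpf) # row-wise: wavelength-specific pathlength
    sol <- solve(A, rbind(od_lo[, ch], od_hi[, ch]))
    hbo[, ch] <- sol[1, ]
    hbr[, ch] <- sol[2, ]
  }
  list(hbo = hbo, hbr = hbr)
}

#' Forward MBLL model: hemoglobin concentrations to optical densities
#'
#' The exact inverse of [mbll_convert()]: maps concentration changes
#' (micromolar) to the optical-density changes they induce at both
#' wavelengths.
#'
#' @param hbo,hbr matrices (time x channels), micromolar.
#' @inheritParams mbll_convert
#' @return List with matrices `od_lo`, `od_hi`.
#' @export
mbll_forward <- function(hbo, hbr, geometry = default_geometry()) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(all(dim(hbo) == dim(hbr)))
  nc <- ncol(hbo)
  sep <- rep_len(geometry$separation, nc)
  E <- geometry$extinction
  od_lo <- od_hi <- matrix(0, nrow(hbo), nc, dimnames = dimnames(hbo))
  for (ch in seq_len(nc)) {
    A <- E * (sep[ch] * geometry$dpf)
    od_lo[, ch] <- A[1, 1] * hbo[, ch] + A[1, 2] * hbr[, ch]
    od_hi[, ch] <- A[2, 1] * hbo[, ch] + A[2, 2] * hbr[, ch]
  }
  list(od_lo = od_lo, od_hi = od_hi)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Removes physiological noise (cardiac, respiration, very-low-frequency
#' drift) with cascaded Butterworth low-pass and high-pass sections of the
#' given order, applied forward-backward (zero phase) so hemodynamic-response
#' timing is preserved. The default cutoffs are 0.026 Hz (the reciprocal of
#' the 38-s trial period) and 0.15 Hz. The series mean is removed before
#' filtering and the series is extended by odd reflection at both ends to
#' suppress edge transients; a constant input therefore maps to (numerically)
#' zero output.
#'
#' @param x numeric vector or matrix (time x channels).
#' @param fs sampling rate, Hz.
#' @param low_cut,high_cut band edges, Hz; must satisfy
#'   `0 < low_cut < high_cut < fs/2`.
#' @param order Butterworth order of each section.
#' @return Filtered series, same dimensions as `x`.
#' @examples
#' fs <- 7.81
#' t <- seq(0, 342, by = 1 / fs)
#' y <- bandpass_filter(sin(2 * pi * 0.06 * t), fs)
#' @export
bandpass_filter <- function(x, fs, low_cut = 0.026, high_cut = 0.15,
                            order = 4) {
  stopifnot_scalar_pos(fs, "fs")
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2)) {
    stop(sprintf(
      "cutoffs must satisfy 0 < low_cut < high_cut < fs/2 (fs = %g Hz)", fs),
      call. = FALSE)
  }
  lp <- signal::butter(order, high_cut / (fs / 2), type = "low")
  hp <- signal::butter(order, low_cut / (fs / 2), type = "high")
  m <- as.matrix(x)
  n <- nrow(m)
  # pad long enough for the slow high-pass transient to die out
  npad <- min(n - 1L, ceiling(3 * fs / low_cut))
  out <- m
  for (ch in seq_len(ncol(m))) {
    y <- m[, ch] - mean(m[, ch])
    pre <- 2 * y[1] - y[(npad + 1L):2L]
    post <- 2 * y[n] - y[(n - 1L):(n - npad)]
    yp <- c(pre, y, post)
    yp <- signal::filtfilt(lp, yp)
    yp <- signal::filtfilt(hp, yp)
    out[, ch] <- yp[(npad + 1L):(npad + n)]
  }
  if (is.null(dim(x))) out <- drop(out)
  out
}

#' Convert a raw recording to a hemoglobin series
#'
#' Full preprocessing of a two-wavelength recording: optical density relative
#' to the resting-state baseline, MBLL inversion to dHbO/dHbR (micromolar)
#' and, optionally, band-pass filtering.
#'
#' @param recording an `fnirs_recording` (see [simulate_subject()] /
#'   [read_recording()]).
#' @param geometry an [default_geometry()] object; when `NULL`, the
#'   geometry attached to the recording (if any) or the package default.
#' @param baseline `"resting"` (default: the pre-task resting-state segment)
#'   or an integer vector of sample indices.
#' @param filter logical; apply [bandpass_filter()] to both chromophores.
#' @param low_cut,high_cut,order filter settings.
#' @return An object of class `fnirs_hemo`: list with `time`, `hbo`, `hbr`
#'   (time x channels, micromolar), `fs`, `schedule`, and a `filtered`
#'   provenance flag.
#' @export
hemoglobin_series <- function(recording, geometry = NULL,
                              baseline = "resting", filter = TRUE,
                              low_cut = 0.026, high_cut = 0.15, order = 4) {
  stopifnot(inherits(recording, "fnirs_recording"))
  if (is.null(geometry)) {
    geometry <- if (!is.null(recording$geometry)) recording$geometry else
      default_geometry()
  }
  if (identical(baseline, "resting")) {
    rest_end <- attr(recording$schedule, "rest_end")
    baseline <- which(recording$time < rest_end)
    if (length(baseline) < 2L) baseline <- seq_along(recording$time)
  }
  od_lo <- optical_density(recording$intensity_lo, baseline)
  od_hi <- optical_density(recording$intensity_hi, baseline)
  hb <- mbll_convert(od_lo, od_hi, geometry)
  filt <- list(applied = FALSE)
  if (filter) {
    hb$hbo <- bandpass_filter(hb$hbo, recording$fs, low_cut, high_cut, order)
    hb$hbr <- bandpass_filter(hb$hbr, recording$fs, low_cut, high_cut, order)
    filt <- list(applied = TRUE, low_cut = low_cut, high_cut = high_cut,
                 order = order, scheme = "zero-phase Butterworth cascade")
  }
  structure(list(time = recording$time, hbo = hb$hbo, hbr = hb$hbr,
                 fs = recording$fs, schedule = recording$schedule,
                 filtered = filt),
            class = "fnirs_hemo")
}

#' @export
print.fnirs_hemo <- function(x, ...) {
  cat(sprintf("fNIRS hemoglobin series: %d samples x %d channels at %g Hz (%s)\n",
              nrow(x$hbo), ncol(x$hbo), x$fs,
              if (isTRUE(x$filtered$applied))
                sprintf("band-pass %g-%g Hz", x$filtered$low_cut,
                        x$filtered$high_cut)
              else "unfiltered"))
  invisible(x)
}
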