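# Synthetic fNIRS cohort generator. Every subject is built from known ground
# truth (evoked amplitude, latent background connectivity, physiological
# noise) and pushed through the forward modified Beer-Lambert model, so the
# whole analysis chain can be validated without clinical recordings.

#' Physiological noise specification
#'
#' Amplitudes (micromolar) and frequencies (Hz) of the nuisance components
#' added to the simulated hemoglobin signal: cardiac and respiratory
#' oscillations (outside the 0.026-0.15 Hz analysis band, hence removed by
#' the band-pass filter), a small Mayer-wave oscillation (inside the band, a
#' genuine confound kept small), a low-frequency random-walk drift and white
#' measurement noise.
#'
#' @param cardiac,respiration,mayer `c(frequency_hz, amplitude_um)` pairs.
#' @param drift random-walk scale, micromolar per sqrt(second).
#' @param white white-noise standard deviation, micromolar.
#' @return An object of class `fnirs_noise_spec`.
#' @export
noise_spec <- function(cardiac = c(1.1, 0.2), respiration = c(0.25, 0.1),
                       mayer = c(0.1, 0.02), drift = 0.01, white = 0.05) {
  spec <- list(cardiac = cardiac, respiration = respiration, mayer = mayer,
               drift = drift, white = white)
  for (nm in c("cardiac", "respiration", "mayer")) {
    v <- spec[[nm]]
    if (length(v) != 2L || v[1] <= 0 || v[2] < 0) {
      stop(sprintf("`%s` must be c(frequency > 0, amplitude >= 0)", nm),
           call. = FALSE)
    }
  }
  if (drift < 0 || white < 0) {
    stop("`drift` and `white` must be non-negative", call. = FALSE)
  }
  structure(spec, class = "fnirs_noise_spec")
}

zero_noise_spec <- function() {
  noise_spec(cardiac = c(1.1, 0), respiration = c(0.25, 0),
             mayer = c(0.1, 0), drift = 0, white = 0)
}

#' Block-structured latent connectivity matrix
#'
#' Target background correlation matrix with two hemispheric blocks:
#' `within` correlation inside each block and `between` across blocks
#' (unit diagonal). Positive semi-definite for the default sizes whenever
#' `between <= within < 1`.
#'
#' @param n number of channels.
#' @param within,between correlations inside / across the two blocks.
#' @param blocks list of two channel-index vectors (default: first and
#'   second half).
#' @return n x n correlation matrix.
#' @export
block_connectivity <- function(n = 20, within = 0.6, between = 0.3,
                               blocks = NULL) {
  if (is.null(blocks)) {
    half <- ceiling(n / 2)
    blocks <- list(seq_len(half), seq(half + 1, n))
  }
  L <- matrix(between, n, n)
  for (b in blocks) L[b, b] <- within
  diag(L) <- 1
  L
}

#' Latent connectivity with progressively decoupled channels
#'
#' Target background correlation matrix for a cohort with channel-level
#' functional decoupling: a uniformly connected core (`core` correlation)
#' from which `n_decoupled` channels have detached. Decoupled channels keep
#' moderate mutual coherence (`weak`) but correlate only weakly (`attach`)
#' with the core. With zero decoupled channels the matrix is uniformly
#' integrated.
#'
#' @param n number of channels.
#' @param n_decoupled how many channels (taken from the end of the channel
#'   list, i.e. the most lateral positions of the default montage) have
#'   decoupled from the core.
#' @param core,weak,attach correlations of core pairs, decoupled-decoupled
#'   pairs and decoupled-core pairs.
#' @return n x n correlation matrix.
#' @export
decoupled_connectivity <- function(n = 20, n_decoupled = 0, core = 0.6,
                                   weak = 0.45, attach = 0.1) {
  L <- matrix(core, n, n)
  if (n_decoupled > 0) {
    W <- seq(n - n_decoupled + 1, n)
    L[W, ] <- attach
    L[, W] <- attach
    L[W, W] <- weak
  }
  diag(L) <- 1
  L
}

#' Group simulation profile
#'
#' Bundles the ground-truth quantities of one cohort group: the task-evoked
#' dHbO peak amplitude on the active channels, the latent background
#' connectivity, the background signal level and the physiological noise.
#' The four default profiles ([default_profiles()]) encode the cohort
#' ordering healthy controls > MCI after a first treatment course > MCI
#' after a second course > untreated MCI, in both evoked amplitude and
#' cross-hemispheric background connectivity.
#'
#' @param label group identifier (e.g. `"HC"`, `"MCI-0"`).
#' @param activation_amplitude mean task-evoked dHbO peak on active
#'   channels, micromolar (>= 0).
#' @param active_channels channel indices carrying the evoked response.
#' @param latent_connectivity target channel x channel correlation matrix of
#'   the background signal (symmetric, unit diagonal, positive
#'   semi-definite).
#' @param background_sd standard deviation of the in-band background signal
#'   per channel, micromolar.
#' @param amplitude_sd between-subject SD of the evoked amplitude,
#'   micromolar.
#' @param noise an [noise_spec()] object.
#' @return An object of class `fnirs_group_profile`.
#' @export
group_profile <- function(label, activation_amplitude,
                          active_channels = 6:13,
                          latent_connectivity = block_connectivity(),
                          background_sd = 0.15, amplitude_sd = 0.05,
                          noise = noise_spec()) {
  if (activation_amplitude < 0) {
    stop("`activation_amplitude` must be >= 0", call. = FALSE)
  }
  check_latent(latent_connectivity)
  stopifnot(inherits(noise, "fnirs_noise_spec"))
  structure(list(label = label,
                 activation_amplitude = activation_amplitude,
                 active_channels = active_channels,
                 latent_connectivity = latent_connectivity,
                 background_sd = background_sd,
                 amplitude_sd = amplitude_sd,
                 noise = noise),
            class = "fnirs_group_profile")
}

check_latent <- function(L) {
  if (!is_symmetric_matrix(L)) {
    stop("`latent_connectivity` must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(L) - 1)) > 1e-8) {
    stop("`latent_connectivity` must have unit diagonal", call. = FALSE)
  }
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("`latent_connectivity` must be positive semi-definite", call. = FALSE)
  }
  invisible(L)
}

#' Default cohort group profiles
#'
#' The four study-like groups with graded evoked amplitude and graded
#' channel decoupling of the background connectivity
#' ([decoupled_connectivity()]). Evoked dHbO peak amplitudes: HC 0.40,
#' MCI-1 0.30, MCI-2 0.20, MCI-0 0.10 uM. Latent connectivity: HC is
#' uniformly integrated (core r = 0.6, no decoupled channels); the MCI
#' grades lose lateral channels from the core progressively (MCI-1 one,
#' MCI-2 two, untreated MCI-0 three decoupled channels), so mean
#' connectivity strength and network integration (global efficiency of the
#' thresholded network) both follow MCI-0 < MCI-2 < MCI-1 < HC.
#'
#' @return Named list of [group_profile()] objects.
#' @export
default_profiles <- function() {
  mk <- function(label, amp, ndec) {
    group_profile(label, amp,
                  latent_connectivity = decoupled_connectivity(n_decoupled = ndec))
  }
  list(`HC` = mk("HC", 0.40, 0),
       `MCI-1` = mk("MCI-1", 0.30, 1),
       `MCI-2` = mk("MCI-2", 0.20, 2),
       `MCI-0` = mk("MCI-0", 0.10, 3))
}

# Correlated hemodynamic background: white noise coloured by a symmetric
# square root of the latent correlation matrix, smoothed into a broad
# low-frequency-oscillation band (0.01-0.5 Hz). The same filter is applied
# to every channel, so the target cross-channel correlations are preserved
# exactly. Channels are rescaled so that the background's standard
# deviation *within the 0.026-0.15 Hz analysis band* equals `sd_target`.
simulate_background <- function(n, L, sd_target, fs) {
  C <- nrow(L)
  if (sd_target == 0) return(matrix(0, n, C))
  ev <- eigen(L, symmetric = TRUE)
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  B <- matrix(rnorm(n * C), n, C) %*% root
  B <- bandpass_filter(B, fs, low_cut = 0.01, high_cut = min(0.5, fs / 2.5),
                       order = 2)
  inband <- bandpass_filter(B, fs)
  sds <- apply(inband, 2, sd)
  sds[sds == 0] <- 1
  sweep(B, 2, sd_target / sds, "*")
}

simulate_nuisance <- function(n, fs, spec) {
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  for (nm in c("cardiac", "respiration", "mayer")) {
    f <- spec[[nm]][1]; a <- spec[[nm]][2]
    if (a > 0) out <- out + a * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  }
  if (spec$drift > 0) {
    out <- out + cumsum(rnorm(n, 0, spec$drift / sqrt(fs)))
  }
  if (spec$white > 0) out <- out + rnorm(n, 0, spec$white)
  out
}

#' Simulate one subject's two-wavelength fNIRS recording
#'
#' Generates ground-truth dHbO/dHbR time series (evoked response + correlated
#' in-band background + physiological noise) for the given group profile and
#' schedule, and maps them through the forward modified Beer-Lambert model
#' to raw light intensities at 760/850 nm (unit baseline intensity). The
#' evoked dHbO component is `amplitude * dHRF` on the active channels; the
#' evoked dHbR component is -1/3 of it, plus independent noise. Identical
#' `(profile, seed)` yield bit-identical recordings.
#'
#' @param profile a [group_profile()].
#' @param montage an `fnirs_montage`; channel count must match the latent
#'   connectivity.
#' @param schedule an `fnirs_schedule`.
#' @param fs sampling rate, Hz; must exceed twice the highest noise
#'   frequency.
#' @param seed RNG seed for this subject.
#' @param geometry optical constants for the forward model; defaults to the
#'   montage separations.
#' @return List with `recording` (class `fnirs_recording`: `time`,
#'   `intensity_lo`, `intensity_hi`, `fs`, `schedule`, `channels`) and
#'   `truth` (class `fnirs_ground_truth`: per-channel evoked `amplitude`,
#'   `latent_connectivity`, the evoked `regressor`, noiseless `hbo`/`hbr`
#'   and the `seed`).
#' @export
simulate_subject <- function(profile, montage = default_montage(),
                             schedule = make_default_schedule(), fs = 7.81,
                             seed = 1, geometry = NULL) {
  stopifnot(inherits(profile, "fnirs_group_profile"))
  stopifnot_scalar_pos(fs, "fs")
  if (nrow(schedule) == 0L) stop("empty schedule", call. = FALSE)
  fmax <- max(profile$noise$cardiac[1], profile$noise$respiration[1],
              profile$noise$mayer[1])
  if (fs <= 2 * fmax) {
    stop(sprintf("fs = %g Hz cannot represent noise at %g Hz", fs, fmax),
         call. = FALSE)
  }
  check_latent(profile$latent_connectivity)
  C <- nrow(profile$latent_connectivity)
  if (is.null(geometry)) {
    geometry <- default_geometry(separation = montage$channels$separation)
  }
  n <- round(attr(schedule, "total") * fs)
  time <- (seq_len(n) - 1) / fs
  dhrf <- build_dhrf(schedule, fs, n_samples = n)

  with_seed(seed, {
    amp_subj <- max(0, rnorm(1, profile$activation_amplitude,
                             profile$amplitude_sd))
    if (profile$activation_amplitude == 0) amp_subj <- 0
    amp <- numeric(C)
    amp[profile$active_channels] <- amp_subj
    evoked <- outer(dhrf$dhrf, amp)

    bg <- simulate_background(n, profile$latent_connectivity,
                              profile$background_sd, fs)
    nuis <- vapply(seq_len(C), function(ch)
      simulate_nuisance(n, fs, profile$noise), numeric(n))

    hbo <- evoked + bg + nuis
    # dHbR: -1/3 of the evoked response plus independent (scaled) noise
    bg_r <- simulate_background(n, diag(C), profile$background_sd / 3, fs)
    nuis_r <- vapply(seq_len(C), function(ch)
      simulate_nuisance(n, fs, profile$noise), numeric(n)) / 3
    hbr <- -evoked / 3 + bg_r + nuis_r

    od <- mbll_forward(hbo, hbr, geometry)
    labels <- channel_labels(C)
    ilo <- 10^(-od$od_lo); ihi <- 10^(-od$od_hi)
    colnames(ilo) <- colnames(ihi) <- labels

    recording <- structure(list(time = time, intensity_lo = ilo,
                                intensity_hi = ihi, fs = fs,
                                schedule = schedule, channels = labels,
                                wavelengths = geometry$wavelengths,
                                geometry = geometry),
                           class = "fnirs_recording")
    truth <- structure(list(amplitude = amp,
                            latent_connectivity = profile$latent_connectivity,
                            regressor = dhrf$dhrf, hbo = hbo, hbr = hbr,
                            evoked = evoked, background = bg, nuisance = nuis,
                            seed = seed, group = profile$label),
                       class = "fnirs_ground_truth")
    list(recording = recording, truth = truth)
  })
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf(
    "fNIRS recording: %d channels x %d samples at %g Hz, wavelengths %s nm\n",
    ncol(x$intensity_lo), length(x$time), x$fs,
    paste(x$wavelengths, collapse = "/")))
  invisible(x)
}

#' Simulate a cohort of subjects across groups
#'
#' Draws `n_per_group` independent subjects for every group profile, with
#' per-subject seeds derived deterministically from the master seed, the
#' group label and the subject index.
#'
#' @param profiles list of [group_profile()] objects with distinct labels.
#' @param n_per_group subjects per group (>= 2).
#' @inheritParams simulate_subject
#' @return An object of class `fnirs_cohort`: list with `subjects` (list of
#'   `simulate_subject()` results), `manifest` (data frame: subject_id,
#'   group, subject_index, seed) and the simulation parameters.
#' @export
simulate_cohort <- function(profiles, n_per_group = 11,
                            montage = default_montage(),
                            schedule = make_default_schedule(), fs = 7.81,
                            seed = 1) {
  labels <- vapply(profiles, function(p) p$label, "")
  if (anyDuplicated(labels)) {
    stop("duplicate group labels in `profiles`", call. = FALSE)
  }
  if (n_per_group < 2) stop("`n_per_group` must be >= 2", call. = FALSE)
  subjects <- list()
  manifest <- NULL
  for (p in profiles) {
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", p$label, i)
      s <- derive_seed(seed, p$label, i)
      subjects[[sid]] <- simulate_subject(p, montage, schedule, fs, seed = s)
      manifest <- rbind(manifest,
                        data.frame(subject_id = sid, group = p$label,
                                   subject_index = i, seed = s,
                                   stringsAsFactors = FALSE))
    }
  }
  structure(list(subjects = subjects, manifest = manifest, fs = fs,
                 master_seed = seed, montage = montage, schedule = schedule),
            class = "fnirs_cohort")
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("fNIRS synthetic cohort: %d subjects (%s), master seed %d\n",
              nrow(x$manifest),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              x$master_seed))
  invisible(x)
}
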