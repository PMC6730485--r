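# Plain-text serialization: recordings and schedules as TSV, matrices as
# labelled square TSV, provenance and manifests as JSON.

#' Write / read a raw recording as wide TSV
#'
#' One `time` column plus one column per channel and wavelength
#' (`ch01_w760`, `ch01_w850`, ...). Reading validates monotone,
#' duplicate-free timestamps and, when a montage is given, that every
#' montage channel is present (missing channels are reported by name).
#'
#' @param recording an `fnirs_recording`.
#' @param path file path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `fnirs_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "fnirs_recording"))
  wl <- recording$wavelengths
  lo <- recording$intensity_lo; hi <- recording$intensity_hi
  colnames(lo) <- sprintf("%s_w%d", recording$channels, wl[1])
  colnames(hi) <- sprintf("%s_w%d", recording$channels, wl[2])
  df <- data.frame(time = recording$time, lo, hi, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param montage optional `fnirs_montage` used to validate channel
#'   completeness.
#' @param schedule schedule to attach (default paradigm if omitted).
#' @export
read_recording <- function(path, montage = NULL, schedule = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- read.delim(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing `time` column", call. = FALSE)
  tm <- df$time
  if (anyDuplicated(tm)) {
    stop(sprintf("duplicated timestamp at row %d",
                 which(duplicated(tm))[1]), call. = FALSE)
  }
  if (any(diff(tm) <= 0)) {
    stop(sprintf("non-monotonic time at row %d", which(diff(tm) <= 0)[1] + 1L),
         call. = FALSE)
  }
  cols <- setdiff(names(df), "time")
  wl <- sort(unique(as.integer(sub(".*_w", "", cols))))
  if (length(wl) != 2L) stop("expected exactly two wavelengths", call. = FALSE)
  chans <- sort(unique(sub("_w\\d+$", "", cols)))
  if (!is.null(montage)) {
    expected <- channel_labels(nrow(montage$channels))
    missing <- setdiff(expected, chans)
    if (length(missing) > 0) {
      stop(sprintf("recording is missing montage channel(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    chans <- expected
  }
  lo <- as.matrix(df[sprintf("%s_w%d", chans, wl[1])])
  hi <- as.matrix(df[sprintf("%s_w%d", chans, wl[2])])
  colnames(lo) <- colnames(hi) <- chans
  fs <- 1 / median(diff(tm))
  if (is.null(schedule)) schedule <- make_default_schedule()
  structure(list(time = tm, intensity_lo = lo, intensity_hi = hi, fs = fs,
                 schedule = schedule, channels = chans, wavelengths = wl),
            class = "fnirs_recording")
}

#' Write / read an event schedule as three-column TSV
#'
#' Columns `onset`, `duration`, `condition` (seconds), the conventional
#' events-table layout.
#'
#' @param schedule an `fnirs_schedule`.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  write.table(as.data.frame(schedule), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- read.delim(path)
  stopifnot(all(c("onset", "duration", "condition") %in% names(df)))
  enc <- df$onset[df$condition == "encode"]
  rest_end <- if (length(enc)) min(enc) else max(df$onset + df$duration)
  task_len <- if (length(enc) && any(df$condition == "probe")) {
    max(df$onset[df$condition == "probe"] + df$duration[df$condition == "probe"]) -
      max(enc)
  } else 24
  trial_len <- if (length(enc) > 1) diff(enc)[1] else 38
  task_end <- if (length(enc)) max(enc) + trial_len else rest_end
  structure(df, rest_end = rest_end, task_start = rest_end,
            task_end = task_end, total = max(df$onset + df$duration),
            trial_length = trial_len, n_trials = length(enc),
            task_duration = task_len,
            class = c("fnirs_schedule", "data.frame"))
}

#' Write / read a connectivity matrix as labelled square TSV
#'
#' The matrix values go to `path`; kind, segment and threshold provenance go
#' to a JSON sidecar `<path>.json`.
#'
#' @param m an `fnirs_fc`.
#' @param path file path.
#' @export
write_fc_matrix <- function(m, path) {
  write.table(as.data.frame(unclass(m)), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  meta <- list(kind = attr(m, "kind"), segment = attr(m, "segment"),
               threshold = attr(m, "threshold"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list(kind = "r", segment = NA_character_, threshold = NULL)
  new_fc(m, kind = meta$kind, segment = meta$segment,
         threshold = meta$threshold)
}
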