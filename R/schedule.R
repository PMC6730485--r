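#' Build the working-memory block-paradigm event schedule
#'
#' Constructs the event schedule of the working-memory experiment: a resting
#' state, then `n_trials` trials each consisting of a task period
#' (encoding, retention, probe) followed by an inter-trial rest whose final
#' seconds carry the ready cue for the next trial, then a post-session rest.
#' The default arguments reproduce the working-memory protocol: a 4-min resting state,
#' nine 38-s trials (24 s task = 8 s encoding + 14 s retention + 2 s probe,
#' then 14 s rest with a 2-s ready cue at its end), and a 30-s post-rest, so
#' the task session lasts 342 s (5 min 42 s).
#'
#' @param rest resting-state duration before the task session, seconds.
#' @param n_trials number of working-memory trials.
#' @param encode,retain,probe durations of the trial task phases, seconds.
#' @param trial_rest inter-trial rest duration, seconds.
#' @param ready ready-cue duration, seconds; the cue occupies the last
#'   `ready` seconds of the rest preceding each task onset.
#' @param post_rest rest after the final trial, seconds.
#' @return An object of class `fnirs_schedule`: a data frame with columns
#'   `onset`, `duration`, `condition` (one of `rest`, `ready`, `encode`,
#'   `retain`, `probe`) and attributes `rest_end`, `task_start`, `task_end`,
#'   `total`, `trial_length`, `n_trials`, `task_duration`.
#' @examples
#' sched <- make_default_schedule()
#' attr(sched, "task_end") - attr(sched, "task_start") # 342 s
#' @export
build_schedule <- function(rest = 240, n_trials = 9, encode = 8, retain = 14,
                           probe = 2, trial_rest = 14, ready = 2,
                           post_rest = 30) {
  for (nm in c("rest", "n_trials", "encode", "retain", "probe", "trial_rest",
               "post_rest")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (ready < 0 || ready > trial_rest) {
    stop("`ready` must lie within the inter-trial rest", call. = FALSE)
  }
  task_len <- encode + retain + probe
  trial_len <- task_len + trial_rest
  onsets <- rest + trial_len * (seq_len(n_trials) - 1)

  rows <- list(data.frame(onset = 0, duration = rest, condition = "rest"))
  for (k in seq_len(n_trials)) {
    t0 <- onsets[k]
    rows[[length(rows) + 1L]] <- data.frame(
      onset = c(t0 - ready, t0, t0 + encode, t0 + encode + retain,
                t0 + task_len),
      duration = c(ready, encode, retain, probe, trial_rest),
      condition = c("ready", "encode", "retain", "probe", "rest")
    )
  }
  task_end <- rest + trial_len * n_trials
  rows[[length(rows) + 1L]] <-
    data.frame(onset = task_end, duration = post_rest, condition = "rest")
  sched <- do.call(rbind, rows)
  sched <- sched[order(sched$onset, sched$condition), , drop = FALSE]
  rownames(sched) <- NULL

  structure(sched,
            rest_end = rest, task_start = rest, task_end = task_end,
            total = task_end + post_rest, trial_length = trial_len,
            n_trials = n_trials, task_duration = task_len,
            class = c("fnirs_schedule", "data.frame"))
}

#' @rdname build_schedule
#' @export
make_default_schedule <- function() build_schedule()

#' Task-block onsets of a schedule
#'
#' Onsets (seconds) of the task periods, i.e. of the encoding phases.
#'
#' @param schedule an `fnirs_schedule`.
#' @return Numeric vector of onsets.
#' @export
task_onsets <- function(schedule) {
  stopifnot(inherits(schedule, "fnirs_schedule"))
  schedule$onset[schedule$condition == "encode"]
}

#' @export
print.fnirs_schedule <- function(x, ...) {
  cat(sprintf(
    "fNIRS event schedule: %gs resting state, %d trials of %gs (%gs task), task session %gs, total %gs\n",
    attr(x, "rest_end"), attr(x, "n_trials"), attr(x, "trial_length"),
    attr(x, "task_duration"), attr(x, "task_end") - attr(x, "task_start"),
    attr(x, "total")))
  print.data.frame(x, ...)
  invisible(x)
}
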