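#' Construct a continuous multichannel session recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts. Row order
#'   must match `channels$names`.
#' @param fs Sampling rate in Hz (default 508.6, the downsampled acquisition
#'   rate). Must exceed 400 Hz so that the 100-200 Hz band is resolvable.
#' @param channels A [channel_layout()].
#' @param session_id Character identifier.
#' @return An `ecog_session` object (list with `data`, `fs`, `channels`,
#'   `session_id`).
#' @examples
#' x <- matrix(rnorm(10 * 1000), nrow = 10)
#' s <- ecog_session(x, session_id = "demo")
#' s
#' @export
ecog_session <- function(data, fs = VIGI_FS, channels = channel_layout(),
                         session_id = "session") {
  data <- as.matrix(data)
  if (nrow(data) != length(channels$names)) {
    abort(sprintf("data has %d rows but the layout names %d channels",
                  nrow(data), length(channels$names)))
  }
  if (!all(is.finite(data))) {
    abort("session data contains non-finite samples")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 2 * 200) {
    abort("fs must be a single value > 400 Hz (the 100-200 Hz band must lie below Nyquist)")
  }
  rownames(data) <- channels$names
  structure(
    list(data = data, fs = fs, channels = channels,
         session_id = as.character(session_id)),
    class = "ecog_session"
  )
}

#' @export
print.ecog_session <- function(x, ...) {
  cat(sprintf("<ecog_session> '%s': %d channels x %d samples @ %.1f Hz (%.1f s)\n",
              x$session_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.ecog_session <- function(x) dim(x$data)

session_duration <- function(session) ncol(session$data) / session$fs

# sample index (1-based) of a time in seconds; times are stored in seconds
# and converted by round(t * fs), the single indexing convention used
# throughout the package
time_to_sample <- function(t, fs) round(t * fs) + 1L

EVENT_COLUMNS <- c("trial_id", "t_trial_start", "t_target_on", "t_delay_cue",
                   "t_go", "t_response", "delay_ms", "outcome",
                   "target_location")

#' Validate a trial event table
#'
#' Checks the per-trial event tibble against the task structure: each trial
#' must satisfy `t_trial_start <= t_target_on < t_delay_cue < t_go`, have a
#' positive delay, and an outcome of `"correct"` or `"incorrect"`.
#' `t_response` may be `NA` (e.g. no-response incorrect trials).
#'
#' @param events A data frame with columns `trial_id`, `t_trial_start`,
#'   `t_target_on`, `t_delay_cue`, `t_go`, `t_response` (seconds from session
#'   start), `delay_ms`, `outcome`, `target_location`.
#' @param session Optional [ecog_session()]; when given, event times are also
#'   checked against the recording length.
#' @return The validated events as a tibble (invisibly usable in pipes).
#' @export
validate_events <- function(events, session = NULL) {
  events <- tibble::as_tibble(events)
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("events table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_order <- events$trial_id[!(events$t_trial_start <= events$t_target_on &
                                   events$t_target_on < events$t_delay_cue &
                                   events$t_delay_cue < events$t_go)]
  if (length(bad_order) > 0) {
    abort(paste0("event times violate trial ordering (t_trial_start <= ",
                 "t_target_on < t_delay_cue < t_go) for trial_id: ",
                 paste(bad_order, collapse = ", ")))
  }
  if (any(events$delay_ms <= 0)) {
    abort(paste0("non-positive delay_ms for trial_id: ",
                 paste(events$trial_id[events$delay_ms <= 0], collapse = ", ")))
  }
  bad_outcome <- !events$outcome %in% c("correct", "incorrect") &
    !is.na(events$outcome)
  if (any(bad_outcome)) {
    abort(paste0("outcome must be 'correct' or 'incorrect'; offending trial_id: ",
                 paste(events$trial_id[bad_outcome], collapse = ", ")))
  }
  if (!is.null(session)) {
    dur <- session_duration(session)
    beyond <- events$trial_id[events$t_go > dur |
                                (!is.na(events$t_response) & events$t_response > dur)]
    if (length(beyond) > 0) {
      abort(paste0("event times beyond recording end (", round(dur, 3),
                   " s) for trial_id: ", paste(beyond, collapse = ", ")))
    }
  }
  events
}
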