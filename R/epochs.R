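#' Extract per-trial analysis epochs
#'
#' Three evaluation periods are defined relative to the task events:
#' `"delay"` starts at the delay-cue onset (the main analysis window),
#' `"target"` starts at target onset (always 1 s), and `"pre_target"` is a
#' fixed-length window ending at target onset. Windows are half-open sample
#' ranges `[start, start + n)` with `start = round(t * fs)` (0-based);
#' every epoch has exactly `round(window_s * fs)` samples.
#'
#' Trials whose window would overrun the recording, and trials with a missing
#' outcome, are dropped; the dropped counts are attached as attributes
#' (`n_dropped_overrun`, `n_dropped_no_outcome`) and reported via a message.
#'
#' @param session An [ecog_session()].
#' @param events Validated event tibble.
#' @param period One of `"pre_target"`, `"target"`, `"delay"`.
#' @param window_s Window length in seconds, `1.0` or `0.5`. The target
#'   period always uses 1 s.
#' @return A tibble with one row per retained trial: `trial_id`, `outcome`,
#'   `period`, `window_s`, and a list-column `signal` of channels x samples
#'   matrices sliced (bit-for-bit) from the session.
#' @examples
#' s <- ecog_session(matrix(rnorm(10 * 12000), 10), session_id = "demo")
#' ev <- tibble::tibble(trial_id = 1:2, t_trial_start = c(0, 10),
#'   t_target_on = c(1.5, 11.5), t_delay_cue = c(2.5, 12.5),
#'   t_go = c(5, 15), t_response = c(5.3, NA), delay_ms = 2500,
#'   outcome = c("correct", "incorrect"), target_location = c(3L, 7L))
#' ep <- extract_epochs(s, ev, "delay", 1.0)
#' @export
extract_epochs <- function(session, events,
                           period = c("delay", "target", "pre_target"),
                           window_s = 1.0) {
  period <- match.arg(period)
  if (!window_s %in% c(0.5, 1.0)) {
    abort("window_s must be 0.5 or 1.0")
  }
  if (period == "target") window_s <- 1.0
  events <- validate_events(events, session)
  fs <- session$fs
  n_win <- as.integer(round(window_s * fs))
  n_total <- ncol(session$data)

  no_outcome <- is.na(events$outcome)
  events_kept <- events[!no_outcome, , drop = FALSE]

  t_anchor <- switch(period,
    delay = events_kept$t_delay_cue,
    target = events_kept$t_target_on,
    pre_target = events_kept$t_target_on - window_s
  )
  start0 <- round(t_anchor * fs) # 0-based start sample
  overrun <- start0 < 0 | (start0 + n_win) > n_total
  n_over <- sum(overrun)
  if (n_over > 0 || any(no_outcome)) {
    message(sprintf("extract_epochs: dropped %d trial(s) with window overrun, %d with missing outcome",
                    n_over, sum(no_outcome)))
  }
  events_kept <- events_kept[!overrun, , drop = FALSE]
  start0 <- start0[!overrun]

  signal <- purrr::map(start0, function(s0) {
    session$data[, (s0 + 1):(s0 + n_win), drop = FALSE]
  })
  out <- tibble::tibble(
    trial_id = events_kept$trial_id,
    outcome = events_kept$outcome,
    period = period,
    window_s = window_s,
    signal = signal
  )
  attr(out, "fs") <- fs
  attr(out, "channels") <- session$channels
  attr(out, "session_id") <- session$session_id
  attr(out, "n_dropped_overrun") <- n_over
  attr(out, "n_dropped_no_outcome") <- sum(no_outcome)
  out
}
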