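test_that("channel layout and session containers enforce their invariants", {
  cl <- channel_layout()
  expect_length(cl$names, 10)
  expect_true(all(cl$artifact_reference %in% cl$frontal))
  expect_error(channel_layout(names = c("A", "A", "B")), "unique")
  expect_error(channel_layout(artifact_reference = "LO"), "frontal")

  expect_error(ecog_session(matrix(0, 9, 100)), "9 rows")
  bad <- matrix(0, 10, 100); bad[3, 7] <- NA
  expect_error(ecog_session(bad), "non-finite")
  expect_error(ecog_session(matrix(0, 10, 100), fs = 250), "Nyquist")
})

test_that("event validation reports offending trials", {
  ns <- noise_session_with_events()
  expect_silent(validate_events(ns$events, ns$session))
  ev <- ns$events
  ev$t_go[2] <- ev$t_delay_cue[2] - 0.1
  expect_error(validate_events(ev), "trial_id: 2")
  ev2 <- ns$events
  ev2$outcome[3] <- "meh"
  expect_error(validate_events(ev2), "trial_id: 3")
  ev3 <- ns$events
  ev3$t_go[1] <- 1e5
  expect_error(validate_events(ev3, ns$session), "beyond recording")
})

test_that("feather container round-trips losslessly and EDF to 16-bit accuracy", {
  g <- tiny_session()
  td <- withr::local_tempdir()
  p <- write_session(g$session, g$events, td, format = "feather")
  r <- read_session(p$signal_path, p$events_path)
  expect_lt(max(abs(r$session$data - g$session$data)) /
              max(abs(g$session$data)), 1e-6)
  expect_equal(r$session$fs, g$session$fs)
  expect_equal(as.data.frame(r$events), as.data.frame(g$events))

  p2 <- write_session(g$session, g$events, td, format = "edf")
  r2 <- read_session(p2$signal_path, p2$events_path)
  n <- ncol(g$session$data)
  # 16-bit quantization: error bounded by one digitization step
  step <- max(abs(g$session$data)) * 1.0001 * 2 / 65535
  expect_lt(max(abs(r2$session$data[, 1:n] - g$session$data)), 1.5 * step)
  expect_equal(r2$session$fs, g$session$fs)
})

test_that("reader normalizes channel order and names missing channels", {
  g <- tiny_session()
  td <- withr::local_tempdir()
  p <- write_session(g$session, g$events, td, format = "feather")
  # scramble channel order on disk
  df <- arrow::read_feather(p$signal_path)
  arrow::write_feather(df[, rev(names(df))], p$signal_path)
  r <- read_session(p$signal_path, p$events_path)
  expect_equal(rownames(r$session$data), channel_layout()$names)
  expect_equal(r$session$data["CZ", 1:50], g$session$data["CZ", 1:50])

  arrow::write_feather(df[, 1:8], p$signal_path)
  expect_error(read_session(p$signal_path, p$events_path), "missing channel")
})

test_that("epoch windows have the exact sample count and are pure slices", {
  ns <- noise_session_with_events(n_trials = 4)
  fs <- ns$session$fs
  ep1 <- extract_epochs(ns$session, ns$events, "delay", 1.0)
  expect_true(all(vapply(ep1$signal, ncol, integer(1)) == round(1.0 * fs)))
  ep2 <- extract_epochs(ns$session, ns$events, "delay", 0.5)
  expect_true(all(vapply(ep2$signal, ncol, integer(1)) == round(0.5 * fs)))
  expect_equal(round(1.0 * 508.6), 509)
  expect_equal(round(0.5 * 508.6), 254)

  # index arithmetic oracle: window starts at round(t * fs), 0-based
  for (i in seq_len(nrow(ep1))) {
    s0 <- round(ns$events$t_delay_cue[i] * fs)
    expect_identical(ep1$signal[[i]],
                     ns$session$data[, (s0 + 1):(s0 + 509), drop = FALSE])
  }

  # pre-target window ends at target onset
  ep3 <- extract_epochs(ns$session, ns$events, "pre_target", 1.0)
  s0 <- round((ns$events$t_target_on[1] - 1.0) * fs)
  expect_identical(ep3$signal[[1]],
                   ns$session$data[, (s0 + 1):(s0 + 509), drop = FALSE])

  expect_error(extract_epochs(ns$session, ns$events, "cue", 1.0))
})

test_that("epoch extraction preserves labels and drops/logs bad trials", {
  ns <- noise_session_with_events(n_trials = 5)
  ep <- extract_epochs(ns$session, ns$events, "delay", 1.0)
  expect_equal(sort(table(ep$outcome)), sort(table(ns$events$outcome)))

  # a trial whose window overruns the recording is dropped and counted
  ev <- ns$events
  ev$t_delay_cue[5] <- ncol(ns$session$data) / ns$session$fs + 2
  ev$t_go[5] <- ev$t_delay_cue[5] + 2.5
  ev$t_response[5] <- NA
  expect_error(validate_events(ev, ns$session), "beyond recording")
  ev$t_go[5] <- ncol(ns$session$data) / ns$session$fs - 0.1
  ev$t_delay_cue[5] <- ev$t_go[5] - 0.05
  ep2 <- suppressMessages(extract_epochs(ns$session, ev, "delay", 1.0))
  expect_equal(nrow(ep2), 4)
  expect_equal(attr(ep2, "n_dropped_overrun"), 1)

  # missing outcome excluded and counted
  ev3 <- ns$events
  ev3$outcome[2] <- NA
  ep3 <- suppressMessages(extract_epochs(ns$session, ev3, "delay", 1.0))
  expect_equal(nrow(ep3), 4)
  expect_equal(attr(ep3, "n_dropped_no_outcome"), 1)

  # target period forces the 1-s window
  ep4 <- extract_epochs(ns$session, ns$events, "target", 0.5)
  expect_true(all(vapply(ep4$signal, ncol, integer(1)) == 509))
})
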