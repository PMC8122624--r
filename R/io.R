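#' Write a session recording and its events to disk
#'
#' Two on-disk signal formats are supported: 16-bit EDF (interchange with
#' standard neurophysiology viewers; quantized to the per-channel physical
#' range) and a lossless float64 Feather container (an Arrow file of one
#' column per channel plus a JSON sidecar holding the sampling rate, channel
#' layout and session id). Events are written as a TSV with the canonical
#' column header (see [validate_events()]).
#'
#' @param session An [ecog_session()].
#' @param events Trial event tibble (validated before writing).
#' @param dir Output directory (created if absent).
#' @param format `"feather"` (lossless, default) or `"edf"` (16-bit).
#' @return Invisibly, a named list with `signal_path` and `events_path`.
#' @seealso [read_session()]
#' @export
write_session <- function(session, events, dir, format = c("feather", "edf")) {
  format <- match.arg(format)
  events <- validate_events(events)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- session$session_id
  signal_path <- file.path(dir, paste0(id, if (format == "edf") ".edf" else ".feather"))
  if (format == "edf") {
    write_edf(session, signal_path)
  } else {
    write_feather_session(session, signal_path)
  }
  events_path <- file.path(dir, paste0(id, "_events.tsv"))
  readr::write_tsv(events[, EVENT_COLUMNS], events_path, progress = FALSE)
  invisible(list(signal_path = signal_path, events_path = events_path))
}

#' Read a session recording and its events
#'
#' The signal format is chosen by file extension (`.edf` or `.feather`).
#' Channel rows are reordered to the requested layout; a channel missing from
#' the file is an error naming it. Event times are validated against the
#' recording length.
#'
#' @param signal_path Path to the `.edf` or `.feather` signal file.
#' @param events_path Path to the events TSV.
#' @param channels Expected [channel_layout()].
#' @return A list with elements `session` ([ecog_session()]) and `events`
#'   (tibble).
#' @export
read_session <- function(signal_path, events_path, channels = channel_layout()) {
  if (!file.exists(signal_path)) {
    abort(paste0("signal file not found: ", signal_path))
  }
  if (!file.exists(events_path)) {
    abort(paste0("events file not found: ", events_path))
  }
  ext <- tolower(tools::file_ext(signal_path))
  raw <- switch(ext,
    edf = read_edf(signal_path),
    feather = read_feather_session(signal_path),
    abort(paste0("unsupported signal format '.", ext, "' (use .edf or .feather)"))
  )
  missing_ch <- setdiff(channels$names, rownames(raw$data))
  if (length(missing_ch) > 0) {
    abort(paste0("signal file is missing channel(s): ",
                 paste(missing_ch, collapse = ", ")))
  }
  data <- raw$data[channels$names, , drop = FALSE]
  session <- ecog_session(data, fs = raw$fs, channels = channels,
                          session_id = raw$session_id)
  events <- read_events(events_path)
  events <- validate_events(events, session)
  list(session = session, events = events)
}

#' Read a trial events TSV
#'
#' @param path Path to a TSV with the canonical event columns.
#' @return Events tibble.
#' @export
read_events <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE,
                  col_types = readr::cols(
                    trial_id = readr::col_integer(),
                    t_trial_start = readr::col_double(),
                    t_target_on = readr::col_double(),
                    t_delay_cue = readr::col_double(),
                    t_go = readr::col_double(),
                    t_response = readr::col_double(),
                    delay_ms = readr::col_double(),
                    outcome = readr::col_character(),
                    target_location = readr::col_integer()
                  ))
}

## ---- Feather container -----------------------------------------------------

write_feather_session <- function(session, path) {
  df <- as.data.frame(t(session$data))
  names(df) <- session$channels$names
  arrow::write_feather(df, path)
  meta <- list(fs = session$fs, session_id = session$session_id,
               channels = session$channels$names,
               frontal = session$channels$frontal,
               artifact_reference = session$channels$artifact_reference)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_feather_session <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    abort(paste0("feather sidecar not found: ", meta_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- arrow::read_feather(path)
  data <- t(as.matrix(as.data.frame(df)))
  rownames(data) <- names(df)
  list(data = data, fs = meta$fs, session_id = meta$session_id)
}

## ---- EDF (16-bit) ----------------------------------------------------------

# record duration giving an integer samples-per-record; 5 s at 508.6 Hz
edf_record_duration <- function(fs) {
  for (d in 1:10) {
    if (abs(fs * d - round(fs * d)) < 1e-9) return(d)
  }
  abort(sprintf("no record duration in 1..10 s gives integer samples at fs = %g", fs))
}

edf_field <- function(x, width) {
  s <- strtrim(as.character(x), width)
  sprintf(paste0("%-", width, "s"), s)
}

write_edf <- function(session, path) {
  data <- session$data
  fs <- session$fs
  nc <- nrow(data)
  dur <- edf_record_duration(fs)
  spr <- as.integer(round(fs * dur))
  n_rec <- ceiling(ncol(data) / spr)
  pad <- n_rec * spr - ncol(data)
  if (pad > 0) data <- cbind(data, matrix(0, nc, pad))

  # physical range strings are written first and re-parsed, so that the
  # scaling used for quantization is exactly the scaling a reader recovers
  pmax_num <- apply(abs(data), 1, max)
  pmax_num <- ifelse(pmax_num <= 0, 1, pmax_num * 1.0001)
  pmax_str <- vapply(pmax_num, function(v)
    strtrim(formatC(signif(v, 6), format = "g", digits = 6), 8), character(1))
  pmax_used <- as.numeric(pmax_str)
  pmin_str <- vapply(pmax_used, function(v)
    strtrim(formatC(-v, format = "g", digits = 6), 8), character(1))
  pmin_used <- as.numeric(pmin_str)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(session$session_id, 80),
    edf_field("vigimark ECoG", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (1 + nc), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(dur, 8),
    edf_field(nc, 4)
  )
  sig_hdr <- paste0(
    paste0(vapply(session$channels$names, edf_field, character(1), width = 16), collapse = ""),
    paste0(rep(edf_field("", 80), nc), collapse = ""),
    paste0(rep(edf_field("uV", 8), nc), collapse = ""),
    paste0(vapply(pmin_str, edf_field, character(1), width = 8), collapse = ""),
    paste0(vapply(pmax_str, edf_field, character(1), width = 8), collapse = ""),
    paste0(rep(edf_field(-32768, 8), nc), collapse = ""),
    paste0(rep(edf_field(32767, 8), nc), collapse = ""),
    paste0(rep(edf_field("", 80), nc), collapse = ""),
    paste0(rep(edf_field(spr, 8), nc), collapse = ""),
    paste0(rep(edf_field("", 32), nc), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  scale <- (pmax_used - pmin_used) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(nc)) {
      d <- round((data[ch, idx] - pmin_used[ch]) / scale[ch]) - 32768
      d <- pmin(pmax(d, -32768), 32767)
      writeBin(as.integer(d), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  session_id <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  rdv <- function(width) {
    vapply(seq_len(nc), function(i) trimws(rd(width)), character(1))
  }
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) {
    abort("EDF with mixed per-signal sampling rates is not supported")
  }
  spr <- spr[1]
  fs <- spr / dur
  data <- matrix(0, nc, n_rec * spr)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(nc)) {
      d <- readBin(con, integer(), n = spr, size = 2, endian = "little",
                   signed = TRUE)
      data[ch, idx] <- pmin[ch] + (d - dmin[ch]) * scale[ch]
    }
  }
  rownames(data) <- labels
  list(data = data, fs = fs, session_id = session_id)
}

## ---- Ground truth ----------------------------------------------------------

#' Write / read synthetic-session ground truth as JSON
#'
#' @param gt A `vigi_ground_truth` object from [generate_session()].
#' @param path Output JSON path.
#' @return `path`, invisibly (`read_ground_truth()` returns the list).
#' @export
write_ground_truth <- function(gt, path) {
  out <- unclass(gt)
  out$trials <- as.data.frame(out$trials)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$trials <- tibble::as_tibble(gt$trials)
  class(gt) <- "vigi_ground_truth"
  gt
}
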