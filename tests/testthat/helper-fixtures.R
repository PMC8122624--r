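# Shared fixtures built in code. Small sessions are cheap to regenerate;
# anything reused across tests in one file is memoised in .fixture_env.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  got <- .fixture_env[[key]]
  if (!is.null(got)) return(got)
  val <- force(expr)
  .fixture_env[[key]] <- val
  val
}

# a tiny deterministic session for structural tests
tiny_session <- function(n_trials = 22, seed = 13, ...) {
  memo(paste0("tiny_", n_trials, "_", seed, "_",
              paste(deparse(substitute(list(...))), collapse = "")),
       generate_session(generator_config(n_trials = n_trials, seed = seed,
                                         ...)))
}

# hand-built event table around a plain-noise session
noise_session_with_events <- function(n_trials = 3, fs = 508.6, seed = 1) {
  dur <- n_trials * 8 + 4
  set.seed(seed)
  s <- ecog_session(matrix(rnorm(10 * ceiling(dur * fs)), 10),
                    fs = fs, session_id = "noise")
  k <- seq_len(n_trials)
  ev <- tibble::tibble(
    trial_id = k,
    t_trial_start = (k - 1) * 8 + 0.5,
    t_target_on = (k - 1) * 8 + 2,
    t_delay_cue = (k - 1) * 8 + 3,
    t_go = (k - 1) * 8 + 5.5,
    t_response = (k - 1) * 8 + 5.8,
    delay_ms = 2500,
    outcome = rep(c("correct", "incorrect"), length.out = n_trials),
    target_location = rep(1L, n_trials)
  )
  list(session = s, events = ev)
}

# feature table of pure noise with the full registry attached; optionally a
# perfectly separating column or constant channels
fake_features <- function(n = 60, seed = 1, p_incorrect = 0.5,
                          separator = NULL, constant_channel = NULL) {
  reg <- feature_registry()
  set.seed(seed)
  y <- rbinom(n, 1, p_incorrect)
  m <- matrix(rnorm(n * nrow(reg)), n, nrow(reg),
              dimnames = list(NULL, reg$column))
  if (!is.null(separator)) {
    m[, separator] <- y + rnorm(n, sd = 0.01)
  }
  if (!is.null(constant_channel)) {
    cols <- reg$column[!is.na(reg$channel) & reg$single_channel &
                         reg$channel == constant_channel]
    m[, cols] <- 1
  }
  ft <- dplyr::bind_cols(
    tibble::tibble(trial_id = seq_len(n),
                   outcome = ifelse(y == 1, "incorrect", "correct")),
    tibble::as_tibble(m)
  )
  attr(ft, "registry") <- reg
  attr(ft, "session_id") <- "fake"
  attr(ft, "period") <- "delay"
  attr(ft, "window_s") <- 1.0
  ft
}

# brute-force best-threshold boosting stump with the xgboost gain criterion
# (lambda = 1, hessian 0.25 per sample at base probability 0.5,
# min_child_weight = 1); independent oracle for the single-tree model
stump_oracle <- function(x, y, eta = 0.3, lambda = 1) {
  g <- 0.5 - y
  h <- rep(0.25, length(y))
  ord <- order(x)
  xs <- x[ord]; gs <- g[ord]; hs <- h[ord]
  G <- sum(g); H <- sum(h)
  best <- list(gain = 0, split = NA)
  cg <- cumsum(gs); chs <- cumsum(hs)
  for (i in seq_len(length(y) - 1)) {
    if (xs[i] == xs[i + 1]) next
    GL <- cg[i]; HL <- chs[i]; GR <- G - GL; HR <- H - HL
    if (HL < 1 || HR < 1) next
    gain <- GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - G^2 / (H + lambda)
    if (gain > best$gain) {
      best <- list(gain = gain, split = (xs[i] + xs[i + 1]) / 2,
                   wl = -GL / (HL + lambda), wr = -GR / (HR + lambda))
    }
  }
  if (is.na(best$split)) {
    w <- -G / (H + lambda)
    return(rep(plogis(eta * w), length(y)))
  }
  ifelse(x < best$split, plogis(eta * best$wl), plogis(eta * best$wr))
}

delay_epoch_power <- function(x, events, band, chn, fs) {
  ep <- extract_epochs(x, events, "delay", 1.0)
  vapply(ep$signal, function(s) band_power(s[chn, ], band, fs), numeric(1))
}
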