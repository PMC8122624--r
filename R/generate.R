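# Synthetic vigilance-task sessions: continuous 10-channel signals, a trial
# event table, and per-trial ground truth for every injected effect.

# run code under a temporary RNG state so generation is reproducible without
# disturbing the caller's random stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic session generator configuration
#'
#' Defaults encode the study conditions the analysis assumes: ~300-trial
#' sessions at 508.6 Hz, delay durations drawn from N(2500 ms, 250 ms)
#' truncated at 500 ms, a latent fatigue random walk that raises the
#' incorrect rate over the session, and four injectable effects that appear
#' on incorrect trials during the delay period: a 1-10 Hz power gain, a
#' wavelet-entropy drop (attenuation of >14 Hz content, concentrating
#' relative energy in the lowest subband), a directed low-band AR coupling
#' added between two channels (FZ -> CZ), and saccade-like biphasic frontal
#' artifacts whose rate is higher on incorrect trials.
#'
#' @param n_trials Trials per session (>= 20; default 300).
#' @param fs Sampling rate (Hz).
#' @param delay_mean_ms,delay_sd_ms Delay distribution (ms).
#' @param fatigue_slope Drift per trial of the latent fatigue walk (logit
#'   scale).
#' @param fatigue_noise Innovation SD of the walk.
#' @param fatigue_gain Slope linking fatigue to the incorrect log-odds.
#' @param target_incorrect Session-mean incorrect probability the outcome
#'   model is calibrated to (0.515 mirrors the balanced subject's 254/270
#'   trial split; 0.719 the unbalanced 202/518 split).
#' @param effect_sizes Named list: `lowfreq_power_gain` (added 1-10 Hz noise,
#'   in units of background SD), `entropy_drop` (fractional attenuation of
#'   >14 Hz content, in `[0, 1)`), `coupling_gain` (added AR pair amplitude,
#'   units of background SD), `pac_gain` (depth of the 3-7 Hz phase
#'   modulation imposed on the 70-130 Hz envelope; power-neutral, so it is
#'   visible to the coupling index but barely to band powers),
#'   `artifact_amplitude` (uV).
#' @param effect_channels Channels carrying the low-frequency and entropy
#'   effects (default: all).
#' @param coupling_pair Length-2 channel vector, source then target.
#' @param coupling_ar AR coefficients of the injected bivariate process
#'   (`a1`, `a2` for the source, `b1` self term and `c1` cross term for the
#'   target); must be stable.
#' @param artifact_rate_correct Expected baseline ocular transients per
#'   trial (placed anywhere in the trial, any outcome).
#' @param artifact_rate_incorrect Expected *additional* intrusive
#'   transients inside the delay window of incorrect trials.
#' @param inject_period `"delay"` (effects only within the delay period,
#'   default) or `"all"` (whole trial).
#' @param background 1/f^alpha exponent, background SD (uV) and the two
#'   oscillation amplitudes (uV at 10 and 20 Hz).
#' @param seed Integer seed; every random draw in the generator flows from
#'   it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_trials = 300, fs = VIGI_FS,
                             delay_mean_ms = 2500, delay_sd_ms = 250,
                             fatigue_slope = 0.015, fatigue_noise = 0.08,
                             fatigue_gain = 3,
                             target_incorrect = 0.515,
                             effect_sizes = list(lowfreq_power_gain = 1,
                                                 entropy_drop = 0.5,
                                                 coupling_gain = 1,
                                                 pac_gain = 0.5,
                                                 artifact_amplitude = 120),
                             effect_channels = NULL,
                             coupling_pair = c("FZ", "CZ"),
                             coupling_ar = list(a1 = NULL, a2 = NULL,
                                                b1 = 0.5, c1 = 0.8),
                             artifact_rate_incorrect = 2.5,
                             artifact_rate_correct = 1.5,
                             inject_period = c("delay", "all"),
                             background = list(alpha = 1.5, sd = 20,
                                               osc10 = 5, osc20 = 3),
                             seed = 1) {
  if (n_trials < 20) abort("n_trials must be >= 20")
  if (delay_sd_ms <= 0) abort("delay_sd_ms must be > 0")
  es <- utils::modifyList(list(lowfreq_power_gain = 1, entropy_drop = 0.5,
                               coupling_gain = 1, pac_gain = 0.5,
                               artifact_amplitude = 120),
                          effect_sizes)
  if (any(unlist(es) < 0)) abort("all effect sizes must be >= 0")
  if (es$entropy_drop >= 1) abort("entropy_drop must be < 1")
  if (is.null(coupling_ar$a1)) {
    # resonance near 4 Hz with pole radius 0.95
    coupling_ar$a1 <- 2 * 0.95 * cos(2 * pi * 4 / fs)
    coupling_ar$a2 <- -0.95^2
  }
  structure(list(
    n_trials = n_trials, fs = fs, delay_mean_ms = delay_mean_ms,
    delay_sd_ms = delay_sd_ms, fatigue_slope = fatigue_slope,
    fatigue_noise = fatigue_noise, fatigue_gain = fatigue_gain,
    target_incorrect = target_incorrect, effect_sizes = es,
    effect_channels = effect_channels, coupling_pair = coupling_pair,
    coupling_ar = coupling_ar,
    artifact_rate_incorrect = artifact_rate_incorrect,
    artifact_rate_correct = artifact_rate_correct,
    inject_period = match.arg(inject_period),
    background = background, seed = seed
  ), class = "generator_config")
}

#' Draw delay-period durations
#'
#' Normal with the configured mean and SD, redrawn below the truncation
#' point (500 ms).
#'
#' @param n Number of draws.
#' @param mean_ms,sd_ms Distribution parameters (ms).
#' @param min_ms Truncation point (ms).
#' @return Numeric vector of durations in ms.
#' @export
draw_delays <- function(n, mean_ms = 2500, sd_ms = 250, min_ms = 500) {
  d <- rnorm(n, mean_ms, sd_ms)
  while (any(d < min_ms)) {
    d[d < min_ms] <- rnorm(sum(d < min_ms), mean_ms, sd_ms)
  }
  d
}

# 1/f^alpha Gaussian noise of length n, unit SD, via spectral shaping
# (generated at a 2-3-5-smooth length so the FFT stays fast, then truncated)
colored_noise <- function(n, alpha) {
  n2 <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(n2)
  W <- fft(w)
  f <- c(1, seq_len(n2 - 1))
  f <- pmin(f, n2 - f + 1) # symmetric frequency index
  W <- W * f^(-alpha / 2)
  x <- Re(fft(W, inverse = TRUE) / n2)[seq_len(n)]
  x / sd(x)
}

# one channel of background: 1/f^alpha floor plus narrowband rhythms at 10
# and 20 Hz. The rhythms are band-limited noise, not pure tones: tones with
# random phases would span a shared rank-2 subspace across channels (any
# mixture of same-frequency sinusoids is again a sinusoid), which is both
# unphysiological and degenerate for the ICA stage.
background_channel <- function(n, fs, bg) {
  n2 <- stats::nextn(n, c(2, 3, 5))
  W <- fft(rnorm(n2))
  fidx <- pmin(c(1, seq_len(n2 - 1)), c(1, rev(seq_len(n2 - 1))))
  f_hz <- (fidx - 1) * fs / n2
  comp <- function(mask) {
    x <- Re(fft(W * mask, inverse = TRUE) / n2)[seq_len(n)]
    x / sd(x)
  }
  x <- bg$sd * comp(pmax(fidx, 1)^(-bg$alpha / 2))
  if ((bg$osc10 %||% 0) > 0) {
    x <- x + bg$osc10 * comp(exp(-(f_hz - 10)^2 / (2 * 0.4^2)))
  }
  if ((bg$osc20 %||% 0) > 0) {
    x <- x + bg$osc20 * comp(exp(-(f_hz - 20)^2 / (2 * 0.6^2)))
  }
  x
}

# biphasic ~50 ms saccade transient plus a low-frequency drift burst
artifact_waveform <- function(fs) {
  t <- seq(0, 0.45, by = 1 / fs)
  spike <- exp(-((t - 0.015) / 0.008)^2) - 0.7 * exp(-((t - 0.035) / 0.012)^2)
  drift <- 0.35 * sin(2 * pi * 2 * t) * exp(-((t - 0.15) / 0.12)^2)
  spike + drift
}

# stable bivariate AR with one-way coupling, unit-SD normalized columns
coupling_process <- function(n, ar) {
  comp <- matrix(0, 4, 4)
  comp[1, ] <- c(ar$a1, ar$a2, 0, 0)
  comp[2, 1] <- 1
  comp[3, ] <- c(ar$c1, 0, ar$b1, 0)
  comp[4, 3] <- 1
  if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1) {
    abort("coupling AR coefficients are unstable (spectral radius >= 1)")
  }
  burn <- 200
  m <- n + burn
  u <- numeric(m); v <- numeric(m)
  eu <- rnorm(m); ev <- rnorm(m)
  for (t in 3:m) {
    u[t] <- ar$a1 * u[t - 1] + ar$a2 * u[t - 2] + eu[t]
    v[t] <- ar$b1 * v[t - 1] + ar$c1 * u[t - 1] + ev[t]
  }
  u <- u[(burn + 1):m]; v <- v[(burn + 1):m]
  cbind(u / sd(u), v / sd(v))
}

# ocular potentials fall off steeply with distance from the orbits: strong
# on the lateral-frontal pair, moderate on the medial-frontal pair, barely
# measurable at the midline, absent occipitally
ARTIFACT_MIXING <- c(LO = 0, RO = 0, LT = 0.01, RT = 0.01,
                     LFL = 1, LFM = 0.6, RFL = 0.95, RFM = 0.6,
                     FZ = 0.1, CZ = 0.02)

#' Generate one synthetic vigilance-task session
#'
#' Produces a continuous 10-channel recording, the per-trial event table,
#' and a ground-truth record (latent fatigue, outcome probabilities,
#' injected effects, artifact mixing, seed). Identical configuration and
#' seed give bit-identical output.
#'
#' @param config A [generator_config()].
#' @param session_id Identifier stored in the session.
#' @return List with `session` ([ecog_session()]), `events` (tibble) and
#'   `ground_truth` (`vigi_ground_truth`).
#' @examples
#' \donttest{
#' g <- generate_session(generator_config(n_trials = 25, seed = 7))
#' g$session
#' }
#' @export
generate_session <- function(config = generator_config(),
                             session_id = paste0("synthetic_", config$seed)) {
  with_local_seed(config$seed, generate_session_impl(config, session_id))
}

generate_session_impl <- function(config, session_id) {
  fs <- config$fs
  layout <- channel_layout()
  ch <- layout$names
  nt <- config$n_trials
  es <- config$effect_sizes
  eff_ch <- config$effect_channels %||% ch

  # ---- trial timing -------------------------------------------------------
  pre_s <- 1.5      # pre-target baseline
  fix_s <- 1.0      # stable fixation between target onset and delay cue
  resp_s <- 0.4
  iti_s <- 1.0
  delay_ms <- draw_delays(nt, config$delay_mean_ms, config$delay_sd_ms)
  trial_len <- pre_s + fix_s + delay_ms / 1000 + resp_s + iti_s
  t_start <- c(0.5, 0.5 + cumsum(trial_len))[seq_len(nt)]
  t_target <- t_start + pre_s
  t_cue <- t_target + fix_s
  t_go <- t_cue + delay_ms / 1000

  # ---- latent fatigue and outcomes ---------------------------------------
  g <- cumsum(c(-2, rnorm(nt - 1, config$fatigue_slope, config$fatigue_noise)))
  fatigue <- plogis(g)
  b <- config$fatigue_gain
  # intercept calibrated so the mean incorrect probability hits the target
  a <- stats::uniroot(function(a0) mean(plogis(a0 + b * fatigue)) -
                        config$target_incorrect,
                      c(-30, 30))$root
  p_inc <- plogis(a + b * fatigue)
  outcome <- ifelse(rbinom(nt, 1, p_inc) == 1, "incorrect", "correct")
  t_resp <- ifelse(outcome == "correct", t_go + runif(nt, 0.25, 0.45),
                   ifelse(runif(nt) < 0.5, t_go + runif(nt, 0.0, 0.15), NA))

  n_total <- ceiling((max(t_go) + resp_s + iti_s) * fs)

  # ---- background ---------------------------------------------------------
  bg <- config$background
  data <- matrix(0, length(ch), n_total, dimnames = list(ch, NULL))
  for (i in seq_along(ch)) {
    # slow multiplicative burst envelope: real field potentials are
    # heavy-tailed, which also keeps the per-channel sources identifiable
    # for the ICA stage (amplitude-modulated Gaussian is super-Gaussian)
    m <- ceiling(n_total / fs * 8) + 4 # envelope band-limited to <0.5 Hz,
    slow <- lowpass(rnorm(m), 0.5, 8)  # so build it at 8 Hz and upsample
    slow <- approx(seq_len(m), slow, xout = seq(1, m, length.out = n_total))$y
    env <- exp(0.7 * slow / sd(slow))
    data[i, ] <- background_channel(n_total, fs, bg) * env / sqrt(mean(env^2))
  }

  # ---- per-trial effect injection ----------------------------------------
  n_art <- integer(nt)
  wave <- artifact_waveform(fs)
  mix <- ARTIFACT_MIXING[ch]
  for (k in seq_len(nt)) {
    win <- if (config$inject_period == "delay") {
      c(round(t_cue[k] * fs) + 1, round(t_go[k] * fs))
    } else {
      c(round(t_start[k] * fs) + 1, round(t_go[k] * fs))
    }
    idx <- win[1]:win[2]
    nwin <- length(idx)
    incorrect <- outcome[k] == "incorrect"

    if (incorrect && es$lowfreq_power_gain > 0) {
      for (cn in eff_ch) {
        extra <- bandpass(rnorm(nwin), 1, 10, fs)
        extra <- extra / sd(extra)
        data[cn, idx] <- data[cn, idx] +
          es$lowfreq_power_gain * bg$sd * extra
      }
    }
    if (incorrect && es$entropy_drop > 0) {
      for (cn in eff_ch) {
        seg <- data[cn, idx]
        lp <- lowpass(seg, 14, fs)
        data[cn, idx] <- lp + (1 - es$entropy_drop) * (seg - lp)
      }
    }
    if (incorrect && es$pac_gain > 0) {
      m <- es$pac_gain
      for (cn in eff_ch) {
        seg <- data[cn, idx]
        hg <- bandpass(seg, 70, 130, fs)
        ph <- Arg(band_analytic(seg, 3, 7, fs))[1, ]
        data[cn, idx] <- (seg - hg) +
          hg * (1 + m * cos(ph)) / sqrt(1 + m^2 / 2)
      }
    }
    if (incorrect && es$coupling_gain > 0) {
      uv <- coupling_process(nwin, config$coupling_ar)
      amp <- es$coupling_gain * bg$sd * 0.8
      data[config$coupling_pair[1], idx] <-
        data[config$coupling_pair[1], idx] + amp * uv[, 1]
      data[config$coupling_pair[2], idx] <-
        data[config$coupling_pair[2], idx] + amp * uv[, 2]
    }
    if (es$artifact_amplitude > 0) {
      # baseline saccades occur throughout every trial; intrusive saccades
      # add extra events inside the delay window of incorrect trials only
      put_events <- function(lo, hi, n_ev) {
        for (e in seq_len(n_ev)) {
          at <- lo + sample.int(max(1, hi - lo - length(wave)), 1)
          aidx <- at:(at + length(wave) - 1)
          amp_e <- es$artifact_amplitude * runif(1, 0.7, 1.3) *
            sample(c(-1, 1), 1)
          data[, aidx] <<- data[, aidx] + outer(mix, amp_e * wave)
        }
        n_ev
      }
      trial_lo <- round(t_start[k] * fs) + 1
      trial_hi <- min(round((t_go[k] + resp_s) * fs), n_total - length(wave))
      n_base <- put_events(trial_lo, trial_hi,
                           rpois(1, config$artifact_rate_correct))
      n_extra <- if (incorrect) {
        put_events(win[1], min(win[2], n_total - length(wave)),
                   rpois(1, config$artifact_rate_incorrect))
      } else 0
      n_art[k] <- n_base + n_extra
    }
  }

  session <- ecog_session(data, fs = fs, channels = layout,
                          session_id = session_id)
  events <- tibble::tibble(
    trial_id = seq_len(nt),
    t_trial_start = t_start, t_target_on = t_target,
    t_delay_cue = t_cue, t_go = t_go, t_response = t_resp,
    delay_ms = delay_ms, outcome = outcome,
    target_location = sample.int(9, nt, replace = TRUE)
  )

  effects <- list()
  if (es$lowfreq_power_gain > 0) {
    # added independent 1-10 Hz noise raises the low bands and total
    # variance, tilts the relative spectrum (lower RMS frequency, shifted
    # wavelet energies), raises the delta-band instantaneous amplitude,
    # and, being spatially independent, flattens the low-band
    # cross-spectral eigenstructure and phase locking
    effects$lowfreq <- list(size = es$lowfreq_power_gain,
                            families = c("delta", "theta", "alpha",
                                         "gc", "pli", "iaif",
                                         "hjorth_activity",
                                         "hjorth_mobility",
                                         "wavelet_entropy"),
                            channels = eff_ch)
  }
  if (es$entropy_drop > 0) {
    # a spectral tilt: concentrates relative energy below 14 Hz, so it also
    # depresses the >14 Hz band powers and the difference-based Hjorth
    # descriptors
    effects$entropy <- list(size = es$entropy_drop,
                            families = c("wavelet_entropy", "low_beta",
                                         "high_beta", "low_gamma", "gamma",
                                         "high_gamma", "hjorth_mobility",
                                         "hjorth_complexity"),
                            channels = eff_ch)
  }
  if (es$pac_gain > 0) {
    effects$pac <- list(size = es$pac_gain, families = "pac",
                        channels = eff_ch)
  }
  if (es$coupling_gain > 0) {
    effects$coupling <- list(size = es$coupling_gain, families = "pdc",
                             channels = config$coupling_pair,
                             bands = c("delta", "theta"))
  }
  if (es$artifact_amplitude > 0) {
    effects$artifact <- list(size = es$artifact_amplitude,
                             families = c("delta", "theta"),
                             channels = names(mix)[mix >= 0.5])
  }
  gt <- structure(list(
    seed = config$seed, session_id = session_id,
    target_incorrect = config$target_incorrect,
    inject_period = config$inject_period,
    trials = tibble::tibble(trial_id = seq_len(nt), fatigue = fatigue,
                            p_incorrect = p_inc, outcome = outcome,
                            n_artifacts = n_art),
    effects = effects,
    artifact_mixing = as.list(mix)
  ), class = "vigi_ground_truth")

  list(session = session, events = events, ground_truth = gt)
}

#' Generate a cohort of synthetic sessions
#'
#' Emulates a multi-session experiment from one of two class-balance
#' regimes: `"balanced"` targets a session-mean incorrect fraction of
#' 270/(254+270) ~ 0.515, `"unbalanced"` 518/720 ~ 0.719 (the two subjects'
#' mean trial splits). Per-session trial counts are drawn around
#' `config$n_trials` (Gaussian, SD = 10% of the mean, floor 25), and each
#' session gets its own derived seed.
#'
#' @param config A [generator_config()] (its `target_incorrect` is
#'   overridden by the regime).
#' @param n_sessions Number of sessions (>= 1).
#' @param regime `"balanced"` or `"unbalanced"`.
#' @return List of `generate_session()` results, one per session.
#' @export
generate_cohort <- function(config = generator_config(), n_sessions = 10,
                            regime = c("balanced", "unbalanced")) {
  regime <- match.arg(regime)
  if (n_sessions < 1) abort("n_sessions must be >= 1")
  target <- if (regime == "balanced") 270 / 524 else 518 / 720
  counts <- with_local_seed(config$seed,
    pmax(25L, as.integer(round(rnorm(n_sessions, config$n_trials,
                                     0.1 * config$n_trials)))))
  purrr::map(seq_len(n_sessions), function(i) {
    cfg <- config
    cfg$n_trials <- counts[i]
    cfg$target_incorrect <- target
    cfg$seed <- config$seed * 1000L + i
    out <- generate_session(cfg, session_id = sprintf("synthetic_%s_%02d",
                                                      regime, i))
    out$ground_truth$regime <- regime
    out
  })
}
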