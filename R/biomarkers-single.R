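# Single-channel biomarkers: band power, Hjorth parameters, phase-amplitude
# coupling, instantaneous amplitude/frequency.

#' Band power of an epoch channel
#'
#' Welch PSD integrated over the half-open band `[f_lo, f_hi)`, in uV^2.
#'
#' @param x Numeric vector (one channel of one epoch).
#' @param band Band name from [band_registry()].
#' @param fs Sampling rate (Hz).
#' @return Non-negative scalar power.
#' @examples
#' band_power(rnorm(509), "theta", 508.6)
#' @export
band_power <- function(x, band, fs = VIGI_FS) {
  lim <- band_limits(band)
  if (lim[2] > fs / 2) {
    abort(sprintf("band '%s' extends above Nyquist (%g Hz)", band, fs / 2))
  }
  ps <- welch_psd(x, fs)
  sel <- ps$freq >= lim[1] & ps$freq < lim[2]
  df <- ps$freq[2] - ps$freq[1]
  sum(ps$psd[sel]) * df
}

#' Hjorth parameters
#'
#' Time-domain descriptors of an epoch channel: activity is the variance;
#' mobility is `sqrt(var(diff(y)) / var(y))`, a root-mean-square frequency
#' proxy in per-sample units; complexity is the mobility of the first
#' difference divided by the mobility of the signal. For a constant signal
#' activity is 0 and mobility/complexity are returned as `NA` (degenerate;
#' imputed downstream by the training-fold median).
#'
#' @param x Numeric vector.
#' @return Named numeric vector `c(activity, mobility, complexity)`.
#' @examples
#' hjorth(sin(2 * pi * 10 * (0:508) / 508.6))
#' @export
hjorth <- function(x) {
  act <- var(x)
  if (act <= 0 || !is.finite(act)) {
    return(c(activity = 0, mobility = NA_real_, complexity = NA_real_))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- var(d1)
  mob <- sqrt(v1 / act)
  comp <- if (v1 > 0) sqrt(var(d2) / v1) / mob else NA_real_
  c(activity = act, mobility = mob, complexity = comp)
}

#' Phase-amplitude coupling modulation index
#'
#' Couples the phase of the 3-7 Hz rhythm to the amplitude envelope of the
#' 70-130 Hz rhythm. The phase axis is divided into `n_bins` bins; `P` is
#' the mean 70-130 Hz envelope per bin normalized to sum one, and the index
#' is `(log N - H(P)) / log N`, i.e. one minus the normalized Shannon
#' entropy of `P`. 0 means a flat phase-amplitude distribution, 1 means all
#' envelope mass in a single phase bin.
#'
#' @param x Numeric vector (one channel of one epoch).
#' @param fs Sampling rate (Hz).
#' @param n_bins Number of phase bins (default 18, i.e. 20 degree bins).
#' @param phase_band,amp_band Band names in [band_registry()].
#' @return Modulation index in `[0, 1]`.
#' @export
pac_mi <- function(x, fs = VIGI_FS, n_bins = 18,
                   phase_band = "pac_phase", amp_band = "pac_amplitude") {
  if (n_bins < 2) {
    abort("n_bins must be >= 2")
  }
  pl <- band_limits(phase_band)
  al <- band_limits(amp_band)
  ph <- Arg(band_analytic(x, pl[1], pl[2], fs))[1, ]
  am <- Mod(band_analytic(x, al[1], al[2], fs))[1, ]
  pac_mi_core(ph, am, n_bins)
}

# modulation index from precomputed phase and envelope series
pac_mi_core <- function(ph, am, n_bins) {
  keep <- interior_idx(length(ph))
  bins <- findInterval(ph[keep], seq(-pi, pi, length.out = n_bins + 1),
                       rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bins, n_bins)
  s <- rowsum(am[keep], factor(bins, levels = seq_len(n_bins)))[, 1]
  p <- ifelse(cnt > 0, s / pmax(cnt, 1), 0)
  mi_from_distribution(p)
}

# modulation index of an (unnormalized) phase-bin amplitude distribution
mi_from_distribution <- function(p) {
  n_bins <- length(p)
  tot <- sum(p)
  if (tot <= 0) return(0)
  p <- p / tot
  (log(n_bins) - shannon_entropy(p)) / log(n_bins)
}

#' Instantaneous amplitude / frequency features
#'
#' Three features per channel: the mean modulus of the analytic signal of
#' the delta-filtered trace (instantaneous amplitude, uV), the mean
#' derivative of the unwrapped analytic phase of the 4-14 Hz trace divided
#' by 2*pi (instantaneous frequency, Hz), and their ratio. Means are taken
#' over the middle 80% of samples to avoid filter/Hilbert edge bias. A
#' non-positive mean frequency makes the ratio undefined (`NA`).
#'
#' @param x Numeric vector (one channel of one epoch).
#' @param fs Sampling rate (Hz).
#' @return Named vector `c(ia, if_, ratio)`.
#' @export
ia_if <- function(x, fs = VIGI_FS) {
  dl <- band_limits("ia_delta")
  fl <- band_limits("if_thetaalpha")
  ia <- Mod(band_analytic(x, dl[1], dl[2], fs))[1, ]
  ph <- Arg(band_analytic(x, fl[1], fl[2], fs))[1, ]
  ia_if_core(ia, ph, fs)
}

# IA/IF features from precomputed envelope and phase series
ia_if_core <- function(ia, ph, fs) {
  keep <- interior_idx(length(ia))
  instf <- diff(unwrap_phase(ph)) * fs / (2 * pi)
  mean_ia <- mean(ia[keep])
  mean_if <- mean(instf[keep[-length(keep)]])
  ratio <- if (is.finite(mean_if) && mean_if > 0) mean_ia / mean_if else NA_real_
  c(ia = mean_ia, if_ = mean_if, ratio = ratio)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}
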