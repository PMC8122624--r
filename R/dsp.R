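# Shared signal-processing primitives: zero-phase band-pass filtering,
# analytic signal, Welch power spectra, sine-taper cross-spectra.
#
# Filtering runs in the frequency domain: the signal is reflection-padded to
# a fast FFT length and its spectrum multiplied by the squared magnitude
# response |H(f)|^2 of a 4-pole Butterworth band-pass, i.e. exactly the
# response of applying the filter forward and backward (zero phase, which
# the Hilbert-based measures require). Batching all channels through one
# matrix FFT is what makes per-epoch feature extraction cheap.

.dsp_cache <- new.env(parent = emptyenv())

# |H(f)|^2 of a forward-backward 4-pole Butterworth at the nfft bin grid
butter_mag2 <- function(f_lo, f_hi, fs, nfft, type = "pass") {
  key <- paste(f_lo, f_hi, fs, nfft, type, sep = "|")
  got <- .dsp_cache[[key]]
  if (!is.null(got)) return(got)
  bf <- if (type == "pass") {
    signal::butter(2, c(f_lo, f_hi) / (fs / 2), type = "pass")
  } else {
    signal::butter(2, f_hi / (fs / 2), type = "low")
  }
  w <- 2 * pi * (seq_len(nfft) - 1) / nfft
  z <- exp(-1i * w)
  H <- outer(z, seq_along(bf$b) - 1, "^") %*% bf$b /
    (outer(z, seq_along(bf$a) - 1, "^") %*% bf$a)
  m2 <- as.numeric(Mod(H)^2)
  .dsp_cache[[key]] <- m2
  m2
}

# odd (point-symmetric) reflection padding of each row to length nfft
pad_reflect <- function(X, nfft) {
  n <- ncol(X)
  left <- (nfft - n) %/% 2
  right <- nfft - n - left
  rl <- min(left, n - 1)
  rr <- min(right, n - 1)
  out <- matrix(0, nrow(X), nfft)
  if (rl > 0) out[, (left - rl + 1):left] <- 2 * X[, 1] - X[, (rl + 1):2]
  if (left - rl > 0) out[, 1:(left - rl)] <- 2 * X[, 1] - X[, rl + 1]
  out[, (left + 1):(left + n)] <- X
  if (rr > 0) out[, (left + n + 1):(left + n + rr)] <-
      2 * X[, n] - X[, (n - 1):(n - rr)]
  if (right - rr > 0) out[, (left + n + rr + 1):nfft] <- 2 * X[, n] - X[, n - rr]
  out
}

hilbert_mask <- function(nfft) {
  h <- numeric(nfft)
  if (nfft %% 2 == 0) {
    h[1] <- 1; h[nfft / 2 + 1] <- 1
    h[2:(nfft / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((nfft + 1) / 2)] <- 2
  }
  h
}

# core: filter all rows of X in one batch; analytic = TRUE additionally
# applies the Hilbert mask so the result is the analytic signal of the
# band-filtered trace
band_filter_mat <- function(X, f_lo, f_hi, fs, analytic = FALSE,
                            type = "pass") {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  n <- ncol(X)
  nfft <- stats::nextn(max(16L, ceiling(1.5 * n)), 2)
  m2 <- butter_mag2(f_lo, f_hi, fs, nfft, type)
  P <- pad_reflect(X, nfft)
  S <- stats::mvfft(t(P)) * m2
  if (analytic) S <- S * hilbert_mask(nfft)
  Y <- stats::mvfft(S, inverse = TRUE) / nfft
  left <- (nfft - n) %/% 2
  out <- t(Y[(left + 1):(left + n), , drop = FALSE])
  if (analytic) out else Re(out)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the squared-magnitude response of a 4-pole Butterworth band-pass
#' (the response of one forward and one backward pass) in the frequency
#' domain, after odd-reflection padding to a fast FFT length. Zero phase
#' matters because several biomarkers take Hilbert phases of the output.
#'
#' @param x Numeric vector.
#' @param f_lo,f_hi Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return Filtered vector, same length as `x`.
#' @export
bandpass <- function(x, f_lo, f_hi, fs) {
  ny <- fs / 2
  if (f_hi > ny) {
    abort(sprintf("band edge %g Hz is above Nyquist (%g Hz)", f_hi, ny))
  }
  as.numeric(band_filter_mat(x, f_lo, f_hi, fs))
}

# analytic signal of the band-filtered trace(s); complex matrix
band_analytic <- function(X, f_lo, f_hi, fs) {
  band_filter_mat(X, f_lo, f_hi, fs, analytic = TRUE)
}

# zero-phase low-pass (forward-backward 2nd-order Butterworth)
lowpass <- function(x, f_hi, fs) {
  as.numeric(band_filter_mat(x, 0, f_hi, fs, type = "low"))
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x Numeric vector.
#' @return Complex vector `x + i * H(x)`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  fft(fft(x) * hilbert_mask(n), inverse = TRUE) / n
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlapping, mean-removed modified periodograms
#' averaged into a one-sided PSD. For a 1-s epoch the default segment
#' length equals the epoch, i.e. a single modified periodogram with ~1 Hz
#' resolution.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param seg_len Segment length in samples (default `length(x)`).
#' @return A list with `freq` (Hz) and `psd` (power per Hz) vectors.
#' @export
welch_psd <- function(x, fs, seg_len = length(x)) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    acc <- acc + periodogram_mat(matrix(x[s:(s + seg_len - 1L)], ncol = 1),
                                 fs)[, 1]
  }
  list(freq = (seq_len(nf) - 1) * fs / seg_len, psd = acc / length(starts))
}

# one-sided Hann modified periodogram of each column (samples x series)
periodogram_mat <- function(X, fs) {
  seg_len <- nrow(X)
  w <- hann_window(seg_len)
  u <- sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  Xc <- sweep(X, 2, colMeans(X)) * w
  P <- Mod(stats::mvfft(Xc))^2 / (u * fs)
  half <- P[seq_len(nf), , drop = FALSE]
  # one-sided: double everything except DC (and Nyquist when present)
  if (seg_len %% 2 == 0) {
    half[2:(nf - 1), ] <- 2 * half[2:(nf - 1), ]
  } else {
    half[2:nf, ] <- 2 * half[2:nf, ]
  }
  half
}

# sine tapers (orthonormal); the k-th taper is sqrt(2/(N+1)) sin(pi k t /(N+1))
sine_tapers <- function(n, k) {
  t <- seq_len(n)
  sapply(seq_len(k), function(j) sqrt(2 / (n + 1)) * sin(pi * j * t / (n + 1)))
}

# multitaper cross-spectral matrices: returns list(freq, S) with S a
# C x C x n_freq complex array averaged over tapers
cross_spectra <- function(x, fs, n_tapers = 3) {
  x <- as.matrix(x)
  nc <- nrow(x)
  n <- ncol(x)
  tapers <- sine_tapers(n, n_tapers)
  nf <- floor(n / 2) + 1L
  S <- array(0 + 0i, dim = c(nc, nc, nf))
  xc <- x - rowMeans(x)
  for (k in seq_len(n_tapers)) {
    Xk <- stats::mvfft(t(xc) * tapers[, k])[seq_len(nf), , drop = FALSE]
    for (i in seq_len(nc)) {
      Xi <- Xk[, i]
      for (j in i:nc) {
        pij <- Xi * Conj(Xk[, j])
        S[i, j, ] <- S[i, j, ] + pij
        if (j > i) S[j, i, ] <- S[j, i, ] + Conj(pij)
      }
    }
  }
  list(freq = (seq_len(nf) - 1) * fs / n, S = S / n_tapers)
}

# instantaneous phase of the band-filtered trace
band_phase <- function(x, f_lo, f_hi, fs) {
  Arg(band_analytic(x, f_lo, f_hi, fs))[1, ]
}

interior_idx <- function(n, trim = 0.1) {
  lo <- floor(n * trim) + 1L
  hi <- n - floor(n * trim)
  lo:hi
}
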