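# Cross-channel biomarkers: partial directed coherence from a fitted MVAR
# model, phase-locking between channel pairs, and global coherence from
# multitaper cross-spectra.

#' Fit a multivariate autoregressive model by least squares
#'
#' Each channel at time t is regressed on the previous `order` samples of
#' all channels. Returns the stacked coefficient matrices `A_k` such that
#' `y_t = sum_k A_k y_{t-k} + e_t`.
#'
#' A small ridge penalty (relative to the mean diagonal of the Gram matrix)
#' keeps the regression defined when the channels are linearly dependent --
#' which is always the case after independent components have been removed,
#' since back-projected data lose one rank per removed component. With
#' `ridge = 0` a rank-deficient design is an error.
#'
#' @param x Channels x samples matrix.
#' @param order Model order p.
#' @param ridge Relative ridge penalty (default 1e-6; 0 for strict least
#'   squares).
#' @return List of `order` coefficient matrices (channels x channels).
#' @export
mvar_fit <- function(x, order = 5, ridge = 1e-6) {
  x <- as.matrix(x)
  nc <- nrow(x)
  n <- ncol(x)
  if (n <= 3 * nc * order) {
    abort(sprintf("epoch too short for MVAR order %d with %d channels (need > %d samples)",
                  order, nc, 3 * nc * order))
  }
  x <- x - rowMeans(x)
  Y <- t(x[, (order + 1):n, drop = FALSE])              # (n - p) x C
  X <- do.call(cbind, lapply(seq_len(order), function(k) {
    t(x[, (order + 1 - k):(n - k), drop = FALSE])
  }))                                                   # (n - p) x (C p)
  G <- crossprod(X)
  if (ridge > 0) {
    G <- G + diag(ridge * mean(diag(G)), ncol(G))
  } else if (rcond(G) < 1e-10) {
    abort("MVAR regression is rank-deficient (singular design)")
  }
  ch <- tryCatch(chol(G), error = function(e)
    abort("MVAR regression is rank-deficient (singular design)"))
  coefs <- backsolve(ch, forwardsolve(t(ch), crossprod(X, Y)))
  lapply(seq_len(order), function(k) {
    t(coefs[((k - 1) * nc + 1):(k * nc), , drop = FALSE])
  })
}

# B(f) = I - sum_k A_k exp(-i 2 pi f k / fs) for each frequency (Hz)
mvar_transfer <- function(A, freqs, fs) {
  nc <- nrow(A[[1]])
  lapply(freqs, function(f) {
    B <- diag(nc) + 0i
    for (k in seq_along(A)) {
      B <- B - A[[k]] * exp(-2i * pi * f * k / fs)
    }
    B
  })
}

#' Partial directed coherence from MVAR coefficients
#'
#' `PDC_ij(f) = |B_ij(f)| / sqrt(b_j(f)* b_j(f))` with `B` the spectral
#' transfer of the coefficients and `b_j` its j-th column, so that for every
#' source j and frequency the squared entries sum to one over targets i.
#' The band feature is the mean of squared PDC over the band frequencies
#' sampled at 1 Hz resolution on `[f_lo, f_hi)`.
#'
#' @param A List of MVAR coefficient matrices (e.g. from [mvar_fit()] or the
#'   generating coefficients of a known system).
#' @param band Band name; one of the four connectivity bands
#'   (delta, theta, alpha, low_beta).
#' @param fs Sampling rate (Hz).
#' @return Channels x channels matrix of band-mean squared PDC
#'   (source = column j, target = row i); the diagonal is kept for the
#'   normalization property but excluded from feature tables.
#' @export
pdc_from_var <- function(A, band, fs = VIGI_FS) {
  lim <- band_limits(band)
  freqs <- seq(lim[1], lim[2] - 1)
  Bs <- mvar_transfer(A, freqs, fs)
  acc <- 0
  for (B in Bs) {
    M <- Mod(B)^2
    acc <- acc + sweep(M, 2, colSums(M), "/")
  }
  acc / length(freqs)
}

#' Partial directed coherence of an epoch
#'
#' Fits an MVAR model of the given order to the epoch and evaluates the
#' band-mean squared PDC (see [pdc_from_var()]).
#'
#' @param x Channels x samples matrix.
#' @param band Connectivity band name.
#' @param fs Sampling rate (Hz).
#' @param order MVAR order (default 5).
#' @return Channels x channels matrix.
#' @export
pdc <- function(x, band, fs = VIGI_FS, order = 5) {
  pdc_from_var(mvar_fit(x, order), band, fs)
}

#' Phase-locking index between two channels
#'
#' Modulus of the mean phase-difference phasor
#' `|T^-1 sum_t exp(i (theta1_t - theta2_t))|` where the phases come from
#' the analytic signals of the band-filtered traces. Edge samples (10% per
#' side) are excluded. 1 for a fixed phase relation, ~0 for independent
#' phases.
#'
#' @param x1,x2 Numeric vectors (one channel each, same epoch).
#' @param band Connectivity band name.
#' @param fs Sampling rate (Hz).
#' @return Value in `[0, 1]`.
#' @export
pli <- function(x1, x2, band, fs = VIGI_FS) {
  lim <- band_limits(band)
  ph <- Arg(band_analytic(rbind(x1, x2), lim[1], lim[2], fs))
  p1 <- ph[1, ]
  p2 <- ph[2, ]
  keep <- interior_idx(length(x1))
  plv_phases(p1[keep] - p2[keep])
}

# modulus of the mean phasor of a phase-difference series
plv_phases <- function(dphi) {
  Mod(mean(exp(1i * dphi)))
}

#' Global coherence of a multichannel epoch
#'
#' Ratio of the largest eigenvalue of the cross-spectral matrix to the sum
#' of all eigenvalues. Cross-spectra are estimated with three orthonormal
#' sine tapers on the full epoch and averaged over the band frequencies
#' before the eigendecomposition: a per-frequency estimate from K tapers has
#' rank K, which for K < C pins the eigenvalue ratio near 1/K regardless of
#' the data, so pooling tapers and band frequencies is what makes the
#' statistic informative on short epochs. Near 1 when a single spatial mode
#' dominates; bounded below by 1/C for C channels.
#'
#' @param x Channels x samples matrix.
#' @param band Band name from [band_registry()].
#' @param fs Sampling rate (Hz).
#' @param n_tapers Number of sine tapers (default 3).
#' @return Scalar in `[1/C, 1]`.
#' @export
global_coherence <- function(x, band, fs = VIGI_FS, n_tapers = 3) {
  lim <- band_limits(band)
  cs <- cross_spectra(x, fs, n_tapers)
  sel <- which(cs$freq >= lim[1] & cs$freq < lim[2])
  if (length(sel) == 0) {
    sel <- which.min(abs(cs$freq - mean(lim)))
  }
  Sband <- apply(cs$S[, , sel, drop = FALSE], c(1, 2), mean)
  ev <- eigen(Sband, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(Re(ev), 0)
  if (sum(ev) <= 0) 1 / nrow(x) else max(ev) / sum(ev)
}
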