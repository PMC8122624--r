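#' Feature extraction configuration
#'
#' @param pac_bins Phase bins for the coupling modulation index (default 18).
#' @param mvar_order MVAR model order for partial directed coherence
#'   (default 5; ~500 parameters are identifiable from a 1-s, 10-channel
#'   epoch, see [mvar_order_scan()]).
#' @param connectivity_bands Bands for PDC and phase-locking features.
#' @param gc_bands Bands for global coherence (default: all eight power
#'   bands).
#' @param wavelet_level,wavelet_subbands Passed to [wavelet_entropy()].
#' @param n_tapers Sine tapers for the cross-spectral estimate.
#' @return A `feature_config` list.
#' @export
feature_config <- function(pac_bins = 18, mvar_order = 5,
                           connectivity_bands = CONNECTIVITY_BANDS,
                           gc_bands = POWER_BANDS,
                           wavelet_level = 4,
                           wavelet_subbands = "all",
                           n_tapers = 3) {
  structure(list(pac_bins = pac_bins, mvar_order = mvar_order,
                 connectivity_bands = connectivity_bands,
                 gc_bands = gc_bands, wavelet_level = wavelet_level,
                 wavelet_subbands = wavelet_subbands, n_tapers = n_tapers),
            class = "feature_config")
}

#' Feature column registry
#'
#' Enumerates every feature column produced by [extract_features()] for a
#' channel layout, with its family (one of the 17 biomarker families),
#' channel(s) and band. For 10 channels and the default configuration this
#' is 708 columns: 80 band powers, 10 wavelet entropies, 30 Hjorth, 10
#' coupling indices, 30 instantaneous amplitude/frequency, 360 directed
#' (PDC) pairs x 4 bands, 180 phase-locking pairs x 4 bands, and 8 global
#' coherence bands.
#'
#' @param channels A [channel_layout()].
#' @param config A [feature_config()].
#' @return Tibble with columns `column`, `family`, `channel`, `channel2`,
#'   `band`, `single_channel`.
#' @export
feature_registry <- function(channels = channel_layout(),
                             config = feature_config()) {
  ch <- channels$names
  rows <- list()
  add <- function(column, family, channel = NA_character_,
                  channel2 = NA_character_, band = NA_character_,
                  single_channel = TRUE) {
    tibble::tibble(column = column, family = family, channel = channel,
                   channel2 = channel2, band = band,
                   single_channel = single_channel)
  }
  for (b in POWER_BANDS) {
    rows[[length(rows) + 1]] <- add(paste0(b, ".", ch), b, channel = ch, band = b)
  }
  rows[[length(rows) + 1]] <- add(paste0("wavelet_entropy.", ch),
                                  "wavelet_entropy", channel = ch)
  for (hp in c("hjorth_activity", "hjorth_mobility", "hjorth_complexity")) {
    rows[[length(rows) + 1]] <- add(paste0(hp, ".", ch), hp, channel = ch)
  }
  rows[[length(rows) + 1]] <- add(paste0("pac.", ch), "pac", channel = ch)
  for (part in c("ia", "if", "ratio")) {
    rows[[length(rows) + 1]] <- add(paste0("iaif.", ch, ".", part),
                                    "iaif", channel = ch)
  }
  pairs <- expand.grid(to = ch, from = ch, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$to != pairs$from, c("from", "to")]
  for (b in config$connectivity_bands) {
    rows[[length(rows) + 1]] <- add(
      paste0("pdc.", pairs$from, "->", pairs$to, ".", b), "pdc",
      channel = pairs$from, channel2 = pairs$to, band = b,
      single_channel = FALSE)
  }
  upairs <- t(utils::combn(ch, 2))
  for (b in config$connectivity_bands) {
    rows[[length(rows) + 1]] <- add(
      paste0("pli.", upairs[, 1], "-", upairs[, 2], ".", b), "pli",
      channel = upairs[, 1], channel2 = upairs[, 2], band = b,
      single_channel = FALSE)
  }
  rows[[length(rows) + 1]] <- add(paste0("gc.", config$gc_bands), "gc",
                                  band = config$gc_bands,
                                  single_channel = FALSE)
  dplyr::bind_rows(rows)
}

# integrate a Welch PSD over the half-open band [lo, hi); with matrix = TRUE
# ps$psd is freq x series and a vector of powers is returned
psd_band_power <- function(ps, band, matrix = FALSE) {
  lim <- band_limits(band)
  sel <- ps$freq >= lim[1] & ps$freq < lim[2]
  df <- ps$freq[2] - ps$freq[1]
  if (matrix) colSums(ps$psd[sel, , drop = FALSE]) * df
  else sum(ps$psd[sel]) * df
}

# all features of one epoch (channels x samples matrix) as a named vector
extract_one_epoch <- function(sig, fs, channels, config) {
  ch <- channels$names
  nc <- length(ch)
  out <- c()

  n <- ncol(sig)
  pg <- periodogram_mat(t(sig), fs)
  freq <- (seq_len(nrow(pg)) - 1) * fs / n
  for (b in POWER_BANDS) {
    v <- psd_band_power(list(freq = freq, psd = pg), b, matrix = TRUE)
    out <- c(out, setNames(v, paste0(b, ".", ch)))
  }
  en <- dwt_energies(t(sig), config$wavelet_level)
  if (config$wavelet_subbands == "details") en <- en[-1, , drop = FALSE]
  tot <- colSums(en)
  if (any(tot <= 0)) {
    abort("wavelet entropy undefined for an all-zero epoch")
  }
  we <- apply(sweep(en, 2, tot, "/"), 2, shannon_entropy)
  out <- c(out, setNames(we, paste0("wavelet_entropy.", ch)))
  hj <- vapply(seq_len(nc), function(i) hjorth(sig[i, ]), numeric(3))
  out <- c(out, setNames(hj["activity", ], paste0("hjorth_activity.", ch)),
           setNames(hj["mobility", ], paste0("hjorth_mobility.", ch)),
           setNames(hj["complexity", ], paste0("hjorth_complexity.", ch)))
  pl <- band_limits("pac_phase")
  al <- band_limits("pac_amplitude")
  pac_ph <- Arg(band_analytic(sig, pl[1], pl[2], fs))
  pac_am <- Mod(band_analytic(sig, al[1], al[2], fs))
  pac <- vapply(seq_len(nc), function(i)
    pac_mi_core(pac_ph[i, ], pac_am[i, ], config$pac_bins), numeric(1))
  out <- c(out, setNames(pac, paste0("pac.", ch)))
  dl <- band_limits("ia_delta")
  fl <- band_limits("if_thetaalpha")
  ia_all <- Mod(band_analytic(sig, dl[1], dl[2], fs))
  if_ph <- Arg(band_analytic(sig, fl[1], fl[2], fs))
  iaif <- vapply(seq_len(nc), function(i)
    ia_if_core(ia_all[i, ], if_ph[i, ], fs), numeric(3))
  out <- c(out, setNames(iaif["ia", ], paste0("iaif.", ch, ".ia")),
           setNames(iaif["if_", ], paste0("iaif.", ch, ".if")),
           setNames(iaif["ratio", ], paste0("iaif.", ch, ".ratio")))

  A <- mvar_fit(sig, config$mvar_order)
  for (b in config$connectivity_bands) {
    M <- pdc_from_var(A, b, fs)
    src <- rep(seq_len(nc), each = nc)
    tgt <- rep(seq_len(nc), times = nc)
    keep <- src != tgt
    out <- c(out, setNames(M[cbind(tgt[keep], src[keep])],
                           paste0("pdc.", ch[src[keep]], "->", ch[tgt[keep]],
                                  ".", b)))
  }

  keep_idx <- interior_idx(ncol(sig))
  upairs <- utils::combn(nc, 2)
  for (b in config$connectivity_bands) {
    lim <- band_limits(b)
    phases <- Arg(band_analytic(sig, lim[1], lim[2], fs))[, keep_idx,
                                                          drop = FALSE]
    v <- apply(upairs, 2, function(p)
      plv_phases(phases[p[1], ] - phases[p[2], ]))
    out <- c(out, setNames(v, paste0("pli.", ch[upairs[1, ]], "-",
                                     ch[upairs[2, ]], ".", b)))
  }

  cs <- cross_spectra(sig, fs, config$n_tapers)
  gcv <- vapply(config$gc_bands, function(b) {
    lim <- band_limits(b)
    sel <- which(cs$freq >= lim[1] & cs$freq < lim[2])
    Sband <- apply(cs$S[, , sel, drop = FALSE], c(1, 2), mean)
    ev <- pmax(Re(eigen(Sband, symmetric = TRUE, only.values = TRUE)$values), 0)
    if (sum(ev) <= 0) 1 / nc else max(ev) / sum(ev)
  }, numeric(1))
  out <- c(out, setNames(gcv, paste0("gc.", config$gc_bands)))
  out
}

#' Extract the trials x biomarkers feature table
#'
#' Computes every biomarker family for every epoch and assembles the table.
#' Degenerate values (Hjorth mobility/complexity of a constant trace,
#' pathological instantaneous-frequency ratios) are left as `NA`; they are
#' imputed with training-fold medians inside the evaluation loop so no
#' test-fold statistic leaks into training. A column with no finite value at
#' all is an error naming the column.
#'
#' @param epochs Epoch tibble from [extract_epochs()] (needs >= 2 epochs
#'   with both outcomes present).
#' @param config A [feature_config()].
#' @return A tibble with `trial_id`, `outcome`, and one column per registry
#'   feature; the registry is attached as attribute `"registry"`.
#' @export
extract_features <- function(epochs, config = feature_config()) {
  fs <- attr(epochs, "fs")
  channels <- attr(epochs, "channels")
  if (is.null(fs) || is.null(channels)) {
    abort("epochs must come from extract_epochs() (missing fs/channels attributes)")
  }
  if (nrow(epochs) < 2 || length(unique(epochs$outcome)) < 2) {
    abort("need at least 2 epochs with both outcomes present")
  }
  reg <- feature_registry(channels, config)
  rows <- purrr::map(epochs$signal, extract_one_epoch, fs = fs,
                     channels = channels, config = config)
  mat <- do.call(rbind, rows)
  mat <- mat[, reg$column, drop = FALSE]
  all_missing <- colnames(mat)[colSums(is.finite(mat)) == 0]
  if (length(all_missing) > 0) {
    abort(paste0("feature column(s) with no finite values: ",
                 paste(all_missing, collapse = ", ")))
  }
  out <- dplyr::bind_cols(
    tibble::tibble(trial_id = epochs$trial_id, outcome = epochs$outcome),
    tibble::as_tibble(mat)
  )
  attr(out, "registry") <- reg
  attr(out, "session_id") <- attr(epochs, "session_id")
  attr(out, "period") <- epochs$period[1]
  attr(out, "window_s") <- epochs$window_s[1]
  out
}

#' Per-feature discriminability (point-biserial R^2)
#'
#' Squared Pearson correlation between each feature column and the binary
#' label (incorrect = 1), the statistic used to rank single features.
#'
#' @param features Feature table from [extract_features()].
#' @return Tibble `column`, `family`, `r2`, sorted decreasing.
#' @export
feature_r2 <- function(features) {
  reg <- attr(features, "registry")
  y <- as.numeric(features$outcome == "incorrect")
  cols <- reg$column
  r2 <- vapply(cols, function(cl) {
    x <- features[[cl]]
    ok <- is.finite(x)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(0)
    cor(x[ok], y[ok])^2
  }, numeric(1))
  tibble::tibble(column = cols, family = reg$family, r2 = unname(r2)) |>
    dplyr::arrange(dplyr::desc(.data$r2))
}

# median-imputation statistics from a training matrix, and application
impute_stats <- function(x) {
  apply(x, 2, function(col) {
    m <- median(col[is.finite(col)])
    if (!is.finite(m)) 0 else m
  })
}

impute_apply <- function(x, stats) {
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- stats[j]
  }
  x
}

#' Scan MVAR model orders by AIC
#'
#' Utility for choosing the autoregressive order of the PDC stage on a given
#' dataset: fits each order to the pooled epochs and reports the mean
#' per-epoch Akaike information criterion.
#'
#' @param epochs Epoch tibble from [extract_epochs()].
#' @param orders Candidate orders.
#' @param n_epochs Number of epochs to use (default up to 20).
#' @return Tibble `order`, `aic`.
#' @export
mvar_order_scan <- function(epochs, orders = 1:8, n_epochs = 20) {
  fs <- attr(epochs, "fs")
  use <- utils::head(seq_len(nrow(epochs)), n_epochs)
  purrr::map_dfr(orders, function(p) {
    aic <- vapply(use, function(i) {
      x <- epochs$signal[[i]]
      nc <- nrow(x)
      n <- ncol(x)
      A <- mvar_fit(x, p)
      xm <- x - rowMeans(x)
      pred <- matrix(0, nc, n - p)
      for (k in seq_len(p)) {
        pred <- pred + A[[k]] %*% xm[, (p + 1 - k):(n - k), drop = FALSE]
      }
      E <- xm[, (p + 1):n, drop = FALSE] - pred
      Sigma <- tcrossprod(E) / (n - p)
      (n - p) * determinant(Sigma, logarithm = TRUE)$modulus +
        2 * nc^2 * p
    }, numeric(1))
    tibble::tibble(order = p, aic = mean(aic))
  })
}
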