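# Frequency band definitions. Bands are half-open intervals [f_lo, f_hi).

BAND_TABLE <- data.frame(
  band = c("delta", "theta", "alpha", "low_beta", "high_beta", "low_gamma",
           "gamma", "high_gamma", "pac_phase", "pac_amplitude",
           "if_thetaalpha", "ia_delta"),
  f_lo = c(1, 4, 8, 13, 20, 30, 60, 100, 3, 70, 4, 1),
  f_hi = c(4, 8, 13, 20, 30, 45, 90, 200, 7, 130, 14, 4),
  role = c(rep("power", 8), rep("aux", 4))
)

BAND_LIMITS <- setNames(
  lapply(seq_len(nrow(BAND_TABLE)), function(i)
    c(BAND_TABLE$f_lo[i], BAND_TABLE$f_hi[i])),
  BAND_TABLE$band
)

#' Frequency band registry
#'
#' The eight band-power bands plus the auxiliary bands used by the
#' phase-amplitude coupling and instantaneous amplitude/frequency measures.
#' Bands are half-open intervals `[f_lo, f_hi)`.
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi`, `role`. Role is
#'   `"power"` for the eight band-power bands, `"aux"` otherwise.
#' @examples
#' band_registry()
#' @export
band_registry <- function() {
  tibble::as_tibble(BAND_TABLE)
}

# bands used for the directed (PDC) and phase-locking connectivity features;
# "beta" in the four-band connectivity set maps to low_beta (13-20 Hz)
CONNECTIVITY_BANDS <- c("delta", "theta", "alpha", "low_beta")

POWER_BANDS <- c("delta", "theta", "alpha", "low_beta", "high_beta",
                 "low_gamma", "gamma", "high_gamma")

band_limits <- function(band) {
  lim <- BAND_LIMITS[[band]]
  if (is.null(lim)) {
    abort(paste0("unknown band '", band, "'"))
  }
  lim
}
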