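# Daubechies-4 discrete wavelet transform (periodized) and wavelet entropy.
# Orthonormal db4 analysis filters; with periodization the subband energies
# sum exactly to the signal energy.

DB4_DEC_LO <- c(-0.010597401784997278, 0.032883011666982945,
                0.030841381835986965, -0.18703481171888114,
                -0.02798376941698385, 0.6308807679295904,
                0.7148465705525415, 0.23037781330885523)
DB4_DEC_HI <- c(-0.23037781330885523, 0.7148465705525415,
                -0.6308807679295904, -0.02798376941698385,
                0.18703481171888114, 0.030841381835986965,
                -0.032883011666982945, -0.010597401784997278)

# one periodized analysis step on a samples x series matrix: returns
# list(approx, detail), each (n/2) x nseries
dwt_step <- function(x) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(x)
  L <- length(DB4_DEC_LO)
  idx <- outer(seq(0, n - 2, by = 2), seq_len(L) - 1L, "+") %% n + 1L
  lo <- rev(DB4_DEC_LO)
  hi <- rev(DB4_DEC_HI)
  nh <- n / 2
  approx <- matrix(0, nh, ncol(x))
  detail <- matrix(0, nh, ncol(x))
  for (k in seq_len(L)) {
    xk <- x[idx[, k], , drop = FALSE]
    approx <- approx + lo[k] * xk
    detail <- detail + hi[k] * xk
  }
  list(approx = approx, detail = detail)
}

# subband energies of a `level`-deep db4 decomposition, coarse to fine:
# (a_level, d_level, ..., d_1) per series. Input is reflection-padded to the
# next multiple of 2^level so each level halves evenly. Accepts a vector or
# a samples x series matrix; returns a (level + 1) x nseries matrix.
dwt_energies <- function(x, level = 4) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n0 <- nrow(x)
  block <- 2^level
  n <- ceiling(n0 / block) * block
  if (n > n0) {
    pad <- n - n0
    x <- rbind(x, x[n0:(n0 - pad + 1), , drop = FALSE])
  }
  details <- matrix(0, level, ncol(x))
  a <- x
  for (l in seq_len(level)) {
    st <- dwt_step(a)
    details[l, ] <- colSums(st$detail^2)
    a <- st$approx
  }
  out <- rbind(colSums(a^2), details[rev(seq_len(level)), , drop = FALSE])
  rownames(out) <- c("approx", paste0("d", rev(seq_len(level))))
  out
}

#' Wavelet entropy of an epoch channel
#'
#' Shannon entropy (nats) of the relative subband energies of a 4-level
#' Daubechies-4 decomposition. All five subbands (details 1-4 plus the
#' level-4 approximation) enter the entropy, so the relative energies sum to
#' one and `0 <= E <= log(5)`. Low values indicate energy concentrated in few
#' subbands; in this task incorrect (fatigued) trials show lower entropy.
#'
#' @param x Numeric vector (one channel of one epoch), length >= 16.
#' @param level Decomposition depth (default 4).
#' @param subbands `"all"` uses the `level + 1` relative energies (default);
#'   `"details"` uses the `level` detail energies only.
#' @return Entropy in nats.
#' @examples
#' wavelet_entropy(rnorm(509))
#' @export
wavelet_entropy <- function(x, level = 4, subbands = c("all", "details")) {
  subbands <- match.arg(subbands)
  if (length(x) < 2^level) {
    abort(sprintf("epoch too short for a %d-level decomposition (need >= %d samples)",
                  level, 2^level))
  }
  e <- dwt_energies(x, level)[, 1]
  if (subbands == "details") e <- e[-1]
  tot <- sum(e)
  if (tot <= 0) {
    abort("wavelet entropy undefined for an all-zero epoch")
  }
  shannon_entropy(e / tot)
}

# -sum p log p with the p log p -> 0 convention for zero entries
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
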