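# Session-level eye-artifact removal: FastICA decomposition, correlation of
# each component with the raw lateral-frontal channels, removal and
# back-projection.

# symmetric FastICA with tanh contrast on a channels x samples matrix;
# deterministic under the given seed. The unmixing matrix is estimated on a
# decimated subset when the session exceeds max_samples points (the
# estimate is a sample average; a quarter-million points pin it down);
# sources and back-projection always use the full data.
fast_ica <- function(x, n_comp = nrow(x), seed = 0, max_iter = 300,
                     tol = 1e-4, max_samples = 250000) {
  nc <- nrow(x)
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors) # whitening
  z_full <- K %*% xc
  z <- if (n > max_samples) {
    z_full[, seq(1L, n, by = ceiling(n / max_samples)), drop = FALSE]
  } else {
    z_full
  }
  W <- with_local_seed(seed, matrix(rnorm(n_comp * nc), n_comp, nc))
  sym_decor <- function(W) {
    sw <- eigen(tcrossprod(W), symmetric = TRUE)
    sw$vectors %*% diag(1 / sqrt(sw$values)) %*% t(sw$vectors) %*% W
  }
  W <- sym_decor(W)
  it <- 0
  repeat {
    it <- it + 1
    wz <- W %*% z
    gz <- tanh(wz)
    W1 <- gz %*% t(z) / ncol(z) - diag(rowMeans(1 - gz^2)) %*% W
    W1 <- sym_decor(W1)
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol) break
    if (it >= max_iter) {
      abort(sprintf("FastICA did not converge after %d iterations (last change %.2e)",
                    it, conv))
    }
  }
  S <- W %*% z_full
  A <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(W) # X - mu = A %*% S
  list(S = S, A = A, W = W, K = K, mean = mu, iterations = it)
}

#' Remove eye-movement components from a session
#'
#' Decomposes the full continuous session into as many independent
#' components as channels (FastICA, tanh contrast, deterministic seeded
#' start), correlates every component time course with the raw LFL and RFL
#' channels over the whole session, removes the components whose
#' correlation exceeds the threshold, and back-projects the rest. With the
#' default criterion a component is removed when `|r|` exceeds the
#' threshold against *both* frontal reference channels, which is selective
#' for bilateral ocular potentials; `criterion = "either"` removes on
#' `max(|r_LFL|, |r_RFL|) > threshold`.
#'
#' Removing zero components makes the back-projection an exact inverse (up
#' to numerical tolerance), so `threshold = 1` returns the input unchanged.
#' Cleaning never alters the sample count, channel count or sampling rate.
#' Note ICA on already-cleaned data may decompose differently; the
#' operation is not idempotent and is intended to run once per session,
#' before epoching.
#'
#' @param session An [ecog_session()].
#' @param threshold Correlation threshold in (0, 1] (default 0.1).
#' @param criterion `"both"` (default) or `"either"`; see above.
#' @param seed Seed for the FastICA start (default 0).
#' @param max_iter,tol FastICA stopping controls; non-convergence is an
#'   error carrying the iteration count.
#' @return List with `session` (cleaned [ecog_session()]) and `report`, a
#'   tibble with one row per component: `component`, `r_lfl`, `r_rfl`,
#'   `removed`; the threshold, criterion and iteration count are attached
#'   as attributes.
#' @export
remove_eye_components <- function(session, threshold = 0.1,
                                  criterion = c("both", "either"),
                                  seed = 0, max_iter = 300, tol = 1e-4) {
  criterion <- match.arg(criterion)
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]")
  }
  refs <- session$channels$artifact_reference
  dec <- fast_ica(session$data, seed = seed, max_iter = max_iter, tol = tol)
  r_lfl <- as.numeric(cor(t(dec$S), session$data[refs[1], ]))
  r_rfl <- as.numeric(cor(t(dec$S), session$data[refs[2], ]))
  removed <- if (criterion == "both") {
    pmin(abs(r_lfl), abs(r_rfl)) > threshold
  } else {
    pmax(abs(r_lfl), abs(r_rfl)) > threshold
  }
  keep <- which(!removed)
  clean <- dec$A[, keep, drop = FALSE] %*% dec$S[keep, , drop = FALSE] +
    dec$mean
  report <- tibble::tibble(component = seq_len(nrow(dec$S)),
                           r_lfl = r_lfl, r_rfl = r_rfl, removed = removed)
  attr(report, "threshold") <- threshold
  attr(report, "criterion") <- criterion
  attr(report, "iterations") <- dec$iterations
  out_session <- ecog_session(clean, fs = session$fs,
                              channels = session$channels,
                              session_id = session$session_id)
  list(session = out_session, report = report)
}
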