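#' Standard 10-channel epidural ECoG layout
#'
#' The recording montage covers left/right occipital (LO, RO), temporal
#' (LT, RT), lateral and medial frontal (LFL, LFM, RFL, RFM) cortex and two
#' midline sites (FZ, CZ). The four frontal channels sit nearest the orbits
#' and carry most of the ocular potential; LFL and RFL are the reference
#' channels for the ICA eye-artifact rule.
#'
#' @param names Character vector of channel labels. Defaults to the standard
#'   10-channel montage; a custom layout must have unique names and contain
#'   `frontal` and `artifact_reference`.
#' @param frontal Labels of the frontal subset.
#' @param artifact_reference Labels correlated against ICA components when
#'   screening for eye-movement components. Must be a subset of `frontal`.
#' @return An object of class `channel_layout`: a list with elements
#'   `names`, `frontal`, `artifact_reference`.
#' @examples
#' channel_layout()
#' @export
channel_layout <- function(names = c("LO", "RO", "LT", "RT", "LFL", "LFM",
                                     "RFL", "RFM", "FZ", "CZ"),
                           frontal = c("LFL", "LFM", "RFL", "RFM"),
                           artifact_reference = c("LFL", "RFL")) {
  names <- as.character(names)
  if (anyDuplicated(names)) {
    abort("channel names must be unique")
  }
  if (!all(frontal %in% names)) {
    abort("frontal channels must be a subset of the channel names")
  }
  if (!all(artifact_reference %in% frontal)) {
    abort("artifact reference channels must be a subset of the frontal set")
  }
  structure(
    list(names = names, frontal = frontal,
         artifact_reference = artifact_reference),
    class = "channel_layout"
  )
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("<channel_layout> ", length(x$names), " channels: ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  cat("  frontal: ", paste(x$frontal, collapse = ", "),
      " | artifact reference: ",
      paste(x$artifact_reference, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# default sampling rate of the downsampled recordings (Hz)
VIGI_FS <- 508.6
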