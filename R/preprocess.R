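# Preprocessing contract: common-average re-referencing, consecutive 2-s
# epoching, threshold-based artifact rejection. Re-referencing precedes
# artifact detection.

#' Re-reference a recording to the common average
#'
#' Subtracts, at every time point, the instantaneous mean across all
#' channels, forcing a zero spatial mean. The operation is idempotent. A
#' single-channel recording degenerates to an all-zero signal.
#'
#' @param rec an [EEGRecording-class].
#' @return The re-referenced [EEGRecording-class] with reference
#'   `"common-average"`.
#' @export
rereferenceCommonAverage <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  avg <- colMeans(rec@samples)
  rec@samples <- sweep(rec@samples, 2, avg)
  rec@reference <- "common-average"
  rec
}

#' Segment a recording into consecutive non-overlapping epochs
#'
#' Epochs are anchored at the first sample; a trailing partial epoch is
#' discarded. All epochs start out flagged as kept.
#'
#' @param rec an [EEGRecording-class].
#' @param epochLength epoch length in seconds (default 2, giving 0.5 Hz
#'   spectral resolution at any sampling rate).
#' @return An [EpochSet-class].
#' @export
segmentEpochs <- function(rec, epochLength = 2) {
  stopifnot(is(rec, "EEGRecording"), epochLength > 0)
  spe <- epochLength * rec@fs
  if (abs(spe - round(spe)) > 1e-9)
    stop("epochLength * fs must be an integer number of samples")
  spe <- as.integer(round(spe))
  n <- floor(ncol(rec@samples) / spe)
  if (n < 1)
    stop(sprintf("recording (%.2f s) shorter than one epoch (%g s)",
                 duration(rec), epochLength))
  ep <- array(0, dim = c(n, nrow(rec@samples), spe))
  for (i in seq_len(n))
    ep[i, , ] <- rec@samples[, ((i - 1) * spe + 1):(i * spe)]
  new("EpochSet", epochs = ep, epochLength = epochLength, fs = rec@fs,
      keptMask = rep(TRUE, n), channels = rec@channels)
}

#' Reject artifact epochs by amplitude and gradient thresholds
#'
#' A deterministic proxy for expert visual artifact rejection: an epoch is
#' rejected when, on any channel, its peak-to-peak amplitude exceeds
#' `ampThreshold` or the largest absolute sample-to-sample step exceeds
#' `gradThreshold`. Rejected epochs stay in the object (flagged in the kept
#' mask) for audit.
#'
#' @param ep an [EpochSet-class].
#' @param ampThreshold peak-to-peak amplitude threshold, microvolts
#'   (default 100).
#' @param gradThreshold maximum sample-to-sample step, microvolts per
#'   sample (default 50).
#' @return The [EpochSet-class] with its kept mask updated. Errors if every
#'   epoch is rejected.
#' @export
rejectArtifactEpochs <- function(ep, ampThreshold = 100, gradThreshold = 50) {
  stopifnot(is(ep, "EpochSet"), ampThreshold > 0, gradThreshold > 0)
  n <- dim(ep@epochs)[1]
  kept <- ep@keptMask
  for (i in seq_len(n)) {
    if (!kept[i]) next
    x <- ep@epochs[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    p2p <- apply(x, 1, function(v) max(v) - min(v))
    grad <- apply(x, 1, function(v) max(abs(diff(v))))
    if (any(p2p > ampThreshold) || any(grad > gradThreshold))
      kept[i] <- FALSE
  }
  if (!any(kept))
    stop("all epochs rejected as artifactual; no data to analyze")
  ep@keptMask <- kept
  ep
}

#' Concatenate the kept epochs back into a signal matrix
#'
#' Utility for audit: reassembles the kept epochs, in order, into a
#' channels x samples matrix.
#'
#' @param ep an [EpochSet-class].
#' @return Numeric matrix, channels x (kept epochs * samples per epoch).
#' @export
concatenateKept <- function(ep) {
  stopifnot(is(ep, "EpochSet"))
  keep <- which(ep@keptMask)
  spe <- dim(ep@epochs)[3]
  out <- matrix(0, dim(ep@epochs)[2], length(keep) * spe)
  for (j in seq_along(keep))
    out[, ((j - 1) * spe + 1):(j * spe)] <- ep@epochs[keep[j], , ]
  rownames(out) <- ep@channels
  out
}
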