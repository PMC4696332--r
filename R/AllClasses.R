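#' @import methods
NULL

#' Canonical 19-channel 10-20 montage
#'
#' The standard 19 scalp positions of the international 10-20 system, in the
#' conventional anterior-to-posterior order. Channel label matching throughout
#' the package is case-insensitive against this set.
#'
#' @return Character vector of 19 channel labels.
#' @export
#' @examples
#' montage1020()
montage1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

.REFERENCES <- c("as-recorded", "linked-mastoid", "common-average")
.OUTCOME_LEVELS <- c("non-converter", "AD-converter", "nonAD-converter")
.RISK_LEVELS <- c("low", "middle", "high")

#' EEGRecording: a multichannel resting-state EEG recording
#'
#' Holds a channels x samples matrix of scalp potentials in microvolts,
#' the sampling rate, ordered channel labels and the active reference scheme.
#'
#' @slot samples numeric matrix, channels x time, microvolts; rownames are
#'   the channel labels.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot channels character, ordered unique channel labels.
#' @slot reference character(1), one of `"as-recorded"`, `"linked-mastoid"`,
#'   `"common-average"`.
#'
#' @export
setClass("EEGRecording",
  representation(
    samples = "matrix",
    fs = "numeric",
    channels = "character",
    reference = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive finite number")
  if (nrow(object@samples) < 1L)
    msg <- c(msg, "recording must have at least one channel")
  if (length(object@channels) != nrow(object@samples))
    msg <- c(msg, sprintf("%d channel labels but %d signal rows",
                          length(object@channels), nrow(object@samples)))
  if (anyDuplicated(tolower(object@channels)))
    msg <- c(msg, "channel labels must be unique (case-insensitive)")
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be numeric")
  if (length(object@reference) != 1L || !object@reference %in% .REFERENCES)
    msg <- c(msg, sprintf("reference must be one of: %s",
                          paste(.REFERENCES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param samples channels x time numeric matrix in microvolts.
#' @param fs sampling rate in Hz.
#' @param channels channel labels; defaults to the matrix rownames.
#' @param reference reference scheme the samples are expressed in.
#' @return An [EEGRecording-class] object.
#' @export
#' @examples
#' x <- matrix(rnorm(19 * 500), 19, 500, dimnames = list(montage1020(), NULL))
#' rec <- EEGRecording(x, fs = 250)
#' duration(rec)
EEGRecording <- function(samples, fs, channels = rownames(samples),
                         reference = "as-recorded") {
  samples <- as.matrix(samples)
  if (is.null(channels))
    channels <- paste0("ch", seq_len(nrow(samples)))
  if (length(channels) == nrow(samples))
    rownames(samples) <- channels            # else let validity report it
  new("EEGRecording", samples = samples, fs = as.numeric(fs),
      channels = as.character(channels), reference = reference)
}

#' EpochSet: a recording segmented into fixed-length epochs
#'
#' @slot epochs numeric array, n_epochs x channels x samples_per_epoch (uV).
#' @slot epochLength numeric(1), epoch length in seconds.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot keptMask logical, one flag per epoch; `FALSE` marks epochs rejected
#'   as artifactual. Rejected epochs are retained in `epochs` for audit.
#' @slot channels character, source channel labels.
#'
#' @export
setClass("EpochSet",
  representation(
    epochs = "array",
    epochLength = "numeric",
    fs = "numeric",
    keptMask = "logical",
    channels = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    msg <- c(msg, "epochs must be a 3-d array (epoch x channel x sample)")
  else {
    if (d[1] < 1L) msg <- c(msg, "need at least one epoch")
    if (length(object@keptMask) != d[1])
      msg <- c(msg, "keptMask length must equal the number of epochs")
    if (length(object@channels) != d[2])
      msg <- c(msg, "channel labels must match the channel dimension")
    spe <- object@epochLength * object@fs
    if (!isTRUE(all.equal(spe, d[3])) )
      msg <- c(msg, "samples per epoch must equal epochLength * fs exactly")
  }
  if (length(msg)) msg else TRUE
})

#' PowerSpectrum: per-channel Welch power spectral density
#'
#' @slot freqs numeric, frequency grid in Hz (fixed spacing, 0 to Nyquist).
#' @slot power numeric matrix, channels x bins, uV^2/Hz.
#' @slot nEpochsUsed integer(1), number of artifact-free epochs averaged.
#'
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", power = "matrix",
                 nEpochsUsed = "integer")
)

setValidity("PowerSpectrum", function(object) {
  msg <- character()
  if (ncol(object@power) != length(object@freqs))
    msg <- c(msg, "power columns must match the frequency grid")
  if (length(object@freqs) >= 2) {
    df <- diff(object@freqs)
    if (max(abs(df - df[1])) > 1e-9)
      msg <- c(msg, "frequency grid must be evenly spaced")
  }
  if (any(object@power < 0))
    msg <- c(msg, "power must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' CollapsedSpectrum: channel-averaged ("global field") power spectrum
#'
#' The arithmetic mean of per-channel Welch spectra over a channel set;
#' the substrate on which the anchor frequencies and band powers are
#' computed.
#'
#' @slot freqs numeric, frequency grid in Hz.
#' @slot power numeric, one power value per bin, uV^2/Hz.
#' @slot channelSet character, the labels that were averaged.
#'
#' @export
setClass("CollapsedSpectrum",
  representation(freqs = "numeric", power = "numeric",
                 channelSet = "character")
)

setValidity("CollapsedSpectrum", function(object) {
  msg <- character()
  if (length(object@power) != length(object@freqs))
    msg <- c(msg, "power length must match the frequency grid")
  if (any(object@power < 0))
    msg <- c(msg, "power must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' AnchorFrequencies: the subject-specific TF and IAF anchors
#'
#' TF is the theta/alpha transition frequency (the spectral trough between
#' theta and alpha activity); IAF is the individual alpha frequency peak
#' (maximum power in the extended alpha range). All subject-specific band
#' edges derive from these two anchors.
#'
#' @slot tf numeric(1), transition frequency in Hz.
#' @slot iaf numeric(1), individual alpha frequency in Hz.
#' @slot flags character, quality flags; any of `"no-alpha-peak"`,
#'   `"double-peak"`, `"tf-at-boundary"`.
#'
#' @export
setClass("AnchorFrequencies",
  representation(tf = "numeric", iaf = "numeric", flags = "character")
)

setValidity("AnchorFrequencies", function(object) {
  msg <- character()
  if (length(object@tf) != 1L || length(object@iaf) != 1L)
    msg <- c(msg, "tf and iaf must be single numbers")
  else {
    if (!is.finite(object@tf) || object@tf <= 0)
      msg <- c(msg, "tf must be positive")
    if (!is.finite(object@iaf) || object@iaf <= object@tf)
      msg <- c(msg, "iaf must exceed tf")
  }
  bad <- setdiff(object@flags,
                 c("no-alpha-peak", "double-peak", "tf-at-boundary"))
  if (length(bad))
    msg <- c(msg, sprintf("unknown quality flag(s): %s",
                          paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an AnchorFrequencies object
#'
#' @param tf theta/alpha transition frequency, Hz.
#' @param iaf individual alpha frequency peak, Hz; must exceed `tf`.
#' @param flags character vector of quality flags.
#' @return An [AnchorFrequencies-class] object.
#' @export
#' @examples
#' anchorFrequencies(tf = 6.9, iaf = 10.9)
anchorFrequencies <- function(tf, iaf, flags = character()) {
  new("AnchorFrequencies", tf = as.numeric(tf), iaf = as.numeric(iaf),
      flags = flags)
}

#' BandScheme: subject-specific frequency band edges
#'
#' An ordered table of half-open frequency bands `[lo, hi)`. The five
#' anchored bands (delta, theta, alpha1, alpha2, alpha3) are contiguous by
#' construction; beta1/beta2/gamma edges are configuration, not anchored by
#' the TF/IAF construct.
#'
#' @slot bands data.frame with columns `band` (character), `lo`, `hi` (Hz).
#' @slot anchors the [AnchorFrequencies-class] the scheme derives from.
#'
#' @export
setClass("BandScheme",
  representation(bands = "data.frame", anchors = "AnchorFrequencies")
)

setValidity("BandScheme", function(object) {
  msg <- character()
  b <- object@bands
  if (!all(c("band", "lo", "hi") %in% names(b)))
    msg <- c(msg, "bands must have columns band, lo, hi")
  else {
    if (any(b$hi <= b$lo)) msg <- c(msg, "band edges must satisfy lo < hi")
    core <- b[match(c("delta", "theta", "alpha1", "alpha2", "alpha3"), b$band), ]
    if (!anyNA(core$lo)) {
      if (max(abs(core$hi[-5] - core$lo[-1])) > 1e-9)
        msg <- c(msg, "delta..alpha3 must be contiguous")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SubjectMarkers: per-subject EEG biomarker panel
#'
#' @slot relPower named numeric, relative power per band (unitless; absolute
#'   band power divided by total power over the 2-45 Hz analysis range).
#' @slot a3a2 numeric(1), alpha3/alpha2 power ratio.
#' @slot thetaGamma numeric(1), theta/gamma power ratio.
#' @slot riskGroup character(1), `"low"`, `"middle"` or `"high"`.
#'
#' @export
setClass("SubjectMarkers",
  representation(relPower = "numeric", a3a2 = "numeric",
                 thetaGamma = "numeric", riskGroup = "character")
)

setValidity("SubjectMarkers", function(object) {
  msg <- character()
  if (any(object@relPower < 0)) msg <- c(msg, "relative powers must be >= 0")
  if (length(object@riskGroup) != 1L ||
      !object@riskGroup %in% c(.RISK_LEVELS, NA_character_))
    msg <- c(msg, "riskGroup must be one of low, middle, high")
  if (length(msg)) msg else TRUE
})
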