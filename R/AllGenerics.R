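#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `samplingRate()`
#' and `channelNames()` for recordings, epoch sets and spectra;
#' `duration()` for recordings; `keptMask()` for epoch sets; `freqs()` and
#' `psdPower()` for spectra; `bandTable()` for band schemes;
#' `relativePowers()` for marker panels.
#'
#' @param object an alphaband S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("keptMask", function(object) standardGeneric("keptMask"))

#' @rdname accessors
#' @export
setGeneric("freqs", function(object) standardGeneric("freqs"))

#' @rdname accessors
#' @export
setGeneric("psdPower", function(object) standardGeneric("psdPower"))

#' @rdname accessors
#' @export
setGeneric("bandTable", function(object) standardGeneric("bandTable"))

#' @rdname accessors
#' @export
setGeneric("relativePowers", function(object) standardGeneric("relativePowers"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@fs)

#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(object) object@channels)

#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channels)

#' @rdname accessors
#' @export
setMethod("channelNames", "PowerSpectrum",
          function(object) rownames(object@power))

#' @rdname accessors
#' @export
setMethod("duration", "EEGRecording",
          function(object) ncol(object@samples) / object@fs)

#' @rdname accessors
#' @export
setMethod("keptMask", "EpochSet", function(object) object@keptMask)

#' @rdname accessors
#' @export
setMethod("freqs", "PowerSpectrum", function(object) object@freqs)

#' @rdname accessors
#' @export
setMethod("freqs", "CollapsedSpectrum", function(object) object@freqs)

#' @rdname accessors
#' @export
setMethod("psdPower", "PowerSpectrum", function(object) object@power)

#' @rdname accessors
#' @export
setMethod("psdPower", "CollapsedSpectrum", function(object) object@power)

#' @rdname accessors
#' @export
setMethod("bandTable", "BandScheme", function(object) object@bands)

#' @rdname accessors
#' @export
setMethod("relativePowers", "SubjectMarkers", function(object) object@relPower)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(object@samples), ncol(object@samples),
              duration(object), object@fs))
  cat("  reference:", object@reference, "\n")
  cat("  channels: ", paste(utils::head(object@channels, 8), collapse = " "),
      if (length(object@channels) > 8) "..." else "", "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet: %d epochs of %g s (%d kept), %d channels at %g Hz\n",
              d[1], object@epochLength, sum(object@keptMask), d[2], object@fs))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d channels x %d bins, %g-%g Hz (df = %g Hz), %d epochs\n",
              nrow(object@power), length(object@freqs), min(object@freqs),
              max(object@freqs), diff(object@freqs[1:2]), object@nEpochsUsed))
})

setMethod("show", "CollapsedSpectrum", function(object) {
  cat(sprintf("CollapsedSpectrum over %d channels: %d bins, %g-%g Hz\n",
              length(object@channelSet), length(object@freqs),
              min(object@freqs), max(object@freqs)))
})

setMethod("show", "AnchorFrequencies", function(object) {
  cat(sprintf("AnchorFrequencies: TF = %g Hz, IAF = %g Hz%s\n",
              object@tf, object@iaf,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ", "), "]")
              else ""))
})

setMethod("show", "BandScheme", function(object) {
  cat("BandScheme (half-open [lo, hi) Hz):\n")
  b <- object@bands
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-7s %5.2f - %5.2f\n", b$band[i], b$lo[i], b$hi[i]))
})

setMethod("show", "SubjectMarkers", function(object) {
  cat("SubjectMarkers:\n")
  cat("  relative power:",
      paste(sprintf("%s=%.4f", names(object@relPower), object@relPower),
            collapse = " "), "\n")
  cat(sprintf("  alpha3/alpha2 = %.4f   theta/gamma = %.4f   risk = %s\n",
              object@a3a2, object@thetaGamma, object@riskGroup))
})
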