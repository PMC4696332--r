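# Welch power spectral density on artifact-free epochs, and the collapsed
# (channel-averaged, "global field") spectrum the band analysis runs on.

# Periodic Hann window of length n.
.hann <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Welch power spectral density of an epoch set
#'
#' One Hann-windowed FFT per kept epoch, no overlap between segments (the
#' segments are the consecutive artifact-free epochs themselves), averaged
#' into a one-sided density per channel. 2-s epochs give the 0.5 Hz grid
#' the banding layer expects. The density is normalized by the window's
#' mean square, so broadband (white) noise levels are unbiased: for white
#' noise of variance s^2 the density integrates back to s^2.
#'
#' @param ep an [EpochSet-class] (only kept epochs are used).
#' @return A [PowerSpectrum-class] on the grid `0, 1/L, ..., fs/2` Hz where
#'   `L` is the epoch length in seconds; units uV^2/Hz.
#' @export
welchPsd <- function(ep) {
  stopifnot(is(ep, "EpochSet"))
  keep <- which(ep@keptMask)
  if (length(keep) == 0) stop("no kept epochs; cannot estimate a spectrum")
  spe <- dim(ep@epochs)[3]
  nch <- dim(ep@epochs)[2]
  w <- .hann(spe)
  U <- mean(w^2)
  nbins <- spe %/% 2 + 1
  fgrid <- (seq_len(nbins) - 1) * ep@fs / spe
  acc <- matrix(0, nch, nbins)
  for (i in keep) {
    x <- ep@epochs[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    xw <- sweep(x, 2, w, `*`)
    X <- t(stats::mvfft(t(xw)))
    p <- (Mod(X[, seq_len(nbins), drop = FALSE])^2) / (ep@fs * spe * U)
    # one-sided: double everything except DC and (for even spe) Nyquist
    dbl <- rep(2, nbins)
    dbl[1] <- 1
    if (spe %% 2 == 0) dbl[nbins] <- 1
    acc <- acc + sweep(p, 2, dbl, `*`)
  }
  power <- acc / length(keep)
  rownames(power) <- ep@channels
  new("PowerSpectrum", freqs = fgrid, power = power,
      nEpochsUsed = length(keep))
}

#' Collapse a per-channel spectrum across electrodes
#'
#' Unweighted arithmetic mean of the selected channels' power vectors —
#' the "global field" spectrum used for anchor detection, chosen to reduce
#' channel-to-channel variability and yield a single robust alpha peak.
#'
#' @param ps a [PowerSpectrum-class].
#' @param channels labels to average, or `"all"` (default).
#' @return A [CollapsedSpectrum-class] on the same grid.
#' @export
collapseSpectrum <- function(ps, channels = "all") {
  stopifnot(is(ps, "PowerSpectrum"))
  have <- rownames(ps@power)
  if (identical(channels, "all")) {
    idx <- seq_along(have)
  } else {
    if (length(channels) == 0) stop("channel subset must be non-empty")
    idx <- matchChannels(channels, have)
  }
  new("CollapsedSpectrum", freqs = ps@freqs,
      power = colMeans(ps@power[idx, , drop = FALSE]),
      channelSet = have[idx])
}

#' Macroarea channel memberships
#'
#' The 10-20 labels assigned to the two macroareas used in the collapsed-
#' spectrum reliability check. Memberships follow 10-20 lobe nomenclature:
#' frontotemporal = frontal + temporal rows, parietoccipital = parietal +
#' occipital rows; the central row (C3, Cz, C4) belongs to neither.
#'
#' @param area `"frontotemporal"` or `"parietoccipital"`.
#' @return Character vector of channel labels.
#' @export
macroareaChannels <- function(area = c("frontotemporal", "parietoccipital")) {
  area <- match.arg(area)
  switch(area,
    frontotemporal = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                       "T3", "T4", "T5", "T6"),
    parietoccipital = c("P3", "Pz", "P4", "O1", "O2"))
}

#' Band power in an absolute band of a spectrum
#'
#' Sum of the power density over the bins falling in the half-open
#' interval `[lo, hi)`, times the grid spacing. Internal building block
#' for relative powers and the macroarea check.
#'
#' @param cs a [CollapsedSpectrum-class] (or [PowerSpectrum-class], summed
#'   per channel).
#' @param band numeric(2), `c(lo, hi)` in Hz.
#' @return Band power (uV^2); for a [PowerSpectrum-class], one value per
#'   channel.
#' @export
absoluteBandPower <- function(cs, band) {
  stopifnot(length(band) == 2, band[2] > band[1])
  f <- freqs(cs)
  sel <- f >= band[1] - 1e-9 & f < band[2] - 1e-9
  if (!any(sel)) stop("no spectral bins fall in the requested band")
  df <- f[2] - f[1]
  if (is(cs, "PowerSpectrum"))
    rowSums(cs@power[, sel, drop = FALSE]) * df
  else
    sum(cs@power[sel]) * df
}

#' Correlation of global-field band power with a macroarea, across subjects
#'
#' Reliability check for the collapsed-spectrum method: Pearson correlation
#' across subjects between total alpha-band power of the global field
#' spectrum and the same band power computed on a macroarea subset of
#' electrodes.
#'
#' @param globalPower numeric vector: per-subject band power of the
#'   all-channel collapsed spectrum.
#' @param areaPower numeric vector: per-subject band power of the macroarea
#'   collapsed spectrum (same subjects, same order).
#' @return A list with `r`, `p` (two-sided), and `n`.
#' @export
macroareaAlphaCorrelation <- function(globalPower, areaPower) {
  if (length(globalPower) != length(areaPower))
    stop("per-subject vectors must have equal length")
  ok <- is.finite(globalPower) & is.finite(areaPower)
  if (sum(ok) < 3) stop("need at least 3 subjects with complete band powers")
  x <- globalPower[ok]; y <- areaPower[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance across subjects; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
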