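# The core construct: subject-specific frequency anchors (TF, IAF) detected
# on the collapsed spectrum, band edges derived from them, relative band
# powers, the alpha3/alpha2 and theta/gamma power ratios, and risk grouping.

#' Detect the individual alpha frequency (IAF) peak
#'
#' The IAF is the frequency of maximum power within the extended alpha
#' range, searched among bins that are local peaks of the spectrum (power
#' not smaller than both neighbours). Ties go to the higher frequency. If
#' the spectrum is monotone in the search range (no local peak), the global
#' maximum in range is returned together with the `no-alpha-peak` quality
#' flag. When a secondary local peak reaches 95% of the winner's power at
#' least 1 Hz away, the `double-peak` flag is raised.
#'
#' @param cs a [CollapsedSpectrum-class].
#' @param search numeric(2), inclusive search range in Hz (default
#'   `c(5, 14)`, the extended alpha range).
#' @return List with `iaf` (Hz, on the spectral grid) and `flags`
#'   (character).
#' @export
detectIAF <- function(cs, search = c(5, 14)) {
  stopifnot(is(cs, "CollapsedSpectrum"), length(search) == 2)
  f <- cs@freqs; p <- cs@power
  if (search[1] < min(f) - 1e-9 || search[2] > max(f) + 1e-9)
    stop("IAF search range extends beyond the spectral grid")
  inRange <- which(f >= search[1] - 1e-9 & f <= search[2] + 1e-9)
  if (length(inRange) == 0) stop("no spectral bins in the IAF search range")

  nb <- length(p)
  isPeak <- vapply(inRange, function(i) {
    left <- if (i > 1) p[i - 1] else -Inf
    right <- if (i < nb) p[i + 1] else -Inf
    p[i] >= left && p[i] >= right
  }, logical(1))

  flags <- character()
  if (any(isPeak)) {
    cand <- inRange[isPeak]
  } else {
    cand <- inRange
    flags <- c(flags, "no-alpha-peak")
  }
  best <- max(p[cand])
  winner <- max(cand[p[cand] >= best * (1 - 1e-12)])   # ties -> higher freq
  if (any(isPeak)) {
    peaks <- inRange[isPeak]
    rival <- peaks[p[peaks] >= 0.95 * best & abs(f[peaks] - f[winner]) >= 1]
    if (length(rival)) flags <- c(flags, "double-peak")
  }
  list(iaf = f[winner], flags = flags)
}

#' Detect the theta/alpha transition frequency (TF)
#'
#' The TF estimates the frequency at which the theta and alpha spectra
#' intersect, computed as the minimum power in the pre-alpha trough. The
#' search window is `[searchLow, iaf - 0.5]` Hz, anchored below the
#' detected IAF so the window is subject-specific and non-empty. Ties go
#' to the lower frequency; if the minimum sits at either window end the
#' `tf-at-boundary` flag is raised.
#'
#' @param cs a [CollapsedSpectrum-class].
#' @param iaf detected individual alpha frequency, Hz.
#' @param searchLow lower end of the trough search window, Hz
#'   (default `max(4, iaf - 6)`).
#' @return List with `tf` (Hz, on the grid) and `flags`.
#' @export
detectTF <- function(cs, iaf, searchLow = max(4, iaf - 6)) {
  stopifnot(is(cs, "CollapsedSpectrum"), length(iaf) == 1)
  hi <- iaf - 0.5
  if (searchLow >= hi) stop("empty TF search window: searchLow must be < iaf - 0.5")
  f <- cs@freqs; p <- cs@power
  win <- which(f >= searchLow - 1e-9 & f <= hi + 1e-9)
  if (length(win) == 0) stop("no spectral bins in the TF search window")
  best <- min(p[win])
  winner <- min(win[p[win] <= best * (1 + 1e-12) + 1e-300])  # ties -> lower
  flags <- character()
  if (winner == win[1] || winner == win[length(win)])
    flags <- "tf-at-boundary"
  list(tf = f[winner], flags = flags)
}

#' Default fixed high-frequency band edges
#'
#' Beta and gamma edges are not anchored by the TF/IAF construct; these
#' defaults place beta1 at `[IAF+2, IAF+5)`, beta2 at `[IAF+5, 30)` and
#' gamma at `[30, 45)` Hz. Theta/gamma ratio results depend on this
#' choice; it is configuration, not a detected quantity.
#'
#' @return Named list of `c(lo, hi)` pairs; `NA` entries are filled from
#'   the anchors at band construction.
#' @export
defaultHighBands <- function() {
  list(beta1 = c(NA, NA), beta2 = c(NA, 30), gamma = c(30, 45))
}

#' Build the subject-specific band scheme from the anchors
#'
#' The anchored bands are: delta `[TF-4, TF-2)`, theta `[TF-2, TF)`,
#' alpha1 `[TF, mid)`, alpha2 `[mid, IAF)`, alpha3 `[IAF, IAF+2)`, with
#' `mid` the midpoint of the TF-IAF range. The midpoint is snapped by
#' rounding the TF-IAF half-range half-up to a 0.5 Hz multiple, so
#' grid-aligned anchors always yield a grid-aligned boundary while the
#' arithmetic of the edges is preserved for off-grid anchors. The optional
#' beta1/beta2/gamma bands are appended from `highBands` (defaults:
#' `[IAF+2, IAF+5)`, `[IAF+5, 30)`, `[30, 45)`).
#'
#' @param anchors an [AnchorFrequencies-class]; `tf` must be at least 4 Hz
#'   so the delta lower edge is nonnegative.
#' @param highBands named list of fixed high-band edges, or `NULL` to omit
#'   them; see [defaultHighBands()].
#' @param grid snapping grid in Hz (default 0.5, the spectral resolution).
#' @return A [BandScheme-class].
#' @export
#' @examples
#' defineBands(anchorFrequencies(tf = 6.9, iaf = 10.9))
defineBands <- function(anchors, highBands = defaultHighBands(), grid = 0.5) {
  stopifnot(is(anchors, "AnchorFrequencies"))
  tf <- anchors@tf; iaf <- anchors@iaf
  if (tf < 4) stop("tf must be >= 4 Hz so that the delta band starts above 0 Hz")
  if (iaf <= tf) stop("iaf must exceed tf")
  mid <- tf + roundHalfUp((iaf - tf) / 2, grid)
  if (mid <= tf || mid >= iaf)
    stop("snapped midpoint collapses a band; anchors too close together")
  bands <- data.frame(
    band = c("delta", "theta", "alpha1", "alpha2", "alpha3"),
    lo = c(tf - 4, tf - 2, tf, mid, iaf),
    hi = c(tf - 2, tf, mid, iaf, iaf + 2),
    stringsAsFactors = FALSE)
  if (!is.null(highBands)) {
    hb <- highBands
    if (!is.null(hb$beta1)) {
      lo <- if (is.na(hb$beta1[1])) iaf + 2 else hb$beta1[1]
      hi <- if (is.na(hb$beta1[2])) iaf + 5 else hb$beta1[2]
      bands <- rbind(bands, data.frame(band = "beta1", lo = lo, hi = hi))
    }
    if (!is.null(hb$beta2)) {
      lo <- if (is.na(hb$beta2[1])) iaf + 5 else hb$beta2[1]
      hi <- hb$beta2[2]
      bands <- rbind(bands, data.frame(band = "beta2", lo = lo, hi = hi))
    }
    if (!is.null(hb$gamma))
      bands <- rbind(bands, data.frame(band = "gamma", lo = hb$gamma[1],
                                       hi = hb$gamma[2]))
  }
  new("BandScheme", bands = bands, anchors = anchors)
}

#' Relative power of a frequency band
#'
#' Absolute band power divided by the total power over the analysis range;
#' bins are assigned half-open `[lo, hi)` for both the band and the total
#' range, so contiguous bands never double-count a bin and their relative
#' powers are additive.
#'
#' @param cs a [CollapsedSpectrum-class].
#' @param band numeric(2) `c(lo, hi)` in Hz, within the total range.
#' @param total numeric(2), the normalization range (default `c(2, 45)` Hz).
#' @param clip if `TRUE`, intersect the band with the total range instead
#'   of erroring when it protrudes (a band entirely outside yields zero);
#'   needed for subjects whose transition frequency sits below 6 Hz, where
#'   the delta band `[TF-4, TF-2)` breaches the 2 Hz analysis floor. The
#'   default is the strict contract.
#' @return Unitless relative power in `[0, 1]` for bands inside the total
#'   range.
#' @export
relativeBandPower <- function(cs, band, total = c(2, 45), clip = FALSE) {
  stopifnot(is(cs, "CollapsedSpectrum"))
  if (band[1] < total[1] - 1e-9 || band[2] > total[2] + 1e-9) {
    if (!clip)
      stop("band must lie within the total normalization range")
    band <- c(max(band[1], total[1]), min(band[2], total[2]))
    if (band[2] <= band[1]) return(0)   # band entirely outside the range
  }
  tot <- absoluteBandPower(cs, total)
  if (tot <= 0) stop("zero total power in the normalization range")
  absoluteBandPower(cs, band) / tot
}

#' Relative power of every band in a scheme
#'
#' @param cs a [CollapsedSpectrum-class].
#' @param scheme a [BandScheme-class].
#' @param total normalization range, Hz.
#' @param clip see [relativeBandPower()].
#' @return Named numeric vector of relative powers.
#' @export
relativeBandPowers <- function(cs, scheme, total = c(2, 45), clip = FALSE) {
  stopifnot(is(scheme, "BandScheme"))
  b <- scheme@bands
  out <- vapply(seq_len(nrow(b)), function(i)
    relativeBandPower(cs, c(b$lo[i], b$hi[i]), total = total, clip = clip),
    numeric(1))
  names(out) <- b$band
  out
}

#' Compute the alpha3/alpha2 and theta/gamma power ratios
#'
#' Ratios of band powers. Because the normalization denominator cancels,
#' the ratios are identical whether computed from absolute or relative
#' powers and are invariant to any positive rescaling of the spectrum.
#'
#' @param powers named numeric vector of band powers (absolute or
#'   relative) containing at least `alpha2` and `alpha3`; `theta` and
#'   `gamma` are needed for the theta/gamma ratio.
#' @return List with `a3a2` and `thetaGamma` (`NA` if theta or gamma is
#'   absent).
#' @export
computeRatios <- function(powers) {
  need <- c("alpha2", "alpha3")
  if (!all(need %in% names(powers)))
    stop("band powers must include alpha2 and alpha3")
  if (powers[["alpha2"]] <= 0)
    stop("zero alpha2 band power; alpha3/alpha2 ratio undefined")
  a3a2 <- powers[["alpha3"]] / powers[["alpha2"]]
  tg <- NA_real_
  if (all(c("theta", "gamma") %in% names(powers))) {
    if (powers[["gamma"]] <= 0)
      stop("zero gamma band power; theta/gamma ratio undefined")
    tg <- powers[["theta"]] / powers[["gamma"]]
  }
  list(a3a2 = a3a2, thetaGamma = tg)
}

#' Classify a subject into a low/middle/high alpha3/alpha2 risk group
#'
#' Fixed cut-off rule (the published tertile boundaries): low when
#' ratio < 1, high when ratio >= 1.17, middle otherwise — the printed
#' 1.16/1.17 gap is closed by assigning `[1.0, 1.17)` to the middle group,
#' since the published high-group range starts at 1.17. The cohort-tertile
#' rule instead uses the empirical tertile boundaries of a supplied cohort,
#' with boundary ties going to the lower group.
#'
#' @param ratio alpha3/alpha2 ratio(s), positive numeric.
#' @param rule `"fixed-cutoff"` (default) or `"cohort-tertile"`.
#' @param cohort numeric vector of cohort ratios (>= 3 values), required
#'   for the tertile rule.
#' @return Factor with levels `low`, `middle`, `high`.
#' @export
#' @examples
#' classifyRisk(c(0.9, 1.08, 1.29))
classifyRisk <- function(ratio, rule = c("fixed-cutoff", "cohort-tertile"),
                         cohort = NULL) {
  rule <- match.arg(rule)
  if (rule == "fixed-cutoff") {
    lab <- ifelse(ratio < 1, "low", ifelse(ratio < 1.17, "middle", "high"))
  } else {
    if (is.null(cohort) || length(cohort) < 3)
      stop("cohort-tertile rule needs at least 3 cohort ratios")
    cuts <- stats::quantile(cohort, c(1, 2) / 3, names = FALSE)
    lab <- ifelse(ratio <= cuts[1], "low",
                  ifelse(ratio <= cuts[2], "middle", "high"))
  }
  factor(lab, levels = .RISK_LEVELS)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the single-subject pipeline with their
#' defaults: 2-s epochs (0.5 Hz resolution), 100 uV peak-to-peak and
#' 50 uV/sample artifact thresholds, IAF search 5-14 Hz, 2-45 Hz
#' normalization range, fixed-cutoff risk rule.
#'
#' @return Named list of configuration values.
#' @export
defaultConfig <- function() {
  list(
    epoch_length_s = 2,
    amp_threshold_uv = 100,
    grad_threshold_uv = 50,
    iaf_search_hz = c(5, 14),
    total_range_hz = c(2, 45),
    high_bands = defaultHighBands(),
    risk_rule = "fixed-cutoff",
    rereference = TRUE
  )
}

#' Run the full single-subject pipeline
#'
#' Re-references to the common average, segments into epochs, rejects
#' artifact epochs, estimates the Welch spectrum, collapses it across all
#' electrodes, detects the anchors, builds the band scheme and computes
#' relative powers, ratios and the risk group. Deterministic; all
#' intermediates are returned for audit. Stage failures are re-signalled
#' with the stage name prefixed.
#'
#' @param rec an [EEGRecording-class].
#' @param config configuration list as from [defaultConfig()]; entries not
#'   supplied fall back to the defaults.
#' @return List with elements `markers` ([SubjectMarkers-class]), `anchors`
#'   ([AnchorFrequencies-class]), `bands` ([BandScheme-class]), `spectrum`
#'   ([CollapsedSpectrum-class]), `perChannel` ([PowerSpectrum-class]),
#'   `epochs` ([EpochSet-class]) and `config`.
#' @export
subjectPipeline <- function(rec, config = defaultConfig()) {
  cfg <- utils::modifyList(defaultConfig(), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (isTRUE(cfg$rereference))
    rec <- stage("rereference", rereferenceCommonAverage(rec))
  ep <- stage("segment", segmentEpochs(rec, cfg$epoch_length_s))
  ep <- stage("artifact-rejection",
              rejectArtifactEpochs(ep, cfg$amp_threshold_uv,
                                   cfg$grad_threshold_uv))
  ps <- stage("welch", welchPsd(ep))
  cs <- stage("collapse", collapseSpectrum(ps, "all"))
  iafRes <- stage("iaf", detectIAF(cs, cfg$iaf_search_hz))
  tfRes <- stage("tf", detectTF(cs, iafRes$iaf))
  anchors <- stage("anchors",
                   anchorFrequencies(tfRes$tf, iafRes$iaf,
                                     flags = c(iafRes$flags, tfRes$flags)))
  scheme <- stage("bands", defineBands(anchors, cfg$high_bands))
  rel <- stage("band-power",
               relativeBandPowers(cs, scheme, total = cfg$total_range_hz,
                                  clip = TRUE))
  ratios <- stage("ratios", computeRatios(rel))
  risk <- stage("risk", classifyRisk(ratios$a3a2, rule = cfg$risk_rule))
  markers <- new("SubjectMarkers", relPower = rel, a3a2 = ratios$a3a2,
                 thetaGamma = ratios$thetaGamma,
                 riskGroup = as.character(risk))
  list(markers = markers, anchors = anchors, bands = scheme, spectrum = cs,
       perChannel = ps, epochs = ep, config = cfg)
}

#' Write a per-subject report
#'
#' Emits the pipeline result as JSON (anchors, flags, band edges, relative
#' powers, ratios, risk group) plus a TSV of band edges and powers.
#'
#' @param result a [subjectPipeline()] result list.
#' @param dir output directory (created if absent).
#' @param name base name for the report files.
#' @return Invisibly, the JSON path.
#' @export
writeSubjectReport <- function(result, dir, name = "subject") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  b <- result$bands@bands
  rep <- list(
    anchors = list(tf = result$anchors@tf, iaf = result$anchors@iaf,
                   flags = result$anchors@flags),
    bands = b,
    relative_power = as.list(result$markers@relPower),
    a3_a2_ratio = result$markers@a3a2,
    theta_gamma_ratio = result$markers@thetaGamma,
    risk_group = result$markers@riskGroup,
    n_epochs_used = result$perChannel@nEpochsUsed)
  jpath <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(rep, jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  tab <- cbind(b, relative_power = result$markers@relPower[b$band])
  utils::write.table(tab, file.path(dir, paste0(name, "_bands.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(jpath)
}
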