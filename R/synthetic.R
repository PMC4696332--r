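# Synthetic EEG and cohort generation. The signal model is a shared
# cortical source per subject — 1/f (pink) background plus narrowband
# oscillators at the theta and alpha anchor frequencies — scaled by a
# per-channel gain map, plus independent white sensor noise per channel.
# Every component has a closed-form expected power spectral density, so
# the whole pipeline can be checked against an analytic oracle.

#' Default posterior-dominant channel gain map
#'
#' Per-channel gains for the shared cortical source, graded from frontal
#' to occipital the way eyes-closed alpha topography is: weakest over the
#' frontopolar row, strongest over the occiput. The spatial variation is
#' essential: a spatially uniform source would be annihilated by
#' common-average re-referencing.
#'
#' @return Named numeric vector over the 19-label montage.
#' @export
defaultGains <- function() {
  c(Fp1 = 0.5, Fp2 = 0.5, F7 = 0.6, F3 = 0.7, Fz = 0.7, F4 = 0.7, F8 = 0.6,
    T3 = 0.7, C3 = 0.9, Cz = 0.9, C4 = 0.9, T4 = 0.7,
    T5 = 1.1, P3 = 1.3, Pz = 1.3, P4 = 1.3, T6 = 1.1, O1 = 1.5, O2 = 1.5)
}

#' Specify a synthetic EEG subject
#'
#' Oscillators are narrowband Gaussian processes (equivalent to
#' amplitude-modulated sinusoids with a Gaussian spectral envelope), so
#' spectral peaks have realistic width. Amplitudes are root-mean-square
#' values in microvolts. Three oscillators shape the spectrum: a theta
#' component 1.5 Hz below the true transition frequency (FWHM
#' `thetaBandwidth`), a low-alpha component 1 Hz below the alpha peak
#' (FWHM `alphaLowBandwidth`) supplying the low-alpha mass real spectra
#' carry, and a sharp high-alpha component at `iafTrue` (FWHM
#' `oscBandwidth`) that defines the detectable peak. The theta/alpha
#' trough between the theta and alpha components is the transition
#' frequency the pipeline should recover.
#'
#' @param iafTrue true individual alpha frequency, Hz (5-14).
#' @param tfTrue true theta/alpha transition frequency, Hz (< `iafTrue`).
#' @param ampTheta,ampAlphaLow,ampAlphaHigh oscillator RMS amplitudes, uV.
#' @param exponent 1/f spectral exponent of the pink background.
#' @param pinkScale RMS amplitude of the pink background over 2-45 Hz, uV.
#' @param noiseSd per-channel white sensor noise SD, uV.
#' @param gains named per-channel gain map (default [defaultGains()]).
#' @param oscBandwidth FWHM of the high-alpha peak, Hz.
#' @param thetaBandwidth FWHM of the theta component, Hz.
#' @param alphaLowBandwidth FWHM of the low-alpha component, Hz.
#' @param seed RNG seed fixing the full sample path.
#' @return A `subjectSpec` list.
#' @export
subjectSpec <- function(iafTrue = 10, tfTrue = 7,
                        ampTheta = 4, ampAlphaLow = 8, ampAlphaHigh = 10,
                        exponent = 1.3, pinkScale = 8, noiseSd = 2,
                        gains = defaultGains(),
                        oscBandwidth = 1, thetaBandwidth = 1.5,
                        alphaLowBandwidth = 1.6,
                        seed = 1) {
  if (iafTrue < 5 || iafTrue > 14) stop("iafTrue must be in [5, 14] Hz")
  if (tfTrue >= iafTrue) stop("tfTrue must be below iafTrue")
  if (min(ampTheta, ampAlphaLow, ampAlphaHigh, pinkScale, noiseSd) < 0)
    stop("amplitudes must be nonnegative")
  structure(list(iafTrue = iafTrue, tfTrue = tfTrue, ampTheta = ampTheta,
                 ampAlphaLow = ampAlphaLow, ampAlphaHigh = ampAlphaHigh,
                 exponent = exponent, pinkScale = pinkScale,
                 noiseSd = noiseSd, gains = gains,
                 oscBandwidth = oscBandwidth,
                 thetaBandwidth = thetaBandwidth,
                 alphaLowBandwidth = alphaLowBandwidth, seed = seed),
            class = "subjectSpec")
}

#' Low-risk and high-risk subject presets
#'
#' Two reference subject specifications whose analytic alpha3/alpha2
#' ratios fall near the published low-risk (0.9) and high-risk (1.29)
#' group means: the high-risk preset has a stronger high-alpha shoulder
#' relative to the mid-alpha peak.
#'
#' @param seed RNG seed.
#' @return A `subjectSpec`.
#' @name presets
#' @export
lowRiskSubject <- function(seed = 1) {
  subjectSpec(iafTrue = 10, tfTrue = 7, ampTheta = 4,
              ampAlphaLow = 8, ampAlphaHigh = 8.5, seed = seed)
}

#' @rdname presets
#' @export
highRiskSubject <- function(seed = 1) {
  subjectSpec(iafTrue = 10, tfTrue = 7, ampTheta = 4,
              ampAlphaLow = 8, ampAlphaHigh = 12.8, seed = seed)
}

# Continuous one-sided source PSD (unit gain), uV^2/Hz. The pink floor is
# flattened below 0.5 Hz to keep the synthesis finite.
.sourcePsd <- function(spec, f) {
  chi <- spec$exponent
  lo <- 2; hi <- 45
  C <- if (abs(chi - 1) < 1e-12) spec$pinkScale^2 / log(hi / lo)
       else spec$pinkScale^2 * (1 - chi) / (hi^(1 - chi) - lo^(1 - chi))
  s <- C * pmax(f, 0.5)^(-chi)
  fwhm2sd <- 1 / (2 * sqrt(2 * log(2)))
  sigN <- spec$oscBandwidth * fwhm2sd
  sigT <- spec$thetaBandwidth * fwhm2sd
  sigB <- spec$alphaLowBandwidth * fwhm2sd
  osc <- function(amp, fc, sig) amp^2 * stats::dnorm(f, fc, sig)
  s + osc(spec$ampTheta, spec$tfTrue - 1.5, sigT) +
    osc(spec$ampAlphaLow, spec$iafTrue - 1, sigB) +
    osc(spec$ampAlphaHigh, spec$iafTrue, sigN)
}

# White sensor-noise PSD (one-sided), uV^2/Hz.
.whitePsd <- function(spec, fs) spec$noiseSd^2 * 2 / fs

#' Analytic expected collapsed spectrum of a subject specification
#'
#' Closed-form expectation of the channel-averaged power spectral density.
#' The effective source gain is `mean(gains^2)` as recorded, or
#' `mean((gains - mean(gains))^2)` after common-average re-referencing
#' (which removes the spatial mean of the shared source and a `1/nch`
#' share of the white noise). With `welchSmoothing = TRUE` (default) the
#' continuous PSD is convolved with the squared-magnitude spectral kernel
#' of the Hann window, i.e. the exact expectation of the package's Welch
#' estimator; without it the raw continuous PSD is sampled at the grid.
#'
#' @param spec a [subjectSpec()].
#' @param fs sampling rate, Hz.
#' @param epochLength Welch segment length, s (grid spacing `1/epochLength`).
#' @param reference `"common-average"` (the pipeline default) or
#'   `"as-recorded"`.
#' @param welchSmoothing convolve with the Hann kernel?
#' @return A [CollapsedSpectrum-class] on the `0 .. fs/2` grid.
#' @export
analyticCollapsedSpectrum <- function(spec, fs = 250, epochLength = 2,
                                      reference = c("common-average",
                                                    "as-recorded"),
                                      welchSmoothing = TRUE) {
  reference <- match.arg(reference)
  spe <- as.integer(round(epochLength * fs))
  nbins <- spe %/% 2 + 1
  fgrid <- (seq_len(nbins) - 1) * fs / spe
  g <- spec$gains
  nch <- length(g)
  if (reference == "common-average") {
    g2 <- mean((g - mean(g))^2)
    white <- .whitePsd(spec, fs) * (1 - 1 / nch)
  } else {
    g2 <- mean(g^2)
    white <- .whitePsd(spec, fs)
  }
  if (!welchSmoothing) {
    pw <- g2 * .sourcePsd(spec, fgrid) + white
  } else {
    w <- .hann(spe)
    U <- mean(w^2)
    dfine <- 0.02
    delta <- seq(-6, 6, by = dfine)
    K <- vapply(delta, function(d)
      Mod(sum(w * exp(2i * pi * d * (0:(spe - 1)) / fs)))^2, numeric(1)) /
      (fs * spe * U)
    pw <- vapply(fgrid, function(f0) {
      fq <- f0 + delta
      s <- g2 * .sourcePsd(spec, abs(fq))
      sum(s * K) * dfine
    }, numeric(1))
    pw <- pw + white
  }
  new("CollapsedSpectrum", freqs = fgrid, power = pw,
      channelSet = names(spec$gains))
}

# Synthesize one realization of a stationary process with one-sided PSD
# sampled by `psdFun(f)`, length n at rate fs, via a Hermitian random
# spectrum.
.synthesize <- function(psdFun, n, fs) {
  half <- n %/% 2
  k <- 1:(half - 1)
  fk <- k * fs / n
  amp <- sqrt(n * fs * psdFun(fk) / 2)   # two-sided: S/2
  X <- complex(length.out = n)
  z <- (stats::rnorm(half - 1) + 1i * stats::rnorm(half - 1)) / sqrt(2)
  X[k + 1] <- amp * z
  X[n - k + 1] <- Conj(X[k + 1])
  if (n %% 2 == 0)
    X[half + 1] <- sqrt(n * fs * psdFun(fs / 2) / 2) * stats::rnorm(1)
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate a synthetic multichannel EEG recording
#'
#' Each channel is `gain * source + white noise`, where the source is the
#' subject's pink background plus the three narrowband oscillators, shared
#' across channels (volume conduction), and the white noise is independent
#' per channel. Deterministic given the spec's seed.
#'
#' @param spec a [subjectSpec()].
#' @param duration recording length in seconds (>= 4).
#' @param fs sampling rate, Hz (default 250).
#' @return An [EEGRecording-class], reference `"as-recorded"`.
#' @export
#' @examples
#' rec <- generateEEG(subjectSpec(iafTrue = 10, seed = 7), duration = 20)
#' res <- subjectPipeline(rec)
#' res$anchors
generateEEG <- function(spec, duration, fs = 250) {
  stopifnot(inherits(spec, "subjectSpec"))
  if (duration < 4) stop("duration must be at least 4 s")
  n <- as.integer(round(duration * fs))
  nch <- length(spec$gains)
  withSeed(spec$seed, {
    source <- .synthesize(function(f) .sourcePsd(spec, f), n, fs)
    noise <- matrix(stats::rnorm(nch * n, sd = spec$noiseSd), nch, n)
    samples <- outer(unname(spec$gains), source) + noise
    rownames(samples) <- names(spec$gains)
    EEGRecording(samples, fs = fs, channels = names(spec$gains))
  })
}

#' Specify a synthetic cohort
#'
#' Group-structured cohort generator specification. Defaults mirror the
#' published follow-up cohort: three outcome groups of 42/18/14 subjects
#' with the printed alpha3/alpha2 means and SDs (1.14 +/- 0.3,
#' 1.26 +/- 0.5, 1.03 +/- 0.7) and the printed age/education/MMSE
#' structure. Theta/gamma and hippocampal-volume group parameters are not
#' printed per outcome group and are package defaults (converter groups
#' get elevated theta/gamma; AD converters the smallest hippocampi).
#'
#' @param groups named list (names = outcome levels), each a list with `n`,
#'   `f` (fraction female) and `c(mean, sd)` entries `a3a2`, `thetaGamma`,
#'   `age`, `education`, `mmse`, `hippL`, `hippR`.
#' @param correlation correlation matrix across the 7 numeric columns (in
#'   the order a3a2, thetaGamma, age, education, mmse, hippL, hippR); must
#'   be positive semidefinite.
#' @param seed RNG seed.
#' @return A `cohortSpec` list.
#' @export
cohortSpec <- function(groups = NULL, correlation = NULL, seed = 1) {
  if (is.null(groups)) {
    groups <- list(
      "non-converter" = list(n = 42, f = 30 / 42,
        a3a2 = c(1.14, 0.3), thetaGamma = c(1.00, 0.30),
        age = c(69.4, 4.1), education = c(7.3, 2.5), mmse = c(27.2, 1.4),
        hippL = c(2500, 400), hippR = c(2550, 430)),
      "AD-converter" = list(n = 18, f = 10 / 18,
        a3a2 = c(1.26, 0.5), thetaGamma = c(1.30, 0.45),
        age = c(71.8, 5.7), education = c(8.4, 3.1), mmse = c(25.7, 1.5),
        hippL = c(2100, 410), hippR = c(2300, 500)),
      "nonAD-converter" = list(n = 14, f = 7 / 14,
        a3a2 = c(1.03, 0.7), thetaGamma = c(1.28, 0.45),
        age = c(70.1, 3.9), education = c(8.8, 4.6), mmse = c(26.8, 1.8),
        hippL = c(2450, 420), hippR = c(2500, 480)))
  }
  vars <- c("a3a2", "thetaGamma", "age", "education", "mmse",
            "hippL", "hippR")
  if (is.null(correlation)) {
    correlation <- diag(7)
    dimnames(correlation) <- list(vars, vars)
    set2 <- function(a, b, r) {
      correlation[a, b] <<- r; correlation[b, a] <<- r
    }
    set2("a3a2", "thetaGamma", 0.2)
    set2("a3a2", "hippL", -0.3)
    set2("a3a2", "hippR", -0.2)
    set2("a3a2", "mmse", -0.2)
    set2("hippL", "hippR", 0.6)
  }
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8)
    stop("correlation matrix must be symmetric positive semidefinite")
  for (g in names(groups)) {
    if (!g %in% .OUTCOME_LEVELS)
      stop("unknown outcome group: ", g)
    if (groups[[g]]$n < 1) stop("each group needs n >= 1")
    for (v in vars)
      if (groups[[g]][[v]][2] < 0) stop("SDs must be nonnegative")
  }
  structure(list(groups = groups, correlation = correlation, vars = vars,
                 seed = seed),
            class = "cohortSpec")
}

#' Generate a synthetic cohort table
#'
#' Draws each outcome group from a multivariate normal with the group's
#' means and SDs and the shared correlation matrix, truncated to plausible
#' ranges (MMSE at most 30, positive ratios and volumes), and attaches ids,
#' sex, outcome labels and the fixed-cutoff risk group. In
#' `mode = "recordings"` the two EEG ratio markers are instead re-derived
#' by generating a synthetic recording per subject (oscillator mix
#' interpolated between the low- and high-risk presets according to the
#' drawn alpha3/alpha2 target) and running the full signal pipeline; the
#' recordings are returned alongside the table.
#'
#' @param spec a [cohortSpec()].
#' @param mode `"draw"` (markers drawn directly) or `"recordings"`.
#' @param duration,fs recording length and rate for `mode = "recordings"`.
#' @return For `mode = "draw"`, a `data.frame`; for `"recordings"`, a list
#'   with `cohort` and `recordings`.
#' @export
generateCohort <- function(spec, mode = c("draw", "recordings"),
                           duration = 60, fs = 250) {
  stopifnot(inherits(spec, "cohortSpec"))
  mode <- match.arg(mode)
  vars <- spec$vars
  withSeed(spec$seed, {
    rows <- list()
    idc <- 0L
    for (g in names(spec$groups)) {
      gs <- spec$groups[[g]]
      mu <- vapply(vars, function(v) gs[[v]][1], numeric(1))
      sd <- vapply(vars, function(v) gs[[v]][2], numeric(1))
      Sigma <- diag(sd) %*% spec$correlation %*% diag(sd)
      draws <- MASS::mvrnorm(gs$n, mu = mu, Sigma = Sigma)
      draws <- matrix(draws, nrow = gs$n, dimnames = list(NULL, vars))
      draws[, "mmse"] <- pmin(draws[, "mmse"], 30)
      for (v in c("a3a2", "thetaGamma")) draws[, v] <- pmax(draws[, v], 0.05)
      for (v in c("hippL", "hippR")) draws[, v] <- pmax(draws[, v], 500)
      draws[, "education"] <- pmax(draws[, "education"], 0)
      sex <- ifelse(stats::runif(gs$n) < gs$f, "f", "m")
      rows[[g]] <- data.frame(
        id = sprintf("S%03d", idc + seq_len(gs$n)),
        age = draws[, "age"], sex = sex,
        education = draws[, "education"], mmse = draws[, "mmse"],
        hippocampal_volume_l = draws[, "hippL"],
        hippocampal_volume_r = draws[, "hippR"],
        a3_a2_ratio = draws[, "a3a2"],
        theta_gamma_ratio = draws[, "thetaGamma"],
        outcome = g, stringsAsFactors = FALSE)
      idc <- idc + gs$n
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    cohort$outcome <- factor(cohort$outcome, levels = .OUTCOME_LEVELS)

    recordings <- NULL
    if (mode == "recordings") {
      lo <- lowRiskSubject(); hi <- highRiskSubject()
      recordings <- vector("list", nrow(cohort))
      names(recordings) <- cohort$id
      seeds <- sample.int(.Machine$integer.max, nrow(cohort))
      for (i in seq_len(nrow(cohort))) {
        w <- (cohort$a3_a2_ratio[i] - 0.9) / (1.29 - 0.9)
        w <- min(max(w, 0), 1)
        sp <- subjectSpec(
          iafTrue = sample(seq(8, 12, by = 0.5), 1),
          tfTrue = 7,
          ampTheta = lo$ampTheta,
          ampAlphaLow = (1 - w) * lo$ampAlphaLow + w * hi$ampAlphaLow,
          ampAlphaHigh = (1 - w) * lo$ampAlphaHigh + w * hi$ampAlphaHigh,
          seed = seeds[i])
        rec <- generateEEG(sp, duration = duration, fs = fs)
        res <- subjectPipeline(rec)
        cohort$a3_a2_ratio[i] <- res$markers@a3a2
        cohort$theta_gamma_ratio[i] <- res$markers@thetaGamma
        recordings[[i]] <- rec
      }
    }
    cohort$risk_group <- classifyRisk(cohort$a3_a2_ratio)
    if (mode == "draw") cohort else list(cohort = cohort,
                                         recordings = recordings)
  })
}
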