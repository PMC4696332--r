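# Shared fixture builders. All fixtures are constructed in code; binary
# files (EDF) only ever live in tempdir().

# A deterministic 19-channel recording of pure sinusoids (channel i gets
# frequency freqs[i] Hz, amplitude amps[i] uV).
toneRecording <- function(freqs, amps = rep(20, length(freqs)),
                          duration = 10, fs = 250,
                          channels = montage1020()[seq_along(freqs)]) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  samples <- t(vapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                      numeric(length(t))))
  rownames(samples) <- channels
  EEGRecording(samples, fs = fs, channels = channels)
}

# A collapsed spectrum built directly from a vector of powers on the
# standard 0-125 Hz grid at 0.5 Hz spacing.
madeSpectrum <- function(power, df = 0.5) {
  f <- (seq_along(power) - 1) * df
  new("CollapsedSpectrum", freqs = f, power = power, channelSet = "synthetic")
}

# 1/f background plus a Gaussian bump, on the standard grid.
bumpSpectrum <- function(center, width = 0.5, amp = 50, nbins = 251) {
  f <- (seq_len(nbins) - 1) * 0.5
  p <- 1 / pmax(f, 0.5) + amp * dnorm(f, center, width)
  madeSpectrum(p)
}

# Small deterministic cohort table for IO round-trips.
smallCohort <- function(n = 6) {
  data.frame(
    id = sprintf("S%02d", seq_len(n)),
    age = seq(60, by = 2, length.out = n),
    sex = rep(c("f", "m"), length.out = n),
    education = rep(8, n),
    mmse = rep(27, n),
    hippocampal_volume_l = seq(2000, by = 50, length.out = n),
    hippocampal_volume_r = seq(2100, by = 50, length.out = n),
    a3_a2_ratio = seq(0.8, 1.4, length.out = n),
    theta_gamma_ratio = seq(0.9, 1.5, length.out = n),
    outcome = rep(c("non-converter", "AD-converter", "nonAD-converter"),
                  length.out = n),
    stringsAsFactors = FALSE)
}
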