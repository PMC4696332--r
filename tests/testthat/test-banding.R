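test_that("IAF detection: constructed peak, monotone fallback, double peaks", {
  # 1/f + bump at 10.0 Hz
  expect_equal(detectIAF(bumpSpectrum(10))$iaf, 10)
  expect_length(detectIAF(bumpSpectrum(10))$flags, 0)

  # strictly decreasing spectrum: endpoint 5 with the no-alpha-peak flag
  dec <- madeSpectrum(1 / pmax((0:250) * 0.5, 0.5))
  res <- detectIAF(dec)
  expect_equal(res$iaf, 5)
  expect_true("no-alpha-peak" %in% res$flags)

  # two exactly equal peaks on a flat floor: higher frequency wins on
  # ties, double-peak flagged
  f <- (0:250) * 0.5
  two <- madeSpectrum(2 + 50 * dnorm(f, 9, 0.5) + 50 * dnorm(f, 11, 0.5))
  res2 <- detectIAF(two)
  expect_equal(res2$iaf, 11)
  expect_true("double-peak" %in% res2$flags)

  # a clearly secondary peak does not trip the double-peak flag
  onePlus <- madeSpectrum(2 + 50 * dnorm(f, 10, 0.5) + 10 * dnorm(f, 7, 0.5))
  expect_length(detectIAF(onePlus)$flags, 0)

  # search range beyond the grid errors
  short <- madeSpectrum(rep(1, 20))            # grid up to 9.5 Hz
  expect_error(detectIAF(short, c(5, 14)), "beyond")
})

test_that("IAF recovery from generated time series, seeds 0-9", {
  hits <- 0
  for (s in 0:9) {
    sp <- subjectSpec(iafTrue = 9.5, tfTrue = 6.5, seed = s)
    res <- subjectPipeline(generateEEG(sp, duration = 300))
    if (abs(res$anchors@iaf - 9.5) <= 0.5) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("TF detection: constructed trough, tie rule, boundary flag", {
  f <- (0:250) * 0.5
  spec <- madeSpectrum(30 / pmax(f, 0.5) + 30 * dnorm(f, 6, 0.5) +
                         50 * dnorm(f, 10, 0.5))
  res <- detectTF(spec, iaf = 10)
  expect_equal(res$tf, 8)

  # flat window: tie broken to the lower end, boundary flagged
  flat <- madeSpectrum(rep(1, 251))
  resFlat <- detectTF(flat, iaf = 10)
  expect_equal(resFlat$tf, 4)
  expect_true("tf-at-boundary" %in% resFlat$flags)

  # empty window errors
  expect_error(detectTF(flat, iaf = 10, searchLow = 9.6), "empty")

  # analytic-spectrum oracle: recovered TF within 0.5 Hz of the noiseless
  # argmin for a theta 5.5 / alpha 10.5 subject
  sp <- subjectSpec(iafTrue = 10.5, tfTrue = 7, seed = 5)
  csA <- analyticCollapsedSpectrum(sp)
  tfA <- detectTF(csA, detectIAF(csA)$iaf)$tf
  res2 <- subjectPipeline(generateEEG(sp, duration = 300))
  expect_lte(abs(res2$anchors@tf - tfA), 0.5)
})

test_that("band definition reproduces the printed cohort-mean scheme", {
  b <- bandTable(defineBands(anchorFrequencies(tf = 6.9, iaf = 10.9)))
  core <- b[match(c("delta", "theta", "alpha1", "alpha2", "alpha3"), b$band), ]
  expect_equal(core$lo, c(2.9, 4.9, 6.9, 8.9, 10.9))
  expect_equal(core$hi, c(4.9, 6.9, 8.9, 10.9, 12.9))
})

test_that("midpoint snapping rounds the half-range half-up to the grid", {
  # (iaf - tf)/2 = 1.75 -> snapped up to 2.0 -> boundary at 8.5
  b <- bandTable(defineBands(anchorFrequencies(6.5, 10)))
  expect_equal(b$hi[b$band == "alpha1"], 8.5)
  # exact half-range multiple is untouched
  b2 <- bandTable(defineBands(anchorFrequencies(7, 10)))
  expect_equal(b2$hi[b2$band == "alpha1"], 8.5)   # 7 + 1.5
  # preconditions
  expect_error(defineBands(anchorFrequencies(3.5, 10)), "tf must be >= 4")
  expect_error(anchorFrequencies(10, 8), "iaf must exceed tf")
})

test_that("band contiguity and ordering hold over an anchor grid sweep", {
  for (tf in seq(4, 8, by = 0.5)) {
    for (iaf in seq(tf + 1, 13, by = 0.5)) {
      b <- bandTable(defineBands(anchorFrequencies(tf, iaf),
                                 highBands = NULL))
      expect_true(all(diff(b$lo) > 0))
      expect_true(all(b$hi > b$lo))
      expect_equal(b$hi[-nrow(b)], b$lo[-1])
      # every edge lands on the 0.5 Hz grid for grid-aligned anchors
      expect_true(all(abs(b$lo * 2 - round(b$lo * 2)) < 1e-9))
    }
  }
})

test_that("relative power: uniform density, identity, point mass, additivity", {
  flat <- madeSpectrum(rep(2, 251))
  # flat spectrum: band share = bin-count fraction (4 bins of 86)
  expect_equal(relativeBandPower(flat, c(8.9, 10.9)), 4 / 86)
  # band = total range -> 1
  expect_equal(relativeBandPower(flat, c(2, 45)), 1)
  # all power in the 10 Hz bin
  pm <- rep(0, 251); pm[which((0:250) * 0.5 == 10)] <- 7
  expect_equal(relativeBandPower(madeSpectrum(pm), c(8.9, 10.9)), 1)
  # out-of-range band errors unless clipped
  expect_error(relativeBandPower(flat, c(1, 3)), "within the total")
  expect_equal(relativeBandPower(flat, c(1, 3), clip = TRUE),
               relativeBandPower(flat, c(2, 3)))

  # additivity: the five contiguous bands sum to the straddling interval
  set.seed(20)
  ragged <- madeSpectrum(abs(rnorm(251)) + 0.2)
  sch <- defineBands(anchorFrequencies(6.5, 10.5), highBands = NULL)
  rel <- relativeBandPowers(ragged, sch)
  expect_equal(sum(rel), relativeBandPower(ragged, c(6.5 - 4, 10.5 + 2)),
               tolerance = 1e-12)
})

test_that("ratios cancel the normalization and rescaling of the spectrum", {
  set.seed(21)
  cs <- madeSpectrum(abs(rnorm(251)) + 0.1)
  sch <- defineBands(anchorFrequencies(6.5, 10))
  rel <- relativeBandPowers(cs, sch)
  absolute <- vapply(seq_len(nrow(bandTable(sch))), function(i)
    absoluteBandPower(cs, unlist(bandTable(sch)[i, c("lo", "hi")])),
    numeric(1))
  names(absolute) <- bandTable(sch)$band

  rAbs <- computeRatios(absolute)
  rRel <- computeRatios(rel)
  expect_equal(rAbs$a3a2, rRel$a3a2, tolerance = 1e-12)
  expect_equal(rAbs$thetaGamma, rRel$thetaGamma, tolerance = 1e-12)

  # positive rescaling of the whole spectrum leaves the ratio untouched
  csScaled <- madeSpectrum(psdPower(cs) * 37.5)
  relS <- relativeBandPowers(csScaled, sch)
  expect_equal(computeRatios(relS)$a3a2, rRel$a3a2, tolerance = 1e-12)

  # simple numerics
  expect_equal(computeRatios(c(alpha2 = 2, alpha3 = 2))$a3a2, 1)
  expect_equal(computeRatios(c(alpha2 = 1, alpha3 = 1.17))$a3a2, 1.17)
  expect_error(computeRatios(c(alpha2 = 0, alpha3 = 1)), "zero alpha2")
})

test_that("risk classification: published boundaries, gap closing, partition", {
  expect_equal(as.character(classifyRisk(1.29)), "high")
  expect_equal(as.character(classifyRisk(0.9)), "low")
  expect_equal(as.character(classifyRisk(1.165)), "middle")
  expect_equal(as.character(classifyRisk(1.17)), "high")   # closed boundary
  expect_equal(as.character(classifyRisk(1.0)), "middle")

  # partition: every positive ratio gets exactly one label
  grid <- seq(0.01, 3, by = 0.01)
  labs <- classifyRisk(grid)
  expect_false(anyNA(labs))

  # tertile rule splits a cohort with ties to the lower group
  ratios <- c(0.8, 0.9, 1.0, 1.1, 1.2, 1.3)
  terc <- classifyRisk(ratios, rule = "cohort-tertile", cohort = ratios)
  expect_equal(as.character(terc),
               c("low", "low", "middle", "middle", "high", "high"))
  expect_error(classifyRisk(1, rule = "cohort-tertile", cohort = c(1, 2)),
               "at least 3")
})

test_that("subject pipeline is deterministic, auditable and error-labelled", {
  rec <- generateEEG(lowRiskSubject(seed = 2), duration = 60)
  r1 <- subjectPipeline(rec)
  r2 <- subjectPipeline(rec)
  expect_identical(r1$markers@relPower, r2$markers@relPower)
  expect_identical(r1$markers@a3a2, r2$markers@a3a2)

  # intermediates retained
  expect_s4_class(r1$perChannel, "PowerSpectrum")
  expect_s4_class(r1$epochs, "EpochSet")
  expect_equal(r1$perChannel@nEpochsUsed, sum(keptMask(r1$epochs)))

  # all epochs rejected surfaces the failing stage
  expect_error(
    subjectPipeline(rec, config = list(amp_threshold_uv = 1e-6)),
    "\\[artifact-rejection\\]")
})

test_that("pipeline a3/a2 tracks the analytic-spectrum oracle, seeds 0-9", {
  oracleRatio <- function(sp) {
    cs <- analyticCollapsedSpectrum(sp)
    i <- detectIAF(cs); t <- detectTF(cs, i$iaf)
    sch <- defineBands(anchorFrequencies(t$tf, i$iaf))
    computeRatios(relativeBandPowers(cs, sch, clip = TRUE))$a3a2
  }
  errs <- vapply(0:9, function(s) {
    sp <- highRiskSubject(seed = s)
    got <- subjectPipeline(generateEEG(sp, duration = 300))$markers@a3a2
    got - oracleRatio(sp)
  }, numeric(1))
  # per-subject sampling noise of the ratio at 5 min is ~0.07 SD; each
  # seed must stay within a generous envelope and the ensemble must be
  # unbiased against the analytic value at the 0.05 level
  expect_true(all(abs(errs) < 0.25))
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("zero alpha amplitude yields the no-alpha-peak flag on its spectrum", {
  # constructed absence: with both alpha oscillators silenced the expected
  # spectrum is monotone over the whole 5-14 Hz search range
  sp <- subjectSpec(iafTrue = 10, tfTrue = 6, ampAlphaLow = 0,
                    ampAlphaHigh = 0, seed = 3)
  cs <- analyticCollapsedSpectrum(sp)
  res <- detectIAF(cs)
  expect_true("no-alpha-peak" %in% res$flags)
  expect_equal(res$iaf, 5)        # global max in range at the low edge
})
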