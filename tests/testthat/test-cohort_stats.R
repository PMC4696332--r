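test_that("ANOVA basics: degenerate equality, separation, F equals t-squared", {
  coh <- data.frame(y = rep(5, 12), g = rep(c("a", "b", "c"), each = 4))
  expect_error(leveneGateAnova(coh, "y", "g"), "constant")

  # near-perfect separation: tiny p, all post-hocs significant
  set.seed(1)
  coh2 <- data.frame(y = rep(0:2, each = 4) + rnorm(12, sd = 1e-6),
                     g = rep(c("a", "b", "c"), each = 4))
  # lm warns about the essentially perfect fit; that is the point here
  res <- suppressWarnings(leveneGateAnova(coh2, "y", "g"))
  expect_lt(res$p, 1e-6)
  expect_true(all(res$posthoc$p < 1e-6))

  # two identical groups: F = 0
  coh3 <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(leveneGateAnova(coh3, "y", "g")$F, 0, tolerance = 1e-12)

  # two-group F equals the square of the pooled t statistic
  set.seed(2)
  coh4 <- data.frame(y = rnorm(30), g = rep(c("a", "b"), 15))
  res4 <- leveneGateAnova(coh4, "y", "g")
  tt <- t.test(y ~ g, data = coh4, var.equal = TRUE)
  expect_equal(res4$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res4$dfBetween, 1)
  expect_equal(res4$dfWithin, 28)
})

test_that("Levene gate selects Games-Howell under heteroscedasticity", {
  set.seed(3)
  hetero <- data.frame(
    y = c(rnorm(30, sd = 0.2), rnorm(30, sd = 5), rnorm(30, 2, sd = 0.2)),
    g = rep(c("a", "b", "c"), each = 30))
  resH <- leveneGateAnova(hetero, "y", "g")
  expect_equal(resH$posthocMethod, "games-howell")
  expect_lt(resH$levene$p, 0.05)

  set.seed(30)
  homo <- data.frame(y = rnorm(90), g = rep(c("a", "b", "c"), each = 30))
  resO <- leveneGateAnova(homo, "y", "g")
  expect_gt(resO$levene$p, 0.05)    # this draw really is homoscedastic
  expect_equal(resO$posthocMethod, "bonferroni")

  # Levene statistic equals a direct lm on absolute deviations
  y <- hetero$y; g <- factor(hetero$g)
  dev <- abs(y - ave(y, g))
  ora <- anova(lm(dev ~ g))
  lev <- leveneTest(y, g)
  expect_equal(lev$statistic, ora$`F value`[1], tolerance = 1e-12)
  expect_equal(lev$p, ora$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("ANCOVA adjusts the group effect for covariates", {
  # group differences induced purely by an age covariate vanish after
  # adjustment
  set.seed(4)
  n <- 60
  g <- rep(c("a", "b", "c"), each = n / 3)
  age <- c(rnorm(20, 60, 3), rnorm(20, 70, 3), rnorm(20, 80, 3))
  y <- 0.5 * age + rnorm(n, sd = 1)
  coh <- data.frame(y = y, g = g, age = age)
  raw <- leveneGateAnova(coh, "y", "g")
  adj <- leveneGateAnova(coh, "y", "g", covariates = "age")
  expect_lt(raw$p, 1e-6)
  expect_gt(adj$p, 0.01)
  expect_equal(adj$dfWithin, n - 3 - 1)

  # listwise deletion on missing covariates, with a message
  coh$age[1] <- NA
  expect_message(res <- leveneGateAnova(coh, "y", "g", covariates = "age"),
                 "1 subject")
  expect_equal(res$n, n - 1)
})

test_that("ANOVA type-I error is calibrated at the 5% level", {
  # reduced-n calibration (the acceptance suite runs the full 1000)
  set.seed(5)
  nsim <- 400
  rej <- 0
  for (i in seq_len(nsim)) {
    coh <- data.frame(y = rnorm(45), g = rep(c("a", "b", "c"), each = 15))
    if (leveneGateAnova(coh, "y", "g")$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / nsim, 0.02)
  expect_lt(rej / nsim, 0.08)
})

test_that("Pearson correlation matches the closed-form oracle", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 6.0, 7.7, 6.1, 8.8, 9.9)
  y <- c(2.0, 3.1, 2.9, 4.8, 5.2, 5.9, 7.1, 7.0, 8.1, 9.5)
  res <- pearsonCorrelation(x, y)
  # brute-force covariance formula
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, rOracle, tolerance = 1e-12)
  tOracle <- rOracle * sqrt(8 / (1 - rOracle^2))
  expect_equal(res$p, 2 * pt(abs(tOracle), 8, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  # pairwise-complete deletion
  x2 <- c(x, NA); y2 <- c(y, 5)
  expect_equal(pearsonCorrelation(x2, y2)$n, 10)
  expect_error(pearsonCorrelation(rep(1, 5), 1:5), "zero variance")
})

test_that("chi-square test matches the textbook formula", {
  expect_equal(chiSquareTest(matrix(c(5, 5, 7, 7), 2))$statistic, 0)
  perfect <- chiSquareTest(matrix(c(10, 0, 0, 10), 2))
  expect_equal(perfect$statistic, 20)
  expect_equal(perfect$df, 1)

  set.seed(6)
  tab <- matrix(rpois(4, 20) + 1, 2)
  res <- chiSquareTest(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-12)
  expect_error(chiSquareTest(matrix(c(0, 0, 1, 2), 2)), "degenerate")
  expect_error(chiSquareTest(matrix(c(-1, 2, 1, 2), 2)), "nonnegative")
})

test_that("stepwise discriminant: separation, selection order, tolerance rule", {
  # at 5 sigma separation a single subject lands beyond the 2.5-sigma
  # midpoint with probability ~0.6%, so a typical 60-subject dataset
  # classifies perfectly; assert the informative feature leads and the
  # typical (median over replicate draws) accuracy is exactly 100%
  set.seed(7)
  n <- 60
  accs <- vapply(1:25, function(i) {
    g <- rep(c("a", "b"), each = n / 2)
    coh <- data.frame(g = g,
                      x1 = ifelse(g == "a", 0, 5) + rnorm(n),
                      x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
    fit <- stepwiseDiscriminant(coh, c("x1", "x2", "x3", "x4"), "g")
    expect_equal(fit$selected[1], "x1")
    expect_equal(unname(rowSums(fit$classification)), c(30, 30))
    fit$meanPercentCorrect
  }, numeric(1))
  expect_equal(median(accs), 100)
  expect_gt(min(accs), 93)
  g <- rep(c("a", "b"), each = n / 2)
  coh <- data.frame(g = g, x1 = ifelse(g == "a", 0, 5) + rnorm(n),
                    x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))

  # a duplicated feature is excluded by the tolerance screen
  coh$x5 <- coh$x1
  fit2 <- stepwiseDiscriminant(coh, c("x1", "x5", "x2"), "g")
  expect_false(all(c("x1", "x5") %in% fit2$selected))
})

test_that("canonical solution agrees with manova and MASS::lda oracles", {
  set.seed(8)
  n <- 90
  g <- factor(rep(c("a", "b", "c"), each = n / 3))
  X <- matrix(rnorm(n * 3), n, 3)
  X[, 1] <- X[, 1] + c(a = 0, b = 1.5, c = 3)[g]
  X[, 2] <- X[, 2] + c(a = 1, b = 0, c = 1)[g]
  coh <- data.frame(g = g, f1 = X[, 1], f2 = X[, 2], f3 = X[, 3])
  fit <- stepwiseDiscriminant(coh, c("f1", "f2", "f3"), "g",
                              fToEnter = 0.0001)

  # Wilks' lambda of the full selected model against stats::manova
  sel <- fit$selected
  mv <- summary(manova(as.matrix(coh[sel]) ~ g), test = "Wilks")
  expect_equal(fit$roots$wilks[1], mv$stats[1, "Wilks"], tolerance = 1e-6)

  # eigenvalues nonincreasing, Wilks in (0, 1], structure within [-1, 1]
  expect_true(all(diff(fit$roots$eigenvalue) <= 1e-12))
  expect_true(all(fit$roots$wilks > 0 & fit$roots$wilks <= 1))
  expect_true(all(abs(fit$structure) <= 1 + 1e-9))
  expect_true(all(fit$roots$p >= 0 & fit$roots$p <= 1))

  # equal-prior nearest-centroid classification equals MASS::lda
  ld <- MASS::lda(coh[sel], grouping = g, prior = rep(1 / 3, 3))
  predLda <- predict(ld)$class
  cmLda <- table(true = g, predicted = predLda)
  expect_equal(unclass(fit$classification), unclass(cmLda),
               ignore_attr = TRUE)
})

test_that("noise features are not entered and label shuffling gives chance accuracy", {
  set.seed(9)
  n <- 75
  g <- factor(rep(c("a", "b", "c"), each = n / 3))
  coh <- data.frame(g = g,
                    sig = rnorm(n) + c(a = 0, b = 2, c = 4)[g],
                    n1 = rnorm(n), n2 = rnorm(n))
  fit <- stepwiseDiscriminant(coh, c("sig", "n1", "n2"), "g")
  expect_true("sig" %in% fit$selected)

  # permutation oracle: resubstitution accuracy on shuffled labels is the
  # same (overfit-inflated) chance level for both the full model and the
  # stepwise model, within simulation error
  nsim <- 60
  accStep <- accOracle <- rep(NA_real_, nsim)
  for (i in seq_len(nsim)) {
    gi <- sample(g)
    cohi <- data.frame(g = gi, x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    f <- try(stepwiseDiscriminant(cohi, c("x1", "x2", "x3"), "g"),
             silent = TRUE)
    accStep[i] <- if (inherits(f, "try-error")) 100 / 3
                  else f$meanPercentCorrect
    # oracle: nearest-centroid on an independent noise feature set with
    # all features forced in
    coho <- data.frame(g = gi, x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    fo <- stepwiseDiscriminant(coho, c("x1", "x2", "x3"), "g",
                               fToEnter = 0)
    accOracle[i] <- fo$meanPercentCorrect
  }
  expect_lt(abs(mean(accStep) - mean(accOracle)), 6)
  expect_gt(mean(accStep), 30)     # never below raw chance
})

test_that("follow-up battery composes the ANOVAs and discriminant", {
  set.seed(10)
  spec <- cohortSpec(seed = 77)
  # inflate n for a stable smoke test of the composition
  for (g in names(spec$groups)) spec$groups[[g]]$n <- 60
  coh <- generateCohort(spec)
  rep <- followupAnalysis(coh)
  expect_s3_class(rep$anova$a3_a2_ratio$unadjusted, "anovaResult")
  expect_s3_class(rep$anova$theta_gamma_ratio$adjusted, "anovaResult")
  expect_s3_class(rep$discriminant, "discriminantModel")
  expect_equal(sum(rep$discriminant$classification), 180)

  # outcome column absent -> error
  coh2 <- coh; coh2$outcome <- NULL
  expect_error(followupAnalysis(coh2), "outcome")

  # report writer emits JSON + TSV + text
  dir <- withr::local_tempdir()
  writeFollowupReport(rep, dir)
  expect_true(file.exists(file.path(dir, "followup.json")))
  expect_true(file.exists(file.path(dir, "classification.tsv")))
  j <- jsonlite::read_json(file.path(dir, "followup.json"))
  expect_equal(length(j$anova), 2)
})
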