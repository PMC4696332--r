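# Cohort statistics layer: Levene-gated ANOVA/ANCOVA with Games-Howell or
# Bonferroni post-hocs, Pearson correlations, chi-square tests, and
# forward-stepwise canonical discriminant analysis with resubstitution
# classification.

#' Levene's test for homogeneity of variance
#'
#' Classic (mean-centred) Levene test: a one-way ANOVA on the absolute
#' deviations of each observation from its group mean.
#'
#' @param y numeric outcome.
#' @param group grouping factor.
#' @return List with `statistic` (F), `df`, and `p`.
#' @export
leveneTest <- function(y, group) {
  group <- droplevels(as.factor(group))
  ok <- is.finite(y) & !is.na(group)
  y <- y[ok]; group <- droplevels(group[ok])
  if (nlevels(group) < 2) stop("Levene's test needs at least 2 groups")
  dev <- abs(y - stats::ave(y, group))
  fit <- stats::anova(stats::lm(dev ~ group))
  list(statistic = fit$`F value`[1],
       df = c(fit$Df[1], fit$Df[2]),
       p = fit$`Pr(>F)`[1])
}

# Games-Howell pairwise comparisons: Welch-type pairwise t statistics
# referred to the studentized range distribution. Appropriate when group
# variances are heterogeneous.
.gamesHowell <- function(y, group) {
  levs <- levels(group)
  k <- length(levs)
  m <- tapply(y, group, mean)
  v <- tapply(y, group, stats::var)
  n <- tapply(y, group, length)
  pairs <- utils::combn(levs, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    difference = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se2 <- v[[a]] / n[[a]] + v[[b]] / n[[b]]
    t <- (m[[a]] - m[[b]]) / sqrt(se2)
    df <- se2^2 / ((v[[a]] / n[[a]])^2 / (n[[a]] - 1) +
                   (v[[b]] / n[[b]])^2 / (n[[b]] - 1))
    out$difference[j] <- m[[a]] - m[[b]]
    out$p[j] <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df,
                              lower.tail = FALSE)
  }
  out
}

# Bonferroni pairwise comparisons with the pooled within-group MSE.
.bonferroni <- function(y, group) {
  levs <- levels(group)
  m <- tapply(y, group, mean)
  n <- tapply(y, group, length)
  fit <- stats::anova(stats::lm(y ~ group))
  mse <- fit$`Mean Sq`[2]; dfw <- fit$Df[2]
  pairs <- utils::combn(levs, 2)
  ncomp <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    difference = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncomp)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(mse * (1 / n[[a]] + 1 / n[[b]]))
    t <- (m[[a]] - m[[b]]) / se
    out$difference[j] <- m[[a]] - m[[b]]
    out$p[j] <- min(1, 2 * stats::pt(abs(t), dfw, lower.tail = FALSE) * ncomp)
  }
  out
}

#' Group comparison with a variance-gated post-hoc
#'
#' One-way ANOVA (or ANCOVA when covariates are given: a linear model with
#' the covariates plus the group factor, reporting the covariate-adjusted
#' type-II F for the group effect). Levene's test on the raw outcome by
#' group selects the post-hoc family: Games-Howell when variances are
#' heterogeneous (Levene p < 0.05), Bonferroni otherwise. Rows with missing
#' values in the outcome, group or covariates are dropped listwise with a
#' message.
#'
#' @param cohort data.frame, one row per subject.
#' @param outcomeVar name of the numeric outcome column.
#' @param groupVar name of the grouping column (>= 2 groups of >= 2).
#' @param covariates character vector of covariate column names (optional).
#' @param leveneAlpha gate threshold on Levene's p (default 0.05).
#' @return An `anovaResult` list: `F`, `dfBetween`, `dfWithin`, `p`,
#'   `covariates`, `levene` (statistic + p), `posthocMethod`, `posthoc`
#'   (pairwise table), `groupMeans`, `n`.
#' @export
leveneGateAnova <- function(cohort, outcomeVar, groupVar,
                            covariates = character(), leveneAlpha = 0.05) {
  stopifnot(is.data.frame(cohort))
  for (v in c(outcomeVar, groupVar, covariates))
    if (!v %in% names(cohort)) stop("column not found in cohort: ", v)
  dat <- cohort[, c(outcomeVar, groupVar, covariates), drop = FALSE]
  complete <- stats::complete.cases(dat)
  if (!all(complete))
    message(sum(!complete), " subject(s) dropped (listwise deletion)")
  dat <- dat[complete, , drop = FALSE]
  y <- dat[[outcomeVar]]
  group <- droplevels(as.factor(dat[[groupVar]]))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs at least 2 subjects")
  if (stats::sd(y) == 0) stop("constant outcome; ANOVA undefined")

  if (length(covariates)) {
    rhsCov <- paste(sprintf("`%s`", covariates), collapse = " + ")
    full <- stats::lm(stats::reformulate(c(sprintf("`%s`", covariates),
                                           ".group"), response = ".y"),
                      data = data.frame(.y = y, .group = group,
                                        dat[covariates], check.names = FALSE))
    red <- stats::lm(stats::reformulate(sprintf("`%s`", covariates),
                                        response = ".y"),
                     data = data.frame(.y = y,
                                       dat[covariates], check.names = FALSE))
    cmp <- stats::anova(red, full)
    Fv <- cmp$F[2]; dfB <- cmp$Df[2]; dfW <- cmp$Res.Df[2]; p <- cmp$`Pr(>F)`[2]
  } else {
    fit <- stats::anova(stats::lm(y ~ group))
    Fv <- fit$`F value`[1]; dfB <- fit$Df[1]; dfW <- fit$Df[2]
    p <- fit$`Pr(>F)`[1]
  }

  lev <- leveneTest(y, group)
  method <- if (lev$p < leveneAlpha) "games-howell" else "bonferroni"
  posthoc <- if (method == "games-howell") .gamesHowell(y, group)
             else .bonferroni(y, group)

  structure(list(F = Fv, dfBetween = dfB, dfWithin = dfW, p = p,
                 covariates = covariates,
                 levene = list(statistic = lev$statistic, p = lev$p),
                 posthocMethod = method, posthoc = posthoc,
                 groupMeans = tapply(y, group, mean),
                 n = length(y)),
            class = "anovaResult")
}

#' @export
print.anovaResult <- function(x, ...) {
  cat(sprintf("Group effect: F(%d, %d) = %.3f, p = %.4g%s\n",
              x$dfBetween, x$dfWithin, x$F, x$p,
              if (length(x$covariates))
                paste0(" (adjusted for ", paste(x$covariates, collapse = ", "), ")")
              else ""))
  cat(sprintf("Levene: F = %.3f, p = %.4g -> %s post-hocs\n",
              x$levene$statistic, x$levene$p, x$posthocMethod))
  print(x$posthoc, digits = 4)
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Pairwise-complete Pearson correlation with the two-sided p-value from
#' the t transform.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with `r`, `p`, `n` (complete pairs used).
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction;
#' df = (rows - 1)(cols - 1).
#'
#' @param tab matrix of nonnegative integer counts with positive row and
#'   column sums.
#' @return List with `statistic`, `df`, `p`.
#' @export
chiSquareTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain nonnegative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero row or column sum")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

# Wilks' lambda det(W)/det(T) for a column subset.
.wilks <- function(W, T, cols) {
  if (length(cols) == 0) return(1)
  det(W[cols, cols, drop = FALSE]) / det(T[cols, cols, drop = FALSE])
}

#' Forward-stepwise canonical discriminant analysis
#'
#' SPSS-style stepwise discriminant factor analysis with forward entry
#' only: at each step the candidate variable with the largest partial F
#' (computed from the decrement in Wilks' lambda) enters, provided its
#' partial F is at least `fToEnter` and its tolerance (one minus the
#' squared multiple correlation with the already-entered variables, on the
#' pooled within-group covariance) is at least `tolerance`. The canonical
#' discriminant solution is then computed on the selected variables;
#' classification is by nearest group centroid in canonical space with
#' equal priors, evaluated by resubstitution.
#'
#' @param cohort data.frame, one row per subject.
#' @param features character vector of candidate feature columns.
#' @param label name of the grouping column (>= 2 groups).
#' @param tolerance minimum tolerance for entry (default 0.01).
#' @param fToEnter minimum partial F for entry (default 1.0).
#' @return A `discriminantModel` list: `selected` (entry order),
#'   `entryF`, `wilks`, `roots` (eigenvalue, wilks, chisq, df, p per root),
#'   `structure` (factor structure matrix), `coefficients` (raw canonical
#'   coefficients), `centroids`, `classification` (true x predicted),
#'   `percentCorrect` (per group), `meanPercentCorrect`, `n`, `groups`.
#' @export
stepwiseDiscriminant <- function(cohort, features, label,
                                 tolerance = 0.01, fToEnter = 1.0) {
  stopifnot(is.data.frame(cohort), length(features) >= 1)
  for (v in c(features, label))
    if (!v %in% names(cohort)) stop("column not found in cohort: ", v)
  dat <- cohort[, c(features, label), drop = FALSE]
  complete <- stats::complete.cases(dat)
  if (!all(complete))
    message(sum(!complete), " subject(s) dropped (listwise deletion)")
  dat <- dat[complete, , drop = FALSE]
  grp <- droplevels(as.factor(dat[[label]]))
  X <- as.matrix(dat[, features, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); g <- nlevels(grp); p <- ncol(X)
  if (g < 2) stop("need at least 2 groups")
  if (n <= p + g) stop("need n > number of features + number of groups")

  grand <- colMeans(X)
  Xc <- sweep(X, 2, grand)
  T <- crossprod(Xc)
  means <- apply(X, 2, function(col) tapply(col, grp, mean))  # g x p
  Xw <- X - means[as.integer(grp), , drop = FALSE]
  W <- crossprod(Xw)
  Sw <- W / (n - g)                    # pooled within-group covariance

  entered <- integer(0)
  entryF <- numeric(0)
  lambda <- 1
  repeat {
    cand <- setdiff(seq_len(p), entered)
    if (length(cand) == 0) break
    bestF <- -Inf; bestJ <- NA_integer_; bestLambda <- NA_real_
    for (j in cand) {
      # tolerance against entered variables (pooled within-group metric)
      if (length(entered)) {
        Sjj <- Sw[j, j]
        See <- Sw[entered, entered, drop = FALSE]
        Sje <- Sw[j, entered, drop = FALSE]
        r2 <- drop(Sje %*% solve(See, t(Sje))) / Sjj
        if (1 - r2 < tolerance) next
      }
      lamNew <- .wilks(W, T, c(entered, j))
      if (!is.finite(lamNew) || lamNew <= 0) next
      pf <- (lambda / lamNew - 1) * (n - g - length(entered)) / (g - 1)
      if (pf > bestF) { bestF <- pf; bestJ <- j; bestLambda <- lamNew }
    }
    if (!is.finite(bestF) || bestF < fToEnter) break
    entered <- c(entered, bestJ)
    entryF <- c(entryF, bestF)
    lambda <- bestLambda
  }
  if (length(entered) == 0)
    stop("no variable reached the F-to-enter threshold; empty model")

  sel <- entered
  Ws <- W[sel, sel, drop = FALSE]
  Bs <- T[sel, sel, drop = FALSE] - Ws
  L <- chol(Ws)
  M <- forwardsolve(t(L), t(forwardsolve(t(L), Bs)))
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  m <- min(g - 1, length(sel))
  ev <- pmax(eg$values[seq_len(m)], 0)
  A <- backsolve(L, eg$vectors[, seq_len(m), drop = FALSE])
  # scale: unit pooled within-group variance of canonical scores
  sc <- sqrt(diag(t(A) %*% (Ws / (n - g)) %*% A))
  A <- sweep(A, 2, sc, `/`)
  rownames(A) <- features[sel]

  roots <- data.frame(root = seq_len(m), eigenvalue = ev,
                      wilks = NA_real_, chisq = NA_real_,
                      df = NA_integer_, p = NA_real_)
  for (k in seq_len(m)) {
    lam <- prod(1 / (1 + ev[k:m]))
    chi <- -(n - 1 - (length(sel) + g) / 2) * log(lam)
    df <- (length(sel) - k + 1) * (g - k)
    roots$wilks[k] <- lam
    roots$chisq[k] <- chi
    roots$df[k] <- df
    roots$p[k] <- stats::pchisq(chi, df, lower.tail = FALSE)
  }

  scores <- sweep(X[, sel, drop = FALSE], 2, grand[sel]) %*% A
  centroids <- apply(scores, 2, function(col) tapply(col, grp, mean))
  centroids <- matrix(centroids, nrow = g,
                      dimnames = list(levels(grp), paste0("root", seq_len(m))))

  # factor structure matrix: pooled within-group correlations between the
  # selected variables and the canonical scores
  withinScores <- Xw[, sel, drop = FALSE] %*% A
  covVS <- crossprod(Xw[, sel, drop = FALSE], withinScores) / (n - g)
  structureM <- covVS / sqrt(diag(Sw)[sel])
  dimnames(structureM) <- list(features[sel], paste0("root", seq_len(m)))

  d2 <- vapply(seq_len(g), function(i)
    rowSums(sweep(scores, 2, centroids[i, ])^2), numeric(n))
  pred <- factor(levels(grp)[max.col(-d2, ties.method = "first")],
                 levels = levels(grp))
  confusion <- table(true = grp, predicted = pred)
  pc <- 100 * diag(confusion) / rowSums(confusion)

  structure(list(selected = features[sel], entryF = entryF,
                 wilks = lambda, roots = roots, structure = structureM,
                 coefficients = A, centroids = centroids,
                 classification = confusion, percentCorrect = pc,
                 meanPercentCorrect = mean(pc), n = n,
                 groups = levels(grp)),
            class = "discriminantModel")
}

#' @export
print.discriminantModel <- function(x, ...) {
  cat("Stepwise canonical discriminant analysis\n")
  cat("  entered:", paste(sprintf("%s (F=%.2f)", x$selected, x$entryF),
                          collapse = ", "), "\n")
  cat(sprintf("  Wilks' lambda = %.4f, n = %d\n", x$wilks, x$n))
  print(x$roots, digits = 4)
  cat("Classification (resubstitution):\n")
  print(x$classification)
  cat(sprintf("  percent correct: %s; mean %.1f%%\n",
              paste(sprintf("%s %.0f%%", names(x$percentCorrect),
                            x$percentCorrect), collapse = ", "),
              x$meanPercentCorrect))
  invisible(x)
}

#' Follow-up outcome analysis of the EEG marker panel
#'
#' The cohort-level follow-up battery: Levene-gated ANOVAs of the
#' alpha3/alpha2 and theta/gamma ratios across the three follow-up outcome
#' groups, unadjusted and covariate-adjusted, followed by a stepwise
#' canonical discriminant analysis of the marker set against the outcome.
#'
#' @param cohort data.frame with an `outcome` factor (3 levels present),
#'   marker columns `a3_a2_ratio` and `theta_gamma_ratio`, and optionally
#'   covariates and further marker columns.
#' @param covariates covariate columns for the adjusted ANOVAs; defaults to
#'   those of `age`, `education`, `mmse`, `hippocampal_volume_l`,
#'   `hippocampal_volume_r` present in the table.
#' @param features discriminant candidate features; defaults to the two
#'   ratio markers plus any `rel_*` relative-power columns present.
#' @return A `followupReport` list with `anova` (per marker, unadjusted and
#'   adjusted) and `discriminant`.
#' @export
followupAnalysis <- function(cohort, covariates = NULL, features = NULL) {
  if (!"outcome" %in% names(cohort))
    stop("cohort has no 'outcome' column; follow-up analysis needs outcomes")
  out <- cohort$outcome
  if (nlevels(droplevels(as.factor(out[!is.na(out)]))) != 3)
    stop("follow-up analysis expects all three outcome groups present")
  markers <- c("a3_a2_ratio", "theta_gamma_ratio")
  if (!all(markers %in% names(cohort)))
    stop("cohort must contain a3_a2_ratio and theta_gamma_ratio")
  if (is.null(covariates))
    covariates <- intersect(c("age", "education", "mmse",
                              "hippocampal_volume_l", "hippocampal_volume_r"),
                            names(cohort))
  if (is.null(features))
    features <- c(markers, grep("^rel_", names(cohort), value = TRUE))

  anovas <- lapply(markers, function(mk) {
    list(unadjusted = leveneGateAnova(cohort, mk, "outcome"),
         adjusted = if (length(covariates))
           leveneGateAnova(cohort, mk, "outcome", covariates = covariates)
         else NULL)
  })
  names(anovas) <- markers
  disc <- stepwiseDiscriminant(cohort, features = features, label = "outcome")
  structure(list(anova = anovas, discriminant = disc,
                 covariates = covariates, features = features),
            class = "followupReport")
}

#' @export
print.followupReport <- function(x, ...) {
  for (mk in names(x$anova)) {
    cat("==", mk, "by outcome ==\n")
    print(x$anova[[mk]]$unadjusted)
    if (!is.null(x$anova[[mk]]$adjusted)) {
      cat("-- adjusted --\n")
      print(x$anova[[mk]]$adjusted)
    }
  }
  cat("== discriminant ==\n")
  print(x$discriminant)
  invisible(x)
}

#' Write a follow-up report to disk
#'
#' JSON for the structured numbers, a text rendering, and the
#' classification matrix as TSV.
#'
#' @param report a [followupAnalysis()] result.
#' @param dir output directory.
#' @return Invisibly, the JSON path.
#' @export
writeFollowupReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  strip <- function(a) a[c("F", "dfBetween", "dfWithin", "p",
                           "posthocMethod")]
  j <- list(
    anova = lapply(report$anova, function(m)
      list(unadjusted = strip(m$unadjusted),
           adjusted = if (!is.null(m$adjusted)) strip(m$adjusted))),
    discriminant = list(
      selected = report$discriminant$selected,
      entryF = report$discriminant$entryF,
      wilks = report$discriminant$wilks,
      roots = report$discriminant$roots,
      percentCorrect = as.list(report$discriminant$percentCorrect),
      meanPercentCorrect = report$discriminant$meanPercentCorrect))
  jpath <- file.path(dir, "followup.json")
  jsonlite::write_json(j, jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.table(as.data.frame.matrix(report$discriminant$classification),
                     file.path(dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "followup.txt"))
  invisible(jpath)
}
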