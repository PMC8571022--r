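# Group statistics battery. Engines are the base R tests; this module owns
# the gating logic, effect sizes and report assembly. All results are
# returned as one-row data.frames with a common column set so they can be
# row-bound into tidy tables.

testRow <- function(test, statistic, p, effect = NA_real_, nX = NA_integer_,
                    nY = NA_integer_, extra = list()) {
  out <- data.frame(test = test, statistic = statistic, p_value = p,
                    effect_size = effect, n_x = nX, n_y = nY,
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Cohen's d
#'
#' d = (mean(x) - mean(y)) / pooled SD, with the pooled SD weighted by
#' (n_x - 1) and (n_y - 1). Antisymmetric: d(x, y) = -d(y, x).
#'
#' @param x,y numeric samples.
#' @return the effect size.
#' @export
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  stopIfNot(sp2 > 0, "zero pooled SD")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Normality-gated two-sample comparison
#'
#' Shapiro-Wilk on both samples; when both pass at \code{alpha} the samples
#' are compared by a two-sided independent t-test (pooled variance by
#' default, Welch behind the flag), otherwise by the two-sided Mann-Whitney
#' U test (normal approximation with continuity correction). Constant
#' samples, for which Shapiro-Wilk is undefined, fall through to
#' Mann-Whitney and are flagged.
#'
#' @param x,y numeric samples, each with at least 3 observations.
#' @param alpha normality-gate level.
#' @param varEqual pooled-variance t-test (default TRUE).
#' @return one-row data.frame: test, statistic, p_value, effect_size
#'   (Cohen's d for the t branch), n_x, n_y, sw_p_x, sw_p_y, gate.
#' @export
normalityGatedCompare <- function(x, y, alpha = 0.05, varEqual = TRUE) {
  stopIfNot(length(x) >= 3 && length(y) >= 3,
            "each sample needs >= 3 observations")
  swp <- function(v) {
    if (stats::sd(v) == 0 || length(unique(v)) < 3) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  px <- swp(x); py <- swp(y)
  normal <- !is.na(px) && !is.na(py) && px >= alpha && py >= alpha
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = varEqual)
    testRow(if (varEqual) "t (pooled)" else "t (Welch)",
            unname(tt$statistic), tt$p.value, cohensD(x, y),
            length(x), length(y),
            list(sw_p_x = px, sw_p_y = py, gate = "normal"))
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    gate <- if (is.na(px) || is.na(py)) "constant-sample" else "non-normal"
    testRow("Mann-Whitney U", unname(wt$statistic), wt$p.value,
            NA_real_, length(x), length(y),
            list(sw_p_x = px, sw_p_y = py, gate = gate))
  }
}

#' Pearson correlation with p-value
#'
#' r with the two-sided p from the t distribution on n - 2 df.
#'
#' @param x,y numeric vectors, n >= 3, nonzero variance.
#' @return one-row data.frame with \code{r}, the t statistic, and p.
#' @export
pearsonWithP <- function(x, y) {
  stopIfNot(length(x) == length(y) && length(x) >= 3, "need n >= 3 pairs")
  stopIfNot(stats::sd(x) > 0 && stats::sd(y) > 0, "zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  testRow("Pearson", unname(ct$statistic), ct$p.value,
          nX = length(x), extra = list(r = unname(ct$estimate)))
}

#' Simple linear regression of y on x
#'
#' Ordinary least squares; reports the slope, its two-sided t-test, and
#' residual-normality diagnostics.
#'
#' @param y response.
#' @param x predictor; a constant x is a degenerate design and errors.
#' @return one-row data.frame with \code{beta}, \code{se}, the t statistic,
#'   p, and \code{resid_sw_p}.
#' @export
simpleRegression <- function(y, x) {
  stopIfNot(length(x) == length(y) && length(x) >= 3, "need n >= 3")
  stopIfNot(stats::sd(x) > 0, "degenerate design: constant predictor")
  fit <- stats::lm(y ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients # exact fits warn
  res <- stats::residuals(fit)
  swp <- if (stats::sd(res) > 0 && length(res) >= 3 &&
             length(unique(res)) >= 3)
    stats::shapiro.test(res)$p.value else NA_real_
  testRow("OLS slope", cf["x", "t value"], cf["x", "Pr(>|t|)"],
          nX = length(x),
          extra = list(beta = cf["x", "Estimate"],
                       se = cf["x", "Std. Error"], resid_sw_p = swp))
}

#' ANCOVA interaction test
#'
#' Fits y ~ group + x + group:x and reports the F test of the interaction
#' (does the slope of y on x differ between groups); the main effects are
#' included as extra columns.
#'
#' @param y response.
#' @param x covariate.
#' @param group two-level factor (coercible), each level with >= 3
#'   observations and nonzero variance in x.
#' @return one-row data.frame with the interaction F and p.
#' @export
ancovaGroupInteraction <- function(y, x, group) {
  group <- factor(group)
  stopIfNot(nlevels(group) == 2, "group must have exactly 2 levels")
  stopIfNot(all(table(group) >= 3), "both groups need >= 3 observations")
  for (g in levels(group))
    stopIfNot(stats::sd(x[group == g]) > 0,
              "zero variance in x within a group")
  fit <- stats::lm(y ~ group * x)
  an <- stats::anova(fit)
  i <- grep(":", rownames(an))
  testRow("ANCOVA interaction", an$`F value`[i], an$`Pr(>F)`[i],
          nX = sum(group == levels(group)[1]),
          nY = sum(group == levels(group)[2]),
          extra = list(F_group = an$`F value`[1], p_group = an$`Pr(>F)`[1],
                       F_x = an$`F value`[2], p_x = an$`Pr(>F)`[2]))
}

#' Multiple-testing adjustment
#'
#' Holm step-down by default; Bonferroni and Benjamini-Hochberg selectable.
#' Adjusted values are monotone in the raw values and never smaller.
#'
#' @param p vector of p-values in [0,1].
#' @param method "holm", "bonferroni" or "BH".
#' @return adjusted p-values.
#' @export
adjustPvalues <- function(p, method = c("holm", "bonferroni", "BH")) {
  method <- match.arg(method)
  stopIfNot(all(p >= 0 & p <= 1), "p-values must lie in [0,1]")
  stats::p.adjust(p, method = method)
}

#' Observed versus expected transition tests
#'
#' For each ordered class pair, tests the subjects' observed transition
#' percentages against their expected (independence-null) percentages by an
#' unpaired t-test (the reported convention) or, behind the flag, a paired
#' t-test. Cohen's d and Holm-adjusted p-values are attached.
#'
#' @param tables list of per-subject \linkS4class{TransitionTable}s with the
#'   expected part filled.
#' @param paired use the paired variant.
#' @param adjustMethod multiplicity adjustment across the K(K-1) cells.
#' @return data.frame with one row per ordered pair: from, to, mean_obs,
#'   mean_exp, t, p_value, p_adjusted, d.
#' @export
compareObservedExpectedTransitions <- function(tables, paired = FALSE,
                                               adjustMethod = "holm") {
  stopIfNot(length(tables) >= 2, "need at least 2 subjects")
  nm <- tables[[1]]@classNames
  K <- length(nm)
  obs <- sapply(tables, function(tt) as.vector(tt@observedPct))
  exp_ <- sapply(tables, function(tt) as.vector(tt@expectedPct))
  stopIfNot(!anyNA(exp_), "expected transitions missing in some table")
  out <- NULL
  for (j in seq_len(K)) for (i in seq_len(K)) {
    if (i == j) next
    cell <- (j - 1L) * K + i
    o <- obs[cell, ]; e <- exp_[cell, ]
    tt <- stats::t.test(o, e, paired = paired, var.equal = !paired)
    d <- if (paired) {
      dd <- o - e
      if (stats::sd(dd) > 0) mean(dd) / stats::sd(dd) else 0
    } else cohensD(o, e)
    out <- rbind(out, data.frame(from = nm[i], to = nm[j],
                                 mean_obs = mean(o), mean_exp = mean(e),
                                 t = unname(tt$statistic),
                                 p_value = tt$p.value, d = d,
                                 stringsAsFactors = FALSE))
  }
  out$p_adjusted <- adjustPvalues(out$p_value, adjustMethod)
  rownames(out) <- NULL
  out
}

# Flatten per-subject parameters into a subjects x (class,measure) table.
parameterTable <- function(parametersList, classNames) {
  rows <- lapply(parametersList, function(p) {
    v <- c(p@durationMs, p@occurrencePerS, p@coveragePct)
    names(v) <- c(paste0("duration_", names(p@durationMs)),
                  paste0("occurrence_", names(p@occurrencePerS)),
                  paste0("coverage_", names(p@coveragePct)))
    v
  })
  do.call(rbind, rows)
}

#' Full group comparison report
#'
#' Runs the whole statistics battery on a cohort: normality-gated group
#' comparisons of all 12 parameter cells (4 classes x duration, occurrence,
#' coverage), pooled Pearson correlations of each cell with the severity
#' score, within-group regressions, ANCOVA interaction tests for the cells
#' with a significant pooled correlation, and the transition analyses
#' (observed vs expected within each group; observed compared between
#' groups with adjustment and Cohen's d).
#'
#' @param cohort list with \code{subjects} (data.frame: subject_id, group
#'   with levels "RBD"/"HC", rbdqhk_score, optionally age/sex),
#'   \code{parameters} (list of \linkS4class{MicrostateParameters}) and
#'   \code{transitions} (list of \linkS4class{TransitionTable}s, expected
#'   filled), all in subject order.
#' @param alpha significance level.
#' @param adjustMethod multiplicity adjustment for the transition cells.
#' @param varEqual pooled-variance t-tests (default TRUE).
#' @return list of tidy data.frames: \code{parameters},
#'   \code{correlations}, \code{regressions}, \code{ancova},
#'   \code{transitionsVsExpected}, \code{transitionsBetweenGroups}.
#' @export
groupComparisonReport <- function(cohort, alpha = 0.05,
                                  adjustMethod = "holm", varEqual = TRUE) {
  subj <- cohort$subjects
  grp <- as.character(subj$group)
  stopIfNot(all(c("RBD", "HC") %in% grp),
            "both groups (RBD, HC) must be present")
  isR <- grp == "RBD"
  classNames <- names(cohort$parameters[[1]]@coveragePct)
  tab <- parameterTable(cohort$parameters, classNames)
  score <- subj$rbdqhk_score

  paramRows <- NULL
  corRows <- NULL
  for (cn in colnames(tab)) {
    v <- tab[, cn]
    ok <- is.finite(v)
    if (sum(ok & isR) >= 3 && sum(ok & !isR) >= 3) {
      r <- normalityGatedCompare(v[ok & isR], v[ok & !isR], alpha, varEqual)
      r <- cbind(data.frame(cell = cn, mean_rbd = mean(v[ok & isR]),
                            mean_hc = mean(v[ok & !isR]),
                            stringsAsFactors = FALSE), r)
      paramRows <- rbind(paramRows, r)
    }
    if (sum(ok) >= 3 && stats::sd(v[ok]) > 0 && stats::sd(score[ok]) > 0) {
      cr <- pearsonWithP(v[ok], score[ok])
      corRows <- rbind(corRows, cbind(data.frame(cell = cn,
                                                 stringsAsFactors = FALSE),
                                      cr))
    }
  }

  regRows <- NULL
  for (cn in colnames(tab)) {
    for (g in c("RBD", "HC")) {
      sel <- (grp == g) & is.finite(tab[, cn])
      if (sum(sel) >= 3 && stats::sd(tab[sel, cn]) > 0) {
        rr <- simpleRegression(score[sel], tab[sel, cn])
        regRows <- rbind(regRows,
                         cbind(data.frame(cell = cn, group = g,
                                          stringsAsFactors = FALSE), rr))
      }
    }
  }

  ancovaRows <- NULL
  if (!is.null(corRows)) {
    sig <- corRows$cell[corRows$p_value < alpha]
    for (cn in sig) {
      sel <- is.finite(tab[, cn])
      if (all(table(grp[sel]) >= 3) &&
          all(tapply(tab[sel, cn], grp[sel], stats::sd) > 0)) {
        ar <- ancovaGroupInteraction(score[sel], tab[sel, cn], grp[sel])
        ancovaRows <- rbind(ancovaRows,
                            cbind(data.frame(cell = cn,
                                             stringsAsFactors = FALSE), ar))
      }
    }
  }

  tve <- NULL
  for (g in c("RBD", "HC")) {
    tl <- cohort$transitions[grp == g]
    rows <- compareObservedExpectedTransitions(tl,
                                               adjustMethod = adjustMethod)
    rows$group <- g
    tve <- rbind(tve, rows)
  }

  tblR <- cohort$transitions[isR]
  tblH <- cohort$transitions[!isR]
  nm <- tblR[[1]]@classNames
  K <- length(nm)
  tbg <- NULL
  for (j in seq_len(K)) for (i in seq_len(K)) {
    if (i == j) next
    oR <- vapply(tblR, function(tt) tt@observedPct[i, j], 0)
    oH <- vapply(tblH, function(tt) tt@observedPct[i, j], 0)
    ct <- stats::t.test(oR, oH, var.equal = varEqual)
    tbg <- rbind(tbg, data.frame(from = nm[i], to = nm[j],
                                 mean_rbd = mean(oR), mean_hc = mean(oH),
                                 t = unname(ct$statistic),
                                 p_value = ct$p.value,
                                 d = cohensD(oR, oH),
                                 stringsAsFactors = FALSE))
  }
  tbg$p_adjusted <- adjustPvalues(tbg$p_value, adjustMethod)

  list(parameters = paramRows, correlations = corRows,
       regressions = regRows, ancova = ancovaRows,
       transitionsVsExpected = tve, transitionsBetweenGroups = tbg)
}
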