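# ANOVA and Bonferroni post-hoc on component scores, confidence-interval
# derived thresholds, and pairwise species classification.

.checkGroups <- function(values, groups, minPer = 2L) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    .gerr("badInput", "values and groups must have the same length")
  tab <- table(groups)
  if (length(tab) < 2L)
    .gerr("insufficientGroups", "need at least 2 groups")
  if (any(tab < minPer))
    .gerr("insufficientGroups",
          sprintf("every group needs at least %d observations", minPer))
  groups
}

#' One-way analysis of variance on component scores
#'
#' Standard one-way decomposition (via [stats::aov()]) of a score vector by
#' species, returning the full ANOVA bookkeeping: sums of squares, degrees
#' of freedom, mean squares, F and its upper-tail probability.
#'
#' @param values numeric response (component scores).
#' @param groups species labels.
#' @return list with ssBetween, ssWithin, ssTotal, dfBetween, dfWithin,
#'   dfTotal, msBetween, msWithin, F, p.
#' @export
oneWayAnova <- function(values, groups) {
  groups <- .checkGroups(values, groups)
  if (all(vapply(split(values, groups), stats::var, numeric(1)) == 0))
    .gerr("zeroWithinVariance", "no within-group variance; F undefined")
  fit <- stats::aov(values ~ factor(groups))
  tab <- stats::anova(fit)
  ssB <- tab$`Sum Sq`[1]; ssW <- tab$`Sum Sq`[2]
  dfB <- tab$Df[1]; dfW <- tab$Df[2]
  list(ssBetween = ssB, ssWithin = ssW, ssTotal = ssB + ssW,
       dfBetween = dfB, dfWithin = dfW, dfTotal = dfB + dfW,
       msBetween = ssB / dfB, msWithin = ssW / dfW,
       F = (ssB / dfB) / (ssW / dfW),
       p = stats::pf((ssB / dfB) / (ssW / dfW), dfB, dfW, lower.tail = FALSE))
}

#' ANOVA arithmetic from printed sums of squares
#'
#' Recomputes mean squares, F and p from a reported ANOVA table's sums of
#' squares and degrees of freedom — the worked-example arithmetic behind a
#' published one-way table.
#'
#' @param ssBetween,dfBetween,ssWithin,dfWithin the printed quantities.
#' @return same structure as [oneWayAnova()].
#' @examples
#' anovaFromSums(47.208, 2, 180.792, 226)$F  # 29.506
#' @export
anovaFromSums <- function(ssBetween, dfBetween, ssWithin, dfWithin) {
  msB <- ssBetween / dfBetween
  msW <- ssWithin / dfWithin
  list(ssBetween = ssBetween, ssWithin = ssWithin,
       ssTotal = ssBetween + ssWithin,
       dfBetween = dfBetween, dfWithin = dfWithin,
       dfTotal = dfBetween + dfWithin,
       msBetween = msB, msWithin = msW, F = msB / msW,
       p = stats::pf(msB / msW, dfBetween, dfWithin, lower.tail = FALSE))
}

#' Bonferroni post-hoc pairwise comparisons
#'
#' For every unordered pair of groups: the mean difference, its pooled
#' standard error sqrt(MSw (1/na + 1/nb)), and the Bonferroni-adjusted
#' two-sided t probability (multiplied by the number of pairs, capped at
#' 1), using the ANOVA within-group mean square and degrees of freedom.
#'
#' @param values numeric scores.
#' @param groups species labels.
#' @param msWithin,dfWithin pooled within-group mean square and df;
#'   computed from `values`/`groups` when omitted.
#' @return data.frame with groupA, groupB, meanDiff (A - B), se, t,
#'   pBonferroni.
#' @export
bonferroniPairwise <- function(values, groups, msWithin = NULL, dfWithin = NULL) {
  groups <- .checkGroups(values, groups)
  if (is.null(msWithin) || is.null(dfWithin)) {
    a <- oneWayAnova(values, groups)
    msWithin <- a$msWithin; dfWithin <- a$dfWithin
  }
  lev <- sort(unique(groups))
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    na <- sum(groups == a); nb <- sum(groups == b)
    diff <- mean(values[groups == a]) - mean(values[groups == b])
    se <- sqrt(msWithin * (1 / na + 1 / nb))
    tstat <- diff / se
    p <- min(1, m * 2 * stats::pt(-abs(tstat), dfWithin))
    data.frame(groupA = a, groupB = b, meanDiff = diff, se = se,
               t = tstat, pBonferroni = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-species descriptive statistics with confidence intervals
#'
#' Group size, mean, standard deviation, standard error and the Student-t
#' confidence interval mean +/- t(n-1, 1-alpha/2) * se for each species.
#'
#' @param values numeric scores.
#' @param groups species labels.
#' @param confidence confidence level (default 0.95).
#' @return data.frame with species, n, mean, sd, se, ciLow, ciHigh.
#' @export
groupDescriptives <- function(values, groups, confidence = 0.95) {
  groups <- .checkGroups(values, groups)
  lev <- sort(unique(groups))
  out <- lapply(lev, function(g) {
    x <- values[groups == g]
    n <- length(x); m <- mean(x); s <- stats::sd(x); se <- s / sqrt(n)
    tcrit <- stats::qt(1 - (1 - confidence) / 2, n - 1)
    data.frame(species = g, n = n, mean = m, sd = s, se = se,
               ciLow = m - tcrit * se, ciHigh = m + tcrit * se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reference pairing plan
#'
#' The component-to-species-pair assignment of the original greenhouse
#' calibration: PC1 separates ryegrass (high side) from wheat, PC2 brome
#' grass (high) from wheat, PC3 ryegrass (low) from wheat.
#' @return data.frame with component, speciesA, speciesB.
#' @export
referencePlan <- function() {
  data.frame(component = c("PC1", "PC2", "PC3"),
             speciesA = c("ryegrass", "brome", "ryegrass"),
             speciesB = c("wheat", "wheat", "wheat"),
             stringsAsFactors = FALSE)
}

#' Derive pairwise discrimination thresholds from confidence intervals
#'
#' For a species pair separated on a component, the threshold is placed at
#' the midpoint of the gap between the upper confidence bound of the lower
#' group and the lower confidence bound of the higher group. With
#' `plan = "auto"` (default) every unordered species pair is assigned the
#' retained component with the widest such gap; an explicit plan (as from
#' [referencePlan()]) fixes component and pair. A planned pair whose
#' intervals overlap on its component has no defined threshold and raises
#' an error rather than guessing.
#'
#' @param scores matrix n x k of component scores (columns PC1..PCk).
#' @param groups species labels (length n).
#' @param plan `"auto"` or a data.frame with columns component, speciesA,
#'   speciesB.
#' @param confidence confidence level for the group intervals.
#' @return a [ThresholdSet-class].
#' @export
deriveThresholds <- function(scores, groups, plan = "auto", confidence = 0.95) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  groups <- .checkGroups(scores[, 1], groups)
  desc <- lapply(seq_len(ncol(scores)), function(j)
    groupDescriptives(scores[, j], groups, confidence))
  names(desc) <- colnames(scores)

  gapFor <- function(comp, a, b) {
    d <- desc[[comp]]
    da <- d[d$species == a, ]; db <- d[d$species == b, ]
    sep <- abs(da$mean - db$mean) / (da$sd + db$sd)
    if (da$mean >= db$mean) {
      list(high = a, low = b, gap = da$ciLow - db$ciHigh, sep = sep,
           boundHigh = da$ciLow, boundLow = db$ciHigh)
    } else {
      list(high = b, low = a, gap = db$ciLow - da$ciHigh, sep = sep,
           boundHigh = db$ciLow, boundLow = da$ciHigh)
    }
  }

  rows <- list()
  if (identical(plan, "auto")) {
    pairs <- utils::combn(sort(unique(groups)), 2)
    for (i in seq_len(ncol(pairs))) {
      gaps <- lapply(colnames(scores), gapFor, a = pairs[1, i], b = pairs[2, i])
      ## among components whose group CIs are disjoint, prefer the one with
      ## the largest standardized mean separation (gap width alone ignores
      ## the group spreads the threshold has to cope with)
      open <- vapply(gaps, `[[`, numeric(1), "gap") > 0
      if (!any(open))
        .gerr("overlappingIntervals", sprintf(
          "confidence intervals of %s and %s overlap on every component",
          pairs[1, i], pairs[2, i]))
      seps <- vapply(gaps, `[[`, numeric(1), "sep")
      seps[!open] <- -Inf
      best <- which.max(seps)
      g <- gaps[[best]]
      rows[[length(rows) + 1L]] <- data.frame(
        component = colnames(scores)[best], speciesHigh = g$high,
        speciesLow = g$low, threshold = (g$boundLow + g$boundHigh) / 2,
        boundLow = g$boundLow, boundHigh = g$boundHigh,
        stringsAsFactors = FALSE)
    }
  } else {
    for (i in seq_len(nrow(plan))) {
      comp <- plan$component[i]
      if (!comp %in% colnames(scores))
        .gerr("missingComponent", paste("scores lack component", comp))
      g <- gapFor(comp, plan$speciesA[i], plan$speciesB[i])
      if (g$gap <= 0)
        .gerr("overlappingIntervals", sprintf(
          "confidence intervals of %s and %s overlap on %s",
          plan$speciesA[i], plan$speciesB[i], comp))
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, speciesHigh = g$high, speciesLow = g$low,
        threshold = (g$boundLow + g$boundHigh) / 2,
        boundLow = g$boundLow, boundHigh = g$boundHigh,
        stringsAsFactors = FALSE)
    }
  }
  new("ThresholdSet", thresholds = do.call(rbind, rows),
      confidence = confidence)
}

#' Classify species pairs against thresholds
#'
#' For every threshold rule, each plant of the rule's two species is
#' labelled by the side of the threshold its component score falls on (a
#' score exactly at the threshold goes to the low side). Accuracy is
#' correct / total per rule.
#'
#' @param scores matrix n x k of component scores.
#' @param groups true species labels.
#' @param thresholds a [ThresholdSet-class].
#' @return list with `summary` (data.frame component, speciesHigh,
#'   speciesLow, nCorrect, nTotal, accuracyPct) and `predictions`
#'   (per-plant data.frame).
#' @export
classifyPairwise <- function(scores, groups, thresholds) {
  stopifnot(is(thresholds, "ThresholdSet"))
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  groups <- as.character(groups)
  th <- thresholds@thresholds
  miss <- setdiff(th$component, colnames(scores))
  if (length(miss))
    .gerr("missingComponent", paste("scores lack:", paste(miss, collapse = ", ")))
  summ <- list(); preds <- list()
  for (i in seq_len(nrow(th))) {
    sel <- groups %in% c(th$speciesHigh[i], th$speciesLow[i])
    s <- scores[sel, th$component[i]]
    pred <- ifelse(s > th$threshold[i], th$speciesHigh[i], th$speciesLow[i])
    correct <- pred == groups[sel]
    summ[[i]] <- data.frame(component = th$component[i],
      speciesHigh = th$speciesHigh[i], speciesLow = th$speciesLow[i],
      nCorrect = sum(correct), nTotal = length(correct),
      accuracyPct = 100 * mean(correct), stringsAsFactors = FALSE)
    preds[[i]] <- data.frame(component = th$component[i],
      index = which(sel), trueSpecies = groups[sel], score = s,
      predicted = pred, correct = correct, stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, summ), predictions = do.call(rbind, preds))
}

#' Random holdout split
#'
#' Uniform random split without replacement; the test set has
#' `round(fraction * n)` rows. Deterministic under `seed`. Splitting 286
#' plants at 20% gives 57 test and 229 training rows.
#'
#' @param table data.frame to split (or an integer n, returning indices).
#' @param fraction test fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` (data.frames, or index vectors when
#'   `table` is a count).
#' @export
holdoutSplit <- function(table, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    .gerr("badInput", "fraction must lie strictly between 0 and 1")
  n <- if (is.data.frame(table)) nrow(table) else as.integer(table)
  nTest <- round(fraction * n)
  set.seed(seed)
  testIdx <- sort(sample.int(n, nTest))
  trainIdx <- setdiff(seq_len(n), testIdx)
  if (is.data.frame(table))
    list(train = table[trainIdx, , drop = FALSE],
         test = table[testIdx, , drop = FALSE])
  else list(train = trainIdx, test = testIdx)
}
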