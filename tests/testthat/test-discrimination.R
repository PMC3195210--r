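# ANOVA bookkeeping, Bonferroni post-hoc, descriptives, CI thresholds,
# pairwise classification and the holdout split.

test_that("ANOVA arithmetic reproduces a published one-way table from its sums", {
  # frozen from the greenhouse calibration's score ANOVA (n = 229, 3 species)
  pc1 <- anovaFromSums(47.208, 2, 180.792, 226)
  expect_equal(pc1$msBetween, 23.604)
  expect_equal(round(pc1$msWithin, 3), 0.800)
  expect_equal(round(pc1$F, 3), 29.506)
  expect_lt(pc1$p, 0.001)
  expect_equal(round(anovaFromSums(22.985, 2, 205.015, 226)$F, 3), 12.669)
  expect_equal(round(anovaFromSums(30.213, 2, 197.787, 226)$F, 3), 17.261)
  expect_equal(pc1$ssTotal, 228)
  expect_equal(pc1$dfTotal, 228)
})

test_that("one-way ANOVA satisfies its algebraic identities", {
  set.seed(11)
  for (rep in 1:5) {
    g <- rep(c("a", "b", "c"), times = sample(5:30, 3, replace = TRUE))
    x <- rnorm(length(g)) + as.numeric(factor(g)) * runif(1, 0, 2)
    a <- oneWayAnova(x, g)
    expect_equal(a$ssBetween + a$ssWithin, a$ssTotal,
                 tolerance = 1e-9 * a$ssTotal)
    expect_equal(a$dfBetween + a$dfWithin, a$dfTotal)
    expect_equal(a$F, a$msBetween / a$msWithin)
    expect_equal(a$ssTotal, var(x) * (length(x) - 1), tolerance = 1e-9)
  }
  # two groups: F is the squared pooled two-sample t statistic
  g2 <- rep(c("a", "b"), c(14, 9))
  x2 <- rnorm(23) + (g2 == "b")
  a2 <- oneWayAnova(x2, g2)
  tt <- t.test(x2[g2 == "a"], x2[g2 == "b"], var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(oneWayAnova(rep(1, 10), rep(c("a", "b"), 5)),
               class = "grassID_zeroWithinVariance")
  expect_error(oneWayAnova(rnorm(5), rep("a", 5)),
               class = "grassID_insufficientGroups")
})

test_that("Bonferroni pairwise arithmetic reproduces the calibration example", {
  # wheat (n 87, mean -0.21) vs ryegrass (n 38, mean 1.02), MSw 0.800:
  # the mean difference and pooled SE of the published post-hoc row
  diff <- -0.21 - 1.02
  se <- sqrt(0.800 * (1 / 87 + 1 / 38))
  expect_equal(diff, -1.23)
  expect_equal(round(se, 2), 0.17)
  # on data engineered to those group statistics the function agrees
  mkgrp <- function(n, m, s) { x <- rnorm(n); m + s * (x - mean(x)) / sd(x) }
  set.seed(12)
  x <- c(mkgrp(87, -0.21, 0.9), mkgrp(38, 1.02, 0.9))
  g <- rep(c("wheat", "ryegrass"), c(87, 38))
  bp <- bonferroniPairwise(x, g, msWithin = 0.800, dfWithin = 226)
  row <- bp[bp$groupA == "ryegrass", ]
  expect_equal(row$meanDiff, 1.23, tolerance = 1e-9)   # ryegrass - wheat
  expect_equal(round(row$se, 2), 0.17)
})

test_that("Bonferroni adjustment is conservative and symmetric", {
  set.seed(13)
  x <- rnorm(60); g <- rep(c("a", "b", "c"), each = 20)
  bp <- bonferroniPairwise(x, g)
  a <- oneWayAnova(x, g)
  for (i in seq_len(nrow(bp))) {
    unadj <- 2 * pt(-abs(bp$t[i]), a$dfWithin)
    expect_gte(bp$pBonferroni[i], unadj)
    expect_lte(bp$pBonferroni[i], 1)
  }
  # identical groups: zero difference, p = 1
  xx <- rep(rnorm(10), 2); gg <- rep(c("a", "b"), each = 10)
  bpp <- bonferroniPairwise(xx, gg)
  expect_equal(bpp$meanDiff, 0)
  expect_equal(bpp$pBonferroni, 1)
})

test_that("group descriptives give t-based confidence intervals", {
  mkgrp <- function(n, m, s) { x <- rnorm(n); m + s * (x - mean(x)) / sd(x) }
  set.seed(14)
  x2 <- c(mkgrp(87, -0.21, 0.76), mkgrp(38, 1.02, 0.82))
  g <- rep(c("wheat", "ryegrass"), c(87, 38))
  d <- groupDescriptives(x2, g)
  w <- d[d$species == "wheat", ]
  expect_equal(w$n, 87)
  expect_equal(round(w$se, 2), 0.08)          # 0.76 / sqrt(87)
  expect_equal(w$se, w$sd / sqrt(w$n))
  tcrit <- qt(0.975, 86)
  expect_equal(w$ciLow, w$mean - tcrit * w$se, tolerance = 1e-12)
  expect_equal(round(c(w$ciLow, w$ciHigh), 2), c(-0.37, -0.05))
  # widening the confidence level widens the interval
  d99 <- groupDescriptives(x2, g, confidence = 0.99)
  expect_lt(d99$ciLow[d99$species == "wheat"], w$ciLow)
})

test_that("thresholds sit at the midpoint of the CI gap", {
  mkgrp <- function(n, m, s) { x <- rnorm(n); m + s * (x - mean(x)) / sd(x) }
  set.seed(15)
  # engineered so the wheat/ryegrass CI bounds land at -0.05 and 0.75,
  # the published PC1 bounds; the derived threshold is their midpoint
  wheat <- mkgrp(87, -0.21, (-0.05 - -0.21) * sqrt(87) / qt(0.975, 86))
  rye <- mkgrp(38, 1.02, (1.02 - 0.75) * sqrt(38) / qt(0.975, 37))
  sc <- matrix(c(wheat, rye), ncol = 1, dimnames = list(NULL, "PC1"))
  g <- rep(c("wheat", "ryegrass"), c(87, 38))
  thr <- deriveThresholds(sc, g)
  tt <- thresholdTable(thr)
  expect_equal(round(tt$boundLow, 2), -0.05)
  expect_equal(round(tt$boundHigh, 2), 0.75)
  expect_equal(tt$threshold, (tt$boundLow + tt$boundHigh) / 2)
  expect_equal(round(tt$threshold, 2), 0.35)
  expect_identical(tt$speciesHigh, "ryegrass")
  # symmetric CIs around +-1 give a zero threshold
  a <- mkgrp(40, -1, 0.3); b <- mkgrp(40, 1, 0.3)
  sc2 <- matrix(c(a, b), ncol = 1, dimnames = list(NULL, "PC1"))
  thr2 <- deriveThresholds(sc2, rep(c("lo", "hi"), each = 40))
  expect_equal(thresholdTable(thr2)$threshold, 0, tolerance = 1e-10)
  # overlapping intervals refuse to produce a threshold
  c1 <- mkgrp(30, 0, 1); c2 <- mkgrp(30, 0.05, 1)
  sc3 <- matrix(c(c1, c2), ncol = 1, dimnames = list(NULL, "PC1"))
  expect_error(deriveThresholds(sc3, rep(c("a", "b"), each = 30)),
               class = "grassID_overlappingIntervals")
})

test_that("an explicit pairing plan is honoured and validated", {
  mkgrp <- function(n, m, s) { x <- rnorm(n); m + s * (x - mean(x)) / sd(x) }
  set.seed(16)
  sc <- cbind(PC1 = c(mkgrp(30, 0, 0.2), mkgrp(30, 2, 0.2), mkgrp(30, 2.05, 0.2)),
              PC2 = c(mkgrp(30, 0, 0.2), mkgrp(30, -0.02, 0.2), mkgrp(30, 2, 0.2)))
  g <- rep(c("wheat", "ryegrass", "brome"), each = 30)
  plan <- data.frame(component = c("PC1", "PC2"),
                     speciesA = c("ryegrass", "brome"),
                     speciesB = c("wheat", "wheat"))
  thr <- deriveThresholds(sc, g, plan = plan)
  tt <- thresholdTable(thr)
  expect_equal(nrow(tt), 2)
  expect_identical(tt$component, c("PC1", "PC2"))
  badPlan <- data.frame(component = "PC1", speciesA = "ryegrass",
                        speciesB = "brome")  # overlapping on PC1
  expect_error(deriveThresholds(sc, g, plan = badPlan),
               class = "grassID_overlappingIntervals")
  missPlan <- data.frame(component = "PC9", speciesA = "a", speciesB = "b")
  expect_error(deriveThresholds(sc, g, plan = missPlan),
               class = "grassID_missingComponent")
})

test_that("pairwise classification respects the threshold and tie rule", {
  tt <- data.frame(component = "PC1", speciesHigh = "rye", speciesLow = "wheat",
                   threshold = 1, boundLow = 0.8, boundHigh = 1.2,
                   stringsAsFactors = FALSE)
  thr <- new("ThresholdSet", thresholds = tt, confidence = 0.95)
  sc <- matrix(c(0.2, 0.9, 1.5, 2, 1), ncol = 1,
               dimnames = list(NULL, "PC1"))
  g <- c("wheat", "wheat", "rye", "rye", "wheat")
  rep1 <- classifyPairwise(sc, g, thr)
  expect_equal(rep1$summary$accuracyPct, 100)          # boundary -> low side
  expect_identical(rep1$predictions$predicted[5], "wheat")
  # misclassification rate of two overlapping normals matches Phi(2)
  set.seed(17)
  n <- 1000
  sc2 <- matrix(c(rnorm(n, 0, 0.5), rnorm(n, 2, 0.5)), ncol = 1,
                dimnames = list(NULL, "PC1"))
  g2 <- rep(c("wheat", "rye"), each = n)
  thr2 <- new("ThresholdSet", confidence = 0.95, thresholds = data.frame(
    component = "PC1", speciesHigh = "rye", speciesLow = "wheat",
    threshold = 1, boundLow = 0.9, boundHigh = 1.1, stringsAsFactors = FALSE))
  acc <- classifyPairwise(sc2, g2, thr2)$summary$accuracyPct
  expect_lt(abs(acc - 100 * pnorm(2)), 1.5)
})

test_that("the holdout split is exact, disjoint and seed-deterministic", {
  sp <- holdoutSplit(286, fraction = 0.2, seed = 5)
  expect_length(sp$test, 57)
  expect_length(sp$train, 229)
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- holdoutSplit(286, fraction = 0.2, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- holdoutSplit(286, fraction = 0.2, seed = 6)
  expect_false(identical(sp$test, sp3$test))
  expect_length(holdoutSplit(4, fraction = 0.5, seed = 1)$test, 2)
  tab <- data.frame(x = 1:10)
  spt <- holdoutSplit(tab, fraction = 0.3, seed = 2)
  expect_equal(nrow(spt$test), 3)
  expect_setequal(c(spt$train$x, spt$test$x), 1:10)
  expect_error(holdoutSplit(10, fraction = 1.2), class = "grassID_badInput")
})
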