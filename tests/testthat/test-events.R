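test_that("quantile event labeling yields the order-statistics counts", {
  set.seed(91)
  ev <- labelLowSsimEvents(runif(100), 0.05)
  expect_equal(sum(eventLabels(ev)), 5L)
  ev <- labelLowSsimEvents(runif(171), 0.10)
  expect_equal(sum(eventLabels(ev)), 17L)
  # constant series: nothing strictly below its quantile
  ev <- labelLowSsimEvents(rep(0.8, 50), 0.05)
  expect_equal(sum(eventLabels(ev)), 0L)
  expect_true(ev@degenerate)
  expect_error(labelLowSsimEvents(runif(10), 1.2), "qS")
})

test_that("event dilation: clipping, identity, absorbing cases", {
  lab <- integer(20); lab[10] <- 1L
  d <- dilateEvents(EventSeries(lab), 2L)
  expect_equal(which(eventLabels(d) == 1L), 8:12)
  expect_equal(eventLabels(dilateEvents(EventSeries(lab), 0L)), lab)
  lab2 <- integer(5); lab2[1] <- 1L          # clipped at the boundary
  expect_equal(which(eventLabels(dilateEvents(EventSeries(lab2), 2L)) == 1L),
               1:3)
  allpos <- rep(1L, 6)
  expect_equal(eventLabels(dilateEvents(EventSeries(allpos), 3L)), allpos)
})

test_that("rank-based AUROC equals the brute-force pairwise oracle", {
  set.seed(92)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    score <- if (i %% 3 == 0) sample(5, n, replace = TRUE) else rnorm(n)
    labels <- rbinom(n, 1, 0.3)
    if (!any(labels == 1) || !any(labels == 0)) next
    expect_equal(aurocScore(score, labels),
                 bruteForceAuroc(score, labels), tolerance = 1e-12)
  }
  # perfect and constant scores
  lab <- c(0, 1, 0, 1, 0)
  expect_equal(aurocScore(lab, lab), 1)
  expect_equal(averagePrecision(lab, lab), 1)
  expect_equal(aurocScore(rep(2, 5), lab), 0.5)   # midrank convention
  expect_true(is.na(aurocScore(rnorm(5), rep(1, 5))))  # degenerate
})

test_that("lag-aware detection credits scores near events", {
  lab <- integer(10); lab[5] <- 1L
  sc <- c(0.01, 0.02, 0.3, 0.4, 0.5, 1, 0.45, 0.05, 0.03, 0.04)
  d2 <- lagAwareDetection(sc, EventSeries(lab), tolerance = 2L)
  expect_equal(d2@auroc, 1)        # spike one index off, inside +/-2
  d0 <- lagAwareDetection(sc, EventSeries(lab), tolerance = 0L)
  expect_equal(d0@auroc, 8 / 9)    # frozen from the pairwise oracle
  expect_lt(d0@auroc, 1)
  # NaN transitions are excluded pairwise
  sc[2] <- NA
  dN <- lagAwareDetection(sc, EventSeries(lab), tolerance = 2L)
  expect_equal(dN@nValid, 9L)
})

test_that("spike binarization matches positive counts and keeps NA", {
  set.seed(93)
  sc <- rnorm(100)
  sp <- spikeBinarize(sc, 0.05)
  expect_equal(sum(sp), 5L)
  expect_equal(which(sp == 1L), which(rank(-abs(sc)) <= 5))
  sc[3] <- NA
  sp <- spikeBinarize(sc, 0.05)
  expect_true(is.na(sp[3]))
  expect_equal(sum(sp, na.rm = TRUE), max(1L, round(0.05 * 99)))
  expect_error(spikeBinarize(rep(NA_real_, 5), 0.1), "all NA")
})

test_that("Matthews correlation: identities and the direct formula", {
  a <- c(1, 1, 0, 0, 1, 0)
  expect_equal(matthewsCorr(a, a), 1)
  expect_equal(matthewsCorr(a, 1 - a), -1)
  # TP=3 TN=90 FP=2 FN=5, frozen from the closed formula
  b <- c(rep(1, 3), rep(0, 90), rep(1, 2), rep(0, 5))
  r <- c(rep(1, 3), rep(0, 90), rep(0, 2), rep(1, 5))
  expect_equal(matthewsCorr(b, r), 0.4397316, tolerance = 1e-6)
  # symmetry and joint relabeling invariance
  set.seed(94)
  for (i in 1:10) {
    u <- rbinom(30, 1, 0.4); v <- rbinom(30, 1, 0.4)
    expect_equal(matthewsCorr(u, v), matthewsCorr(v, u))
    expect_equal(matthewsCorr(1 - u, 1 - v), matthewsCorr(u, v))
  }
  # zero denominator convention
  expect_equal(matthewsCorr(rep(1, 4), c(1, 0, 1, 0)), 0)
})

test_that("permutation test: add-one estimator and null behaviour", {
  set.seed(95)
  a <- rbinom(60, 1, 0.2)
  while (sum(a) < 2) a <- rbinom(60, 1, 0.2)
  r <- permutationTest(a, a, nPerm = 999, seed = 1)
  expect_equal(r$observed, 1)
  expect_lte(r$pValue, 5 / 1000)   # only coincidental permutations match
  expect_error(permutationTest(a, a, nPerm = 50), "99")
  # p-values are super-uniform under independence (Monte-Carlo)
  set.seed(96)
  ps <- replicate(120, {
    u <- rbinom(40, 1, 0.3); v <- rbinom(40, 1, 0.3)
    permutationTest(u, v, nPerm = 99)$pValue
  })
  expect_gte(mean(ps <= 0.05), 0)        # sanity
  expect_lte(mean(ps <= 0.05), 0.12)     # close to the nominal 5% level
  expect_gt(median(ps), 0.25)
  # circular scheme is a valid permutation scheme too
  r2 <- permutationTest(a, a, nPerm = 99, seed = 2, scheme = "circular")
  expect_true(r2$pValue > 0 && r2$pValue <= 1)
})
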