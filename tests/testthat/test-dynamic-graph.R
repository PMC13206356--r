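test_that("window segmentation counts and boundaries", {
  x <- matrix(rnorm(176 * 3), 176)
  expect_length(segmentWindows(x, 5, 1), 172L)
  expect_length(segmentWindows(matrix(rnorm(30), 10), 10, 1), 1L)
  expect_error(segmentWindows(matrix(rnorm(27), 9), 10),
               "9 time points.*10")
  # property sweep: floor((T - w)/s) + 1 windows of exactly w rows
  set.seed(81)
  for (i in 1:20) {
    Tn <- sample(10:60, 1); w <- sample(2:Tn, 1); s <- sample(1:5, 1)
    segs <- segmentWindows(matrix(rnorm(Tn * 2), Tn), w, s)
    expect_length(segs, (Tn - w) %/% s + 1L)
    expect_true(all(vapply(segs, nrow, integer(1)) == w))
  }
})

test_that("correlation graph: diagonal, range, degenerate columns", {
  set.seed(82)
  seg <- matrix(rnorm(20), 5, 4)
  seg[, 2] <- seg[, 1]              # identical columns
  seg[, 3] <- -seg[, 1]             # negated column
  A <- correlationGraph(seg)
  expect_equal(diag(A), rep(0, 4))
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], -1)
  expect_true(all(A >= -1 & A <= 1))
  # zero-variance column is disconnected for that window
  seg[, 4] <- 2
  A <- correlationGraph(seg)
  expect_equal(A[4, ], rep(0, 4))
  expect_equal(attr(A, "nConstant"), 1L)
})

test_that("Pearson graphs are invariant to per-column affine rescaling", {
  set.seed(83)
  seg <- matrix(rnorm(8 * 6), 8)
  zs <- scale(seg)                        # z-scoring
  af <- sweep(sweep(seg, 2, runif(6, 0.5, 3), "*"), 2, rnorm(6), "+")
  expect_equal(correlationGraph(zs), correlationGraph(seg),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(correlationGraph(af), correlationGraph(seg),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("binarization is strict and drops negative correlations", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.5      # exactly at threshold: no edge
  A[1, 3] <- A[3, 1] <- 0.51
  A[2, 3] <- A[3, 2] <- -0.9
  B <- binarizeGraph(A, 0.5)
  expect_equal(B[1, 2], 0)
  expect_equal(B[1, 3], 1)
  expect_equal(B[2, 3], 0)
  expect_true(all(B %in% c(0, 1)) && all(diag(B) == 0))
})

test_that("global SSIM: identity, symmetry, constants, complement", {
  set.seed(84)
  for (i in 1:10) {
    A <- rBinaryGraph(8, 0.4)
    B <- rBinaryGraph(8, 0.4)
    expect_equal(ssimPair(A, A), 1)
    expect_equal(ssimPair(A, B), ssimPair(B, A))
  }
  expect_equal(ssimPair(matrix(0, 5, 5), matrix(0, 5, 5)), 1)
  # balanced complement: strongly dissimilar (frozen from direct formula)
  a <- matrix(0, 6, 6); a[1:3, 4:6] <- 1; a[4:6, 1:3] <- 1
  b <- (a == 0) * 1; diag(b) <- 0
  expect_equal(ssimPair(a, b), -0.6486033, tolerance = 1e-6)
  expect_lt(ssimPair(a, b), 0)
  # windowed variant agrees at the identity and stays bounded
  expect_equal(ssimPair(a, a, windowed = TRUE), 1)
  expect_true(abs(ssimPair(a, b, windowed = TRUE)) <= 1)
})

test_that("pipeline composition: counts, binarization, weighted mode", {
  set.seed(85)
  x <- matrix(rnorm(176 * 12), 176)
  gs <- buildDynamicGraph(x, 5, 1, 0.5)
  expect_equal(nWindows(gs), 172L)
  expect_length(ssimSeries(gs), 171L)
  expect_true(gs@binary)
  expect_true(all(gs[[7]] %in% c(0, 1)))

  wt <- buildDynamicGraph(x, 5, 1, keepWeighted = TRUE)
  expect_false(wt@binary)
  expect_equal(binarizeGraph(wt[[7]], 0.5), gs[[7]], ignore_attr = TRUE)

  # pure noise with many regions: near-empty binary graphs on average
  set.seed(86)
  xn <- matrix(rnorm(60 * 20), 60)
  gn <- buildDynamicGraph(xn, 5, 1, 0.5)
  dens <- mean(vapply(graphs(gn), mean, numeric(1)))
  expect_lt(dens, 0.25)
})

test_that("sequence container validates its graphs", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  expect_error(WindowedGraphSequence(list(A, matrix(0, 4, 4))), "nodes")
  bad <- A; bad[1, 3] <- 5
  expect_error(WindowedGraphSequence(list(bad)), "symmetric")
})
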