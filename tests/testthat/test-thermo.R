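test_that("normalized Laplacian matches closed forms", {
  K2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalizedLaplacian(K2),
               matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(sort(eigen(normalizedLaplacian(K2))$values), c(0, 2))

  K3 <- matrix(1, 3, 3) - diag(3)
  L3 <- normalizedLaplacian(K3)
  expect_equal(diag(L3), rep(1, 3))
  expect_equal(L3[1, 2], -0.5)
  expect_equal(sort(eigen(L3)$values), c(0, 1.5, 1.5))

  # isolated node: its row/column are zero, including the diagonal
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  L <- normalizedLaplacian(A)
  expect_equal(L[3, ], rep(0, 3))
  expect_equal(L[, 3], rep(0, 3))
  expect_equal(diag(L), c(1, 1, 0))
})

test_that("invalid adjacency inputs are rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)          # non-symmetric
  expect_error(normalizedLaplacian(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)        # negative weight
  expect_error(normalizedLaplacian(neg), "non-negative")
  dg <- matrix(c(1, 0, 0, 0), 2, 2)           # nonzero diagonal
  expect_error(normalizedLaplacian(dg), "diagonal")
})

test_that("spectrum: K4 eigenvalues and the trace identity", {
  K4 <- matrix(1, 4, 4) - diag(4)
  sp <- graphSpectrum(K4)
  expect_equal(sp$eigenvalues, c(4/3, 4/3, 4/3, 0))
  # full-spectrum sum equals node count for isolate-free graphs
  set.seed(11)
  for (i in 1:5) {
    A <- rBinaryGraph(25, 0.3)
    while (any(rowSums(A) == 0)) A <- rBinaryGraph(25, 0.3)
    expect_equal(sum(graphSpectrum(A)$eigenvalues), 25, tolerance = 1e-10)
  }
  # with isolates the trace is the number of connected nodes
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1
  expect_equal(sum(graphSpectrum(A)$eigenvalues), 2, tolerance = 1e-12)
})

test_that("spectral core entropy matches closed forms on K4 and K2", {
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(spectralCoreEntropy(K4, alpha = 4), log(3))
  expect_equal(spectralCoreEntropy(K4, alpha = 2), (2/3) * log(3))
  expect_equal(spectralCoreEntropy(K4, alpha = 2, renormalize = TRUE),
               log(2))
  K2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(spectralCoreEntropy(K2, alpha = 2), 0)  # p = {1, 0}
})

test_that("von Neumann entropy: block spectra and the SCE identity", {
  expect_equal(vonNeumannEntropy(matrix(0, 5, 5)), 0)   # no edges
  # two disjoint edges: eigenvalues {2, 2, 0, 0}, p = {.5, .5, 0, 0}
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  expect_equal(vonNeumannEntropy(A), log(2))
  set.seed(21)
  for (i in 1:5) {
    A <- rWeightedGraph(15, 0.4)
    expect_equal(vonNeumannEntropy(A),
                 spectralCoreEntropy(A, alpha = 15), tolerance = 1e-12)
  }
})

test_that("plain SCE is non-decreasing in alpha", {
  set.seed(31)
  for (i in 1:5) {
    A <- rBinaryGraph(30, 0.25)
    s <- vapply(1:30, function(a) spectralCoreEntropy(A, alpha = a),
                numeric(1))
    expect_true(all(diff(s) >= -1e-12))
  }
})

test_that("node energy: closed forms and exact conservation", {
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(nodeEnergy(star), c(2.25, 0.25, 0.25, 0.25))
  expect_equal(sum(nodeEnergy(star)), internalEnergy(star))
  # d-regular: every node gets d/2
  C5 <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; C5[i, j] <- C5[j, i] <- 1 }
  expect_equal(nodeEnergy(C5), rep(1, 5))
  # isolated nodes get zero
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 2.5
  expect_equal(nodeEnergy(A)[3], 0)
  # conservation property over random binary and weighted graphs
  set.seed(41)
  for (i in 1:50) {
    A <- if (i %% 2) rBinaryGraph(20, 0.3) else rWeightedGraph(20, 0.3)
    expect_equal(sum(nodeEnergy(A)), sum(A[upper.tri(A)]),
                 tolerance = 1e-10)
  }
})

test_that("internal energy is the total edge mass", {
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_identical(internalEnergy(K4), 6)
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.5; W[1, 3] <- W[3, 1] <- 1.5
  expect_equal(internalEnergy(W), 2.0)
  expect_identical(internalEnergy(matrix(0, 4, 4)), 0)
})

test_that("temperature series: arithmetic, boundary and degeneracy guard", {
  tt <- temperatureSeries(c(3, 5, 5), c(1.0, 1.5, 2.0))
  expect_equal(as.numeric(tt), c(0, 4, 0))
  expect_equal(attr(tt, "nDegenerate"), 0L)

  expect_equal(as.numeric(temperatureSeries(7, 2.2)), 0)  # single window

  tt <- temperatureSeries(c(2, 4), c(1.0, 1.0))
  expect_identical(as.numeric(tt)[2], NaN)
  expect_equal(attr(tt, "nDegenerate"), 1L)

  expect_error(temperatureSeries(1:3, 1:2), "mismatch")
})

test_that("scale invariance: weights times c leave the spectrum and SCE fixed, scale U by c", {
  set.seed(51)
  A <- rWeightedGraph(25, 0.3)
  for (cc in c(0.1, 3, 42)) {
    expect_equal(normalizedLaplacian(cc * A), normalizedLaplacian(A),
                 tolerance = 1e-12)
    expect_equal(spectralCoreEntropy(cc * A, alpha = 10),
                 spectralCoreEntropy(A, alpha = 10), tolerance = 1e-10)
    expect_equal(internalEnergy(cc * A), cc * internalEnergy(A),
                 tolerance = 1e-10)
  }
})

test_that("thermoTrajectory composes the per-window descriptors", {
  set.seed(61)
  A <- rBinaryGraph(12, 0.4)
  gs <- WindowedGraphSequence(list(A, A, A))
  tr <- thermoTrajectory(gs, alpha = 8)
  expect_equal(internalEnergy(tr), rep(internalEnergy(A), 3))
  expect_equal(temperatureIndex(tr)[1], 0)
  expect_true(all(is.nan(temperatureIndex(tr)[-1])))
  expect_equal(tr@nDegenerate, 2L)

  # binary sequence: U series is the edge-count series exactly
  gl <- lapply(1:4, function(i) rBinaryGraph(12, 0.4))
  tr2 <- thermoTrajectory(WindowedGraphSequence(gl), alpha = 8,
                          withVne = TRUE)
  expect_identical(internalEnergy(tr2),
                   vapply(gl, function(A) sum(A) / 2, numeric(1)))
  expect_equal(rowSums(nodeEnergy(tr2)), internalEnergy(tr2),
               tolerance = 1e-10)
  expect_length(vonNeumannEntropy(tr2), 4L)
  df <- as.data.frame(tr2)
  expect_named(df, c("window_index", "U", "S", "VNE", "T"))
  expect_equal(df$window_index, 0:3)
})
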