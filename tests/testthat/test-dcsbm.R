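test_that("DC-SBM sampling reduces to Erdos-Renyi and respects blocks", {
  scn <- DCSBMScenario("R1", nNodes = 40L, thetaRange = c(1, 1))
  set.seed(141)
  # theta = 1, p_in = p_out = p: density matches the binomial oracle
  p <- 0.2
  nPairs <- choose(40, 2)
  dens <- replicate(200, {
    A <- sampleDcsbmGraph(scn, p, p, theta = rep(1, 40))
    sum(A[upper.tri(A)] > 0) / nPairs
  })
  se <- sqrt(p * (1 - p) / nPairs / 200)
  expect_lt(abs(mean(dens) - p), 3 * se)

  # p_out = 0: strictly block-diagonal
  scn2 <- DCSBMScenario("R1", nNodes = 40L,
                        wiringGrid = cbind(0.5, 1e-9))
  set.seed(142)
  A <- sampleDcsbmGraph(scn2, 0.5, 0, theta = rep(1, 40))
  blk <- scn2@blocks
  cross <- A[outer(blk, blk, "!=")]
  expect_true(all(cross == 0))

  # planted high-propensity node has the top expected degree
  scn3 <- DCSBMScenario("R1", nNodes = 40L)
  th <- rep(1, 40); th[13] <- 3
  set.seed(143)
  degs <- Reduce(`+`, lapply(1:40, function(i)
    rowSums(sampleDcsbmGraph(scn3, 0.3, 0.08, theta = th) > 0)))
  expect_equal(which.max(degs), 13L)
})

test_that("regime series: layout, change points, regime contracts", {
  set.seed(151)
  for (rg in c("R1", "R2", "R3")) {
    ser <- generateRegimeSeries(DCSBMScenario(rg))
    expect_equal(nWindows(ser$sequence), 45L)
    expect_equal(ser$changePoints, c(15L, 30L))
  }
  # R1: exact edge-mass preservation at every transition
  set.seed(152)
  u <- internalEnergy(generateRegimeSeries(DCSBMScenario("R1"))$sequence)
  expect_equal(max(abs(diff(u))), 0, tolerance = 1e-8)

  # R2 pure-gain variant: entropy exactly constant within segments
  set.seed(153)
  ser <- generateRegimeSeries(DCSBMScenario("R2", weightRedraw = FALSE))
  S <- spectralCoreEntropy(ser$sequence)
  for (segStart in c(1, 16, 31))
    expect_equal(max(abs(diff(S[segStart:(segStart + 14)]))), 0)
  # while U jumps across boundaries with the gain
  u2 <- internalEnergy(ser$sequence)
  expect_equal(u2[16] / u2[15], ser$gains[2] / ser$gains[1],
               tolerance = 1e-10)

  # R3 gains are a permutation of the configured levels
  set.seed(154)
  ser3 <- generateRegimeSeries(DCSBMScenario("R3"))
  expect_setequal(ser3$gains, c(1.2, 1.5, 2.0))
})

test_that("benchmark aggregates per-regime medians and means", {
  tab <- runBenchmark(regimes = "R3", nSeries = 8, seed = 7)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$median >= 0 & tab$median <= 1, na.rm = TRUE))
  per <- attr(tab, "perSeries")
  expect_equal(dim(per$R3), c(8L, 4L))
  # deterministic given the seed
  tab2 <- runBenchmark(regimes = "R3", nSeries = 8, seed = 7)
  expect_equal(tab$median, tab2$median)
})

test_that("extreme parameter separation makes every score near-perfect in its regime", {
  # exact boundaries (tolerance 0) so the detection ceiling is 1.
  # Structure-sensitive scores under drastic rewiring:
  scnS <- DCSBMScenario("R3",
                        wiringGrid = cbind(c(0.60, 0.30, 0.08),
                                           c(0.02, 0.30, 0.08)),
                        gainLevels = c(1, 20, 400))
  tabS <- runBenchmark(regimes = "R3", nSeries = 12, seed = 11,
                       tolerance = 0L, scenario = list(R3 = scnS))
  sub <- tabS[tabS$score %in% c("abs_dSCE", "netlsd", "one_minus_ssim"), ]
  expect_true(all(sub$median > 0.9))
  # the ratio score |T| under drastic gain modulation on fixed wiring:
  scnG <- DCSBMScenario("R2", gainLevels = c(1, 20, 400))
  tabG <- runBenchmark(regimes = "R2", nSeries = 12, seed = 11,
                       tolerance = 0L, scenario = list(R2 = scnG))
  expect_gt(tabG$median[tabG$score == "abs_T"], 0.9)
})
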