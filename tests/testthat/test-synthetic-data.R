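test_that("MVAR simulation matches closed-form and brute-force oracles", {
  # degenerate: no dynamics, no noise -> all-zero series
  z <- simulateMvar(groundTruthNetwork(array(0, c(2, 2, 1)),
                                       innovationSd = 0), 50, seed = 1)
  expect_true(all(seriesValues(z) == 0))

  # univariate AR(1), a = 0.9: stationary variance 1/(1 - 0.81)
  ar1 <- groundTruthNetwork(array(0.9, c(1, 1, 1)))
  x <- seriesValues(simulateMvar(ar1, 50000, seed = 1))
  expect_equal(var(as.numeric(x)), 1 / (1 - 0.81), tolerance = 0.05)

  # directed edge 1 -> 2 shows up in lag-1 cross-covariance, one-way
  ts <- simulateMvar(twoChannelNet(coupling = 0.5, self = 0),
                     50000, seed = 2)
  v <- seriesValues(ts)
  n <- ncol(v)
  fwd <- cov(v[1, 1:(n - 1)], v[2, 2:n])
  bwd <- cov(v[2, 1:(n - 1)], v[1, 2:n])
  expect_gt(fwd, 0.4)
  expect_lt(abs(bwd), 0.05)
})

test_that("MVAR simulation is seed-reproducible and rejects unstable nets", {
  net <- twoChannelNet()
  a <- simulateMvar(net, 300, seed = 7)
  b <- simulateMvar(net, 300, seed = 7)
  expect_identical(seriesValues(a), seriesValues(b))
  expect_false(identical(seriesValues(simulateMvar(net, 300, seed = 8)),
                         seriesValues(a)))
  expect_error(groundTruthNetwork(array(1.05, c(1, 1, 1))),
               "spectral radius 1.05")
  # stable nets stay bounded
  expect_lt(max(abs(seriesValues(simulateMvar(net, 5000, seed = 9)))), 1e6)
})

test_that("time-varying schedules interpolate between coefficient sets", {
  A0 <- array(0, c(2, 2, 1)); A1 <- A0; A1[2, 1, 1] <- 0.8
  ramp <- groundTruthNetwork(A0, coeffsEnd = A1, schedule = "ramp")
  expect_equal(networkCoeffsAt(ramp, 1, 101), A0)
  expect_equal(networkCoeffsAt(ramp, 101, 101), A1)
  expect_equal(networkCoeffsAt(ramp, 51, 101)[2, 1, 1], 0.4)
  pw <- groundTruthNetwork(A0, coeffsEnd = A1, changePoint = 50)
  expect_equal(networkCoeffsAt(pw, 49, 100), A0)
  expect_equal(networkCoeffsAt(pw, 50, 100), A1)
})

test_that("vertex maps realize planted clusters and reject overlap", {
  nT <- 40
  course <- latentCourse(nT)
  lay <- roiLayout(list(list(center = c(0, 0), radiusMm = 4,
                             amplitude = 3, course = course)),
                   patchHalfWidthMm = 10, gridSpacingMm = 2,
                   jitterSdMm = 0, noiseSd = 0)
  map <- simulateVertexMap(lay, nT, seed = 1)
  memb <- plantedMembership(lay, map)[[1]]
  expect_gt(length(memb), 3)
  # zero noise: member courses exactly proportional to the latent course
  act <- seriesValues(map)[match(memb, vertexIds(map)), , drop = FALSE]
  for (i in seq_len(nrow(act)))
    expect_equal(cor(act[i, ], course), 1, tolerance = 1e-10)
  # non-members are exactly zero
  bg <- setdiff(vertexIds(map), memb)
  expect_true(all(seriesValues(map)[match(bg, vertexIds(map)), ] == 0))

  over <- roiLayout(list(
    list(center = c(0, 0), radiusMm = 4, amplitude = 3, course = course),
    list(center = c(5, 0), radiusMm = 4, amplitude = 3, course = course)),
    patchHalfWidthMm = 10, gridSpacingMm = 2, noiseSd = 1)
  expect_error(simulateVertexMap(over, nT, seed = 1, recoveryTest = TRUE),
               "overlap")
  # without the recovery flag the same layout simulates fine
  expect_s4_class(simulateVertexMap(over, nT, seed = 1),
                  "VertexActivationMap")
})

test_that("a pure-noise map has spatially unclustered extremes", {
  nT <- 40
  lay <- roiLayout(list(), patchHalfWidthMm = 15, gridSpacingMm = 2,
                   jitterSdMm = 0, noiseSd = 1)
  map <- simulateVertexMap(lay, nT, seed = 3)
  strength <- rowMeans(seriesValues(map))
  top <- order(-strength)[1:20]
  xy <- vertexCoords(map)[top, 1:2]
  # mean pairwise distance of the top vertices is comparable to that of
  # random vertices (no spatial concentration)
  dTop <- mean(dist(xy))
  set.seed(4)
  dRand <- replicate(50, mean(dist(vertexCoords(map)[
    sample(length(vertexIds(map)), 20), 1:2])))
  expect_gt(dTop, mean(dRand) - 3 * sd(dRand))
})

test_that("behavioral simulation honors the factorial design", {
  tt <- simulateBehavior(behaviorDesign(nSubjects = 2), seed = 1)
  expect_equal(nrow(tt), 2 * 270)
  one <- tt[tt$subject_id == "s01", ]
  expect_equal(nrow(one), 270)
  cellCounts <- table(one$context, one$step)
  expect_true(all(cellCounts == 27))
  # groups alternate and condition follows the group-context mapping
  expect_equal(unique(tt$group[tt$subject_id == "s01"]),
               "sr-familiarization")
  expect_equal(unique(tt$group[tt$subject_id == "s02"]),
               "shl-familiarization")
  expect_identical(tt$condition, assignCondition(tt$group, tt$context))
  expect_identical(tt$unrepaired, codeUnrepaired(tt$context, tt$response))
})

test_that("behavioral rates converge to the generating psychometric curve", {
  des <- behaviorDesign(nSubjects = 1, trialsPerCell = 10000,
                        learningShift = 1)
  tt <- simulateBehavior(des, seed = 2)
  rates <- repairRates(tt)
  for (i in seq_len(nrow(rates))) {
    pTrue <- psychometricProb(des, rates$context[i], rates$step[i],
                              rates$condition[i])
    expect_lt(abs(rates$rate[i] - pTrue),
              2 * sqrt(pTrue * (1 - pTrue) / rates$n_trials[i]) + 1e-12)
  }
})

test_that("a zero learning shift leaves conditions exchangeable", {
  des <- behaviorDesign(nSubjects = 12, learningShift = 0)
  tt <- filterAnalysisTrials(simulateBehavior(des, seed = 3))
  byCond <- tapply(tt$unrepaired, tt$condition, mean)
  n <- tapply(tt$unrepaired, tt$condition, length)
  se <- sqrt(sum(byCond * (1 - byCond) / n))
  expect_lt(abs(byCond["Trained"] - byCond["Naive"]), 3 * se)
})
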