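test_that("trial table reading recomputes and validates derived columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,context,step,response",
               "s01,sr-familiarization,_r,2,S"), f)
  tt <- readTrialTable(f)
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$condition, "Trained")
  expect_true(tt$unrepaired)

  # header-only file gives an empty, well-formed table
  writeLines("subject_id,group,context,step,response", f)
  tt0 <- readTrialTable(f)
  expect_equal(nrow(tt0), 0L)
  expect_true(all(c("condition", "unrepaired") %in% names(tt0)))

  # domain violations are named with their row
  writeLines(c("subject_id,group,context,step,response",
               "s01,sr-familiarization,_r,6,S"), f)
  expect_error(readTrialTable(f), "step.*row 1")
  writeLines(c("subject_id,group,context,step,response",
               "s01,sr-familiarization,_x,2,S"), f)
  expect_error(readTrialTable(f), "context")
  writeLines(c("subject_id,group,step,response",
               "s01,sr-familiarization,2,S"), f)
  expect_error(readTrialTable(f), "missing column.*context")

  # stored derived columns that disagree are rejected
  writeLines(c("subject_id,group,context,step,response,condition",
               "s01,sr-familiarization,_r,2,S,Naive"), f)
  expect_error(readTrialTable(f), "condition column disagrees")
})

test_that("time-series container round-trips bit-exactly", {
  ts <- multiTimeSeries(matrix(rnorm(300), nrow = 3),
                        labels = c("a", "b", "c"),
                        samplingRate = 1000, t0Ms = -100)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTimeSeries(ts, f)
  back <- readTimeSeries(f)
  expect_identical(seriesValues(back), seriesValues(ts))
  expect_identical(channelLabels(back), channelLabels(ts))
  expect_identical(samplingRate(back), samplingRate(ts))
  expect_identical(timeOrigin(back), timeOrigin(ts))

  # write -> read -> write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeTimeSeries(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # minimal 1x1 series round-trips
  one <- multiTimeSeries(matrix(pi, 1, 1))
  writeTimeSeries(one, f)
  expect_identical(seriesValues(readTimeSeries(f)), seriesValues(one))

  # missing metadata is a format error
  lines <- readLines(f)
  writeLines(lines[!grepl("^#sampling_rate", lines)], f)
  expect_error(readTimeSeries(f), "sampling_rate")
  writeLines("plain text", f)
  expect_error(readTimeSeries(f), "not a phonoflux")
})

test_that("vertex-map container round-trips coordinates and courses", {
  lay <- roiLayout(list(list(center = c(0, 0), radiusMm = 3,
                             amplitude = 4,
                             course = latentCourse(20))),
                   patchHalfWidthMm = 6, gridSpacingMm = 2, noiseSd = 0.5)
  map <- simulateVertexMap(lay, 20, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeVertexMap(map, f)
  back <- readVertexMap(f)
  expect_identical(vertexCoords(back), vertexCoords(map))
  expect_identical(seriesValues(back), seriesValues(map))
  expect_identical(vertexIds(back), vertexIds(map))
})

test_that("configuration defaults match the study constants", {
  cfg <- analysisConfig()
  expect_identical(cfg@modelOrder, 5L)
  expect_identical(cfg@nBootstrap, 2000L)
  expect_identical(cfg@alpha, 0.05)
  expect_identical(cfg@windowMs, c(100, 500))
  expect_identical(cfg@centroidPercentile, 95)
  expect_identical(cfg@exclusionRadiusMm, 5)
  expect_identical(cfg@growthSdFactor, 0.5)
  expect_identical(cfg@redundancySdFactor, 0.9)
  expect_identical(cfg@stepsIncluded, 2:5)
})

test_that("YAML config loading applies defaults, overrides and checks", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  expect_identical(loadConfig(f)@nBootstrap, 2000L)

  writeLines("n_bootstrap: 200", f)
  cfg <- loadConfig(f)
  expect_identical(cfg@nBootstrap, 200L)
  expect_identical(cfg@modelOrder, 5L)

  writeLines("alpha: 1.5", f)
  expect_error(loadConfig(f), "alpha")

  writeLines(c("n_bootstrap: 100", "mystery_knob: 3"), f)
  expect_warning(cfg <- loadConfig(f), "mystery_knob")
  expect_identical(cfg@nBootstrap, 100L)
})

test_that("millisecond windows map to samples rounding toward the interior", {
  ts <- multiTimeSeries(matrix(0, 1, 501), samplingRate = 1000, t0Ms = 0)
  idx <- windowIndices(ts, c(100, 500))
  expect_length(idx, 401L)
  expect_equal(idx[1], 101L)
  # half-sample offsets shrink, never widen, the window
  ts2 <- multiTimeSeries(matrix(0, 1, 250), samplingRate = 500, t0Ms = 1)
  idx2 <- windowIndices(ts2, c(100, 500))
  tms <- timesMs(ts2)[idx2]
  expect_true(all(tms >= 100 & tms <= 500))
  expect_error(windowIndices(ts, c(900, 1000)), "outside the data span")
})

test_that("container objects validate their invariants", {
  expect_error(multiTimeSeries(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(multiTimeSeries(matrix(1, 2, 2), labels = c("a", "a")),
               "unique")
  expect_error(multiTimeSeries(matrix(1, 1, 1), samplingRate = 0),
               "samplingRate")
  expect_error(vertexActivationMap(matrix(0, 2, 3), matrix(1, 3, 5)),
               "row per vertex")
  expect_error(analysisConfig(alpha = 0), "alpha")
  expect_error(analysisConfig(stepsIncluded = 6L), "steps")
  expect_error(kalmanSettings(errorSmoothing = 0), "errorSmoothing")
})
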