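test_that("centroid selection keeps strong peaks and excludes near maxima", {
  cfg <- analysisConfig(windowMs = c(0, 9), exclusionRadiusMm = 5)
  # 100 vertices on a line, one clear peak
  nV <- 100
  coords <- cbind(seq_len(nV) * 2, 0, 0)
  act <- matrix(0, nV, 10)
  act[40, ] <- 10
  map <- vertexActivationMap(coords, act, samplingRate = 1000, t0Ms = 0)
  expect_identical(selectCentroids(map, cfg), vertexIds(map)[40])

  # two peaks 3 mm apart: only the stronger survives; 20 mm apart: both
  twoPeak <- function(sep) {
    coords <- rbind(c(0, 0, 0), c(sep, 0, 0),
                    cbind(100 + seq_len(60), 50, 0))
    act <- rbind(matrix(10, 1, 10), matrix(8, 1, 10),
                 matrix(0, 60, 10))
    vertexActivationMap(coords, act)
  }
  near <- twoPeak(3)
  expect_identical(selectCentroids(near, cfg), vertexIds(near)[1])
  far <- twoPeak(20)
  expect_identical(selectCentroids(far, cfg), vertexIds(far)[1:2])

  # all-equal activation: empty result with a warning, not an error
  flat <- vertexActivationMap(coords[1:10, ], matrix(1, 10, 10))
  expect_warning(out <- selectCentroids(flat, cfg), "percentile")
  expect_length(out, 0)
})

test_that("ROI growth collects contiguous vertices with similar courses", {
  map <- tinyTwoBlobMap()
  cfg <- analysisConfig(windowMs = c(0, 59), contiguityRadiusMm = 2.5)
  cen <- selectCentroids(map, cfg)
  expect_gte(length(cen), 2)
  roi <- growRoi(cen[1], map, cfg)
  truth <- plantedMembership(
    roiLayout(list(
      list(center = c(-10, 0), radiusMm = 3, amplitude = 5,
           course = latentCourse(60, peakFrac = 0.3)),
      list(center = c(10, 0), radiusMm = 3, amplitude = 5,
           course = latentCourse(60, peakFrac = 0.7))),
      patchHalfWidthMm = 15, gridSpacingMm = 2, jitterSdMm = 0,
      noiseSd = 0.2), map)
  # the grown ROI matches one planted blob and excludes the other
  overlaps <- vapply(truth, function(tv)
    length(intersect(roiMembers(roi), tv)) / length(union(roiMembers(roi), tv)),
    numeric(1))
  expect_gt(max(overlaps), 0.8)
  expect_equal(min(overlaps), 0)
  expect_true(roi@centroidVertex %in% roiMembers(roi))
  expect_error(growRoi("nope", map, cfg), "not a map vertex")
})

test_that("an isolated centroid grows a singleton ROI", {
  # centroid far from every candidate neighbour
  coords <- rbind(c(0, 0, 0), cbind(40 + 2 * seq_len(30), 40, 0))
  set.seed(1)
  act <- rbind(matrix(sin(1:20) * 5, 1, 20),
               matrix(rnorm(30 * 20), 30, 20))
  act[1, ] <- act[1, ] + 10
  map <- vertexActivationMap(coords, act)
  cfg <- analysisConfig(windowMs = c(0, 19), contiguityRadiusMm = 2)
  roi <- growRoi(vertexIds(map)[1], map, cfg)
  expect_identical(roiMembers(roi), vertexIds(map)[1])
})

test_that("redundancy pruning removes duplicate courses, keeps distinct ones", {
  cfg <- analysisConfig()
  mkRoi <- function(id, course, strength) {
    new("Roi", roiId = id, centroidVertex = paste0(id, "_c"),
        members = paste0(id, "_c"), meanCourse = course,
        strength = strength)
  }
  t <- seq(0, 2 * pi, length.out = 50)
  # one ROI: identity
  one <- new("RoiSet", rois = list(mkRoi("a", sin(t), 10)), config = cfg)
  expect_equal(roiIds(pruneRedundant(one, cfg)), "a")

  # identical courses, strengths 10 and 5: the weaker is eliminated;
  # an orthogonal third course survives
  set <- new("RoiSet", rois = list(mkRoi("a", sin(t), 10),
                                   mkRoi("b", sin(t) * 3, 5),
                                   mkRoi("c", cos(t), 2)), config = cfg)
  pruned <- pruneRedundant(set, cfg)
  expect_setequal(roiIds(pruned), c("a", "c"))

  # two orthogonal courses: both retained (distance exceeds threshold)
  two <- new("RoiSet", rois = list(mkRoi("a", sin(t), 10),
                                   mkRoi("b", cos(t), 5)), config = cfg)
  expect_equal(length(pruneRedundant(two, cfg)), 2L)
})

test_that("full ROI identification recovers planted clusters deterministically", {
  nT <- 200
  lay <- plantedClusterLayout(4, nT, separationMm = 22, snr = 10,
                              patchHalfWidthMm = 22)
  cfg <- analysisConfig(windowMs = c(0, 199))
  map <- simulateVertexMap(lay, nT, seed = 10, recoveryTest = TRUE)
  rois <- identifyRois(map, cfg)
  expect_equal(length(rois), 4L)
  match <- matchRoisToClusters(rois, plantedMembership(lay, map))
  expect_true(all(match$jaccard >= 0.8))
  # determinism: identical map in, identical RoiSet out
  rois2 <- identifyRois(map, cfg)
  expect_identical(roiMembers(rois2), roiMembers(rois))
  # member sets disjoint, ids unique (validity), courses distinct
  expect_s4_class(rois, "RoiSet")
})

test_that("raising the centroid percentile never adds centroids", {
  map <- tinyTwoBlobMap()
  base <- analysisConfig(windowMs = c(0, 59))
  counts <- vapply(c(80, 90, 95, 99), function(p)
    length(selectCentroids(map, analysisConfig(windowMs = c(0, 59),
                                               centroidPercentile = p))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pruning never increases ROI count and separates survivors", {
  nT <- 120
  lay <- plantedClusterLayout(3, nT, separationMm = 20, snr = 8,
                              patchHalfWidthMm = 20)
  cfg <- analysisConfig(windowMs = c(0, nT - 1))
  map <- simulateVertexMap(lay, nT, seed = 21)
  cen <- selectCentroids(map, cfg)
  grown <- lapply(seq_along(cen), function(i) {
    r <- growRoi(cen[i], map, cfg)
    r@roiId <- sprintf("g%02d", i)
    r
  })
  # overlapping grown ROIs are possible pre-resolution; prune on the
  # distinct ones only
  keep <- !duplicated(vapply(grown, function(r) r@centroidVertex,
                             character(1)))
  grown <- grown[keep]
  dis <- grown[!duplicated(unlist(lapply(grown, roiMembers)))]
  set <- tryCatch(new("RoiSet", rois = grown, config = cfg),
                  error = function(e) NULL)
  if (!is.null(set))
    expect_lte(length(pruneRedundant(set, cfg)), length(set))
  rois <- identifyRois(map, cfg)
  expect_lte(length(rois), length(cen))
})

test_that("representative vertices track the group course per subject", {
  nT <- 80
  lay <- plantedClusterLayout(3, nT, separationMm = 20, snr = 10,
                              patchHalfWidthMm = 20)
  cfg <- analysisConfig(windowMs = c(0, nT - 1))
  group <- simulateVertexMap(lay, nT, seed = 30)
  rois <- identifyRois(group, cfg)
  expect_gte(length(rois), 2)

  # subject identical to the group map: representative equals the member
  # vertex best correlated with the ROI mean (includes centroid case)
  out <- extractRoiTimeseries(list(s1 = group), rois, cfg)
  expect_named(out, "s1")
  expect_identical(channelLabels(out$s1), roiIds(rois))
  expect_equal(nrow(seriesValues(out$s1)), length(rois))

  # noisy subject: representative beats every non-member vertex by
  # brute-force correlation comparison
  subj <- vertexActivationMap(vertexCoords(group),
                              seriesValues(group) +
                                matrix(rnorm(length(seriesValues(group)),
                                             sd = 0.5),
                                       nrow = nrow(seriesValues(group))),
                              vertexIds = vertexIds(group))
  rep2 <- extractRoiTimeseries(list(s2 = subj), rois, cfg)$s2
  idx <- windowIndices(subj, cfg@windowMs)
  for (k in seq_len(length(rois))) {
    roi <- rois[[k]]
    repCourse <- seriesValues(rep2)[k, idx]
    repCor <- cor(repCourse, roi@meanCourse)
    nonMembers <- setdiff(vertexIds(subj), roiMembers(roi))
    others <- seriesValues(subj)[match(nonMembers, vertexIds(subj)), idx]
    bestOther <- max(apply(others, 1, cor, y = roi@meanCourse))
    expect_gt(repCor, bestOther)
  }

  # a subject lacking member vertices is an informative error
  shrunk <- vertexActivationMap(vertexCoords(group)[1:5, ],
                                seriesValues(group)[1:5, ],
                                vertexIds = vertexIds(group)[1:5])
  expect_error(extractRoiTimeseries(list(bad = shrunk), rois, cfg),
               "bad.*ROI|lacks member")
})
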