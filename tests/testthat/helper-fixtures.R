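# Small generators shared across test files.

# static 2-channel network: self terms + one directed edge 1 -> 2
twoChannelNet <- function(coupling = 0.5, self = 0.4, sd = 1) {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- self
  A[2, 2, 1] <- self
  A[2, 1, 1] <- coupling
  groundTruthNetwork(A, innovationSd = sd)
}

# 6-channel static network with 3 planted edges (>= 0.4), as used by the
# edge-recovery checks
sixChannelNet <- function() {
  A <- array(0, c(6, 6, 1))
  diag(A[, , 1]) <- 0.3
  A[2, 1, 1] <- 0.5
  A[4, 3, 1] <- 0.45
  A[6, 5, 1] <- 0.4
  groundTruthNetwork(A)
}

plantedSixEdges <- function()
  data.frame(source = c("ch1", "ch3", "ch5"),
             target = c("ch2", "ch4", "ch6"))

# deterministic tiny map: two spatial blobs with distinct courses, no noise
tinyTwoBlobMap <- function(nT = 60) {
  lay <- roiLayout(list(
    list(center = c(-10, 0), radiusMm = 3, amplitude = 5,
         course = latentCourse(nT, peakFrac = 0.3)),
    list(center = c(10, 0), radiusMm = 3, amplitude = 5,
         course = latentCourse(nT, peakFrac = 0.7))),
    patchHalfWidthMm = 15, gridSpacingMm = 2, jitterSdMm = 0,
    noiseSd = 0.2)
  simulateVertexMap(lay, nT, seed = 99)
}

fastKs <- function(...) kalmanSettings(...)
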