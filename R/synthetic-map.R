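## Synthetic vertex activation maps with planted spatial clusters.

#' Planted-cluster layout for a synthetic activation map
#'
#' Describes a planar cortical patch populated by vertices on a jittered
#' grid. Each planted cluster has a center, a spatial radius, a peak
#' amplitude and a latent time course; member vertices receive the
#' course scaled by a Gaussian spatial falloff plus i.i.d. vertex noise,
#' background vertices receive noise only.
#'
#' @slot clusters list of cluster descriptors (center, radiusMm,
#'   amplitude, course).
#' @slot patchHalfWidthMm half-width of the square patch, mm.
#' @slot gridSpacingMm vertex grid spacing, mm.
#' @slot jitterSdMm SD of the positional jitter applied to grid points.
#' @slot noiseSd SD of the per-vertex, per-sample background noise.
#' @seealso [roiLayout()], [plantedClusterLayout()], [simulateVertexMap()]
#' @exportClass RoiLayout
setClass("RoiLayout",
  representation(clusters = "list", patchHalfWidthMm = "numeric",
                 gridSpacingMm = "numeric", jitterSdMm = "numeric",
                 noiseSd = "numeric"))

setValidity("RoiLayout", function(object) {
  for (cl in object@clusters) {
    if (!all(c("center", "radiusMm", "amplitude", "course") %in% names(cl)))
      return("each cluster needs center, radiusMm, amplitude, course")
    if (cl$radiusMm <= 0) return("cluster radii must be > 0")
    if (length(cl$center) != 2L)
      return("cluster centers are 2-D coordinates on the patch")
  }
  if (object@gridSpacingMm <= 0) return("gridSpacingMm must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Construct a RoiLayout
#'
#' @param clusters list of lists, each with `center` (xy, mm),
#'   `radiusMm`, `amplitude`, and `course` (latent time course).
#' @param patchHalfWidthMm half-width of the square patch (default 30).
#' @param gridSpacingMm vertex spacing (default 1.5 mm, comparable to a
#'   dense source space).
#' @param jitterSdMm positional jitter SD (default 0.2 mm).
#' @param noiseSd background noise SD (default 1).
#' @return a [RoiLayout-class].
#' @export
roiLayout <- function(clusters, patchHalfWidthMm = 30, gridSpacingMm = 1.5,
                      jitterSdMm = 0.2, noiseSd = 1) {
  new("RoiLayout", clusters = clusters,
      patchHalfWidthMm = as.numeric(patchHalfWidthMm),
      gridSpacingMm = as.numeric(gridSpacingMm),
      jitterSdMm = as.numeric(jitterSdMm), noiseSd = as.numeric(noiseSd))
}

#' Smooth unimodal latent course (for planted clusters)
#'
#' Gaussian bump peaking at `peakFrac` of the span, scaled to unit RMS,
#' so that cluster `amplitude / noiseSd` equals the per-sample SNR.
#'
#' @param nTimepoints course length.
#' @param peakFrac peak position as a fraction of the span.
#' @param widthFrac bump SD as a fraction of the span.
#' @return numeric vector of length `nTimepoints`.
#' @export
latentCourse <- function(nTimepoints, peakFrac = 0.5, widthFrac = 0.12) {
  t <- seq_len(nTimepoints)
  x <- exp(-((t - peakFrac * nTimepoints)^2) /
             (2 * (widthFrac * nTimepoints)^2))
  x / sqrt(mean(x^2))
}

#' Standard layout with well-separated planted clusters
#'
#' Places `nClusters` clusters on a circle so that neighboring centers
#' are at least `separationMm` apart, with distinct latent courses
#' (bumps at staggered latencies) and amplitude `snr * noiseSd`.
#'
#' @param nClusters number of planted clusters.
#' @param nTimepoints length of the latent courses.
#' @param separationMm minimum center-to-center distance.
#' @param snr per-sample amplitude-to-noise ratio at cluster centers.
#' @param radiusMm cluster radius (default 5 mm).
#' @param noiseSd background noise SD (default 1).
#' @param ... passed to [roiLayout()].
#' @return a [RoiLayout-class].
#' @examples
#' lay <- plantedClusterLayout(4, 401, separationMm = 20, snr = 10)
#' @export
plantedClusterLayout <- function(nClusters, nTimepoints, separationMm = 20,
                                 snr = 10, radiusMm = 5, noiseSd = 1, ...) {
  ## circumradius such that adjacent centers sit separationMm apart
  R <- if (nClusters > 1L)
    separationMm / (2 * sin(pi / nClusters)) else 0
  ang <- 2 * pi * (seq_len(nClusters) - 1L) / max(nClusters, 1L)
  clusters <- lapply(seq_len(nClusters), function(i) {
    ## peaks staggered over the central part of the span so every
    ## planted course lies well inside the default analysis window
    list(center = c(R * cos(ang[i]), R * sin(ang[i])),
         radiusMm = radiusMm, amplitude = snr * noiseSd,
         course = latentCourse(nTimepoints,
                               peakFrac = 0.35 + 0.5 * (i - 1) /
                                 max(nClusters - 1L, 1L),
                               widthFrac = 0.1))
  })
  args <- list(...)
  if (is.null(args$patchHalfWidthMm))
    args$patchHalfWidthMm <- max(30, R + 2 * radiusMm)
  do.call(roiLayout, c(list(clusters = clusters, noiseSd = noiseSd), args))
}

clusterCenters <- function(layout)
  do.call(rbind, lapply(layout@clusters, function(cl) cl$center))

#' Simulate a vertex activation map with planted clusters
#'
#' Vertices sit on a jittered grid over a planar patch (embedded at
#' z = 0). A vertex within a cluster's radius receives that cluster's
#' latent course scaled by `amplitude * exp(-d^2 / (2 radius^2))` plus
#' noise; all other vertices receive noise only. With zero noise, member
#' courses are exactly proportional to the latent course.
#'
#' @param layout a [RoiLayout-class].
#' @param nTimepoints number of samples (must match course lengths).
#' @param seed integer seed.
#' @param samplingRate,t0Ms time base (defaults 1000 Hz, 0 ms).
#' @param recoveryTest if TRUE, require planted clusters to be pairwise
#'   non-overlapping (centers farther apart than the sum of radii);
#'   overlap is then a configuration error.
#' @return a [VertexActivationMap-class].
#' @seealso [plantedMembership()] for the ground-truth member sets.
#' @export
simulateVertexMap <- function(layout, nTimepoints, seed,
                              samplingRate = 1000, t0Ms = 0,
                              recoveryTest = FALSE) {
  stopifnot(is(layout, "RoiLayout"))
  K <- length(layout@clusters)
  if (recoveryTest && K > 1L) {
    ctr <- clusterCenters(layout)
    for (i in seq_len(K - 1L)) for (j in seq.int(i + 1L, K)) {
      lim <- layout@clusters[[i]]$radiusMm + layout@clusters[[j]]$radiusMm
      if (sqrt(sum((ctr[i, ] - ctr[j, ])^2)) <= lim)
        stop(sprintf("clusters %d and %d overlap; recovery test requires separated clusters",
                     i, j), call. = FALSE)
    }
  }
  for (cl in layout@clusters)
    if (length(cl$course) != nTimepoints)
      stop("cluster course length must equal nTimepoints", call. = FALSE)

  set.seed(seed)
  g <- seq(-layout@patchHalfWidthMm, layout@patchHalfWidthMm,
           by = layout@gridSpacingMm)
  xy <- as.matrix(expand.grid(x = g, y = g))
  if (layout@jitterSdMm > 0)
    xy <- xy + matrix(rnorm(length(xy), sd = layout@jitterSdMm),
                      ncol = 2L)
  nV <- nrow(xy)
  act <- matrix(rnorm(nV * nTimepoints, sd = layout@noiseSd),
                nrow = nV)
  for (cl in layout@clusters) {
    d2 <- (xy[, 1] - cl$center[1])^2 + (xy[, 2] - cl$center[2])^2
    memb <- which(d2 <= cl$radiusMm^2)
    if (!length(memb)) next
    fall <- cl$amplitude * exp(-d2[memb] / (2 * cl$radiusMm^2))
    act[memb, ] <- act[memb, ] + outer(fall, cl$course)
  }
  vertexActivationMap(xy, act, samplingRate = samplingRate, t0Ms = t0Ms)
}

#' Ground-truth cluster membership for a simulated map
#'
#' Vertices within a cluster's radius belong to it; a vertex inside
#' several radii is assigned to the nearest center. Used as the oracle
#' when scoring ROI recovery.
#'
#' @param layout the [RoiLayout-class] used for simulation.
#' @param map the [VertexActivationMap-class] it produced.
#' @return named list (`cluster1`, ...) of vertex-id vectors.
#' @export
plantedMembership <- function(layout, map) {
  xy <- vertexCoords(map)[, 1:2, drop = FALSE]
  K <- length(layout@clusters)
  d2 <- vapply(layout@clusters, function(cl)
    (xy[, 1] - cl$center[1])^2 + (xy[, 2] - cl$center[2])^2,
    numeric(nrow(xy)))
  inR <- vapply(seq_len(K), function(k)
    d2[, k] <= layout@clusters[[k]]$radiusMm^2, logical(nrow(xy)))
  nearest <- apply(d2, 1L, which.min)
  out <- lapply(seq_len(K), function(k)
    vertexIds(map)[inR[, k] & nearest == k])
  names(out) <- paste0("cluster", seq_len(K))
  out
}
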