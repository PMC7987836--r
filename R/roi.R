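## Data-driven ROI identification: centroid selection by activation
## strength, similarity-based contiguous growth, redundancy pruning, and
## per-subject representative-vertex extraction.

## z-score each row over its span; zero-variance rows become all-zero
zscoreRows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

windowCourses <- function(map, cfg) {
  idx <- windowIndices(map, cfg@windowMs)
  seriesValues(map)[, idx, drop = FALSE]
}

#' Select candidate ROI centroids
#'
#' Candidates are vertices whose mean activation over the analysis
#' window exceeds the `centroidPercentile` percentile
#' (linear-interpolation definition) of all vertices' means. Scanning
#' candidates in descending strength (ties broken by vertex id), any
#' candidate within `exclusionRadiusMm` (Euclidean) of an
#' already-accepted stronger candidate is dropped, so each local
#' activation maximum contributes one centroid.
#'
#' @param map a [VertexActivationMap-class].
#' @param cfg an [AnalysisConfig-class].
#' @return character vector of accepted centroid vertex ids in
#'   descending strength; empty (with a warning) when no vertex clears
#'   the percentile, e.g. under all-equal activation.
#' @export
selectCentroids <- function(map, cfg = analysisConfig()) {
  if (length(vertexIds(map)) < 2L)
    stop("centroid selection needs at least 2 vertices", call. = FALSE)
  strength <- rowMeans(windowCourses(map, cfg))
  thr <- quantile(strength, cfg@centroidPercentile / 100, type = 7,
                  names = FALSE)
  cand <- which(strength > thr)
  if (!length(cand)) {
    warning("no vertex exceeds the centroid percentile", call. = FALSE)
    return(character(0))
  }
  ids <- vertexIds(map)
  cand <- cand[order(-strength[cand], ids[cand])]
  xyz <- vertexCoords(map)
  accepted <- integer(0)
  for (v in cand) {
    if (length(accepted)) {
      d2 <- colSums((t(xyz[accepted, , drop = FALSE]) - xyz[v, ])^2)
      if (any(d2 < cfg@exclusionRadiusMm^2)) next
    }
    accepted <- c(accepted, v)
  }
  ids[accepted]
}

## distances between each vertex's normalized window course and the
## centroid's; Z may be precomputed
centroidDistances <- function(Z, centroidRow)
  sqrt(rowSums((Z - rep(Z[centroidRow, ], each = nrow(Z)))^2))

#' Grow one ROI from a centroid
#'
#' Each vertex's activation course over the analysis window is
#' normalized (z-scored), and its similarity to the centroid is the
#' Euclidean distance between normalized courses. The reference scale is
#' the SD of these distances over the supra-threshold candidate set; a
#' vertex joins the ROI when its distance is below
#' `growthSdFactor * SD` **and** it is reachable from the centroid
#' through the spatial adjacency graph (vertices within
#' `contiguityRadiusMm` are adjacent), so ROIs are contiguous patches of
#' similar time course. The centroid is always a member.
#'
#' @param centroid centroid vertex id.
#' @param map a [VertexActivationMap-class].
#' @param cfg an [AnalysisConfig-class].
#' @param candidates supra-threshold vertex ids defining the reference
#'   SD; recomputed from `cfg@centroidPercentile` when NULL.
#' @return a [Roi-class] (id left empty; assigned by [identifyRois()]).
#' @export
growRoi <- function(centroid, map, cfg = analysisConfig(),
                    candidates = NULL) {
  ids <- vertexIds(map)
  ci <- match(centroid, ids)
  if (is.na(ci)) stop("centroid is not a map vertex", call. = FALSE)
  W <- windowCourses(map, cfg)
  Z <- zscoreRows(W)
  if (is.null(candidates)) {
    strength <- rowMeans(W)
    thr <- quantile(strength, cfg@centroidPercentile / 100, type = 7,
                    names = FALSE)
    candidates <- ids[strength > thr]
  }
  d <- centroidDistances(Z, ci)
  refSd <- sd(d[match(candidates, ids)])
  if (is.na(refSd) || refSd == 0) {
    warning("degenerate similarity distribution; ROI = vertices at distance 0",
            call. = FALSE)
    members <- union(centroid, ids[d == 0])
  } else {
    eligible <- d < cfg@growthSdFactor * refSd
    eligible[ci] <- TRUE
    members <- ids[bfsReachable(vertexCoords(map), ci, eligible,
                                cfg@contiguityRadiusMm)]
  }
  makeRoi("", centroid, members, map, cfg)
}

## breadth-first search over the radius adjacency graph restricted to
## eligible vertices
bfsReachable <- function(xyz, start, eligible, radiusMm) {
  elig <- which(eligible)
  sub <- xyz[elig, , drop = FALSE]
  s <- match(start, elig)
  visited <- logical(length(elig))
  visited[s] <- TRUE
  frontier <- s
  r2 <- radiusMm^2
  while (length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      d2 <- colSums((t(sub) - sub[f, ])^2)
      new <- which(!visited & d2 <= r2)
      visited[new] <- TRUE
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  elig[visited]
}

makeRoi <- function(roiId, centroid, members, map, cfg) {
  W <- windowCourses(map, cfg)
  rows <- match(members, vertexIds(map))
  sub <- W[rows, , drop = FALSE]
  new("Roi", roiId = as.character(roiId), centroidVertex = centroid,
      members = as.character(members), meanCourse = colMeans(sub),
      strength = mean(sub))
}

#' Prune redundant ROIs
#'
#' Granger analysis assumes every signal carries unique predictive
#' information, so ROIs whose normalized mean courses nearly duplicate a
#' stronger ROI's are removed. ROIs are scanned in descending strength; a
#' ROI is dropped when the Euclidean distance between its normalized
#' (z-scored) mean course and that of any retained stronger ROI falls
#' below `redundancySdFactor * SD` of the pairwise distance distribution
#' over all ROI mean courses.
#'
#' @param rois a [RoiSet-class].
#' @param cfg an [AnalysisConfig-class].
#' @return the pruned [RoiSet-class]; a single-ROI set is returned
#'   unchanged.
#' @export
pruneRedundant <- function(rois, cfg = analysisConfig()) {
  K <- length(rois)
  if (K < 2L) return(rois)
  courses <- do.call(rbind, lapply(rois@rois, function(r) r@meanCourse))
  Z <- zscoreRows(courses)
  D <- as.matrix(dist(Z))
  refSd <- sd(D[upper.tri(D)])
  ## with a single pairwise distance no distributional scale exists;
  ## fall back to pruning exact duplicates only
  thr <- if (is.na(refSd) || refSd == 0) 1e-8
         else cfg@redundancySdFactor * refSd
  strength <- vapply(rois@rois, function(r) r@strength, numeric(1))
  ord <- order(-strength)
  retained <- integer(0)
  for (i in ord) {
    if (length(retained) && any(D[i, retained] < thr)) next
    retained <- c(retained, i)
  }
  new("RoiSet", rois = rois@rois[sort(retained)], config = cfg)
}

#' Identify ROIs from an activation map
#'
#' The three-step algorithm: (1) candidate centroids = supra-percentile
#' vertices with local-maximum exclusion ([selectCentroids()]); (2) one
#' ROI grown from each centroid by contiguous time-course similarity
#' ([growRoi()]); (3) redundancy pruning ([pruneRedundant()]). Vertices
#' claimed by several surviving ROIs are assigned to the strongest, and
#' ROI statistics are recomputed on the final membership. ROIs are
#' labeled `ROI_01, ROI_02, ...` in descending strength. Deterministic
#' for a given map and configuration.
#'
#' @param map a [VertexActivationMap-class].
#' @param cfg an [AnalysisConfig-class].
#' @return a [RoiSet-class] (possibly empty).
#' @examples
#' lay <- plantedClusterLayout(2, 101, separationMm = 25, snr = 10)
#' map <- simulateVertexMap(lay, 101, seed = 1)
#' identifyRois(map, analysisConfig(windowMs = c(0, 100)))
#' @export
identifyRois <- function(map, cfg = analysisConfig()) {
  centroids <- selectCentroids(map, cfg)
  if (!length(centroids))
    return(new("RoiSet", rois = list(), config = cfg))
  W <- windowCourses(map, cfg)
  strength <- rowMeans(W)
  ids <- vertexIds(map)
  thr <- quantile(strength, cfg@centroidPercentile / 100, type = 7,
                  names = FALSE)
  candidates <- ids[strength > thr]

  grown <- lapply(centroids, growRoi, map = map, cfg = cfg,
                  candidates = candidates)
  ## a centroid swallowed by an earlier, stronger ROI does not found its
  ## own region
  seen <- character(0)
  keep <- logical(length(grown))
  for (i in seq_along(grown)) {
    keep[i] <- !(grown[[i]]@centroidVertex %in% seen)
    if (keep[i]) seen <- union(seen, grown[[i]]@members)
  }
  grown <- grown[keep]

  ## overlaps resolved in favor of the stronger ROI before validity
  ## (disjointness) applies
  strengthOf <- vapply(grown, function(r) r@strength, numeric(1))
  ord <- order(-strengthOf)
  taken <- character(0)
  resolved <- list()
  for (i in ord) {
    members <- setdiff(grown[[i]]@members, taken)
    if (!length(members) || !(grown[[i]]@centroidVertex %in% members)) next
    taken <- c(taken, members)
    resolved[[length(resolved) + 1L]] <-
      makeRoi(sprintf("tmp%03d", length(resolved) + 1L),
              grown[[i]]@centroidVertex, members, map, cfg)
  }
  if (!length(resolved))
    return(new("RoiSet", rois = list(), config = cfg))
  pruned <- pruneRedundant(new("RoiSet", rois = resolved, config = cfg),
                           cfg)
  final <- pruned@rois[order(-vapply(pruned@rois, function(r) r@strength,
                                     numeric(1)))]
  for (i in seq_along(final)) final[[i]]@roiId <- sprintf("ROI_%02d", i)
  new("RoiSet", rois = final, config = cfg)
}

#' Extract per-subject representative ROI time series
#'
#' For each ROI and subject, the representative course is the full time
#' series of the member vertex whose windowed course correlates best
#' with the group-level ROI mean course, compensating for residual
#' source-localization differences between subjects. Channels follow the
#' RoiSet order.
#'
#' @param maps named list of per-subject [VertexActivationMap-class]
#'   objects registered to the common vertex space.
#' @param rois a [RoiSet-class] from the group-level map.
#' @param cfg an [AnalysisConfig-class].
#' @return named list of [MultiTimeSeries-class], one per subject, with
#'   one channel per ROI.
#' @export
extractRoiTimeseries <- function(maps, rois, cfg = analysisConfig()) {
  stopifnot(is(rois, "RoiSet"), length(rois) > 0L)
  if (is(maps, "VertexActivationMap")) maps <- list(subject1 = maps)
  if (is.null(names(maps)))
    names(maps) <- paste0("subject", seq_along(maps))
  lapply(stats::setNames(names(maps), names(maps)), function(sn) {
    map <- maps[[sn]]
    idx <- windowIndices(map, cfg@windowMs)
    ids <- vertexIds(map)
    act <- seriesValues(map)
    picks <- vapply(rois@rois, function(r) {
      rows <- match(r@members, ids)
      if (anyNA(rows))
        stop(sprintf("subject %s lacks member vertices of %s", sn, r@roiId),
             call. = FALSE)
      cors <- apply(act[rows, idx, drop = FALSE], 1L, cor, y = r@meanCourse)
      cors[is.na(cors)] <- -Inf
      rows[which.max(cors)]
    }, integer(1))
    multiTimeSeries(act[picks, , drop = FALSE], labels = roiIds(rois),
                    samplingRate = samplingRate(map),
                    t0Ms = timeOrigin(map))
  })
}
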