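## S4 classes for the containers shared across pipeline stages.

#' Multichannel neural time series
#'
#' Holds an `n_channels x n_timepoints` real matrix of sampled signals
#' (e.g., trial-averaged source waveforms, one channel per ROI) together
#' with channel labels, the sampling rate in Hz, and the time of the
#' first sample relative to stimulus onset in milliseconds.
#'
#' @slot labels character vector of unique channel identifiers.
#' @slot values numeric matrix, channels in rows, timepoints in columns.
#' @slot samplingRate samples per second (> 0).
#' @slot t0Ms time of the first sample relative to stimulus onset, ms.
#' @seealso [multiTimeSeries()], [simulateMvar()], [fitFullModel()]
#' @exportClass MultiTimeSeries
setClass("MultiTimeSeries",
  representation(labels = "character", values = "matrix",
                 samplingRate = "numeric", t0Ms = "numeric"))

setValidity("MultiTimeSeries", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L) return("values must be non-empty")
  if (!all(is.finite(v))) return("values must all be finite")
  if (length(object@labels) != nrow(v))
    return("length(labels) must equal nrow(values)")
  if (anyDuplicated(object@labels)) return("channel labels must be unique")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  if (length(object@t0Ms) != 1L || !is.finite(object@t0Ms))
    return("t0Ms must be a single finite number")
  TRUE
})

#' Construct a MultiTimeSeries
#'
#' @param values numeric matrix, channels in rows, timepoints in columns.
#' @param labels channel identifiers; defaults to `ch1, ch2, ...`.
#' @param samplingRate samples per second; default 1000 Hz.
#' @param t0Ms time of the first sample relative to stimulus onset (ms).
#' @return A [MultiTimeSeries-class] object.
#' @examples
#' ts <- multiTimeSeries(matrix(rnorm(300), nrow = 3))
#' nTimepoints(ts)
#' @export
multiTimeSeries <- function(values, labels = NULL, samplingRate = 1000,
                            t0Ms = 0) {
  values <- as.matrix(values)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(values))) rownames(values)
              else paste0("ch", seq_len(nrow(values)))
  }
  rownames(values) <- labels
  new("MultiTimeSeries", labels = as.character(labels), values = values,
      samplingRate = as.numeric(samplingRate), t0Ms = as.numeric(t0Ms))
}

#' Vertex-level cortical activation map
#'
#' Source-space activation estimates: one row per vertex, with 3-D vertex
#' coordinates in millimetres and a per-vertex activation time series in
#' arbitrary source-amplitude units. Input to the ROI identification
#' stage.
#'
#' @slot vertexIds character vector of unique vertex identifiers.
#' @slot coordsMm numeric matrix `n_vertices x 3`, millimetres.
#' @slot activation numeric matrix `n_vertices x n_timepoints`.
#' @slot samplingRate samples per second.
#' @slot t0Ms time of first sample relative to stimulus onset, ms.
#' @seealso [vertexActivationMap()], [simulateVertexMap()], [identifyRois()]
#' @exportClass VertexActivationMap
setClass("VertexActivationMap",
  representation(vertexIds = "character", coordsMm = "matrix",
                 activation = "matrix", samplingRate = "numeric",
                 t0Ms = "numeric"))

setValidity("VertexActivationMap", function(object) {
  if (anyDuplicated(object@vertexIds)) return("vertex ids must be unique")
  if (nrow(object@coordsMm) != length(object@vertexIds))
    return("coordsMm must have one row per vertex id")
  if (ncol(object@coordsMm) != 3L) return("coordsMm must have 3 columns")
  if (nrow(object@activation) != length(object@vertexIds))
    return("activation must have one row per vertex id")
  if (!all(is.finite(object@coordsMm))) return("coordinates must be finite")
  if (!all(is.finite(object@activation))) return("activation must be finite")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  TRUE
})

#' Construct a VertexActivationMap
#'
#' @param coordsMm numeric matrix `n x 3` of vertex coordinates (mm); a
#'   2-column matrix is accepted and embedded at z = 0.
#' @param activation numeric matrix `n x n_timepoints`.
#' @param vertexIds vertex identifiers; default `v0001, ...`.
#' @param samplingRate samples per second; default 1000.
#' @param t0Ms time of first sample (ms); default 0.
#' @return A [VertexActivationMap-class] object.
#' @export
vertexActivationMap <- function(coordsMm, activation, vertexIds = NULL,
                                samplingRate = 1000, t0Ms = 0) {
  coordsMm <- as.matrix(coordsMm)
  if (ncol(coordsMm) == 2L) coordsMm <- cbind(coordsMm, 0)
  activation <- as.matrix(activation)
  if (is.null(vertexIds))
    vertexIds <- sprintf("v%04d", seq_len(nrow(coordsMm)))
  dimnames(coordsMm) <- list(NULL, c("x", "y", "z"))
  if (length(vertexIds) == nrow(coordsMm))
    rownames(coordsMm) <- vertexIds
  if (length(vertexIds) == nrow(activation))
    rownames(activation) <- vertexIds
  new("VertexActivationMap", vertexIds = as.character(vertexIds),
      coordsMm = coordsMm, activation = activation,
      samplingRate = as.numeric(samplingRate), t0Ms = as.numeric(t0Ms))
}

#' Analysis configuration
#'
#' Bundles the constants of the analysis: MVAR model order, bootstrap
#' replicate count, significance level, the analysis window in
#' milliseconds, and the thresholds of the ROI identification algorithm.
#' Defaults follow the study design: model order 5, 2000 bootstrap
#' replicates, alpha 0.05, 100-500 ms window, 95th-percentile centroid
#' selection with a 5 mm exclusion radius, ROI growth at 0.5 SD and
#' redundancy pruning at 0.9 SD, and continuum steps 2-5.
#'
#' @slot modelOrder MVAR model order (lags), default 5.
#' @slot nBootstrap bootstrap replicates for the GCi null, default 2000.
#' @slot alpha significance level in (0,1), default 0.05.
#' @slot windowMs closed analysis window in ms, default c(100, 500).
#' @slot centroidPercentile percentile of mean activation above which
#'   vertices are candidate ROI centroids, default 95.
#' @slot exclusionRadiusMm local maxima closer than this to a stronger
#'   accepted centroid are excluded, default 5 mm.
#' @slot growthSdFactor ROI growth threshold in SD units of the
#'   centroid-distance distribution, default 0.5.
#' @slot redundancySdFactor redundancy-pruning threshold in SD units of
#'   the pairwise ROI-course distance distribution, default 0.9.
#' @slot contiguityRadiusMm vertices within this distance are adjacent
#'   for contiguous ROI growth, default 2 mm.
#' @slot stepsIncluded continuum steps retained for analysis, default 2:5.
#' @slot randomSeed integer seed for stochastic stages.
#' @seealso [analysisConfig()], [loadConfig()]
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(modelOrder = "integer", nBootstrap = "integer",
                 alpha = "numeric", windowMs = "numeric",
                 centroidPercentile = "numeric",
                 exclusionRadiusMm = "numeric", growthSdFactor = "numeric",
                 redundancySdFactor = "numeric",
                 contiguityRadiusMm = "numeric", stepsIncluded = "integer",
                 randomSeed = "integer"))

setValidity("AnalysisConfig", function(object) {
  if (object@modelOrder < 1L) return("modelOrder must be >= 1")
  if (object@nBootstrap < 1L) return("nBootstrap must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie strictly between 0 and 1")
  if (length(object@windowMs) != 2L || diff(object@windowMs) < 0)
    return("windowMs must be c(lo, hi) with lo <= hi")
  if (object@centroidPercentile <= 0 || object@centroidPercentile >= 100)
    return("centroidPercentile must lie strictly between 0 and 100")
  for (nm in c("exclusionRadiusMm", "growthSdFactor", "redundancySdFactor",
               "contiguityRadiusMm"))
    if (slot(object, nm) <= 0) return(paste(nm, "must be > 0"))
  if (length(object@stepsIncluded) < 1L ||
      !all(object@stepsIncluded %in% 1:5))
    return("stepsIncluded must be a non-empty subset of 1..5")
  TRUE
})

#' Construct an AnalysisConfig
#'
#' All arguments default to the study constants; see
#' [AnalysisConfig-class] for their meaning.
#'
#' @param modelOrder,nBootstrap,alpha,windowMs,centroidPercentile
#'   see [AnalysisConfig-class].
#' @param exclusionRadiusMm,growthSdFactor,redundancySdFactor see
#'   [AnalysisConfig-class].
#' @param contiguityRadiusMm,stepsIncluded,randomSeed see
#'   [AnalysisConfig-class].
#' @return An [AnalysisConfig-class] object.
#' @examples
#' cfg <- analysisConfig(nBootstrap = 200)
#' cfg
#' @export
analysisConfig <- function(modelOrder = 5, nBootstrap = 2000, alpha = 0.05,
                           windowMs = c(100, 500), centroidPercentile = 95,
                           exclusionRadiusMm = 5, growthSdFactor = 0.5,
                           redundancySdFactor = 0.9, contiguityRadiusMm = 2,
                           stepsIncluded = 2:5, randomSeed = 1) {
  new("AnalysisConfig", modelOrder = as.integer(modelOrder),
      nBootstrap = as.integer(nBootstrap), alpha = as.numeric(alpha),
      windowMs = as.numeric(windowMs),
      centroidPercentile = as.numeric(centroidPercentile),
      exclusionRadiusMm = as.numeric(exclusionRadiusMm),
      growthSdFactor = as.numeric(growthSdFactor),
      redundancySdFactor = as.numeric(redundancySdFactor),
      contiguityRadiusMm = as.numeric(contiguityRadiusMm),
      stepsIncluded = as.integer(sort(unique(stepsIncluded))),
      randomSeed = as.integer(randomSeed))
}

#' Kalman filter settings
#'
#' Constants of the adaptive coefficient filter. Coefficients follow a
#' random walk with isotropic process noise; the observation noise
#' variance is fixed; the per-timepoint prediction-error scale is an
#' exponentially weighted SD of the innovations. The warm-up period is
#' excluded from all downstream statistics (the filter converges within
#' roughly the first 100 ms at 1000 Hz).
#'
#' @slot processNoiseScale random-walk variance added to each
#'   coefficient per step; 0 reduces the filter to recursive least
#'   squares. Default 1e-4.
#' @slot observationNoiseScale fixed observation noise variance, default 1.
#' @slot initialCovarianceScale diagonal of the initial state covariance
#'   (diffuse prior), default 100.
#' @slot errorSmoothing exponential-decay constant in (0,1] for the
#'   bias-corrected innovation-SD estimate, default 0.95 (an effective
#'   averaging window of about 20 ms at 1000 Hz, preserving per-timepoint
#'   resolution of the prediction-error scale).
#' @slot warmupMs initial span excluded from downstream statistics, ms.
#' @seealso [kalmanSettings()], [fitFullModel()]
#' @exportClass KalmanSettings
setClass("KalmanSettings",
  representation(processNoiseScale = "numeric",
                 observationNoiseScale = "numeric",
                 initialCovarianceScale = "numeric",
                 errorSmoothing = "numeric", warmupMs = "numeric"))

setValidity("KalmanSettings", function(object) {
  if (object@processNoiseScale < 0) return("processNoiseScale must be >= 0")
  if (object@observationNoiseScale <= 0)
    return("observationNoiseScale must be > 0")
  if (object@initialCovarianceScale <= 0)
    return("initialCovarianceScale must be > 0")
  if (object@errorSmoothing <= 0 || object@errorSmoothing > 1)
    return("errorSmoothing must lie in (0, 1]")
  if (object@warmupMs < 0) return("warmupMs must be >= 0")
  TRUE
})

#' Construct KalmanSettings
#'
#' @param processNoiseScale,observationNoiseScale,initialCovarianceScale
#'   see [KalmanSettings-class].
#' @param errorSmoothing,warmupMs see [KalmanSettings-class].
#' @return A [KalmanSettings-class] object.
#' @export
kalmanSettings <- function(processNoiseScale = 1e-4,
                           observationNoiseScale = 1,
                           initialCovarianceScale = 100,
                           errorSmoothing = 0.95, warmupMs = 100) {
  new("KalmanSettings", processNoiseScale = as.numeric(processNoiseScale),
      observationNoiseScale = as.numeric(observationNoiseScale),
      initialCovarianceScale = as.numeric(initialCovarianceScale),
      errorSmoothing = as.numeric(errorSmoothing),
      warmupMs = as.numeric(warmupMs))
}

#' Region of interest
#'
#' A cluster of source-space vertices with similar, strong activation
#' time courses, treated as one node of the effective-connectivity
#' network.
#'
#' @slot roiId ROI label.
#' @slot centroidVertex identifier of the centroid vertex.
#' @slot members identifiers of member vertices (centroid included).
#' @slot meanCourse mean raw activation course of the members over the
#'   analysis window.
#' @slot strength mean non-normalized activation of the members over the
#'   analysis window.
#' @exportClass Roi
setClass("Roi",
  representation(roiId = "character", centroidVertex = "character",
                 members = "character", meanCourse = "numeric",
                 strength = "numeric"))

setValidity("Roi", function(object) {
  if (length(object@members) < 1L) return("members must be non-empty")
  if (!(object@centroidVertex %in% object@members))
    return("centroid must be a member")
  TRUE
})

#' A set of ROIs with the configuration that produced it
#'
#' @slot rois list of [Roi-class] objects with disjoint member sets.
#' @slot config the [AnalysisConfig-class] used to build the set.
#' @seealso [identifyRois()]
#' @exportClass RoiSet
setClass("RoiSet",
  representation(rois = "list", config = "AnalysisConfig"))

setValidity("RoiSet", function(object) {
  if (!all(vapply(object@rois, is, logical(1), class2 = "Roi")))
    return("rois must be a list of Roi objects")
  ids <- vapply(object@rois, function(r) r@roiId, character(1))
  if (anyDuplicated(ids)) return("roi ids must be unique")
  mem <- unlist(lapply(object@rois, function(r) r@members))
  if (anyDuplicated(mem)) return("member sets must be pairwise disjoint")
  TRUE
})

#' Time-varying MVAR model for one target channel
#'
#' Per-timepoint autoregressive coefficients estimated by the Kalman
#' filter, with the innovation sequence and the running prediction-error
#' scale. One model per target channel per variant (full model or
#' counter-model omitting one candidate source).
#'
#' @slot target identifier of the predicted channel.
#' @slot predictors ordered identifiers of the channels whose lags enter
#'   the regressor.
#' @slot order model order p (lags per predictor).
#' @slot coeffs numeric matrix `n_time x (n_predictors * p)`; column
#'   `(k-1)*n_predictors + j` is the lag-k coefficient of predictor j.
#' @slot errorScale per-timepoint prediction-error scale (> 0).
#' @slot innovations per-timepoint one-step prediction residuals.
#' @slot tIndex sample indices (into the source series) the rows refer to.
#' @slot samplingRate,t0Ms time base copied from the input series.
#' @seealso [fitFullModel()], [fitCounterModel()]
#' @exportClass TvMvarModel
setClass("TvMvarModel",
  representation(target = "character", predictors = "character",
                 order = "integer", coeffs = "matrix",
                 errorScale = "numeric", innovations = "numeric",
                 tIndex = "integer", samplingRate = "numeric",
                 t0Ms = "numeric"))

setValidity("TvMvarModel", function(object) {
  if (!all(is.finite(object@coeffs))) return("coefficients must be finite")
  if (any(object@errorScale <= 0)) return("errorScale must be > 0")
  if (nrow(object@coeffs) != length(object@tIndex))
    return("coeffs rows must match tIndex")
  if (ncol(object@coeffs) !=
      length(object@predictors) * object@order)
    return("coeffs columns must equal n_predictors * order")
  TRUE
})

#' Per-timepoint Granger Causality Index for one directed edge
#'
#' @slot source,target channel identifiers of the directed pair.
#' @slot condition condition label (may be empty).
#' @slot gci per-timepoint GCi over the analysis window.
#' @slot p per-timepoint bootstrap p-values (NA when no null was built).
#' @slot sig logical, `p < alpha`.
#' @slot tIndex sample indices of the window timepoints.
#' @slot samplingRate,t0Ms time base.
#' @seealso [edgeGci()], [bootstrapNull()]
#' @exportClass GciSeries
setClass("GciSeries",
  representation(source = "character", target = "character",
                 condition = "character", gci = "numeric", p = "numeric",
                 sig = "logical", tIndex = "integer",
                 samplingRate = "numeric", t0Ms = "numeric"))

setValidity("GciSeries", function(object) {
  if (!all(is.finite(object@gci))) return("gci must be finite")
  if (length(object@p) != length(object@gci))
    return("p must match gci length")
  if (any(!is.na(object@p) & (object@p < 0 | object@p > 1)))
    return("p-values must lie in [0, 1]")
  TRUE
})

## show methods ---------------------------------------------------------

setMethod("show", "MultiTimeSeries", function(object) {
  cat(sprintf("MultiTimeSeries: %d channel(s) x %d timepoints @ %g Hz, t0 = %g ms\n",
              nrow(object@values), ncol(object@values),
              object@samplingRate, object@t0Ms))
  cat("  channels:", paste(head(object@labels, 6), collapse = ", "),
      if (length(object@labels) > 6) "..." else "", "\n")
})

setMethod("show", "VertexActivationMap", function(object) {
  cat(sprintf("VertexActivationMap: %d vertices x %d timepoints @ %g Hz\n",
              length(object@vertexIds), ncol(object@activation),
              object@samplingRate))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat(sprintf("  model order %d, %d bootstrap replicates, alpha %g\n",
              object@modelOrder, object@nBootstrap, object@alpha))
  cat(sprintf("  window %g-%g ms; centroid pct %g, exclusion %g mm\n",
              object@windowMs[1], object@windowMs[2],
              object@centroidPercentile, object@exclusionRadiusMm))
  cat(sprintf("  growth %g SD, redundancy %g SD, contiguity %g mm; steps {%s}\n",
              object@growthSdFactor, object@redundancySdFactor,
              object@contiguityRadiusMm,
              paste(object@stepsIncluded, collapse = ",")))
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet with %d ROI(s)\n", length(object@rois)))
  for (r in head(object@rois, 8))
    cat(sprintf("  %s: centroid %s, %d member(s), strength %.3g\n",
                r@roiId, r@centroidVertex, length(r@members), r@strength))
  if (length(object@rois) > 8) cat("  ...\n")
})

setMethod("show", "TvMvarModel", function(object) {
  cat(sprintf("TvMvarModel for target %s: %d predictor(s), order %d, %d timepoints\n",
              object@target, length(object@predictors), object@order,
              length(object@tIndex)))
})

setMethod("show", "GciSeries", function(object) {
  cat(sprintf("GciSeries %s -> %s%s: %d window timepoints, %d significant\n",
              object@source, object@target,
              if (nzchar(object@condition))
                paste0(" [", object@condition, "]") else "",
              length(object@gci), sum(object@sig, na.rm = TRUE)))
})
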