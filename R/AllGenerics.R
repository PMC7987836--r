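## Accessor generics. Slots are never reached into from user code.

#' Channel labels of a time series or map
#' @param x a [MultiTimeSeries-class] or [VertexActivationMap-class].
#' @return character vector of identifiers.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "MultiTimeSeries", function(x) x@labels)

#' Signal matrix (channels or vertices in rows)
#' @param x a container object.
#' @return numeric matrix.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname seriesValues
#' @export
setMethod("seriesValues", "MultiTimeSeries", function(x) x@values)

#' @rdname seriesValues
#' @export
setMethod("seriesValues", "VertexActivationMap", function(x) x@activation)

#' Sampling rate in Hz
#' @param x a container object.
#' @return samples per second.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "MultiTimeSeries", function(x) x@samplingRate)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "VertexActivationMap", function(x) x@samplingRate)

#' Time of the first sample relative to stimulus onset (ms)
#' @param x a container object.
#' @return milliseconds.
#' @export
setGeneric("timeOrigin", function(x) standardGeneric("timeOrigin"))

#' @rdname timeOrigin
#' @export
setMethod("timeOrigin", "MultiTimeSeries", function(x) x@t0Ms)

#' @rdname timeOrigin
#' @export
setMethod("timeOrigin", "VertexActivationMap", function(x) x@t0Ms)

#' Number of timepoints
#' @param x a container object.
#' @return integer count.
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname nTimepoints
#' @export
setMethod("nTimepoints", "MultiTimeSeries", function(x) ncol(x@values))

#' @rdname nTimepoints
#' @export
setMethod("nTimepoints", "VertexActivationMap",
          function(x) ncol(x@activation))

#' Vertex identifiers of an activation map
#' @param x a [VertexActivationMap-class].
#' @return character vector.
#' @export
setGeneric("vertexIds", function(x) standardGeneric("vertexIds"))

#' @rdname vertexIds
#' @export
setMethod("vertexIds", "VertexActivationMap", function(x) x@vertexIds)

#' Vertex coordinates in millimetres
#' @param x a [VertexActivationMap-class].
#' @return numeric matrix `n x 3`.
#' @export
setGeneric("vertexCoords", function(x) standardGeneric("vertexCoords"))

#' @rdname vertexCoords
#' @export
setMethod("vertexCoords", "VertexActivationMap", function(x) x@coordsMm)

#' Sample times in milliseconds
#' @param x a container with a time base.
#' @return numeric vector, one entry per timepoint.
#' @export
setGeneric("timesMs", function(x) standardGeneric("timesMs"))

#' @rdname timesMs
#' @export
setMethod("timesMs", "MultiTimeSeries", function(x)
  x@t0Ms + (seq_len(ncol(x@values)) - 1L) * 1000 / x@samplingRate)

#' @rdname timesMs
#' @export
setMethod("timesMs", "VertexActivationMap", function(x)
  x@t0Ms + (seq_len(ncol(x@activation)) - 1L) * 1000 / x@samplingRate)

#' ROI identifiers of a RoiSet
#' @param x a [RoiSet-class].
#' @return character vector in set order (descending strength).
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname roiIds
#' @export
setMethod("roiIds", "RoiSet",
          function(x) vapply(x@rois, function(r) r@roiId, character(1)))

#' Member vertices of each ROI
#' @param x a [RoiSet-class] or [Roi-class].
#' @return for a RoiSet, a named list of character vectors; for a Roi,
#'   a character vector.
#' @export
setGeneric("roiMembers", function(x) standardGeneric("roiMembers"))

#' @rdname roiMembers
#' @export
setMethod("roiMembers", "Roi", function(x) x@members)

#' @rdname roiMembers
#' @export
setMethod("roiMembers", "RoiSet", function(x) {
  out <- lapply(x@rois, function(r) r@members)
  names(out) <- roiIds(x)
  out
})

#' Number of ROIs
#' @param x a [RoiSet-class].
#' @export
setMethod("length", "RoiSet", function(x) length(x@rois))

#' Extract one ROI by position or id
#' @param x a [RoiSet-class].
#' @param i integer position or ROI id.
#' @export
setMethod("[[", "RoiSet", function(x, i) {
  if (is.character(i)) i <- match(i, roiIds(x))
  x@rois[[i]]
})

#' Per-timepoint prediction-error scale of a fitted model
#' @param x a [TvMvarModel-class].
#' @return numeric vector aligned with `modelTimeIndex(x)`.
#' @export
setGeneric("errorScale", function(x) standardGeneric("errorScale"))

#' @rdname errorScale
#' @export
setMethod("errorScale", "TvMvarModel", function(x) x@errorScale)

#' Per-timepoint filtered coefficients
#' @param x a [TvMvarModel-class].
#' @return numeric matrix `n_time x (n_predictors * order)`.
#' @export
setGeneric("modelCoeffs", function(x) standardGeneric("modelCoeffs"))

#' @rdname modelCoeffs
#' @export
setMethod("modelCoeffs", "TvMvarModel", function(x) x@coeffs)

#' Innovation (one-step residual) sequence of a fitted model
#' @param x a [TvMvarModel-class].
#' @return numeric vector.
#' @export
setGeneric("modelInnovations", function(x) standardGeneric("modelInnovations"))

#' @rdname modelInnovations
#' @export
setMethod("modelInnovations", "TvMvarModel", function(x) x@innovations)

#' Sample indices a fitted model's rows refer to
#' @param x a [TvMvarModel-class] or [GciSeries-class].
#' @return integer vector of indices into the original series.
#' @export
setGeneric("modelTimeIndex", function(x) standardGeneric("modelTimeIndex"))

#' @rdname modelTimeIndex
#' @export
setMethod("modelTimeIndex", "TvMvarModel", function(x) x@tIndex)

#' @rdname modelTimeIndex
#' @export
setMethod("modelTimeIndex", "GciSeries", function(x) x@tIndex)

#' GCi values of an edge series
#' @param x a [GciSeries-class].
#' @return numeric vector over the analysis window.
#' @export
setGeneric("gciValues", function(x) standardGeneric("gciValues"))

#' @rdname gciValues
#' @export
setMethod("gciValues", "GciSeries", function(x) x@gci)

#' Per-timepoint bootstrap p-values of an edge series
#' @param x a [GciSeries-class].
#' @return numeric vector (NA when no null was computed).
#' @export
setGeneric("gciPvalues", function(x) standardGeneric("gciPvalues"))

#' @rdname gciPvalues
#' @export
setMethod("gciPvalues", "GciSeries", function(x) x@p)
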