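## Kalman-filter estimation of time-varying MVAR prediction models.

## lag-matrix builder: row t (for sample p+t) holds, in column
## (k-1)*n + j, the value of channel j at lag k
buildLagMatrix <- function(values, p, channels = seq_len(nrow(values))) {
  n <- length(channels); T <- ncol(values)
  X <- matrix(0, T - p, n * p)
  for (k in seq_len(p))
    X[, (k - 1L) * n + seq_len(n)] <-
      t(values[channels, seq.int(p + 1L - k, T - k), drop = FALSE])
  X
}

fitTargetModel <- function(ts, target, predictors, cfg, ks) {
  vals <- seriesValues(ts)
  labels <- channelLabels(ts)
  p <- cfg@modelOrder
  if (ncol(vals) <= p + 1L)
    stop("series too short for the model order", call. = FALSE)
  if (!all(is.finite(vals))) stop("non-finite input", call. = FALSE)
  ti <- match(target, labels)
  pi <- match(predictors, labels)
  if (anyNA(c(ti, pi))) stop("unknown channel identifier", call. = FALSE)
  X <- buildLagMatrix(vals, p, pi)
  y <- vals[ti, seq.int(p + 1L, ncol(vals))]
  fit <- .kalman_ar_filter(X, y, ks@processNoiseScale,
                           ks@observationNoiseScale,
                           ks@initialCovarianceScale, ks@errorSmoothing)
  new("TvMvarModel", target = target, predictors = predictors,
      order = as.integer(p), coeffs = fit$coeffs,
      errorScale = as.numeric(fit$error_scale),
      innovations = as.numeric(fit$innovations),
      tIndex = seq.int(p + 1L, ncol(vals)),
      samplingRate = samplingRate(ts), t0Ms = timeOrigin(ts))
}

#' Fit the full time-varying MVAR model
#'
#' For each target channel, runs a Kalman filter whose state is the
#' vector of AR coefficients for all channels and lags (model order
#' `cfg@modelOrder`), with the regressor built from the p preceding
#' samples of every channel. Coefficients follow a random walk
#' (process noise `ks@processNoiseScale`); the per-timepoint
#' prediction-error scale is an exponentially weighted SD of the
#' innovations. The filter converges within roughly the first 100 ms, so
#' the model is computed from the start of the series and consumed over
#' the post-warm-up analysis window.
#'
#' @param ts a [MultiTimeSeries-class] with at least 2 channels.
#' @param cfg an [AnalysisConfig-class].
#' @param ks a [KalmanSettings-class].
#' @return named list of [TvMvarModel-class], one per target channel.
#' @examples
#' A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 0.5; A[2, 1, 1] <- 0.4
#' ts <- simulateMvar(groundTruthNetwork(A), 600, seed = 1)
#' models <- fitFullModel(ts, analysisConfig(modelOrder = 1))
#' @export
fitFullModel <- function(ts, cfg = analysisConfig(),
                         ks = kalmanSettings()) {
  labels <- channelLabels(ts)
  if (length(labels) < 2L)
    stop("the full model needs at least 2 channels", call. = FALSE)
  out <- lapply(labels, fitTargetModel, ts = ts, predictors = labels,
                cfg = cfg, ks = ks)
  names(out) <- labels
  out
}

#' Fit a counter-model omitting one candidate source
#'
#' Identical filter run with the omitted channel's lags removed from the
#' regressor. With only two channels this reduces to a univariate AR(p)
#' model of the target.
#'
#' @param ts a [MultiTimeSeries-class].
#' @param omit identifier of the channel to leave out (the hypothesized
#'   cause; must differ from `target`).
#' @param target identifier of the predicted channel.
#' @param cfg an [AnalysisConfig-class].
#' @param ks a [KalmanSettings-class].
#' @return a [TvMvarModel-class].
#' @export
fitCounterModel <- function(ts, omit, target, cfg = analysisConfig(),
                            ks = kalmanSettings()) {
  labels <- channelLabels(ts)
  if (!(omit %in% labels))
    stop(sprintf("channel '%s' not in the series", omit), call. = FALSE)
  if (identical(omit, target))
    stop("cannot omit the target channel itself", call. = FALSE)
  fitTargetModel(ts, target, setdiff(labels, omit), cfg, ks)
}

#' Post-warm-up sample indices of a fitted model
#'
#' @param model a [TvMvarModel-class].
#' @param ks a [KalmanSettings-class] (provides `warmupMs`).
#' @return positions (rows of the model) past the warm-up period.
#' @export
postWarmup <- function(model, ks = kalmanSettings()) {
  warm <- round(ks@warmupMs / 1000 * model@samplingRate)
  tms <- model@t0Ms + (model@tIndex - 1L) * 1000 / model@samplingRate
  which(tms >= model@t0Ms + ks@warmupMs - 1e-9)
}

#' Time-averaged coefficient matrix of a fitted model
#'
#' Mean of the filtered coefficients over the post-warm-up rows,
#' reshaped to an `n_predictors x order` matrix (rows follow
#' `model@predictors`). Comparable to a static least-squares MVAR fit on
#' stationary data.
#'
#' @param model a [TvMvarModel-class].
#' @param ks a [KalmanSettings-class].
#' @return numeric matrix `n_predictors x order`.
#' @export
meanCoeffMatrix <- function(model, ks = kalmanSettings()) {
  rows <- postWarmup(model, ks)
  m <- colMeans(model@coeffs[rows, , drop = FALSE])
  matrix(m, nrow = length(model@predictors),
         dimnames = list(model@predictors, NULL))
}
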