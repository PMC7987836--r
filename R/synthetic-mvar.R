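## Ground-truth MVAR networks and simulation of multichannel series.

#' Ground-truth MVAR network
#'
#' Defines the generating process for synthetic multichannel series:
#' `x(t) = sum_k A_k(t) x(t-k) + eps(t)` with zero-mean Gaussian
#' innovations. Coefficient entry `A[i, j, k]` is the influence of
#' channel j at lag k on channel i. The schedule may be static, a
#' piecewise-constant switch at `changePoint`, or a linear ramp from
#' `coeffs` to `coeffsEnd` over the simulated span.
#'
#' @slot nChannels number of channels.
#' @slot order model order p.
#' @slot coeffs numeric array `n x n x p` (initial/static coefficients).
#' @slot coeffsEnd second coefficient array for piecewise/ramp schedules.
#' @slot changePoint sample index of the piecewise switch (NA otherwise).
#' @slot scheduleType one of "static", "piecewise", "ramp".
#' @slot innovationSd per-channel innovation SD (> 0).
#' @seealso [groundTruthNetwork()], [simulateMvar()]
#' @exportClass GroundTruthNetwork
setClass("GroundTruthNetwork",
  representation(nChannels = "integer", order = "integer",
                 coeffs = "array", coeffsEnd = "array",
                 changePoint = "integer", scheduleType = "character",
                 innovationSd = "numeric"))

setValidity("GroundTruthNetwork", function(object) {
  n <- object@nChannels; p <- object@order
  if (!identical(dim(object@coeffs), c(n, n, p)))
    return("coeffs must be an n x n x p array")
  if (!(object@scheduleType %in% c("static", "piecewise", "ramp")))
    return("scheduleType must be static, piecewise or ramp")
  if (object@scheduleType != "static" &&
      !identical(dim(object@coeffsEnd), c(n, n, p)))
    return("coeffsEnd must be an n x n x p array for time-varying schedules")
  if (object@scheduleType == "piecewise" && is.na(object@changePoint))
    return("piecewise schedule requires a changePoint")
  if (length(object@innovationSd) != n || any(object@innovationSd < 0))
    return("innovationSd must be one non-negative value per channel")
  TRUE
})

#' Spectral radius of the MVAR companion matrix
#'
#' Stability diagnostic: the process is stable iff the spectral radius of
#' the `np x np` companion matrix is below 1.
#'
#' @param A numeric array `n x n x p` of lag coefficient matrices.
#' @return the largest eigenvalue modulus.
#' @export
companionRadius <- function(A) {
  d <- dim(A)
  n <- d[1]; p <- d[3]
  C <- matrix(0, n * p, n * p)
  for (k in seq_len(p))
    C[seq_len(n), (k - 1L) * n + seq_len(n)] <- A[, , k]
  if (p > 1L)
    C[n + seq_len(n * (p - 1L)), seq_len(n * (p - 1L))] <-
      diag(n * (p - 1L))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Construct a ground-truth MVAR network
#'
#' @param coeffs numeric array `n x n x p` (a matrix is treated as p = 1).
#'   Entry `[i, j, k]`: influence of channel j at lag k on channel i.
#' @param innovationSd per-channel innovation SD; a scalar is recycled.
#' @param coeffsEnd optional second coefficient array; selects a
#'   time-varying schedule.
#' @param changePoint sample index at which a piecewise schedule switches
#'   from `coeffs` to `coeffsEnd`.
#' @param schedule "static", "piecewise" or "ramp". Defaults to "static"
#'   unless `coeffsEnd` is given (then "piecewise" if `changePoint` is
#'   set, otherwise "ramp").
#' @return a [GroundTruthNetwork-class]; errors if any coefficient set is
#'   unstable, naming the offending spectral radius.
#' @examples
#' A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.5
#' net <- groundTruthNetwork(A)
#' @export
groundTruthNetwork <- function(coeffs, innovationSd = 1, coeffsEnd = NULL,
                               changePoint = NA, schedule = NULL) {
  if (is.matrix(coeffs)) coeffs <- array(coeffs, c(dim(coeffs), 1L))
  n <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  if (is.null(schedule))
    schedule <- if (is.null(coeffsEnd)) "static"
                else if (!is.na(changePoint)) "piecewise" else "ramp"
  if (is.null(coeffsEnd)) coeffsEnd <- coeffs
  if (is.matrix(coeffsEnd)) coeffsEnd <- array(coeffsEnd, c(dim(coeffsEnd), 1L))
  for (A in list(coeffs, coeffsEnd)) {
    r <- companionRadius(A)
    if (r >= 1)
      stop(sprintf("unstable MVAR coefficients: companion spectral radius %.4f >= 1",
                   r), call. = FALSE)
  }
  new("GroundTruthNetwork", nChannels = as.integer(n), order = as.integer(p),
      coeffs = coeffs, coeffsEnd = coeffsEnd,
      changePoint = as.integer(changePoint), scheduleType = schedule,
      innovationSd = rep(as.numeric(innovationSd), length.out = n))
}

#' Coefficient array of a network at a given timepoint
#'
#' @param net a [GroundTruthNetwork-class].
#' @param t sample index in 1..nTimepoints.
#' @param nTimepoints span over which a ramp schedule is interpolated.
#' @return numeric array `n x n x p`.
#' @export
networkCoeffsAt <- function(net, t, nTimepoints) {
  switch(net@scheduleType,
    static = net@coeffs,
    piecewise = if (t < net@changePoint) net@coeffs else net@coeffsEnd,
    ramp = {
      w <- if (nTimepoints > 1L) (t - 1) / (nTimepoints - 1) else 0
      (1 - w) * net@coeffs + w * net@coeffsEnd
    })
}

## Vectorised coefficient schedule: (n*n*p) x T matrix, column-major
## A[target, source, lag] per column, as consumed by .mvar_iterate.
networkCoeffMatrix <- function(net, nTimepoints, offset = 0L) {
  n <- net@nChannels; p <- net@order
  if (net@scheduleType == "static")
    return(matrix(as.vector(net@coeffs), n * n * p, nTimepoints))
  vapply(seq_len(nTimepoints),
         function(t) as.vector(networkCoeffsAt(net, t - offset,
                                               nTimepoints - offset)),
         numeric(n * n * p))
}

setMethod("show", "GroundTruthNetwork", function(object) {
  cat(sprintf("GroundTruthNetwork: %d channel(s), order %d, %s schedule\n",
              object@nChannels, object@order, object@scheduleType))
  nz <- which(apply(object@coeffs != 0 | object@coeffsEnd != 0, c(1, 2), any),
              arr.ind = TRUE)
  nz <- nz[nz[, 1] != nz[, 2], , drop = FALSE]
  if (nrow(nz))
    cat("  directed edges:",
        paste(sprintf("%d->%d", nz[, 2], nz[, 1]), collapse = ", "), "\n")
})

#' Simulate a multichannel MVAR time series
#'
#' Iterates the network equation with Gaussian innovations. The first p
#' samples are drawn from the innovation distribution; a burn-in segment
#' (generated under the initial coefficients) is discarded so that the
#' returned series is close to its stationary regime. Time-varying
#' schedules unfold over the returned (post-burn-in) span.
#'
#' @param net a [GroundTruthNetwork-class].
#' @param nTimepoints number of samples to return (> order).
#' @param seed integer seed.
#' @param samplingRate,t0Ms time base for the returned series.
#' @param burnIn samples discarded from the start (default 200).
#' @return a [MultiTimeSeries-class] with channels `ch1..chn`.
#' @examples
#' A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.5; A[1, 1, 1] <- 0.3
#' ts <- simulateMvar(groundTruthNetwork(A), 500, seed = 1)
#' @export
simulateMvar <- function(net, nTimepoints, seed, samplingRate = 1000,
                         t0Ms = 0, burnIn = 200) {
  stopifnot(is(net, "GroundTruthNetwork"))
  if (nTimepoints <= net@order)
    stop("nTimepoints must exceed the model order", call. = FALSE)
  n <- net@nChannels
  total <- burnIn + nTimepoints
  ## burn-in runs under the initial coefficients; the schedule applies to
  ## the returned span
  Astart <- matrix(as.vector(net@coeffs), n * n * net@order, burnIn)
  Amain <- networkCoeffMatrix(net, nTimepoints)
  A <- cbind(Astart, Amain)
  set.seed(seed)
  eps <- matrix(rnorm(n * total, sd = rep(net@innovationSd, total)),
                nrow = n)
  x <- .mvar_iterate(A, eps, n, net@order)
  x <- x[, seq.int(burnIn + 1L, total), drop = FALSE]
  if (any(!is.finite(x)) || max(abs(x)) > 1e6)
    stop("simulated series diverged; check network stability", call. = FALSE)
  multiTimeSeries(x, samplingRate = samplingRate, t0Ms = t0Ms)
}
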