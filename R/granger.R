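## Granger Causality Index, bootstrap significance, condition
## comparison, FDR control and influence reports.

#' Granger Causality Index from prediction-error scales
#'
#' `gci(t) = ln(reduced_error(t) / full_error(t))`: the log ratio of the
#' prediction-error scale of the model omitting the candidate source to
#' that of the full model. Positive values mean the omitted channel
#' carried unique predictive information about the target.
#'
#' @param fullError per-timepoint error scale of the full model.
#' @param reducedError per-timepoint error scale of the counter-model
#'   (same length).
#' @return per-timepoint GCi.
#' @examples
#' gci(1, 2)  # log(2)
#' @export
gci <- function(fullError, reducedError) {
  if (length(fullError) != length(reducedError))
    stop("error-scale vectors must have equal length", call. = FALSE)
  bad <- which(fullError <= 0 | reducedError <= 0)
  if (length(bad))
    stop(sprintf("non-positive error scale at timepoint %d", bad[1]),
         call. = FALSE)
  log(reducedError / fullError)
}

## model rows falling in the analysis window and past warm-up
gciWindowRows <- function(model, cfg, ks) {
  tms <- model@t0Ms + (model@tIndex - 1L) * 1000 / model@samplingRate
  eps <- 1e-9
  rows <- which(tms >= cfg@windowMs[1] - eps & tms <= cfg@windowMs[2] + eps)
  rows[rows %in% postWarmup(model, ks)]
}

#' Observed GCi series for one directed edge
#'
#' Fits the full model for the target (or reuses a fitted one) and the
#' counter-model omitting the source, and evaluates the GCi on the
#' post-warm-up analysis window.
#'
#' @param ts a [MultiTimeSeries-class].
#' @param source,target channel identifiers of the directed pair.
#' @param cfg an [AnalysisConfig-class].
#' @param ks a [KalmanSettings-class].
#' @param fullModels optional output of [fitFullModel()] to reuse.
#' @param condition optional condition label stored on the result.
#' @return a [GciSeries-class] with `p` all NA (no null attached).
#' @seealso [edgeSignificance()] for the bootstrap-tested version.
#' @export
edgeGci <- function(ts, source, target, cfg = analysisConfig(),
                    ks = kalmanSettings(), fullModels = NULL,
                    condition = "") {
  if (identical(source, target))
    stop("source and target must differ", call. = FALSE)
  full <- if (is.null(fullModels)) {
    fitTargetModel(ts, target, channelLabels(ts), cfg, ks)
  } else fullModels[[target]]
  counter <- fitCounterModel(ts, source, target, cfg, ks)
  rows <- gciWindowRows(full, cfg, ks)
  g <- gci(errorScale(full)[rows], errorScale(counter)[rows])
  new("GciSeries", source = source, target = target,
      condition = condition, gci = g, p = rep(NA_real_, length(g)),
      sig = rep(NA, length(g)), tIndex = full@tIndex[rows],
      samplingRate = full@samplingRate, t0Ms = full@t0Ms)
}

## coefficient schedule (n*n*p) x T for .mvar_iterate, assembled from
## the fitted per-target models; columns 1..p are unused by the iterator
fullModelCoeffSchedule <- function(fullModels) {
  labels <- names(fullModels)
  n <- length(labels)
  p <- fullModels[[1]]@order
  T <- max(fullModels[[1]]@tIndex)
  A <- matrix(0, n * n * p, T)
  for (i in seq_len(n)) {
    m <- fullModels[[i]]
    A[i + (seq_len(n * p) - 1L) * n, m@tIndex] <- t(m@coeffs)
  }
  A
}

## centered moving average along rows (reflecting nothing; window is
## clipped at the edges)
smoothSchedule <- function(A, window) {
  if (window <= 1L) return(A)
  T <- ncol(A)
  half <- window %/% 2L
  lo <- pmax(seq_len(T) - half, 1L)
  hi <- pmin(seq_len(T) + half, T)
  t(apply(A, 1L, function(row) {
    cs <- cumsum(c(0, row))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }))
}

#' Bootstrap null distribution of the GCi for one edge
#'
#' Surrogate data are reconstructed from the fitted time-varying full
#' model with all source-to-target coefficients set to zero and
#' innovations resampled with replacement from the fitted residual pool
#' (per channel, post-warm-up residuals). Each surrogate is passed
#' through the same full + counter-model analysis, yielding an
#' independent per-timepoint null distribution of the GCi under "no
#' source-to-target influence, everything else intact". Before
#' iteration the fitted coefficient schedule is smoothed by a centered
#' moving average spanning the warm-up period: the raw filtered
#' trajectories carry estimation noise at the filter's own adaptation
#' timescale, and re-iterating that noise would bias the null downward,
#' while task-related coefficient changes are slower and survive the
#' smoothing. Surrogates that diverge are redrawn (count in the
#' `rejected` attribute).
#'
#' @param fullModels output of [fitFullModel()] on the observed series.
#' @param source,target the directed edge under test.
#' @param cfg an [AnalysisConfig-class] (`nBootstrap` replicates).
#' @param ks a [KalmanSettings-class].
#' @param seed integer seed for the resampling.
#' @return matrix `nBootstrap x n_window_timepoints` of null GCi values,
#'   with attribute `rejected` counting redrawn replicates.
#' @export
bootstrapNull <- function(fullModels, source, target,
                          cfg = analysisConfig(), ks = kalmanSettings(),
                          seed = 1) {
  labels <- names(fullModels)
  n <- length(labels)
  p <- fullModels[[1]]@order
  T <- max(fullModels[[1]]@tIndex)
  si <- match(source, labels); ti <- match(target, labels)
  if (anyNA(c(si, ti))) stop("unknown channel identifier", call. = FALSE)

  srate <- fullModels[[1]]@samplingRate
  win <- max(1L, round(ks@warmupMs / 1000 * srate))
  if (win %% 2L == 0L) win <- win + 1L
  A <- smoothSchedule(fullModelCoeffSchedule(fullModels), win)
  ## zero the source -> target block at every lag and timepoint
  A[ti + (si - 1L) * n + (seq_len(p) - 1L) * n * n, ] <- 0

  pool <- lapply(fullModels, function(m)
    as.numeric(m@innovations[postWarmup(m, ks)]))
  rows <- gciWindowRows(fullModels[[ti]], cfg, ks)

  set.seed(seed)
  B <- cfg@nBootstrap
  drawIdx <- function(nb) {
    m <- matrix(0L, n, T * nb)
    for (j in seq_len(n))
      m[j, ] <- sample.int(length(pool[[j]]), T * nb, replace = TRUE)
    m
  }
  res <- .bootstrap_gci_batch(A, pool, drawIdx(B), n, p, rows, ti, si,
                              ks@processNoiseScale,
                              ks@observationNoiseScale,
                              ks@initialCovarianceScale,
                              ks@errorSmoothing)
  nullG <- res$gci
  rejected <- 0L
  round <- 0L
  while (any(!res$ok)) {
    bad <- which(!res$ok)
    rejected <- rejected + length(bad)
    round <- round + 1L
    if (round > 20L)
      stop("surrogate iteration kept diverging; refit the full model",
           call. = FALSE)
    res <- .bootstrap_gci_batch(A, pool, drawIdx(length(bad)), n, p,
                                rows, ti, si, ks@processNoiseScale,
                                ks@observationNoiseScale,
                                ks@initialCovarianceScale,
                                ks@errorSmoothing)
    nullG[bad[seq_len(nrow(res$gci))], ] <- res$gci
  }
  attr(nullG, "rejected") <- rejected
  nullG
}

#' Edge-level p-value from the bootstrap count statistic
#'
#' The per-edge summary statistic is the number of window timepoints
#' whose pointwise bootstrap p-value falls below `alpha`. Timepoint
#' autocorrelation makes a nominal Binomial reference for this count
#' anti-conservative, so the count's null distribution is taken from
#' the bootstrap itself: each replicate is scored against the remaining
#' replicates exactly as the observed series is scored against all of
#' them, and the edge p-value is the empirical fraction of replicate
#' counts reaching the observed count (the same plain-fraction
#' convention as the pointwise p-values).
#'
#' @param nullG matrix from [bootstrapNull()].
#' @param observedGci observed GCi over the same window timepoints.
#' @param cfg an [AnalysisConfig-class] (`alpha`).
#' @return list with `p` (edge-level p-value), `count` (observed
#'   significant-timepoint count) and `nullCounts`.
#' @export
edgeCountPvalue <- function(nullG, observedGci, cfg = analysisConfig()) {
  B <- nrow(nullG)
  obsP <- colMeans(nullG >= rep(observedGci, each = B))
  count <- sum(obsP < cfg@alpha)
  ## leave-self-out pointwise p for each replicate, via column ranks
  nullP <- apply(nullG, 2L, function(v)
    (B - rank(v, ties.method = "min")) / (B - 1))
  nullCounts <- rowSums(nullP < cfg@alpha)
  list(p = mean(nullCounts >= count), count = count,
       nullCounts = nullCounts)
}

#' GCi with bootstrap significance for one edge
#'
#' Combines [edgeGci()] and [bootstrapNull()]: the per-timepoint p-value
#' is the fraction of null GCi values at that timepoint greater than or
#' equal to the observed GCi (upper tail; a positive GCi is the only
#' direction that means unique predictive information), and `sig` marks
#' `p < cfg@alpha`.
#'
#' @inheritParams edgeGci
#' @param seed integer seed for the bootstrap.
#' @return a [GciSeries-class] with p-values and significance flags.
#' @export
edgeSignificance <- function(ts, source, target, cfg = analysisConfig(),
                             ks = kalmanSettings(), seed = 1,
                             fullModels = NULL, condition = "") {
  if (is.null(fullModels)) fullModels <- fitFullModel(ts, cfg, ks)
  obs <- edgeGci(ts, source, target, cfg, ks, fullModels, condition)
  nullG <- bootstrapNull(fullModels, source, target, cfg, ks, seed)
  pv <- colMeans(nullG >= rep(obs@gci, each = nrow(nullG)))
  initialize(obs, p = pv, sig = pv < cfg@alpha)
}

#' Count significant timepoints in the analysis window
#'
#' @param g a [GciSeries-class] with p-values.
#' @param cfg an [AnalysisConfig-class] (`alpha`).
#' @return integer count of window timepoints with `p < alpha`.
#' @export
countSignificant <- function(g, cfg = analysisConfig()) {
  stopifnot(is(g, "GciSeries"))
  sum(g@p < cfg@alpha, na.rm = TRUE)
}

#' Compare conditions by significant-timepoint counts
#'
#' Conditional (sign-test style) exact binomial comparison: given
#' `k = countA + countB` significant timepoints overall, `countA` is
#' referred to Binomial(k, 1/2); the two-sided p-value is twice the
#' smaller tail, capped at 1. `k = 0` gives p = 1.
#'
#' @param countA,countB significant-timepoint counts in the two
#'   conditions.
#' @param nWindow number of timepoints in the analysis window (counts
#'   may not exceed it).
#' @return list with `p` and `favored` (`"A"`, `"B"` or `"tie"`).
#' @examples
#' compareConditions(40, 10, 401)
#' @export
compareConditions <- function(countA, countB, nWindow) {
  stopifnot(countA >= 0, countB >= 0, countA <= nWindow,
            countB <= nWindow)
  k <- countA + countB
  p <- if (k == 0) 1 else min(1, 2 * pbinom(min(countA, countB), k, 0.5))
  list(p = p,
       favored = if (countA > countB) "A"
                 else if (countB > countA) "B" else "tie")
}

#' Benjamini-Hochberg FDR decisions across edge tests
#'
#' Step-up control of the false discovery rate at level `cfg@alpha` over
#' the family of directed-edge p-values.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param cfg an [AnalysisConfig-class].
#' @return logical vector of rejection decisions (empty input gives an
#'   empty result).
#' @export
fdrCorrect <- function(pvalues, cfg = analysisConfig()) {
  if (!length(pvalues)) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH") <= cfg@alpha
}

#' Full-network connectivity analysis for one condition
#'
#' Fits the full model once, then for every ordered channel pair
#' computes the observed GCi and its bootstrap null, and counts
#' significant timepoints. Per-edge bootstrap seeds are derived from
#' `seed` by edge index (documented counter scheme, reproducible).
#'
#' @param ts a [MultiTimeSeries-class] (e.g. the ROI series of one
#'   condition).
#' @param cfg an [AnalysisConfig-class].
#' @param ks a [KalmanSettings-class].
#' @param seed integer base seed.
#' @param condition condition label attached to the results.
#' @return list with `edges` (list of [GciSeries-class], named
#'   `"src->tgt"`), `counts` (data.frame source, target, count),
#'   `nWindow`, and `condition`.
#' @export
analyzeConnectivity <- function(ts, cfg = analysisConfig(),
                                ks = kalmanSettings(), seed = 1,
                                condition = "") {
  labels <- channelLabels(ts)
  fullModels <- fitFullModel(ts, cfg, ks)
  pairs <- expand.grid(source = labels, target = labels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  edges <- vector("list", nrow(pairs))
  counts <- integer(nrow(pairs))
  edgeP <- numeric(nrow(pairs))
  for (e in seq_len(nrow(pairs))) {
    obs <- edgeGci(ts, pairs$source[e], pairs$target[e], cfg, ks,
                   fullModels, condition)
    nullG <- bootstrapNull(fullModels, pairs$source[e], pairs$target[e],
                           cfg, ks, seed = seed + e)
    pv <- colMeans(nullG >= rep(obs@gci, each = nrow(nullG)))
    edges[[e]] <- initialize(obs, p = pv, sig = pv < cfg@alpha)
    ec <- edgeCountPvalue(nullG, obs@gci, cfg)
    counts[e] <- ec$count
    edgeP[e] <- ec$p
  }
  names(edges) <- paste0(pairs$source, "->", pairs$target)
  list(edges = edges,
       counts = data.frame(source = pairs$source, target = pairs$target,
                           count = counts, edge_p = edgeP,
                           row.names = NULL),
       nWindow = length(edges[[1]]@gci), condition = condition)
}

#' Detect edges of a single-condition connectivity analysis
#'
#' Applies Benjamini-Hochberg FDR control to the edge-level count
#' p-values of [analyzeConnectivity()].
#'
#' @param res result of [analyzeConnectivity()].
#' @param cfg an [AnalysisConfig-class].
#' @return the `counts` data.frame with a logical `detected` column.
#' @export
detectEdges <- function(res, cfg = analysisConfig()) {
  out <- res$counts
  out$detected <- fdrCorrect(out$edge_p, cfg)
  out
}

#' Compare two conditions edge by edge
#'
#' Joins the per-edge significant-timepoint counts of two
#' [analyzeConnectivity()] results, applies the exact binomial
#' comparison to each edge, and controls the FDR across the edge family.
#'
#' @param resA,resB results of [analyzeConnectivity()] for the two
#'   conditions (same channel set).
#' @param cfg an [AnalysisConfig-class].
#' @return data.frame with columns `source, target, count_a, count_b,
#'   n_window, diff, binomial_p, fdr_significant, favored_condition`.
#' @export
compareConnectivity <- function(resA, resB, cfg = analysisConfig()) {
  stopifnot(identical(paste(resA$counts$source, resA$counts$target),
                      paste(resB$counts$source, resB$counts$target)))
  condA <- if (nzchar(resA$condition)) resA$condition else "A"
  condB <- if (nzchar(resB$condition)) resB$condition else "B"
  nW <- resA$nWindow
  out <- resA$counts[, c("source", "target")]
  out$count_a <- resA$counts$count
  out$count_b <- resB$counts$count
  out$n_window <- nW
  out$diff <- out$count_a - out$count_b
  cmp <- mapply(function(a, b) compareConditions(a, b, nW),
                out$count_a, out$count_b, SIMPLIFY = FALSE)
  out$binomial_p <- vapply(cmp, `[[`, numeric(1), "p")
  out$favored_condition <- vapply(cmp, function(x)
    switch(x$favored, A = condA, B = condB, "tie"), character(1))
  out$fdr_significant <- fdrCorrect(out$binomial_p, cfg)
  out
}

#' Ranked influence report for one focus channel
#'
#' The tabular equivalent of a bubble plot: FDR-significant edges onto
#' (or from) the focus channel, ranked by the absolute difference in
#' significant-timepoint counts, with the favored condition.
#'
#' @param comparisons output of [compareConnectivity()].
#' @param focus channel identifier to center the report on.
#' @param direction `"onto"` (edges with `target == focus`) or `"from"`
#'   (edges with `source == focus`).
#' @return the filtered, sorted comparison rows (possibly zero rows).
#' @export
influenceReport <- function(comparisons, focus,
                            direction = c("onto", "from")) {
  direction <- match.arg(direction)
  known <- unique(c(comparisons$source, comparisons$target))
  if (!(focus %in% known))
    stop(sprintf("unknown focus channel '%s'", focus), call. = FALSE)
  sel <- if (direction == "onto") comparisons$target == focus
         else comparisons$source == focus
  out <- comparisons[sel & comparisons$fdr_significant, , drop = FALSE]
  out <- out[order(-abs(out$diff)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
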