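## Behavioral analysis: condition assignment, unrepaired-response
## coding, trial filtering, repair rates, and the condition test.

#' Assign Trained/Naive condition from group and onset context
#'
#' A continuum is Trained for a subject when its potential onset cluster
#' appeared in that subject's word-learning set: the /sr/-continuum
#' (`_r` context) for the sr-familiarization group and the
#' /shl/-continuum (`_l` context) for the shl-familiarization group.
#' The other context is Naive.
#'
#' @param group `"sr-familiarization"` or `"shl-familiarization"`
#'   (vectorized).
#' @param context `"_l"` or `"_r"` (vectorized).
#' @return character vector, `"Trained"` or `"Naive"`.
#' @examples
#' assignCondition("sr-familiarization", "_r")  # "Trained"
#' @export
assignCondition <- function(group, context) {
  group <- as.character(group); context <- as.character(context)
  bad <- which(!(group %in% TRIAL_GROUPS))
  if (length(bad))
    stop(sprintf("unknown group '%s'", group[bad[1]]), call. = FALSE)
  bad <- which(!(context %in% TRIAL_CONTEXTS))
  if (length(bad))
    stop(sprintf("unknown context '%s'", context[bad[1]]), call. = FALSE)
  trained <- (group == "sr-familiarization" & context == "_r") |
             (group == "shl-familiarization" & context == "_l")
  ifelse(trained, "Trained", "Naive")
}

#' Code a response as phonotactically unrepaired
#'
#' A response is unrepaired when it reports the onset cluster that is
#' illegal in English: "S" on the /sr/-/shr/ continuum (`_r` context),
#' "SH" on the /shl/-/sl/ continuum (`_l` context).
#'
#' @param context `"_l"` or `"_r"` (vectorized).
#' @param response `"S"` or `"SH"` (vectorized).
#' @return logical vector.
#' @examples
#' codeUnrepaired("_r", "S")   # TRUE
#' codeUnrepaired("_l", "SH")  # TRUE
#' @export
codeUnrepaired <- function(context, response) {
  context <- as.character(context); response <- as.character(response)
  bad <- which(!(context %in% TRIAL_CONTEXTS))
  if (length(bad))
    stop(sprintf("unknown context '%s'", context[bad[1]]), call. = FALSE)
  bad <- which(!(response %in% TRIAL_RESPONSES))
  if (length(bad))
    stop(sprintf("unknown response '%s'", response[bad[1]]), call. = FALSE)
  (context == "_r" & response == "S") | (context == "_l" & response == "SH")
}

#' Filter trials for analysis
#'
#' Retains trials whose continuum step is in `cfg@stepsIncluded`
#' (default 2-5; step 1 sits at the floor of the psychometric function
#' and carries no learning signal). With `unrepairedOnly = TRUE`, also
#' restricts to unrepaired responses, the subset entering the effective
#' connectivity branch.
#'
#' @param tt a validated trial table.
#' @param cfg an [AnalysisConfig-class].
#' @param unrepairedOnly restrict to unrepaired responses.
#' @return the filtered trial table; warns (does not error) when empty.
#' @export
filterAnalysisTrials <- function(tt, cfg = analysisConfig(),
                                 unrepairedOnly = FALSE) {
  out <- tt[tt$step %in% cfg@stepsIncluded, , drop = FALSE]
  if (unrepairedOnly) out <- out[out$unrepaired, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("trial filter returned an empty table", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Unrepaired-response rates by condition, context and step
#'
#' One row per (condition, context, step) cell with trial counts, the
#' unrepaired-response rate, and its binomial standard error
#' `sqrt(rate (1 - rate) / n)`.
#'
#' @param tt a validated, non-empty trial table.
#' @return data.frame with columns `condition, context, step, n_trials,
#'   n_unrepaired, rate, standard_error`.
#' @export
repairRates <- function(tt) {
  if (nrow(tt) == 0L) stop("trial table is empty", call. = FALSE)
  agg <- aggregate(cbind(n_unrepaired = tt$unrepaired,
                         n_trials = rep(1L, nrow(tt))),
                   by = list(condition = tt$condition,
                             context = tt$context, step = tt$step),
                   FUN = sum)
  agg <- agg[order(agg$condition, agg$context, agg$step), ]
  agg$rate <- agg$n_unrepaired / agg$n_trials
  agg$standard_error <- sqrt(agg$rate * (1 - agg$rate) / agg$n_trials)
  agg <- agg[, c("condition", "context", "step", "n_trials",
                 "n_unrepaired", "rate", "standard_error")]
  rownames(agg) <- NULL
  agg
}

fitRepairGlm <- function(tt, formula, augment = FALSE) {
  dat <- tt
  dat$step <- factor(dat$step)
  dat$condition <- factor(dat$condition, levels = TRIAL_CONDITIONS)
  dat$context <- factor(dat$context, levels = TRIAL_CONTEXTS)
  dat$.w <- 1
  if (augment) {
    ## symmetric pseudo-observations per design cell: a weak
    ## data-augmentation prior that keeps estimates finite under
    ## complete separation
    cells <- unique(dat[, intersect(c("condition", "context", "step"),
                                    all.vars(formula))])
    aug <- cells[rep(seq_len(nrow(cells)), each = 2L), , drop = FALSE]
    aug$unrepaired <- rep(c(TRUE, FALSE), nrow(cells))
    aug$.w <- 0.5
    for (nm in setdiff(names(dat), names(aug))) aug[[nm]] <- dat[[nm]][1]
    dat <- rbind(dat[names(dat)], aug[names(dat)])
  }
  suppressWarnings(glm(formula, family = binomial(), data = dat,
                       weights = .w))
}

#' Likelihood-ratio test of the word-learning condition effect
#'
#' Fits a fixed-effects logistic regression of the unrepaired-response
#' indicator and tests the Condition term by a likelihood-ratio test of
#' the full model against the model without it. By default the model has
#' main effects of Condition, Context and Step (categorical), giving a
#' 1-df test; `interactions = TRUE` uses the full factorial model and
#' drops Condition together with all its interactions. Under complete
#' separation the models are refit with symmetric half-weight
#' pseudo-observations per design cell (a weak data-augmentation prior)
#' and the result is flagged.
#'
#' @param tt a trial table containing both conditions, typically already
#'   restricted to the analysis steps via [filterAnalysisTrials()].
#' @param interactions use the full factorial model (see above).
#' @param includeSubject add subject as a fixed covariate.
#' @return list with `estimate` (log-odds of the Condition term;
#'   Trained relative to Naive), `lr` (likelihood-ratio statistic), `df`,
#'   `p`, and `separation` (logical).
#' @examples
#' tt <- simulateBehavior(behaviorDesign(nSubjects = 4), seed = 1)
#' testConditionEffect(filterAnalysisTrials(tt))
#' @export
testConditionEffect <- function(tt, interactions = FALSE,
                                includeSubject = FALSE) {
  if (length(unique(tt$condition)) < 2L)
    stop("both conditions must be present", call. = FALSE)
  base <- if (interactions) "condition * context * step"
          else "condition + context + step"
  null <- if (interactions) "context * step" else "context + step"
  if (includeSubject) {
    base <- paste(base, "+ subject_id")
    null <- paste(null, "+ subject_id")
  }
  fullF <- as.formula(paste("unrepaired ~", base))
  nullF <- as.formula(paste("unrepaired ~", null))

  full <- fitRepairGlm(tt, fullF)
  separation <- !full$converged ||
    any(abs(coef(full)) > 12, na.rm = TRUE)
  if (separation) {
    warning("possible complete separation; refitting with pseudo-observations",
            call. = FALSE)
    full <- fitRepairGlm(tt, fullF, augment = TRUE)
    reduced <- fitRepairGlm(tt, nullF, augment = TRUE)
  } else {
    reduced <- fitRepairGlm(tt, nullF)
  }
  lr <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
  df <- attr(logLik(full), "df") - attr(logLik(reduced), "df")
  cf <- coef(full)
  est <- cf[grep("^conditionNaive$", names(cf))]
  ## coefficient reported as Trained - Naive on the log-odds scale
  estimate <- if (length(est)) -unname(est) else {
    alt <- cf[grep("^conditionTrained$", names(cf))]
    if (length(alt)) unname(alt) else NA_real_
  }
  list(estimate = estimate, lr = lr, df = df,
       p = pchisq(lr, df = df, lower.tail = FALSE),
       separation = separation)
}
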