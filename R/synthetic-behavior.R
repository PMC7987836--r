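## Synthetic behavioral trial tables with a planted learning effect.

#' Behavioral design for synthetic categorization data
#'
#' Emulates the two-alternative phoneme categorization protocol: each
#' subject belongs to one familiarization group and completes
#' `trialsPerCell` trials in each of the 10 stimulus cells (2 onset
#' contexts x 5 continuum steps), 270 trials at the defaults. The
#' probability of an unrepaired response follows a logistic psychometric
#' function of continuum step with a context-specific midpoint, and the
#' planted learning effect `learningShift` adds to the log-odds in the
#' Trained condition only.
#'
#' @slot nSubjects number of subjects (default 12, half per group).
#' @slot trialsPerCell trials per context-by-step cell (default 27).
#' @slot slope psychometric slope per continuum step (log-odds).
#' @slot midpointL,midpointR psychometric midpoints (step units) for the
#'   `_l` and `_r` contexts; their difference is the context effect.
#' @slot learningShift additive log-odds change in unrepaired-response
#'   probability in the Trained condition.
#' @seealso [behaviorDesign()], [simulateBehavior()]
#' @exportClass BehaviorDesign
setClass("BehaviorDesign",
  representation(nSubjects = "integer", trialsPerCell = "integer",
                 slope = "numeric", midpointL = "numeric",
                 midpointR = "numeric", learningShift = "numeric"))

setValidity("BehaviorDesign", function(object) {
  if (object@nSubjects < 1L) return("nSubjects must be >= 1")
  if (object@trialsPerCell < 1L) return("trialsPerCell must be >= 1")
  TRUE
})

#' Construct a BehaviorDesign
#'
#' Defaults reflect the study protocol (12 subjects, 27 trials per cell,
#' hence 270 trials per subject) with a psychometric curve rising from
#' near-floor at step 1. See [BehaviorDesign-class].
#'
#' @param nSubjects,trialsPerCell,slope,midpointL,midpointR,learningShift
#'   see [BehaviorDesign-class].
#' @return a [BehaviorDesign-class].
#' @export
behaviorDesign <- function(nSubjects = 12, trialsPerCell = 27, slope = 1.2,
                           midpointL = 3.2, midpointR = 3.6,
                           learningShift = 1.0) {
  new("BehaviorDesign", nSubjects = as.integer(nSubjects),
      trialsPerCell = as.integer(trialsPerCell), slope = as.numeric(slope),
      midpointL = as.numeric(midpointL), midpointR = as.numeric(midpointR),
      learningShift = as.numeric(learningShift))
}

#' Analytic unrepaired-response probability of a design
#'
#' The generating psychometric function, usable as the oracle when
#' checking empirical repair rates.
#'
#' @param design a [BehaviorDesign-class].
#' @param context `"_l"` or `"_r"`.
#' @param step continuum step 1..5.
#' @param condition `"Trained"` or `"Naive"`.
#' @return probability of an unrepaired response.
#' @export
psychometricProb <- function(design, context, step, condition) {
  mid <- ifelse(context == "_l", design@midpointL, design@midpointR)
  plogis(design@slope * (step - mid) +
           design@learningShift * (condition == "Trained"))
}

#' Simulate a behavioral trial table
#'
#' Subjects alternate between the sr- and shl-familiarization groups;
#' every subject completes the full factorial design (both contexts, all
#' five steps, `trialsPerCell` trials each). Condition labels follow the
#' group-by-context mapping of [assignCondition()], responses are drawn
#' from the design's psychometric function, and the response letter is
#' the one whose unrepaired-coding matches the drawn outcome.
#'
#' @param design a [BehaviorDesign-class].
#' @param seed integer seed.
#' @return a validated trial table (data.frame) with columns
#'   `subject_id, group, condition, context, step, response, unrepaired`
#'   and `block` (each subject's randomly ordered trials split into
#'   three equal presentation blocks).
#' @examples
#' tt <- simulateBehavior(behaviorDesign(nSubjects = 2), seed = 1)
#' nrow(tt)  # 2 x 270
#' @export
simulateBehavior <- function(design, seed) {
  stopifnot(is(design, "BehaviorDesign"))
  set.seed(seed)
  groups <- rep(TRIAL_GROUPS, length.out = design@nSubjects)
  cells <- expand.grid(context = TRIAL_CONTEXTS, step = 1:5,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(design@nSubjects), function(s) {
    df <- cells[rep(seq_len(nrow(cells)), each = design@trialsPerCell), ]
    df$subject_id <- sprintf("s%02d", s)
    df$group <- groups[s]
    ## trials randomly ordered into three equal blocks (270 -> 3 x 90
    ## at the default design); left NA when not divisible by 3
    df <- df[sample.int(nrow(df)), ]
    df$block <- if (nrow(df) %% 3L == 0L)
      rep(1:3, each = nrow(df) %/% 3L) else NA_integer_
    df
  })
  tt <- do.call(rbind, rows)
  tt$condition <- assignCondition(tt$group, tt$context)
  p <- psychometricProb(design, tt$context, tt$step, tt$condition)
  tt$unrepaired <- runif(nrow(tt)) < p
  ## response letter implied by context and the drawn unrepaired outcome
  tt$response <- ifelse(tt$context == "_r",
                        ifelse(tt$unrepaired, "S", "SH"),
                        ifelse(tt$unrepaired, "SH", "S"))
  tt <- tt[, c("subject_id", "group", "condition", "context", "step",
               "response", "unrepaired", "block")]
  rownames(tt) <- NULL
  validateTrialTable(tt)
}
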