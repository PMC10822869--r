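#' @useDynLib dopfer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats dnorm median plogis qlogis qlnorm plnorm rbinom rnorm
#'   runif sd setNames var quantile dbinom integrate
#' @importFrom utils read.csv write.csv head
NULL

#' Canonical factor levels of the recognition task
#'
#' The six basic emotions, the two training groups (differential and
#' non-differential outcomes) and the two feedback conditions, in the fixed
#' order used for parameter indexing throughout the package.
#'
#' @name task-levels
#' @aliases dopferEmotions dopferGroups dopferFeedbacks
NULL

#' @rdname task-levels
#' @export
dopferEmotions <- c("Anger", "Disgust", "Fear", "Happiness", "Sadness",
                    "Surprise")

#' @rdname task-levels
#' @export
dopferGroups <- c("DOP", "NOP")

#' @rdname task-levels
#' @export
dopferFeedbacks <- c("NoFeedback", "Feedback")

#' TrialDataset: validated trial-level behavioral data
#'
#' Container for one-row-per-trial behavioral records (participant, group,
#' feedback condition, emotion, actor, within-condition trial index, reaction
#' time in seconds, correctness) plus an optional table of SPQ factor
#' profiles for the participants who completed the questionnaire.
#'
#' @slot trials data.frame with columns `participant_id`, `group`,
#'   `feedback`, `emotion`, `actor_id`, `trial_index`, `rt_seconds`,
#'   `correct` (plus any extra metadata columns, preserved as-is).
#' @slot spq data.frame with columns `participant_id`, `raw_cp`, `raw_in`,
#'   `raw_di`, `raw_total`, and (once standardized) `z_cp`, `z_in`, `z_di`;
#'   zero rows when no questionnaire data are available.
#' @exportClass TrialDataset
setClass("TrialDataset",
         slots = c(trials = "data.frame", spq = "data.frame"))

#' ConditionIndex: parameter slot maps over task conditions
#'
#' Maps every (group, feedback, emotion) cell to an intercept slot
#' (`cond24`, 24 slots in the full design) and every
#' (feedback-condition, emotion) cell to a slope slot (`cond18`, 18 slots in
#' the full design). The two groups share a slope slot in the no-feedback
#' block, where no group difference in penalties is expected.
#'
#' @slot groups,feedbacks,emotions character vectors of levels present.
#' @slot cond24 named integer vector, names `group.feedback.emotion`.
#' @slot cond18 named integer vector, names `fcond.emotion` with
#'   feedback-condition levels `NoFeedback`, `FeedbackDOP`, `FeedbackNOP`.
#' @exportClass ConditionIndex
setClass("ConditionIndex",
         slots = c(groups = "character", feedbacks = "character",
                   emotions = "character", cond24 = "integer",
                   cond18 = "integer"))

#' ModelParams: the full parameter set of the accuracy model
#'
#' All scalar parameters of the trial-level model grouped by role: 24
#' condition intercepts (log-odds at full intensity, last trial), 18
#' non-negative reaction-time penalty slopes, 18 learning-curve slopes, and
#' the nine SPQ effect families (3 direct, 3 RT moderation, 3 trial
#' moderation, each over 18 conditions) -- 222 scalars in the full design.
#'
#' @slot index the [ConditionIndex-class] the parameters are laid out over.
#' @slot alpha named numeric, one intercept per `cond24` slot.
#' @slot betaRt named numeric, one RT penalty per `cond18` slot (>= 0).
#' @slot betaTrial named numeric, one learning slope per `cond18` slot.
#' @slot spqDirect,spqRtMod,spqTrialMod 3 x n18 matrices with rows
#'   `CP`, `IN`, `DI` (direct effects, RT moderation, trial moderation).
#' @exportClass ModelParams
setClass("ModelParams",
         slots = c(index = "ConditionIndex", alpha = "numeric",
                   betaRt = "numeric", betaTrial = "numeric",
                   spqDirect = "matrix", spqRtMod = "matrix",
                   spqTrialMod = "matrix"))

#' PosteriorDraws: MCMC draws over ModelParams
#'
#' Post-warmup posterior draws with chain labels, the condition index used
#' for the fit, the resolved sampler configuration and convergence
#' diagnostics.
#'
#' @slot draws numeric matrix, one row per saved draw, one named column per
#'   scalar parameter (natural scale; `beta_rt` columns are non-negative).
#' @slot chain integer vector of chain ids, one per row of `draws`.
#' @slot index the [ConditionIndex-class] of the fit.
#' @slot includeSpq logical, whether SPQ parameter families were sampled.
#' @slot config list, resolved sampler configuration.
#' @slot diagnostics list with elements `rhat` (named vector),
#'   `accept_rate`, `divergences`, `step_size`.
#' @exportClass PosteriorDraws
setClass("PosteriorDraws",
         slots = c(draws = "matrix", chain = "integer",
                   index = "ConditionIndex", includeSpq = "logical",
                   config = "list", diagnostics = "list"))

#' Rope: a region of practical equivalence
#'
#' An interval around a reference value inside which effects are treated as
#' negligible; may be degenerate (`lower == upper`, e.g. the \{0\} ROPE used
#' for reaction-time-penalty contrasts).
#'
#' @slot lower,upper numeric bounds, `lower <= upper`.
#' @slot scale character tag for the scale the bounds live on
#'   (`"percent"`, `"logodds"` or `"proportional"`).
#' @exportClass Rope
setClass("Rope",
         slots = c(lower = "numeric", upper = "numeric", scale = "character"))

setValidity("Rope", function(object) {
  if (length(object@lower) != 1L || length(object@upper) != 1L)
    return("lower and upper must be scalars")
  if (object@lower > object@upper) return("lower must be <= upper")
  TRUE
})

setValidity("ConditionIndex", function(object) {
  msgs <- character()
  n24 <- length(object@groups) * length(object@feedbacks) *
    length(object@emotions)
  if (length(object@cond24) != n24 ||
      !setequal(object@cond24, seq_len(n24)))
    msgs <- c(msgs, "cond24 must be a bijection onto its slots")
  if (anyDuplicated(object@cond18[!duplicated(names(object@cond18))]))
    msgs <- c(msgs, "cond18 slots must be distinct per feedback-condition")
  if (length(msgs)) msgs else TRUE
})

setValidity("ModelParams", function(object) {
  msgs <- character()
  n24 <- length(object@index@cond24)
  n18 <- max(object@index@cond18)
  if (length(object@alpha) != n24)
    msgs <- c(msgs, sprintf("alpha must have %d entries", n24))
  if (length(object@betaRt) != n18 || length(object@betaTrial) != n18)
    msgs <- c(msgs, sprintf("betaRt/betaTrial must have %d entries", n18))
  if (any(object@betaRt < 0))
    msgs <- c(msgs, "betaRt must be non-negative elementwise")
  for (nm in c("spqDirect", "spqRtMod", "spqTrialMod")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(3L, n18)) ||
        !identical(rownames(m), c("CP", "IN", "DI")))
      msgs <- c(msgs, sprintf("%s must be a 3 x %d matrix with rows CP/IN/DI",
                              nm, n18))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TrialDataset", function(object) {
  tr <- object@trials
  cat(sprintf("TrialDataset: %d trials, %d participants",
              nrow(tr), length(unique(tr$participant_id))))
  if (nrow(tr)) {
    tab <- table(unique(tr[, c("participant_id", "group")])$group)
    cat(" (", paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", "), ")", sep = "")
  }
  cat(sprintf("\n  SPQ profiles: %d participants\n", nrow(object@spq)))
})

setMethod("show", "ConditionIndex", function(object) {
  cat(sprintf(paste0("ConditionIndex: %d groups x %d feedback x %d emotions",
                     " -> %d intercept slots, %d slope slots\n"),
              length(object@groups), length(object@feedbacks),
              length(object@emotions), length(object@cond24),
              max(object@cond18)))
})

setMethod("show", "ModelParams", function(object) {
  n <- countParameterSlots(object@index)
  cat(sprintf(paste0("ModelParams: %d scalars (alpha %d, beta_rt %d,",
                     " beta_trial %d, SPQ 9 x %d)\n"),
              n[["cond24"]] + 2L * n[["cond18"]] + 9L * n[["cond18"]],
              n[["cond24"]], n[["cond18"]], n[["cond18"]], n[["cond18"]]))
})

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf("PosteriorDraws: %d draws x %d parameters, %d chains\n",
              nrow(object@draws), ncol(object@draws),
              length(unique(object@chain))))
  rh <- object@diagnostics$rhat
  if (!is.null(rh))
    cat(sprintf("  split R-hat: max %.3f (median %.3f)\n",
                max(rh, na.rm = TRUE), median(rh, na.rm = TRUE)))
})

setMethod("show", "Rope", function(object) {
  cat(sprintf("ROPE [%g, %g] on %s scale\n", object@lower, object@upper,
              object@scale))
})
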