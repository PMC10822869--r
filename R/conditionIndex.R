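#' Build the condition index for a task design
#'
#' Enumerates intercept slots over group x feedback x emotion and slope
#' slots over feedback-condition x emotion. In the no-feedback block both
#' groups share a slope slot per emotion (no group difference in penalties
#' is expected before outcomes differ), while the feedback block carries one
#' slope slot per group per emotion. The full design (2 groups, 2 feedback
#' conditions, 6 emotions) yields 24 intercept and 18 slope slots.
#'
#' @param groups,feedbacks,emotions character vectors of levels; defaults
#'   are the full task design.
#' @return A [ConditionIndex-class].
#' @examples
#' idx <- conditionIndex()
#' countParameterSlots(idx)   # 24 intercepts, 18 slopes
#' @export
conditionIndex <- function(groups = dopferGroups,
                           feedbacks = dopferFeedbacks,
                           emotions = dopferEmotions) {
  stopifnot(length(groups) >= 1, length(feedbacks) >= 1,
            length(emotions) >= 1, !anyDuplicated(groups),
            !anyDuplicated(feedbacks), !anyDuplicated(emotions))
  cells <- expand.grid(emotion = emotions, feedback = feedbacks,
                       group = groups, stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$group, groups),
                       match(cells$feedback, feedbacks),
                       match(cells$emotion, emotions)), ]
  cond24 <- seq_len(nrow(cells))
  names(cond24) <- paste(cells$group, cells$feedback, cells$emotion,
                         sep = ".")

  fconds <- character()
  if ("NoFeedback" %in% feedbacks) fconds <- "NoFeedback"
  if ("Feedback" %in% feedbacks)
    fconds <- c(fconds, paste0("Feedback", groups))
  fcells <- expand.grid(emotion = emotions, fcond = fconds,
                        stringsAsFactors = FALSE)
  fcells <- fcells[order(match(fcells$fcond, fconds),
                         match(fcells$emotion, emotions)), ]
  cond18 <- seq_len(nrow(fcells))
  names(cond18) <- paste(fcells$fcond, fcells$emotion, sep = ".")

  new("ConditionIndex", groups = groups, feedbacks = feedbacks,
      emotions = emotions,
      cond24 = setNames(as.integer(cond24), names(cond24)),
      cond18 = setNames(as.integer(cond18), names(cond18)))
}

#' Derive a condition index from observed data
#'
#' Uses the factor levels present in a dataset, kept in canonical order;
#' an empty dataset yields the full design index.
#'
#' @param dataset a [TrialDataset-class].
#' @return A [ConditionIndex-class].
#' @export
conditionIndexFromData <- function(dataset) {
  tr <- trials(dataset)
  if (!nrow(tr)) return(conditionIndex())
  keep <- function(canon, seen) canon[canon %in% unique(seen)]
  conditionIndex(groups = keep(dopferGroups, tr$group),
                 feedbacks = keep(dopferFeedbacks, tr$feedback),
                 emotions = keep(dopferEmotions, tr$emotion))
}

#' Count distinct parameter slots of a condition index
#'
#' @param index a [ConditionIndex-class].
#' @return Named integer vector `c(cond24 = ..., cond18 = ...)`.
#' @export
countParameterSlots <- function(index) {
  c(cond24 = length(unique(index@cond24)),
    cond18 = length(unique(index@cond18)))
}

#' Look up intercept (cond24) slots for trials
#'
#' @param index a [ConditionIndex-class].
#' @param group,feedback,emotion character vectors (recycled to a common
#'   length).
#' @return Integer slot numbers (1-based).
#' @export
slotCond24 <- function(index, group, feedback, emotion) {
  key <- paste(group, feedback, emotion, sep = ".")
  out <- index@cond24[key]
  if (anyNA(out))
    stop("unknown condition cell(s): ",
         paste(unique(key[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Look up slope (cond18) slots for trials
#'
#' @inheritParams slotCond24
#' @return Integer slot numbers (1-based).
#' @export
slotCond18 <- function(index, group, feedback, emotion) {
  fcond <- ifelse(feedback == "NoFeedback", "NoFeedback",
                  paste0("Feedback", group))
  key <- paste(fcond, emotion, sep = ".")
  out <- index@cond18[key]
  if (anyNA(out))
    stop("unknown feedback-condition cell(s): ",
         paste(unique(key[is.na(out)]), collapse = ", "))
  unname(out)
}
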