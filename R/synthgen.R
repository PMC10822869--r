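## Synthetic-data generator: task design, RTs, SPQ profiles and responses
## simulated from known "true" parameters, for parameter-recovery studies.

#' Design specification for a simulated recognition task
#'
#' Defaults reproduce the study conditions: 88 DOP and 95 NOP participants,
#' 10 actors, six emotions, a no-feedback block followed by a feedback
#' block (60 trials each), and 58/51 SPQ completers per group (109 of 183).
#'
#' @param n_dop,n_nop participants per group.
#' @param n_actors presentations of each emotion per block (actor models).
#' @param emotions emotion labels.
#' @param spq_completers named counts of questionnaire completers per
#'   group, each at most the group size; `NULL` takes the study counts
#'   (58, 51) capped at the group sizes.
#' @param seed integer seed driving the whole generation pipeline.
#' @return Named list (the design spec).
#' @export
designSpec <- function(n_dop = 88, n_nop = 95, n_actors = 10,
                       emotions = dopferEmotions,
                       spq_completers = NULL,
                       seed = 1L) {
  if (is.null(spq_completers))
    spq_completers <- c(DOP = min(58, n_dop), NOP = min(51, n_nop))
  stopifnot(n_dop >= 0, n_nop >= 0, n_actors >= 1, n_actors <= 10,
            length(emotions) >= 1,
            spq_completers[["DOP"]] <= n_dop,
            spq_completers[["NOP"]] <= n_nop)
  list(n_dop = n_dop, n_nop = n_nop, n_actors = n_actors,
       emotions = emotions, blocks = dopferFeedbacks,
       spq_completers = spq_completers, seed = as.integer(seed))
}

#' Lay out the trial skeleton of a simulated task
#'
#' Per participant: two blocks (NoFeedback then Feedback); within each
#' block every emotion appears once per actor in seeded-random order, and
#' `trial_index` counts the running presentations of that emotion within
#' the block (1..n_actors). RT and correctness are left unset.
#'
#' @param spec a [designSpec()].
#' @return data.frame skeleton with columns `participant_id`, `group`,
#'   `block`, `feedback`, `emotion`, `actor_id`, `trial_index`.
#' @export
makeDesign <- function(spec = designSpec()) {
  n <- spec$n_dop + spec$n_nop
  ids <- sprintf("P%03d", seq_len(n))
  groups <- rep(c("DOP", "NOP"), c(spec$n_dop, spec$n_nop))
  set.seed(spec$seed)
  cells <- expand.grid(emotion = spec$emotions,
                       actor_id = seq_len(spec$n_actors),
                       stringsAsFactors = FALSE)
  perBlock <- nrow(cells)
  out <- vector("list", n * 2L)
  k <- 0L
  for (i in seq_len(n)) {
    for (b in 1:2) {
      ord <- cells[sample.int(perBlock), , drop = FALSE]
      ord$trial_index <- stats::ave(seq_len(perBlock), ord$emotion,
                                    FUN = seq_along)
      k <- k + 1L
      out[[k]] <- data.frame(participant_id = ids[i], group = groups[i],
                             block = b, feedback = spec$blocks[b],
                             emotion = ord$emotion,
                             actor_id = ord$actor_id,
                             trial_index = ord$trial_index,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Reaction-time generating law for simulation
#'
#' A per-(feedback-condition, emotion) lognormal location/scale, truncated
#' to (0, 10]. The defaults (median `exp(meanlog)` = 4 s, `sdlog` = 0.45)
#' put most mass over 2-8 s; the task model treats RT as an observed
#' covariate, so this law is fixture machinery only.
#'
#' @param index a [ConditionIndex-class] naming the conditions.
#' @param meanlog,sdlog log-scale location and scale, recycled over the
#'   conditions; `sdlog` must be positive.
#' @return data.frame with columns `fcond_emotion`, `meanlog`, `sdlog`.
#' @export
rtModel <- function(index = conditionIndex(), meanlog = log(4),
                    sdlog = 0.45) {
  if (any(sdlog <= 0)) stop("rt model scale (sdlog) must be positive")
  data.frame(fcond_emotion = names(index@cond18),
             meanlog = rep_len(meanlog, length(index@cond18)),
             sdlog = rep_len(sdlog, length(index@cond18)),
             stringsAsFactors = FALSE)
}

#' Sample reaction times into a design skeleton
#'
#' Draws i.i.d. truncated-lognormal RTs per trial from the law of the
#' trial's feedback-condition x emotion cell, by inverse-CDF sampling on
#' (0, 10].
#'
#' @param skeleton a [makeDesign()] data.frame.
#' @param rt_model an [rtModel()] table.
#' @param seed integer seed.
#' @return `skeleton` with an `rt_seconds` column, all values in (0, 10].
#' @export
sampleRts <- function(skeleton, rt_model = rtModel(), seed = 1L) {
  if (any(rt_model$sdlog <= 0))
    stop("rt model scale (sdlog) must be positive")
  fcond <- ifelse(skeleton$feedback == "NoFeedback", "NoFeedback",
                  paste0("Feedback", skeleton$group))
  key <- paste(fcond, skeleton$emotion, sep = ".")
  m <- match(key, rt_model$fcond_emotion)
  if (anyNA(m))
    stop("rt model is missing condition(s): ",
         paste(unique(key[is.na(m)]), collapse = ", "))
  set.seed(seed)
  u <- runif(nrow(skeleton))
  pmax_cap <- plnorm(10, rt_model$meanlog[m], rt_model$sdlog[m])
  skeleton$rt_seconds <- qlnorm(u * pmax_cap, rt_model$meanlog[m],
                                rt_model$sdlog[m])
  skeleton
}

#' Sample SPQ profiles for a subset of participants
#'
#' Draws standardized factor scores for the chosen completers from a
#' zero-mean unit-variance trivariate normal with the given factor
#' correlation, then back-fills raw scores by a rank-preserving affine map
#' into the 0-33/0-33/0-16 ranges (anchored at realistic sample moments).
#' Only the standardized scores enter the model, so the raw map affects no
#' inference. Non-completers get no profile; completers are sampled
#' uniformly at random within group.
#'
#' @param skeleton a design skeleton (one row per trial; participants and
#'   groups are taken from it).
#' @param completers named counts per group, e.g. `c(DOP = 58, NOP = 51)`.
#' @param correlation 3 x 3 positive-definite factor correlation matrix
#'   (CP, IN, DI); the scalar default 0.5 fills the off-diagonals.
#' @param seed integer seed.
#' @return data.frame of SPQ profiles (raw and standardized columns).
#' @export
sampleSpq <- function(skeleton, completers = c(DOP = 58, NOP = 51),
                      correlation = 0.5, seed = 1L) {
  if (is.matrix(correlation)) R <- correlation
  else { R <- matrix(correlation, 3, 3); diag(R) <- 1 }
  ch <- tryCatch(chol(R), error = function(e)
    stop("factor correlation matrix is not positive definite"))
  pg <- unique(skeleton[, c("participant_id", "group")])
  set.seed(seed)
  chosen <- unlist(lapply(names(completers), function(g) {
    pool <- pg$participant_id[pg$group == g]
    if (completers[[g]] > length(pool))
      stop("completer count exceeds group size for ", g)
    sample(pool, completers[[g]])
  }), use.names = FALSE)
  nC <- length(chosen)
  if (!nC)
    return(data.frame(participant_id = character(), raw_cp = integer(),
                      raw_in = integer(), raw_di = integer(),
                      raw_total = integer(), z_cp = numeric(),
                      z_in = numeric(), z_di = numeric()))
  lat <- matrix(rnorm(nC * 3), nC, 3) %*% ch
  # anchor raw scores at plausible sample moments of the three factors
  anchor <- list(cp = c(m = 9.5, s = 5.9, max = 33),
                 `in` = c(m = 11.9, s = 6.3, max = 33),
                 di = c(m = 4.8, s = 3.6, max = 16))
  prof <- data.frame(participant_id = chosen, stringsAsFactors = FALSE)
  for (j in 1:3) {
    a <- anchor[[j]]
    raw <- as.integer(pmin(a[["max"]],
                           pmax(0, round(a[["m"]] + a[["s"]] * lat[, j]))))
    prof[[paste0("raw_", names(anchor)[j])]] <- raw
  }
  # synthetic Suspiciousness overlap (bounded by both factors and 8 items)
  su <- pmin(8L, pmin(prof$raw_cp, prof$raw_in) %/% 2L)
  prof$raw_total <- prof$raw_cp + prof$raw_in + prof$raw_di - su
  standardizeFactors(prof)
}

#' Simulate trial correctness from true model parameters
#'
#' Draws `correct ~ Bernoulli(p)` with `p` the inverse-logit of the model's
#' linear predictor: the base predictor for participants without an SPQ
#' profile, the SPQ-extended predictor for completers.
#'
#' @param skeleton a design skeleton with `rt_seconds` filled in.
#' @param true_params a [ModelParams-class] used as ground truth.
#' @param spq optional SPQ profile table from [sampleSpq()].
#' @param seed integer seed.
#' @return A validated [TrialDataset-class]; the true parameters are
#'   attached as attribute `"true_params"`.
#' @export
simulateResponses <- function(skeleton, true_params, spq = NULL,
                              seed = 1L) {
  if (is.null(skeleton$rt_seconds))
    stop("skeleton has no rt_seconds; run sampleRts() first")
  z <- .zForTrials(skeleton, spq)
  p <- plogis(linearPredictor(skeleton, true_params, z))
  set.seed(seed)
  skeleton$correct <- rbinom(nrow(skeleton), 1L, p)
  ds <- trialDataset(skeleton, spq = spq)
  attr(ds, "true_params") <- true_params
  ds
}

#' Named true-parameter presets for simulation studies
#'
#' Deterministic, documented parameter sets:
#' * `"null"`: every effect 0 (overall accuracy 0.5 regardless of RT).
#' * `"paper-like"`: condition effects of realistic magnitude -- intercept
#'   accuracies in the 75-99 percent band, RT penalties in \[0.1, 1.8\]
#'   with the NOP-feedback penalty for Fear and Surprise exceeding the
#'   DOP-feedback one, learning slopes in \[-1.2, 1.0\]; all SPQ effects 0.
#' * `"strong-moderation"`: `"paper-like"` plus alternating-sign SPQ direct
#'   effects (0.2) and proportional moderation (0.05).
#'
#' @param name preset name.
#' @param index a [ConditionIndex-class]; restricted designs take the
#'   matching subset of the full-design values.
#' @return A [ModelParams-class] satisfying all parameter constraints.
#' @export
presetTrueParams <- function(name = c("null", "paper-like",
                                      "strong-moderation"),
                             index = conditionIndex()) {
  name <- match.arg(name)
  if (name == "null") return(modelParams(index))

  pct <- list(  # accuracy (%) at full intensity, last trial, per cell
    DOP.Feedback   = c(Anger = 98.7, Disgust = 91.7, Fear = 84.5,
                       Happiness = 99.2, Sadness = 96.8, Surprise = 95.4),
    DOP.NoFeedback = c(Anger = 88.4, Disgust = 84.5, Fear = 75.6,
                       Happiness = 97.7, Sadness = 95.3, Surprise = 93.9),
    NOP.Feedback   = c(Anger = 97.7, Disgust = 91.3, Fear = 93.1,
                       Happiness = 99.8, Sadness = 99.0, Surprise = 98.1),
    NOP.NoFeedback = c(Anger = 90.3, Disgust = 84.2, Fear = 77.6,
                       Happiness = 98.8, Sadness = 94.8, Surprise = 93.8))
  brt <- list(
    NoFeedback  = c(Anger = 0.58, Disgust = 0.85, Fear = 1.18,
                    Happiness = 0.13, Sadness = 0.84, Surprise = 0.38),
    FeedbackDOP = c(Anger = 1.79, Disgust = 0.74, Fear = 0.75,
                    Happiness = 0.45, Sadness = 0.96, Surprise = 0.22),
    FeedbackNOP = c(Anger = 1.24, Disgust = 0.52, Fear = 1.66,
                    Happiness = 1.25, Sadness = 1.42, Surprise = 1.23))
  btr <- list(
    NoFeedback  = c(Anger = -0.75, Disgust = -0.66, Fear = -1.18,
                    Happiness = -0.27, Sadness = -0.61, Surprise = -0.33),
    FeedbackDOP = c(Anger = -0.66, Disgust = -0.58, Fear = -0.71,
                    Happiness = 0.97, Sadness = -0.18, Surprise = -0.14),
    FeedbackNOP = c(Anger = -0.43, Disgust = -0.44, Fear = -0.81,
                    Happiness = 0.70, Sadness = 0.25, Surprise = 0.28))

  split24 <- strsplit(names(index@cond24), ".", fixed = TRUE)
  alpha <- vapply(split24, function(s) {
    p <- min(99, max(75, pct[[paste(s[1], s[2], sep = ".")]][[s[3]]]))
    qlogis(p / 100)
  }, numeric(1))
  split18 <- strsplit(names(index@cond18), ".", fixed = TRUE)
  betaRt <- vapply(split18, function(s) brt[[s[1]]][[s[2]]], numeric(1))
  betaTrial <- vapply(split18, function(s) btr[[s[1]]][[s[2]]], numeric(1))

  n18 <- length(index@cond18)
  sDir <- sRt <- sTr <- matrix(0, 3, n18)
  if (name == "strong-moderation") {
    sgn <- rep_len(c(1, -1), n18)
    sDir <- rbind(0.2 * sgn, -0.2 * sgn, 0.2 * rev(sgn))
    sRt <- rbind(0.05 * sgn, 0.05 * rev(sgn), -0.05 * sgn)
    sTr <- rbind(-0.05 * sgn, 0.05 * sgn, 0.05 * rev(sgn))
  }
  modelParams(index, alpha = alpha, betaRt = betaRt, betaTrial = betaTrial,
              spqDirect = sDir, spqRtMod = sRt, spqTrialMod = sTr)
}

#' Simulate a complete dataset in one call
#'
#' Chains [makeDesign()], [sampleRts()], [sampleSpq()] and
#' [simulateResponses()] with sub-seeds derived from the spec seed, so the
#' whole pipeline is reproducible from one integer.
#'
#' @param spec a [designSpec()].
#' @param true_params a [ModelParams-class] or a preset name for
#'   [presetTrueParams()].
#' @param rt_model an [rtModel()] table (defaults to the spec's index).
#' @param index optional [ConditionIndex-class]; by default built from the
#'   spec's emotions over the full group/feedback design.
#' @return A [TrialDataset-class] with attribute `"true_params"`.
#' @export
simulateDataset <- function(spec = designSpec(),
                            true_params = "paper-like",
                            rt_model = NULL, index = NULL) {
  if (is.null(index))
    index <- conditionIndex(emotions = spec$emotions)
  if (is.character(true_params))
    true_params <- presetTrueParams(true_params, index)
  if (is.null(rt_model)) rt_model <- rtModel(index)
  sk <- makeDesign(spec)
  sk <- sampleRts(sk, rt_model, seed = spec$seed + 1L)
  spq <- if (sum(spec$spq_completers) > 0)
    sampleSpq(sk, spec$spq_completers, seed = spec$seed + 2L)
  else NULL
  simulateResponses(sk, true_params, spq = spq, seed = spec$seed + 3L)
}
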