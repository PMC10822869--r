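## HDI + ROPE machinery, posterior contrasts, summary tables and
## posterior-predictive grids.

#' Highest density interval of a sample
#'
#' The shortest contiguous interval containing `ceil(mass * n)` of the
#' sorted draws, found by exhaustive window search; ties are broken toward
#' the leftmost shortest window, so the result is deterministic.
#'
#' @param draws numeric vector of posterior draws.
#' @param mass interval probability mass (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!length(draws)) stop("hdi of an empty sample")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[seq.int(k, n)] - x[seq_len(n - k + 1L)]
  j <- which.min(widths)          # which.min takes the first (leftmost) tie
  c(lower = x[j], upper = x[j + k - 1L])
}

#' Build a region of practical equivalence
#'
#' @param lower,upper interval bounds (`lower == upper` gives a degenerate
#'   ROPE such as \{0\}).
#' @param scale scale tag: `"percent"`, `"logodds"` or `"proportional"`.
#' @return A [Rope-class].
#' @export
rope <- function(lower, upper = lower,
                 scale = c("logodds", "percent", "proportional")) {
  new("Rope", lower = lower, upper = upper, scale = match.arg(scale))
}

#' Three-way HDI + ROPE decision
#'
#' `"credible"` when the HDI completely excludes the ROPE (disjoint,
#' endpoints included -- touching intervals overlap), `"negligible"` when
#' the HDI lies entirely within the ROPE, `"withheld"` otherwise. For a
#' degenerate \{0\} ROPE the decision is credible exactly when 0 is outside
#' the HDI.
#'
#' @param interval named numeric `c(lower, upper)` from [hdi()].
#' @param rope a [Rope-class].
#' @return One of `"credible"`, `"negligible"`, `"withheld"`.
#' @export
ropeDecision <- function(interval, rope) {
  lo <- interval[["lower"]]; hi <- interval[["upper"]]
  if (hi < rope@lower || lo > rope@upper) return("credible")
  if (lo >= rope@lower && hi <= rope@upper) return("negligible")
  "withheld"
}

#' ROPE half-width for a probability change on the log-odds scale
#'
#' The log-odds displacement that shifts a reference probability by
#' `delta_p` (e.g. by 5 percentage points, half the per-participant
#' resolution of a 10-trial condition), optionally spread over a span of
#' standard deviations of a standardized predictor. At reference log-odds 0
#' and `delta_p = 0.05` the half-width is `qlogis(0.55)` (about 0.2); over
#' a 2-SD span the per-SD half-width is about 0.1.
#'
#' @param delta_p probability change, in (0, 0.5).
#' @param reference_logodds comparison point on the log-odds scale.
#' @param sd_span number of predictor standard deviations the change is
#'   spread over (1 = the raw log-odds bound).
#' @return Scalar half-width (log-odds, per SD when `sd_span > 1`).
#' @export
ropeHalfwidthProbability <- function(delta_p = 0.05,
                                     reference_logodds = 0, sd_span = 1) {
  stopifnot(delta_p >= 0, delta_p < 0.5, sd_span > 0)
  (qlogis(plogis(reference_logodds) + delta_p) - reference_logodds) /
    sd_span
}

#' ROPE half-width for proportional moderation effects
#'
#' The per-SD proportional change bound: a `delta_effect` change in an
#' effect's magnitude spread over `sd_span` standard deviations of the
#' moderator. Defaults (1% over 2 SDs) give 0.005.
#'
#' @param delta_effect proportional change in the moderated effect.
#' @param sd_span standard-deviation span of the moderator.
#' @return Scalar half-width on the proportional scale.
#' @export
ropeHalfwidthModeration <- function(delta_effect = 0.01, sd_span = 2) {
  stopifnot(delta_effect >= 0, sd_span > 0)
  delta_effect / sd_span
}

#' ROPE half-width for accuracy contrasts in percentage points
#'
#' Half the per-participant detection resolution of a condition with
#' `n_trials` trials: with 10 trials per condition accuracy moves in 10%
#' steps, so a change under 5 percentage points (half a correct response
#' per individual) is treated as negligible.
#'
#' @param n_trials trials per condition per participant.
#' @return Half-width in percentage points (5.0 for the default design).
#' @export
ropeHalfwidthAccuracy <- function(n_trials = 10) {
  stopifnot(n_trials >= 1)
  100 / n_trials / 2
}

#' Map intercept draws to accuracy percentages
#'
#' `100 * plogis(alpha)`: the probability (in percent) of a correct
#' response at full intensity in the last trial of a condition.
#'
#' @param alpha_draws numeric log-odds draws.
#' @return Percent draws.
#' @export
alphaToPercent <- function(alpha_draws) 100 * plogis(alpha_draws)

#' Posterior contrasts by draw-wise subtraction
#'
#' `contrastDraws` subtracts aligned draws (`a - b` per draw);
#' `doubleContrast` forms the difference of differences
#' `(a1 - a0) - (b1 - b0)` per draw.
#'
#' @param a,b,a1,a0,b1,b0 numeric draw vectors of equal length in aligned
#'   draw order.
#' @return Numeric vector of difference draws.
#' @export
contrastDraws <- function(a, b) {
  if (length(a) != length(b)) stop("draw vectors must have equal length")
  a - b
}

#' @rdname contrastDraws
#' @export
doubleContrast <- function(a1, a0, b1, b0) {
  contrastDraws(contrastDraws(a1, a0), contrastDraws(b1, b0))
}

.summRow <- function(emotion, quantity, draws, rp = NULL, mass = 0.95) {
  h <- hdi(draws, mass)
  data.frame(emotion = emotion, quantity = quantity,
             mean = mean(draws), hdi_lower = h[["lower"]],
             hdi_upper = h[["upper"]],
             rope_lower = if (is.null(rp)) NA_real_ else rp@lower,
             rope_upper = if (is.null(rp)) NA_real_ else rp@upper,
             decision = if (is.null(rp)) NA_character_
                        else ropeDecision(h, rp),
             credible = if (is.null(rp)) NA
                        else ropeDecision(h, rp) == "credible",
             stringsAsFactors = FALSE)
}

#' Accuracy summary table (intercepts on the percent scale)
#'
#' Per emotion: posterior mean and 95% HDI of accuracy (percent) in each
#' group x feedback cell, the Feedback - NoFeedback change per group, and
#' the DOP - NOP difference of those changes, with decisions against the
#' (-5, 5) percentage-point ROPE on all three contrasts.
#'
#' @param samples a [PosteriorDraws-class].
#' @param rope_pct accuracy-contrast ROPE half-width in percentage points.
#' @param mass HDI mass.
#' @return Tidy data.frame, one row per emotion x quantity (7 quantities
#'   per emotion in the full design).
#' @export
buildTableAlpha <- function(samples, rope_pct = ropeHalfwidthAccuracy(),
                            mass = 0.95) {
  idx <- samples@index
  rp <- rope(-rope_pct, rope_pct, scale = "percent")
  out <- list()
  for (em in idx@emotions) {
    cell <- list()
    for (g in idx@groups)
      for (fb in idx@feedbacks) {
        d <- alphaToPercent(drawsFor(samples, "alpha",
                                     paste(g, fb, em, sep = ".")))
        cell[[paste(g, fb, sep = ".")]] <- d
        out[[length(out) + 1L]] <- .summRow(em, paste(g, fb, sep = "."),
                                            d, NULL, mass)
      }
    diffs <- list()
    if (all(dopferFeedbacks %in% idx@feedbacks))
      for (g in idx@groups) {
        diffs[[g]] <- contrastDraws(cell[[paste0(g, ".Feedback")]],
                                    cell[[paste0(g, ".NoFeedback")]])
        out[[length(out) + 1L]] <- .summRow(
          em, paste0(g, ".FeedbackVsNoFeedback"), diffs[[g]], rp, mass)
      }
    if (all(dopferGroups %in% names(diffs)))
      out[[length(out) + 1L]] <- .summRow(
        em, "DOPvsNOP", contrastDraws(diffs[["DOP"]], diffs[["NOP"]]),
        rp, mass)
  }
  do.call(rbind, out)
}

#' Reaction-time penalty summary table
#'
#' Per emotion: posterior mean and 95% HDI of the RT penalty in each
#' feedback condition (NoFeedback shared, FeedbackDOP, FeedbackNOP) and
#' the FeedbackDOP - FeedbackNOP contrast judged against the degenerate
#' \{0\} ROPE (credible when the HDI excludes 0).
#'
#' @inheritParams buildTableAlpha
#' @return Tidy data.frame, one row per emotion x quantity.
#' @export
buildTableBetaRt <- function(samples, mass = 0.95) {
  idx <- samples@index
  fconds <- unique(sub("\\..*$", "", names(idx@cond18)))
  rp <- rope(0, 0, scale = "logodds")
  out <- list()
  for (em in idx@emotions) {
    d <- lapply(setNames(fconds, fconds), function(fc)
      drawsFor(samples, "beta_rt", paste(fc, em, sep = ".")))
    for (fc in fconds)
      out[[length(out) + 1L]] <- .summRow(em, fc, d[[fc]], NULL, mass)
    if (all(c("FeedbackDOP", "FeedbackNOP") %in% fconds))
      out[[length(out) + 1L]] <- .summRow(
        em, "FeedbackDOPvsFeedbackNOP",
        contrastDraws(d[["FeedbackDOP"]], d[["FeedbackNOP"]]), rp, mass)
  }
  do.call(rbind, out)
}

#' Learning-curve summary table
#'
#' Per emotion: posterior mean and 95% HDI of the learning slope in each
#' feedback condition, plus the three pairwise feedback-condition
#' contrasts judged against the (-0.2, 0.2) log-odds ROPE. Contrast sign
#' follows the column label (left minus right) by default.
#'
#' @inheritParams buildTableAlpha
#' @param rope_halfwidth learning-curve ROPE half-width (log-odds).
#' @param sign `"first-minus-second"` (default, matches the printed
#'   labels) or `"second-minus-first"`.
#' @return Tidy data.frame, one row per emotion x quantity.
#' @export
buildTableBetaTrial <- function(samples,
                                rope_halfwidth =
                                  round(ropeHalfwidthProbability(), 1),
                                sign = c("first-minus-second",
                                         "second-minus-first"),
                                mass = 0.95) {
  sign <- match.arg(sign)
  flip <- if (sign == "first-minus-second") 1 else -1
  idx <- samples@index
  fconds <- unique(sub("\\..*$", "", names(idx@cond18)))
  rp <- rope(-rope_halfwidth, rope_halfwidth, scale = "logodds")
  pairs <- list(NoFeedbackVsFeedbackNOP = c("NoFeedback", "FeedbackNOP"),
                NoFeedbackVsFeedbackDOP = c("NoFeedback", "FeedbackDOP"),
                FeedbackDOPvsFeedbackNOP = c("FeedbackDOP", "FeedbackNOP"))
  out <- list()
  for (em in idx@emotions) {
    d <- lapply(setNames(fconds, fconds), function(fc)
      drawsFor(samples, "beta_trial", paste(fc, em, sep = ".")))
    for (fc in fconds)
      out[[length(out) + 1L]] <- .summRow(em, fc, d[[fc]], rp, mass)
    for (nm in names(pairs)) {
      pq <- pairs[[nm]]
      if (all(pq %in% fconds))
        out[[length(out) + 1L]] <- .summRow(
          em, nm, flip * contrastDraws(d[[pq[1]]], d[[pq[2]]]), rp, mass)
    }
  }
  do.call(rbind, out)
}

#' SPQ effect summary (direct and moderation families)
#'
#' Posterior mean, 95% HDI and ROPE decision for each of the nine SPQ
#' parameter families in every feedback-condition x emotion cell: direct
#' effects against (-0.1, 0.1) log-odds per SD, moderation effects against
#' (-0.005, 0.005) proportional per SD. The full design yields
#' 18 x 9 = 162 rows.
#'
#' @param samples a [PosteriorDraws-class] from an SPQ-bearing fit.
#' @param rope_direct,rope_moderation ROPE half-widths.
#' @param mass HDI mass.
#' @return Tidy data.frame with columns `condition`, `family`, `mean`,
#'   `hdi_lower`, `hdi_upper`, `rope_lower`, `rope_upper`, `decision`,
#'   `credible`.
#' @export
spqEffectSummary <- function(samples,
                             rope_direct =
                               ropeHalfwidthProbability(sd_span = 2),
                             rope_moderation = ropeHalfwidthModeration(),
                             mass = 0.95) {
  if (!samples@includeSpq)
    stop("this fit has no SPQ parameter families")
  rope_direct <- round(rope_direct, 1)
  direct <- c("beta_cp", "beta_in", "beta_di")
  out <- list()
  for (cond in names(samples@index@cond18))
    for (fam in spqFamilies) {
      rp <- if (fam %in% direct)
        rope(-rope_direct, rope_direct, scale = "logodds")
      else rope(-rope_moderation, rope_moderation, scale = "proportional")
      row <- .summRow(NA_character_, fam, drawsFor(samples, fam, cond),
                      rp, mass)
      row$emotion <- NULL
      row <- cbind(data.frame(condition = cond, family = fam,
                              stringsAsFactors = FALSE),
                   row[, setdiff(names(row), "quantity")])
      out[[length(out) + 1L]] <- row
    }
  do.call(rbind, out)
}

#' Posterior-predictive probabilities over a covariate grid
#'
#' For each grid point the linear predictor is evaluated per posterior
#' draw and mapped through the inverse logit; the draws of `p` are
#' summarized by their mean and 95% HDI. SPQ scores default to 0 (the
#' completer mean) unless `z_cp`/`z_in`/`z_di` columns are supplied.
#'
#' @param samples a [PosteriorDraws-class].
#' @param grid data.frame with columns `group`, `feedback`, `emotion`,
#'   `rt_seconds`, `trial_index` (see [ppGridFullIntensity()],
#'   [ppGridRtBins()], [ppGridTrials()]).
#' @param mass HDI mass.
#' @return `grid` with `p_mean`, `p_lower`, `p_upper` columns appended.
#' @export
posteriorPredictive <- function(samples, grid, mass = 0.95) {
  idx <- samples@index
  c24 <- slotCond24(idx, grid$group, grid$feedback, grid$emotion)
  c18 <- slotCond18(idx, grid$group, grid$feedback, grid$emotion)
  xrt <- rtCovariate(grid$rt_seconds)
  xtr <- trialCovariate(grid$trial_index)
  dm <- samples@draws
  nms <- colnames(dm)
  a <- dm[, sprintf("alpha[%s]", names(idx@cond24))[c24], drop = FALSE]
  b <- dm[, sprintf("beta_rt[%s]", names(idx@cond18))[c18], drop = FALSE]
  tt <- dm[, sprintf("beta_trial[%s]", names(idx@cond18))[c18],
           drop = FALSE]
  zc <- grid$z_cp %||% rep(0, nrow(grid))
  zi <- grid$z_in %||% rep(0, nrow(grid))
  zd <- grid$z_di %||% rep(0, nrow(grid))
  useSpq <- samples@includeSpq && any(c(zc, zi, zd) != 0)
  eta <- sweep(b, 2, xrt, "*") + sweep(tt, 2, xtr, "*") + a
  if (useSpq) {
    pick <- function(fam) dm[, sprintf("%s[%s]", fam,
                                       names(idx@cond18))[c18],
                             drop = FALSE]
    direct <- sweep(pick("beta_cp"), 2, zc, "*") +
      sweep(pick("beta_in"), 2, zi, "*") +
      sweep(pick("beta_di"), 2, zd, "*")
    mrt <- sweep(pick("beta_cp_rt"), 2, zc, "*") +
      sweep(pick("beta_in_rt"), 2, zi, "*") +
      sweep(pick("beta_di_rt"), 2, zd, "*")
    mtr <- sweep(pick("beta_cp_trial"), 2, zc, "*") +
      sweep(pick("beta_in_trial"), 2, zi, "*") +
      sweep(pick("beta_di_trial"), 2, zd, "*")
    eta <- a + sweep(b * (1 + mrt), 2, xrt, "*") +
      sweep(tt * (1 + mtr), 2, xtr, "*") + direct
  }
  p <- plogis(eta)
  grid$p_mean <- colMeans(p)
  hs <- apply(p, 2, hdi, mass = mass)
  grid$p_lower <- hs["lower", ]
  grid$p_upper <- hs["upper", ]
  grid
}

#' Built-in posterior-predictive grids
#'
#' `ppGridFullIntensity()`: every condition at full intensity (RT = 10 s)
#' in the last trial, where both covariate terms vanish.
#' `ppGridRtBins()`: RT aggregated in `n_bins` equal bins from `from` to
#' `to` seconds, predictions at bin centres (15 bins over 1-10 s give a
#' 0.6-s width and a first centre at 1.3 s), at the last trial.
#' `ppGridTrials()`: trials 1..10 at full intensity.
#'
#' @param index a [ConditionIndex-class].
#' @param n_bins,from,to RT binning of the predictive grid.
#' @return data.frame grid for [posteriorPredictive()].
#' @name ppGrids
#' @export
ppGridFullIntensity <- function(index = conditionIndex()) {
  g <- expand.grid(emotion = index@emotions, feedback = index@feedbacks,
                   group = index@groups, stringsAsFactors = FALSE)
  g$rt_seconds <- 10
  g$trial_index <- 10L
  g[, c("group", "feedback", "emotion", "rt_seconds", "trial_index")]
}

#' @rdname ppGrids
#' @export
ppGridRtBins <- function(index = conditionIndex(), n_bins = 15, from = 1,
                         to = 10) {
  width <- (to - from) / n_bins
  centers <- from + width * (seq_len(n_bins) - 0.5)
  base <- ppGridFullIntensity(index)
  g <- merge(base[, c("group", "feedback", "emotion")],
             data.frame(rt_seconds = centers), by = NULL)
  g$trial_index <- 10L
  g[order(g$group, g$feedback, g$emotion, g$rt_seconds), ]
}

#' @rdname ppGrids
#' @export
ppGridTrials <- function(index = conditionIndex()) {
  base <- ppGridFullIntensity(index)
  g <- merge(base[, c("group", "feedback", "emotion")],
             data.frame(trial_index = 1:10), by = NULL)
  g$rt_seconds <- 10
  g[order(g$group, g$feedback, g$emotion, g$trial_index),
    c("group", "feedback", "emotion", "rt_seconds", "trial_index")]
}
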