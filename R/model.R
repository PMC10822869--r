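#' Prior specification of the accuracy model
#'
#' Fixed prior constants: intercepts `alpha ~ Normal(0, 1.5)`, RT penalties
#' `beta_RT ~ HalfNormal(0, 1)` (positive half of a normal), learning
#' slopes `beta_Trial ~ Normal(0, 1)`, SPQ direct effects `~ Normal(0,
#' 0.25)` and all six moderation families `~ Normal(0, 0.1)`. Second
#' arguments are standard deviations.
#'
#' @param sd_alpha,sd_beta_rt,sd_beta_trial,sd_spq_direct,sd_spq_mod prior
#'   standard deviations.
#' @return A named list of prior SDs.
#' @export
priorSpec <- function(sd_alpha = 1.5, sd_beta_rt = 1, sd_beta_trial = 1,
                      sd_spq_direct = 0.25, sd_spq_mod = 0.1) {
  stopifnot(sd_alpha > 0, sd_beta_rt > 0, sd_beta_trial > 0,
            sd_spq_direct > 0, sd_spq_mod > 0)
  list(sd_alpha = sd_alpha, sd_beta_rt = sd_beta_rt,
       sd_beta_trial = sd_beta_trial, sd_spq_direct = sd_spq_direct,
       sd_spq_mod = sd_spq_mod)
}

#' Reaction-time (intensity) covariate
#'
#' `log(rt / 10)`: 0 at the 10-s cap (full intensity, no penalty) and
#' decreasing to -Inf as the response approaches 0 s, so that early
#' responses are penalized progressively more steeply.
#'
#' @param rt_seconds reaction times in seconds, each in (0, 10].
#' @return `log(rt_seconds / 10)`, in (-Inf, 0].
#' @examples
#' rtCovariate(10)      # 0: full intensity
#' rtCovariate(10 / exp(1))  # -1
#' @export
rtCovariate <- function(rt_seconds) {
  if (any(!is.finite(rt_seconds)) || any(rt_seconds <= 0) ||
      any(rt_seconds > 10))
    stop("rt_seconds must be in (0, 10]")
  log(rt_seconds / 10)
}

#' Learning-curve (trial) covariate
#'
#' `((10 - t) / 9)^e`: 1 at the first presentation of an emotion within a
#' block and 0 at the tenth (last), decreasing convexly so that learning is
#' fastest over the earliest trials and flattens towards an asymptote.
#'
#' @param trial_index integer trial positions in 1..10.
#' @return `((10 - trial_index) / 9)^exp(1)`, in \[0, 1\].
#' @examples
#' trialCovariate(1)   # 1
#' trialCovariate(10)  # 0
#' @export
trialCovariate <- function(trial_index) {
  if (any(trial_index != round(trial_index)) || any(trial_index < 1) ||
      any(trial_index > 10))
    stop("trial_index must be an integer in 1..10")
  ((10 - trial_index) / 9)^exp(1)
}

## z matrix (n x 3, cols z_cp/z_in/z_di) aligned to a trial table; rows of
## participants without a profile are NA.
.zForTrials <- function(tr, spq) {
  z <- matrix(NA_real_, nrow(tr), 3,
              dimnames = list(NULL, c("z_cp", "z_in", "z_di")))
  if (!is.null(spq) && nrow(spq) && all(c("z_cp", "z_in", "z_di") %in%
                                        names(spq))) {
    m <- match(tr$participant_id, spq$participant_id)
    ok <- !is.na(m)
    z[ok, ] <- as.matrix(spq[m[ok], c("z_cp", "z_in", "z_di")])
  }
  z
}

#' Trial-level linear predictor (log-odds of a correct response)
#'
#' Without SPQ scores the predictor is
#' `alpha[c24] + beta_RT[c18] * log(RT/10) + beta_Trial[c18] *
#' ((10 - Trial)/9)^e`. For trials with standardized SPQ factor scores the
#' direct terms `beta_CP*CP + beta_IN*IN + beta_DI*DI` are added and each
#' slope is multiplied by `(1 + beta_CP_.*CP + beta_IN_.*IN + beta_DI_.*DI)`
#' (proportional moderation). All slopes are indexed by the trial's
#' feedback-condition slot.
#'
#' @param tr data.frame with columns `group`, `feedback`, `emotion`,
#'   `rt_seconds`, `trial_index` (and `participant_id` if `z` comes from a
#'   dataset).
#' @param params a [ModelParams-class].
#' @param z optional n x 3 matrix of standardized SPQ scores (columns CP,
#'   IN, DI); rows of NA mark participants without a questionnaire, whose
#'   predictor uses the base model only.
#' @return Numeric vector of log-odds, one per row of `tr`.
#' @export
linearPredictor <- function(tr, params, z = NULL) {
  idx <- params@index
  c24 <- slotCond24(idx, tr$group, tr$feedback, tr$emotion)
  c18 <- slotCond18(idx, tr$group, tr$feedback, tr$emotion)
  xrt <- rtCovariate(tr$rt_seconds)
  xtr <- trialCovariate(tr$trial_index)
  if (is.null(z))
    z <- matrix(NA_real_, nrow(tr), 3)
  has <- !is.na(z[, 1])
  zz <- z
  zz[!has, ] <- 0
  d <- params@spqDirect[, c18, drop = FALSE]
  mrt <- params@spqRtMod[, c18, drop = FALSE]
  mtr <- params@spqTrialMod[, c18, drop = FALSE]
  direct <- colSums(d * t(zz))
  modrt <- colSums(mrt * t(zz))
  modtr <- colSums(mtr * t(zz))
  unname(params@alpha[c24] +
           params@betaRt[c18] * (1 + modrt) * xrt +
           params@betaTrial[c18] * (1 + modtr) * xtr +
           direct)
}

#' Bernoulli log-likelihood of a dataset
#'
#' Sum over trials of `correct*log(p) + (1-correct)*log(1-p)` with
#' `p = plogis(linear predictor)`. Participants without SPQ profiles
#' contribute through the base predictor, completers through the
#' SPQ-extended one -- a single joint likelihood with shared condition
#' parameters. Evaluated in the numerically safe form
#' `-log1p(exp(-sign * eta))`, which cannot round to `-Inf` for finite
#' log-odds.
#'
#' @param dataset a [TrialDataset-class].
#' @param params a [ModelParams-class].
#' @return Scalar log-likelihood.
#' @export
logLikelihood <- function(dataset, params) {
  tr <- trials(dataset)
  if (!nrow(tr)) return(0)
  z <- .zForTrials(tr, spqProfiles(dataset))
  eta <- linearPredictor(tr, params, z)
  s <- ifelse(tr$correct == 1, 1, -1)
  sum(-log1p(exp(-s * eta)))
}

.halfNormLogDens <- function(x, sd) {
  ifelse(x < 0, -Inf, log(2) + dnorm(x, 0, sd, log = TRUE))
}

#' Log prior density of the model parameters
#'
#' Sum of the six prior families' log densities; `-Inf` exactly when any RT
#' penalty is negative (outside the half-normal support).
#'
#' @param params a [ModelParams-class].
#' @param priors a [priorSpec()] list.
#' @return Scalar log prior density.
#' @export
logPrior <- function(params, priors = priorSpec()) {
  if (any(params@betaRt < 0)) return(-Inf)
  sum(dnorm(params@alpha, 0, priors$sd_alpha, log = TRUE)) +
    sum(.halfNormLogDens(params@betaRt, priors$sd_beta_rt)) +
    sum(dnorm(params@betaTrial, 0, priors$sd_beta_trial, log = TRUE)) +
    sum(dnorm(params@spqDirect, 0, priors$sd_spq_direct, log = TRUE)) +
    sum(dnorm(params@spqRtMod, 0, priors$sd_spq_mod, log = TRUE)) +
    sum(dnorm(params@spqTrialMod, 0, priors$sd_spq_mod, log = TRUE))
}

#' Log posterior density (unnormalized)
#'
#' `logLikelihood + logPrior`; finite on the constrained parameter space
#' and `-Inf` off it.
#'
#' @inheritParams logLikelihood
#' @param priors a [priorSpec()] list.
#' @return Scalar unnormalized log posterior.
#' @export
logPosterior <- function(dataset, params, priors = priorSpec()) {
  lp <- logPrior(params, priors)
  if (!is.finite(lp)) return(lp)
  lp + logLikelihood(dataset, params)
}

## Pack a dataset into the flat arrays the C++ kernel consumes.
.modelData <- function(dataset, index) {
  tr <- trials(dataset)
  if (!nrow(tr))
    return(list(correct = integer(), c24 = integer(), c18 = integer(),
                xrt = numeric(), xtr = numeric(),
                z = matrix(0, 0, 3), has_spq = logical()))
  z <- .zForTrials(tr, spqProfiles(dataset))
  has <- !is.na(z[, 1])
  z[!has, ] <- 0
  list(correct = as.integer(tr$correct),
       c24 = slotCond24(index, tr$group, tr$feedback, tr$emotion) - 1L,
       c18 = slotCond18(index, tr$group, tr$feedback, tr$emotion) - 1L,
       xrt = rtCovariate(tr$rt_seconds),
       xtr = trialCovariate(tr$trial_index),
       z = unname(z), has_spq = has)
}

## Unconstrained-scale log posterior + gradient (Rcpp kernel). theta uses
## u = log(beta_rt); value includes the exact log-Jacobian sum(u).
.lpGrad <- function(theta, md, index, includeSpq, priors = priorSpec()) {
  n <- countParameterSlots(index)
  lpGradCpp(theta, md$correct, md$c24, md$c18, md$xrt, md$xtr, md$z,
            md$has_spq, n[["cond24"]], n[["cond18"]], includeSpq,
            c(priors$sd_alpha, priors$sd_beta_rt, priors$sd_beta_trial,
              priors$sd_spq_direct, priors$sd_spq_mod))
}

## natural-scale vector -> unconstrained theta and back
.toUnconstrained <- function(v, n24, n18) {
  i <- seq.int(n24 + 1L, n24 + n18)
  v[i] <- log(pmax(v[i], 1e-8))
  v
}

.toConstrained <- function(theta, n24, n18) {
  i <- seq.int(n24 + 1L, n24 + n18)
  theta[i] <- exp(theta[i])
  theta
}
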