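## Parameter container, canonical naming and (un)flattening.

spqFamilies <- c("beta_cp", "beta_in", "beta_di",
                 "beta_cp_rt", "beta_in_rt", "beta_di_rt",
                 "beta_cp_trial", "beta_in_trial", "beta_di_trial")

#' Construct a ModelParams object
#'
#' Builds the full parameter set over a condition index. Unspecified
#' components default to zero (a valid "null" parameterization).
#'
#' @param index a [ConditionIndex-class].
#' @param alpha numeric of length `n24` (intercept log-odds).
#' @param betaRt numeric of length `n18`, non-negative (RT penalties).
#' @param betaTrial numeric of length `n18` (learning-curve slopes).
#' @param spqDirect,spqRtMod,spqTrialMod 3 x `n18` matrices (rows CP, IN,
#'   DI) of SPQ direct effects and proportional moderation coefficients.
#' @return A validated [ModelParams-class].
#' @export
modelParams <- function(index = conditionIndex(),
                        alpha = NULL, betaRt = NULL, betaTrial = NULL,
                        spqDirect = NULL, spqRtMod = NULL,
                        spqTrialMod = NULL) {
  n <- countParameterSlots(index)
  n24 <- n[["cond24"]]; n18 <- n[["cond18"]]
  zmat <- function(m) {
    if (is.null(m)) m <- matrix(0, 3L, n18)
    rownames(m) <- c("CP", "IN", "DI")
    colnames(m) <- names(index@cond18)
    m
  }
  vec <- function(v, len, nms) {
    if (is.null(v)) v <- numeric(len)
    setNames(as.numeric(v), nms)
  }
  new("ModelParams", index = index,
      alpha = vec(alpha, n24, names(index@cond24)),
      betaRt = vec(betaRt, n18, names(index@cond18)),
      betaTrial = vec(betaTrial, n18, names(index@cond18)),
      spqDirect = zmat(spqDirect), spqRtMod = zmat(spqRtMod),
      spqTrialMod = zmat(spqTrialMod))
}

#' Canonical scalar parameter names
#'
#' One name per scalar parameter, e.g. `alpha[DOP.Feedback.Anger]` or
#' `beta_cp_rt[FeedbackNOP.Fear]`, in the flattening order used by the
#' sampler and by [paramVector()].
#'
#' @param index a [ConditionIndex-class].
#' @param includeSpq include the nine SPQ families?
#' @return Character vector of parameter names.
#' @export
paramNames <- function(index, includeSpq = TRUE) {
  c24 <- names(index@cond24); c18 <- names(index@cond18)
  nms <- c(sprintf("alpha[%s]", c24),
           sprintf("beta_rt[%s]", c18),
           sprintf("beta_trial[%s]", c18))
  if (includeSpq)
    nms <- c(nms, unlist(lapply(spqFamilies,
                                function(f) sprintf("%s[%s]", f, c18))))
  nms
}

#' Flatten ModelParams to a named numeric vector
#'
#' @param params a [ModelParams-class].
#' @param includeSpq include the nine SPQ families?
#' @return Named numeric vector in [paramNames()] order.
#' @export
paramVector <- function(params, includeSpq = TRUE) {
  v <- c(params@alpha, params@betaRt, params@betaTrial)
  if (includeSpq)
    v <- c(v, t(params@spqDirect)[, "CP"], t(params@spqDirect)[, "IN"],
           t(params@spqDirect)[, "DI"],
           t(params@spqRtMod)[, "CP"], t(params@spqRtMod)[, "IN"],
           t(params@spqRtMod)[, "DI"],
           t(params@spqTrialMod)[, "CP"], t(params@spqTrialMod)[, "IN"],
           t(params@spqTrialMod)[, "DI"])
  setNames(as.numeric(v), paramNames(params@index, includeSpq))
}

#' Rebuild ModelParams from a flat vector
#'
#' Inverse of [paramVector()]; missing SPQ blocks are filled with zeros.
#'
#' @param v numeric vector in [paramNames()] order.
#' @param index a [ConditionIndex-class].
#' @param includeSpq whether `v` carries the SPQ families.
#' @return A [ModelParams-class].
#' @export
paramsFromVector <- function(v, index, includeSpq = TRUE) {
  n <- countParameterSlots(index)
  n24 <- n[["cond24"]]; n18 <- n[["cond18"]]
  need <- n24 + 2L * n18 + if (includeSpq) 9L * n18 else 0L
  if (length(v) != need)
    stop(sprintf("expected %d parameters, got %d", need, length(v)))
  at <- function(i, k) v[seq.int(i + 1L, i + k)]
  i <- 0L
  alpha <- at(i, n24); i <- i + n24
  brt <- at(i, n18); i <- i + n18
  btr <- at(i, n18); i <- i + n18
  mats <- list(spqDirect = NULL, spqRtMod = NULL, spqTrialMod = NULL)
  if (includeSpq)
    for (nm in names(mats)) {
      m <- matrix(0, 3L, n18, dimnames = list(c("CP", "IN", "DI"), NULL))
      for (r in 1:3) { m[r, ] <- at(i, n18); i <- i + n18 }
      mats[[nm]] <- m
    }
  modelParams(index, alpha = alpha, betaRt = brt, betaTrial = btr,
              spqDirect = mats$spqDirect, spqRtMod = mats$spqRtMod,
              spqTrialMod = mats$spqTrialMod)
}

#' @rdname trials
#' @export
spqProfiles <- function(dataset) dataset@spq

#' Accessors for TrialDataset
#'
#' `trials()` returns the trial table; `spqProfiles()` the SPQ factor-score
#' table (zero rows when absent).
#'
#' @param dataset a [TrialDataset-class].
#' @return A data.frame.
#' @export
trials <- function(dataset) dataset@trials
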