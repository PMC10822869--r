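#' Item-to-subscale key of the Schizotypal Personality Questionnaire
#'
#' The standard published allocation of the 74 dichotomous SPQ items to the
#' nine subscales (Ideas of Reference 9 items, Excessive Social Anxiety 8,
#' Odd Beliefs or Magical Thinking 7, Unusual Perceptual Experiences 9,
#' Odd or Eccentric Behaviour 7, No Close Friends 9, Odd Speech 9,
#' Constricted Affect 8, Suspiciousness 8). This is the only allocation
#' consistent with the three-factor score ranges 0-33 (Cognitive-
#' Perceptual), 0-33 (Interpersonal) and 0-16 (Disorganized) and a total of
#' 74.
#'
#' @return Named list of integer item numbers per subscale.
#' @export
spqSubscaleKey <- function() {
  key <- list(
    IdeasOfReference            = c(1, 10, 19, 28, 37, 45, 53, 60, 63),
    SocialAnxiety               = c(2, 11, 20, 29, 38, 46, 54, 71),
    OddBeliefsMagicalThinking   = c(3, 12, 21, 30, 39, 47, 55),
    UnusualPerceptualExperiences = c(4, 13, 22, 31, 40, 48, 56, 61, 64),
    OddEccentricBehaviour       = c(5, 14, 23, 32, 41, 49, 57),
    NoCloseFriends              = c(6, 15, 24, 33, 42, 50, 58, 62, 66),
    OddSpeech                   = c(7, 16, 25, 34, 43, 51, 59, 68, 70),
    ConstrictedAffect           = c(8, 17, 26, 35, 44, 52, 65, 69),
    Suspiciousness              = c(9, 18, 27, 36, 67, 72, 73, 74))
  lapply(key, as.integer)
}

#' Subscale composition of the three SPQ factors
#'
#' Cognitive-Perceptual = Odd Beliefs or Magical Thinking + Unusual
#' Perceptual Experiences + Ideas of Reference + Suspiciousness;
#' Interpersonal = Social Anxiety + No Close Friends + Constricted Affect +
#' Suspiciousness; Disorganized = Odd or Eccentric Behaviour + Odd Speech.
#' Suspiciousness loads on both CP and IN but counts once in the total.
#'
#' @return Named list with elements `cp`, `in_` and `di` of subscale names.
#' @export
spqFactorComposition <- function() {
  list(cp = c("OddBeliefsMagicalThinking", "UnusualPerceptualExperiences",
              "IdeasOfReference", "Suspiciousness"),
       in_ = c("SocialAnxiety", "NoCloseFriends", "ConstrictedAffect",
               "Suspiciousness"),
       di = c("OddEccentricBehaviour", "OddSpeech"))
}

.checkItems <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) != 74)
    stop("SPQ item matrix must have 74 columns, got ", ncol(items))
  if (!all(items %in% c(0, 1)))
    stop("SPQ item responses must be 0 or 1")
  storage.mode(items) <- "integer"
  items
}

#' Score the nine SPQ subscales
#'
#' Sums "Yes" (1) responses per subscale for each participant.
#'
#' @param items participants x 74 matrix (or data.frame) of 0/1 responses,
#'   columns in item order 1..74.
#' @param key item-to-subscale allocation, see [spqSubscaleKey()].
#' @return Integer matrix, participants x 9 subscales.
#' @export
scoreSubscales <- function(items, key = spqSubscaleKey()) {
  items <- .checkItems(items)
  stopifnot(identical(sort(unlist(key, use.names = FALSE)), 1:74))
  out <- vapply(key, function(ii) as.integer(rowSums(items[, ii,
                                                           drop = FALSE])),
                integer(nrow(items)))
  if (!is.matrix(out))    # a single participant collapses to a vector
    out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(key)))
  rownames(out) <- rownames(items)
  out
}

#' Aggregate subscale sums into the three factor scores
#'
#' @param subscales participants x 9 matrix from [scoreSubscales()].
#' @param composition a [spqFactorComposition()] list.
#' @return data.frame with columns `raw_cp` (0-33), `raw_in` (0-33),
#'   `raw_di` (0-16) and `raw_total` (0-74; Suspiciousness counted once).
#' @export
factorScores <- function(subscales, composition = spqFactorComposition()) {
  sumOf <- function(cols) as.integer(rowSums(subscales[, cols,
                                                       drop = FALSE]))
  data.frame(raw_cp = sumOf(composition$cp),
             raw_in = sumOf(composition$in_),
             raw_di = sumOf(composition$di),
             raw_total = as.integer(rowSums(subscales)))
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of the total)`
#' over the items composing one factor.
#'
#' @param items participants x k matrix of item responses (k >= 2).
#' @return Scalar alpha (always <= 1).
#' @export
cronbachAlpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2 || nrow(items) < 2)
    stop("cronbachAlpha needs >= 2 items and >= 2 participants")
  vtot <- var(rowSums(items))
  if (vtot == 0)
    stop("total score has zero variance; alpha is undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, var)) / vtot)
}

#' Standardize SPQ factor scores over a reference sample
#'
#' Adds `z_cp`, `z_in`, `z_di` columns: raw scores centred and scaled over
#' the completer sample. The default divisor is the population standard
#' deviation (divide by n); `divisor = "sample"` uses n - 1.
#'
#' @param profiles data.frame with `raw_cp`, `raw_in`, `raw_di`.
#' @param reference data.frame supplying the means/SDs (defaults to
#'   `profiles` itself).
#' @param divisor `"population"` or `"sample"`.
#' @return `profiles` with standardized columns appended (replaced if
#'   already present, so re-standardizing is idempotent).
#' @export
standardizeFactors <- function(profiles, reference = profiles,
                               divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  if (nrow(reference) < 2) stop("need >= 2 completers to standardize")
  for (f in c("cp", "in", "di")) {
    raw <- profiles[[paste0("raw_", f)]]
    ref <- reference[[paste0("raw_", f)]]
    m <- mean(ref)
    s <- sd(ref)
    if (divisor == "population")
      s <- s * sqrt((length(ref) - 1) / length(ref))
    if (is.na(s) || s == 0)
      stop("zero standard deviation in factor ", toupper(f))
    profiles[[paste0("z_", f)]] <- (raw - m) / s
  }
  profiles
}
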