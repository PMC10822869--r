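test_that("covariate transforms match their closed forms and domains", {
  expect_identical(rtCovariate(10), 0)          # full intensity, no penalty
  expect_equal(rtCovariate(10 / exp(1)), -1)
  expect_equal(rtCovariate(5), log(0.5))
  expect_error(rtCovariate(0), "rt_seconds")
  expect_error(rtCovariate(-1), "rt_seconds")
  expect_error(rtCovariate(10.5), "rt_seconds")

  expect_identical(trialCovariate(1), 1)        # first presentation
  expect_identical(trialCovariate(10), 0)       # last presentation
  expect_equal(trialCovariate(5), (5 / 9)^exp(1))
  expect_true(all(diff(trialCovariate(1:10)) < 0))  # strictly decreasing
  expect_error(trialCovariate(0), "trial_index")
  expect_error(trialCovariate(11), "trial_index")
  expect_error(trialCovariate(2.5), "trial_index")
})

test_that("condition indices count slots for full and restricted designs", {
  expect_equal(unname(countParameterSlots(conditionIndex())), c(24, 18))
  idx2 <- conditionIndex(emotions = c("Anger", "Fear"))
  expect_equal(unname(countParameterSlots(idx2)), c(8, 6))
  # enumeration oracle: distinct (group, feedback, emotion) cells and
  # distinct (fcond, emotion) cells for the 2-emotion design
  cells <- expand.grid(g = dopferGroups, f = dopferFeedbacks,
                       e = c("Anger", "Fear"))
  fcells <- unique(data.frame(
    fc = ifelse(cells$f == "NoFeedback", "NoFeedback",
                paste0("Feedback", cells$g)), e = cells$e))
  expect_equal(nrow(cells), 8)
  expect_equal(nrow(fcells), 6)
  # no-feedback-only design: 12 intercepts (2 groups x 6 emotions)
  idxNF <- conditionIndex(feedbacks = "NoFeedback")
  expect_equal(unname(countParameterSlots(idxNF)), c(12, 6))
  # both groups share a cond18 slot per emotion without feedback
  expect_equal(slotCond18(conditionIndex(), "DOP", "NoFeedback", "Fear"),
               slotCond18(conditionIndex(), "NOP", "NoFeedback", "Fear"))
  expect_false(slotCond24(conditionIndex(), "DOP", "NoFeedback", "Fear") ==
                 slotCond24(conditionIndex(), "NOP", "NoFeedback", "Fear"))
})

test_that("the full parameter set has 222 scalars with valid constraints", {
  p <- modelParams()
  expect_length(paramVector(p), 222)
  expect_error(modelParams(betaRt = rep(-0.1, 18)), "non-negative")
  v <- paramVector(presetTrueParams("paper-like"))
  expect_length(v, 222)
  expect_identical(paramsFromVector(v, conditionIndex())@alpha,
                   presetTrueParams("paper-like")@alpha)
})

test_that("the linear predictor reproduces hand-computed cases", {
  idx <- conditionIndex()
  tr <- makeTrials(1, group = "DOP", feedback = "Feedback",
                   emotion = "Fear", rt = 10, trial = 10)
  # all parameters zero -> log-odds 0 (p = 0.5)
  expect_equal(linearPredictor(tr, modelParams(idx)), 0)
  # alpha alone survives at full intensity, last trial
  a <- setNames(numeric(24), names(idx@cond24))
  a["DOP.Feedback.Fear"] <- 1
  expect_equal(linearPredictor(tr, modelParams(idx, alpha = a)), 1)
  # moderation: beta_rt = 1, CP moderation 0.5, z_cp = 1, rt = 10/e,
  # trial = 10 -> -(1 + 0.5) * 1 = -1.5
  s <- slotCond18(idx, "DOP", "Feedback", "Fear")
  brt <- numeric(18); brt[s] <- 1
  mod <- matrix(0, 3, 18, dimnames = list(c("CP", "IN", "DI"), NULL))
  mod["CP", s] <- 0.5
  tr2 <- makeTrials(1, group = "DOP", feedback = "Feedback",
                    emotion = "Fear", rt = 10 / exp(1), trial = 10)
  z <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(linearPredictor(tr2, modelParams(idx, betaRt = brt,
                                                spqRtMod = mod), z),
               -1.5)
})

test_that("zero SPQ scores reduce the extended model to the base model", {
  idx <- conditionIndex()
  set.seed(1)
  p <- modelParams(idx, alpha = rnorm(24), betaRt = abs(rnorm(18)),
                   betaTrial = rnorm(18),
                   spqDirect = matrix(rnorm(54, 0, 0.25), 3),
                   spqRtMod = matrix(rnorm(54, 0, 0.1), 3),
                   spqTrialMod = matrix(rnorm(54, 0, 0.1), 3))
  pBase <- modelParams(idx, alpha = p@alpha, betaRt = p@betaRt,
                       betaTrial = p@betaTrial)
  tr <- makeTrials(6, rt = c(1, 3, 5, 7, 9, 10), trial = c(1:5, 10))
  z0 <- matrix(0, 6, 3)
  expect_equal(linearPredictor(tr, p, z0), linearPredictor(tr, pBase))
})

test_that("predicted accuracy rises with intensity when beta_rt > 0", {
  idx <- conditionIndex()
  p <- modelParams(idx, betaRt = rep(0.7, 18))
  tr <- makeTrials(9, rt = 1:9, trial = 10)
  eta <- linearPredictor(tr, p)
  expect_true(all(diff(plogis(eta)) > 0))
})

test_that("log-likelihood matches a brute-force Bernoulli product", {
  ds <- mixedSpqDataset()
  idx <- conditionIndex()
  p <- presetTrueParams("strong-moderation", idx)
  tr <- trials(ds)
  z <- dopfer:::.zForTrials(tr, spqProfiles(ds))
  eta <- linearPredictor(tr, p, z)
  probs <- plogis(eta)
  brute <- sum(log(ifelse(tr$correct == 1, probs, 1 - probs)))
  expect_equal(logLikelihood(ds, p), brute, tolerance = 1e-12)
  # one correct trial, all params zero -> log 0.5
  one <- trialDataset(makeTrials(1))
  expect_equal(logLikelihood(one, modelParams(idx)), log(0.5))
  # additivity: duplicated data doubles the log-likelihood
  two <- trialDataset(rbind(trials(one),
                            within(trials(one),
                                   participant_id <- "P999")))
  expect_equal(logLikelihood(two, p), 2 * logLikelihood(one, p))
})

test_that("the log prior matches closed forms and the support constraint", {
  idx <- conditionIndex()
  p0 <- modelParams(idx)
  pr <- priorSpec()
  closed <- 24 * dnorm(0, 0, 1.5, log = TRUE) +
    18 * (log(2) + dnorm(0, 0, 1, log = TRUE)) +
    18 * dnorm(0, 0, 1, log = TRUE) +
    54 * dnorm(0, 0, 0.25, log = TRUE) +
    108 * dnorm(0, 0, 0.1, log = TRUE)
  expect_equal(logPrior(p0, pr), closed)
  # moving one alpha from 0 to its prior SD costs exactly 1/2
  a <- setNames(numeric(24), names(idx@cond24)); a[1] <- 1.5
  expect_equal(logPrior(p0, pr) - logPrior(modelParams(idx, alpha = a), pr),
               0.5)
  # negative RT penalty is off-support
  pneg <- p0; pneg@betaRt[3] <- -1e-9
  expect_identical(logPrior(pneg, pr), -Inf)
  expect_identical(logPosterior(emptyDataset(), pneg), -Inf)
})

test_that("analytic gradients agree with finite differences", {
  ds <- mixedSpqDataset()
  idx <- conditionIndex()
  md <- dopfer:::.modelData(ds, idx)
  set.seed(7)
  for (rep in 1:3) {
    theta <- rnorm(222, 0, 0.3)
    r <- dopfer:::.lpGrad(theta, md, idx, TRUE)
    num <- vapply(seq_along(theta), function(j) {
      h <- 1e-6 * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (dopfer:::.lpGrad(tp, md, idx, TRUE)$lp -
         dopfer:::.lpGrad(tm, md, idx, TRUE)$lp) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(num - r$grad) / pmax(1, abs(r$grad))), 1e-6)
  }
})

test_that("the C++ kernel agrees with the R reference log posterior", {
  ds <- mixedSpqDataset()
  idx <- conditionIndex()
  md <- dopfer:::.modelData(ds, idx)
  set.seed(3)
  theta <- rnorm(222, 0, 0.4)
  r <- dopfer:::.lpGrad(theta, md, idx, TRUE)
  p <- paramsFromVector(dopfer:::.toConstrained(theta, 24, 18), idx, TRUE)
  jac <- sum(theta[seq.int(25, 42)])
  expect_equal(r$lp, logPosterior(ds, p) + jac, tolerance = 1e-10)
})
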