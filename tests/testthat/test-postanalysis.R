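test_that("hdi matches the brute-force shortest-window search", {
  # sorted 1..100 at mass 0.95: any 95-point window has width 94
  h <- hdi(1:100)
  expect_equal(h[["upper"]] - h[["lower"]], 94)
  expect_equal(unname(h), c(1, 95))         # leftmost tie
  # constant draws collapse to a point
  expect_equal(unname(hdi(rep(3.3, 50))), c(3.3, 3.3))
  # right-skewed sample: HDI sits left of the equal-tailed interval
  set.seed(11)
  x <- exp(rnorm(5000))
  h2 <- hdi(x)
  eq <- quantile(x, c(0.025, 0.975))
  expect_lt(h2[["upper"]], eq[[2]])
  expect_lt(h2[["lower"]], eq[[1]])
  # brute-force agreement on many random samples
  set.seed(12)
  for (i in 1:25) {
    y <- switch(1 + i %% 3, rnorm(200), rexp(200), runif(200))
    expect_equal(unname(hdi(y)), bruteHdi(y))
  }
  expect_error(hdi(numeric(0)), "empty")
})

test_that("ROPE decisions implement the three-way rule", {
  expect_equal(ropeDecision(c(lower = 0.3, upper = 0.5),
                            rope(-0.2, 0.2)), "credible")
  expect_equal(ropeDecision(c(lower = -0.1, upper = 0.1),
                            rope(-0.2, 0.2)), "negligible")
  expect_equal(ropeDecision(c(lower = -0.3, upper = 0.1),
                            rope(-0.2, 0.2)), "withheld")
  # touching endpoints do not count as complete exclusion
  expect_equal(ropeDecision(c(lower = 0.2, upper = 0.5),
                            rope(-0.2, 0.2)), "withheld")
  # degenerate {0} ROPE: credible iff 0 outside the HDI
  expect_equal(ropeDecision(c(lower = -1.47, upper = -0.34), rope(0)),
               "credible")
  expect_equal(ropeDecision(c(lower = -0.5, upper = 0.5), rope(0)),
               "withheld")
  expect_equal(ropeDecision(c(lower = 0, upper = 0), rope(0)),
               "negligible")
})

test_that("ROPE half-width calculators reproduce the stated bounds", {
  expect_equal(ropeHalfwidthProbability(), qlogis(0.55))
  expect_equal(round(ropeHalfwidthProbability(), 1), 0.2)
  expect_equal(ropeHalfwidthProbability(0), 0)
  expect_equal(round(ropeHalfwidthProbability(sd_span = 2), 1), 0.1)
  expect_equal(ropeHalfwidthModeration(), 0.005)
  expect_equal(ropeHalfwidthModeration(0.02, 2), 0.01)
  expect_equal(ropeHalfwidthModeration(0), 0)
  expect_equal(ropeHalfwidthAccuracy(), 5)
  # non-zero reference: the bound is the log-odds change, not qlogis(p+d)
  ref <- 1
  expect_equal(ropeHalfwidthProbability(0.05, ref),
               qlogis(plogis(ref) + 0.05) - ref)
})

test_that("percent transform and contrasts behave linearly", {
  expect_equal(alphaToPercent(0), 50)
  expect_equal(alphaToPercent(2), 88.07971, tolerance = 1e-6)
  expect_true(all(diff(alphaToPercent(seq(-3, 3, 0.5))) > 0))
  # inverse identity on (0, 100)
  p <- seq(1, 99, 0.5)
  expect_equal(alphaToPercent(qlogis(p / 100)), p, tolerance = 1e-10)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(contrastDraws(a, a), rep(0, 100))
  expect_equal(mean(contrastDraws(a, b)), mean(a) - mean(b))
  expect_equal(unique(doubleContrast(rep(10, 5), rep(0, 5), rep(7, 5),
                                     rep(0, 5))), 3)
  expect_error(contrastDraws(1:3, 1:4), "equal length")
})

# a PosteriorDraws stub with prescribed constant draws per parameter
constantPosterior <- function(values = NULL, n = 40, includeSpq = TRUE) {
  idx <- conditionIndex()
  nms <- paramNames(idx, includeSpq)
  draws <- matrix(0, n, length(nms), dimnames = list(NULL, nms))
  for (nm in names(values)) draws[, nm] <- values[[nm]]
  new("PosteriorDraws", draws = draws,
      chain = rep(1:2, each = n / 2), index = idx,
      includeSpq = includeSpq,
      config = list(), diagnostics = list())
}

test_that("the accuracy table has the study layout and replays decisions", {
  ps <- constantPosterior()
  tab <- buildTableAlpha(ps)
  expect_equal(nrow(tab), 6 * 7)            # 7 quantities per emotion
  expect_true(all(tab$mean[is.na(tab$decision)] == 50))  # cells at 50%
  contrasts <- tab[!is.na(tab$decision), ]
  expect_equal(nrow(contrasts), 6 * 3)
  expect_true(all(contrasts$mean == 0))
  expect_true(all(contrasts$decision == "negligible"))
  # decision replay from each row's own interval and ROPE
  replay <- mapply(function(lo, hi, rl, ru)
    ropeDecision(c(lower = lo, upper = hi), rope(rl, ru)),
    contrasts$hdi_lower, contrasts$hdi_upper,
    contrasts$rope_lower, contrasts$rope_upper)
  expect_equal(unname(replay), contrasts$decision)
})

test_that("slope tables flag credible contrasts under their ROPEs", {
  # constructed posterior: DOP - NOP RT-penalty difference inside
  # [0.34, 1.47] for Fear -> credible against the {0} ROPE
  ps <- constantPosterior(values = list(
    "beta_rt[FeedbackDOP.Fear]" = seq(1.0, 1.6, length.out = 40),
    "beta_rt[FeedbackNOP.Fear]" = rep(0.5, 40)))
  t2 <- buildTableBetaRt(ps)
  expect_equal(nrow(t2), 6 * 4)
  fearRow <- t2[t2$emotion == "Fear" &
                  t2$quantity == "FeedbackDOPvsFeedbackNOP", ]
  expect_true(fearRow$credible)
  # all-zero draws: zero-width contrast HDI at 0 vs {0} -> negligible
  t2z <- buildTableBetaRt(constantPosterior())
  zrow <- t2z[t2z$quantity == "FeedbackDOPvsFeedbackNOP", ]
  expect_true(all(zrow$decision == "negligible"))

  t3 <- buildTableBetaTrial(constantPosterior())
  expect_equal(nrow(t3), 6 * 6)             # 3 conditions + 3 contrasts
  expect_true(all(t3$decision == "negligible"))  # 0 inside (-0.2, 0.2)
  expect_equal(unique(t3$rope_upper), 0.2)
  # sign convention flips the contrast draws
  psA <- constantPosterior(values = list(
    "beta_trial[NoFeedback.Anger]" = rep(-0.75, 40),
    "beta_trial[FeedbackNOP.Anger]" = rep(-0.43, 40)))
  t3a <- buildTableBetaTrial(psA)
  row <- t3a[t3a$emotion == "Anger" &
               t3a$quantity == "NoFeedbackVsFeedbackNOP", ]
  expect_equal(row$mean, -0.32)             # left label minus right label
  t3b <- buildTableBetaTrial(psA, sign = "second-minus-first")
  rowb <- t3b[t3b$emotion == "Anger" &
                t3b$quantity == "NoFeedbackVsFeedbackNOP", ]
  expect_equal(rowb$mean, 0.32)
})

test_that("the SPQ effect summary covers 18 x 9 cells with both ROPEs", {
  ps <- constantPosterior()
  s <- spqEffectSummary(ps)
  expect_equal(nrow(s), 162)
  expect_true(all(s$decision == "negligible"))
  expect_equal(unique(s$rope_upper[s$family %in%
                                     c("beta_cp", "beta_in", "beta_di")]),
               0.1)
  expect_equal(unique(s$rope_upper[grepl("_rt$|_trial$", s$family)]),
               0.005)
  replay <- mapply(function(lo, hi, rl, ru)
    ropeDecision(c(lower = lo, upper = hi), rope(rl, ru)),
    s$hdi_lower, s$hdi_upper, s$rope_lower, s$rope_upper)
  expect_equal(unname(replay), s$decision)
  psNo <- constantPosterior(includeSpq = FALSE)
  expect_error(spqEffectSummary(psNo), "SPQ")
})

test_that("posterior-predictive grids follow the plotting conventions", {
  ps <- constantPosterior()
  # all-zero draws predict 0.5 everywhere
  g <- posteriorPredictive(ps, ppGridFullIntensity())
  expect_true(all(g$p_mean == 0.5))
  expect_equal(nrow(g), 24)
  # RT binning: 15 centres per condition, first at 1.3, width 0.6
  gr <- ppGridRtBins()
  perCond <- gr[gr$group == "DOP" & gr$feedback == "Feedback" &
                  gr$emotion == "Fear", ]
  expect_equal(nrow(perCond), 15)
  expect_equal(min(perCond$rt_seconds), 1.3)
  expect_equal(unique(round(diff(sort(perCond$rt_seconds)), 10)), 0.6)
  # at rt = 10, trial = 10 the prediction equals the intercept accuracy
  a <- list("alpha[NOP.Feedback.Fear]" = 1.7)
  ps2 <- constantPosterior(values = a)
  g2 <- posteriorPredictive(ps2, ppGridFullIntensity())
  cell <- g2[g2$group == "NOP" & g2$feedback == "Feedback" &
               g2$emotion == "Fear", ]
  expect_equal(100 * cell$p_mean, alphaToPercent(1.7))
  expect_error(posteriorPredictive(ps, within(ppGridFullIntensity(),
                                              rt_seconds <- 0)),
               "rt_seconds")
})
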