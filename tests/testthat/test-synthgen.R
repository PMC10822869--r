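test_that("the default design yields the task's trial structure", {
  spec <- designSpec(n_dop = 2, n_nop = 1, seed = 5)
  sk <- makeDesign(spec)
  expect_equal(nrow(sk), 3 * 120)           # 120 trials per participant
  perBlock <- table(sk$participant_id, sk$block)
  expect_true(all(perBlock == 60))          # 60 per block
  # each emotion appears exactly n_actors times per block
  one <- sk[sk$participant_id == "P001" & sk$block == 1, ]
  expect_true(all(table(one$emotion) == 10))
  # trial_index counts presentations of an emotion within a block
  fear <- one[one$emotion == "Fear", ]
  expect_equal(sort(fear$trial_index), 1:10)
  # blocks map to the feedback factor in order
  expect_equal(unique(sk$feedback[sk$block == 1]), "NoFeedback")
  expect_equal(unique(sk$feedback[sk$block == 2]), "Feedback")
})

test_that("single-actor designs collapse to one presentation per emotion", {
  sk <- makeDesign(designSpec(n_dop = 1, n_nop = 0, n_actors = 1,
                              spq_completers = c(DOP = 0, NOP = 0)))
  expect_equal(nrow(sk), 12)                # 6 per block
  expect_true(all(sk$trial_index == 1))
})

test_that("design generation is deterministic under a fixed seed", {
  s1 <- makeDesign(designSpec(n_dop = 3, n_nop = 3, seed = 77))
  s2 <- makeDesign(designSpec(n_dop = 3, n_nop = 3, seed = 77))
  expect_identical(s1, s2)
  s3 <- makeDesign(designSpec(n_dop = 3, n_nop = 3, seed = 78))
  expect_false(identical(s1, s3))
})

test_that("sampled RTs honour truncation and the configured median", {
  sk <- makeDesign(designSpec(n_dop = 50, n_nop = 50, seed = 2))
  rtm <- rtModel(conditionIndex(), meanlog = log(4), sdlog = 0.45)
  out <- sampleRts(sk, rtm, seed = 9)
  expect_true(all(out$rt_seconds > 0 & out$rt_seconds <= 10))
  # quantile oracle: median of the truncated law is
  # qlnorm(0.5 * plnorm(10)) on the untruncated law
  med <- qlnorm(0.5 * plnorm(10, log(4), 0.45), log(4), 0.45)
  expect_lt(abs(median(out$rt_seconds) - med),
            3 * 1.2533 * 0.45 * med / sqrt(nrow(out)) + 0.05)
  # near-degenerate scale collapses on the location back-transform
  rtm2 <- rtModel(conditionIndex(), meanlog = log(4), sdlog = 1e-9)
  out2 <- sampleRts(sk[1:100, ], rtm2, seed = 9)
  expect_equal(out2$rt_seconds, rep(4, 100), tolerance = 1e-6)
  expect_error(rtModel(conditionIndex(), sdlog = 0), "positive")
})

test_that("SPQ sampling hits completer counts and correlation structure", {
  sk <- makeDesign(designSpec(seed = 4))
  spq <- sampleSpq(sk, c(DOP = 58, NOP = 51), seed = 12)
  expect_equal(nrow(spq), 109)              # 58 DOP + 51 NOP completers
  pg <- unique(sk[, c("participant_id", "group")])
  g <- pg$group[match(spq$participant_id, pg$participant_id)]
  expect_equal(unname(table(g)[c("DOP", "NOP")]), c(58L, 51L),
               ignore_attr = TRUE)
  expect_true(all(spq$raw_cp %in% 0:33 & spq$raw_in %in% 0:33 &
                    spq$raw_di %in% 0:16 & spq$raw_total %in% 0:74))
  expect_equal(sampleSpq(sk, c(DOP = 0, NOP = 0)) |> nrow(), 0)
  expect_error(sampleSpq(sk, c(DOP = 1, NOP = 1),
                         correlation = matrix(c(1, 2, 2, 2, 1, 2,
                                                2, 2, 1), 3)),
               "positive definite")
  # identity correlation: empirical pairwise correlations near zero
  big <- data.frame(participant_id = sprintf("Q%04d", 1:4000),
                    group = "DOP")
  spq2 <- sampleSpq(big, c(DOP = 4000), correlation = diag(3), seed = 8)
  cors <- cor(spq2[, c("z_cp", "z_in", "z_di")])
  expect_lt(max(abs(cors[upper.tri(cors)])), 3 / sqrt(4000) + 0.02)
})

test_that("simulated correctness follows the model's success probability", {
  idx <- conditionIndex()
  sk <- makeDesign(designSpec(n_dop = 50, n_nop = 50, seed = 3))
  sk <- sampleRts(sk, rtModel(idx), seed = 3)
  # null truth: accuracy 0.5 regardless of covariates
  dsNull <- simulateResponses(sk, presetTrueParams("null", idx), seed = 6)
  acc <- mean(trials(dsNull)$correct)
  expect_lt(abs(acc - 0.5), 3 * 0.5 / sqrt(nrow(sk)))
  # saturated intercept: accuracy ~ 1
  pSat <- modelParams(idx, alpha = rep(20, 24))
  dsSat <- simulateResponses(sk, pSat, seed = 6)
  expect_gt(mean(trials(dsSat)$correct), 0.999)
  # closed-form mean oracle in one condition at rt = 10, trial = 10
  skC <- makeTrials(10000, group = "NOP", feedback = "Feedback",
                    emotion = "Fear", rt = 10, trial = 10)
  a <- setNames(numeric(24), names(idx@cond24))
  a["NOP.Feedback.Fear"] <- 1.2
  dsC <- simulateResponses(skC, modelParams(idx, alpha = a), seed = 10)
  p <- plogis(1.2)
  expect_lt(abs(mean(trials(dsC)$correct) - p),
            3 * sqrt(p * (1 - p) / 10000))
})

test_that("presets are deterministic and satisfy parameter constraints", {
  for (nm in c("null", "paper-like", "strong-moderation")) {
    p <- presetTrueParams(nm)
    expect_true(all(p@betaRt >= 0))
    expect_identical(paramVector(p), paramVector(presetTrueParams(nm)))
  }
  expect_true(all(paramVector(presetTrueParams("null")) == 0))
  pl <- presetTrueParams("paper-like")
  # the NOP feedback penalty for Fear exceeds the DOP one
  expect_gt(pl@betaRt[["FeedbackNOP.Fear"]], pl@betaRt[["FeedbackDOP.Fear"]])
  # intercept accuracies stay in the 75-99% band
  expect_true(all(plogis(pl@alpha) >= 0.749 & plogis(pl@alpha) <= 0.991))
  expect_error(presetTrueParams("bogus"))
  # presets subset cleanly to restricted designs
  idx2 <- conditionIndex(emotions = c("Anger", "Fear"))
  p2 <- presetTrueParams("paper-like", idx2)
  expect_length(paramVector(p2), 8 + 2 * 6 + 9 * 6)
  expect_equal(p2@betaRt[["FeedbackNOP.Fear"]],
               pl@betaRt[["FeedbackNOP.Fear"]])
})

test_that("the full generation pipeline is reproducible and valid", {
  spec <- designSpec(n_dop = 4, n_nop = 4, emotions = c("Anger", "Fear"),
                     spq_completers = c(DOP = 2, NOP = 2), seed = 21)
  d1 <- simulateDataset(spec, "paper-like")
  d2 <- simulateDataset(spec, "paper-like")
  expect_identical(trials(d1), trials(d2))
  expect_identical(spqProfiles(d1), spqProfiles(d2))
  expect_s4_class(d1, "TrialDataset")       # passed full validation
})
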