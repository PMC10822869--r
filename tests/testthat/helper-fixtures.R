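# Shared fixtures, built in code.

# minimal valid trial table (one participant per row avoids duplicate
# (participant, feedback, emotion, trial_index) triples)
makeTrials <- function(n = 4, group = "DOP", feedback = "Feedback",
                       emotion = "Fear", rt = 5, trial = 5, correct = 1) {
  data.frame(participant_id = sprintf("P%03d", seq_len(n)),
             group = rep_len(group, n), feedback = rep_len(feedback, n),
             emotion = rep_len(emotion, n), actor_id = rep_len(1L, n),
             trial_index = as.integer(rep_len(trial, n)),
             rt_seconds = as.double(rep_len(rt, n)),
             correct = as.integer(rep_len(correct, n)),
             stringsAsFactors = FALSE)
}

# intercept-only dataset: k successes in n one-trial participants, all
# covariate terms vanishing (rt = 10, trial_index = 10)
interceptOnlyDataset <- function(k, n) {
  tr <- makeTrials(n, group = "DOP", feedback = "NoFeedback",
                   emotion = "Anger", rt = 10, trial = 10,
                   correct = rep(c(1, 0), c(k, n - k)))
  trialDataset(tr)
}

emptyDataset <- function() {
  trialDataset(makeTrials(0))
}

# brute-force shortest-window HDI (independent oracle)
bruteHdi <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  best <- c(x[1], x[k]); bw <- x[k] - x[1]
  for (j in seq_len(n - k + 1)) {
    w <- x[j + k - 1] - x[j]
    if (w < bw - 0) { bw <- w; best <- c(x[j], x[j + k - 1]) }
  }
  best
}

# a tiny mixed dataset with two SPQ completers and one non-completer
mixedSpqDataset <- function(seed = 99) {
  set.seed(seed)
  tr <- rbind(
    makeTrials(3, group = "DOP", feedback = "Feedback", emotion = "Fear",
               rt = c(3, 6, 9), trial = c(1, 5, 10), correct = c(1, 0, 1)),
    within(makeTrials(3, group = "NOP", feedback = "NoFeedback",
                      emotion = "Anger", rt = c(2, 5, 10),
                      trial = c(2, 6, 10), correct = c(0, 1, 1)),
           participant_id <- sprintf("P%03d", 4:6)))
  spq <- data.frame(participant_id = c("P001", "P004", "P005"),
                    raw_cp = c(5L, 12L, 20L), raw_in = c(7L, 15L, 3L),
                    raw_di = c(2L, 8L, 11L))
  spq$raw_total <- spq$raw_cp + spq$raw_in + spq$raw_di - c(2L, 5L, 1L)
  spq <- standardizeFactors(spq)
  trialDataset(tr, spq = spq)
}
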