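---
title: "Modelling dynamic facial-emotion recognition under differential outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dynamic facial-emotion recognition under differential outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopfer)
```

## The task and the scientific question

`dopfer` analyses trial-level accuracy in a dynamic emotional-facial-
expression recognition task. In each 10-second trial a face morphs from a
neutral expression to one of the six basic emotions (Anger, Disgust, Fear,
Happiness, Sadness, Surprise) at full intensity; the participant responds as
soon as they recognise the emotion, so the reaction time (RT) doubles as the
expression intensity at the moment of the response (0 s = 0%, 10 s = 100%).
Each of two blocks presents every emotion once per each of 10 actor models
(60 trials per block). The first block gives no feedback; in the second,
one group receives a *differential outcomes procedure* (DOP: each emotion is
always followed by its own specific reinforcer after a correct response)
and the other a *non-differential* one (NOP: any reinforcer may follow any
correct response). A subset of participants additionally completes the
Schizotypal Personality Questionnaire (SPQ), whose three factor scores
(Cognitive-Perceptual, Interpersonal, Disorganized) enter the model as
standardized covariates.

The questions the model answers are: does the DOP improve recognition
accuracy, reduce the penalty for responding at lower intensities, or change
the learning curve, per emotion — and do schizotypy levels shift or
moderate any of those effects?

## The model

Each trial's correctness is Bernoulli with a logit-linear success
probability:

$$P_i \sim \mathrm{Binomial}(1, p_i), \qquad
\mathrm{logit}(p_i) = \alpha_{c24[i]}
 + \beta_{RT,c18[i]}\,\log\!\frac{RT_i}{10}
 + \beta_{Trial,c18[i]}\left(\frac{10-\mathrm{Trial}_i}{9}\right)^{e}.$$

* $\alpha$ is the log-odds of a correct response at full intensity in the
  last trial of a condition. It is indexed over all
  group × feedback × emotion cells — 24 slots in the full design.
* $\beta_{RT} \ge 0$ scales the *intensity penalty* $\log(RT/10)$, which is
  0 at the 10-s cap and diverges to $-\infty$ as $RT \to 0$ (an emotion at
  0% intensity cannot be recognised except by chance). Because no group
  difference in penalties can exist before outcomes differ, the two groups
  share a slot in the no-feedback block: the slope index runs over
  {NoFeedback, Feedback-DOP, Feedback-NOP} × emotion — 18 slots.
* $\beta_{Trial}$ scales the learning covariate $((10-t)/9)^e$, which is 1
  at the first presentation of an emotion within a block and 0 at the
  tenth, so the coefficient reads directly as the first-vs-last-trial
  difference in log-odds. The exponent $e$ makes learning fastest early
  and asymptotic late.

For SPQ completers the predictor gains direct terms
$\beta_{CP}CP + \beta_{IN}IN + \beta_{DI}DI$ (per slope slot) and each
slope is multiplied by a proportional moderation factor
$1 + \beta_{\cdot\_RT}\,z$ (and analogously for the trial slope). With all
standardized scores at zero the extended model reduces exactly to the base
model. Completers and non-completers enter one joint likelihood with
shared condition-level parameters; the full design carries
$24 + 18 + 18 + 3\times54 = 222$ scalars.

Priors are fixed: $\alpha \sim N(0, 1.5)$,
$\beta_{RT} \sim \mathrm{HalfNormal}(0, 1)$, $\beta_{Trial} \sim N(0, 1)$,
direct SPQ effects $\sim N(0, 0.25)$ and all moderation coefficients
$\sim N(0, 0.1)$ (second arguments are standard deviations). The
half-normal constraint encodes that a fuller expression is never harder to
recognise. The moderation factor $1 + \sum\beta z$ can in principle turn
an *effective* slope negative at extreme $z$; the positivity constraint
binds the base $\beta_{RT}$ only, exactly as the model is written, and the
tight moderation priors make such reversals rare.

## Inference: HDI + ROPE

All conclusions are read off the joint posterior. Contrasts are formed by
draw-wise subtraction (`contrastDraws()`, `doubleContrast()`), summarised
by the 95% highest density interval — the shortest interval holding 95% of
the draws, computed by a deterministic sorted-window search with leftmost
tie-breaking — and judged against a *region of practical equivalence*:

| Quantity | ROPE | Rationale |
|---|---|---|
| accuracy contrasts (percent) | (−5, 5) | half of the 10% per-participant resolution of a 10-trial condition |
| $\beta_{RT}$ contrasts | {0} | any nonzero penalty difference matters because the covariate is unbounded below |
| $\beta_{Trial}$ contrasts | (−0.2, 0.2) | the log-odds change that moves p = 0.5 by 5 points, `qlogis(0.55) ≈ 0.2007` |
| SPQ direct effects | (−0.1, 0.1) | the same 5-point bound spread over a 2-SD predictor span |
| SPQ moderation | (−0.005, 0.005) | a 1% proportional change over a 2-SD span |

A contrast is *credible* when its HDI completely excludes the ROPE
(disjoint, endpoints included — "completely" is read literally, so a
touching endpoint withholds the decision), *negligible* when the HDI lies
inside the ROPE, and *withheld* otherwise. Every table row carries its own
interval, ROPE and decision so any decision can be replayed from the row
alone.

The printed learning-table contrasts follow their column labels
(left label minus right label); the convention is configurable
(`buildTableBetaTrial(sign = )`) because the labels alone do not fix a
sign.

## Sampling

The posterior is explored with an adaptive Hamiltonian Monte Carlo sampler
written for this model: the log posterior and its analytic gradient are
evaluated in C++ on an unconstrained scale ($\beta_{RT}$ log-transformed
with the exact Jacobian), with a dual-averaging step size targeting 0.8
acceptance, a diagonal mass matrix estimated from the middle 60% of
warmup, and a leapfrog count jittered uniformly up to 32 to avoid
resonance. Initial points are prior draws shrunk halfway toward zero
(keeping the log transform finite), with bounded reinitialization retries.
A random-walk Metropolis fallback (`algorithm = "rw"`) targets the same
posterior for environments where gradients are unavailable or distrusted.
The likelihood is evaluated as `-log1p(exp(-sign * eta))`, which cannot
round to `-Inf` for finite log-odds.

The default budget is 4 chains × 2500 saved draws after 1000 warmup
iterations each (10,000 saved draws). Convergence is monitored by the
split-chain Gelman–Rubin statistic (each chain halved before the
between/within variance ratio — strictly more conservative than the plain
statistic, which remains available via `gelmanRubin(split = FALSE)`).

A sampler is only trusted here to the extent it passes its oracles: an
intercept-only posterior is compared against dense numeric quadrature of
the exact density; an empty-data run must reproduce every prior family's
standard deviation (1.5, the half-normal moments
$\sqrt{2/\pi} \approx 0.798$ and $\sqrt{1-2/\pi} \approx 0.603$, 1, 0.25,
0.1); and the analytic gradient is checked against finite differences at
random interior points to 1e−6 relative error.

## The synthetic-data generator

`simulateDataset()` reproduces the study's *design* exactly — 88 DOP and
95 NOP participants, two 60-trial blocks of 6 emotions × 10 actors in
seeded-random order, and 58 + 51 = 109 SPQ completers chosen uniformly
within group — and fills in the *stochastic* ingredients the model treats
as given:

* **Reaction times** are truncated-lognormal per feedback-condition ×
  emotion (inverse-CDF sampling on (0, 10]). The defaults
  (`meanlog = log(4)`, `sdlog = 0.45`) put the median near 4 s with most
  mass over 2–8 s, the occupancy a 1–10 s binning of real data shows. The
  task model conditions on RT, so this law is fixture machinery; it is
  configurable per condition.
* **SPQ scores** are drawn as a correlated trivariate normal
  (default inter-factor correlation 0.5, in the range questionnaire
  studies report) and back-filled to raw scores by a rank-preserving
  affine map anchored at realistic factor means/SDs, with a synthetic
  Suspiciousness overlap keeping the total consistent. Only the
  standardized scores enter the model, so the back-fill affects no
  inference.
* **Correctness** is drawn from the model's own linear predictor given the
  chosen true parameters.

Three deterministic presets supply ground truth: `"null"` (all effects 0 —
accuracy 0.5 everywhere), `"paper-like"` (intercept accuracies clamped to
the 75–99% band, RT penalties in [0.1, 1.8] with the NOP-feedback penalty
for Fear and Surprise exceeding the DOP one, learning slopes in
[−1.2, 1.0], SPQ effects 0), and `"strong-moderation"` (adds
alternating-sign direct effects of 0.2 and moderations of 0.05).

What passing recovery tests on these data shows — and does not show: the
generator draws correctness from the very model being fitted, so recovery
demonstrates the sampler and the inferential pipeline are faithful to the
model, not that the model is true of real behaviour. Real data bring
participant heterogeneity (no random effects are modelled, matching the
target analysis), non-lognormal RTs, label-confusion structure among the
six emotions (only correctness is simulated), and timed-out trials whose
logging convention is unknown; an RT recorded exactly at the 10-s cap is
stored as 10.0 and yields zero penalty.

## Numerical and design choices

* **Validation** collects *all* violations with row numbers before
  erroring; RTs in (0, 0.05) are accepted with a warning (the model is
  defined for all RT > 0, but the covariate is extreme), while RT ≤ 0 is
  rejected (the log is undefined at 0).
* **SPQ scoring** uses the standard published 74-item key (subscale sizes
  9/8/7/9/7/9/9/8), the only allocation that reproduces the factor ranges
  0–33/0–33/0–16 and the 74-item total; descriptions of the instrument
  sometimes state seven items per subscale, which is inconsistent with
  those ranges and is not followed. Suspiciousness loads on both CP and IN
  but counts once in the total. Standardization uses the completer sample
  with the population (divide-by-n) SD by default; the divisor is
  configurable.
* **HDI** ties break toward the leftmost shortest window, making every
  reported interval deterministic.
* **Probability floors**: none are needed in the likelihood thanks to the
  `log1p`-based form; posterior-predictive probabilities are exact
  inverse-logits.
* **Problem sizes in the test suite** are the package's own choices:
  parameter recovery runs the full 183-participant design at a reduced
  budget (4 × 500 draws after 500 warmup), null-calibration runs 20
  smoke-scale datasets (20 participants, 2 emotions, 2 × 150 draws), and
  prior recovery uses the full default budget on an empty dataset.

## Limitations

The model deliberately contains no participant random effects, no RT
likelihood, and no multinomial structure over the six response labels —
it matches the target analysis, not the most general account of the task.
The HMC implementation is single-threaded and unoptimised for models far
larger than the 222-parameter design; the random-walk fallback mixes far
more slowly and is only suitable for small designs. Raw SPQ back-fill in
the generator is synthetic and should not be used to study raw-score
psychometrics.
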