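# dopfer

Bayesian trial-level modelling of **d**ynamic facial-emotion recognition
under differential **o**utcomes **p**rocedures, with schizotypy
(**f**actor) **e**ffects and HDI+ROPE infe**r**ence.

## The problem

In a dynamic recognition task a face morphs from neutral to one of the six
basic emotions over 10 s; the participant responds as soon as they
recognise the emotion, so reaction time doubles as expression intensity at
the moment of the response. Two groups are compared: one trained with a
differential outcomes procedure (DOP — every emotion has its own specific
reinforcer) and one with non-differential outcomes (NOP). A subset of
participants also completes the Schizotypal Personality Questionnaire
(SPQ). The analyst wants, per emotion: the accuracy in every
group × feedback cell, the penalty for responding at lower intensity, the
learning curve across the 10 presentations of an emotion, and whether
schizotypy shifts or moderates any of these.

`dopfer` implements the full analysis as a tested, reusable package: the
trial-level model, its sampler, the decision machinery, SPQ scoring, and a
synthetic-data generator so the entire pipeline is exercised by parameter
recovery without any download.

## The model

Per trial $i$,

$$P_i \sim \mathrm{Binomial}(1, p_i),\qquad
\mathrm{logit}(p_i)=\alpha_{c24[i]}
+\beta_{RT,c18[i]}\log\frac{RT_i}{10}
+\beta_{Trial,c18[i]}\Big(\frac{10-\mathrm{Trial}_i}{9}\Big)^{e},$$

with 24 intercept slots (group × feedback × emotion), 18 slope slots (the
groups share the no-feedback block), $\beta_{RT}\sim$ HalfNormal(0, 1),
$\alpha\sim N(0,1.5)$, $\beta_{Trial}\sim N(0,1)$. SPQ completers add
direct effects ($N(0,0.25)$ priors) and proportional moderation of both
slopes ($N(0,0.1)$) — 222 parameters in all, estimated jointly by an
adaptive Hamiltonian Monte Carlo sampler (C++ gradient, split-chain
Gelman–Rubin diagnostics; default budget 4 chains × 2500 saved draws).
Contrasts are draw-wise subtractions summarised by 95% highest-density
intervals and judged against regions of practical equivalence
(±5 percentage points for accuracy, {0} for RT-penalty contrasts, ±0.2
for learning contrasts, ±0.1 / ±0.005 for SPQ direct / moderation
effects). See `vignette("dopfer-methods")` for the full account.

## Worked example

```r
library(dopfer)

# a small synthetic study: 20 participants, 2 emotions, 12 SPQ completers
spec <- designSpec(n_dop = 10, n_nop = 10, emotions = c("Anger", "Fear"),
                   spq_completers = c(DOP = 6, NOP = 6), seed = 42)
ds <- simulateDataset(spec, "paper-like")
ds
#> TrialDataset: 800 trials, 20 participants (DOP n=10, NOP n=10)
#>   SPQ profiles: 12 participants

ps <- samplePosterior(ds, samplerConfig(n_chains = 2, n_warmup = 300,
                                        n_saved_per_chain = 300, seed = 7))
ps
#> PosteriorDraws: 600 draws x 74 parameters, 2 chains
#>   split R-hat: max 1.007 (median 0.999)

tab <- buildTableAlpha(ps)
subset(tab, emotion == "Fear" & quantity == "DOPvsNOP",
       c(mean, hdi_lower, hdi_upper, decision))
#>         mean hdi_lower hdi_upper decision
#> 14 -10.03865 -26.67758   10.6336 withheld
```

The `mean` column is the posterior mean of the DOP-vs-NOP difference in
feedback-induced accuracy change for Fear, in percentage points; at this
tiny sample the 95% HDI overlaps the (−5, 5) ROPE, so the decision is
withheld rather than forced. `buildTableBetaRt()`, `buildTableBetaTrial()`
and `spqEffectSummary()` produce the analogous penalty, learning-curve and
schizotypy summaries; `posteriorPredictive()` evaluates the fitted curves
on full-intensity, RT-bin and trial grids.

A full pipeline (simulate → fit → report, with every table, a decisions
JSON and resolved configs written to disk) runs from one configuration:

```r
runAll(runConfig(out_dir = "my_run", seed = 1))
```

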