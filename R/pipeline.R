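## End-to-end pipeline: simulate -> fit -> report, driven by one
## serializable configuration.

#' Build a run configuration
#'
#' One serializable list driving the whole pipeline; every stage echoes the
#' resolved configuration next to its outputs for provenance. Any field can
#' be overridden; defaults reproduce the study conditions at the default
#' sampler budget.
#'
#' @param out_dir output directory.
#' @param seed master integer seed (design, RTs, SPQ, responses and the
#'   sampler all derive their seeds from it).
#' @param preset true-parameter preset name for simulation.
#' @param n_dop,n_nop,n_actors,emotions,spq_completers design fields, see
#'   [designSpec()].
#' @param sampler a [samplerConfig()].
#' @param rope_alpha,rope_trial,rope_spq_direct,rope_spq_moderation ROPE
#'   overrides for the report stage.
#' @param contrast_sign learning-table contrast sign convention.
#' @param rt_meanlog,rt_sdlog RT-generator parameters.
#' @return Named list (the run configuration).
#' @export
runConfig <- function(out_dir = tempfile("dopfer_run_"), seed = 1L,
                      preset = "paper-like", n_dop = 88, n_nop = 95,
                      n_actors = 10, emotions = dopferEmotions,
                      spq_completers = c(DOP = 58, NOP = 51),
                      sampler = samplerConfig(seed = seed),
                      rope_alpha = ropeHalfwidthAccuracy(),
                      rope_trial = round(ropeHalfwidthProbability(), 1),
                      rope_spq_direct =
                        round(ropeHalfwidthProbability(sd_span = 2), 1),
                      rope_spq_moderation = ropeHalfwidthModeration(),
                      contrast_sign = "first-minus-second",
                      rt_meanlog = log(4), rt_sdlog = 0.45) {
  list(out_dir = out_dir, seed = as.integer(seed), preset = preset,
       n_dop = n_dop, n_nop = n_nop, n_actors = n_actors,
       emotions = emotions,
       spq_completers = as.list(spq_completers),
       sampler = sampler, rope_alpha = rope_alpha,
       rope_trial = rope_trial, rope_spq_direct = rope_spq_direct,
       rope_spq_moderation = rope_spq_moderation,
       contrast_sign = contrast_sign, rt_meanlog = rt_meanlog,
       rt_sdlog = rt_sdlog)
}

.writeResolvedConfig <- function(config, stage) {
  yaml::write_yaml(config, file.path(config$out_dir,
                                     paste0("config_", stage, ".yaml")))
}

.configPaths <- function(config) {
  list(trials = file.path(config$out_dir, "trials.csv"),
       spq = file.path(config$out_dir, "spq.csv"),
       draws = file.path(config$out_dir, "draws.csv"),
       report = file.path(config$out_dir, "report"))
}

#' Pipeline stages
#'
#' `runSimulate()` generates a synthetic dataset from the configured design
#' and preset and writes the trial and SPQ CSVs. `runFit()` reads them back
#' through the validating readers and samples the posterior, persisting
#' draws and diagnostics. `runReport()` is a pure function of the persisted
#' draws: it writes the three condition summary tables, the SPQ effect
#' summary (when fitted), posterior-predictive grids and a JSON decisions
#' report. `runAll()` chains the three.
#'
#' @param config a [runConfig()] list (or a path to a YAML file of one).
#' @return `runSimulate`: the dataset; `runFit`: the
#'   [PosteriorDraws-class]; `runReport`/`runAll`: named list of result
#'   tables (invisibly for `runAll`).
#' @name pipeline
NULL

.loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config
}

#' @rdname pipeline
#' @export
runSimulate <- function(config = runConfig()) {
  config <- .loadConfig(config)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  spec <- designSpec(n_dop = config$n_dop, n_nop = config$n_nop,
                     n_actors = config$n_actors,
                     emotions = config$emotions,
                     spq_completers = unlist(config$spq_completers),
                     seed = config$seed)
  index <- conditionIndex(emotions = config$emotions)
  ds <- simulateDataset(spec, true_params = config$preset,
                        rt_model = rtModel(index, config$rt_meanlog,
                                           config$rt_sdlog),
                        index = index)
  paths <- .configPaths(config)
  writeTrialTable(ds, paths$trials, paths$spq)
  .writeResolvedConfig(config, "simulate")
  message(sprintf("simulate: %d trials, %d participants, %d SPQ -> %s",
                  nrow(trials(ds)),
                  length(unique(trials(ds)$participant_id)),
                  nrow(spqProfiles(ds)), paths$trials))
  invisible(ds)
}

#' @rdname pipeline
#' @export
runFit <- function(config = runConfig()) {
  config <- .loadConfig(config)
  paths <- .configPaths(config)
  if (!file.exists(paths$trials))
    stop("no trial file at ", paths$trials, "; run runSimulate() first")
  spq <- if (file.exists(paths$spq))
    standardizeFactors(readSpqTable(paths$spq)) else NULL
  ds <- readTrialTable(paths$trials, spq = spq)
  cfg <- do.call(samplerConfig, config$sampler)
  ps <- samplePosterior(ds, cfg)
  writeDraws(ps, paths$draws)
  .writeResolvedConfig(config, "fit")
  rh <- ps@diagnostics$rhat
  message(sprintf("fit: %d draws x %d params, R-hat in [%.3f, %.3f]",
                  nrow(posteriorMatrix(ps)), ncol(posteriorMatrix(ps)),
                  if (length(rh)) min(rh) else NA,
                  if (length(rh)) max(rh) else NA))
  invisible(ps)
}

#' @rdname pipeline
#' @export
runReport <- function(config = runConfig()) {
  config <- .loadConfig(config)
  paths <- .configPaths(config)
  if (!file.exists(paths$draws))
    stop("no draws file at ", paths$draws, "; run runFit() first")
  ps <- readDraws(paths$draws)
  results <- list(
    table_alpha = buildTableAlpha(ps, rope_pct = config$rope_alpha),
    table_beta_rt = buildTableBetaRt(ps),
    table_beta_trial = buildTableBetaTrial(
      ps, rope_halfwidth = config$rope_trial,
      sign = config$contrast_sign),
    predictive_full_intensity = posteriorPredictive(
      ps, ppGridFullIntensity(ps@index)),
    predictive_rt_bins = posteriorPredictive(ps, ppGridRtBins(ps@index)),
    predictive_trials = posteriorPredictive(ps, ppGridTrials(ps@index)))
  if (ps@includeSpq)
    results$spq_effects <- spqEffectSummary(
      ps, rope_direct = config$rope_spq_direct,
      rope_moderation = config$rope_spq_moderation)
  writeSummary(results, paths$report, config = config)
  .writeResolvedConfig(config, "report")
  dec <- unlist(lapply(results, function(df)
    if ("decision" %in% names(df)) df$decision[!is.na(df$decision)]))
  tal <- table(factor(dec, c("credible", "negligible", "withheld")))
  message(sprintf("report: decisions credible=%d negligible=%d withheld=%d",
                  tal[["credible"]], tal[["negligible"]],
                  tal[["withheld"]]))
  invisible(results)
}

#' @rdname pipeline
#' @export
runAll <- function(config = runConfig()) {
  config <- .loadConfig(config)
  runSimulate(config)
  runFit(config)
  runReport(config)
}
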