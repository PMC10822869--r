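## Readers, writers and dataset validation.

.trialCols <- c("participant_id", "group", "feedback", "emotion",
                "actor_id", "trial_index", "rt_seconds", "correct")

#' Construct and validate a TrialDataset
#'
#' Checks every stated invariant and reports *all* violations (with row
#' numbers), not only the first: enumeration labels, `rt_seconds` in
#' (0, 10], `trial_index` in 1..10, `actor_id` in 1..10, binary `correct`,
#' one group per participant, at most one trial per
#' (participant, feedback, emotion, trial_index), and SPQ rows referencing
#' existing participants with factor scores inside their ranges.
#' Reaction times below 0.05 s are accepted with a warning (the log
#' covariate becomes extreme); rejection is reserved for `rt <= 0`.
#'
#' @param trials data.frame of trial records (see [TrialDataset-class]).
#' @param spq optional data.frame of SPQ profiles.
#' @return A validated [TrialDataset-class].
#' @export
trialDataset <- function(trials, spq = NULL) {
  if (is.null(spq))
    spq <- data.frame(participant_id = character(), raw_cp = integer(),
                      raw_in = integer(), raw_di = integer(),
                      raw_total = integer())
  miss <- setdiff(.trialCols, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  probs <- character()
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      probs <<- c(probs, sprintf("%s (rows %s)", what,
                                 paste(head(rows, 10), collapse = ", ")))
  }
  bad(!trials$group %in% dopferGroups, "unknown group label")
  bad(!trials$feedback %in% dopferFeedbacks, "unknown feedback label")
  bad(!trials$emotion %in% dopferEmotions, "unknown emotion label")
  bad(!is.finite(trials$rt_seconds) | trials$rt_seconds <= 0 |
        trials$rt_seconds > 10, "rt_seconds outside (0, 10]")
  bad(trials$trial_index != round(trials$trial_index) |
        trials$trial_index < 1 | trials$trial_index > 10,
      "trial_index outside 1..10")
  bad(trials$actor_id != round(trials$actor_id) | trials$actor_id < 1 |
        trials$actor_id > 10, "actor_id outside 1..10")
  bad(!trials$correct %in% c(0, 1), "correct must be 0 or 1")
  key <- paste(trials$participant_id, trials$feedback, trials$emotion,
               trials$trial_index)
  bad(duplicated(key),
      "duplicated (participant, feedback, emotion, trial_index)")
  pg <- unique(trials[, c("participant_id", "group")])
  multi <- pg$participant_id[duplicated(pg$participant_id)]
  if (length(multi))
    probs <- c(probs, sprintf("participant(s) with more than one group: %s",
                              paste(unique(multi), collapse = ", ")))
  if (nrow(spq)) {
    orphan <- setdiff(spq$participant_id, trials$participant_id)
    if (length(orphan) && nrow(trials))
      probs <- c(probs, sprintf("SPQ profiles for unknown participant(s): %s",
                                paste(orphan, collapse = ", ")))
    rng <- list(raw_cp = 33, raw_in = 33, raw_di = 16, raw_total = 74)
    for (f in names(rng)) {
      v <- spq[[f]]
      if (!is.null(v) && any(!is.na(v) & (v < 0 | v > rng[[f]])))
        probs <- c(probs, sprintf("%s outside 0..%d", f, rng[[f]]))
    }
  }
  if (length(probs))
    stop("invalid trial dataset:\n  - ", paste(probs, collapse = "\n  - "))
  slow <- sum(trials$rt_seconds < 0.05)
  if (slow)
    warning(sprintf("%d trial(s) with rt_seconds < 0.05 s: log covariate %s",
                    slow, "will be extreme"))
  new("TrialDataset", trials = trials, spq = spq)
}

#' Read a trial table from delimited text
#'
#' One row per trial. Columns may be remapped from an arbitrary dialect via
#' `col_map`; unknown columns are preserved as metadata and row order is
#' retained. The resulting records are fully validated (see
#' [trialDataset()]).
#'
#' @param path file path.
#' @param dialect list with `sep` (default `","`) and `col_map`, a named
#'   character vector mapping canonical names to file column names, e.g.
#'   `c(rt_seconds = "RT")`.
#' @param spq optional SPQ profile table to attach.
#' @return A [TrialDataset-class] (trials only unless `spq` is given).
#' @export
readTrialTable <- function(path, dialect = list(), spq = NULL) {
  sep <- dialect$sep %||% ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  cm <- dialect$col_map
  if (!is.null(cm))
    for (canon in names(cm)) {
      j <- match(cm[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
  miss <- setdiff(.trialCols, names(df))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  # enforce the typed schema regardless of how the text parsed
  df$rt_seconds <- as.double(df$rt_seconds)
  for (cl in c("actor_id", "trial_index", "correct"))
    df[[cl]] <- as.integer(df[[cl]])
  trialDataset(df, spq = spq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an SPQ table (items or precomputed factor scores)
#'
#' Accepts either 74 item columns (`item_1` .. `item_74`, values 0/1),
#' which are scored through [scoreSubscales()] and [factorScores()], or
#' precomputed factor columns `raw_cp`, `raw_in`, `raw_di`, `raw_total`.
#' Standardization is deferred to [standardizeFactors()].
#'
#' @param path file path (CSV with a `participant_id` column).
#' @return data.frame of profiles with raw scores populated.
#' @export
readSpqTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(df))
    stop("SPQ table needs a participant_id column")
  itemCols <- paste0("item_", 1:74)
  if (all(itemCols %in% names(df))) {
    fs <- factorScores(scoreSubscales(df[, itemCols]))
    return(cbind(data.frame(participant_id = df$participant_id,
                            stringsAsFactors = FALSE), fs))
  }
  facCols <- c("raw_cp", "raw_in", "raw_di", "raw_total")
  if (!all(facCols %in% names(df)))
    stop("SPQ table must carry item_1..item_74 or ",
         paste(facCols, collapse = ", "))
  rng <- c(raw_cp = 33, raw_in = 33, raw_di = 16, raw_total = 74)
  for (f in names(rng))
    if (any(df[[f]] < 0 | df[[f]] > rng[[f]]))
      stop(f, " outside its range 0..", rng[[f]])
  df[, c("participant_id", facCols)]
}

## %.17g formatting so numeric CSV round-trips are bit-exact
.numToChar <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Write a trial dataset to CSV files
#'
#' @param dataset a [TrialDataset-class].
#' @param trials_path output CSV for the trial table.
#' @param spq_path optional output CSV for the SPQ profile table (written
#'   only when profiles exist).
#' @return Invisibly, the paths written.
#' @export
writeTrialTable <- function(dataset, trials_path, spq_path = NULL) {
  write.csv(.numToChar(trials(dataset)), trials_path, row.names = FALSE,
            quote = FALSE)
  out <- trials_path
  if (!is.null(spq_path) && nrow(spqProfiles(dataset))) {
    write.csv(.numToChar(spqProfiles(dataset)), spq_path,
              row.names = FALSE, quote = FALSE)
    out <- c(out, spq_path)
  }
  invisible(out)
}

#' Write posterior summary tables and a decisions report
#'
#' Writes every data.frame in `results` as a CSV (numerics serialized so a
#' read-back is bit-exact) plus one JSON report collecting all interval /
#' ROPE decisions and the resolved configuration for provenance.
#'
#' @param results named list of data.frames (e.g. the output of
#'   [buildTableAlpha()], [buildTableBetaRt()], [buildTableBetaTrial()],
#'   [spqEffectSummary()], [posteriorPredictive()]).
#' @param path output directory (created if needed).
#' @param config optional list echoed into the JSON report.
#' @return Invisibly, the file paths written.
#' @export
writeSummary <- function(results, path, config = list()) {
  stopifnot(is.list(results))
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE)
  files <- character()
  for (nm in names(results)) {
    f <- file.path(path, paste0(nm, ".csv"))
    write.csv(.numToChar(results[[nm]]), f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  decisions <- list()
  for (nm in names(results)) {
    df <- results[[nm]]
    if (is.data.frame(df) && all(c("decision", "hdi_lower", "hdi_upper")
                                 %in% names(df))) {
      keep <- !is.na(df$decision)
      decisions[[nm]] <- df[keep, , drop = FALSE]
    }
  }
  jf <- file.path(path, "decisions.json")
  jsonlite::write_json(list(config = config, decisions = decisions), jf,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(files, jf))
}
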