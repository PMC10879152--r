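#' Write / read a stimulation train as CSV
#'
#' Long-format CSV with columns \code{onset_s}, \code{amplitude_ua},
#' \code{pulse_width_us}, \code{charge_nc}; the encoding label and duration
#' travel in a header comment line.
#'
#' @param train a \linkS4class{StimTrain}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeStimTrainCsv <- function(train, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# encoding=%s duration=%.9g", train@encoding,
                     train@duration), con)
  df <- data.frame(onset_s = train@onsets, amplitude_ua = train@amplitudeUa,
                   pulse_width_us = train@pulseWidthUs,
                   charge_nc = chargePerPulse(train))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStimTrainCsv
#' @export
readStimTrainCsv <- function(path) {
  header <- readLines(path, n = 1)
  meta <- regmatches(header,
                     regexec("encoding=(\\S+) duration=(\\S+)", header))[[1]]
  df <- read.csv(path, comment.char = "#")
  new("StimTrain", onsets = df$onset_s, amplitudeUa = df$amplitude_ua,
      pulseWidthUs = df$pulse_width_us, encoding = meta[2],
      duration = as.numeric(meta[3]))
}

#' Write spike trains as long-format CSV
#'
#' Columns \code{unit_id}, \code{class}, \code{spike_time_s}.
#'
#' @param spikeSet a \linkS4class{SpikeTrainSet}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSpikesCsv <- function(spikeSet, path) {
  n <- vapply(spikeSet@spikes, length, integer(1))
  df <- data.frame(unit_id = rep(seq_along(n), n),
                   class = rep(spikeSet@unitClass, n),
                   spike_time_s = unlist(spikeSet@spikes, use.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

RATINGS_COLUMNS <- c("participant", "site", "region", "encoding", "trial",
                     "naturalness")
TASK_COLUMNS <- c("participant", "condition", "session", "metric", "value")

#' Read a sensation-ratings table
#'
#' Expects the schema \code{participant, site, region, encoding, trial,
#' naturalness} (an \code{intensity} column is optional); naturalness is a
#' 0-5 visual analog scale.  A YAML mapping file can translate foreign
#' column names, e.g. for the deposited study tables.
#'
#' @param path CSV path.
#' @param mappingYaml optional YAML file mapping our column names to the
#'   file's column names (\code{ours: theirs} entries).
#' @return validated data.frame.
#' @export
readRatingsTable <- function(path, mappingYaml = NULL) {
  df <- read.csv(path)
  df <- applyColumnMapping(df, mappingYaml)
  missing <- setdiff(RATINGS_COLUMNS, names(df))
  if (length(missing))
    stop("ratings table lacks columns: ", paste(missing, collapse = ", "))
  if (any(df$naturalness < 0 | df$naturalness > 5))
    stop("naturalness must lie in [0, 5]")
  df
}

#' Read a functional-task table
#'
#' Expects the schema \code{participant, condition, session, metric, value}
#' with conditions NF/LIN/DISC/BIOM and metrics such as
#' \code{laps_per_session}, \code{walking_speed_mps},
#' \code{spelling_accuracy_pct} and \code{confidence_vas}.
#'
#' @inheritParams readRatingsTable
#' @return validated data.frame.
#' @export
readTaskTable <- function(path, mappingYaml = NULL) {
  df <- read.csv(path)
  df <- applyColumnMapping(df, mappingYaml)
  missing <- setdiff(TASK_COLUMNS, names(df))
  if (length(missing))
    stop("task table lacks columns: ", paste(missing, collapse = ", "))
  acc <- df$value[df$metric == "spelling_accuracy_pct"]
  if (length(acc) && any(acc < 0 | acc > 100))
    stop("spelling accuracy must lie in [0, 100]")
  conf <- df$value[df$metric == "confidence_vas"]
  if (length(conf) && any(conf < 0 | conf > 10))
    stop("confidence VAS must lie in [0, 10]")
  df
}

applyColumnMapping <- function(df, mappingYaml) {
  if (is.null(mappingYaml)) return(df)
  mp <- yaml::read_yaml(mappingYaml)
  for (ours in names(mp)) {
    theirs <- mp[[ours]]
    if (!theirs %in% names(df))
      stop("mapped column not found in file: ", theirs)
    names(df)[names(df) == theirs] <- ours
  }
  df
}

#' Recompute the published human-study benchmarks from deposited tables
#'
#' Given a directory containing \code{ratings.csv} and \code{tasks.csv} in
#' the package schema (use the YAML mapping to adapt foreign columns),
#' recomputes the pooled naturalness medians per encoding family
#' (biomimetic versus linear) and the stairs-task speed per condition.
#'
#' @param dir directory with the deposited tables.
#' @param mappingYaml optional YAML column mapping applied to both tables.
#' @return list with \code{naturalness} (summary data.frame) and
#'   \code{stairSpeed} (mean laps/session per participant and condition).
#' @export
depositedBenchmarks <- function(dir, mappingYaml = NULL) {
  ratingsPath <- file.path(dir, "ratings.csv")
  tasksPath <- file.path(dir, "tasks.csv")
  if (!file.exists(ratingsPath) || !file.exists(tasksPath))
    stop("deposited tables not found under ", dir)
  ratings <- readRatingsTable(ratingsPath, mappingYaml)
  tasks <- readTaskTable(tasksPath, mappingYaml)
  ratings$family <- ifelse(grepl("^BIOM", ratings$encoding), "biomimetic",
                    ifelse(ratings$encoding == "LIN", "linear",
                           tolower(ratings$encoding)))
  nat <- summarizeRatings(ratings, "naturalness",
                          c("participant", "family"))
  st <- tasks[tasks$metric == "laps_per_session", , drop = FALSE]
  speed <- if (nrow(st)) {
    agg <- tapply(st$value, list(st$participant, st$condition), mean)
    as.data.frame.table(agg, responseName = "laps_per_session")
  } else data.frame()
  list(naturalness = nat, stairSpeed = speed)
}

#' Tidy result table of a synthetic-experiment run
#'
#' Long-format data.frame (\code{condition}, \code{metric}, \code{value})
#' with the headline numbers of a \code{\link{runSyntheticExperiment}}
#' result; write it with \code{write.csv} for downstream tooling.
#'
#' @param results list returned by \code{\link{runSyntheticExperiment}}.
#' @return data.frame in long format.
#' @export
resultsTable <- function(results) {
  rows <- list(
    c("biomimetic", "kl_vs_natural", klValue(results$klBiom)),
    c("tonic", "kl_vs_natural", klValue(results$klTonic)),
    c("natural", "summed_activity", results$activity[["natural"]]),
    c("biomimetic", "summed_activity", results$activity[["biomimetic"]]),
    c("tonic", "summed_activity", results$activity[["tonic"]]),
    c("biomimetic", "csd_median_channel_r",
      median(channelR(results$corrBiom), na.rm = TRUE)),
    c("tonic", "csd_median_channel_r",
      median(channelR(results$corrTonic), na.rm = TRUE)),
    c("biomimetic", "csd_shuffled_median_r",
      median(shuffleR(results$corrBiom), na.rm = TRUE)),
    c("biomimetic", "transmission_xcorr_peak", results$transmission@peak))
  out <- data.frame(condition = vapply(rows, `[`, "", 1),
                    metric = vapply(rows, `[`, "", 2),
                    value = as.numeric(vapply(rows, `[`, "", 3)))
  out
}

#' Write an analysis report as JSON
#'
#' Flattens the headline numbers of a synthetic-experiment result (KL
#' divergences, summed normalized activity, CSD correlation summaries,
#' transmission peak) into a JSON file.
#'
#' @param results list returned by \code{\link{runSyntheticExperiment}}.
#' @param path output JSON path.
#' @return the report list, invisibly.
#' @export
writeAnalysisReport <- function(results, path) {
  rep <- list(
    kl_biomimetic_vs_natural = klValue(results$klBiom),
    kl_tonic_vs_natural = klValue(results$klTonic),
    summed_activity = as.list(results$activity),
    csd_median_channel_r_biomimetic = median(channelR(results$corrBiom),
                                             na.rm = TRUE),
    csd_median_channel_r_tonic = median(channelR(results$corrTonic),
                                        na.rm = TRUE),
    csd_shuffle_median_r_biomimetic = median(shuffleR(results$corrBiom),
                                             na.rm = TRUE),
    transmission_xcorr_peak = results$transmission@peak)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
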