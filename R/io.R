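# Text-format I/O: trace CSVs with JSON sidecars, cohort directories, all
# UTF-8 with "." decimal separators and full-precision numerics so a fixed
# seed reproduces byte-identical files.

#' Write a motion trace to CSV plus a JSON sidecar
#'
#' The CSV holds one sample per row with a leading time column `t` (s)
#' followed by the named channels; the sidecar carries `activity`, `fs`,
#' `participant_id` and the phase annotations. Numerics are written with
#' full precision so read-back is lossless.
#'
#' @param trace A [motion_trace].
#' @param csv_path,sidecar_path Output paths.
#' @return Invisibly, `csv_path`.
#' @export
write_trace <- function(trace, csv_path, sidecar_path) {
  df <- data.frame(t = (seq_len(trace$n) - 1) / trace$fs)
  for (nm in names(trace$channels)) df[[nm]] <- trace$channels[[nm]]
  write_csv_exact(df, csv_path)
  side <- list(activity = trace$activity, fs = trace$fs,
               participant_id = trace$participant_id,
               phases = trace$phases)
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", null = "null")
  invisible(csv_path)
}

#' Read a motion trace from CSV plus its JSON sidecar
#'
#' Validates the sidecar schema (activity, sampling rate, phase bounds) and
#' the channel set against the activity's requirements; errors name the
#' offending field.
#'
#' @param csv_path,sidecar_path Input paths written by [write_trace()] (or
#'   any files in the same dialect).
#' @return A validated [motion_trace].
#' @export
read_trace <- function(csv_path, sidecar_path) {
  if (!file.exists(csv_path)) {
    mvh_stop(sprintf("trace file not found: %s", csv_path))
  }
  if (!file.exists(sidecar_path)) {
    mvh_stop(sprintf("sidecar file not found: %s", sidecar_path))
  }
  side <- jsonlite::fromJSON(sidecar_path)
  for (field in c("activity", "fs")) {
    if (is.null(side[[field]])) {
      mvh_stop(sprintf("sidecar %s is missing required field '%s'",
                       sidecar_path, field))
    }
  }
  df <- utils::read.csv(csv_path)
  if (names(df)[1] != "t") {
    mvh_stop(sprintf("trace CSV %s must start with a time column 't'",
                     csv_path))
  }
  channels <- as.list(df[-1])
  phases <- side$phases
  if (!is.null(phases) && length(phases) == 0) phases <- NULL
  motion_trace(activity = side$activity, fs = side$fs, channels = channels,
               phases = phases, participant_id = side$participant_id)
}

#' Write a simulated cohort to a directory
#'
#' Emits the full text bundle: per-activity trace CSVs and sidecars under
#' `traces/`, the long functional-trial table, the balance-sway sample
#' table, the per-trial score table, the participant table, and a manifest
#' JSON echoing the generation settings. All paths in the manifest are
#' relative; re-running with the same seed reproduces identical bytes.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  trace_files <- list()
  for (id in names(cohort$traces)) {
    for (act in names(cohort$traces[[id]])) {
      stem <- file.path("traces", paste0(id, "_", act))
      write_trace(cohort$traces[[id]][[act]],
                  file.path(dir, paste0(stem, ".csv")),
                  file.path(dir, paste0(stem, ".json")))
      trace_files[[length(trace_files) + 1]] <-
        list(participant_id = id, activity = act,
             csv = paste0(stem, ".csv"), sidecar = paste0(stem, ".json"))
    }
  }

  trial_rows <- do.call(rbind, lapply(names(cohort$tests), function(id) {
    cbind(participant_id = id, cohort$tests[[id]]$trials)
  }))
  write_csv_exact(trial_rows, file.path(dir, "functional_trials.csv"))

  acc_rows <- do.call(rbind, lapply(names(cohort$tests), function(id) {
    acc <- cohort$tests[[id]]$acc
    do.call(rbind, lapply(names(acc), function(test) {
      do.call(rbind, lapply(seq_along(acc[[test]]), function(k) {
        cbind(participant_id = id, test = test, trial = k, acc[[test]][[k]])
      }))
    }))
  }))
  if (is.null(acc_rows)) {
    acc_rows <- data.frame(participant_id = character(), test = character(),
                           trial = integer(), x = numeric(), y = numeric())
  }
  write_csv_exact(acc_rows, file.path(dir, "balance_acc.csv"))

  write_csv_exact(cohort$scores, file.path(dir, "scores.csv"))
  write_csv_exact(cohort$profiles, file.path(dir, "participants.csv"))

  manifest <- list(
    format = "movemetrics-cohort",
    tool_version = as.character(utils::packageVersion("movemetrics")),
    spec = unclass(cohort$spec),
    n_participants = nrow(cohort$profiles),
    files = list(participants = "participants.csv", scores = "scores.csv",
                 functional_trials = "functional_trials.csv",
                 balance_acc = "balance_acc.csv"),
    traces = trace_files
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest_path)
}

#' Read a cohort directory back into memory
#'
#' Inverse of [write_cohort()]; traces are re-validated on ingestion.
#'
#' @param dir Directory containing a `manifest.json`.
#' @return A list of class `mvh_cohort` with the same shape as
#'   [simulate_cohort()].
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    mvh_stop(sprintf("no manifest.json in %s", dir))
  }
  manifest <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = TRUE)
  profiles <- utils::read.csv(file.path(dir, manifest$files$participants))
  scores <- utils::read.csv(file.path(dir, manifest$files$scores))
  trials <- utils::read.csv(file.path(dir, manifest$files$functional_trials),
                            colClasses = c(limb = "character"))
  trials$limb[is.na(trials$limb)] <- ""
  acc_rows <- utils::read.csv(file.path(dir, manifest$files$balance_acc))

  traces <- list()
  tr <- manifest$traces
  for (i in seq_len(nrow(tr))) {
    id <- tr$participant_id[i]
    traces[[id]][[tr$activity[i]]] <- read_trace(
      file.path(dir, tr$csv[i]), file.path(dir, tr$sidecar[i]))
  }

  tests <- list()
  for (id in profiles$participant_id) {
    t_id <- trials[trials$participant_id == id, -1, drop = FALSE]
    acc_id <- acc_rows[acc_rows$participant_id == id, , drop = FALSE]
    acc <- lapply(c(ctsib = "ctsib", romberg = "romberg"), function(test) {
      a <- acc_id[acc_id$test == test, , drop = FALSE]
      lapply(sort(unique(a$trial)), function(k) {
        a[a$trial == k, c("x", "y"), drop = FALSE]
      })
    })
    tests[[id]] <- list(trials = t_id, acc = acc)
  }

  spec <- manifest$spec
  structure(
    list(spec = spec, profiles = profiles, traces = traces,
         scores = scores, tests = tests),
    class = "mvh_cohort"
  )
}
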