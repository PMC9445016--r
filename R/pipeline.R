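# End-to-end pipeline: simulate -> write -> read back -> extract -> score
# -> validate. Also the per-stage assemblers the CLI wrapper calls.

#' Extract activity metrics for every participant of a cohort
#'
#' @param traces List keyed by participant id, each a named list of
#'   [motion_trace] objects by activity (as in an `mvh_cohort`).
#' @return Data frame with one row per participant (see [extract_all()]).
#' @export
extract_cohort_metrics <- function(traces) {
  do.call(rbind, lapply(names(traces), function(id) {
    extract_all(traces[[id]], participant_id = id)
  }))
}

#' Score the functional tests for every participant of a cohort
#'
#' @param tests List keyed by participant id with `trials` and `acc`
#'   entries (as in an `mvh_cohort`).
#' @param profiles Participant table carrying `leg_length` and
#'   `arm_length`.
#' @return Data frame with one row per participant (see
#'   [assemble_test_scores()]).
#' @export
score_cohort_tests <- function(tests, profiles) {
  do.call(rbind, lapply(names(tests), function(id) {
    pr <- profiles[profiles$participant_id == id, ]
    assemble_test_scores(tests[[id]]$trials, acc = tests[[id]]$acc,
                         leg_length = pr$leg_length,
                         arm_length = pr$arm_length,
                         participant_id = id)
  }))
}

#' Run the full validation pipeline on a synthetic cohort
#'
#' Generates a cohort at the given seed, writes it to `out_dir/cohort/`,
#' reads it back through the ingestion readers (so the round trip is part
#' of every run), extracts the sensor metrics, scores the functional
#' tests, builds the validation report, and writes `metrics.csv`,
#' `test_scores.csv`, `report.json` and the correlation-grid CSVs to
#' `out_dir`. A fixed seed reproduces every output byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for cohort generation.
#' @param n Number of participants (default 150).
#' @param alpha Significance level (default 0.05).
#' @param gate Normality gate mode, see [gated_correlation()].
#' @param var_equal Equal-variance t-tests (default `TRUE`).
#' @param p_adjust Multiple-testing correction (default `"none"`).
#' @param quiet Suppress progress messages (messages go to stderr).
#' @param spec Optional pre-built [cohort_spec()]; overrides `n`/`seed`.
#' @return Invisibly, a list with the `report` and the output `paths`.
#' @export
run_pipeline <- function(out_dir, seed, n = 150, alpha = 0.05,
                         gate = "both", var_equal = TRUE, p_adjust = "none",
                         quiet = FALSE, spec = NULL) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(spec)) {
    spec <- cohort_spec(n = n, seed = seed)
  }
  say("simulating cohort (n = %d, seed = %d)", spec$n, spec$seed)
  cohort <- simulate_cohort(spec)

  cohort_dir <- file.path(out_dir, "cohort")
  say("writing cohort to %s", cohort_dir)
  write_cohort(cohort, cohort_dir)
  cohort <- read_cohort(cohort_dir)

  say("extracting activity metrics")
  metrics <- extract_cohort_metrics(cohort$traces)
  say("scoring functional tests")
  test_scores <- score_cohort_tests(cohort$tests, cohort$profiles)

  say("building validation report")
  config <- list(alpha = alpha, gate = gate, var_equal = var_equal,
                 p_adjust = p_adjust, required_trials = 3,
                 seed = spec$seed, n = spec$n)
  report <- build_report(metrics, test_scores, cohort$scores,
                         cohort$profiles, config = config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    metrics = file.path(out_dir, "metrics.csv"),
    test_scores = file.path(out_dir, "test_scores.csv"),
    report = file.path(out_dir, "report.json")
  )
  write_csv_exact(metrics, paths$metrics)
  write_csv_exact(test_scores, paths$test_scores)
  write_report(report, paths$report)
  say("done: %s", paths$report)
  invisible(list(report = report, paths = paths, cohort_dir = cohort_dir))
}
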