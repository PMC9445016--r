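# Concurrent-validity statistics: Shapiro-Wilk-gated correlation,
# direction-agreement evaluation, group comparisons, null calibration, and
# intrasubject test-retest reliability.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with the sample-size and
#' degeneracy checks the gating logic relies on.
#'
#' @param x Numeric values; `NA`s are dropped. Requires 3 to 5000 values.
#' @return List with `W`, `p` and `n`.
#' @export
normality_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) {
    mvh_stop("Shapiro-Wilk requires at least 3 observations",
             class = "mvh_insufficient_data_error")
  }
  if (n > 5000) {
    mvh_stop("Shapiro-Wilk supports at most 5000 observations")
  }
  if (stats::sd(x) == 0) {
    mvh_stop("all values are identical; normality is undefined",
             class = "mvh_degenerate_error")
  }
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value, n = n)
}

#' Normality-gated correlation with direction agreement
#'
#' Correlates two variables the way the validation analysis prescribes:
#' Pearson's product-moment coefficient when the variables are normally
#' distributed (Shapiro-Wilk p > `alpha`), Spearman's rank coefficient
#' otherwise. By default *both* variables must pass normality for Pearson
#' to be used (`gate = "both"`); `gate = "either"` relaxes this to one.
#' Missing values are removed pairwise. The `agreement` flag records a
#' statistically significant correlation in the hypothesised direction.
#'
#' @param x,y Numeric vectors of equal length.
#' @param alpha Significance level for both the normality gate and the
#'   agreement flag (default 0.05).
#' @param hypothesized_sign `"+"`, `"-"`, or `"none"`.
#' @param gate `"both"` (default) or `"either"`.
#' @return An object of class `mvh_correlation`: list with `r`, `method`
#'   (`"pearson"`/`"spearman"`), two-sided `p`, `n`, `hypothesized_sign`
#'   and `agreement`.
#' @export
gated_correlation <- function(x, y, alpha = 0.05,
                              hypothesized_sign = c("none", "+", "-"),
                              gate = c("both", "either")) {
  hypothesized_sign <- match.arg(hypothesized_sign)
  gate <- match.arg(gate)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4) {
    mvh_stop("at least 4 complete pairs are required",
             class = "mvh_insufficient_data_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    mvh_stop("a variable with zero variance cannot be correlated",
             class = "mvh_degenerate_error")
  }
  px <- normality_test(x)$p
  py <- normality_test(y)$p
  normal <- if (gate == "both") px > alpha && py > alpha else px > alpha || py > alpha
  method <- if (normal) "pearson" else "spearman"
  ct <- if (method == "pearson") {
    stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  } else {
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided",
                    exact = FALSE)
  }
  r <- unname(ct$estimate)
  agreement <- hypothesized_sign != "none" &&
    ct$p.value < alpha &&
    sign(r) == (if (hypothesized_sign == "+") 1 else -1)
  structure(
    list(r = r, method = method, p = ct$p.value, n = length(x),
         normal_x_p = px, normal_y_p = py,
         hypothesized_sign = hypothesized_sign, agreement = agreement),
    class = "mvh_correlation"
  )
}

#' @export
print.mvh_correlation <- function(x, ...) {
  cat(sprintf("%s r = %.3f (p = %.3g, n = %d)%s\n",
              x$method, x$r, x$p, x$n,
              if (x$hypothesized_sign != "none") {
                sprintf(", hypothesis %s: %s", x$hypothesized_sign,
                        if (x$agreement) "agrees" else "no agreement")
              } else ""))
  invisible(x)
}

#' Correlation grid between a score and a set of features
#'
#' One normality-gated correlation per feature column against the score
#' column, with the hypothesised direction taken from `hypotheses`. Cells
#' that are not statistically significant are flagged (`significant =
#' FALSE`) so downstream rendering can grey them out.
#'
#' @param data Data frame containing the score and feature columns.
#' @param score_col Name of the score column.
#' @param feature_cols Names of the feature columns.
#' @param hypotheses Named character vector (`"+"`/`"-"`/`"none"`) over the
#'   features; unnamed features default to `"none"`.
#' @param alpha Significance level (default 0.05).
#' @param gate Normality gate mode, see [gated_correlation()].
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; the default `"none"` mirrors per-cell testing at
#'   `alpha`. `"BH"` gives Benjamini-Hochberg adjusted p-values.
#' @return Data frame with one row per feature: `feature`, `hypothesis`,
#'   `method`, `r`, `p`, `n`, `significant`, `agreement`.
#' @export
correlation_grid <- function(data, score_col, feature_cols,
                             hypotheses = NULL, alpha = 0.05,
                             gate = c("both", "either"),
                             p_adjust = "none") {
  gate <- match.arg(gate)
  if (length(feature_cols) == 0) {
    return(data.frame(feature = character(), hypothesis = character(),
                      method = character(), r = numeric(), p = numeric(),
                      n = integer(), significant = logical(),
                      agreement = logical()))
  }
  rows <- lapply(feature_cols, function(f) {
    hyp <- if (!is.null(hypotheses) && f %in% names(hypotheses)) {
      unname(hypotheses[[f]])
    } else "none"
    res <- tryCatch(
      gated_correlation(data[[score_col]], data[[f]], alpha = alpha,
                        hypothesized_sign = hyp, gate = gate),
      mvh_error = function(e) NULL)  # unusable cell -> missing row
    if (is.null(res)) {
      return(data.frame(feature = f, hypothesis = hyp,
                        method = NA_character_, r = NA_real_, p = NA_real_,
                        n = sum(!is.na(data[[score_col]]) & !is.na(data[[f]])),
                        agreement = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(feature = f, hypothesis = hyp, method = res$method,
               r = res$r, p = res$p, n = res$n,
               agreement = res$agreement, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  grid$p <- stats::p.adjust(grid$p, method = p_adjust)
  grid$significant <- !is.na(grid$p) & grid$p < alpha
  # re-evaluate agreement against (possibly adjusted) p-values
  grid$agreement <- grid$agreement & grid$significant
  grid[, c("feature", "hypothesis", "method", "r", "p", "n",
           "significant", "agreement")]
}

#' Null calibration of the correlation grid
#'
#' Estimates the type-I error of the gated correlation procedure by
#' correlating each feature against independently permuted copies of the
#' score column. Each (replicate, feature) cell draws its own permutation,
#' so the pooled significance rate is a binomial proportion with
#' `n_perm * length(feature_cols)` independent trials and should sit at
#' `alpha` up to binomial sampling error.
#'
#' @inheritParams correlation_grid
#' @param n_perm Number of permutation replicates per feature (default 200).
#' @return List with `rate` (pooled significant-cell rate), `n_cells`,
#'   `alpha` and the binomial standard error `se`.
#' @export
null_calibration <- function(data, score_col, feature_cols, alpha = 0.05,
                             gate = "both", n_perm = 200) {
  score <- data[[score_col]]
  hits <- 0L
  total <- 0L
  for (j in seq_len(n_perm)) {
    for (f in feature_cols) {
      perm <- sample(score)
      res <- gated_correlation(perm, data[[f]], alpha = alpha, gate = gate)
      hits <- hits + (res$p < alpha)
      total <- total + 1L
    }
  }
  rate <- hits / total
  list(rate = rate, n_cells = total, alpha = alpha,
       se = sqrt(alpha * (1 - alpha) / total))
}

#' Pairwise two-sided t-tests between participant classes
#'
#' Student's two-sided t-test (equal variances by default; set
#' `var_equal = FALSE` for Welch) between every pair of classes.
#'
#' @param values Numeric outcome (e.g. overall movement health score).
#' @param groups Class labels, same length as `values`.
#' @param var_equal Assume equal variances (default `TRUE`).
#' @return Data frame with one row per class pair: group labels, per-group
#'   `n`/`mean`/`sd`, the `t` statistic and two-sided `p`.
#' @export
group_ttests <- function(values, groups, var_equal = TRUE) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  lv <- if (is.factor(groups)) {
    intersect(levels(groups), unique(as.character(groups[ok])))
  } else {
    unique(as.character(groups[ok]))
  }
  groups <- as.character(groups[ok])
  levels <- lv
  if (length(levels) < 2) {
    mvh_stop("need at least two groups to compare")
  }
  counts <- table(groups)
  if (any(counts < 2)) {
    mvh_stop(sprintf("group '%s' has fewer than 2 observations",
                     names(counts)[which(counts < 2)[1]]))
  }
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    tt <- stats::t.test(a, b, var.equal = var_equal,
                        alternative = "two.sided")
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(a), mean1 = mean(a), sd1 = stats::sd(a),
               n2 = length(b), mean2 = mean(b), sd2 = stats::sd(b),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Intrasubject coefficient of variation across assessment trials
#'
#' Test-retest reliability of the overall score: per subject with exactly
#' `required_trials` recorded trials, CV = sample standard deviation divided
#' by the mean of the trials, in percent; subjects with fewer trials are
#' excluded. Summarised as mean +/- SD across subjects.
#'
#' @param scores Long data frame of trial scores.
#' @param id_col,score_col Column names (defaults `participant_id`,
#'   `score`).
#' @param required_trials Trials a subject must have to enter (default 3).
#' @return List with `per_subject` (data frame `participant_id`, `cv_pct`),
#'   `mean_cv`, `sd_cv` (percent) and `n_subjects`.
#' @export
intrasubject_cv <- function(scores, id_col = "participant_id",
                            score_col = "score", required_trials = 3) {
  scores <- as.data.frame(scores)
  scores <- scores[!is.na(scores[[score_col]]), , drop = FALSE]
  split_scores <- split(scores[[score_col]], scores[[id_col]])
  keep <- vapply(split_scores, length, integer(1)) == required_trials
  split_scores <- split_scores[keep]
  cv <- vapply(split_scores, function(v) {
    m <- mean(v)
    if (m == 0) {
      mvh_stop("CV undefined for a zero-mean trial set",
               class = "mvh_degenerate_error")
    }
    100 * stats::sd(v) / m
  }, numeric(1))
  per_subject <- data.frame(participant_id = names(cv), cv_pct = unname(cv),
                            stringsAsFactors = FALSE)
  list(per_subject = per_subject,
       mean_cv = if (length(cv)) mean(cv) else NA_real_,
       sd_cv = if (length(cv) > 1) stats::sd(cv) else NA_real_,
       n_subjects = length(cv))
}

#' Build the full validation report
#'
#' Assembles everything the concurrent-validity analysis produces: the
#' per-variable normality table, the score-versus-sensor-metric and
#' score-versus-functional-test correlation grids with direction-agreement
#' flags, the pairwise class comparisons of the overall score, and the
#' intrasubject reliability summary. Deterministic given its inputs; the
#' configuration is echoed verbatim into the report.
#'
#' @param metrics Data frame from [extract_all()] rows (one per
#'   participant).
#' @param test_scores Data frame from [assemble_test_scores()] rows.
#' @param scores Long data frame of per-trial overall scores
#'   (`participant_id`, `trial`, `score`).
#' @param participants Data frame with `participant_id` and `class`.
#' @param config List of analysis settings: `alpha`, `gate`, `var_equal`,
#'   `p_adjust`, `required_trials`, and anything else worth echoing.
#' @return List of class `mvh_validation_report`.
#' @export
build_report <- function(metrics, test_scores, scores, participants,
                         config = list()) {
  config <- utils::modifyList(
    list(alpha = 0.05, gate = "both", var_equal = TRUE, p_adjust = "none",
         required_trials = 3),
    config)

  mean_scores <- stats::aggregate(score ~ participant_id, data = scores,
                                  FUN = mean)
  df <- merge(participants[, c("participant_id", "class")], mean_scores,
              by = "participant_id")
  df <- merge(df, metrics, by = "participant_id", all.x = TRUE)
  df <- merge(df, test_scores, by = "participant_id", all.x = TRUE)

  vars <- c("score", activity_metric_names(), functional_test_names())
  normality <- do.call(rbind, lapply(vars, function(v) {
    x <- df[[v]]
    x <- x[!is.na(x)]
    if (length(x) < 3 || stats::sd(x) == 0) {
      return(data.frame(variable = v, W = NA_real_, p = NA_real_,
                        n = length(x), stringsAsFactors = FALSE))
    }
    nt <- normality_test(x)
    data.frame(variable = v, W = nt$W, p = nt$p, n = nt$n,
               stringsAsFactors = FALSE)
  }))

  grid_metrics <- correlation_grid(df, "score", activity_metric_names(),
                                   hypotheses = metric_hypotheses(),
                                   alpha = config$alpha, gate = config$gate,
                                   p_adjust = config$p_adjust)
  grid_tests <- correlation_grid(df, "score", functional_test_names(),
                                 hypotheses = test_hypotheses(),
                                 alpha = config$alpha, gate = config$gate,
                                 p_adjust = config$p_adjust)
  groups <- group_ttests(df$score, df$class, var_equal = config$var_equal)
  reliability <- intrasubject_cv(scores,
                                 required_trials = config$required_trials)

  structure(
    list(
      n_participants = nrow(df),
      class_counts = as.list(table(df$class)),
      normality = normality,
      correlations_metrics = grid_metrics,
      correlations_tests = grid_tests,
      group_comparisons = groups,
      reliability = list(mean_cv_pct = reliability$mean_cv,
                         sd_cv_pct = reliability$sd_cv,
                         n_subjects = reliability$n_subjects,
                         per_subject = reliability$per_subject),
      config = config
    ),
    class = "mvh_validation_report"
  )
}

#' @export
print.mvh_validation_report <- function(x, ...) {
  cat(sprintf("<validation report> %d participants (%s)\n", x$n_participants,
              paste(sprintf("%s: %d", names(x$class_counts),
                            unlist(x$class_counts)), collapse = ", ")))
  agree <- c(x$correlations_metrics$agreement, x$correlations_tests$agreement)
  cat(sprintf("  direction agreement: %d/%d hypothesised cells\n",
              sum(agree), length(agree)))
  cat(sprintf("  intrasubject CV: %.2f +/- %.2f %% (n = %d)\n",
              x$reliability$mean_cv_pct, x$reliability$sd_cv_pct,
              x$reliability$n_subjects))
  for (i in seq_len(nrow(x$group_comparisons))) {
    g <- x$group_comparisons[i, ]
    cat(sprintf("  %s (%.2f) vs %s (%.2f): t = %.2f, p = %.2g\n",
                g$group1, g$mean1, g$group2, g$mean2, g$t, g$p))
  }
  invisible(x)
}

#' Write a validation report to JSON (plus correlation CSVs)
#'
#' Serialises the report to pretty-printed JSON; the two correlation grids
#' are additionally written as CSV next to it (same stem, suffixes
#' `_metrics.csv` / `_tests.csv`) for spreadsheet use.
#'
#' @param report A `mvh_validation_report`.
#' @param path Output JSON path.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       dataframe = "rows")
  stem <- sub("\\.json$", "", path)
  write_csv_exact(report$correlations_metrics,
                  paste0(stem, "_metrics.csv"))
  write_csv_exact(report$correlations_tests, paste0(stem, "_tests.csv"))
  invisible(path)
}
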