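# Normality gating, correlation agreement, group comparisons, reliability.

test_that("normality test accepts normal and rejects lognormal samples", {
  withr::with_seed(81, {
    normal_pass <- vapply(1:100, function(i) {
      normality_test(rnorm(150))$p > 0.05
    }, logical(1))
    lognormal_reject <- vapply(1:100, function(i) {
      normality_test(exp(rnorm(150)))$p < 0.05
    }, logical(1))
    expect_gte(mean(normal_pass), 0.90)
    expect_gte(mean(lognormal_reject), 0.99)
  })
  expect_error(normality_test(c(1, 2)), class = "mvh_insufficient_data_error")
  expect_error(normality_test(rep(1, 10)), class = "mvh_degenerate_error")
})

test_that("correlation method is gated on normality of both variables", {
  withr::with_seed(91, {
    x <- rnorm(100)
    # exact linear relation between normal variables: Pearson r = 1
    res <- gated_correlation(x, 2 * x + 1, hypothesized_sign = "+")
    expect_equal(res$method, "pearson")
    expect_equal(res$r, 1)
    expect_true(res$agreement)
    # monotone transform breaks normality, Spearman keeps r_s = 1
    res2 <- gated_correlation(x, exp(3 * x), hypothesized_sign = "+")
    expect_equal(res2$method, "spearman")
    expect_equal(res2$r, 1)
    # Spearman r invariant under any strictly monotone transform
    y <- x + rnorm(100)
    r1 <- gated_correlation(x, exp(3 * y))
    r2 <- gated_correlation(x, (3 * y)^3)
    expect_equal(r1$method, "spearman")
    expect_equal(r1$r, r2$r)
  })
})

test_that("agreement requires both the hypothesised sign and significance", {
  withr::with_seed(101, {
    x <- rnorm(12)
    y <- 0.2 * x + rnorm(12)  # weak: typically insignificant at n = 12
    res <- gated_correlation(x, y, hypothesized_sign = "+")
    if (res$p >= 0.05) expect_false(res$agreement)
    # wrong hypothesised sign never agrees
    res2 <- gated_correlation(x, 2 * x, hypothesized_sign = "-")
    expect_false(res2$agreement)
  })
  expect_error(gated_correlation(1:10, rep(1, 10)),
               class = "mvh_degenerate_error")
  expect_error(gated_correlation(1:3, 1:3),
               class = "mvh_insufficient_data_error")
})

test_that("correlation grid deletes missing values pairwise", {
  withr::with_seed(111, {
    df <- data.frame(score = rnorm(60))
    df$a <- df$score + rnorm(60)
    df$b <- -df$score + rnorm(60)
    df$a[1:10] <- NA
    grid <- correlation_grid(df, "score", c("a", "b"),
                             hypotheses = c(a = "+", b = "-"))
    expect_equal(grid$n, c(50, 60))
    expect_true(all(grid$agreement))
    expect_equal(nrow(correlation_grid(df, "score", character())), 0)
  })
})

test_that("group t-tests are symmetric and degenerate cleanly", {
  withr::with_seed(121, {
    vals <- c(rnorm(20, 10), rnorm(25, 12))
    grp <- rep(c("a", "b"), c(20, 25))
    tt <- group_ttests(vals, grp)
    tt_rev <- group_ttests(vals, factor(grp, levels = c("b", "a")))
    expect_equal(tt$t, -tt_rev$t)
    expect_equal(tt$p, tt_rev$p)
    # identical groups: t = 0, p = 1
    same <- group_ttests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    expect_error(group_ttests(c(1, 2, 3), c("a", "a", "b")),
                 class = "mvh_input_error")
  })
})

test_that("two-sided t-tests separate groups at paper-like separations", {
  withr::with_seed(131, {
    rejections <- vapply(1:100, function(i) {
      a <- rnorm(17, 86, 5)
      b <- rnorm(20, 68, 7)
      group_ttests(c(a, b), rep(c("ath", "imp"), c(17, 20)))$p < 0.05
    }, logical(1))
    expect_gte(mean(rejections), 0.99)
  })
})

test_that("intrasubject CV matches hand computation and is scale-invariant", {
  scores <- data.frame(
    participant_id = rep(c("A", "B", "C"), each = 3),
    trial = rep(1:3, 3),
    score = c(80, 80, 80, 70, 80, 90, 60, 60, 60))
  cv <- intrasubject_cv(scores)
  expect_equal(cv$n_subjects, 3)
  expect_equal(cv$per_subject$cv_pct[cv$per_subject$participant_id == "A"], 0)
  expect_equal(cv$per_subject$cv_pct[cv$per_subject$participant_id == "B"], 12.5)
  scaled <- scores
  scaled$score <- scaled$score * 2
  expect_equal(intrasubject_cv(scaled)$per_subject$cv_pct,
               cv$per_subject$cv_pct)
  # subjects lacking the required trial count are excluded
  expect_equal(intrasubject_cv(scores[-1, ])$n_subjects, 2)
})

test_that("the report assembles shapes, survives a missing column, and is deterministic", {
  spec <- cohort_spec(n = 25, seed = 77)
  coh <- simulate_cohort(spec)
  metrics <- suppressWarnings(extract_cohort_metrics(coh$traces))
  tests <- score_cohort_tests(coh$tests, coh$profiles)
  rep1 <- build_report(metrics, tests, coh$scores, coh$profiles)
  expect_s3_class(rep1, "mvh_validation_report")
  expect_equal(nrow(rep1$correlations_metrics), 18)
  expect_equal(nrow(rep1$correlations_tests), 15)
  expect_equal(rep1$n_participants, 25)
  rep2 <- build_report(metrics, tests, coh$scores, coh$profiles)
  expect_identical(rep1, rep2)
  # a fully-missing test column becomes an NA cell, not a crash
  tests$single_leg_hop <- NA_real_
  rep3 <- build_report(metrics, tests, coh$scores, coh$profiles)
  hop <- rep3$correlations_tests[rep3$correlations_tests$feature ==
                                   "single_leg_hop", ]
  expect_true(is.na(hop$r))
  expect_false(hop$agreement)
})
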