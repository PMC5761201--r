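test_that("confusion matrices count truth-by-prediction pairs", {
  cm <- confusion_matrix(c(0, 1, 1, 2), c(0, 0, 1, 2))
  expect_equal(cm["0", "1"], 1)
  expect_equal(unname(diag(cm)), c(1, 1, 1))
  expect_equal(sum(cm), 4)
  perfect <- confusion_matrix(c(0, 1, 2), c(0, 1, 2))
  expect_equal(sum(diag(perfect)), 3)
  expect_error(confusion_matrix(c(0, 3), c(0, 1)), "labels")
  ## row sums are the truth class counts
  set.seed(2)
  truth <- sample(0:2, 200, TRUE); pred <- sample(0:2, 200, TRUE)
  cm2 <- confusion_matrix(pred, truth)
  expect_equal(unname(rowSums(cm2)), as.vector(table(factor(truth, 0:2))))
})

test_that("one-vs-all metrics equal per-sample counting", {
  set.seed(5)
  for (rep in 1:5) {
    truth <- sample(0:2, 150, TRUE)
    pred <- sample(0:2, 150, TRUE)
    cm <- confusion_matrix(pred, truth)
    for (c in 0:2) {
      m <- sens_spec_one_vs_all(cm, c)
      o <- count_sens_spec(pred, truth, c)
      expect_equal(m$sensitivity, o$sensitivity)
      expect_equal(m$specificity, o$specificity)
    }
  }
  ## degenerate predictor: everything class 0
  truth <- rep(0:2, each = 10)
  cm <- confusion_matrix(rep(0L, 30), truth)
  m0 <- sens_spec_one_vs_all(cm, 0)
  expect_equal(m0$sensitivity, 1)
  expect_equal(m0$specificity, 0)
  ## perfect prediction
  cmp <- confusion_matrix(truth, truth)
  for (c in 0:2) {
    m <- sens_spec_one_vs_all(cmp, c)
    expect_equal(unlist(m), c(sensitivity = 1, specificity = 1))
  }
})

test_that("the moving average truncates at edges as documented", {
  expect_equal(moving_average_prediction(c(1, 0, 2, 1), 1), c(1, 0, 2, 1))
  expect_equal(moving_average_prediction(rep(2L, 6), 3), rep(2, 6))
  expect_equal(moving_average_prediction(c(0, 0, 0, 2, 2, 2), 3),
               c(0, 0, 2 / 3, 4 / 3, 2, 2))
  expect_error(moving_average_prediction(1:5, 4), "window")
})

test_that("model error is the per-class MSE against the smoothed prediction", {
  truth <- c(rep(0L, 20), rep(1L, 20), rep(2L, 20))
  err0 <- model_error(truth, truth, window = 1)
  expect_equal(unlist(err0), c(class_0 = 0, class_1 = 0, class_2 = 0,
                               total = 0))
  err1 <- model_error(rep(1L, 20), rep(0L, 20), window = 1)
  expect_equal(err1$class_0, 1)
  expect_true(is.na(err1$class_1))
  ## total is the sum of the per-class errors (brute-force check)
  set.seed(8)
  pred <- sample(0:2, length(truth), TRUE)
  err <- model_error(pred, truth, window = 5)
  sm <- moving_average_prediction(pred, 5)
  by_class <- vapply(0:2, function(c) mean((sm[truth == c] - c)^2), numeric(1))
  expect_equal(err$total, sum(by_class))
  expect_equal(c(err$class_0, err$class_1, err$class_2), by_class)
})

test_that("log odds ratios follow their closed forms", {
  expect_equal(log_odds_ratio(0.25, 0.25), 0)
  expect_equal(log_odds_ratio(0.1, 0.7), log(7))
  expect_equal(log_odds_ratio(0.7, 0.1), -log(7))
  ## antisymmetry under swapping the probabilities
  set.seed(1)
  p0 <- stats::runif(20, 0.01, 0.9); p2 <- stats::runif(20, 0.01, 0.9)
  expect_equal(log_odds_ratio(p0, p2), -log_odds_ratio(p2, p0))
  ## the epsilon floor keeps zero probabilities finite
  expect_true(is.finite(log_odds_ratio(0, 1)))
})

test_that("cutoff optimization matches exhaustive search at coarse step", {
  set.seed(12)
  for (rep in 1:4) {
    lor <- c(stats::rnorm(25, -3), stats::rnorm(25, 0), stats::rnorm(25, 3))
    truth <- rep(0:2, each = 25)
    got <- optimize_cutoffs(lor, truth, step = 0.1)
    want <- brute_force_cutoffs(lor, truth, step = 0.1)
    expect_equal(got$objective, want$obj, tolerance = 1e-9)
    expect_equal(got$low, want$low, tolerance = 1e-9)
    expect_equal(got$high, want$high, tolerance = 1e-9)
  }
})

test_that("separated log-odds bands achieve perfect cutoff metrics", {
  lor <- c(stats::runif(30, -6, -3), stats::runif(30, -1, 1),
           stats::runif(30, 3, 6))
  truth <- rep(0:2, each = 30)
  cc <- optimize_cutoffs(lor, truth)
  expect_equal(cc$metrics$sensitivity, rep(1, 3))
  expect_equal(cc$metrics$specificity, rep(1, 3))
  expect_true(cc$low < cc$high)
  ## degenerate all-equal input: every pair ties; smallest pair returned
  cc2 <- optimize_cutoffs(rep(0.5, 30), rep(0:2, 10), step = 0.01)
  expect_equal(cc2$low, 0.5 - 0.01)
  expect_equal(cc2$high, 0.5)
  expect_error(optimize_cutoffs(c(0, 1), c(0, 1)), "three classes")
})

test_that("cohort summaries use linear-interpolation quantiles", {
  s1 <- summarize_cohort(0.7)
  expect_equal(s1$median, 0.7)
  expect_equal(s1$q25, 0.7)
  expect_equal(s1$n, 1L)
  expect_equal(summarize_cohort(c(0.2, 0.4, 0.6, 0.8))$median, 0.5)
  ## sort-based oracle on random vectors
  set.seed(3)
  for (rep in 1:3) {
    v <- stats::runif(17)
    s <- summarize_cohort(v)
    sv <- sort(v)
    idx <- 1 + (length(v) - 1) * c(0.25, 0.5, 0.75)
    oracle <- vapply(idx, function(h) {
      lo <- floor(h); hi <- ceiling(h)
      sv[lo] + (h - lo) * (sv[hi] - sv[lo])
    }, numeric(1))
    expect_equal(c(s$q25, s$median, s$q75), oracle)
  }
  ## undefined values are excluded
  expect_equal(summarize_cohort(c(NA, 0.5, NA))$n, 1L)
  expect_true(is.na(summarize_cohort(c(NA_real_, NA_real_))$median))
})

test_that("tidy/glance/evaluate_run summarize a run coherently", {
  run <- fixture_strong_loso()
  td <- tidy(run)
  expect_setequal(names(td), c("subject_id", "class", "sensitivity",
                               "specificity", "mse", "total_error"))
  expect_equal(nrow(td), 3 * length(unique(run$subject_id)))
  g <- glance(run)
  expect_equal(nrow(g), 6)
  expect_true(all(g$median >= 0 & g$median <= 1, na.rm = TRUE))
  rep <- evaluate_run(run, window = 31)
  expect_s3_class(rep, "eval_report")
  expect_equal(sum(rep$confusion), nrow(run))
  expect_lt(rep$cutoffs$pair$low, rep$cutoffs$pair$high)
  ## per-subject cutoff variant runs and returns one row per subject
  rep2 <- evaluate_run(run, per_subject_cutoffs = TRUE)
  expect_equal(nrow(rep2$cutoffs), length(unique(run$subject_id)))
})

test_that("probability-estimate cutoff analysis tends to raise class-2 sensitivity", {
  ## the motivation for the log-odds method: across seeded runs, cutoff-based
  ## class-2 sensitivity is at least the argmax-based one in the majority
  run <- fixture_strong_loso()
  lor <- log_odds_ratio(run$p0, run$p2)
  wins <- 0L; total <- 0L
  for (s in unique(run$subject_id)) {
    idx <- run$subject_id == s
    if (!all(0:2 %in% run$truth[idx])) next
    cm_arg <- confusion_matrix(run$pred[idx], run$truth[idx])
    sens_arg <- sens_spec_one_vs_all(cm_arg, 2)$sensitivity
    cc <- optimize_cutoffs(lor[idx], run$truth[idx], step = 0.05)
    sens_cut <- cc$metrics$sensitivity[3]
    total <- total + 1L
    if (sens_cut >= sens_arg - 1e-9) wins <- wins + 1L
  }
  expect_gte(total, 10L)
  expect_gt(wins / total, 0.5)
})
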