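# Shared fixtures, built once per test session and cached.

.fix <- new.env(parent = emptyenv())

noise_off <- function() {
  list(beat_jitter = 0, bp_mmHg = 0, fv_cm_s = 0, slow_sd = 0,
       mayer_mmHg = 0)
}

sd_off <- function() {
  list(hr_sd = 0, sap_sd = 0, dap_sd = 0, sv_sd = 0, mfv_sd = 0,
       etco2_sd = 0, ti_sd = 0, o2hb_sd = 0, hhb_sd = 0)
}

# short noise-free recording with known per-beat template truth
fixture_clean_recording <- function() {
  if (is.null(.fix$clean_rec)) {
    cfg <- cohort_config(n_subjects = 1, seed = 11,
                         baseline_duration_s = 60,
                         lbnp_duration_range_s = c(150, 150),
                         noise = noise_off())
    .fix$clean_rec <- simulate_subject(cfg, subject_seed = 101)
  }
  .fix$clean_rec
}

# short default-noise recording + its beat table
fixture_beat_table <- function() {
  if (is.null(.fix$beat_tab)) {
    cfg <- cohort_config(n_subjects = 1, seed = 12,
                         baseline_duration_s = 60,
                         lbnp_duration_range_s = c(200, 200))
    rec <- simulate_subject(cfg, subject_seed = 202)
    .fix$beat_rec <- rec
    .fix$beat_tab <- build_beat_table(rec, tfa = FALSE)
  }
  .fix$beat_tab
}

fixture_beat_recording <- function() {
  fixture_beat_table()
  .fix$beat_rec
}

# full-length recording (> 3 min) for transfer-function features
fixture_long_beat_table <- function() {
  if (is.null(.fix$long_tab)) {
    cfg <- cohort_config(n_subjects = 1, seed = 13,
                         baseline_duration_s = 120,
                         lbnp_duration_range_s = c(300, 300))
    rec <- simulate_subject(cfg, subject_seed = 303)
    .fix$long_rec <- rec
    .fix$long_tab <- build_beat_table(rec, tfa = TRUE)
  }
  .fix$long_tab
}

fixture_long_recording <- function() {
  fixture_long_beat_table()
  .fix$long_rec
}

# 12-subject strong-effect, low-noise cohort and its model-8 features:
# the parameter-recovery regime
fixture_strong_features8 <- function() {
  if (is.null(.fix$strong8)) {
    cfg <- cohort_config_strong(n_subjects = 12, seed = 7,
                                baseline_duration_s = 180,
                                lbnp_duration_range_s = c(300, 480))
    cohort <- simulate_cohort(cfg)
    .fix$strong8 <- cohort_feature_matrices(cohort, model_ids = 8,
                                            tfa = FALSE)[[1]]
  }
  .fix$strong8
}

fixture_strong_loso <- function() {
  if (is.null(.fix$strong_loso)) {
    .fix$strong_loso <- loso_evaluate(fixture_strong_features8(),
                                      C = 1, gamma = 0.1, seed = 7)
  }
  .fix$strong_loso
}

# tiny hand-made feature matrix: 4 subjects, separable classes; cheap enough
# for exhaustive grid-search oracles
fixture_toy_features <- function() {
  if (is.null(.fix$toy)) {
    set.seed(99)
    rows <- lapply(sprintf("T%02d", 1:4), function(s) {
      n <- 30
      lab <- rep(0:2, each = n / 3)
      tibble::tibble(
        subject_id = s,
        t = seq_len(n) * 2,
        label = lab,
        f1 = lab + stats::rnorm(n, 0, 0.15),
        f2 = -lab + stats::rnorm(n, 0, 0.15)
      )
    })
    .fix$toy <- cvreserve:::new_feature_matrix(dplyr::bind_rows(rows), 9L)
  }
  .fix$toy
}

# brute-force cutoff search: the definitional oracle for optimize_cutoffs
brute_force_cutoffs <- function(lor, truth, step) {
  grid <- seq(min(lor) - step, max(lor) + step, by = step)
  best <- NULL
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (j <= i) next
      pred <- cutoff_classify(lor, grid[i], grid[j])
      cm <- confusion_matrix(pred, truth)
      obj <- 0
      for (c in 0:2) {
        m <- sens_spec_one_vs_all(cm, c)
        obj <- obj + m$sensitivity + m$specificity
      }
      if (is.null(best) || obj > best$obj + 1e-9) {
        best <- list(low = grid[i], high = grid[j], obj = obj)
      }
    }
  }
  best
}

# per-sample counting oracle for sensitivity/specificity
count_sens_spec <- function(pred, truth, c) {
  tp <- sum(truth == c & pred == c)
  fn <- sum(truth == c & pred != c)
  tn <- sum(truth != c & pred != c)
  fp <- sum(truth != c & pred == c)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}
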