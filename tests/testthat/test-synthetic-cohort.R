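test_that("identical config and seed reproduce a recording bit-identically", {
  cfg <- cohort_config(n_subjects = 2, seed = 5, baseline_duration_s = 40,
                       lbnp_duration_range_s = c(80, 120))
  r1 <- simulate_subject(cfg, subject_seed = 42)
  r2 <- simulate_subject(cfg, subject_seed = 42)
  expect_identical(r1$channels$bp$samples, r2$channels$bp$samples)
  expect_identical(r1$channels$fv$samples, r2$channels$fv$samples)
  expect_identical(r1$truth, r2$truth)

  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1[[1]]$channels$bp$samples, c2[[1]]$channels$bp$samples)
  expect_identical(c1[[2]]$marks, c2[[2]]$marks)
})

test_that("protocol marks are ordered and channels cover the protocol", {
  cfg <- cohort_config(n_subjects = 3, seed = 9, baseline_duration_s = 40,
                       lbnp_duration_range_s = c(80, 120))
  for (rec in simulate_cohort(cfg)) {
    m <- rec$marks
    expect_lt(m$t_baseline_start, m$t_lbnp_onset)
    expect_lt(m$t_lbnp_onset, m$t_presyncope)
    for (ch in rec$channels) {
      expect_true(all(is.finite(ch$samples)))
      dur <- (length(ch$samples) - 1) / ch$fs
      expect_gte(dur, m$t_presyncope - 1 / ch$fs)
    }
  }
})

test_that("a degenerate LBNP duration range is honoured exactly", {
  cfg <- cohort_config(n_subjects = 2, seed = 4, baseline_duration_s = 30,
                       lbnp_duration_range_s = c(90, 90))
  for (rec in simulate_cohort(cfg))
    expect_equal(rec$marks$t_presyncope - rec$marks$t_lbnp_onset, 90)
})

test_that("cohort subjects get distinct ids and in-range LBNP durations", {
  cfg <- cohort_config(n_subjects = 6, seed = 21, baseline_duration_s = 30,
                       lbnp_duration_range_s = c(60, 100))
  cohort <- simulate_cohort(cfg)
  ids <- vapply(cohort, function(r) r$subject_id, character(1))
  expect_length(unique(ids), 6)
  durs <- vapply(cohort, function(r)
    r$marks$t_presyncope - r$marks$t_lbnp_onset, numeric(1))
  expect_true(all(durs >= 60 & durs <= 100))
})

test_that("zero noise and zero effects produce statistically identical beats", {
  cfg <- cohort_config(
    n_subjects = 1, seed = 3, baseline_duration_s = 60,
    lbnp_duration_range_s = c(120, 120),
    baseline = sd_off(), noise = noise_off(),
    effects = list(sv_decline = 0, pp_decline = 0, mfv_decline = 0,
                   hr_rise_hrdom = 0, hr_rise_resist = 0,
                   dap_rise_resist = 0, etco2_decline = 0, ti_rise = 0,
                   o2hb_drop_umol = 0, hhb_rise_umol = 0,
                   collapse_sap_mmHg = 1e6, collapse_hr_drop = 0)
  )
  rec <- simulate_subject(cfg, subject_seed = 8)
  tr <- rec$truth$bp
  expect_equal(diff(range(tr$sap)), 0, tolerance = 1e-9)
  expect_equal(diff(range(tr$ibi)), 0, tolerance = 1e-9)
  ## downstream trend features vanish on the flat protocol
  tv <- windowed_trend_variance(tr$t_onset, tr$sap)
  expect_true(all(abs(as.matrix(tv)) < 1e-9))
})

test_that("expected trajectories are monotone during compensated LBNP", {
  cfg <- cohort_config(n_subjects = 1, seed = 6, baseline_duration_s = 60,
                       lbnp_duration_range_s = c(200, 200),
                       noise = noise_off())
  rec <- simulate_subject(cfg, subject_seed = 31)
  tr <- rec$truth$bp
  m <- rec$marks
  L <- m$t_presyncope - m$t_lbnp_onset
  comp <- tr$t_onset >= m$t_lbnp_onset &
    tr$t_onset <= m$t_presyncope - 0.05 * L - 2
  pp <- tr$sap[comp] - tr$dap[comp]
  hr <- 60 / tr$ibi[comp]
  expect_true(all(diff(pp) <= 1e-9))
  expect_true(all(diff(hr) >= -1e-9))
  fv <- rec$truth$fv
  expect_true(all(diff(fv$sfv[comp]) <= 1e-9))
})

test_that("the terminal collapse reproduces the pre-syncope abort criterion", {
  ## systolic pressure crosses below 80 mmHg in the final minute
  for (seed in c(101, 202, 303)) {
    cfg <- cohort_config(n_subjects = 1, seed = 1, baseline_duration_s = 60,
                         lbnp_duration_range_s = c(240, 300))
    rec <- simulate_subject(cfg, subject_seed = seed)
    tr <- rec$truth$bp
    last10 <- tr$t_onset >= rec$marks$t_presyncope -
      0.1 * (rec$marks$t_presyncope - rec$marks$t_lbnp_onset)
    expect_lt(min(tr$sap[last10]), 80)
    last60 <- tr$t_onset >= rec$marks$t_presyncope - 60
    expect_lt(min(tr$sap[last60]), 80)
  }
})

test_that("non-physiological configurations are refused", {
  expect_error(cohort_config(baseline = list(hr_bpm = -10)), "heart rate")
  expect_error(cohort_config(baseline = list(sap_mmHg = 60, dap_mmHg = 70)),
               "SAP")
  expect_error(simulate_cohort(cohort_config(n_subjects = 1)), "n_subjects")
})

test_that("subject recordings round-trip through the text writer", {
  rec <- fixture_clean_recording()
  dir <- withr::local_tempdir()
  write_subject_recording(rec, dir)
  back <- read_subject_recording(dir)
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$marks, rec$marks)
  expect_equal(back$channels$bp$fs, rec$channels$bp$fs)
  expect_equal(back$channels$bp$samples, rec$channels$bp$samples,
               tolerance = 1e-6)
  expect_error(read_subject_recording(withr::local_tempdir()),
               "recording.json")
})
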