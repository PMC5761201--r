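test_that("per-beat scalar definitions hold on a parametrized pulse", {
  rec <- fixture_clean_recording()
  fs <- rec$channels$bp$fs
  onsets <- detect_beats(rec$channels$bp)
  i0 <- round(onsets[5] * fs) + 1L
  i1 <- round(onsets[6] * fs) + 1L
  beat <- rec$channels$bp$samples[i0:i1]
  lm <- parametrize_pulse(beat, fs, t_onset = onsets[5])
  sc <- beat_scalars(beat, fs, lm, next_onset = onsets[6])
  expect_equal(sc$PP, sc$SAP - sc$DAP)
  expect_equal(sc$HR, 60 / sc$IBI)
  expect_equal(sc$IBI, onsets[6] - onsets[5])
  expect_true(sc$DAP <= sc$MAP && sc$MAP <= sc$SAP)
  ## LVET equals the generator's foot-to-notch time within one sample
  truth <- rec$truth$bp
  k <- which.min(abs(truth$t_onset - onsets[5]))
  expect_lt(abs(sc$LVET - truth$lvet[k]), 1 / fs + 1e-9)
  expect_error(beat_scalars(beat, fs, lm, next_onset = onsets[5] + 3),
               "interbeat")
})

test_that("stroke volume, cardiac output and resistance follow their identities", {
  rec <- tibble::tibble(SAP = 120, DAP = 80, MAP = 93, PP = 40, HR = 60)
  ## calibration chosen so SV = 80 mL at this operating point
  calib <- 80 * (120 + 80) / 40
  out <- estimate_sv(rec, calib)
  expect_equal(out$SV, 80)
  expect_equal(out$CO, 4.8)
  expect_equal(out$TPR, 93 / 4.8)
  ## homogeneity: halving PP at constant SAP + DAP halves SV
  rec2 <- dplyr::mutate(rec, PP = 20)
  expect_equal(estimate_sv(rec2, calib)$SV, 40)
})

test_that("slow channels interpolate linearly at beat times", {
  const <- structure(list(name = "etco2", samples = rep(40, 101), fs = 10,
                          units = "mmHg"), class = "channel_signal")
  expect_equal(as.numeric(interpolate_slow_channel(const, c(1, 5, 9.3))),
               rep(40, 3))
  ramp <- structure(list(name = "etco2", samples = seq(30, 40, length.out = 101),
                         fs = 10, units = "mmHg"), class = "channel_signal")
  expect_equal(as.numeric(interpolate_slow_channel(ramp, 5)), 35)
  v <- interpolate_slow_channel(ramp, seq(0, 10, length.out = 375))
  expect_length(as.numeric(v), 375)
  ## out-of-support beats take edge values and are flagged
  v2 <- interpolate_slow_channel(ramp, c(-1, 5, 11))
  expect_equal(as.numeric(v2), c(30, 35, 40))
  expect_equal(attr(v2, "extrapolated"), c(TRUE, FALSE, TRUE))
})

test_that("the capnogram envelope option keeps breath-wise end-tidal peaks", {
  tt <- seq(0, 60, by = 0.1)
  raw <- 20 + 18 * (sin(2 * pi * tt / 4) > 0) * abs(sin(2 * pi * tt / 4)) +
    0.5 * sin(2 * pi * tt * 1.7)
  ch <- structure(list(name = "etco2", samples = raw, fs = 10, units = "mmHg"),
                  class = "channel_signal")
  v <- as.numeric(interpolate_slow_channel(ch, seq(5, 55, by = 1),
                                           envelope = TRUE))
  expect_true(all(v > 30))   # near the end-tidal plateau, not the trough
})

test_that("oxygenation features are the five documented quantities", {
  nf <- nirs_features(c(30, 40), c(10, 10))
  expect_equal(ncol(nf), 5)
  expect_equal(nf$tHb_bt, c(40, 50))
  expect_equal(nf$ratio_O2Hb[1], 0.75)
  expect_equal(nf$ratio_HHb[1], 0.25)
  expect_equal(nf$ratio_O2Hb + nf$ratio_HHb, c(1, 1))
  bad <- nirs_features(c(-5), c(2))
  expect_true(is.na(bad$ratio_O2Hb))
})

test_that("windowed trends and variances match direct per-window computation", {
  set.seed(42)
  t <- cumsum(stats::runif(260, 0.7, 1.1))
  x <- 0.3 * t + stats::rnorm(260)
  tv <- windowed_trend_variance(t, x)
  ## independent oracle: naive lm()/var() per window
  for (i in c(60, 130, 250)) {
    for (w in c(30, 60, 90, 120)) {
      idx <- which(t > t[i] - w & t <= t[i])
      if (length(idx) < 3 || (t[i] - max(t[i] - w, t[1])) / w < 0.5) next
      fit <- stats::lm(x[idx] ~ t[idx])
      expect_equal(tv[[paste0("trend_", w)]][i], unname(stats::coef(fit)[2]),
                   tolerance = 1e-8)
      expect_equal(tv[[paste0("var_", w)]][i], stats::var(x[idx]),
                   tolerance = 1e-8)
    }
  }
})

test_that("trend/variance handles degenerate and exact inputs", {
  t <- seq(1, 200, by = 1)
  ## constant series: all trends and variances zero
  tv <- windowed_trend_variance(t, rep(5, 200))
  expect_true(all(abs(as.matrix(tv)) < 1e-10))
  ## exact line of slope 2: every valid trend is 2; variance has the
  ## closed form of a sampled line, var(x) = 4 * var(t_window)
  tv2 <- windowed_trend_variance(t, 2 * t)
  i <- 150
  for (w in c(30, 60, 90, 120)) {
    expect_equal(tv2[[paste0("trend_", w)]][i], 2, tolerance = 1e-9)
    expect_equal(tv2[[paste0("var_", w)]][i],
                 4 * stats::var(t[t > t[i] - w & t <= t[i]]),
                 tolerance = 1e-9)
  }
  ## the block contributes exactly 40 features: 5 parameters x 4 windows x 2
  nm <- grep("^(SAP|DAP|HR|PP|SV)_(trend|var)_", model_feature_columns(1),
             value = TRUE)
  expect_length(nm, 40)
})

test_that("trend/variance is time-translation invariant and affine equivariant", {
  set.seed(7)
  t <- cumsum(stats::runif(150, 0.8, 1.0))
  x <- sin(t / 10) + stats::rnorm(150, 0, 0.1)
  tv <- windowed_trend_variance(t, x)
  tv_shift <- windowed_trend_variance(t + 500, x)
  expect_equal(as.matrix(tv), as.matrix(tv_shift), tolerance = 1e-6)
  tv_aff <- windowed_trend_variance(t, 3 * x + 10)
  for (w in c(30, 60, 90, 120)) {
    expect_equal(tv_aff[[paste0("trend_", w)]], 3 * tv[[paste0("trend_", w)]],
                 tolerance = 1e-8)
    expect_equal(tv_aff[[paste0("var_", w)]], 9 * tv[[paste0("var_", w)]],
                 tolerance = 1e-8)
  }
})

test_that("transfer-function analysis recovers closed-form sinusoid oracles", {
  t <- seq(0, 300, by = 0.25)
  map <- 90 + 5 * sin(2 * pi * 0.1 * t)
  ## pure gain: mfv = 2 * map
  tf <- tfa_autoregulation(t, map, 2 * map)
  expect_true(all(abs(tf$gain - 2) / 2 < 0.01))
  expect_true(all(abs(tf$phase) < 0.05))
  expect_true(all(tf$mean_coherence > 0.99))
  ## gain recovery across the physiological range
  for (g in c(0.5, 1.5, 4)) {
    tfg <- tfa_autoregulation(t, map, g * map)
    expect_true(all(abs(tfg$gain - g) / g < 0.01))
  }
  ## pure delay: phase = 2 * pi * f * tau
  tau <- 0.4
  tf2 <- tfa_autoregulation(t, map, 90 + 5 * sin(2 * pi * 0.1 * (t - tau)))
  expect_true(all(abs(tf2$phase - 2 * pi * 0.1 * tau) < 0.05))
  ## independent white noise: coherence collapses and bins are rejected
  ## (longer window / shorter segments so the coherence estimate has
  ## enough averaging to discriminate)
  set.seed(1)
  tf3 <- tfa_autoregulation(t, stats::rnorm(length(t)),
                            stats::rnorm(length(t)),
                            window_s = 300, segment_s = 50)
  expect_true(all(tf3$n_bins <= 2))
  expect_true(any(tf3$n_bins == 0))
  expect_error(tfa_autoregulation(t[t < 100], map[t < 100], map[t < 100]),
               "180")
})

test_that("beat-record identities hold for every emitted beat", {
  tab <- fixture_beat_table()
  expect_equal(tab$PP, tab$SAP - tab$DAP, tolerance = 1e-10)
  expect_equal(tab$HR, 60 / tab$IBI, tolerance = 1e-10)
  expect_equal(tab$CO, tab$SV * tab$HR / 1000, tolerance = 1e-10)
  expect_equal(tab$TPR, tab$MAP / tab$CO, tolerance = 1e-10)
  expect_true(all(tab$SAP > tab$DAP))
  expect_true(all(tab$DAP <= tab$MAP & tab$MAP <= tab$SAP))
  expect_true(all(tab$FV_PH >= 0))
  expect_equal(tab$FV_PH, tab$SFV - tab$DFV, tolerance = 1e-10)
  expect_equal(tab$ratio_O2Hb + tab$ratio_HHb, rep(1, nrow(tab)),
               tolerance = 1e-10)
  ## stroke-volume calibration anchors the baseline mean
  marks <- attr(tab, "marks")
  expect_equal(mean(tab$SV[tab$t < marks$t_lbnp_onset]), 85, tolerance = 1e-6)
})
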