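#' Per-beat scalar hemodynamics from a parametrized pulse
#'
#' @param samples Beat samples (foot to next foot inclusive).
#' @param fs Sampling rate (Hz).
#' @param lm `beat_landmarks` for this beat.
#' @param next_onset Absolute onset time of the next beat (s).
#' @return One-row tibble: `SAP` (value at the systolic peak), `DAP` (value
#'   at the foot), `MAP` (time average of the beat), `PP`, `IBI`, `HR`,
#'   `LVET` (foot-to-dicrotic-notch time).
#' @export
beat_scalars <- function(samples, fs, lm, next_onset) {
  stopifnot(inherits(lm, "beat_landmarks"))
  ibi <- next_onset - unname(lm$A["time"])
  if (ibi < 0.25 || ibi > 2.5)
    stop("interbeat interval ", signif(ibi, 3), " s outside [0.25, 2.5]")
  sap <- unname(lm$C["value"]); dap <- unname(lm$A["value"])
  tibble::tibble(
    SAP = sap, DAP = dap,
    MAP = mean(samples[-length(samples)]),
    PP = sap - dap, IBI = ibi, HR = 60 / ibi,
    LVET = lm$t_AD
  )
}

#' Pulse-contour stroke volume, cardiac output and peripheral resistance
#'
#' Stroke volume uses a calibrated Liljestrand-Zander pulse-contour form,
#' `SV = calibration * PP / (SAP + DAP)`: a documented stand-in for
#' proprietary pulse-contour algorithms that preserves the coupling between
#' pulse pressure and stroke volume. `CO = SV * HR / 1000` (L/min) and
#' `TPR = MAP / CO` (mmHg.min/L).
#'
#' @param rec Data frame with columns `SAP`, `DAP`, `MAP`, `PP`, `HR`.
#' @param calibration Scale factor (mL.mmHg/mmHg); see
#'   [sv_calibration_factor()].
#' @return `rec` with columns `SV`, `CO`, `TPR` added.
#' @export
estimate_sv <- function(rec, calibration) {
  sv <- calibration * rec$PP / (rec$SAP + rec$DAP)
  co <- sv * rec$HR / 1000
  if (any(co == 0)) stop("cardiac output of zero; cannot form TPR")
  dplyr::mutate(rec, SV = sv, CO = co, TPR = rec$MAP / co)
}

#' Calibration factor fixing mean baseline stroke volume
#'
#' @param rec Data frame of beats with columns `t`, `SAP`, `DAP`, `PP`.
#' @param marks Protocol marks list.
#' @param sv_baseline_ml Target mean stroke volume over baseline (mL).
#' @return Scalar calibration factor for [estimate_sv()].
#' @export
sv_calibration_factor <- function(rec, marks, sv_baseline_ml = 85) {
  base <- rec$t < marks$t_lbnp_onset
  if (!any(base)) stop("no baseline beats for stroke-volume calibration")
  sv_baseline_ml / mean(rec$PP[base] / (rec$SAP[base] + rec$DAP[base]))
}

#' Interpolate a slow channel at beat times
#'
#' Linear interpolation of a low-rate channel (NIRS, end-tidal CO2 envelope,
#' thoracic impedance) at per-beat times. For a raw capnogram,
#' `envelope = TRUE` first reduces the signal to its breath-wise end-tidal
#' (local-maximum) envelope. Beat times outside the channel support take the
#' edge value and are flagged.
#'
#' @param ch A `channel_signal`.
#' @param beat_times Numeric vector of beat times (s).
#' @param envelope Reduce to the breath-wise peak envelope first?
#' @return Numeric vector, one value per beat; attribute `extrapolated` is a
#'   logical flag per beat.
#' @export
interpolate_slow_channel <- function(ch, beat_times, envelope = FALSE) {
  tt <- (seq_along(ch$samples) - 1) / ch$fs
  x <- ch$samples
  if (envelope) {
    n <- length(x)
    pk <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
    ## end-tidal plateau peaks only: discard ripple maxima near the trough
    pk <- pk[x[pk] >= min(x) + 0.5 * (max(x) - min(x))]
    if (length(pk) >= 2) { tt <- tt[pk]; x <- x[pk] }
  }
  out <- stats::approx(tt, x, xout = beat_times, rule = 2)$y
  attr(out, "extrapolated") <- beat_times < tt[1] | beat_times > tt[length(tt)]
  out
}

#' Cerebral oxygenation feature block
#'
#' From per-beat oxygenated and deoxygenated hemoglobin concentrations,
#' returns the five oxygenation features: both concentrations, their sum
#' (total Hb), and the two ratios to total Hb.
#'
#' @param o2hb_bt,hhb_bt Per-beat concentrations (umol/L), equal length.
#' @return Tibble with columns `O2Hb_bt`, `HHb_bt`, `tHb_bt`, `ratio_O2Hb`,
#'   `ratio_HHb`; beats with non-positive total Hb are `NA` (flagged
#'   missing).
#' @export
nirs_features <- function(o2hb_bt, hhb_bt) {
  stopifnot(length(o2hb_bt) == length(hhb_bt))
  thb <- o2hb_bt + hhb_bt
  bad <- thb <= 0
  r1 <- ifelse(bad, NA_real_, o2hb_bt / thb)
  r2 <- ifelse(bad, NA_real_, hhb_bt / thb)
  tibble::tibble(O2Hb_bt = o2hb_bt, HHb_bt = hhb_bt, tHb_bt = thb,
                 ratio_O2Hb = r1, ratio_HHb = r2)
}

#' Windowed trend and variance of a per-beat series
#'
#' For each beat time `t[i]` and each window length `w`, computes over the
#' beats in `(t[i] - w, t[i]]` the ordinary-least-squares slope (trend,
#' units/s) and the sample variance. Windows holding fewer than 3 beats or
#' covering less than half their nominal span take the value of the longest
#' valid shorter window for that beat, else 0 (flagged).
#'
#' @param t Beat times (s), sorted increasing.
#' @param x Per-beat values.
#' @param windows Window lengths in seconds (default `c(30, 60, 90, 120)`).
#' @return Tibble with columns `trend_<w>` and `var_<w>` per window length;
#'   attribute `filled` is a logical matrix of fallback use.
#' @export
windowed_trend_variance <- function(t, x, windows = c(30, 60, 90, 120)) {
  stopifnot(length(t) == length(x), !is.unsorted(t))
  n <- length(t)
  ## zero-padded prefix sums for O(1) window statistics; times are shifted
  ## to the window end before summing to avoid cancellation for large t
  t <- t - t[1]
  ct <- c(0, cumsum(t)); cx <- c(0, cumsum(x))
  ctt <- c(0, cumsum(t * t)); cxx <- c(0, cumsum(x * x))
  ctx <- c(0, cumsum(t * x))
  S <- function(cs, i0, i1) cs[i1 + 1] - cs[i0]

  trend <- matrix(NA_real_, n, length(windows))
  varr <- matrix(NA_real_, n, length(windows))
  valid <- matrix(FALSE, n, length(windows))
  for (k in seq_along(windows)) {
    w <- windows[k]
    ## first beat strictly inside (t - w, t]
    i0 <- findInterval(t - w, t) + 1L
    i1 <- seq_len(n)
    m <- i1 - i0 + 1L
    cover <- (t - pmax(t - w, t[1])) / w
    ok <- m >= 3 & cover >= 0.5
    St <- S(ct, i0, i1); Sx <- S(cx, i0, i1)
    Stt <- S(ctt, i0, i1); Sxx <- S(cxx, i0, i1); Stx <- S(ctx, i0, i1)
    den <- m * Stt - St^2
    sl <- ifelse(den > 0, (m * Stx - St * Sx) / den, 0)
    vv <- pmax((Sxx - Sx^2 / m) / pmax(m - 1, 1), 0)
    trend[ok, k] <- sl[ok]
    varr[ok, k] <- vv[ok]
    valid[, k] <- ok
  }
  ## fallback: carry from the longest valid shorter window, else 0
  filled <- !valid
  last_tr <- rep(NA_real_, n); last_va <- rep(NA_real_, n)
  for (k in order(windows)) {
    miss <- !valid[, k]
    if (any(miss)) {
      trend[miss, k] <- ifelse(is.na(last_tr[miss]), 0, last_tr[miss])
      varr[miss, k] <- ifelse(is.na(last_va[miss]), 0, last_va[miss])
    }
    upd <- valid[, k]
    last_tr[upd] <- trend[upd, k]
    last_va[upd] <- varr[upd, k]
  }
  out <- vector("list", 2 * length(windows))
  nms <- character(2 * length(windows))
  for (k in seq_along(windows)) {
    out[[2 * k - 1]] <- trend[, k]; nms[2 * k - 1] <- paste0("trend_", windows[k])
    out[[2 * k]] <- varr[, k]; nms[2 * k] <- paste0("var_", windows[k])
  }
  names(out) <- nms
  res <- tibble::as_tibble(out)
  attr(res, "filled") <- filled
  res
}

#' Transfer-function cerebral autoregulation gain and phase
#'
#' Estimates the transfer function between mean arterial pressure and mean
#' cerebral flow velocity over a moving window. Both beat-sampled series are
#' linearly resampled to a uniform grid, linearly detrended per window, and
#' cross/auto spectra are formed by Welch averaging (cosine-tapered segments
#' with 50% overlap). Gain `|Sxy|/Sxx` and phase `arg(Sxy)` are averaged
#' over the low-frequency band bins whose magnitude-squared coherence
#' reaches the threshold; with the convention used here a pure delay of the
#' flow-velocity signal by `tau` yields phase `+2*pi*f*tau`.
#'
#' @param t Beat times (s).
#' @param map_series Per-beat mean arterial pressure (mmHg).
#' @param mfv_series Per-beat mean flow velocity (cm/s).
#' @param window_s Moving-window length (s), default 180 (3 min).
#' @param step_s Window step (s).
#' @param fs_resample Uniform resampling rate (Hz).
#' @param segment_s Welch segment length (s).
#' @param band Frequency band (Hz) averaged, default `c(0.06, 0.15)`.
#' @param coherence_min Minimum magnitude-squared coherence for a bin to
#'   contribute.
#' @return Tibble: `window_center` (s), `gain` ((cm/s)/mmHg), `phase` (rad),
#'   `mean_coherence`, `n_bins` (qualifying bins; 0 rows are flagged missing
#'   with `NA` gain/phase).
#' @export
tfa_autoregulation <- function(t, map_series, mfv_series,
                               window_s = 180, step_s = 60,
                               fs_resample = 4, segment_s = 100,
                               band = c(0.06, 0.15), coherence_min = 0.5) {
  stopifnot(length(t) == length(map_series),
            length(t) == length(mfv_series))
  span <- t[length(t)] - t[1]
  if (span < window_s) stop("need at least ", window_s, " s of data")
  tg <- seq(t[1], t[length(t)], by = 1 / fs_resample)
  xg <- stats::approx(t, map_series, xout = tg, rule = 2)$y
  yg <- stats::approx(t, mfv_series, xout = tg, rule = 2)$y

  nwin <- round(window_s * fs_resample)
  nseg <- round(segment_s * fs_resample)
  step <- round(step_s * fs_resample)
  starts <- seq(1, length(tg) - nwin + 1, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  freqs <- (seq_len(nseg) - 1) * fs_resample / nseg
  bin <- which(freqs >= band[1] & freqs <= band[2])

  purrr::map_dfr(starts, function(s0) {
    idx <- s0:(s0 + nwin - 1)
    x <- xg[idx]; y <- yg[idx]
    tw <- tg[idx]
    detrend <- function(v) stats::lm.fit(cbind(1, tw), v)$residuals
    x <- detrend(x); y <- detrend(y)
    seg_starts <- seq(1, nwin - nseg + 1, by = nseg %/% 2)
    Sxx <- Syy <- numeric(nseg); Sxy <- complex(nseg)
    for (k in seg_starts) {
      xs <- x[k:(k + nseg - 1)]; ys <- y[k:(k + nseg - 1)]
      X <- stats::fft((xs - mean(xs)) * taper)
      Y <- stats::fft((ys - mean(ys)) * taper)
      Sxx <- Sxx + Mod(X)^2
      Syy <- Syy + Mod(Y)^2
      Sxy <- Sxy + X * Conj(Y)
    }
    coh <- Mod(Sxy[bin])^2 / pmax(Sxx[bin] * Syy[bin], .Machine$double.xmin)
    ok <- coh >= coherence_min & Sxx[bin] > 0
    if (!any(ok)) {
      return(tibble::tibble(window_center = tg[s0] + window_s / 2,
                            gain = NA_real_, phase = NA_real_,
                            mean_coherence = mean(coh), n_bins = 0L))
    }
    b <- bin[ok]
    tibble::tibble(
      window_center = tg[s0] + window_s / 2,
      gain = mean(Mod(Sxy[b]) / Sxx[b]),
      phase = mean(Arg(Sxy[b])),
      mean_coherence = mean(coh[ok]),
      n_bins = sum(ok)
    )
  })
}

## per-beat MAP (time-average between onset samples) via prefix sums
.beat_means <- function(samples, fs, t_on, t_off) {
  cs <- c(0, cumsum(samples))
  i0 <- round(t_on * fs) + 1L
  i1 <- round(t_off * fs) + 1L
  (cs[i1] - cs[i0]) / (i1 - i0)
}

#' Full per-beat table for one subject
#'
#' Runs the complete waveform-to-features chain on a `subject_recording`:
#' beat detection and pulse parametrization of the arterial-pressure and
#' flow-velocity waves, per-beat scalar hemodynamics (with pulse-contour
#' stroke volume calibrated so the baseline mean matches
#' `sv_baseline_ml`), slow-channel interpolation, oxygenation features,
#' windowed trend/variance blocks for the five pressure parameters and five
#' flow-velocity parameters, and transfer-function autoregulation gain and
#' phase (carried forward between window positions; carried back before the
#' first full window).
#'
#' Flow-velocity per-beat quantities are interpolated onto the
#' arterial-pressure beat grid so every row describes one pressure beat.
#'
#' @param rec A `subject_recording`.
#' @param sv_baseline_ml Baseline mean stroke volume used for calibration.
#' @param tfa Logical; compute transfer-function gain/phase (needs a
#'   recording longer than the 3-min window)? When `FALSE` or infeasible the
#'   `tfa_gain`/`tfa_phase` columns carry the flag value `NA` and are
#'   back-filled with 0 at assembly only if never observed.
#' @param windows Trend/variance window lengths (s).
#' @return Tibble, one row per beat, with attribute `marks`.
#' @export
build_beat_table <- function(rec, sv_baseline_ml = 85, tfa = TRUE,
                             windows = c(30, 60, 90, 120)) {
  stopifnot(inherits(rec, "subject_recording"))
  bp <- rec$channels$bp; fv <- rec$channels$fv
  bp_tab <- beat_landmark_table(bp, prefix = "bp_")
  fv_tab <- beat_landmark_table(fv, prefix = "fv_")

  ## pressure scalars
  ibi <- bp_tab$t_next - bp_tab$t
  tab <- tibble::tibble(
    subject_id = rec$subject_id,
    beat = bp_tab$beat, t = bp_tab$t,
    SAP = bp_tab$v_C, DAP = bp_tab$v_A,
    MAP = .beat_means(bp$samples, bp$fs, bp_tab$t, bp_tab$t_next),
    PP = bp_tab$v_C - bp_tab$v_A,
    IBI = ibi, HR = 60 / ibi,
    LVET = bp_tab$bp_t_AD
  )
  calib <- sv_calibration_factor(tab, rec$marks, sv_baseline_ml)
  tab <- estimate_sv(tab, calib)

  ## flow-velocity scalars on the FV beat grid, then onto the BP beat grid
  fv_scal <- tibble::tibble(
    t = fv_tab$t,
    SFV = fv_tab$v_C, DFV = fv_tab$v_A,
    MFV = .beat_means(fv$samples, fv$fs, fv_tab$t, fv_tab$t_next),
    FV_PH = fv_tab$v_C - fv_tab$v_A,
    FV_area = fv_tab$fv_area_total
  )
  onto_bp <- function(tv, xv) stats::approx(tv, xv, xout = tab$t, rule = 2)$y
  for (nm in c("SFV", "DFV", "MFV", "FV_PH", "FV_area"))
    tab[[nm]] <- onto_bp(fv_scal$t, fv_scal[[nm]])
  fv_curve <- grep("^fv_", names(fv_tab), value = TRUE)
  for (nm in fv_curve) tab[[nm]] <- onto_bp(fv_tab$t, fv_tab[[nm]])
  bp_curve <- grep("^bp_", names(bp_tab), value = TRUE)
  for (nm in bp_curve) tab[[nm]] <- bp_tab[[nm]]

  ## slow channels at beat times
  tab$ETCO2_bt <- as.numeric(interpolate_slow_channel(rec$channels$etco2, tab$t))
  tab$TI_bt <- as.numeric(interpolate_slow_channel(rec$channels$ti, tab$t))
  o2 <- as.numeric(interpolate_slow_channel(rec$channels$o2hb, tab$t))
  hh <- as.numeric(interpolate_slow_channel(rec$channels$hhb, tab$t))
  tab <- dplyr::bind_cols(tab, nirs_features(o2, hh))

  ## trend/variance blocks
  for (p in c("SAP", "DAP", "HR", "PP", "SV")) {
    blk <- windowed_trend_variance(tab$t, tab[[p]], windows)
    names(blk) <- paste0(p, "_", names(blk))
    tab <- dplyr::bind_cols(tab, blk)
  }
  for (p in c("SFV", "DFV", "MFV", "FV_PH", "FV_area")) {
    blk <- windowed_trend_variance(tab$t, tab[[p]], windows)
    names(blk) <- paste0(p, "_", names(blk))
    tab <- dplyr::bind_cols(tab, blk)
  }

  ## transfer-function autoregulation, interpolated per beat
  tab$tfa_gain <- NA_real_; tab$tfa_phase <- NA_real_
  if (isTRUE(tfa) && (tab$t[nrow(tab)] - tab$t[1]) >= 180) {
    tf <- tfa_autoregulation(tab$t, tab$MAP, tab$MFV)
    tf <- tf[!is.na(tf$gain), , drop = FALSE]
    if (nrow(tf) > 0) {
      ## step-wise carry-forward (constant interpolation), carry-back before
      ## the first full window
      tab$tfa_gain <- stats::approx(tf$window_center, tf$gain, xout = tab$t,
                                    method = "constant", rule = 2)$y
      tab$tfa_phase <- stats::approx(tf$window_center, tf$phase, xout = tab$t,
                                     method = "constant", rule = 2)$y
    }
  }
  if (anyNA(tab$tfa_gain)) {
    tab$tfa_gain[is.na(tab$tfa_gain)] <- 0
    tab$tfa_phase[is.na(tab$tfa_phase)] <- 0
  }
  attr(tab, "marks") <- rec$marks
  tab
}

#' Write a per-beat table as tab-separated text
#'
#' @param tab Beat table from [build_beat_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_beat_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
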