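#' Detect heartbeat onsets (pulse feet) in a pulsatile waveform
#'
#' Finds the foot of every pulse: regions of steep upstroke are located on
#' the first derivative, and each foot is the local minimum immediately
#' preceding the steepest point of its upstroke. Successive onsets are
#' constrained to physiological interbeat intervals (0.25-2.5 s).
#'
#' @param signal A `channel_signal` (or numeric vector via `fs`).
#' @param fs Sampling rate in Hz, required when `signal` is a bare vector.
#' @return Numeric vector of onset times in seconds (empty when the input
#'   has no pulsatile component).
#' @export
detect_beats <- function(signal, fs = NULL) {
  if (inherits(signal, "channel_signal")) {
    x <- signal$samples; fs <- signal$fs
  } else {
    x <- as.numeric(signal)
    if (is.null(fs)) stop("fs must be given for a bare numeric signal")
  }
  if (fs < 50) stop("sampling rate too low for pulse-foot detection (need >= 50 Hz)")
  n <- length(x)
  if (n < fs * 0.5 || diff(range(x)) < 1e-9) return(numeric(0))

  ## slope thresholding on a lightly smoothed copy (40 ms moving average)
  ## so that measurement noise cannot mimic an upstroke; feet are then
  ## localized on the raw samples
  k <- max(3L, round(0.04 * fs))
  xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  d <- diff(xs) * fs
  pos <- d[d > 0]
  if (!length(pos)) return(numeric(0))
  th <- 0.25 * stats::quantile(pos, 0.98, names = FALSE)
  if (th <= 0) return(numeric(0))

  up <- which(d > th)
  if (!length(up)) return(numeric(0))
  ## group contiguous upstroke runs (allow small gaps)
  gap <- fs * 0.05
  brk <- c(0, which(diff(up) > gap), length(up))
  steepest <- vapply(seq_len(length(brk) - 1), function(k) {
    idx <- up[(brk[k] + 1):brk[k + 1]]
    idx[which.max(d[idx])]
  }, integer(1))

  ## merge steepest points closer than the minimum IBI, keeping the steeper
  min_sep <- round(0.25 * fs)
  keep <- c()
  for (i in steepest) {
    if (length(keep) && i - keep[length(keep)] < min_sep) {
      if (d[i] > d[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }

  ## foot: latest minimal sample in the window preceding the steepest point
  feet <- vapply(keep, function(i) {
    i0 <- max(1L, as.integer(i - round(0.30 * fs)))
    w <- x[i0:i]
    i0 + max(which(w == min(w))) - 1L
  }, integer(1))
  feet <- unique(feet)

  ## enforce IBI bounds
  if (length(feet) > 1) {
    ok <- c(TRUE, diff(feet) >= min_sep)
    feet <- feet[ok]
    feet <- feet[c(TRUE, diff(feet) <= 2.5 * fs)]
  }
  (feet - 1) / fs
}

#' Parametrize a single pulse into its landmark set
#'
#' Decomposes one beat of an arterial-pressure (or cerebral flow-velocity)
#' pulse into five primary points and derived quantities:
#' \itemize{
#'   \item `A` wave foot (beat onset), `B` point of maximal upstroke slope,
#'     `C` systolic peak, `D` dicrotic notch, `E` end of beat (next foot);
#'   \item tangent slopes `slope_I` (derivative at B), `slope_II`
#'     (least-squares slope C to D), `slope_III` (least-squares slope D to E);
#'   \item areas above the foot value by trapezoidal integration:
#'     `area_sys` (A to D), `area_dia` (D to E), `area_total` (A to E);
#'   \item durations `t_AB`, `t_AC`, `t_AD`, `t_AE` and relative amplitudes
#'     `h_B`, `h_C`, `h_D`.
#' }
#' The dicrotic notch is the most prominent local minimum between C and E,
#' falling back to the point of maximal second derivative when hypotension
#' renders the notch shallow.
#'
#' @param samples Numeric vector: one beat, from its foot up to and including
#'   the next beat's foot.
#' @param fs Sampling rate (Hz).
#' @param t_onset Absolute time of the first sample (s).
#' @return A `beat_landmarks` list.
#' @export
parametrize_pulse <- function(samples, fs, t_onset = 0) {
  x <- as.numeric(samples)
  n <- length(x)
  dur <- (n - 1) / fs
  if (dur < 0.25 || dur > 2.5)
    stop("beat duration ", signif(dur, 3), " s outside physiological bounds")

  iA <- 1L
  iE <- n
  ## systolic peak: global max, excluding the terminal sample
  iC <- which.max(x[1:(n - 1L)])
  if (iC <= iA || x[iC] <= x[iA])
    stop("degenerate pulse: no systolic peak above the foot")

  ## B: steepest upstroke between A and C
  dx <- diff(x) * fs
  iB <- if (iC > iA + 1L) iA + which.max(dx[iA:(iC - 1L)]) - 1L else iA
  iB <- max(iB, iA + 1L)

  ## D: most prominent local minimum in (C, E)
  iD <- NA_integer_
  if (iE - iC > 2L) {
    seg <- x[iC:iE]
    m <- length(seg)
    is_min <- which(seg[2:(m - 1)] <= seg[1:(m - 2)] &
                    seg[2:(m - 1)] <= seg[3:m]) + 1L
    if (length(is_min)) {
      prom <- vapply(is_min, function(j) {
        before <- max(seg[1:j]) - seg[j]
        after <- max(seg[j:m]) - seg[j]
        min(before, after)
      }, numeric(1))
      if (any(prom > 0)) iD <- iC + is_min[which.max(prom)] - 1L
    }
  }
  if (is.na(iD)) {
    ## curvature fallback: maximal second derivative on the decay
    lo <- iC + 2L; hi <- iE - 2L
    if (hi - lo < 3L) stop("degenerate pulse: dicrotic notch search failed")
    d2 <- diff(x, differences = 2) * fs^2
    iD <- lo + which.max(d2[(lo - 1L):(hi - 1L)]) - 1L
  }
  if (iD <= iC || iD >= iE) stop("degenerate pulse: dicrotic notch search failed")

  tt <- t_onset + (seq_len(n) - 1) / fs
  foot <- x[iA]
  ols_slope <- function(i0, i1) {
    if (i1 - i0 < 1L) return(0)
    stats::cov(tt[i0:i1], x[i0:i1]) / stats::var(tt[i0:i1])
  }
  trapz <- function(i0, i1) {
    if (i1 <= i0) return(0)
    y <- x[i0:i1] - foot
    sum((y[-1] + y[-length(y)]) / 2) / fs
  }

  lm <- list(
    A = c(time = tt[iA], value = x[iA]),
    B = c(time = tt[iB], value = x[iB]),
    C = c(time = tt[iC], value = x[iC]),
    D = c(time = tt[iD], value = x[iD]),
    E = c(time = tt[iE], value = x[iE]),
    slope_I = dx[iB - 1L],
    slope_II = ols_slope(iC, iD),
    slope_III = ols_slope(iD, iE),
    area_sys = trapz(iA, iD),
    area_dia = trapz(iD, iE),
    area_total = trapz(iA, iE),
    t_AB = tt[iB] - tt[iA], t_AC = tt[iC] - tt[iA],
    t_AD = tt[iD] - tt[iA], t_AE = tt[iE] - tt[iA],
    h_B = x[iB] - foot, h_C = x[iC] - foot, h_D = x[iD] - foot,
    fs = fs
  )
  class(lm) <- "beat_landmarks"
  lm
}

#' Fixed-order 15-entry curve-dynamics feature vector
#'
#' Flattens a `beat_landmarks` object into the curve-dynamics feature block:
#' `(t_AB, t_AC, t_AD, t_AE, h_B, h_C, h_D, slope_I, slope_II, slope_III,
#' area_sys, area_dia, area_total, h_D/h_C, area_sys/area_total)`.
#'
#' @param lm A `beat_landmarks` from [parametrize_pulse()].
#' @return Named numeric vector of length 15, all finite.
#' @export
curve_feature_vector <- function(lm) {
  stopifnot(inherits(lm, "beat_landmarks"))
  need <- c("t_AB", "t_AC", "t_AD", "t_AE", "h_B", "h_C", "h_D",
            "slope_I", "slope_II", "slope_III",
            "area_sys", "area_dia", "area_total")
  if (any(vapply(lm[need], function(v) is.null(v) || !is.finite(v), logical(1))))
    stop("missing or non-finite landmark")
  v <- c(unlist(lm[need]),
         ratio_hD_hC = lm$h_D / lm$h_C,
         ratio_area_sys = lm$area_sys / lm$area_total)
  if (any(!is.finite(v))) stop("non-finite curve feature")
  v
}

#' Per-beat landmark table for a whole channel
#'
#' Runs [detect_beats()] and [parametrize_pulse()] over a recording channel.
#' Beats whose parametrization fails (degenerate pulses) are interpolated
#' from their neighbours, mirroring the manual removal + interpolation of
#' invalid beats in offline waveform analysis; the last (open-ended) beat is
#' dropped.
#'
#' @param signal A `channel_signal`.
#' @param prefix Column-name prefix for the 15 curve features (e.g. `"bp_"`).
#' @return A tibble: `beat`, `t` (onset s), `t_next`, the five landmark
#'   times/values, and the 15 prefixed curve features; attribute
#'   `n_degenerate` counts interpolated beats.
#' @export
beat_landmark_table <- function(signal, prefix = "") {
  onsets <- detect_beats(signal)
  if (length(onsets) < 2) stop("fewer than two beats detected")
  fs <- signal$fs
  x <- signal$samples
  n_beat <- length(onsets) - 1L
  rows <- vector("list", n_beat)
  degenerate <- logical(n_beat)
  for (i in seq_len(n_beat)) {
    i0 <- round(onsets[i] * fs) + 1L
    i1 <- round(onsets[i + 1] * fs) + 1L
    res <- tryCatch(parametrize_pulse(x[i0:i1], fs, t_onset = onsets[i]),
                    error = function(e) NULL)
    if (is.null(res)) { degenerate[i] <- TRUE; next }
    cf <- curve_feature_vector(res)
    names(cf) <- paste0(prefix, names(cf))
    rows[[i]] <- tibble::as_tibble(c(
      list(beat = i, t = onsets[i], t_next = onsets[i + 1],
           t_A = unname(res$A["time"]), v_A = unname(res$A["value"]),
           t_B = unname(res$B["time"]), v_B = unname(res$B["value"]),
           t_C = unname(res$C["time"]), v_C = unname(res$C["value"]),
           t_D = unname(res$D["time"]), v_D = unname(res$D["value"]),
           t_E = unname(res$E["time"]), v_E = unname(res$E["value"])),
      as.list(cf)))
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("all beats degenerate")
  tab <- dplyr::bind_rows(rows[ok])
  if (any(!ok)) {
    ## interpolate invalid beats from valid neighbours on the onset-time axis
    full <- tibble::tibble(beat = seq_len(n_beat), t = onsets[seq_len(n_beat)],
                           t_next = onsets[-1])
    tab <- dplyr::left_join(full, dplyr::select(tab, -t, -t_next), by = "beat")
    num <- setdiff(names(tab), c("beat", "t", "t_next"))
    for (nm in num) {
      tab[[nm]] <- stats::approx(tab$t[ok], tab[[nm]][ok], xout = tab$t,
                                 rule = 2)$y
    }
  }
  attr(tab, "n_degenerate") <- sum(!ok)
  attr(tab, "interpolated") <- !ok
  tab
}
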