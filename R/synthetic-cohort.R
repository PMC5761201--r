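#' Configuration for a synthetic LBNP cohort
#'
#' Builds the parameter set that drives [simulate_subject()] and
#' [simulate_cohort()]. Defaults emulate a progressive central-hypovolemia
#' protocol: supine rest (baseline), a single-step application of lower body
#' negative pressure (LBNP) that progressively sequesters central blood
#' volume, and protocol termination at pre-syncope. During LBNP the expected
#' per-beat trajectories drift monotonically (heart rate up, stroke volume /
#' pulse pressure / cerebral flow velocity down, thoracic impedance up,
#' end-tidal CO2 down, oxygenated hemoglobin down, deoxygenated up), and the
#' final `collapse_fraction` of LBNP carries a terminal vasovagal collapse in
#' which systolic pressure falls below the 80 mmHg abort criterion.
#'
#' Two responder phenotypes are mixed: resistance-dominant compensators
#' (diastolic pressure rises, modest tachycardia) and heart-rate-dominant
#' compensators (strong tachycardia, flat diastolic pressure), so that no
#' single stereotyped trajectory separates the classes.
#'
#' @param n_subjects Number of subjects in the cohort (>= 2 for a cohort).
#' @param seed Integer seed controlling all randomness.
#' @param baseline_duration_s Baseline rest duration before LBNP onset, in
#'   seconds.
#' @param lbnp_duration_range_s Length-2 numeric; per-subject LBNP duration is
#'   drawn uniformly from this range (seconds).
#' @param collapse_fraction Fraction of the LBNP period occupied by the
#'   terminal collapse (default 0.05).
#' @param baseline Named list overriding baseline set-points:
#'   `hr_bpm`, `sap_mmHg`, `dap_mmHg`, `sv_ml`, `mfv_cm_s`, `etco2_mmHg`,
#'   `ti_ohm`, `o2hb_umol`, `hhb_umol`, and their inter-subject SDs
#'   (`*_sd`).
#' @param effects Named list overriding LBNP effect sizes (fractional change
#'   from baseline to end of the compensated phase): `sv_decline`,
#'   `pp_decline`, `mfv_decline`, `hr_rise_hrdom`, `hr_rise_resist`,
#'   `dap_rise_resist`, `etco2_decline`, `ti_rise`, `o2hb_drop_umol`,
#'   `hhb_rise_umol`, plus terminal-collapse parameters
#'   `collapse_sap_mmHg` (systolic pressure reached at pre-syncope),
#'   `collapse_hr_drop` (fractional HR fall during collapse).
#' @param noise Named list overriding noise amplitudes: `beat_jitter`
#'   (multiplicative SD on per-beat interbeat interval and amplitudes),
#'   `bp_mmHg`, `fv_cm_s` (additive white noise on the fast channels),
#'   `slow_sd` (AR(1) innovation SD on slow channels), `slow_ar` (AR(1)
#'   coefficient), `mayer_mmHg` (amplitude of the shared ~0.1 Hz arterial
#'   pressure oscillation), `ca_gain` (cerebral transfer of that oscillation,
#'   (cm/s)/mmHg).
#' @param phenotype_mix Probability that a subject is a heart-rate-dominant
#'   responder (the remainder are resistance-dominant).
#'
#' @return A `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 2, baseline_duration_s = 60,
#'                      lbnp_duration_range_s = c(120, 150))
#' rec <- simulate_subject(cfg, subject_seed = 1)
#' rec$marks
cohort_config <- function(n_subjects = 12,
                          seed = 1L,
                          baseline_duration_s = 300,
                          lbnp_duration_range_s = c(420, 720),
                          collapse_fraction = 0.05,
                          baseline = list(),
                          effects = list(),
                          noise = list(),
                          phenotype_mix = 0.5) {
  base_def <- list(
    hr_bpm = 62, hr_sd = 5,
    sap_mmHg = 120, sap_sd = 7,
    dap_mmHg = 70, dap_sd = 4,
    sv_ml = 85, sv_sd = 7,
    mfv_cm_s = 60, mfv_sd = 5,
    etco2_mmHg = 40, etco2_sd = 2,
    ti_ohm = 30, ti_sd = 1.5,
    o2hb_umol = 55, o2hb_sd = 3,
    hhb_umol = 25, hhb_sd = 2
  )
  eff_def <- list(
    sv_decline = 0.40,
    pp_decline = 0.35,
    mfv_decline = 0.25,
    hr_rise_hrdom = 0.55,
    hr_rise_resist = 0.20,
    dap_rise_resist = 0.08,
    etco2_decline = 0.15,
    ti_rise = 0.05,
    o2hb_drop_umol = 6,
    hhb_rise_umol = 3,
    collapse_sap_mmHg = 74,
    collapse_hr_drop = 0.22
  )
  noise_def <- list(
    beat_jitter = 0.02,
    bp_mmHg = 0.4,
    fv_cm_s = 0.4,
    slow_sd = 0.15,
    slow_ar = 0.95,
    mayer_mmHg = 1.5,
    ca_gain = 0.9
  )
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    baseline_duration_s = baseline_duration_s,
    lbnp_duration_range_s = as.numeric(lbnp_duration_range_s),
    collapse_fraction = collapse_fraction,
    baseline = utils::modifyList(base_def, baseline),
    effects = utils::modifyList(eff_def, effects),
    noise = utils::modifyList(noise_def, noise),
    phenotype_mix = phenotype_mix,
    fs = list(bp = 200, fv = 200, o2hb = 10, hhb = 10, etco2 = 10, ti = 10)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects >= 1,
    cfg$baseline_duration_s > 0,
    length(cfg$lbnp_duration_range_s) == 2,
    all(cfg$lbnp_duration_range_s > 0),
    diff(cfg$lbnp_duration_range_s) >= 0,
    cfg$collapse_fraction > 0, cfg$collapse_fraction < 1,
    cfg$phenotype_mix >= 0, cfg$phenotype_mix <= 1
  )
  b <- cfg$baseline
  if (b$hr_bpm <= 0) stop("baseline heart rate must be positive")
  if (b$sap_mmHg <= b$dap_mmHg) stop("baseline SAP must exceed DAP")
  if (b$dap_mmHg <= 0) stop("baseline DAP must be positive")
  invisible(cfg)
}

#' A "strong effect, low noise" preset configuration
#'
#' Convenience wrapper around [cohort_config()] with large hemodynamic effect
#' sizes and small noise, the regime in which the three hypovolemia classes
#' are well separated. Used for parameter-recovery exercises.
#'
#' @inheritParams cohort_config
#' @param ... Passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
cohort_config_strong <- function(n_subjects = 12, seed = 1L, ...) {
  cohort_config(
    n_subjects = n_subjects, seed = seed,
    effects = list(sv_decline = 0.50, pp_decline = 0.45, mfv_decline = 0.35,
                   hr_rise_hrdom = 0.65, hr_rise_resist = 0.35),
    noise = list(beat_jitter = 0.008, bp_mmHg = 0.2, fv_cm_s = 0.2,
                 slow_sd = 0.05, mayer_mmHg = 0.8),
    ...
  )
}

# Smooth ramp of the compensated-phase effect: 0 at LBNP onset, 1 at the
# start of terminal collapse, constant thereafter.
.ramp <- function(t, t_onset, t_end, collapse_fraction) {
  L <- t_end - t_onset
  u <- (t - t_onset) / L
  s <- pmin(pmax(u / (1 - collapse_fraction), 0), 1)
  s[t < t_onset] <- 0
  s
}

# Collapse progress: 0 before the terminal phase, 1 at pre-syncope.
.collapse_progress <- function(t, t_onset, t_end, collapse_fraction) {
  L <- t_end - t_onset
  t_col <- t_end - collapse_fraction * L
  pmin(pmax((t - t_col) / (t_end - t_col), 0), 1)
}

# Render one pulse template on sample offsets tau in [0, T).
# Piecewise: cosine-ease upstroke foot->systolic peak, cosine descent
# peak->dicrotic notch (a true local minimum), sinusoidal dicrotic wave
# notch->dicrotic peak, then a normalized exponential decay to the next
# beat's foot value. Landmarks are analytically placed, so the generator can
# serve as an oracle for the landmark detector.
.render_pulse <- function(tau, T, d, s, d_next, tau_peak, tau_notch,
                          notch_depth = 0.42, dic_frac = 0.55,
                          tau_dec_frac = 0.35) {
  v_n <- d + notch_depth * (s - d)
  v_d <- d + dic_frac * (s - d)
  tau_d <- tau_notch + 0.25 * (T - tau_notch)
  tau_dec <- tau_dec_frac * T
  y <- numeric(length(tau))

  i1 <- tau < tau_peak
  y[i1] <- d + (s - d) * (1 - cos(pi * tau[i1] / tau_peak)) / 2

  i2 <- tau >= tau_peak & tau < tau_notch
  y[i2] <- v_n + (s - v_n) *
    (1 + cos(pi * (tau[i2] - tau_peak) / (tau_notch - tau_peak))) / 2

  i3 <- tau >= tau_notch & tau < tau_d
  y[i3] <- v_n + (v_d - v_n) * sin(pi / 2 * (tau[i3] - tau_notch) / (tau_d - tau_notch))

  i4 <- tau >= tau_d
  e_end <- exp(-(T - tau_d) / tau_dec)
  y[i4] <- d_next + (v_d - d_next) *
    (exp(-(tau[i4] - tau_d) / tau_dec) - e_end) / (1 - e_end)
  y
}

# AR(1) noise of length n.
.ar1 <- function(n, sd, coef) {
  if (sd <= 0 || n == 0) return(numeric(n))
  as.numeric(stats::arima.sim(list(ar = coef), n = n,
                              sd = sd * sqrt(1 - coef^2)))
}

#' Simulate one subject's multi-channel LBNP recording
#'
#' Generates a `subject_recording`: pulsatile arterial pressure (200 Hz) and
#' cerebral blood flow velocity (200 Hz) waveforms rendered beat by beat from
#' parametric pulse templates, plus slow channels (NIRS oxygenated and
#' deoxygenated hemoglobin, end-tidal CO2 envelope, thoracic impedance at
#' 10 Hz), protocol marks, and a ground-truth beat table used by oracle
#' tests. The recording always terminates in pre-syncope: in the terminal
#' collapse the systolic pressure falls below 80 mmHg.
#'
#' @param config A [cohort_config()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier (default derived from the seed).
#' @param lbnp_duration_s LBNP duration in seconds; if `NULL`, drawn from
#'   `config$lbnp_duration_range_s`.
#' @return A `subject_recording` list with elements `subject_id`, `channels`
#'   (named list of `channel_signal`s: `bp`, `fv`, `o2hb`, `hhb`, `etco2`,
#'   `ti`), `marks` (`t_baseline_start`, `t_lbnp_onset`, `t_presyncope`),
#'   `phenotype`, and `truth` (tibbles `bp` and `fv` of per-beat template
#'   parameters).
#' @export
simulate_subject <- function(config, subject_seed,
                             subject_id = sprintf("S%05d", subject_seed %% 100000L),
                             lbnp_duration_s = NULL) {
  validate_cohort_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(subject_seed))

  b <- config$baseline; eff <- config$effects; nz <- config$noise
  cf <- config$collapse_fraction

  ## subject-level draws
  phenotype <- if (stats::runif(1) < config$phenotype_mix) "hr_dominant" else "resistance_dominant"
  if (is.null(lbnp_duration_s)) {
    lbnp_duration_s <- stats::runif(1, config$lbnp_duration_range_s[1],
                                    config$lbnp_duration_range_s[2])
  }
  t0 <- 0
  t_onset <- config$baseline_duration_s
  t_end <- t_onset + lbnp_duration_s

  hr0 <- b$hr_bpm + stats::rnorm(1, 0, b$hr_sd)
  sap0 <- b$sap_mmHg + stats::rnorm(1, 0, b$sap_sd)
  dap0 <- b$dap_mmHg + stats::rnorm(1, 0, b$dap_sd)
  sv0 <- b$sv_ml + stats::rnorm(1, 0, b$sv_sd)
  mfv0 <- b$mfv_cm_s + stats::rnorm(1, 0, b$mfv_sd)
  if (hr0 <= 20 || dap0 <= 20 || sap0 <= dap0 + 10 || sv0 <= 10 || mfv0 <= 10)
    stop("drawn baseline trajectory parameters are non-physiological")
  pp0 <- sap0 - dap0
  sfv0 <- mfv0 * 1.5
  dfv0 <- mfv0 * 0.75

  hr_rise <- if (phenotype == "hr_dominant") eff$hr_rise_hrdom else eff$hr_rise_resist
  dap_rise <- if (phenotype == "hr_dominant") 0 else eff$dap_rise_resist

  ## shared low-frequency (Mayer-wave band) oscillation: drives coherent
  ## MAP<->MFV power in 0.06-0.15 Hz for transfer-function analysis
  m_freqs <- c(0.08, 0.10, 0.12)
  m_phase <- stats::runif(3, 0, 2 * pi)
  m_amp <- nz$mayer_mmHg * c(0.5, 1, 0.5)
  mayer <- function(t) {
    out <- 0
    for (k in seq_along(m_freqs))
      out <- out + m_amp[k] * sin(2 * pi * m_freqs[k] * t + m_phase[k])
    out
  }

  ## ---- per-beat trajectory ----
  beat_t <- c(); ibis <- c()
  t <- 0
  repeat {
    s <- .ramp(t, t_onset, t_end, cf)
    cc <- .collapse_progress(t, t_onset, t_end, cf)
    hr_t <- hr0 * (1 + hr_rise * s) * (1 - eff$collapse_hr_drop * cc)
    if (hr_t <= 0) stop("trajectory produced non-positive heart rate")
    ibi <- 60 / hr_t * exp(stats::rnorm(1, 0, nz$beat_jitter))
    ibi <- min(max(ibi, 0.3), 2.4)
    if (t + ibi > t_end) break
    beat_t <- c(beat_t, t); ibis <- c(ibis, ibi)
    t <- t + ibi
  }
  n_beats <- length(beat_t)
  if (n_beats < 8) stop("recording too short to contain a beat train")

  s <- .ramp(beat_t, t_onset, t_end, cf)
  cc <- .collapse_progress(beat_t, t_onset, t_end, cf)
  jit <- function() exp(stats::rnorm(n_beats, 0, nz$beat_jitter))

  dap <- dap0 * (1 + dap_rise * s) * jit()
  pp <- pp0 * (1 - eff$pp_decline * s) * jit()
  sap <- dap + pp
  ## terminal collapse: compress toward the configured pre-syncopal SAP
  sap_target <- eff$collapse_sap_mmHg
  col_scale <- 1 - cc * (1 - sap_target / pmax(sap, sap_target))
  sap <- sap * col_scale
  dap <- dap * (1 - 0.20 * cc)
  dap <- pmin(dap, sap - 2)
  if (any(sap <= 0) || any(dap <= 0))
    stop("trajectory produced non-physiological pressures")

  sfv <- sfv0 * (1 - (eff$mfv_decline + 0.08) * s) * (1 - 0.25 * cc) * jit()
  dfv <- dfv0 * (1 - 0.80 * eff$mfv_decline * s) * (1 - 0.15 * cc) * jit()
  dfv <- pmin(dfv, sfv - 1)

  lvet <- 0.35 * sqrt(pmin(pmax(ibis, 0.3), 2.4))

  truth_bp <- tibble::tibble(
    beat = seq_len(n_beats), t_onset = beat_t, ibi = ibis,
    sap = sap, dap = dap,
    t_peak = beat_t + 0.34 * lvet, t_notch = beat_t + lvet, lvet = lvet
  )
  truth_fv <- tibble::tibble(
    beat = seq_len(n_beats), t_onset = beat_t, ibi = ibis,
    sfv = sfv, dfv = dfv,
    t_peak = beat_t + 0.34 * lvet, t_notch = beat_t + lvet, lvet = lvet
  )

  ## ---- render fast channels ----
  render_channel <- function(d_beat, s_beat, fs, noise_sd, lf_scale) {
    n_s <- floor(t_end * fs) + 1L
    tt <- (seq_len(n_s) - 1L) / fs
    y <- numeric(n_s)
    d_next <- c(d_beat[-1], d_beat[n_beats])
    for (i in seq_len(n_beats)) {
      i0 <- ceiling(beat_t[i] * fs) + 1L
      i1 <- if (i < n_beats) ceiling(beat_t[i + 1] * fs) else n_s
      if (i1 < i0) next
      idx <- i0:i1
      tau <- tt[idx] - beat_t[i]
      y[idx] <- .render_pulse(tau, ibis[i], d_beat[i], s_beat[i], d_next[i],
                              tau_peak = 0.34 * lvet[i], tau_notch = lvet[i])
    }
    ## before first beat onset: hold the first foot value
    if (beat_t[1] > 0) y[tt < beat_t[1]] <- d_beat[1]
    y <- y + lf_scale * mayer(tt)
    if (noise_sd > 0) y <- y + stats::rnorm(n_s, 0, noise_sd)
    y
  }
  bp_samples <- render_channel(dap, sap, config$fs$bp, nz$bp_mmHg, 1)
  fv_samples <- render_channel(dfv, sfv, config$fs$fv, nz$fv_cm_s, nz$ca_gain)

  ## ---- slow channels: piecewise-linear expectation + AR(1) noise ----
  slow_channel <- function(base0, delta_ramp, delta_col, fs, sd) {
    n_s <- floor(t_end * fs) + 1L
    tt <- (seq_len(n_s) - 1L) / fs
    mu <- base0 + delta_ramp * .ramp(tt, t_onset, t_end, cf) +
      delta_col * .collapse_progress(tt, t_onset, t_end, cf)
    mu + .ar1(n_s, sd, nz$slow_ar)
  }
  etco2_b <- b$etco2_mmHg + stats::rnorm(1, 0, b$etco2_sd)
  ti_b <- b$ti_ohm + stats::rnorm(1, 0, b$ti_sd)
  o2hb_b <- b$o2hb_umol + stats::rnorm(1, 0, b$o2hb_sd)
  hhb_b <- b$hhb_umol + stats::rnorm(1, 0, b$hhb_sd)
  etco2 <- slow_channel(etco2_b, -eff$etco2_decline * etco2_b, -1.5,
                        config$fs$etco2, nz$slow_sd * 2)
  ti <- slow_channel(ti_b, eff$ti_rise * ti_b, 0.2, config$fs$ti, nz$slow_sd)
  o2hb <- slow_channel(o2hb_b, -eff$o2hb_drop_umol, -1.5, config$fs$o2hb,
                       nz$slow_sd)
  hhb <- slow_channel(hhb_b, eff$hhb_rise_umol, 0.8, config$fs$hhb, nz$slow_sd)

  chan <- function(name, samples, fs, units) {
    if (any(!is.finite(samples))) stop("non-finite samples in channel ", name)
    structure(list(name = name, samples = samples, fs = fs, units = units),
              class = "channel_signal")
  }
  rec <- structure(list(
    subject_id = subject_id,
    channels = list(
      bp = chan("bp", bp_samples, config$fs$bp, "mmHg"),
      fv = chan("fv", fv_samples, config$fs$fv, "cm/s"),
      o2hb = chan("o2hb", o2hb, config$fs$o2hb, "umol/L"),
      hhb = chan("hhb", hhb, config$fs$hhb, "umol/L"),
      etco2 = chan("etco2", etco2, config$fs$etco2, "mmHg"),
      ti = chan("ti", ti, config$fs$ti, "ohm")
    ),
    marks = list(t_baseline_start = t0, t_lbnp_onset = t_onset,
                 t_presyncope = t_end),
    phenotype = phenotype,
    truth = list(bp = truth_bp, fv = truth_fv)
  ), class = "subject_recording")
  rec
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a cohort of subjects
#'
#' Draws an independent seed per subject from `config$seed` and calls
#' [simulate_subject()] for each; LBNP durations vary across subjects within
#' `config$lbnp_duration_range_s`, emulating inter-individual differences in
#' tolerance to central hypovolemia.
#'
#' @param config A [cohort_config()].
#' @return A list of `subject_recording`s of length `config$n_subjects`.
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  if (config$n_subjects < 2) stop("a cohort needs n_subjects >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  lapply(seq_len(config$n_subjects), function(i) {
    tryCatch(
      simulate_subject(config, subject_seed = seeds[i],
                       subject_id = sprintf("S%02d", i)),
      error = function(e) stop("subject ", i, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  })
}

#' @export
print.subject_recording <- function(x, ...) {
  cat("<subject_recording>", x$subject_id, "-", x$phenotype, "\n")
  cat(sprintf("  baseline %gs | LBNP onset %gs | pre-syncope %gs\n",
              x$marks$t_baseline_start, x$marks$t_lbnp_onset,
              x$marks$t_presyncope))
  for (ch in x$channels)
    cat(sprintf("  %-6s %6d samples @ %g Hz [%s]\n", ch$name,
                length(ch$samples), ch$fs, ch$units))
  invisible(x)
}

#' Write / read a subject recording as plain text
#'
#' One directory per subject: a two-column (`time_s`, `value`) whitespace
#' table per channel plus a JSON sidecar with the subject id, sampling rates,
#' units, protocol marks and phenotype. `read_subject_recording()` is the
#' strict inverse (ground-truth beat tables are not serialized).
#'
#' @param rec A `subject_recording`.
#' @param dir Output directory (created if needed).
#' @return `write_subject_recording()` returns `dir` invisibly;
#'   `read_subject_recording()` returns a `subject_recording`.
#' @export
write_subject_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "subject_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in rec$channels) {
    tt <- (seq_along(ch$samples) - 1) / ch$fs
    utils::write.table(
      data.frame(time_s = tt, value = ch$samples),
      file.path(dir, paste0(ch$name, ".txt")),
      row.names = FALSE, quote = FALSE, sep = "\t"
    )
  }
  meta <- list(
    subject_id = rec$subject_id,
    phenotype = rec$phenotype,
    marks = rec$marks,
    channels = lapply(rec$channels, function(ch)
      list(fs = ch$fs, units = ch$units))
  )
  jsonlite::write_json(meta, file.path(dir, "recording.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_subject_recording
#' @export
read_subject_recording <- function(dir) {
  meta_path <- file.path(dir, "recording.json")
  if (!file.exists(meta_path)) stop("no recording.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  marks <- as.list(meta$marks)
  if (!(marks$t_baseline_start < marks$t_lbnp_onset &&
        marks$t_lbnp_onset < marks$t_presyncope))
    stop("invalid protocol marks in ", meta_path)
  channels <- lapply(names(meta$channels), function(nm) {
    f <- file.path(dir, paste0(nm, ".txt"))
    if (!file.exists(f)) stop("missing channel file ", f)
    tab <- utils::read.table(f, header = TRUE)
    structure(list(name = nm, samples = tab$value,
                   fs = meta$channels[[nm]]$fs,
                   units = meta$channels[[nm]]$units),
              class = "channel_signal")
  })
  names(channels) <- names(meta$channels)
  structure(list(subject_id = meta$subject_id, channels = channels,
                 marks = marks, phenotype = meta$phenotype, truth = NULL),
            class = "subject_recording")
}
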