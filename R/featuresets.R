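## Feature-set definitions: nine models built from the per-beat table.
## Column-count contract per model id:
##   1:65  2:66  3:66  4:70  5:125  6:66  7:66  8:10  9:4

.basic10 <- c("SAP", "DAP", "MAP", "PP", "IBI", "HR", "SV", "CO", "TPR", "LVET")

.curve15 <- function(prefix) {
  paste0(prefix, c("t_AB", "t_AC", "t_AD", "t_AE", "h_B", "h_C", "h_D",
                   "slope_I", "slope_II", "slope_III",
                   "area_sys", "area_dia", "area_total",
                   "ratio_hD_hC", "ratio_area_sys"))
}

.trendvar40 <- function(params, windows = c(30, 60, 90, 120)) {
  unlist(lapply(params, function(p)
    unlist(lapply(windows, function(w)
      paste0(p, "_", c("trend_", "var_"), w)))))
}

#' Feature columns for each of the nine models
#'
#' Model #1 is the arterial-pressure curve-dynamics set: 10 basic
#' hemodynamics + 15 curve-dynamics features + 40 windowed trend/variance
#' features (5 parameters x 4 windows x 2 statistics). Models #2-#7 append
#' end-tidal CO2, thoracic impedance, 5 oxygenation features, the
#' flow-velocity curve-dynamics block (60 features incl. transfer-function
#' gain and phase), mean flow velocity, or flow-velocity pulse height.
#' Models #8 (10 basic hemodynamics) and #9 (pressures + heart rate) stand
#' alone.
#'
#' @param model_id Integer 1-9.
#' @return Character vector of beat-table column names.
#' @export
model_feature_columns <- function(model_id) {
  stopifnot(length(model_id) == 1, model_id %in% 1:9)
  m1 <- c(.basic10, .curve15("bp_"),
          .trendvar40(c("SAP", "DAP", "HR", "PP", "SV")))
  fv60 <- c(.curve15("fv_"), c("SFV", "DFV", "MFV"),
            .trendvar40(c("SFV", "DFV", "MFV", "FV_PH", "FV_area")),
            "tfa_gain", "tfa_phase")
  switch(model_id,
    m1,                                   # 1
    c(m1, "ETCO2_bt"),                    # 2
    c(m1, "TI_bt"),                       # 3
    c(m1, "O2Hb_bt", "HHb_bt", "tHb_bt", "ratio_O2Hb", "ratio_HHb"), # 4
    c(m1, fv60),                          # 5
    c(m1, "MFV"),                         # 6
    c(m1, "FV_PH"),                       # 7
    .basic10,                             # 8
    c("SAP", "DAP", "MAP", "HR")          # 9
  )
}

#' Label beat/sample times into the three hypovolemia classes
#'
#' Class 0 = baseline rest; class 1 = first 75% of the LBNP period; class
#' 2 = last 25% of LBNP (end-stage, ending at pre-syncope). The 75%
#' boundary belongs to class 2 (half-open convention). Times outside
#' `[t_baseline_start, t_presyncope]` get `NA` (rejected rows).
#'
#' @param times Numeric vector of sample times (s).
#' @param marks Protocol marks: list with `t_baseline_start`,
#'   `t_lbnp_onset`, `t_presyncope`.
#' @return Integer vector of labels in `{0, 1, 2}` (or `NA`).
#' @export
label_samples <- function(times, marks) {
  stopifnot(marks$t_baseline_start < marks$t_lbnp_onset,
            marks$t_lbnp_onset < marks$t_presyncope)
  L <- marks$t_presyncope - marks$t_lbnp_onset
  cut2 <- marks$t_lbnp_onset + 0.75 * L
  out <- rep(NA_integer_, length(times))
  out[times >= marks$t_baseline_start & times < marks$t_lbnp_onset] <- 0L
  out[times >= marks$t_lbnp_onset & times < cut2] <- 1L
  out[times >= cut2 & times <= marks$t_presyncope] <- 2L
  out
}

#' Assemble a labeled feature matrix for one model
#'
#' Selects the model's feature columns from a per-beat table, labels each
#' row by its time relative to the protocol marks, and drops rows outside
#' the protocol. The result is a `feature_matrix` tibble whose metadata
#' columns are `subject_id`, `t`, `label`; all remaining columns are
#' features.
#'
#' @param beat_table Per-beat table from [build_beat_table()] (or several
#'   subjects' tables row-bound; marks are then taken per subject from the
#'   `marks` argument).
#' @param model_id Integer 1-9.
#' @param marks Protocol marks; defaults to `attr(beat_table, "marks")`.
#' @return A `feature_matrix` tibble.
#' @export
assemble_features <- function(beat_table, model_id,
                              marks = attr(beat_table, "marks")) {
  cols <- model_feature_columns(model_id)
  missing_cols <- setdiff(cols, names(beat_table))
  if (length(missing_cols))
    stop("beat table lacks channel-derived column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(marks)) stop("protocol marks are required for labeling")
  lab <- label_samples(beat_table$t, marks)
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = beat_table$subject_id, t = beat_table$t,
                   label = lab),
    beat_table[, cols]
  )
  out <- out[!is.na(out$label), , drop = FALSE]
  out <- dplyr::arrange(out, .data$subject_id, .data$t)
  new_feature_matrix(out, model_id)
}

new_feature_matrix <- function(tbl, model_id) {
  structure(tbl, model_id = as.integer(model_id),
            class = c("feature_matrix", class(tbl)))
}

#' Feature column names of a feature matrix
#' @param X A `feature_matrix`.
#' @return Character vector (everything except `subject_id`, `t`, `label`).
#' @export
feature_cols <- function(X) setdiff(names(X), c("subject_id", "t", "label"))

#' Normalize features to each subject's baseline
#'
#' Each feature is divided by its within-subject mean over baseline rows
#' (label 0), expressing it as relative change from rest. Features whose
#' baseline mean magnitude is below `1e-9` (e.g. trends, which hover at 0
#' at rest) are baseline-mean-subtracted instead.
#'
#' @param X A `feature_matrix` with a `label` column.
#' @return The normalized `feature_matrix`.
#' @export
normalize_to_baseline <- function(X) {
  fc <- feature_cols(X)
  mid <- attr(X, "model_id")
  out <- X |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      base <- df$label == 0L
      if (!any(base)) stop("subject without baseline rows; cannot normalize")
      for (nm in fc) {
        mu <- mean(df[[nm]][base])
        df[[nm]] <- if (abs(mu) < 1e-9) df[[nm]] - mu else df[[nm]] / mu
      }
      df
    }) |>
    dplyr::ungroup()
  new_feature_matrix(out[, names(X)], mid)
}

#' Min-max scale features to the unit interval
#'
#' Per-feature minimum and maximum are computed on the training matrix only;
#' the same bounds are applied to any other matrix, with clipping to
#' `[0, 1]`. Zero-range features map to 0.5.
#'
#' @param train Training `feature_matrix`.
#' @param apply_to Optional second matrix transformed with the training
#'   bounds (e.g. a held-out subject).
#' @return List with `train`, `apply_to` (or `NULL`) and `scaler` (tibble of
#'   per-feature `min`, `max`).
#' @export
scale_unit_interval <- function(train, apply_to = NULL) {
  fc <- feature_cols(train)
  lo <- vapply(train[fc], min, numeric(1))
  hi <- vapply(train[fc], max, numeric(1))
  scaler <- tibble::tibble(feature = fc, min = unname(lo), max = unname(hi))
  apply_scaler <- function(X) {
    for (i in seq_along(fc)) {
      nm <- fc[i]
      if (hi[i] - lo[i] <= 0) {
        X[[nm]] <- rep(0.5, nrow(X))
      } else {
        X[[nm]] <- pmin(pmax((X[[nm]] - lo[i]) / (hi[i] - lo[i]), 0), 1)
      }
    }
    X
  }
  list(train = apply_scaler(train),
       apply_to = if (!is.null(apply_to)) apply_scaler(apply_to),
       scaler = scaler)
}

#' Decimate feature-matrix rows
#'
#' Keeps every `factor`-th row (offset 0) within each subject — decimation,
#' not averaging — with labels, times and ids kept aligned.
#'
#' @param X A `feature_matrix`.
#' @param factor Positive integer stride (default 10).
#' @return The downsampled `feature_matrix`.
#' @export
downsample_rows <- function(X, factor = 10) {
  stopifnot(factor >= 1)
  factor <- as.integer(factor)
  mid <- attr(X, "model_id")
  out <- X |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter((dplyr::row_number() - 1L) %% factor == 0L) |>
    dplyr::ungroup()
  new_feature_matrix(out, mid)
}

#' Write / read a feature matrix (TSV + JSON sidecar)
#'
#' Bit-exact round-trip: values are written with full precision
#' (`digits = 17`) and the sidecar records the model id and column order.
#'
#' @param X A `feature_matrix`.
#' @param path Output `.tsv` path; the sidecar is `<path>.json`.
#' @return `path` invisibly; `read_feature_matrix()` returns the matrix.
#' @export
write_feature_matrix <- function(X, path) {
  df <- as.data.frame(X)
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num]) df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(model_id = attr(X, "model_id"), columns = names(X)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  stopifnot(identical(names(df), meta$columns))
  for (nm in setdiff(names(df), "subject_id")) df[[nm]] <- as.numeric(df[[nm]])
  df$label <- as.integer(df$label)
  new_feature_matrix(tibble::as_tibble(df), meta$model_id)
}

#' Assemble all or several models' feature matrices for a cohort
#'
#' Convenience wrapper: builds beat tables for every subject (once),
#' assembles the requested models, normalizes to baseline and downsamples.
#' Unit-interval scaling is deliberately left to training time so the
#' scaler can be fit on training subjects only.
#'
#' @param cohort List of `subject_recording`s.
#' @param model_ids Models to assemble (default 1:9).
#' @param downsample Row decimation factor (default 10).
#' @param sv_baseline_ml Passed to [build_beat_table()].
#' @param tfa Passed to [build_beat_table()].
#' @return Named list of `feature_matrix` objects (`"model_1"`, ...).
#' @export
cohort_feature_matrices <- function(cohort, model_ids = 1:9,
                                    downsample = 10, sv_baseline_ml = 85,
                                    tfa = TRUE) {
  tabs <- lapply(cohort, function(rec) {
    tab <- build_beat_table(rec, sv_baseline_ml = sv_baseline_ml, tfa = tfa)
    list(tab = tab, marks = rec$marks)
  })
  out <- lapply(model_ids, function(mid) {
    per_subj <- lapply(tabs, function(x)
      assemble_features(x$tab, mid, marks = x$marks))
    pooled <- dplyr::bind_rows(per_subj)
    pooled <- new_feature_matrix(pooled, mid)
    pooled <- normalize_to_baseline(pooled)
    downsample_rows(pooled, downsample)
  })
  names(out) <- paste0("model_", model_ids)
  out
}
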