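#' End-to-end hypovolemia-classification pipeline
#'
#' Runs the full chain for one model: simulate a cohort, build per-beat
#' tables and the model's feature matrix (baseline-normalized,
#' downsampled), optionally grid-search the SVM hyperparameters, run the
#' leave-one-subject-out protocol, and evaluate with the three
#' quantification methods. A reproducibility manifest records every seed
#' and parameter; re-running from the same configuration reproduces all
#' outputs bit-identically.
#'
#' @param config A [cohort_config()] describing the cohort.
#' @param model_id Feature-set model, 1-9.
#' @param C,gamma SVM configuration; ignored when `tune = TRUE`.
#' @param tune Run the 8 x 8 hyperparameter grid search first? (64
#'   leave-one-subject-out runs; costly.)
#' @param n_train Training subjects per iteration (see [loso_evaluate()]).
#' @param downsample Row decimation factor (default 10).
#' @param window Moving-average window for evaluation (odd samples).
#' @param cutoff_step Log-odds cutoff grid step.
#' @param tfa Compute transfer-function features (only needed for model 5)?
#' @param out Optional directory; when given, the manifest (JSON), the
#'   feature matrix (TSV), predictions and report tables are written there.
#' @return A `pipeline_result` list: `features`, `config_used`, `run`
#'   (`loso_run`), `report` (`eval_report`), `manifest`.
#' @export
run_pipeline <- function(config, model_id = 8, C = 1, gamma = 0.1,
                         tune = FALSE, n_train = NULL,
                         downsample = 10, window = 31, cutoff_step = 0.01,
                         tfa = model_id == 5, out = NULL) {
  if (!model_id %in% 1:9) stop("unknown model_id ", model_id,
                               "; must be in 1..9")
  validate_cohort_config(config)

  cohort <- simulate_cohort(config)
  feats <- cohort_feature_matrices(cohort, model_ids = model_id,
                                   downsample = downsample, tfa = tfa)[[1]]
  gs <- NULL
  if (isTRUE(tune)) {
    gs <- grid_search(feats, n_train = n_train, seed = config$seed)
    C <- gs$C; gamma <- gs$gamma
  }
  run <- loso_evaluate(feats, C = C, gamma = gamma, n_train = n_train,
                       seed = config$seed)
  report <- evaluate_run(run, window = window, cutoff_step = cutoff_step)

  manifest <- list(
    model_id = model_id,
    seed = config$seed,
    n_subjects = config$n_subjects,
    baseline_duration_s = config$baseline_duration_s,
    lbnp_duration_range_s = config$lbnp_duration_range_s,
    collapse_fraction = config$collapse_fraction,
    phenotype_mix = config$phenotype_mix,
    svm = list(C = C, gamma = gamma, kernel = "radial",
               probability = "pairwise-coupled sigmoid (libsvm/e1071)",
               grid_searched = isTRUE(tune),
               shared_subsets = TRUE),
    n_train = attr(run, "n_train"),
    downsample_factor = downsample,
    trend_windows_s = c(30, 60, 90, 120),
    tfa = list(window_s = 180, band_hz = c(0.06, 0.15),
               coherence_min = 0.5, resample_hz = 4, segment_s = 100,
               assumed = c("resample_hz", "segment_s", "taper")),
    moving_average_window = window,
    moving_average_window_assumed = TRUE,
    cutoff_step = cutoff_step,
    cutoff_step_assumed = TRUE,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  res <- structure(list(features = feats, run = run, report = report,
                        grid = gs, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_feature_matrix(feats, file.path(out, "features.tsv"))
    utils::write.table(as.data.frame(run), file.path(out, "predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(report$sens_spec),
                       file.path(out, "sens_spec.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(report$errors),
                       file.path(out, "model_error.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(report$confusion, file.path(out, "confusion.tsv"),
                       sep = "\t", quote = FALSE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> model", x$manifest$model_id,
      "| C =", x$manifest$svm$C, "gamma =", x$manifest$svm$gamma, "\n")
  print(x$report)
  invisible(x)
}
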