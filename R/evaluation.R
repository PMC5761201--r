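#' 3 x 3 confusion matrix of hypovolemia classes
#'
#' @param pred,truth Equal-length label sequences in `{0, 1, 2}`.
#' @return Integer matrix; entry `[i, j]` counts truth class `i - 1`
#'   predicted as class `j - 1`.
#' @export
confusion_matrix <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (!all(pred %in% 0:2) || !all(truth %in% 0:2))
    stop("labels must lie in {0, 1, 2}")
  cm <- table(factor(truth, levels = 0:2), factor(pred, levels = 0:2))
  m <- matrix(as.integer(cm), 3, 3,
              dimnames = list(truth = 0:2, pred = 0:2))
  m
}

#' One-vs-all sensitivity and specificity for a class
#'
#' Sensitivity is the fraction of class-`c` samples predicted as `c`;
#' specificity the fraction of non-`c` samples predicted as any other
#' class. Empty denominators yield `NA` (flagged undefined; excluded from
#' cohort medians).
#'
#' @param cm 3 x 3 confusion matrix from [confusion_matrix()].
#' @param c Class index 0, 1 or 2.
#' @return List with `sensitivity` and `specificity`.
#' @export
sens_spec_one_vs_all <- function(cm, c) {
  stopifnot(all(dim(cm) == c(3, 3)), c %in% 0:2)
  i <- c + 1L
  pos <- sum(cm[i, ])
  neg <- sum(cm[-i, ])
  list(
    sensitivity = if (pos > 0) cm[i, i] / pos else NA_real_,
    specificity = if (neg > 0) sum(cm[-i, -i]) / neg else NA_real_
  )
}

#' Centered moving average of a prediction sequence
#'
#' Moving mean of the integer class predictions with edge truncation
#' (partial windows at the ends), yielding the continuous prediction line
#' used for visualizing progression toward pre-syncope and for the model
#' error.
#'
#' @param pred Label sequence.
#' @param window Odd window size in samples (>= 1).
#' @return Numeric sequence in `[0, 2]`, same length as `pred`.
#' @export
moving_average_prediction <- function(pred, window = 31) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(as.numeric(pred))
  zoo::rollapply(as.numeric(pred), width = window, FUN = mean,
                 align = "center", partial = TRUE)
}

#' Model error: MSE between classes and the smoothed prediction
#'
#' Per class, the mean squared error between the true class value and the
#' moving-averaged prediction over the samples of that class; the total is
#' the sum over the three classes. Classes absent from `truth` are flagged
#' `NA`.
#'
#' @param pred,truth Aligned label sequences.
#' @param window Moving-average window (odd).
#' @return Tibble with `class_0`, `class_1`, `class_2`, `total`.
#' @export
model_error <- function(pred, truth, window = 31) {
  stopifnot(length(pred) == length(truth))
  sm <- moving_average_prediction(pred, window)
  err <- vapply(0:2, function(c) {
    idx <- truth == c
    if (!any(idx)) return(NA_real_)
    mean((sm[idx] - c)^2)
  }, numeric(1))
  tibble::tibble(class_0 = err[1], class_1 = err[2], class_2 = err[3],
                 total = sum(err, na.rm = FALSE))
}

#' Log odds ratio of end-stage vs. baseline probability
#'
#' `LOR = ln(max(p2, eps) / max(p0, eps))` with `eps = 1e-6`: the model's
#' scalar progression index toward end-stage hypovolemia.
#'
#' @param p0,p2 Class-0 and class-2 probabilities (vectors allowed).
#' @param eps Floor avoiding infinite ratios.
#' @return Numeric vector of log odds ratios.
#' @export
log_odds_ratio <- function(p0, p2, eps = 1e-6) {
  log(pmax(p2, eps) / pmax(p0, eps))
}

#' Optimal lower/upper cutoffs on the log odds ratio
#'
#' Classification rule: `LOR <= low -> 0`, `low < LOR <= high -> 1`,
#' `LOR > high -> 2`. Candidate cutoffs run on a grid of step `step`
#' spanning `[min(lor) - step, max(lor) + step]`; the returned pair
#' maximizes the summed one-vs-all sensitivity + specificity over the three
#' classes, with ties broken toward the smallest `low`, then smallest
#' `high`. The objective decomposes exactly into a term depending only on
#' `low` plus a term depending only on `high`, so the search is linear in
#' the grid rather than quadratic; it agrees with exhaustive pair
#' enumeration.
#'
#' @param lor Log-odds-ratio sequence.
#' @param truth Labels in `{0, 1, 2}`; all three classes must be present.
#' @param step Grid step (default 0.01).
#' @return List: `low`, `high`, `objective`, and `metrics` (tibble of
#'   per-class sensitivity/specificity achieved by the returned pair).
#' @export
optimize_cutoffs <- function(lor, truth, step = 0.01) {
  stopifnot(length(lor) == length(truth))
  if (!all(0:2 %in% truth)) stop("all three classes must be present in truth")
  grid <- seq(min(lor) - step, max(lor) + step, by = step)
  G <- length(grid)
  n_c <- vapply(0:2, function(c) sum(truth == c), numeric(1))
  ## cumulative counts per class at each grid point: A_c[g] = #{truth==c, lor <= grid[g]}
  A <- vapply(0:2, function(c)
    as.numeric(findInterval(grid, sort(lor[truth == c]))), numeric(G))
  ## decomposition: objective(i, j) = F[i] + G2[j]
  F_low <- A[, 1] / n_c[1] +
    (n_c[2] - A[, 2] + n_c[3] - A[, 3]) / (n_c[2] + n_c[3]) -
    A[, 2] / n_c[2] +
    A[, 1] / (n_c[1] + n_c[3])
  G_high <- (n_c[3] - A[, 3]) / n_c[3] +
    (A[, 1] + A[, 2]) / (n_c[1] + n_c[2]) +
    A[, 2] / n_c[2] +
    (n_c[3] - A[, 3]) / (n_c[1] + n_c[3])

  ## best pair with i < j under lexicographic (smallest low, then high) ties
  suf_max <- rev(cummax(rev(G_high)))
  eps <- 1e-9
  best_total <- max(F_low[seq_len(G - 1)] + suf_max[2:G])
  i_star <- which(F_low[seq_len(G - 1)] + suf_max[2:G] >= best_total - eps)[1]
  j_cand <- which(G_high[(i_star + 1):G] >= suf_max[i_star + 1] - eps)[1] + i_star
  low <- grid[i_star]; high <- grid[j_cand]

  pred <- cutoff_classify(lor, low, high)
  cm <- confusion_matrix(pred, truth)
  metrics <- purrr::map_dfr(0:2, function(c) {
    m <- sens_spec_one_vs_all(cm, c)
    tibble::tibble(class = c, sensitivity = m$sensitivity,
                   specificity = m$specificity)
  })
  list(low = low, high = high,
       objective = sum(metrics$sensitivity + metrics$specificity),
       metrics = metrics)
}

#' Classify by log-odds-ratio cutoffs
#'
#' @param lor Log-odds-ratio values.
#' @param low,high Cutoffs with `low < high`.
#' @return Integer labels in `{0, 1, 2}`.
#' @export
cutoff_classify <- function(lor, low, high) {
  stopifnot(low < high)
  ifelse(lor <= low, 0L, ifelse(lor <= high, 1L, 2L))
}

#' Median and quartiles across subjects
#'
#' @param x Numeric vector of per-subject metric values (`NA` = undefined,
#'   excluded).
#' @return Tibble with `median`, `q25`, `q75`, `n` (linear-interpolation
#'   quantiles, type 7).
#' @export
summarize_cohort <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x))
    return(tibble::tibble(median = NA_real_, q25 = NA_real_,
                          q75 = NA_real_, n = 0L))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], q25 = q[1], q75 = q[3], n = length(x))
}

#' Per-subject, per-class metrics of a leave-one-subject-out run
#'
#' @param x A `loso_run` from [loso_evaluate()].
#' @param ... Unused.
#' @return Tibble: `subject_id`, `class`, `sensitivity`, `specificity`,
#'   and the per-class and total moving-average model errors.
#' @method tidy loso_run
#' @export
tidy.loso_run <- function(x, ...) {
  window <- list(...)$window %||% 31
  x |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      cm <- confusion_matrix(df$pred, df$truth)
      err <- model_error(df$pred, df$truth, window = window)
      purrr::map_dfr(0:2, function(c) {
        m <- sens_spec_one_vs_all(cm, c)
        tibble::tibble(class = c, sensitivity = m$sensitivity,
                       specificity = m$specificity,
                       mse = err[[paste0("class_", c)]],
                       total_error = err$total)
      })
    }) |>
    dplyr::ungroup()
}

#' Cohort summary of a leave-one-subject-out run
#'
#' Median and interquartile range, across subjects, of per-class one-vs-all
#' sensitivity and specificity (undefined metrics excluded).
#'
#' @param x A `loso_run`.
#' @param ... Passed to [tidy.loso_run()].
#' @return Tibble with one row per class and metric.
#' @method glance loso_run
#' @export
glance.loso_run <- function(x, ...) {
  td <- tidy.loso_run(x, ...)
  td |>
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "metric") |>
    dplyr::group_by(.data$class, .data$metric) |>
    dplyr::group_modify(function(df, key) summarize_cohort(df$value)) |>
    dplyr::ungroup()
}

#' Full evaluation report for a leave-one-subject-out run
#'
#' Applies the three quantification methods to a `loso_run`:
#' \enumerate{
#'   \item one-vs-all sensitivity/specificity per class, summarized across
#'     subjects as median and quartiles;
#'   \item per-class mean squared error between the true classes and the
#'     moving-averaged prediction, summarized as the cohort median;
#'   \item log-odds-ratio cutoff analysis (pooled across subjects by
#'     default), reporting the optimal cutoff pair and its achieved
#'     metrics.
#' }
#'
#' @param run A `loso_run`.
#' @param window Moving-average window (odd number of samples).
#' @param cutoff_step Grid step for the cutoff search.
#' @param per_subject_cutoffs Optimize cutoffs per subject instead of
#'   pooled?
#' @return An `eval_report` list: `sens_spec`, `errors`, `cutoffs`,
#'   `confusion`, `confusion_cutoff`, `window`, `cutoff_step`.
#' @export
evaluate_run <- function(run, window = 31, cutoff_step = 0.01,
                         per_subject_cutoffs = FALSE) {
  td <- tidy.loso_run(run, window = window)
  sens_spec <- glance.loso_run(run, window = window)
  errors <- td |>
    dplyr::distinct(.data$subject_id, .data$class, .data$mse, .data$total_error) |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(df, key) summarize_cohort(df$mse)) |>
    dplyr::ungroup()
  total_err <- td |>
    dplyr::distinct(.data$subject_id, .data$total_error)
  lor <- log_odds_ratio(run$p0, run$p2)
  if (per_subject_cutoffs) {
    cuts <- run |>
      dplyr::mutate(lor = lor) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_modify(function(df, key) {
        if (!all(0:2 %in% df$truth))
          return(tibble::tibble(low = NA_real_, high = NA_real_,
                                objective = NA_real_))
        cc <- optimize_cutoffs(df$lor, df$truth, step = cutoff_step)
        tibble::tibble(low = cc$low, high = cc$high,
                       objective = cc$objective)
      }) |>
      dplyr::ungroup()
    pred_cut <- run$pred  # per-subject rule not pooled into one sequence
    cutoffs <- cuts
    cm_cut <- NULL
  } else {
    cc <- optimize_cutoffs(lor, run$truth, step = cutoff_step)
    pred_cut <- cutoff_classify(lor, cc$low, cc$high)
    cutoffs <- tibble::tibble(low = cc$low, high = cc$high,
                              objective = cc$objective)
    cutoffs <- list(pair = cutoffs, metrics = cc$metrics)
    cm_cut <- confusion_matrix(pred_cut, run$truth)
  }
  structure(list(
    sens_spec = sens_spec,
    errors = errors,
    total_error = summarize_cohort(total_err$total_error),
    cutoffs = cutoffs,
    confusion = confusion_matrix(run$pred, run$truth),
    confusion_cutoff = cm_cut,
    window = window, cutoff_step = cutoff_step
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat("One-vs-all sensitivity/specificity (cohort median [q25; q75]):\n")
  print(x$sens_spec)
  cat("\nModel error (MSE vs moving-averaged prediction, window ",
      x$window, "):\n", sep = "")
  print(x$errors)
  if (!is.null(x$cutoffs$pair)) {
    cat("\nLog-odds-ratio cutoffs: low =", x$cutoffs$pair$low,
        " high =", x$cutoffs$pair$high, "\n")
    print(x$cutoffs$metrics)
  }
  invisible(x)
}

#' Prediction-line plot for a leave-one-subject-out run
#'
#' Plots, per subject, the moving-averaged class prediction against time —
#' the visual progression index that rises from baseline toward the
#' end-stage class as pre-syncope approaches — over the true class bands.
#'
#' @param object A `loso_run`.
#' @param window Moving-average window (odd).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loso_run
#' @export
autoplot.loso_run <- function(object, window = 31, ...) {
  df <- object |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(smoothed = moving_average_prediction(.data$pred, window)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$truth), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "#b2182b") +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "time (s)", y = "class / smoothed prediction",
                  title = "Moving-averaged model prediction vs. true class") +
    ggplot2::theme_minimal()
}

#' Channel overview plot for a simulated subject
#'
#' @param object A `subject_recording`.
#' @param channels Channels to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subject_recording
#' @export
autoplot.subject_recording <- function(object,
                                       channels = c("bp", "fv", "etco2", "ti"),
                                       ...) {
  df <- purrr::map_dfr(channels, function(nm) {
    ch <- object$channels[[nm]]
    tibble::tibble(channel = paste0(nm, " (", ch$units, ")"),
                   t = (seq_along(ch$samples) - 1) / ch$fs,
                   value = ch$samples)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$marks$t_lbnp_onset,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL, title = object$subject_id) +
    ggplot2::theme_minimal()
}
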