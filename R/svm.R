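#' The 8 x 8 hyperparameter grid
#'
#' Log-spaced grids for the soft-margin penalty `C` (8 values from 1e-2 to
#' 1e2) and the RBF kernel width `gamma` (8 values from 1e-3 to 1), giving
#' 64 candidate configurations.
#'
#' @return List with sorted numeric vectors `C` and `gamma`, 8 values each.
#' @export
hyperparameter_grids <- function() {
  list(C = 10^seq(-2, 2, length.out = 8),
       gamma = 10^seq(-3, 0, length.out = 8))
}

#' Train an RBF-kernel support vector classifier
#'
#' Soft-margin SVM with Gaussian kernel
#' `k(u, v) = exp(-gamma * ||u - v||^2)`, one-vs-one multiclass, and
#' pairwise-coupled sigmoid probability estimates (the libsvm scheme, via
#' \pkg{e1071}). Deterministic given `(X, y, C, gamma, seed)`.
#'
#' @param X Data frame / matrix of scaled features (rows = samples).
#' @param y Class labels in `{0, 1, 2}`.
#' @param C Penalty parameter (> 0).
#' @param gamma Kernel width (> 0).
#' @param seed Integer seed for the probability-calibration cross-validation.
#' @return A `trained_classifier` list: the fitted machine, feature names,
#'   and the configuration.
#' @export
train_svm <- function(X, y, C = 1, gamma = 0.1, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y, levels = sort(unique(as.integer(y))))
  if (nlevels(y) < 2) stop("training data contains a single class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, probability = TRUE,
                    scale = FALSE)
  structure(list(fit = fit, features = colnames(X),
                 config = list(C = C, gamma = gamma, seed = seed)),
            class = "trained_classifier")
}

#' Predict classes and per-class probabilities
#'
#' Returns the per-row probability triplet and the argmax class: the class
#' with the highest probability, ties broken toward the lower class index.
#'
#' @param object A `trained_classifier`.
#' @param newdata Data frame / matrix with the training feature columns.
#' @param ... Unused.
#' @return Tibble with `pred` (integer class) and `p0`, `p1`, `p2`
#'   (probabilities summing to 1).
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  if (ncol(X) != length(object$features))
    stop("column mismatch with the trained model")
  pr <- attr(stats::predict(object$fit, X, probability = TRUE),
             "probabilities")
  classes <- as.integer(colnames(pr))
  ord <- order(classes)
  pr <- pr[, ord, drop = FALSE]
  classes <- classes[ord]
  full <- matrix(0, nrow(pr), 3, dimnames = list(NULL, c("p0", "p1", "p2")))
  full[, classes + 1L] <- pr
  tibble::tibble(pred = .argmax_class(full), p0 = full[, 1], p1 = full[, 2],
                 p2 = full[, 3])
}

## class with the highest probability; ties toward the lower class index
.argmax_class <- function(prob3) {
  as.integer(max.col(prob3, ties.method = "first") - 1L)
}

#' Leave-one-subject-out evaluation
#'
#' For each subject in turn: draw `n_train` training subjects uniformly
#' without replacement from the remaining subjects (a fresh draw per test
#' subject), fit the unit-interval scaler and the SVM on the pooled
#' training rows, and predict every row of the held-out subject. The test
#' subject is never part of its own training set.
#'
#' @param features A pooled, baseline-normalized `feature_matrix`
#'   (downsampled), covering all subjects.
#' @param C,gamma SVM configuration.
#' @param n_train Training subjects per iteration; `NULL` chooses 30 when
#'   the cohort exceeds 30 subjects and `floor(0.7 * (N - 1))` otherwise.
#' @param seed Integer seed controlling subset draws and probability
#'   calibration.
#' @return A `loso_run`: tibble of `subject_id`, `t`, `truth`, `pred`,
#'   `p0..p2`, with attributes `config`, `n_train`, `train_sets`.
#' @export
loso_evaluate <- function(features, C = 1, gamma = 0.1, n_train = NULL,
                          seed = 1L) {
  subjects <- unique(features$subject_id)
  N <- length(subjects)
  if (is.null(n_train))
    n_train <- if (N - 1 >= 30) 30L else max(1L, floor(0.7 * (N - 1)))
  if (N < n_train + 1) stop("cohort too small for ", n_train,
                            " training subjects + 1 test subject")
  fc <- feature_cols(features)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  subset_seeds <- sample.int(.Machine$integer.max - 1L, N)

  train_sets <- list()
  out <- vector("list", N)
  for (i in seq_len(N)) {
    s <- subjects[i]
    others <- setdiff(subjects, s)
    set.seed(subset_seeds[i])
    tr_subj <- sample(others, n_train)
    train_sets[[s]] <- tr_subj
    tr <- features[features$subject_id %in% tr_subj, , drop = FALSE]
    te <- features[features$subject_id == s, , drop = FALSE]
    sc <- scale_unit_interval(new_feature_matrix(tr, attr(features, "model_id")),
                              new_feature_matrix(te, attr(features, "model_id")))
    model <- train_svm(sc$train[, fc], sc$train$label, C = C, gamma = gamma,
                       seed = subset_seeds[i])
    pr <- predict(model, sc$apply_to[, fc])
    out[[i]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = s, t = te$t, truth = te$label), pr)
  }
  structure(dplyr::bind_rows(out),
            config = list(C = C, gamma = gamma, seed = seed),
            n_train = n_train, train_sets = train_sets,
            class = c("loso_run", "tbl_df", "tbl", "data.frame"))
}

#' Grid search over the 64 hyperparameter configurations
#'
#' Runs [loso_evaluate()] for every `(C, gamma)` pair of
#' [hyperparameter_grids()] with the same seed (shared random subject
#' subsets across configurations, for variance reduction) and scores each by
#' the mean over tested subjects of the summed one-vs-all sensitivity +
#' specificity over the three classes. Ties break toward smaller `C`, then
#' smaller `gamma`.
#'
#' @inheritParams loso_evaluate
#' @param grids Grids as from [hyperparameter_grids()].
#' @return List: `C`, `gamma` (the maximizer), and `objective` (tibble of
#'   all 64 logged objective values).
#' @export
grid_search <- function(features, n_train = NULL, seed = 1L,
                        grids = hyperparameter_grids()) {
  best <- NULL
  log <- list()
  k <- 0L
  for (C in sort(grids$C)) {
    for (gamma in sort(grids$gamma)) {
      run <- loso_evaluate(features, C = C, gamma = gamma,
                           n_train = n_train, seed = seed)
      obj <- .loso_objective(run)
      k <- k + 1L
      log[[k]] <- tibble::tibble(C = C, gamma = gamma, objective = obj)
      if (is.null(best) || obj > best$objective + 1e-12) {
        best <- list(C = C, gamma = gamma, objective = obj)
      }
    }
  }
  list(C = best$C, gamma = best$gamma, objective = dplyr::bind_rows(log))
}

## mean over subjects of sum over classes of (sensitivity + specificity);
## undefined per-class metrics are skipped within a subject's sum
.loso_objective <- function(run) {
  per_subject <- run |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(df, key) {
      cm <- confusion_matrix(df$pred, df$truth)
      total <- 0
      for (c in 0:2) {
        m <- sens_spec_one_vs_all(cm, c)
        total <- total + sum(c(m$sensitivity, m$specificity), na.rm = TRUE)
      }
      total
    })
  mean(unlist(per_subject))
}
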