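#' Classifier configuration for the linear-SVM stage
#'
#' @param c_grid Candidate soft-margin penalties; default
#'   `c(0.01, 0.1, 1, 10)`. The grid search keeps the best-performing
#'   value, breaking ties toward the smallest C (strongest
#'   regularization).
#' @param feature_set `"base"` (maximum 3D diameter, surface area,
#'   volume) or `"extended"` (base plus the four form factors afl, aco,
#'   kfl, mps that discriminate the classes in both datasets).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(c_grid = c(0.01, 0.1, 1, 10),
                              feature_set = c("base", "extended")) {
  feature_set <- match.arg(feature_set)
  if (any(c_grid <= 0)) stop("all penalty values must be positive")
  structure(list(c_grid = sort(c_grid), feature_set = feature_set,
                 kernel = "linear"),
            class = "classifier_config")
}

#' Columns of the base and extended feature sets
#'
#' @param feature_set `"base"` or `"extended"`.
#' @return Character vector of feature column names.
#' @export
feature_set_columns <- function(feature_set = c("base", "extended")) {
  feature_set <- match.arg(feature_set)
  base <- c("max3ddiam", "surfarea", "volume")
  if (feature_set == "base") base else c(base, "afl", "aco", "kfl", "mps")
}

#' Fit per-feature Z-score normalization parameters
#'
#' Column means and population SDs (n denominator) of the feature columns
#' of one dataset. Normalization is always fitted per dataset, each
#' dataset blind to the other; a zero-variance column is mapped to all
#' zeros by [zscore_apply()] with a warning.
#'
#' @param features A data frame / tibble of numeric feature columns (or a
#'   cohort tibble restricted by `columns`).
#' @param columns Columns to normalize; default all numeric feature
#'   columns present in [feature_names()].
#' @return A list of class `zscore_params` with `mean` and `sd` vectors.
#' @export
zscore_fit <- function(features, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(feature_names(), names(features))
  x <- as.matrix(features[, columns, drop = FALSE])
  if (nrow(x) < 2L) stop("Z-score fit requires at least 2 samples")
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))  # population SD
  structure(list(mean = mu, sd = sdev, columns = columns),
            class = "zscore_params")
}

#' Apply Z-score normalization
#'
#' @param params From [zscore_fit()].
#' @param features Table containing at least the fitted columns.
#' @return The table with the fitted columns standardized.
#' @export
zscore_apply <- function(params, features) {
  out <- features
  degenerate <- params$sd == 0
  if (any(degenerate))
    warning("zero-variance feature(s) mapped to 0: ",
            paste(params$columns[degenerate], collapse = ", "))
  for (j in seq_along(params$columns)) {
    col <- params$columns[j]
    out[[col]] <- if (degenerate[j]) rep(0, nrow(features))
      else (features[[col]] - params$mean[j]) / params$sd[j]
  }
  out
}

#' Train a soft-margin linear SVM
#'
#' Deterministic linear decision function (weight vector and bias) at
#' penalty `c`, fitted with the libsvm solver ([e1071::svm()]) at fixed
#' tolerance 1e-6 and no internal rescaling (features are expected to be
#' Z-scored already).
#'
#' @param features Numeric matrix or data frame of predictors.
#' @param labels Two-level factor or character vector.
#' @param c Soft-margin penalty (> 0).
#' @return A list of class `lsvm` with `weights`, `bias`, `levels`, and
#'   the underlying fit.
#' @export
train_lsvm <- function(features, labels, c = 1) {
  x <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2L)
    stop("training labels must contain exactly two classes, got ",
         nlevels(y))
  fit <- e1071::svm(x, y, kernel = "linear", cost = c, scale = FALSE,
                    tolerance = 1e-6)
  w <- drop(t(fit$coefs) %*% fit$SV)
  structure(list(weights = w, bias = -fit$rho, levels = levels(y),
                 c = c, fit = fit),
            class = "lsvm")
}

#' @export
predict.lsvm <- function(object, newdata, ...) {
  as.character(predict(object$fit, as.matrix(newdata)))
}

eval_result <- function(train_id, test_id, feature_set, correct, total,
                        chosen_c) {
  structure(list(train = train_id, test = test_id,
                 feature_set = feature_set,
                 accuracy = correct / total,
                 accuracy_pct = 100 * correct / total,
                 correct = as.integer(correct), total = as.integer(total),
                 chosen_c = chosen_c),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s/%s [%s] accuracy %s, C = %g\n",
              x$train, x$test, x$feature_set,
              format_accuracy(x$correct, x$total), x$chosen_c))
  invisible(x)
}

#' Format an accuracy as "percentage (fraction)"
#'
#' @param correct,total Integers.
#' @return Character scalar, e.g. `"49.4 (41/83)"`.
#' @export
format_accuracy <- function(correct, total) {
  sprintf("%.1f (%d/%d)", 100 * correct / total, correct, total)
}

cohort_xy <- function(cohort, feature_set) {
  cols <- feature_set_columns(feature_set)
  check_cohort(cohort, cols)
  list(x = as.matrix(cohort[, cols, drop = FALSE]),
       y = factor(as.character(cohort$label),
                  levels = c("benign", "malignant")))
}

cohort_id <- function(cohort) {
  if ("dataset" %in% names(cohort)) as.character(cohort$dataset[1]) else "dataset"
}

#' Leave-one-out evaluation of a linear SVM on one dataset
#'
#' Each sample is predicted by a model trained on the remaining n - 1.
#' By default the Z-score parameters are fitted once on the whole dataset
#' and reused inside every fold, replicating the published protocol of
#' per-dataset normalization (a mild information leak, documented);
#' `strict_normalization = TRUE` refits the normalization inside each
#' training fold instead.
#'
#' @param cohort A cohort tibble (single dataset).
#' @param feature_set `"base"` or `"extended"`.
#' @param c Penalty value.
#' @param strict_normalization Refit Z-scoring inside each fold?
#' @return An `eval_result`.
#' @export
loo_eval <- function(cohort, feature_set = "base", c = 1,
                     strict_normalization = FALSE) {
  cols <- feature_set_columns(feature_set)
  check_cohort(cohort, cols)
  n <- nrow(cohort)
  if (n < 3L) stop("leave-one-out needs at least 3 samples")
  whole <- zscore_fit(cohort, cols)
  correct <- 0L
  for (i in seq_len(n)) {
    train <- cohort[-i, , drop = FALSE]
    params <- if (strict_normalization) zscore_fit(train, cols) else whole
    ztest <- zscore_apply(params, cohort[i, , drop = FALSE])[, cols, drop = FALSE]
    if (length(unique(train$label)) == 1L) {
      # fold training set collapsed to one class: constant classifier
      pred <- as.character(train$label[1])
    } else {
      ztrain <- cohort_xy(zscore_apply(params, train), feature_set)
      model <- train_lsvm(ztrain$x, ztrain$y, c = c)
      pred <- predict(model, ztest)
    }
    correct <- correct + as.integer(pred == as.character(cohort$label[i]))
  }
  id <- cohort_id(cohort)
  eval_result(id, id, feature_set, correct, n, c)
}

#' Cross-dataset (or identity) holdout evaluation
#'
#' Fits on the training cohort Z-scored with its own parameters and
#' predicts the test cohort Z-scored with the *test* cohort's own
#' parameters: each dataset is normalized blind to the other, so
#' cross-dataset transfer is judged on standardized feature scales.
#'
#' @param train,test Cohort tibbles sharing the feature schema.
#' @param feature_set `"base"` or `"extended"`.
#' @param c Penalty value.
#' @return An `eval_result`.
#' @export
cross_eval <- function(train, test, feature_set = "base", c = 1) {
  cols <- feature_set_columns(feature_set)
  check_cohort(train, cols)
  if (!all(cols %in% names(test)))
    stop("test cohort is missing feature columns: ",
         paste(setdiff(cols, names(test)), collapse = ", "))
  ztrain <- cohort_xy(zscore_apply(zscore_fit(train, cols), train),
                      feature_set)
  test_params <- if (nrow(test) >= 2L) zscore_fit(test, cols)
    else zscore_fit(train, cols)
  ztest <- zscore_apply(test_params, test)[, cols, drop = FALSE]
  model <- train_lsvm(ztrain$x, ztrain$y, c = c)
  pred <- predict(model, ztest)
  correct <- sum(pred == as.character(test$label))
  eval_result(cohort_id(train), cohort_id(test), feature_set,
              correct, nrow(test), c)
}

#' Grid search over the SVM penalty
#'
#' Evaluates every penalty in the grid under the declared protocol
#' (leave-one-out on `train`, or holdout on `test`) and returns the best
#' result; ties in accuracy are broken toward the smallest C.
#'
#' @param train Training cohort.
#' @param protocol `"loo"` or `"holdout"`.
#' @param config A [classifier_config()].
#' @param test Test cohort (required for `"holdout"`).
#' @param strict_normalization Passed to [loo_eval()].
#' @return The best `eval_result` (its `chosen_c` records the winner).
#' @export
grid_search_c <- function(train, protocol = c("loo", "holdout"),
                          config = classifier_config(), test = NULL,
                          strict_normalization = FALSE) {
  protocol <- match.arg(protocol)
  if (protocol == "holdout" && is.null(test))
    stop("holdout protocol requires a test cohort")
  best <- NULL
  for (c_val in config$c_grid) {  # ascending: first strict improvement wins
    res <- if (protocol == "loo")
      loo_eval(train, config$feature_set, c = c_val,
               strict_normalization = strict_normalization)
    else
      cross_eval(train, test, config$feature_set, c = c_val)
    if (is.null(best) || res$accuracy > best$accuracy) best <- res
  }
  best
}

#' Accuracy gain of the extended over the base feature set
#'
#' @param base,extended `eval_result`s for the same train/test pair.
#' @return A list with `gain_pp` (percentage points), `gain_correct`
#'   (difference in correctly classified samples), `total`, and a
#'   formatted `label` like `"14.5 (12/83)"`.
#' @export
gain <- function(base, extended) {
  if (!identical(base$train, extended$train) ||
      !identical(base$test, extended$test) ||
      base$total != extended$total)
    stop("gain requires results for the same train/test pair")
  d <- extended$correct - base$correct
  list(gain_pp = extended$accuracy_pct - base$accuracy_pct,
       gain_correct = d, total = base$total,
       label = sprintf("%.1f (%d/%d)",
                       extended$accuracy_pct - base$accuracy_pct,
                       d, base$total))
}
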