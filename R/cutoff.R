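#' Accuracy-maximising cutoff threshold for one feature
#'
#' Scans candidate thresholds at the midpoints between consecutive
#' distinct sorted values, plus two sentinels (classify-everything one
#' way, so the search is total even for useless features), and returns
#' the threshold that maximises overall classification accuracy. With
#' `direction = "greater"` a value above the threshold is called
#' malignant; with `"less"`, below. Ties in accuracy are broken toward
#' the lowest threshold for `"greater"` and the highest for `"less"`, so
#' the rule is symmetric under value negation.
#'
#' @param values Numeric feature values, one per lesion.
#' @param labels `"benign"`/`"malignant"` labels of the same length.
#' @param direction `"greater"` or `"less"`: which side of the threshold
#'   is called malignant.
#' @return A list of class `cutoff_result` with `direction`, `threshold`,
#'   `accuracy`, `correct`, and `total`.
#' @examples
#' optimal_cutoff(c(0.1, 0.2, 0.3, 0.4),
#'                c("benign", "benign", "malignant", "malignant"),
#'                "greater")  # threshold 0.25, accuracy 1
#' @export
optimal_cutoff <- function(values, labels, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.character(labels)
  if (length(values) != length(labels))
    stop("values and labels must have the same length")
  if (!all(labels %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'")
  if (length(unique(labels)) < 2L)
    stop("cutoff estimation requires both classes")
  sorted <- sort(unique(values))
  candidates <- c(-Inf,
                  if (length(sorted) > 1L) (head(sorted, -1) + sorted[-1]) / 2,
                  Inf)
  malignant <- labels == "malignant"
  acc <- vapply(candidates, function(th) {
    pred_malignant <- if (direction == "greater") values > th else values < th
    mean(pred_malignant == malignant)
  }, numeric(1))
  # tie-break: lowest threshold for "greater", highest for "less"
  ord <- if (direction == "greater") seq_along(candidates)
    else rev(seq_along(candidates))
  best <- ord[which.max(acc[ord])]
  structure(list(direction = direction,
                 threshold = candidates[best],
                 accuracy = acc[best],
                 correct = as.integer(round(acc[best] * length(values))),
                 total = length(values)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> malignant if value %s %.3f; accuracy %s\n",
              if (x$direction == "greater") ">" else "<", x$threshold,
              format_accuracy(x$correct, x$total)))
  invisible(x)
}

default_cutoff_directions <- c(aco = "greater", mps = "greater",
                               afl = "less", kfl = "less")

#' Cutoff table across two datasets
#'
#' For each requested form factor, estimates the accuracy-maximising
#' cutoff on dataset 1, dataset 2, the pooled data, and reports the
#' arithmetic mean of the two per-dataset thresholds. Directions default
#' to the established biomarker readings — compact/equant features (aco,
#' mps) call malignancy above the threshold, flatness features (afl, kfl)
#' below — or can be inferred from the pooled group means with
#' `directions = "infer"` for new features.
#'
#' @param ds1,ds2 Cohort tibbles for the two datasets.
#' @param features Feature columns; default `c("aco", "afl", "kfl", "mps")`.
#' @param directions Named character vector (`"greater"`/`"less"`) per
#'   feature, or `"infer"`.
#' @return A tibble with columns `feature`, `direction`,
#'   `threshold_ds1`, `threshold_ds2`, `threshold_pooled`,
#'   `threshold_avg`, and the corresponding accuracies.
#' @export
cutoff_table <- function(ds1, ds2,
                         features = c("aco", "afl", "kfl", "mps"),
                         directions = default_cutoff_directions) {
  check_cohort(ds1, features)
  check_cohort(ds2, features)
  pooled <- rbind(ds1[, c("label", features)], ds2[, c("label", features)])
  rows <- lapply(features, function(f) {
    dir <- if (identical(directions, "infer")) {
      mal <- mean(pooled[[f]][pooled$label == "malignant"])
      ben <- mean(pooled[[f]][pooled$label == "benign"])
      if (mal >= ben) "greater" else "less"
    } else {
      if (is.null(directions[[f]]))
        stop("no direction given for feature ", f)
      directions[[f]]
    }
    r1 <- optimal_cutoff(ds1[[f]], ds1$label, dir)
    r2 <- optimal_cutoff(ds2[[f]], ds2$label, dir)
    rp <- optimal_cutoff(pooled[[f]], pooled$label, dir)
    tibble::tibble(feature = f, direction = dir,
                   threshold_ds1 = r1$threshold,
                   threshold_ds2 = r2$threshold,
                   threshold_pooled = rp$threshold,
                   threshold_avg = (r1$threshold + r2$threshold) / 2,
                   accuracy_ds1 = r1$accuracy,
                   accuracy_ds2 = r2$accuracy,
                   accuracy_pooled = rp$accuracy)
  })
  do.call(rbind, rows)
}
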