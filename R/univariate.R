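#' Mann-Whitney U test for a two-group comparison
#'
#' Rank-sum comparison of one feature between two groups. The statistic
#' `U` counts pairs `(x_i, y_j)` with `x_i > y_j`, plus half of the tied
#' pairs. The two-sided p-value uses the exact permutation distribution
#' when both samples have at most 25 observations and there are no ties,
#' and the tie-corrected normal approximation with continuity correction
#' otherwise. Computation is delegated to [stats::wilcox.test()], whose
#' `W` statistic is exactly this `U`.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param exact_max Largest per-group size for the exact path (default 25).
#' @return A list with elements `u` and `p_value`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # u = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 25L) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must contain at least one value")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(u = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Benjamini-Hochberg significance flags
#'
#' Standard step-up procedure controlling the false discovery rate: with
#' the m p-values sorted ascending, the largest k with
#' `p_(k) <= k * fdr / m` determines the k smallest p-values flagged as
#' significant. Implemented via [stats::p.adjust()] (`"BH"`), which is
#' algebraically equivalent; flags are returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param fdr False discovery rate, default 0.05.
#' @return Logical vector of the same length.
#' @export
bh_flags <- function(p_values, fdr = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  stats::p.adjust(p_values, method = "BH") <= fdr
}

#' Parse printed p-values, mapping "<cap" entries to a numeric stand-in
#'
#' Published tables often print very small p-values as e.g. `"<0.001"`.
#' For re-analysis such entries are replaced by `lt_cap` (default 0.0005);
#' any stand-in below the printed cap yields the same step-up flags.
#'
#' @param p Character or numeric vector.
#' @param lt_cap Numeric stand-in for `"<..."` entries.
#' @return Numeric vector.
#' @export
parse_printed_p <- function(p, lt_cap = 0.0005) {
  if (is.numeric(p)) return(p)
  out <- suppressWarnings(as.numeric(p))
  lt <- grepl("^<", trimws(p))
  out[lt] <- lt_cap
  if (any(!is.finite(out))) stop("unparseable p-value entries: ",
                                 paste(p[!is.finite(out) & !lt], collapse = ", "))
  out
}

#' Configuration for the univariate screening stage
#'
#' @param fdr False discovery rate for the Benjamini-Hochberg step-up,
#'   default 0.05.
#' @param lt_cap Numeric stand-in for printed `"<0.001"`-style entries
#'   when re-analyzing published tables.
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(fdr = 0.05, lt_cap = 0.0005) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  structure(list(fdr = fdr, lt_cap = lt_cap), class = "stats_config")
}

#' Univariate benign-vs-malignant screening table
#'
#' For every feature column of a cohort: group mean and sample SD
#' (n - 1 denominator) per class, the two-sided Mann-Whitney p-value, and
#' the Benjamini-Hochberg significance flag computed across all features
#' of the cohort at the configured FDR.
#'
#' @param cohort A cohort tibble with a `label` column
#'   (`"benign"`/`"malignant"`) and feature columns.
#' @param config A [stats_config()].
#' @param features Feature columns to screen; defaults to the canonical
#'   11-feature schema.
#' @return A tibble with columns `feature`, `benign_mean`, `benign_sd`,
#'   `malignant_mean`, `malignant_sd`, `p_value`, `significant`.
#' @export
univariate_table <- function(cohort, config = stats_config(),
                             features = feature_names()) {
  check_cohort(cohort, features)
  benign <- cohort[cohort$label == "benign", , drop = FALSE]
  malignant <- cohort[cohort$label == "malignant", , drop = FALSE]
  rows <- lapply(features, function(f) {
    xb <- benign[[f]]
    xm <- malignant[[f]]
    tibble::tibble(
      feature = f,
      benign_mean = mean(xb), benign_sd = stats::sd(xb),
      malignant_mean = mean(xm), malignant_sd = stats::sd(xm),
      p_value = mann_whitney_u(xb, xm)$p_value
    )
  })
  out <- do.call(rbind, rows)
  out$significant <- bh_flags(out$p_value, config$fdr)
  out
}

check_cohort <- function(cohort, features = feature_names()) {
  if (!all(features %in% names(cohort)))
    stop("cohort is missing feature columns: ",
         paste(setdiff(features, names(cohort)), collapse = ", "))
  if (!"label" %in% names(cohort))
    stop("cohort must have a 'label' column")
  present <- unique(as.character(cohort$label))
  if (!setequal(intersect(present, c("benign", "malignant")), present))
    stop("labels must be 'benign' or 'malignant'")
  if (length(present) < 2L)
    stop("cohort must contain both classes, found only: ",
         paste(present, collapse = ", "))
  invisible(cohort)
}
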