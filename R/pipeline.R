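#' Configuration of a full study run
#'
#' Each dataset input may be (i) a cohort tibble, (ii) the name of a
#' built-in calibration (`"SSR1"`, `"LUNGx"`) or the path to a
#' calibration CSV — in which case a synthetic cohort is simulated with
#' the run seed — or (iii) a `list(features = , labels = )` pair of CSV
#' paths (feature table with `lesion_id` plus the 11 feature columns;
#' labels table with `lesion_id,label,dataset`).
#'
#' @param ds1,ds2 Dataset inputs (see Details).
#' @param fdr False discovery rate for the univariate stage.
#' @param c_grid SVM penalty grid.
#' @param cutoff_features Features for the cutoff table.
#' @param seed Integer seed used by any simulated input.
#' @param out_dir Optional directory; when set, [run_study()] writes all
#'   report tables there as CSV plus a run log.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ds1, ds2, fdr = 0.05,
                       c_grid = c(0.01, 0.1, 1, 10),
                       cutoff_features = c("aco", "afl", "kfl", "mps"),
                       seed = 1L, out_dir = NULL) {
  if (missing(ds1) || missing(ds2) || is.null(ds1) || is.null(ds2))
    stop("run_config: both 'ds1' and 'ds2' dataset inputs are required")
  structure(list(ds1 = ds1, ds2 = ds2, fdr = fdr, c_grid = c_grid,
                 cutoff_features = cutoff_features,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

resolve_cohort <- function(input, seed, which) {
  if (is.data.frame(input)) return(tibble::as_tibble(input))
  if (inherits(input, "cohort_calibration"))
    return(simulate_cohort(input, seed = seed * 2L + (which - 1L)))
  if (is.character(input) && length(input) == 1L) {
    cal <- load_calibration(input)
    # distinct sub-seeds per dataset so the two cohorts are independent
    return(simulate_cohort(cal, seed = seed * 2L + (which - 1L)))
  }
  if (is.list(input) && all(c("features", "labels") %in% names(input)))
    return(read_cohort(input$features, input$labels))
  stop("cannot interpret dataset input '", which,
       "': give a cohort, a calibration, or feature+labels CSV paths")
}

#' Read a cohort from a feature CSV and a labels CSV
#'
#' @param features_csv CSV with `lesion_id` plus the 11 feature columns.
#' @param labels_csv CSV with `lesion_id`, `label`, and `dataset`.
#' @return A cohort tibble.
#' @export
read_cohort <- function(features_csv, labels_csv) {
  f <- utils::read.csv(features_csv, stringsAsFactors = FALSE)
  l <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!"lesion_id" %in% names(f) || !"lesion_id" %in% names(l))
    stop("both CSVs need a 'lesion_id' column")
  m <- merge(l, f, by = "lesion_id", sort = FALSE)
  if (nrow(m) != nrow(f))
    warning("labels matched only ", nrow(m), " of ", nrow(f), " lesions")
  tibble::as_tibble(m)
}

#' Write a cohort's feature table and labels as CSV
#'
#' @param cohort A cohort tibble.
#' @param features_csv,labels_csv Output paths.
#' @return `features_csv`, invisibly.
#' @export
write_cohort <- function(cohort, features_csv, labels_csv = NULL) {
  utils::write.csv(cohort[, c("lesion_id", intersect(feature_names(),
                                                     names(cohort)))],
                   features_csv, row.names = FALSE)
  if (!is.null(labels_csv))
    utils::write.csv(cohort[, c("lesion_id", "label", "dataset")],
                     labels_csv, row.names = FALSE)
  invisible(features_csv)
}

#' Run the full benign-vs-malignant study pipeline
#'
#' Executes, on two datasets: the univariate screening stage (group
#' summaries, Mann-Whitney U, Benjamini-Hochberg flags), the linear-SVM
#' stage (base and extended feature sets over the four train/test
#' combinations ds1/ds1, ds2/ds2, ds1/ds2, ds2/ds1, with per-row penalty
#' grid search), and the cutoff-estimation stage. Deterministic given
#' the configuration: a rerun reproduces every table byte-identically.
#'
#' @param config A [run_config()].
#' @return A list of class `analysis_report` with elements `univariate`
#'   (one screening tibble per dataset), `classification` (one row per
#'   train/test pair and feature set), `gains`, `cutoffs`, `cohorts`,
#'   and `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  ds1 <- stage("input", resolve_cohort(config$ds1, config$seed, 1L))
  ds2 <- stage("input", resolve_cohort(config$ds2, config$seed, 2L))
  id1 <- cohort_id(ds1); id2 <- cohort_id(ds2)
  if (identical(id1, id2)) id2 <- paste0(id2, "_2")

  sc <- stats_config(fdr = config$fdr)
  uni <- stage("univariate", {
    out <- list(univariate_table(ds1, sc), univariate_table(ds2, sc))
    names(out) <- c(id1, id2)
    out
  })

  cls <- stage("classification", {
    pairs <- list(list(ds1, ds1, "loo"), list(ds2, ds2, "loo"),
                  list(ds1, ds2, "holdout"), list(ds2, ds1, "holdout"))
    rows <- list()
    for (p in pairs) {
      per_set <- list()
      for (fs in c("base", "extended")) {
        cfg <- classifier_config(c_grid = config$c_grid, feature_set = fs)
        res <- if (p[[3]] == "loo")
          grid_search_c(p[[1]], "loo", cfg)
        else
          grid_search_c(p[[1]], "holdout", cfg, test = p[[2]])
        per_set[[fs]] <- res
        rows[[length(rows) + 1L]] <- tibble::tibble(
          train = res$train, test = res$test, feature_set = fs,
          accuracy_pct = res$accuracy_pct, correct = res$correct,
          total = res$total, chosen_c = res$chosen_c,
          accuracy_label = format_accuracy(res$correct, res$total))
      }
      g <- gain(per_set$base, per_set$extended)
      rows[[length(rows)]]$gain_pp <- g$gain_pp
      rows[[length(rows)]]$gain_label <- g$label
    }
    do.call(rbind, lapply(rows, function(r) {
      if (!"gain_pp" %in% names(r)) { r$gain_pp <- NA_real_; r$gain_label <- NA_character_ }
      r
    }))
  })

  cuts <- stage("cutoff", cutoff_table(ds1, ds2, config$cutoff_features))

  report <- structure(list(
    univariate = uni,
    classification = cls,
    cutoffs = cuts,
    cohorts = stats::setNames(list(ds1, ds2), c(id1, id2)),
    provenance = list(
      seed = config$seed, fdr = config$fdr, c_grid = config$c_grid,
      cutoff_features = config$cutoff_features,
      package_version = as.character(utils::packageVersion("lesionshape")),
      timestamp = NA)  # kept NA so reruns are byte-identical
  ), class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write all report tables to a directory as CSV
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$univariate))
    utils::write.csv(report$univariate[[nm]],
                     file.path(dir, sprintf("univariate_%s.csv", tolower(nm))),
                     row.names = FALSE)
  utils::write.csv(report$classification,
                   file.path(dir, "classification.csv"), row.names = FALSE)
  utils::write.csv(report$cutoffs, file.path(dir, "cutoffs.csv"),
                   row.names = FALSE)
  prov <- report$provenance
  writeLines(c(sprintf("seed: %d", prov$seed),
               sprintf("fdr: %g", prov$fdr),
               sprintf("c_grid: %s", paste(prov$c_grid, collapse = " ")),
               sprintf("cutoff_features: %s",
                       paste(prov$cutoff_features, collapse = " ")),
               sprintf("package_version: %s", prov$package_version)),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' Render a human-readable summary with boxplots
#'
#' Writes a text summary of the report and, for every form factor that
#' the univariate stage flagged significant in either dataset, a
#' benign-vs-malignant boxplot/stripplot image. All numbers in the
#' summary are taken from the report tables; nothing is recomputed.
#'
#' @param report An `analysis_report` (with its `cohorts`).
#' @param dir Output directory.
#' @param device `"png"` or `"svg"` plot format.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, dir, device = c("png", "svg")) {
  device <- match.arg(device)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  sig <- unique(unlist(lapply(report$univariate, function(tb)
    tb$feature[tb$significant])))
  sig <- intersect(sig, setdiff(feature_names(), SIZE_FEATURES))

  for (f in sort(sig)) {
    dat <- do.call(rbind, lapply(names(report$cohorts), function(nm) {
      co <- report$cohorts[[nm]]
      tibble::tibble(dataset = nm, label = co$label, value = co[[f]])
    }))
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = label, y = value)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
      ggplot2::facet_wrap(~dataset) +
      ggplot2::labs(title = f, x = NULL, y = f) +
      ggplot2::theme_bw()
    out <- file.path(dir, sprintf("boxplot_%s.%s", f, device))
    ggplot2::ggsave(out, p, width = 5, height = 4, dpi = 150)
    files <- c(files, out)
  }

  summary_file <- file.path(dir, "summary.txt")
  lines <- c("Benign vs malignant shape-biomarker study", "")
  for (nm in names(report$univariate)) {
    tb <- report$univariate[[nm]]
    lines <- c(lines, sprintf("Dataset %s: %d/%d features significant: %s",
                              nm, sum(tb$significant), nrow(tb),
                              paste(tb$feature[tb$significant],
                                    collapse = ", ")))
  }
  lines <- c(lines, "", "Classification accuracy (test set):")
  cl <- report$classification
  for (i in seq_len(nrow(cl)))
    lines <- c(lines, sprintf("  %s -> %s [%s]: %s", cl$train[i], cl$test[i],
                              cl$feature_set[i], cl$accuracy_label[i]))
  lines <- c(lines, "", "Cutoff thresholds (malignant side of threshold):")
  ct <- report$cutoffs
  for (i in seq_len(nrow(ct)))
    lines <- c(lines, sprintf("  %s %s %.3f (ds1) / %.3f (ds2) / %.3f (pooled) / %.3f (avg)",
                              ct$feature[i],
                              if (ct$direction[i] == "greater") ">" else "<",
                              ct$threshold_ds1[i], ct$threshold_ds2[i],
                              ct$threshold_pooled[i], ct$threshold_avg[i]))
  writeLines(lines, summary_file)
  invisible(c(files, summary_file))
}
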