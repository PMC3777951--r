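#' Confusion counts for template-matching classification
#'
#' Tallies the classifier outcome against ground-truth resemblance labels:
#' TP = complex resembles the template and its coefficient satisfies the
#' correlation factor CF; FP = does not resemble but satisfies CF; TN =
#' does not resemble and is rejected; FN = resembles but is rejected.
#'
#' @param truth Logical vector: does each complex truly resemble the
#'   template?
#' @param predicted Logical vector: was each complex accepted (its
#'   coefficient satisfied CF)?
#'
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`
#'   (`tp + fp + tn + fn == length(truth)`).
#' @export
#' @examples
#' confusion_counts(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, TRUE, FALSE))
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_cardiofp("truth and predicted labels must have equal length", "input")
  }
  truth <- as.logical(truth)
  predicted <- as.logical(predicted)
  tibble(
    tp = sum(truth & predicted),
    fp = sum(!truth & predicted),
    tn = sum(!truth & !predicted),
    fn = sum(truth & !predicted)
  )
}

metric_pct <- function(num, den, digits = 2) {
  out <- ifelse(den > 0, num / den * 100, NA_real_)
  if (is.null(digits)) out else round(out, digits)
}

#' Classification performance metrics
#'
#' Positive predictive value `TP/(TP+FP)`, sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`, each in percent rounded to 2 decimals. A zero
#' denominator yields `NA` (rendered as an en dash in printed summaries).
#'
#' @param counts A data frame with columns `tp`, `fp`, `tn`, `fn` (one row
#'   per dataset), e.g. from [confusion_counts()].
#' @param digits Decimal places (default 2); `NULL` for full precision.
#' @return Numeric percent vector, one value per row.
#' @export
#' @examples
#' ppv(tibble::tibble(tp = 38, fp = 2, tn = 18, fn = 0))
ppv <- function(counts, digits = 2) {
  metric_pct(counts$tp, counts$tp + counts$fp, digits)
}

#' @rdname ppv
#' @export
sensitivity <- function(counts, digits = 2) {
  metric_pct(counts$tp, counts$tp + counts$fn, digits)
}

#' @rdname ppv
#' @export
specificity <- function(counts, digits = 2) {
  metric_pct(counts$tn, counts$tn + counts$fp, digits)
}

#' Summarise classification performance across datasets
#'
#' Computes PPV, sensitivity and specificity per dataset from the counts
#' and then their unweighted (macro) arithmetic means across datasets.
#' Means are taken over the full-precision per-dataset values and rounded
#' to 2 decimals at the end; undefined per-dataset values are excluded from
#' the mean.
#'
#' @param datasets A data frame with one row per dataset and columns `tp`,
#'   `fp`, `tn`, `fn` (extra columns are carried through).
#' @return An `fp_validation` object; [tidy()] returns the per-dataset
#'   table (2-decimal metrics), [glance()] the macro-means.
#' @export
#' @examples
#' glance(summarize_validation(validation_benchmark("multi_dataset")))
summarize_validation <- function(datasets) {
  if (!is.data.frame(datasets) || nrow(datasets) == 0) {
    stop_cardiofp("at least one dataset of confusion counts is required",
                  "insufficient_data")
  }
  need <- c("tp", "fp", "tn", "fn")
  if (!all(need %in% names(datasets))) {
    stop_cardiofp("datasets must carry columns tp, fp, tn, fn", "input")
  }
  full <- tibble(
    ppv = ppv(datasets, digits = NULL),
    sensitivity = sensitivity(datasets, digits = NULL),
    specificity = specificity(datasets, digits = NULL)
  )
  per <- dplyr::bind_cols(
    as_tibble(datasets),
    tibble(ppv = round(full$ppv, 2),
           sensitivity = round(full$sensitivity, 2),
           specificity = round(full$specificity, 2))
  )
  means <- tibble(
    n_datasets = nrow(datasets),
    mean_ppv = round(mean(full$ppv, na.rm = TRUE), 2),
    mean_sensitivity = round(mean(full$sensitivity, na.rm = TRUE), 2),
    mean_specificity = round(mean(full$specificity, na.rm = TRUE), 2)
  )
  structure(list(per_dataset = per, means = means, full_precision = full),
            class = "fp_validation")
}

#' @export
print.fp_validation <- function(x, ...) {
  cat("<fp_validation>\n")
  shown <- x$per_dataset
  for (m in c("ppv", "sensitivity", "specificity")) {
    shown[[m]] <- ifelse(is.na(shown[[m]]), "\u2013", format(shown[[m]]))
  }
  print(shown, ...)
  cat(sprintf("Macro-means over %d dataset(s): PPV %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              x$means$n_datasets, x$means$mean_ppv,
              x$means$mean_sensitivity, x$means$mean_specificity))
  invisible(x)
}

#' @export
tidy.fp_validation <- function(x, ...) x$per_dataset

#' @export
glance.fp_validation <- function(x, ...) x$means

#' Bundled published validation benchmark
#'
#' Confusion counts (TP/FP/TN/FN) from a published validation of
#' correlation-based field-potential classification on human
#' iPSC-cardiomyocyte MEA recordings challenged with the hERG blocker
#' E-4031 and the beta-blocker Esmolol, together with the percentages as
#' printed in that publication. `"cf_sweep"` holds one normal, one
#' morphology-changing and one arrhythmogenic recording analysed at
#' correlation factors 0.88/0.93/0.98; `"multi_dataset"` holds eight
#' datasets at CF 0.98 whose macro-averaged metrics are the published
#' summary performance. In the sweep table, specificity cells the source
#' prints as an en dash are `NA`. One printed sensitivity cell is
#' arithmetically inconsistent with its own printed counts
#' (`printed_sensitivity_matches_counts`); the counts are authoritative.
#'
#' @param which `"multi_dataset"` or `"cf_sweep"`.
#' @return A tibble of counts and printed percentages.
#' @export
validation_benchmark <- function(which = c("multi_dataset", "cf_sweep")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0(which, "_benchmark.csv"),
                   package = "cardiofp", mustWork = TRUE)
  readr::read_csv(f, show_col_types = FALSE)
}
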