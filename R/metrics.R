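# Confusion-matrix metrics. Malignant is the positive class throughout
# (benign = negative); balanced accuracy is the mean of sensitivity and
# specificity, the natural summary when class counts are unequal.

#' Construct a 2x2 confusion matrix
#'
#' @param tn,fp,fn,tp Non-negative counts, with benign as the negative class
#'   and malignant as the positive class.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0)) stop("confusion matrix counts must be non-negative")
  if (sum(counts) == 0) stop("confusion matrix is empty (total = 0)")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(c("Actual: benign", "Actual: malignant"),
                              c("Pred: benign", "Pred: malignant")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity, accuracy and balanced accuracy
#'
#' Computes the four case-classification metrics from a 2x2 confusion matrix:
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total`, and balanced accuracy, the mean of sensitivity and
#' specificity. Values are carried unrounded; printing rounds half-up to 3
#' decimals.
#'
#' @param cm A [confusion_matrix()] (or list with `tn`, `fp`, `fn`, `tp`).
#' @param rounded_inputs If `TRUE`, balanced accuracy is the mean of the
#'   already-rounded (3-decimal) sensitivity and specificity rather than of
#'   the exact values -- the convention apparently used in some published
#'   tables.
#' @return An object of class `metrics_report`.
#' @export
compute_metrics <- function(cm, rounded_inputs = FALSE) {
  if (cm$tp + cm$fn == 0) stop("undefined metric: no positive (malignant) cases")
  if (cm$tn + cm$fp == 0) stop("undefined metric: no negative (benign) cases")
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  acc <- (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn)
  bal <- if (rounded_inputs) {
    mean(c(round_half_up(sens), round_half_up(spec)))
  } else {
    (sens + spec) / 2
  }
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 balanced_accuracy = bal, confusion = cm,
                 rounded_inputs = rounded_inputs),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  v <- round_half_up(c(sensitivity = x$sensitivity,
                       specificity = x$specificity,
                       accuracy = x$accuracy,
                       balanced_accuracy = x$balanced_accuracy), digits)
  print(format(v, nsmall = digits))
  invisible(x)
}

#' Tabulate case results into a confusion matrix
#'
#' @param results Case-result data frame (see [run_cross_validation()]) with
#'   `true_label` and either `probability` or `predicted_label`.
#' @param threshold Malignancy-probability threshold (default 0.5) applied
#'   when `probability` is present.
#' @return A [confusion_matrix()].
#' @export
results_to_confusion <- function(results, threshold = 0.5) {
  if (is.null(results) || nrow(results) == 0) {
    stop("confusion matrix is empty: no case results")
  }
  pred <- if ("probability" %in% names(results)) {
    ifelse(results$probability >= threshold, "malignant", "benign")
  } else {
    results$predicted_label
  }
  truth <- results$true_label
  confusion_matrix(
    tn = sum(truth == "benign" & pred == "benign"),
    fp = sum(truth == "benign" & pred == "malignant"),
    fn = sum(truth == "malignant" & pred == "benign"),
    tp = sum(truth == "malignant" & pred == "malignant")
  )
}

#' Reference confusion matrices from the original clinical evaluation
#'
#' The case-level confusion matrices reported in the original evaluation of
#' this method on a 322-case lung cytology dataset (108 benign, 214
#' malignant), for the five AD MIL backbones and the supervised baseline
#' (patch-level and case-level). These are inputs for reproducing the
#' published metric table; the underlying images are not distributed.
#'
#' @return Data frame with columns `regime`, `backbone`, `evaluation`, `tn`,
#'   `fp`, `fn`, `tp`.
#' @export
reference_confusions <- function() {
  read.csv(system.file("extdata", "reference_confusion_matrices.csv",
                       package = "admil"), stringsAsFactors = FALSE)
}

#' Reference metric table from the original clinical evaluation
#'
#' The published sensitivity / specificity / accuracy / balanced-accuracy
#' table for all regimes and backbones. The `known_inconsistencies` column
#' flags entries that do not follow from the corresponding published
#' confusion matrix under any standard rounding (they are excluded from
#' reproduction checks and discussed in the package vignette).
#'
#' @return Data frame with one row per regime/backbone/evaluation.
#' @export
reference_metrics <- function() {
  read.csv(system.file("extdata", "reference_reported_metrics.csv",
                       package = "admil"), stringsAsFactors = FALSE)
}
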