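#' Confusion matrix of sample-level CNV status
#'
#' Compares called against true sample statuses ("positive" means
#' `cnv_positive`). Inputs are tibbles with columns `sample_id` and `status`
#' as produced by [sample_status()], or named character vectors.
#'
#' @param calls Called statuses.
#' @param truth True statuses.
#' @return An object of class `confusion_matrix` with integer fields `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion <- function(calls, truth) {
  as_status <- function(x, what) {
    if (is.data.frame(x)) {
      setNames(as.character(x$status), x$sample_id)
    } else if (!is.null(names(x))) {
      setNames(as.character(x), names(x))
    } else {
      stop_masscnv(paste0(what, " must be a sample_id/status table or named vector"),
                   "masscnv_argument_error")
    }
  }
  cvec <- as_status(calls, "calls")
  tvec <- as_status(truth, "truth")
  only_c <- setdiff(names(cvec), names(tvec))
  only_t <- setdiff(names(tvec), names(cvec))
  if (length(only_c) > 0 || length(only_t) > 0) {
    stop_masscnv(
      paste0(
        "sample sets differ between calls and truth",
        if (length(only_c) > 0)
          paste0("; only in calls: ", paste(head(only_c, 5), collapse = ", ")),
        if (length(only_t) > 0)
          paste0("; only in truth: ", paste(head(only_t, 5), collapse = ", "))
      ),
      "masscnv_argument_error"
    )
  }
  tvec <- tvec[names(cvec)]
  cp <- cvec == "cnv_positive"
  tp_ <- tvec == "cnv_positive"
  structure(list(
    tp = sum(cp & tp_), fp = sum(cp & !tp_),
    tn = sum(!cp & !tp_), fn = sum(!cp & tp_)
  ), class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_masscnv("confusion counts must be non-negative integers",
                 "masscnv_argument_error")
  }
  out <- as.list(as.integer(counts))
  names(out) <- names(counts)
  structure(out, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity = 100 * tp / (tp + fn); specificity = 100 * tn / (tn + fp);
#' PPV = 100 * tp / (tp + fp); NPV = 100 * tn / (tn + fn). A metric whose
#' denominator is zero is undefined and reported as `NA` (never silently 0).
#' Values are kept at full precision; `display` columns round half-up to one
#' decimal place for reporting.
#'
#' @param cm A `confusion_matrix`.
#' @return A tibble with columns `metric`, `value` (percent, full precision)
#'   and `display` (percent, 1 decimal, half-up).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  vals <- c(
    sensitivity = pct(cm$tp, cm$tp + cm$fn),
    specificity = pct(cm$tn, cm$tn + cm$fp),
    ppv = pct(cm$tp, cm$tp + cm$fp),
    npv = pct(cm$tn, cm$tn + cm$fn)
  )
  tibble::tibble(
    metric = names(vals),
    value = unname(vals),
    display = round_half_up(unname(vals), 1)
  )
}

#' Cohort CNV prevalence in percent
#'
#' @param positives Number of CNV-positive samples (or a `confusion_matrix`,
#'   in which case true positives + false negatives are used).
#' @param total Total number of samples (ignored when a matrix is given).
#' @param digits Display rounding (half-up), default 1 decimal.
#' @return Prevalence in percent, rounded.
#' @export
prevalence <- function(positives, total = NULL, digits = 1) {
  if (inherits(positives, "confusion_matrix")) {
    cm <- positives
    total <- cm$tp + cm$fp + cm$tn + cm$fn
    positives <- cm$tp + cm$fn
  }
  if (is.null(total) || total <= 0) {
    stop_masscnv("total sample count must be positive", "masscnv_argument_error")
  }
  round_half_up(100 * positives / total, digits)
}
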