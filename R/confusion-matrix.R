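#' Construct a binary confusion matrix
#'
#' The raw record of a binary validation experiment: counts of true
#' positives, false negatives, false positives and true negatives. Counts
#' may be fractional, because matrices reconstructed at an arbitrary target
#' prevalence (see [calibrate_matrix()]) generally have non-integer cells;
#' set `strict_integer = TRUE` for raw validation data where fractional
#' counts would indicate an upstream bug.
#'
#' @param tp,fn,fp,tn Non-negative counts. `tp`/`fn` are actual positives
#'   predicted positive/negative; `fp`/`tn` are actual negatives predicted
#'   positive/negative.
#' @param strict_integer Require all four counts to be whole numbers.
#' @return An object of class `"confusion_matrix"`.
#' @examples
#' cm <- confusion_matrix(tp = 816, fn = 384, fp = 120, tn = 680)
#' prevalence(cm)
#' sensitivity(cm)
#' specificity(cm)
#' @seealso [confusion_from_labels()], [as_profile()], [derive_matrix()]
#' @export
confusion_matrix <- function(tp, fn, fp, tn, strict_integer = FALSE) {
  check_number(tp, "tp", lo = 0)
  check_number(fn, "fn", lo = 0)
  check_number(fp, "fp", lo = 0)
  check_number(tn, "tn", lo = 0)
  n <- tp + fn + fp + tn
  if (n <= 0) abort_validation("total count N = tp + fn + fp + tn must be > 0")
  if (isTRUE(strict_integer)) {
    cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
    off <- abs(cells - round(cells)) > 1e-8
    if (any(off)) {
      abort_validation(sprintf(
        "non-integer counts (%s) not allowed with strict_integer = TRUE",
        paste(names(cells)[off], collapse = ", ")
      ))
    }
  }
  structure(
    list(tp = as.numeric(tp), fn = as.numeric(fn),
         fp = as.numeric(fp), tn = as.numeric(tn)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, digits = 4, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("actual_positive", "actual_negative"),
                              c("pred_positive", "pred_negative")))
  cat(sprintf("<confusion_matrix>  N = %s\n", format(n_instances(x))))
  print(round(m, digits))
  cat(sprintf("prevalence %s   sensitivity %s   specificity %s\n",
              format(round(prevalence(x), 3)),
              format(round(sensitivity(x), 3)),
              format(round(specificity(x), 3))))
  invisible(x)
}

is_confusion_matrix <- function(x) inherits(x, "confusion_matrix")

#' Total number of instances in a confusion matrix
#' @param cm A [confusion_matrix()].
#' @return The total count N.
#' @export
n_instances <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  cm$tp + cm$fn + cm$fp + cm$tn
}

#' Positive prevalence, sensitivity and specificity of a confusion matrix
#'
#' The three statistics that, together with N, fully characterise a binary
#' confusion matrix. Positive prevalence `(tp + fn) / N` measures test-set
#' imbalance; sensitivity `tp / (tp + fn)` and specificity `tn / (fp + tn)`
#' measure the model and do not depend on prevalence.
#'
#' When a denominator is zero (no actual positives for sensitivity, no
#' actual negatives for specificity) the statistic is undefined and is
#' returned as `NA_real_`, the package-wide undefined marker — never a
#' silent 0 or 1. Operations that need a defined value raise a
#' `prevcal_undefined_error` when given this marker.
#'
#' @param cm A [confusion_matrix()].
#' @return A single number in `[0, 1]`, or `NA_real_` when undefined.
#' @export
prevalence <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  (cm$tp + cm$fn) / n_instances(cm)
}

#' @rdname prevalence
#' @export
sensitivity <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  pos <- cm$tp + cm$fn
  if (pos == 0) return(NA_real_)
  cm$tp / pos
}

#' @rdname prevalence
#' @export
specificity <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  neg <- cm$fp + cm$tn
  if (neg == 0) return(NA_real_)
  cm$tn / neg
}

#' Tabulate a confusion matrix from label vectors
#'
#' @param actual,predicted Vectors of class labels, same length. At most two
#'   distinct labels may occur across the two vectors.
#' @param positive_label The label counted as positive. Must occur in the
#'   label alphabet; there is no implicit ordering convention.
#' @param strict_integer Passed to [confusion_matrix()]; defaults to `TRUE`
#'   since tabulated counts are always whole.
#' @return A [confusion_matrix()].
#' @examples
#' confusion_from_labels(c("a", "a", "b", "b"), c("a", "b", "a", "b"), "a")
#' @export
confusion_from_labels <- function(actual, predicted, positive_label,
                                  strict_integer = TRUE) {
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (length(actual) == 0L) abort_validation("label vectors must be non-empty")
  if (length(actual) != length(predicted)) {
    abort_validation(sprintf(
      "`actual` (%d) and `predicted` (%d) differ in length",
      length(actual), length(predicted)))
  }
  if (anyNA(actual) || anyNA(predicted)) {
    abort_validation("labels must not contain NA")
  }
  alphabet <- sort(unique(c(actual, predicted)))
  if (length(alphabet) > 2L) {
    abort_validation(sprintf(
      "more than two distinct labels: %s", paste(alphabet, collapse = ", ")))
  }
  if (length(positive_label) != 1L || !positive_label %in% alphabet) {
    abort_validation(sprintf(
      "positive_label %s not found in the label alphabet (%s)",
      deparse(as.character(positive_label)), paste(alphabet, collapse = ", ")))
  }
  act_pos <- actual == positive_label
  prd_pos <- predicted == positive_label
  confusion_matrix(
    tp = sum(act_pos & prd_pos),
    fn = sum(act_pos & !prd_pos),
    fp = sum(!act_pos & prd_pos),
    tn = sum(!act_pos & !prd_pos),
    strict_integer = strict_integer
  )
}
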