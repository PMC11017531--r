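#' Count-based validation metrics
#'
#' Standard binary-classification metrics computed directly from the four
#' confusion-matrix counts. Each returns a single number, or `NA_real_`
#' (the undefined marker) when the defining denominator vanishes.
#'
#' * `accuracy`: `(tp + tn) / N`, in `[0, 1]`.
#' * `mcc`: Matthews correlation coefficient
#'   `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in `[-1, 1]`.
#'   By convention the value is 0 whenever a marginal sum is zero,
#'   consistent with MCC tending to 0 at extreme prevalence; this is a
#'   documented convention, not a limit claim.
#' * `balanced_accuracy`: `(sen + spe) / 2` — accuracy calibrated to
#'   prevalence 0.5, hence prevalence-independent.
#' * `ppv` / `npv`: positive/negative predictivity `tp/(tp+fp)`,
#'   `tn/(tn+fn)`.
#' * `cohens_kappa`: chance-corrected agreement,
#'   `2*(tp*tn - fn*fp) / ((tp+fp)(fp+tn) + (tp+fn)(fn+tn))`.
#' * `f1`: `2*tp / (2*tp + fp + fn)`, positive class only.
#' * `informedness`: Youden's index `sen + spe - 1`, identical to balanced
#'   accuracy rescaled to `[-1, 1]`.
#' * `markedness`: `ppv + npv - 1`.
#'
#' @param cm A [confusion_matrix()].
#' @return A single number, or `NA_real_` when undefined.
#' @examples
#' cm <- confusion_matrix(816, 384, 120, 680)
#' accuracy(cm)
#' mcc(cm)          # 0.520 at 3 d.p.
#' balanced_accuracy(cm)
#' @name count_metrics
NULL

#' @rdname count_metrics
#' @export
accuracy <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  (cm$tp + cm$tn) / n_instances(cm)
}

#' @rdname count_metrics
#' @export
mcc <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  m1 <- cm$tp + cm$fp
  m2 <- cm$tp + cm$fn
  m3 <- cm$tn + cm$fp
  m4 <- cm$tn + cm$fn
  if (m1 == 0 || m2 == 0 || m3 == 0 || m4 == 0) return(0)
  (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(m1 * m2 * m3 * m4)
}

#' @rdname count_metrics
#' @export
balanced_accuracy <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  (sensitivity(cm) + specificity(cm)) / 2
}

#' @rdname count_metrics
#' @export
ppv <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  d <- cm$tp + cm$fp
  if (d == 0) return(NA_real_)
  cm$tp / d
}

#' @rdname count_metrics
#' @export
npv <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  d <- cm$tn + cm$fn
  if (d == 0) return(NA_real_)
  cm$tn / d
}

#' @rdname count_metrics
#' @export
cohens_kappa <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  d <- (cm$tp + cm$fp) * (cm$fp + cm$tn) + (cm$tp + cm$fn) * (cm$fn + cm$tn)
  if (d == 0) return(NA_real_)
  2 * (cm$tp * cm$tn - cm$fn * cm$fp) / d
}

#' @rdname count_metrics
#' @export
f1 <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  d <- 2 * cm$tp + cm$fp + cm$fn
  if (d == 0) return(NA_real_)
  2 * cm$tp / d
}

#' @rdname count_metrics
#' @export
informedness <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  sensitivity(cm) + specificity(cm) - 1
}

#' @rdname count_metrics
#' @export
markedness <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  ppv(cm) + npv(cm) - 1
}

#' Rescale a unit-interval metric to the signed interval
#'
#' The linear map `2 * x - 1` from `[0, 1]` onto `[-1, 1]`. Applied to
#' balanced accuracy it yields informedness (Youden's index), which is also
#' the numerator of the MCC in its (sen, spe, pre) form.
#'
#' @param value_01 A number in `[0, 1]` (or `NA_real_`).
#' @return `2 * value_01 - 1`; 0.5 maps to 0.
#' @examples
#' rescale_unit_to_signed(0.765)  # 0.53 = sen + spe - 1 for (0.68, 0.85)
#' @export
rescale_unit_to_signed <- function(value_01) {
  check_number(value_01, "value_01", lo = 0, hi = 1, allow_na = TRUE)
  2 * value_01 - 1
}

# --- metric catalogue -------------------------------------------------------

.metric_registry <- list(
  accuracy          = list(fn = accuracy,          range = c(0, 1),  label = "Accuracy"),
  balanced_accuracy = list(fn = balanced_accuracy, range = c(0, 1),  label = "Balanced accuracy"),
  mcc               = list(fn = mcc,               range = c(-1, 1), label = "MCC"),
  balanced_mcc      = list(fn = function(cm) balanced_mcc(sensitivity(cm), specificity(cm)),
                           range = c(-1, 1), label = "Balanced MCC"),
  ppv               = list(fn = ppv,               range = c(0, 1),  label = "Positive predictivity"),
  npv               = list(fn = npv,               range = c(0, 1),  label = "Negative predictivity"),
  kappa             = list(fn = cohens_kappa,      range = c(-1, 1), label = "Cohen's kappa"),
  f1                = list(fn = f1,                range = c(0, 1),  label = "F1 score"),
  informedness      = list(fn = informedness,      range = c(-1, 1), label = "Informedness"),
  markedness        = list(fn = markedness,        range = c(-1, 1), label = "Markedness")
)

#' The metric catalogue
#'
#' Stable string identifiers of every metric the package computes, in
#' reporting order.
#'
#' @return A character vector of metric identifiers.
#' @export
metric_catalogue <- function() names(.metric_registry)

#' Compute one catalogue metric by identifier
#'
#' @param cm A [confusion_matrix()].
#' @param metric A catalogue identifier, see [metric_catalogue()].
#' @return A single number (or `NA_real_` when undefined).
#' @export
compute_metric <- function(cm, metric) {
  entry <- .metric_registry[[metric]]
  if (is.null(entry)) {
    abort_validation(sprintf(
      "unknown metric '%s'; see metric_catalogue()", metric))
  }
  val <- entry$fn(cm)
  as.numeric(val)
}

#' Declared range of a catalogue metric
#' @inheritParams compute_metric
#' @return Numeric length-2 vector `(lo, hi)`.
#' @export
metric_range <- function(metric) {
  entry <- .metric_registry[[metric]]
  if (is.null(entry)) {
    abort_validation(sprintf(
      "unknown metric '%s'; see metric_catalogue()", metric))
  }
  entry$range
}

#' Tabulate catalogue metrics for one confusion matrix
#'
#' One row per metric: the identifier, the value at full double precision,
#' the prevalence of the matrix it was computed from, and the metric's
#' declared range. Display rounding (3 d.p. is conventional for reporting)
#' is left to the caller.
#'
#' @param cm A [confusion_matrix()].
#' @param metrics Identifiers to compute; defaults to the full catalogue.
#' @return A data.frame with columns `metric`, `value`, `at_prevalence`,
#'   `range_lo`, `range_hi`.
#' @examples
#' metric_values(confusion_matrix(639, 261, 11, 89))
#' @export
metric_values <- function(cm, metrics = metric_catalogue()) {
  stopifnot(is_confusion_matrix(cm))
  bad <- setdiff(metrics, metric_catalogue())
  if (length(bad)) {
    abort_validation(sprintf("unknown metric(s): %s", paste(bad, collapse = ", ")))
  }
  values <- vapply(metrics, function(m) compute_metric(cm, m), numeric(1))
  ranges <- vapply(metrics, function(m) metric_range(m), numeric(2))
  data.frame(
    metric = metrics,
    value = unname(values),
    at_prevalence = prevalence(cm),
    range_lo = ranges[1, ],
    range_hi = ranges[2, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
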