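#' Construct a performance profile
#'
#' The equivalent re-parameterisation of a confusion matrix as
#' (sensitivity, specificity, prevalence, N). Prevalence and N characterise
#' the test set; sensitivity and specificity characterise the model. The
#' four numbers fully determine a unique confusion matrix (see
#' [derive_matrix()]), which is what makes prevalence calibration possible.
#'
#' `sen` may be `NA` (undefined) only when `pre = 0` (the test set has no
#' positives), and `spe` only when `pre = 1`.
#'
#' @param sen,spe,pre Proportions in `[0, 1]`; `sen`/`spe` may be
#'   `NA_real_` in the degenerate cases above.
#' @param n Total number of instances, > 0.
#' @return An object of class `"performance_profile"`.
#' @examples
#' performance_profile(sen = 0.71, spe = 0.89, pre = 0.9, n = 1000)
#' @export
performance_profile <- function(sen, spe, pre, n) {
  check_number(pre, "pre", lo = 0, hi = 1)
  check_number(n, "n")
  if (n <= 0) abort_validation("`n` must be > 0")
  check_number(sen, "sen", lo = 0, hi = 1, allow_na = TRUE)
  check_number(spe, "spe", lo = 0, hi = 1, allow_na = TRUE)
  if (is.na(sen) && pre > 0) {
    abort_validation("`sen` may be NA only when pre = 0 (no positive instances)")
  }
  if (is.na(spe) && pre < 1) {
    abort_validation("`spe` may be NA only when pre = 1 (no negative instances)")
  }
  structure(
    list(sen = as.numeric(sen), spe = as.numeric(spe),
         pre = as.numeric(pre), n = as.numeric(n)),
    class = "performance_profile"
  )
}

is_performance_profile <- function(x) inherits(x, "performance_profile")

#' @export
print.performance_profile <- function(x, ...) {
  cat(sprintf(
    "<performance_profile>  sen = %s  spe = %s  pre = %s  N = %s\n",
    format(round(x$sen, 4)), format(round(x$spe, 4)),
    format(round(x$pre, 4)), format(x$n)))
  invisible(x)
}

#' Summarise a confusion matrix as a performance profile
#'
#' Degenerate statistics (no positives / no negatives) propagate as
#' `NA_real_` markers into the profile.
#'
#' @param cm A [confusion_matrix()].
#' @return A [performance_profile()].
#' @examples
#' as_profile(confusion_matrix(816, 384, 120, 680))
#' @export
as_profile <- function(cm) {
  stopifnot(is_confusion_matrix(cm))
  performance_profile(
    sen = sensitivity(cm), spe = specificity(cm),
    pre = prevalence(cm), n = n_instances(cm)
  )
}

#' Reconstruct the derived confusion matrix from a profile
#'
#' Inverts [as_profile()]: the four counts are `TP = sen * pre * n`,
#' `FN = (1 - sen) * pre * n`, `FP = (1 - spe) * (1 - pre) * n` and
#' `TN = spe * (1 - pre) * n`. Counts are real-valued; no rounding is
#' applied (see [realise_counts()] for integer realisation). When a class
#' is absent (`pre` 0 or 1) the corresponding row is zero.
#'
#' @param profile A [performance_profile()].
#' @return A [confusion_matrix()] with prevalence `profile$pre`,
#'   sensitivity `profile$sen` and specificity `profile$spe`.
#' @examples
#' derive_matrix(performance_profile(0.68, 0.85, 0.6, 2000))
#' @export
derive_matrix <- function(profile) {
  stopifnot(is_performance_profile(profile))
  sen <- profile$sen
  spe <- profile$spe
  pre <- profile$pre
  n <- profile$n
  if (pre == 0) sen <- 0   # zero row regardless of (undefined) sen
  if (pre == 1) spe <- 0
  pos <- pre * n           # complements by subtraction so that
  neg <- (1 - pre) * n     # tp + fn == pre*n and fp + tn == (1-pre)*n exactly
  tp <- sen * pos
  tn <- spe * neg
  confusion_matrix(tp = tp, fn = pos - tp, fp = neg - tn, tn = tn)
}

#' Reconstruct a confusion matrix at a target prevalence
#'
#' The central calibration operation: keep the model description (sen, spe)
#' fixed and rebuild the derived confusion matrix as if the test set had
#' prevalence `target_prevalence`. Metrics computed on the calibrated
#' matrix are "calibrated metrics"; at target 0.5 they are the "balanced"
#' metrics.
#'
#' Calibrating a matrix with defined sensitivity and specificity to a
#' prevalence of exactly 0 or 1 collapses one class and destroys
#' information, so it raises an error unless `allow_degenerate = TRUE`.
#'
#' @param x A [performance_profile()] or [confusion_matrix()].
#' @param target_prevalence Prevalence of the reconstructed test set.
#' @param target_n Size of the reconstructed test set; defaults to the
#'   source N. Metric values do not depend on it (N cancels out).
#' @param allow_degenerate Permit targets 0 and 1 (one-class matrices).
#' @return A [confusion_matrix()] with the target prevalence and the source
#'   sensitivity and specificity. Cells are generally fractional.
#' @examples
#' p <- performance_profile(0.71, 0.89, 0.9, 1000)
#' calibrate_matrix(p, target_prevalence = 0.5)
#' @export
calibrate_matrix <- function(x, target_prevalence = 0.5, target_n = NULL,
                             allow_degenerate = FALSE) {
  profile <- if (is_confusion_matrix(x)) as_profile(x) else x
  stopifnot(is_performance_profile(profile))
  check_number(target_prevalence, "target_prevalence", lo = 0, hi = 1)
  if (is.null(target_n)) target_n <- profile$n
  check_number(target_n, "target_n")
  if (target_n <= 0) abort_validation("`target_n` must be > 0")
  if ((target_prevalence == 0 || target_prevalence == 1) && !allow_degenerate) {
    abort_validation(paste0(
      "target_prevalence of exactly 0 or 1 discards one class; ",
      "use allow_degenerate = TRUE if a one-class matrix is intended"))
  }
  if (is.na(profile$sen) && target_prevalence > 0) {
    abort_undefined("sensitivity is undefined; cannot calibrate to a target with positives")
  }
  if (is.na(profile$spe) && target_prevalence < 1) {
    abort_undefined("specificity is undefined; cannot calibrate to a target with negatives")
  }
  derive_matrix(performance_profile(
    sen = profile$sen, spe = profile$spe,
    pre = target_prevalence, n = target_n
  ))
}
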