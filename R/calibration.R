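#' Accuracy as a closed-form function of sensitivity, specificity, prevalence
#'
#' `acc(pre) = sen * pre + spe * (1 - pre)`: a prevalence-weighted average
#' of sensitivity and specificity, affine in prevalence with slope
#' `sen - spe` and intercept `spe`. At `pre = 0.5` it reduces to balanced
#' accuracy `(sen + spe) / 2`.
#'
#' @param sen,spe Proportions in `[0, 1]`.
#' @param pre Prevalence in `[0, 1]`; may be a vector.
#' @return Accuracy value(s), same length as `pre`.
#' @examples
#' accuracy_at(0.71, 0.89, 0.5)  # balanced accuracy 0.80
#' @export
accuracy_at <- function(sen, spe, pre) {
  check_number(sen, "sen", lo = 0, hi = 1)
  check_number(spe, "spe", lo = 0, hi = 1)
  if (!is.numeric(pre) || anyNA(pre) || any(pre < 0 | pre > 1)) {
    abort_validation("`pre` must be numeric in [0, 1]")
  }
  sen * pre + spe * (1 - pre)
}

#' MCC as a closed-form function of sensitivity, specificity, prevalence
#'
#' For interior prevalence the value is
#' `(sen + spe - 1) / sqrt((sen + (1-spe)(1-pre)/pre) * (spe + (1-sen) pre/(1-pre)))`.
#' The curve over prevalence is umbrella-shaped with two invariant anchor
#' points: for interior sensitivity and specificity the MCC is 0 at
#' prevalence 0 and 1, and those endpoints return 0 carrying attribute
#' `degenerate_point = TRUE`. When sensitivity or specificity is exactly 0
#' or 1 the endpoint limit is not defined and a
#' `prevcal_undefined_limit_error` is raised.
#'
#' @inheritParams accuracy_at
#' @return MCC value(s) in `[-1, 1]`, same length as `pre`.
#' @examples
#' mcc_at(0.68, 0.85, 0.6)   # 0.520 at 3 d.p.
#' mcc_at(0.71, 0.89, 0.9)   # 0.377 at 3 d.p.
#' @export
mcc_at <- function(sen, spe, pre) {
  check_number(sen, "sen", lo = 0, hi = 1)
  check_number(spe, "spe", lo = 0, hi = 1)
  if (!is.numeric(pre) || anyNA(pre) || any(pre < 0 | pre > 1)) {
    abort_validation("`pre` must be numeric in [0, 1]")
  }
  at_edge <- pre == 0 | pre == 1
  if (any(at_edge) && (sen %in% c(0, 1) || spe %in% c(0, 1))) {
    abort_undefined_limit(paste0(
      "MCC limit at prevalence 0/1 is not defined when sensitivity or ",
      "specificity equals exactly 0 or 1"))
  }
  out <- numeric(length(pre))
  inner <- !at_edge
  if (any(inner)) {
    p <- pre[inner]
    d1 <- sen + (1 - spe) * (1 - p) / p
    d2 <- spe + (1 - sen) * p / (1 - p)
    out[inner] <- (sen + spe - 1) / sqrt(d1 * d2)
  }
  out[at_edge] <- 0
  if (any(at_edge)) attr(out, "degenerate_point") <- TRUE
  out
}

#' Balanced Matthews correlation coefficient
#'
#' The MCC calibrated to a balanced test set (prevalence 0.5):
#' `(sen + spe - 1) / sqrt(1 - (sen - spe)^2)`. Its numerator is
#' informedness (Youden's index); when `sen == spe` the denominator is 1
#' and the balanced MCC equals the rescaled balanced accuracy
#' `sen + spe - 1`.
#'
#' When `|sen - spe| == 1` both numerator and denominator vanish (0/0);
#' the value returned is 0 with attribute `degenerate_point = TRUE`.
#'
#' @param sen,spe Proportions in `[0, 1]`.
#' @return A single number in `[-1, 1]`.
#' @examples
#' balanced_mcc(0.68, 0.85)  # 0.538 at 3 d.p.
#' balanced_mcc(0.71, 0.89)  # 0.610 at 3 d.p.
#' @export
balanced_mcc <- function(sen, spe) {
  check_number(sen, "sen", lo = 0, hi = 1, allow_na = TRUE)
  check_number(spe, "spe", lo = 0, hi = 1, allow_na = TRUE)
  if (is.na(sen) || is.na(spe)) return(NA_real_)
  if (abs(sen - spe) == 1) {
    return(structure(0, degenerate_point = TRUE))
  }
  (sen + spe - 1) / sqrt(1 - (sen - spe)^2)
}

#' Calibrate any catalogue metric to a target prevalence
#'
#' The generic calibration mechanism: reconstruct the derived confusion
#' matrix at `target_prevalence` from (sen, spe) and evaluate the metric on
#' it. The test-set size cancels out of every catalogue metric, so the
#' result depends only on (sen, spe, target_prevalence). At target 0.5
#' this produces the balanced version of the metric; notable closed forms
#' are `balanced ppv = sen / (sen + 1 - spe)`,
#' `balanced npv = spe / (spe + 1 - sen)` and
#' `balanced kappa = sen + spe - 1` (informedness).
#'
#' @param metric A catalogue identifier, see [metric_catalogue()].
#' @param sen,spe Proportions in `[0, 1]`.
#' @param target_prevalence Prevalence of the reconstructed test set;
#'   defaults to 0.5, the balanced reference calibration.
#' @param n Internal size of the reconstructed matrix; the result does not
#'   depend on it.
#' @return A single number.
#' @examples
#' calibrated_metric("mcc", 0.71, 0.89)        # 0.610: balanced MCC
#' calibrated_metric("ppv", 0.71, 0.89, 0.5)   # 0.71 / 0.82
#' @export
calibrated_metric <- function(metric, sen, spe, target_prevalence = 0.5,
                              n = 1000) {
  if (!metric %in% metric_catalogue()) {
    abort_validation(sprintf(
      "unknown metric '%s'; see metric_catalogue()", metric))
  }
  check_number(sen, "sen", lo = 0, hi = 1)
  check_number(spe, "spe", lo = 0, hi = 1)
  check_number(target_prevalence, "target_prevalence", lo = 0, hi = 1)
  if (target_prevalence == 0 || target_prevalence == 1) {
    # one class vanishes from the reconstructed matrix; endpoint behaviour
    # is an analytic limit, served by accuracy_at()/mcc_at()
    abort_undefined(sprintf(
      "metric '%s' is undefined at target prevalence %s; endpoints are limits",
      metric, format(target_prevalence)))
  }
  cm <- calibrate_matrix(
    performance_profile(sen = sen, spe = spe, pre = 0.5, n = n),
    target_prevalence = target_prevalence, target_n = n
  )
  val <- compute_metric(cm, metric)
  if (is.na(val)) {
    abort_undefined(sprintf(
      "metric '%s' is undefined at target prevalence %s",
      metric, format(target_prevalence)))
  }
  val
}

#' Sweep a metric over a prevalence grid
#'
#' Evaluates a calibrated metric on a uniform grid of prevalences at fixed
#' sensitivity and specificity, tracing how the raw metric would move if
#' only the test-set composition changed. Accuracy traces a straight line
#' with slope `sen - spe`; the MCC traces the umbrella curve that vanishes
#' toward both prevalence endpoints.
#'
#' The grid spans the open interval `[epsilon, 1 - epsilon]`: the exact
#' endpoints are analytic limits (0 for interior sen/spe in the MCC case)
#' and are not evaluated.
#'
#' @inheritParams calibrated_metric
#' @param grid_size Number of grid points (>= 3). The default 199 renders
#'   the umbrella curve smoothly.
#' @param epsilon Distance of the first/last grid point from the prevalence
#'   endpoints, in `(0, 0.5)`.
#' @return A `sweep_curve`: a data.frame with columns `prevalence` and
#'   `value` and attributes `metric`, `sen`, `spe`.
#' @examples
#' sc <- prevalence_sweep("mcc", 0.71, 0.89, grid_size = 9, epsilon = 0.1)
#' sc$value[5]  # at prevalence 0.5: the balanced MCC
#' @export
prevalence_sweep <- function(metric, sen, spe, grid_size = 199,
                             epsilon = 0.005) {
  if (!metric %in% metric_catalogue()) {
    abort_validation(sprintf(
      "unknown metric '%s'; see metric_catalogue()", metric))
  }
  check_number(sen, "sen", lo = 0, hi = 1)
  check_number(spe, "spe", lo = 0, hi = 1)
  check_number(grid_size, "grid_size", lo = 3)
  check_number(epsilon, "epsilon")
  if (epsilon <= 0 || epsilon >= 0.5) {
    abort_validation("`epsilon` must be in (0, 0.5)")
  }
  grid <- seq(epsilon, 1 - epsilon, length.out = as.integer(grid_size))
  values <- vapply(
    grid,
    function(p) calibrated_metric(metric, sen, spe, target_prevalence = p),
    numeric(1)
  )
  new_sweep_curve(grid, values, metric = metric, sen = sen, spe = spe)
}

new_sweep_curve <- function(grid, values, metric, sen, spe) {
  if (length(grid) != length(values)) {
    abort_validation("grid and values must have equal length")
  }
  if (any(diff(grid) <= 0) || any(grid <= 0 | grid >= 1)) {
    abort_validation("grid must be strictly increasing within (0, 1)")
  }
  structure(
    data.frame(prevalence = grid, value = values),
    metric = metric, sen = sen, spe = spe,
    class = c("sweep_curve", "data.frame")
  )
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf(
    "<sweep_curve> metric = %s  sen = %s  spe = %s  (%d prevalence points in [%s, %s])\n",
    attr(x, "metric"), format(attr(x, "sen")), format(attr(x, "spe")),
    nrow(x), format(min(x$prevalence)), format(max(x$prevalence))))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}
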