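#' Built-in synthetic validation scenarios
#'
#' Four synthetic use cases in which a classifier is validated against more
#' than one test set, each defined purely at the confusion-matrix level by
#' per-run performance profiles. They exercise the situations where
#' prevalence must be minded:
#'
#' * `same_prevalence` — internal (N = 2000) vs external (N = 1000)
#'   validation at identical prevalence 0.900: every metric's variation
#'   agrees with the drop in sensitivity and specificity.
#' * `shifted_prevalence` — the same model but the external set has
#'   prevalence 0.600: sensitivity and specificity still drop, yet several
#'   raw metrics (MCC, accuracy, kappa) *increase*, the misleading pattern
#'   balanced metrics correct.
#' * `ad_split` — applicability-domain filtering: the full test set
#'   (sen 0.680, spe 0.850, pre 0.600, N 2000) vs the in-domain half
#'   (sen 0.710, spe 0.890, pre 0.900, N 1000). Coverage drops to 50%, the
#'   raw MCC falls 0.520 -> 0.377 despite the model improving, while the
#'   balanced MCC rises 0.538 -> 0.610.
#' * `stream_drift` — ten temporal windows (N 500 each) with prevalence
#'   drifting linearly 0.3 -> 0.9 at fixed sen 0.75, spe 0.85: raw
#'   accuracy drifts monotonically while balanced accuracy stays constant.
#'
#' All profiles are synthetic and integer-realisable: every cell of
#' the derived confusion matrix is a whole number at the stated
#' (sen, spe, pre, n), so label-level fixtures reproduce them exactly.
#'
#' @param name One of `"same_prevalence"`, `"shifted_prevalence"`,
#'   `"ad_split"`, `"stream_drift"`.
#' @return A `validation_scenario`: list with elements `name`, `runs` (each
#'   a list with `label` and `profile`) and `expected_flags` (the report
#'   flags the scenario is constructed to trigger).
#' @examples
#' sc <- scenario("ad_split")
#' sc$runs[[1]]$profile
#' @export
scenario <- function(name) {
  defs <- list(
    same_prevalence = list(
      runs = list(
        list(label = "internal",
             profile = performance_profile(0.700, 0.950, 0.900, 2000)),
        list(label = "external",
             profile = performance_profile(0.680, 0.900, 0.900, 1000))
      ),
      expected_flags = character(0)
    ),
    shifted_prevalence = list(
      runs = list(
        list(label = "internal",
             profile = performance_profile(0.700, 0.950, 0.900, 2000)),
        list(label = "external",
             profile = performance_profile(0.680, 0.900, 0.600, 1000))
      ),
      expected_flags = c("prevalence_shift", "raw_metric_contradiction")
    ),
    ad_split = list(
      runs = list(
        list(label = "full",
             profile = performance_profile(0.680, 0.850, 0.600, 2000)),
        list(label = "in_domain",
             profile = performance_profile(0.710, 0.890, 0.900, 1000))
      ),
      expected_flags = c("prevalence_shift", "raw_metric_contradiction")
    ),
    stream_drift = list(
      runs = local({
        pre <- seq(0.3, 0.9, length.out = 10)
        lapply(seq_along(pre), function(i) {
          list(label = sprintf("window_%02d", i),
               profile = performance_profile(0.75, 0.85, pre[i], 500))
        })
      }),
      expected_flags = "prevalence_shift"
    )
  )
  if (length(name) != 1L || !name %in% names(defs)) {
    abort_validation(sprintf(
      "unknown scenario '%s'; available: %s",
      paste(name, collapse = ","), paste(names(defs), collapse = ", ")))
  }
  structure(
    c(list(name = name), defs[[name]]),
    class = "validation_scenario"
  )
}

#' @export
print.validation_scenario <- function(x, ...) {
  cat(sprintf("<validation_scenario> %s  (%d runs)\n", x$name, length(x$runs)))
  for (r in x$runs) {
    p <- r$profile
    cat(sprintf("  %-10s sen %-6s spe %-6s pre %-6s N %s\n",
                r$label, format(p$sen), format(p$spe), format(p$pre),
                format(p$n)))
  }
  if (length(x$expected_flags)) {
    cat("  expected flags:", paste(x$expected_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Integer realisation of a performance profile
#'
#' Maps the real-valued derived counts `sen*pre*n`, `(1-sen)*pre*n`,
#' `(1-spe)(1-pre)*n`, `spe*(1-pre)*n` to whole numbers by largest-remainder
#' rounding: each cell is floored and the leftover units (N is preserved
#' exactly) go to the cells with the largest fractional parts, ties broken
#' in cell order tp, fn, fp, tn. Profiles whose parameters are already
#' integer-consistent (as in all packaged scenarios) are reproduced
#' exactly.
#'
#' @param profile A [performance_profile()].
#' @return An integer-valued [confusion_matrix()] with total `profile$n`.
#' @examples
#' realise_counts(performance_profile(0.68, 0.85, 0.6, 2000))
#' @export
realise_counts <- function(profile) {
  stopifnot(is_performance_profile(profile))
  if (abs(profile$n - round(profile$n)) > 1e-8) {
    abort_validation("profile n must be a whole number to realise counts")
  }
  cm <- derive_matrix(profile)
  cells <- c(cm$tp, cm$fn, cm$fp, cm$tn)
  base <- floor(cells + 1e-9)            # guard against 815.9999999
  left <- round(profile$n) - sum(base)
  if (left > 0) {
    rem <- cells - base
    take <- order(-rem, seq_along(cells))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  confusion_matrix(base[1], base[2], base[3], base[4], strict_integer = TRUE)
}

#' Realise a profile as shuffled label pairs
#'
#' Generates `(actual, predicted)` label vectors whose tabulation via
#' [confusion_from_labels()] reproduces exactly the integer realisation of
#' the profile ([realise_counts()]). The pair order is shuffled
#' deterministically by `seed`; the caller's RNG state is left untouched.
#'
#' @param profile A [performance_profile()].
#' @param seed Integer seed for the shuffle.
#' @param labels Named character vector giving the two class labels.
#' @return A data.frame with character columns `actual` and `predicted`,
#'   `profile$n` rows.
#' @examples
#' lp <- realise_labels(performance_profile(1, 1, 0.5, 4), seed = 1)
#' confusion_from_labels(lp$actual, lp$predicted, "positive")
#' @export
realise_labels <- function(profile, seed,
                           labels = c(positive = "positive",
                                      negative = "negative")) {
  cm <- realise_counts(profile)
  pos <- labels[["positive"]]
  neg <- labels[["negative"]]
  actual <- c(rep(pos, cm$tp), rep(pos, cm$fn), rep(neg, cm$fp), rep(neg, cm$tn))
  predicted <- c(rep(pos, cm$tp), rep(neg, cm$fn), rep(pos, cm$fp), rep(neg, cm$tn))
  ord <- with_preserved_rng(seed, sample.int(length(actual)))
  data.frame(actual = actual[ord], predicted = predicted[ord],
             stringsAsFactors = FALSE)
}

#' Draw a random performance profile
#'
#' Property-test support: samples (sen, spe, pre) uniformly within the
#' given bounds and N uniformly on the integer range `n_range`.
#'
#' @param seed Integer seed; the caller's RNG state is preserved. `NULL`
#'   uses (and advances) the current RNG state.
#' @param sen_range,spe_range,pre_range Length-2 sub-intervals of `[0, 1]`.
#' @param n_range Integer range for N.
#' @return A [performance_profile()].
#' @examples
#' random_profile(seed = 42)
#' @export
random_profile <- function(seed = NULL,
                           sen_range = c(0, 1), spe_range = c(0, 1),
                           pre_range = c(0, 1), n_range = c(10, 1e6)) {
  for (nm in c("sen_range", "spe_range", "pre_range", "n_range")) {
    r <- get(nm)
    if (length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      abort_validation(sprintf("`%s` must be a valid interval", nm))
    }
  }
  draw <- function() {
    performance_profile(
      sen = stats::runif(1, sen_range[1], sen_range[2]),
      spe = stats::runif(1, spe_range[1], spe_range[2]),
      pre = stats::runif(1, pre_range[1], pre_range[2]),
      n = round(stats::runif(1, n_range[1], n_range[2]))
    )
  }
  if (is.null(seed)) draw() else with_preserved_rng(seed, draw())
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
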