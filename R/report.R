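#' Compare two validation runs under possible prevalence shift
#'
#' Computes every catalogue metric for both runs, twice: "raw" on each
#' run's own confusion matrix, and "calibrated" on the matrix reconstructed
#' at a common reference prevalence (0.5 by default, i.e. the balanced
#' metrics). Each metric's qualitative variation from the first to the
#' second run is classified as increase / decrease / constant
#' (`|delta| < tol` counts as constant, so floating noise cannot create a
#' spurious verdict).
#'
#' The verdict follows the variations of sensitivity and specificity only,
#' which are prevalence-free: `better` iff both increase, `worse` iff both
#' decrease, `trade_off` otherwise, and `undefined` when either statistic
#' is undefined in either run. Two flags are raised where raw metrics
#' become untrustworthy:
#'
#' * `prevalence_shift` — the runs' prevalences differ by more than
#'   `shift_threshold`, so raw prevalence-dependent metrics are not
#'   comparable;
#' * `raw_metric_contradiction` — some raw metric moves *against* the
#'   verdict direction (e.g. raw MCC drops although both sensitivity and
#'   specificity improved).
#'
#' With more than two runs, each later run is compared pairwise against the
#' first and a list of reports is returned.
#'
#' @param runs A list of two or more [validation_run()] objects (or a
#'   [scenario()], whose runs are materialised automatically).
#' @param target_prevalence Reference prevalence for the calibrated table.
#' @param shift_threshold Absolute prevalence difference above which
#'   `prevalence_shift` is flagged.
#' @param tol Variations smaller than this count as constant.
#' @return A `comparison_report` (or list of them): run summaries, `raw`
#'   and `calibrated` metric tables with variations, `verdict` and `flags`.
#' @examples
#' rep <- compare_runs(scenario("ad_split"))
#' rep$verdict
#' rep$flags
#' @export
compare_runs <- function(runs, target_prevalence = 0.5,
                         shift_threshold = 0.02, tol = 1e-9) {
  if (inherits(runs, "validation_scenario")) {
    runs <- lapply(runs$runs, function(r) {
      validation_run(r$label, r$profile, source = "scenario")
    })
  }
  if (!is.list(runs) || length(runs) < 2L ||
      !all(vapply(runs, inherits, logical(1), "validation_run"))) {
    abort_validation("`runs` must be a list of at least two validation_run objects")
  }
  labels <- vapply(runs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    abort_validation("run labels must be unique within a comparison")
  }
  if (length(runs) > 2L) {
    return(lapply(runs[-1], function(r) {
      compare_runs(list(runs[[1]], r), target_prevalence = target_prevalence,
                   shift_threshold = shift_threshold, tol = tol)
    }))
  }
  check_number(target_prevalence, "target_prevalence", lo = 0, hi = 1)
  check_number(shift_threshold, "shift_threshold", lo = 0)
  check_number(tol, "tol", lo = 0)

  cms <- lapply(runs, `[[`, "matrix")
  profs <- lapply(cms, as_profile)
  sen <- vapply(profs, `[[`, numeric(1), "sen")
  spe <- vapply(profs, `[[`, numeric(1), "spe")
  pre <- vapply(profs, `[[`, numeric(1), "pre")
  nn <- vapply(profs, `[[`, numeric(1), "n")

  classify <- function(a, b) {
    if (is.na(a) || is.na(b)) return("undefined")
    d <- b - a
    if (abs(d) < tol) "constant" else if (d > 0) "increase" else "decrease"
  }
  sen_var <- classify(sen[1], sen[2])
  spe_var <- classify(spe[1], spe[2])
  verdict <- if (sen_var == "undefined" || spe_var == "undefined") {
    "undefined"
  } else if (sen_var == "increase" && spe_var == "increase") {
    "better"
  } else if (sen_var == "decrease" && spe_var == "decrease") {
    "worse"
  } else {
    "trade_off"
  }

  metric_table <- function(values_1, values_2) {
    tab <- data.frame(
      metric = metric_catalogue(),
      v1 = values_1, v2 = values_2,
      stringsAsFactors = FALSE, row.names = NULL
    )
    names(tab)[2:3] <- labels
    tab$variation <- mapply(classify, values_1, values_2)
    tab
  }
  raw_vals <- vapply(cms, function(cm) {
    vapply(metric_catalogue(), function(m) compute_metric(cm, m), numeric(1))
  }, numeric(length(metric_catalogue())))
  raw <- metric_table(raw_vals[, 1], raw_vals[, 2])

  cal_one <- function(i) {
    vapply(metric_catalogue(), function(m) {
      if (is.na(sen[i]) || is.na(spe[i])) return(NA_real_)
      tryCatch(
        calibrated_metric(m, sen[i], spe[i],
                          target_prevalence = target_prevalence),
        prevcal_error = function(e) NA_real_)
    }, numeric(1))
  }
  calibrated <- metric_table(cal_one(1), cal_one(2))

  flags <- character(0)
  delta_pre <- abs(pre[2] - pre[1])
  if (delta_pre > shift_threshold) flags <- c(flags, "prevalence_shift")
  if (verdict %in% c("better", "worse")) {
    opposing <- if (verdict == "better") "decrease" else "increase"
    if (any(raw$variation == opposing)) {
      flags <- c(flags, "raw_metric_contradiction")
    }
  }

  structure(
    list(
      run_labels = labels,
      sources = vapply(runs, function(r) as.character(r$source), character(1)),
      n = nn, prevalence = pre, sen = sen, spe = spe,
      sen_variation = sen_var, spe_variation = spe_var,
      raw = raw, calibrated = calibrated,
      target_prevalence = target_prevalence,
      delta_prevalence = unname(delta_pre),
      verdict = verdict, flags = flags,
      shift_threshold = shift_threshold, tol = tol
    ),
    class = "comparison_report"
  )
}

arrow <- function(v) {
  switch(v, increase = "+", decrease = "-", constant = "=", "?")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat(sprintf("<comparison_report>  %s vs %s\n",
              x$run_labels[1], x$run_labels[2]))
  cat(sprintf("  N          %8s %8s\n", format(x$n[1]), format(x$n[2])))
  cat(sprintf("  prevalence %8s %8s\n",
              format(round(x$prevalence[1], digits)),
              format(round(x$prevalence[2], digits))))
  cat(sprintf("  sen        %8s %8s  %s\n",
              format(round(x$sen[1], digits)), format(round(x$sen[2], digits)),
              arrow(x$sen_variation)))
  cat(sprintf("  spe        %8s %8s  %s\n",
              format(round(x$spe[1], digits)), format(round(x$spe[2], digits)),
              arrow(x$spe_variation)))
  fmt_tab <- function(tab, title) {
    cat(title, "\n")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-18s %8s %8s  %s\n", tab$metric[i],
                  format(round(tab[[2]][i], digits)),
                  format(round(tab[[3]][i], digits)),
                  arrow(tab$variation[i])))
    }
  }
  fmt_tab(x$raw, "raw metrics (each run's own prevalence):")
  fmt_tab(x$calibrated,
          sprintf("calibrated metrics (prevalence %s):",
                  format(x$target_prevalence)))
  cat(sprintf("verdict: %s    flags: %s\n", x$verdict,
              if (length(x$flags)) paste(x$flags, collapse = ", ") else "none"))
  invisible(x)
}

#' Applicability-domain coverage
#'
#' The proportion of the full test set for which the model makes a
#' prediction after applicability-domain filtering.
#'
#' @param full_n Size of the unfiltered test set (> 0).
#' @param in_domain_n Number of in-domain instances, `0 <= in_domain_n <=
#'   full_n`.
#' @return `in_domain_n / full_n`, in `[0, 1]`.
#' @examples
#' coverage(2000, 1000)  # 0.5
#' @export
coverage <- function(full_n, in_domain_n) {
  check_number(full_n, "full_n")
  check_number(in_domain_n, "in_domain_n", lo = 0)
  if (full_n <= 0) abort_validation("`full_n` must be > 0")
  if (in_domain_n > full_n) {
    abort_validation("`in_domain_n` must not exceed `full_n`")
  }
  in_domain_n / full_n
}

#' Serialise and restore comparison reports as JSON
#'
#' `write_report()` produces a self-contained JSON document (runs, raw and
#' calibrated metric tables, verdict, flags, thresholds);
#' `read_report()` restores an identical `comparison_report`.
#'
#' @param report A `comparison_report` from [compare_runs()].
#' @param path JSON file.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   report.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  tab_doc <- function(tab) {
    lapply(seq_len(nrow(tab)), function(i) list(
      metric = tab$metric[i],
      values = stats::setNames(as.list(c(tab[[2]][i], tab[[3]][i])),
                               report$run_labels),
      variation = tab$variation[i]
    ))
  }
  doc <- list(
    schema = "prevcal/comparison_report/v1",
    runs = lapply(seq_along(report$run_labels), function(i) list(
      label = report$run_labels[i],
      source = report$sources[i],
      n = report$n[i],
      prevalence = report$prevalence[i],
      sen = report$sen[i],
      spe = report$spe[i]
    )),
    sen_variation = report$sen_variation,
    spe_variation = report$spe_variation,
    raw_metrics = tab_doc(report$raw),
    calibrated_metrics = tab_doc(report$calibrated),
    target_prevalence = report$target_prevalence,
    delta_prevalence = report$delta_prevalence,
    verdict = report$verdict,
    flags = as.list(report$flags),
    shift_threshold = report$shift_threshold,
    tol = report$tol
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) abort_io(sprintf(
                    "cannot parse JSON in %s: %s", path, conditionMessage(e))))
  need <- c("runs", "raw_metrics", "calibrated_metrics", "verdict", "flags",
            "sen_variation", "spe_variation", "target_prevalence",
            "delta_prevalence", "shift_threshold", "tol")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    abort_io(sprintf("report document missing field(s): %s",
                     paste(missing, collapse = ", ")))
  }
  labels <- vapply(doc$runs, `[[`, character(1), "label")
  num_field <- function(field) {
    vapply(doc$runs, function(r) {
      v <- r[[field]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  tab_from <- function(entries) {
    tab <- data.frame(
      metric = vapply(entries, `[[`, character(1), "metric"),
      v1 = vapply(entries, function(e) {
        v <- e$values[[labels[1]]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1)),
      v2 = vapply(entries, function(e) {
        v <- e$values[[labels[2]]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1)),
      variation = vapply(entries, `[[`, character(1), "variation"),
      stringsAsFactors = FALSE
    )
    names(tab)[2:3] <- labels
    tab
  }
  structure(
    list(
      run_labels = labels,
      sources = vapply(doc$runs, function(r) {
        v <- r$source
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1)),
      n = num_field("n"), prevalence = num_field("prevalence"),
      sen = num_field("sen"), spe = num_field("spe"),
      sen_variation = doc$sen_variation, spe_variation = doc$spe_variation,
      raw = tab_from(doc$raw_metrics),
      calibrated = tab_from(doc$calibrated_metrics),
      target_prevalence = as.numeric(doc$target_prevalence),
      delta_prevalence = as.numeric(doc$delta_prevalence),
      verdict = doc$verdict,
      flags = as.character(unlist(doc$flags)),
      shift_threshold = as.numeric(doc$shift_threshold),
      tol = as.numeric(doc$tol)
    ),
    class = "comparison_report"
  )
}
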