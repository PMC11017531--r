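#' Read a confusion matrix from JSON or CSV
#'
#' JSON documents are objects with numeric fields `tp`, `fn`, `fp`, `tn`
#' and an optional `metadata` object (`name`, `description`,
#' `calibrated`). CSV documents are 2x2 tables whose row and column
#' headers name the classes explicitly (`actual_positive`/`actual_negative`
#' vs `pred_positive`/`pred_negative`); either orientation is accepted and
#' resolved from the headers, never positionally, so a transposed file can
#' not be mis-read. Lines starting with `#` may carry metadata
#' (`# calibrated: true`).
#'
#' Fractional counts are accepted only when the document is marked
#' `calibrated`; raw validation matrices must be integers.
#'
#' @param path File to read.
#' @param format `"json"`, `"csv"` or `"auto"` (by file extension).
#' @return A [confusion_matrix()].
#' @seealso [write_confusion_matrix()]
#' @export
read_confusion_matrix <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") read_cm_json(path) else read_cm_csv(path)
}

read_cm_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) abort_io(sprintf(
                    "cannot parse JSON in %s: %s", path, conditionMessage(e))))
  missing <- setdiff(c("tp", "fn", "fp", "tn"), names(doc))
  if (length(missing)) {
    abort_io(sprintf("missing field(s) %s in %s",
                     paste(missing, collapse = ", "), path))
  }
  calibrated <- isTRUE(doc$metadata$calibrated)
  build_read_matrix(doc$tp, doc$fn, doc$fp, doc$tn, calibrated, path)
}

read_cm_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  calibrated <- any(grepl("^#\\s*calibrated\\s*:?\\s*true\\s*$", meta,
                          ignore.case = TRUE))
  body <- lines[!grepl("^#", lines)]
  tab <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"), row.names = 1,
                    check.names = FALSE),
    error = function(e) abort_io(sprintf(
      "cannot parse CSV in %s: %s", path, conditionMessage(e))))
  if (nrow(tab) != 2 || ncol(tab) != 2) {
    abort_io(sprintf("expected a 2x2 table with header row and column in %s", path))
  }
  rn <- trimws(rownames(tab))
  cn <- trimws(colnames(tab))
  m <- as.matrix(tab)
  if (!is.numeric(m) || anyNA(m)) abort_io(sprintf("missing or non-numeric cells in %s", path))
  if (any(m < 0)) abort_io(sprintf("negative counts in %s", path))
  rows_actual <- all(grepl("^actual_", rn)) && all(grepl("^pred_", cn))
  rows_pred <- all(grepl("^pred_", rn)) && all(grepl("^actual_", cn))
  if (!rows_actual && !rows_pred) {
    abort_io(paste0(
      "ambiguous headers: rows and columns must be labelled ",
      "actual_positive/actual_negative and pred_positive/pred_negative ",
      "(either orientation)"))
  }
  if (rows_pred) {
    m <- t(m)
    tmp <- rn; rn <- cn; cn <- tmp
  }
  need_r <- c("actual_positive", "actual_negative")
  need_c <- c("pred_positive", "pred_negative")
  if (!setequal(rn, need_r) || !setequal(cn, need_c)) {
    abort_io(sprintf(
      "headers must be exactly {%s} x {%s}",
      paste(need_r, collapse = ", "), paste(need_c, collapse = ", ")))
  }
  rownames(m) <- rn
  colnames(m) <- cn
  build_read_matrix(
    tp = m["actual_positive", "pred_positive"],
    fn = m["actual_positive", "pred_negative"],
    fp = m["actual_negative", "pred_positive"],
    tn = m["actual_negative", "pred_negative"],
    calibrated = calibrated, path = path
  )
}

build_read_matrix <- function(tp, fn, fp, tn, calibrated, path) {
  for (v in list(tp, fn, fp, tn)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      abort_io(sprintf("counts must be single numbers in %s", path))
    }
    if (v < 0) abort_io(sprintf("negative counts in %s", path))
  }
  tryCatch(
    confusion_matrix(tp, fn, fp, tn, strict_integer = !calibrated),
    prevcal_validation_error = function(e) abort_io(sprintf(
      "%s (in %s; fractional counts require '# calibrated: true' / metadata)",
      conditionMessage(e), path))
  )
}

#' Write a confusion matrix to JSON or CSV
#'
#' @param cm A [confusion_matrix()].
#' @param path Output file.
#' @param format `"json"`, `"csv"` or `"auto"` (by extension).
#' @param metadata Optional named list (`name`, `description`,
#'   `calibrated`). A matrix with fractional cells is written with
#'   `calibrated = TRUE` automatically so it round-trips.
#' @return `path`, invisibly.
#' @export
write_confusion_matrix <- function(cm, path, format = c("auto", "json", "csv"),
                                   metadata = NULL) {
  stopifnot(is_confusion_matrix(cm))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  cells <- c(cm$tp, cm$fn, cm$fp, cm$tn)
  fractional <- any(abs(cells - round(cells)) > 1e-8)
  if (fractional && !isTRUE(metadata$calibrated)) {
    metadata <- c(metadata, list(calibrated = TRUE))
  }
  if (format == "json") {
    doc <- list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn)
    if (length(metadata)) doc$metadata <- metadata
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    lines <- character(0)
    if (isTRUE(metadata$calibrated)) lines <- c(lines, "# calibrated: true")
    if (!is.null(metadata$name)) lines <- c(lines, paste0("# name: ", metadata$name))
    lines <- c(
      lines,
      ",pred_positive,pred_negative",
      sprintf("actual_positive,%s,%s", format_count(cm$tp), format_count(cm$fn)),
      sprintf("actual_negative,%s,%s", format_count(cm$fp), format_count(cm$tn))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

format_count <- function(x) {
  if (abs(x - round(x)) <= 1e-8) format(round(x), scientific = FALSE)
  else format(x, digits = 17, scientific = FALSE)
}

#' Read (actual, predicted) label pairs from a delimited file
#'
#' Requires a header with columns `actual` and `predicted`; the delimiter
#' is a tab for `.tsv` files and a comma otherwise. The file may contain at
#' most two distinct labels and must contain `positive_label`.
#'
#' @param path CSV/TSV file.
#' @param positive_label Label counted as positive.
#' @return List with character vectors `actual` and `predicted` and the
#'   tabulated `matrix` ([confusion_matrix()]).
#' @export
read_labels <- function(path, positive_label) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                      check.names = FALSE),
    error = function(e) abort_io(sprintf(
      "cannot parse %s: %s", path, conditionMessage(e))))
  missing <- setdiff(c("actual", "predicted"), names(tab))
  if (length(missing)) {
    abort_io(sprintf("missing column(s) %s in %s",
                     paste(missing, collapse = ", "), path))
  }
  cm <- tryCatch(
    confusion_from_labels(tab$actual, tab$predicted, positive_label),
    prevcal_validation_error = function(e) abort_io(sprintf(
      "%s (in %s)", conditionMessage(e), path))
  )
  list(actual = tab$actual, predicted = tab$predicted, matrix = cm)
}

#' Write and read prevalence-sweep curves as CSV
#'
#' The file carries the sweep parameters as `#` metadata lines
#' (`# metric:`, `# sen:`, `# spe:`) followed by a `prevalence,value`
#' table; reading restores an identical [prevalence_sweep()] object.
#'
#' @param curve A `sweep_curve`.
#' @param path CSV file.
#' @return `write_sweep_curve()` returns `path` invisibly;
#'   `read_sweep_curve()` returns the `sweep_curve`.
#' @export
write_sweep_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sweep_curve"))
  lines <- c(
    paste0("# metric: ", attr(curve, "metric")),
    paste0("# sen: ", format(attr(curve, "sen"), digits = 17)),
    paste0("# spe: ", format(attr(curve, "spe"), digits = 17)),
    "prevalence,value",
    sprintf("%s,%s",
            format(curve$prevalence, digits = 17, scientific = FALSE, trim = TRUE),
            format(curve$value, digits = 17, scientific = FALSE, trim = TRUE))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sweep_curve
#' @export
read_sweep_curve <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(sprintf("^#\\s*%s\\s*:", key), meta, value = TRUE)
    if (!length(hit)) abort_io(sprintf("missing '# %s:' metadata in %s", key, path))
    trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", hit[1]))
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("prevalence", "value") %in% names(tab))) {
    abort_io(sprintf("expected columns prevalence,value in %s", path))
  }
  new_sweep_curve(tab$prevalence, tab$value,
                  metric = get_meta("metric"),
                  sen = as.numeric(get_meta("sen")),
                  spe = as.numeric(get_meta("spe")))
}

#' Bundle a confusion matrix as a labelled validation run
#'
#' @param label Non-empty run label, unique within a comparison.
#' @param x A [confusion_matrix()] or [performance_profile()] (profiles are
#'   materialised via [derive_matrix()]).
#' @param source Provenance string (file path or scenario id), optional.
#' @return A `validation_run`.
#' @export
validation_run <- function(label, x, source = NA_character_) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort_validation("`label` must be a non-empty string")
  }
  cm <- if (is_performance_profile(x)) derive_matrix(x) else x
  if (!is_confusion_matrix(cm)) {
    abort_validation("`x` must be a confusion_matrix or performance_profile")
  }
  structure(list(label = label, matrix = cm, source = source),
            class = "validation_run")
}

#' @export
print.validation_run <- function(x, ...) {
  cat(sprintf("<validation_run> '%s'%s\n", x$label,
              if (!is.na(x$source)) paste0("  (", x$source, ")") else ""))
  print(x$matrix)
  invisible(x)
}

#' Export a scenario to JSON plus label CSV files
#'
#' Writes `<name>.json` describing each run's profile and integer-realised
#' counts, and one `<name>_<label>.csv` label file per run (generated with
#' [realise_labels()]). Used by the command-line `fixtures` subcommand.
#'
#' @param scn A [scenario()].
#' @param dir Output directory (created if needed).
#' @param seed Base seed for the deterministic label shuffles.
#' @return Character vector of written paths, invisibly.
#' @export
write_scenario <- function(scn, dir, seed = 1L) {
  stopifnot(inherits(scn, "validation_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  runs <- lapply(seq_along(scn$runs), function(i) {
    r <- scn$runs[[i]]
    cm <- realise_counts(r$profile)
    csv <- file.path(dir, sprintf("%s_%s.csv", scn$name, r$label))
    lp <- realise_labels(r$profile, seed = seed + i)
    utils::write.csv(lp, csv, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, csv)
    list(label = r$label,
         profile = list(sen = r$profile$sen, spe = r$profile$spe,
                        pre = r$profile$pre, n = r$profile$n),
         counts = list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn),
         labels_file = basename(csv))
  })
  json <- file.path(dir, paste0(scn$name, ".json"))
  jsonlite::write_json(
    list(name = scn$name, expected_flags = scn$expected_flags, runs = runs),
    json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(json, paths))
}
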