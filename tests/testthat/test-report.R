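test_that("the applicability-domain split reproduces the two-MCC contradiction", {
  rep <- compare_runs(scenario("ad_split"))

  expect_identical(rep$verdict, "better")
  expect_true(all(c("prevalence_shift", "raw_metric_contradiction") %in% rep$flags))

  raw_mcc <- rep$raw[rep$raw$metric == "mcc", ]
  expect_identical(raw_mcc$variation, "decrease")
  expect_equal(round(unlist(raw_mcc[, 2:3]), 3),
               c(full = 0.520, in_domain = 0.377))

  bal_mcc <- rep$raw[rep$raw$metric == "balanced_mcc", ]
  expect_identical(bal_mcc$variation, "increase")
  expect_equal(round(unlist(bal_mcc[, 2:3]), 3),
               c(full = 0.538, in_domain = 0.610))

  cal_mcc <- rep$calibrated[rep$calibrated$metric == "mcc", ]
  expect_identical(cal_mcc$variation, "increase")
  expect_equal(unlist(cal_mcc[, 2:3], use.names = FALSE),
               unlist(bal_mcc[, 2:3], use.names = FALSE), tolerance = 1e-12)
})

test_that("equal-prevalence validation raises no flags and agrees throughout", {
  rep <- compare_runs(scenario("same_prevalence"))
  expect_identical(rep$verdict, "worse")
  expect_identical(rep$flags, character(0))
  defined <- !is.na(rep$raw[[2]]) & !is.na(rep$raw[[3]])
  expect_true(all(rep$raw$variation[defined] == "decrease"))
})

test_that("a prevalence shift makes raw metrics contradict the verdict", {
  rep <- compare_runs(scenario("shifted_prevalence"))
  expect_identical(rep$verdict, "worse")
  expect_true(all(c("prevalence_shift", "raw_metric_contradiction") %in% rep$flags))
  # raw MCC, accuracy and kappa move against the (worse) verdict ...
  up <- rep$raw$metric[rep$raw$variation == "increase"]
  expect_true(all(c("mcc", "accuracy", "kappa") %in% up))
  # ... while every calibrated metric agrees with it
  expect_true(all(rep$calibrated$variation == "decrease"))
})

test_that("identical runs give constant variations, trade_off, no flags", {
  cm <- confusion_matrix(50, 10, 5, 35)
  rep <- compare_runs(list(validation_run("a", cm), validation_run("b", cm)))
  expect_true(all(rep$raw$variation == "constant"))
  expect_identical(rep$verdict, "trade_off")
  expect_identical(rep$flags, character(0))
})

test_that("runs sharing sen/spe across prevalences: balanced constant, accuracy moves", {
  set.seed(103)
  for (i in 1:50) {
    sen <- stats::runif(1, 0.05, 0.95)
    spe <- stats::runif(1, 0.05, 0.95)
    p1 <- stats::runif(1, 0.05, 0.45)
    p2 <- stats::runif(1, 0.55, 0.95)
    rep <- compare_runs(list(
      validation_run("low", performance_profile(sen, spe, p1, 1000)),
      validation_run("high", performance_profile(sen, spe, p2, 1000))
    ))
    bal <- rep$raw$variation[rep$raw$metric %in%
                               c("balanced_accuracy", "balanced_mcc",
                                 "informedness")]
    expect_true(all(bal == "constant"))
    expect_true(all(rep$calibrated$variation == "constant"))
    acc_var <- rep$raw$variation[rep$raw$metric == "accuracy"]
    if (abs(sen - spe) > 1e-6) expect_false(acc_var == "constant")
  }
})

test_that("the verdict is antisymmetric under run order", {
  scenarios <- c("ad_split", "same_prevalence", "shifted_prevalence")
  flip <- c(better = "worse", worse = "better", trade_off = "trade_off")
  for (name in scenarios) {
    runs <- lapply(scenario(name)$runs, function(r) {
      validation_run(r$label, r$profile)
    })
    fwd <- compare_runs(runs)
    rev_ <- compare_runs(rev(runs))
    expect_identical(rev_$verdict, unname(flip[fwd$verdict]))
    expect_setequal(rev_$flags, fwd$flags)
  }
})

test_that("undefined sensitivity suppresses the verdict and marks metrics", {
  no_pos <- confusion_matrix(0, 0, 10, 90)
  ok <- confusion_matrix(50, 10, 5, 35)
  rep <- compare_runs(list(validation_run("degenerate", no_pos),
                           validation_run("ok", ok)))
  expect_identical(rep$verdict, "undefined")
  expect_identical(rep$sen_variation, "undefined")
  expect_true(any(is.na(rep$raw[[2]])))
  expect_true(all(is.na(rep$calibrated[[2]])))
  # the prevalence shift is still reported, but no contradiction can be
  # diagnosed without a verdict
  expect_identical(rep$flags, "prevalence_shift")
})

test_that("more than two runs compare pairwise against the first", {
  runs <- lapply(scenario("stream_drift")$runs[1:4], function(r) {
    validation_run(r$label, r$profile)
  })
  reps <- compare_runs(runs)
  expect_length(reps, 3L)
  expect_identical(reps[[2]]$run_labels, c("window_01", "window_03"))
  expect_true(all(vapply(reps, function(r) "prevalence_shift" %in% r$flags,
                         logical(1))))
})

test_that("comparison inputs are validated", {
  cm <- confusion_matrix(5, 5, 5, 5)
  expect_error(compare_runs(list(validation_run("a", cm))),
               class = "prevcal_validation_error")
  expect_error(compare_runs(list(validation_run("a", cm),
                                 validation_run("a", cm))),
               class = "prevcal_validation_error")
  expect_error(validation_run("", cm), class = "prevcal_validation_error")
})

test_that("coverage is the in-domain fraction of the full test set", {
  expect_equal(coverage(2000, 1000), 0.5)
  expect_equal(coverage(100, 100), 1)
  expect_equal(coverage(100, 0), 0)
  expect_error(coverage(0, 0), class = "prevcal_validation_error")
  expect_error(coverage(100, 101), class = "prevcal_validation_error")
  expect_error(coverage(100, -1), class = "prevcal_validation_error")
})
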