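test_that("closed-form accuracy is affine in prevalence with slope sen - spe", {
  expect_equal(accuracy_at(0.71, 0.89, 0.5), 0.800)
  expect_equal(accuracy_at(0.71, 0.89, 0), 0.890)   # intercept = spe
  expect_equal(accuracy_at(0.71, 0.89, 1), 0.71)    # limit = sen
  expect_equal(accuracy_at(0.68, 0.85, 0.6), 0.748)

  grid <- c(0.1, 0.45, 0.8)
  vals <- accuracy_at(0.71, 0.89, grid)
  slopes <- diff(vals) / diff(grid)
  expect_equal(slopes, rep(0.71 - 0.89, 2), tolerance = 1e-12)
})

test_that("closed-form mcc matches the reference values and the anchors", {
  expect_equal(round(as.numeric(mcc_at(0.680, 0.850, 0.600)), 3), 0.520)
  expect_equal(round(as.numeric(mcc_at(0.710, 0.890, 0.900)), 3), 0.377)
  expect_equal(mcc_at(0.5, 0.5, 0.37), 0)

  # anchor points: 0 with a degenerate flag for interior sen/spe
  at0 <- mcc_at(0.7, 0.8, 0)
  expect_equal(as.numeric(at0), 0)
  expect_true(attr(at0, "degenerate_point"))
  expect_equal(as.numeric(mcc_at(0.7, 0.8, 1)), 0)

  # exempt edge cases: the limit is undefined
  expect_error(mcc_at(1, 0.8, 0), class = "prevcal_undefined_limit_error")
  expect_error(mcc_at(0.7, 0, 1), class = "prevcal_undefined_limit_error")

  # approach to the anchors
  for (eps in c(1e-3, 1e-5, 1e-7)) {
    expect_lt(abs(mcc_at(0.7, 0.8, eps)), 0.1)
    expect_lt(abs(mcc_at(0.7, 0.8, 1 - eps)), 0.1)
  }
  expect_lt(abs(mcc_at(0.7, 0.8, 1e-7)), abs(mcc_at(0.7, 0.8, 1e-3)))
})

test_that("balanced mcc closed form, its identities and degenerate case", {
  expect_equal(round(balanced_mcc(0.680, 0.850), 3), 0.538)
  expect_equal(round(balanced_mcc(0.710, 0.890), 3), 0.610)
  expect_equal(balanced_mcc(0.9, 0.9), 0.8)  # sen = spe: equals sen + spe - 1

  set.seed(61)
  for (i in 1:200) {
    sen <- stats::runif(1)
    spe <- stats::runif(1)
    # Eq-level identity with the prevalence-parameterised form at 0.5
    expect_equal(balanced_mcc(sen, spe), mcc_at(sen, spe, 0.5),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # sen = spe collapses the denominator to 1
    expect_equal(balanced_mcc(sen, sen), 2 * sen - 1, tolerance = 1e-12)
  }

  degenerate <- balanced_mcc(1, 0)
  expect_equal(as.numeric(degenerate), 0)
  expect_true(attr(degenerate, "degenerate_point"))
})

test_that("closed forms agree with count-based metrics on derived matrices", {
  set.seed(67)
  for (i in 1:2000) {
    p <- random_interior_profile()
    cm <- derive_matrix(p)
    expect_equal(accuracy_at(p$sen, p$spe, p$pre), accuracy(cm),
                 tolerance = 1e-12)
    expect_equal(as.numeric(mcc_at(p$sen, p$spe, p$pre)), mcc(cm),
                 tolerance = 1e-12)
  }
})

test_that("generic calibration is n-independent and matches closed forms", {
  expect_equal(calibrated_metric("accuracy", 0.71, 0.89, 0.5), 0.800)
  expect_equal(round(calibrated_metric("mcc", 0.71, 0.89, 0.5), 3), 0.610)
  expect_equal(round(calibrated_metric("ppv", 0.71, 0.89, 0.5), 4), 0.8659)
  expect_equal(calibrated_metric("ppv", 0.71, 0.89, 0.5), 0.71 / 0.82)

  set.seed(71)
  for (i in 1:100) {
    p <- random_interior_profile()
    target <- stats::runif(1, 0.01, 0.99)
    a <- calibrated_metric("mcc", p$sen, p$spe, target, n = 100)
    b <- calibrated_metric("mcc", p$sen, p$spe, target, n = 987654)
    expect_equal(a, b, tolerance = 1e-12)
    expect_equal(a, as.numeric(mcc_at(p$sen, p$spe, target)),
                 tolerance = 1e-12)
    expect_equal(calibrated_metric("accuracy", p$sen, p$spe, target),
                 accuracy_at(p$sen, p$spe, target), tolerance = 1e-12)
  }

  expect_error(calibrated_metric("auroc", 0.7, 0.8, 0.5),
               class = "prevcal_validation_error")
  expect_error(calibrated_metric("ppv", 0.7, 0.8, 0),
               class = "prevcal_undefined_error")
})

test_that("balanced metrics are invariant to the source prevalence", {
  set.seed(73)
  for (i in 1:100) {
    sen <- stats::runif(1, 0.05, 0.95)
    spe <- stats::runif(1, 0.05, 0.95)
    p_low <- performance_profile(sen, spe, 0.1, 4000)
    p_high <- performance_profile(sen, spe, 0.93, 700)
    for (m in c("mcc", "accuracy", "kappa", "ppv")) {
      v_low <- compute_metric(calibrate_matrix(p_low, 0.5), m)
      v_high <- compute_metric(calibrate_matrix(p_high, 0.5), m)
      expect_equal(v_low, v_high, tolerance = 1e-12)
    }
  }
})

test_that("balanced kappa, ppv and npv reduce to their sen/spe closed forms", {
  set.seed(79)
  for (i in 1:200) {
    sen <- stats::runif(1, 0.02, 0.98)
    spe <- stats::runif(1, 0.02, 0.98)
    expect_equal(calibrated_metric("kappa", sen, spe, 0.5), sen + spe - 1,
                 tolerance = 1e-12)
    expect_equal(calibrated_metric("ppv", sen, spe, 0.5),
                 sen / (sen + 1 - spe), tolerance = 1e-12)
    expect_equal(calibrated_metric("npv", sen, spe, 0.5),
                 spe / (spe + 1 - sen), tolerance = 1e-12)
    expect_equal(calibrated_metric("informedness", sen, spe, 0.5),
                 2 * calibrated_metric("balanced_accuracy", sen, spe, 0.5) - 1,
                 tolerance = 1e-12)
  }
})

test_that("sweep curves have the documented shape properties", {
  acc <- prevalence_sweep("accuracy", 0.71, 0.89, grid_size = 3,
                          epsilon = 0.01)
  expect_s3_class(acc, "sweep_curve")
  expect_equal(nrow(acc), 3)
  slopes <- diff(acc$value) / diff(acc$prevalence)
  expect_equal(slopes, rep(-0.18, 2), tolerance = 1e-9)

  m <- prevalence_sweep("mcc", 0.71, 0.89, grid_size = 9, epsilon = 0.1)
  expect_equal(m$prevalence[5], 0.5)
  expect_equal(round(m$value[5], 3), 0.610)

  flat <- prevalence_sweep("mcc", 0.5, 0.5, grid_size = 21, epsilon = 0.02)
  expect_equal(flat$value, rep(0, 21))

  # umbrella symmetry about 0.5 iff sen = spe, with the extremum at 0.5
  sym <- prevalence_sweep("mcc", 0.8, 0.8, grid_size = 41, epsilon = 0.05)
  expect_equal(sym$value, rev(sym$value), tolerance = 1e-12)
  expect_equal(which.max(sym$value), 21L)
  asym <- prevalence_sweep("mcc", 0.71, 0.89, grid_size = 41, epsilon = 0.05)
  expect_gt(max(abs(asym$value - rev(asym$value))), 1e-3)

  expect_error(prevalence_sweep("mcc", 0.7, 0.8, grid_size = 2),
               class = "prevcal_validation_error")
  expect_error(prevalence_sweep("mcc", 0.7, 0.8, epsilon = 0.6),
               class = "prevcal_validation_error")
  expect_error(prevalence_sweep("nope", 0.7, 0.8),
               class = "prevcal_validation_error")
})
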