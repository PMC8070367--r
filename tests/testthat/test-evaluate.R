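test_that("confusion matrix counts truth-by-prediction", {
  ls <- prostateLabels()
  cm <- confusionCounts(c("Bladder", "Bladder", "Rectum"),
                        c("Bladder", "Rectum", "Rectum"), ls)
  expect_equal(cm["Bladder", "Bladder"], 1)
  expect_equal(cm["Bladder", "Rectum"], 1)
  expect_equal(cm["Rectum", "Rectum"], 1)
  expect_equal(sum(cm), 3)
  expect_error(confusionCounts("Bladder", "Colon", ls), "unknown label")

  withr::with_seed(2, {
    for (i in 1:10) {
      n <- sample(5:60, 1)
      truth <- sample(classNames(ls), n, replace = TRUE)
      pred <- sample(classNames(ls), n, replace = TRUE)
      expect_equal(sum(confusionCounts(truth, pred, ls)), n)
    }
  })
})

test_that("metrics match an independent tally oracle on random matrices", {
  ls <- lungLabels()
  withr::with_seed(19, {
    for (i in 1:25) {
      n <- sample(10:80, 1)
      truth <- sample(classNames(ls), n, replace = TRUE)
      pred <- sample(classNames(ls), n, replace = TRUE)
      got <- macroMetrics(computeMetrics(confusionCounts(truth, pred, ls)))
      want <- oracleMetrics(truth, pred, classNames(ls))
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
  # perfect predictions give all-ones metrics
  truth <- rep(c("Heart", "PTV", "other"), 4)
  r <- computeMetrics(confusionCounts(truth, truth, ls))
  expect_equal(unname(macroMetrics(r)), rep(1, 4))
  # accuracy is always trace/total
  withr::with_seed(23, {
    for (i in 1:10) {
      truth <- sample(classNames(ls), 40, replace = TRUE)
      pred <- sample(classNames(ls), 40, replace = TRUE)
      cm <- confusionCounts(truth, pred, ls)
      expect_equal(computeMetrics(cm)@accuracy, sum(diag(cm)) / sum(cm))
    }
  })
})

test_that("majority baseline predicts the modal label with ordered ties", {
  ls <- prostateLabels()
  clf <- majorityLabelBaseline(c("other", "other", "other", "PTV"), ls)
  expect_identical(predict(clf, 5), rep("other", 5))
  # tie -> first label in task order
  tie <- majorityLabelBaseline(c("Femur_R", "Femur_L"), ls)
  expect_identical(tie@label, "Femur_L")
})

test_that("analytic MLB rows reproduce from majority fraction and class count", {
  # closed forms: recall 1/N, precision a/N, F1 (2a/(1+a))/N, accuracy a
  tol <- 0.005  # printed 2 d.p. agreement
  prost <- prostateLabels()
  lung <- lungLabels()

  # multi-center test split: a = 0.73 over all 8 prostate classes
  r <- mlbMetricsFromCounts(mlbCountsFor(0.73, prost, 8), prost)
  expectWithin(r@macroPrecision, 0.090, tol)
  expectWithin(r@macroRecall, 0.120, tol)
  expectWithin(r@macroF1, 0.110, tol)
  expectWithin(r@accuracy, 0.730, tol)

  # a = 0.78 over all 6 lung classes
  r <- mlbMetricsFromCounts(mlbCountsFor(0.78, lung, 6), lung)
  expectWithin(r@macroPrecision, 0.130, tol)
  expectWithin(r@macroRecall, 0.170, tol)
  expectWithin(r@macroF1, 0.150, tol)

  # external single-institution prostate test set: one bowel class absent,
  # so the union convention evaluates N = 7 labels (a = 0.80)
  counts <- c(Bladder = 50, Femur_R = 29, Femur_L = 29, Rectum = 50,
              Bowel_Small = 49, Bowel_Large = 0, other = 980, PTV = 38)
  r <- mlbMetricsFromCounts(counts[counts > 0], prost)
  expect_equal(r@nEvaluated, 7L)
  expectWithin(r@macroPrecision, 0.110, tol)
  expectWithin(r@macroRecall, 0.140, tol)
  expectWithin(r@macroF1, 0.130, tol)
  expectWithin(r@accuracy, 0.800, tol)

  # external lung test set: a = 0.81 over 6 classes
  r <- mlbMetricsFromCounts(mlbCountsFor(0.81, lung, 6), lung)
  expectWithin(r@macroPrecision, 0.140, tol)
  expectWithin(r@macroRecall, 0.170, tol)
  expectWithin(r@macroF1, 0.150, tol)
})

test_that("stratified k-fold balances classes and covers all records", {
  labels <- c(rep("other", 80), rep("PTV", 20))
  plan <- stratifiedKFold(labels, k = 5, seed = 3)
  expect_length(plan@splits, 5)
  for (sp in plan@splits) {
    expect_length(sp$validation, 20)
    expect_equal(sum(labels[sp$validation] == "other"), 16)
    expect_equal(sum(labels[sp$validation] == "PTV"), 4)
    expect_setequal(c(sp$train, sp$validation), seq_along(labels))
    expect_length(intersect(sp$train, sp$validation), 0)
  }
  expect_identical(stratifiedKFold(labels, 5, seed = 3)@splits,
                   plan@splits)
  expect_error(stratifiedKFold(labels, 1), "k must be >= 2")
  expect_error(stratifiedKFold(c("a", "b"), 5), "exceeds")

  # ragged class sizes still differ by <= 1 per fold
  withr::with_seed(6, {
    labels2 <- sample(c("A", "B", "C"), 53, replace = TRUE,
                      prob = c(0.6, 0.3, 0.1))
    plan2 <- stratifiedKFold(labels2, 5, seed = 1)
    for (cl in unique(labels2)) {
      perFold <- vapply(plan2@splits, function(sp)
        sum(labels2[sp$validation] == cl), numeric(1))
      expect_lte(diff(range(perFold)), 1)
    }
  })
})

test_that("center-wise splits never leak a center across sides", {
  centers <- rep(sprintf("VC%02d", 1:6), times = c(3, 5, 2, 4, 4, 2))
  plan <- centerCrossValidation(centers)
  expect_length(plan@splits, 6)
  covered <- sort(unname(unlist(lapply(plan@splits, `[[`, "validation"))))
  expect_identical(covered, seq_along(centers))  # each record once
  for (sp in plan@splits)
    expect_length(intersect(centers[sp$train], centers[sp$validation]), 0)
  expect_error(centerCrossValidation(rep("VC01", 5)), "at least 2")

  hold <- centerHoldout(centers, 2, seed = 4)
  sp <- hold@splits[[1]]
  expect_length(sp$testCenters, 2)
  expect_length(intersect(centers[sp$train], centers[sp$test]), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(centers))
  expect_identical(centerHoldout(centers, 2, seed = 4)@splits[[1]],
                   sp)
  expect_error(centerHoldout(centers, 6), "nTestCenters")

  # two centers -> two complementary leave-one-out splits
  two <- centerCrossValidation(c("A", "A", "B"))
  expect_identical(two@splits[[1]]$validation, two@splits[[2]]$train)
})
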