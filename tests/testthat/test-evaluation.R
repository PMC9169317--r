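# Metrics against constructed fixtures and brute-force pixel-loop oracles.

test_that("confusion counts recover a constructed 10x10 fixture exactly", {
  mask <- matrix(0, 10, 10)
  mask[1:10] <- 1              # 10 vessel pixels
  pred <- matrix(0, 10, 10)
  pred[1:8] <- 1               # 8 of them found ...
  pred[11:12] <- 1             # ... plus 2 false alarms
  cc <- confusion_counts(pred, mask)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 8L, fp = 2L, fn = 2L, tn = 88L))
  ms <- metric_suite(cc)
  expect_equal(ms$sensitivity, 0.8)
  expect_equal(ms$specificity, 88 / 90)
  expect_equal(ms$accuracy, 0.96)
})

test_that("degenerate confusion cases behave as specified", {
  m <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(confusion_counts(m, m)$fp + confusion_counts(m, m)$fn, 0L)
  inv <- confusion_counts(1 - m, m)
  expect_equal(inv$tp + inv$tn, 0L)
  expect_error(confusion_counts(matrix(0.5, 2, 2), m), "binary")

  # no positives in the mask: sensitivity is flagged undefined, not 0
  z <- matrix(0, 2, 2)
  se0 <- metric_suite(confusion_counts(z, z))$sensitivity
  expect_true(is.na(se0))
  expect_true(isTRUE(attr(se0, "undefined")))
  # tp = 0 with fn > 0 is a defined 0
  expect_equal(metric_suite(confusion_counts(z, m))$sensitivity, 0)
})

test_that("Dice and mean IoU match hand-countable fixtures", {
  m <- matrix(0, 2, 2); m[1] <- 1
  expect_equal(dice_coefficient(m, m), 1, tolerance = 1e-6)
  expect_equal(mean_iou(m, m), 1)

  # 4x4 fixture: vessel IoU = 3/5, background IoU = 11/13
  mask <- matrix(0, 4, 4); mask[1:4] <- 1
  pred <- matrix(0, 4, 4); pred[2:5] <- 1
  expect_equal(mean_iou(pred, mask), (3 / 5 + 11 / 13) / 2, tolerance = 1e-12)

  # disjoint equal-size masks: vessel IoU 0
  a <- matrix(0, 2, 2); a[1] <- 1
  b <- matrix(0, 2, 2); b[4] <- 1
  expect_equal(mean_iou(a, b), (0 + 2 / 4) / 2)

  # an absent class is excluded with a warning
  expect_warning(v <- mean_iou(matrix(0, 2, 2), matrix(0, 2, 2)), "absent")
  expect_equal(v, 1)
})

test_that("metrics agree with pixel-loop oracles on random binary pairs", {
  set.seed(404)
  for (i in 1:200) {
    pred <- matrix(rbinom(64, 1, 0.4), 8, 8)
    mask <- matrix(rbinom(64, 1, 0.3), 8, 8)
    oc <- oracle_confusion(pred, mask)
    cc <- confusion_counts(pred, mask)
    expect_identical(unclass(cc)[names(oc)], oc)
    if (sum(mask) > 0 || sum(pred) > 0)
      expect_equal(dice_coefficient(pred, mask), oracle_dice(pred, mask),
                   tolerance = 1e-9)
  }
})

test_that("AUC equals the pairwise rank oracle and is rank-invariant", {
  set.seed(17)
  mask <- matrix(rbinom(64, 1, 0.3), 8, 8)
  mask[1] <- 1; mask[2] <- 0    # both classes guaranteed
  scores <- matrix(runif(64), 8, 8)
  expect_equal(roc_auc(scores, mask), oracle_auc(scores, mask),
               tolerance = 1e-12)

  # perfectly separating scores and constant scores
  sep <- mask * 0.9 + 0.05
  expect_equal(roc_auc(sep, mask), 1)
  expect_equal(roc_auc(matrix(0.5, 8, 8), mask), 0.5)

  # invariance under a strictly monotone transform
  expect_equal(roc_auc(scores^3, mask), roc_auc(scores, mask))
  expect_equal(roc_auc(1 - exp(-5 * scores), mask), roc_auc(scores, mask))

  # independent reference implementation agrees
  ref <- as.numeric(pROC::auc(pROC::roc(as.vector(mask), as.vector(scores),
                                        quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(scores, mask), ref, tolerance = 1e-9)

  expect_warning(a <- roc_auc(scores, matrix(1, 8, 8)), "single-class")
  expect_true(is.na(a))
})

test_that("roc_curve starts at (0,0)-ish corner and ends at (1,1)", {
  set.seed(3)
  mask <- matrix(rbinom(100, 1, 0.3), 10, 10)
  sc <- matrix(runif(100), 10, 10)
  rc <- roc_curve(sc, mask)
  expect_true(all(diff(rc$tpr) >= 0))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_equal(rc$fpr[nrow(rc)], 1)
})

test_that("small-component filter removes exactly the sub-threshold islands", {
  m <- matrix(0, 120, 120)
  m[10:109, 10:109] <- 1                 # 10000-pixel component
  m[1, 1:2] <- 1                         # 2-pixel island
  filtered <- remove_small_components(m, fraction = 0.0003)
  expect_equal(sum(filtered), 10000)
  expect_equal(filtered[1, 1:2], c(0, 0))

  # idempotent
  expect_identical(remove_small_components(filtered), filtered)

  # single component and empty masks unchanged
  single <- matrix(0, 5, 5); single[2:3, 2:3] <- 1
  expect_identical(remove_small_components(single), single)
  expect_identical(remove_small_components(matrix(0, 4, 4)),
                   matrix(0, 4, 4))
})

test_that("connectivity choice separates diagonal components", {
  m <- matrix(0, 6, 6)
  # a diagonal line: one component under 8-connectivity, pixels split under 4
  for (i in 1:4) m[i, i] <- 1
  m[6, 6] <- 1
  lab8 <- dnlseg:::label_components_cpp(matrix(as.integer(m), 6, 6), 8L)
  lab4 <- dnlseg:::label_components_cpp(matrix(as.integer(m), 6, 6), 4L)
  expect_equal(max(lab8), 2L)
  expect_equal(max(lab4), 5L)
  # under 8-connectivity the isolated pixel is 1/5 = 20% of foreground: kept
  expect_identical(remove_small_components(m, fraction = 0.1), m)
  # under 4-connectivity every pixel is its own 20% component: also kept
  expect_identical(remove_small_components(m, fraction = 0.1,
                                           connectivity = 4L), m)
})

test_that("metrics_report populates every field on a synthetic pair", {
  set.seed(5)
  mask <- matrix(rbinom(256, 1, 0.2), 16, 16)
  mask[1] <- 1; mask[2] <- 0
  prob <- pmin(pmax(mask * 0.7 + runif(256) * 0.3, 0), 1)
  rep <- metrics_report(prob, mask)
  expect_named(rep, c("dice_soft", "dice", "mean_iou", "sensitivity",
                      "specificity", "accuracy", "auc"))
  for (v in rep) expect_true(is.finite(v) && v >= 0 && v <= 1)
})
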