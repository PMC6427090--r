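test_that("t-test selection agrees with stats::t.test and handles edge cases", {
  set.seed(21)
  x <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(NULL, paste0("f", 1:8)))
  x[, 1] <- c(0, 0.1, -0.1, rnorm(3, 0, 0.1), 10, 10.1, 9.9, rnorm(3, 10, 0.1))
  x[, 2] <- 7                       # identical in both groups
  y <- rep(c("control", "patient"), each = 6)
  sel <- ttestSelect(x, y, alpha = 0.05)
  # cross-check every p against the reference implementation
  ref <- apply(x[, -2], 2, function(col)
    stats::t.test(col[y == "patient"], col[y == "control"],
                  var.equal = TRUE)$p.value)
  expect_equal(unname(pValues(sel)[-2]), unname(ref), tolerance = 1e-12)
  expect_equal(unname(pValues(sel)[2]), 1)          # no-signal feature
  expect_true(selectedFeatures(sel)[[1]])
  expect_false(selectedFeatures(sel)[[2]])
  # Welch variant cross-checks too
  selw <- ttestSelect(x, y, alpha = 0.05, variant = "welch")
  refw <- stats::t.test(x[y == "patient", 1], x[y == "control", 1])$p.value
  expect_equal(unname(pValues(selw)[1]), refw, tolerance = 1e-12)
  # vacuous threshold selects everything with finite signal
  expect_true(all(selectedFeatures(ttestSelect(x[, -2], y, alpha = 1))))
  expect_error(ttestSelect(x, rep(c("control", "patient"), c(1, 11))),
               "at least 2")
})

test_that("separable data trains a perfect linear SVM; RF is seed-deterministic", {
  set.seed(31)
  x <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 6), 10, 4))
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c("control", "patient"), each = 10)
  fit <- trainClassifier(x, y, ClassifierSpec("svm"))
  pr <- predictLabels(fit, x)
  expect_equal(pr$label, y)
  expect_true(all(pr$score[y == "patient"] > pr$score[y == "control"]))
  # duplicating every subject leaves the linear SVM decision boundary alone
  fit2 <- trainClassifier(rbind(x, x), c(y, y), ClassifierSpec("svm"))
  expect_equal(predictLabels(fit2, x)$label, pr$label)
  expect_equal(predictLabels(fit2, x)$score, predictLabels(fit, x)$score,
               tolerance = 1e-6)
  # fixed seed makes random forest reproducible
  rf1 <- predictLabels(trainClassifier(x, y, ClassifierSpec("random_forest",
                                                            trees = 101L,
                                                            seed = 9L)), x)
  rf2 <- predictLabels(trainClassifier(x, y, ClassifierSpec("random_forest",
                                                            trees = 101L,
                                                            seed = 9L)), x)
  expect_identical(rf1, rf2)
  expect_error(trainClassifier(x[1:10, ], y[1:10]), "both classes")
})

test_that("metrics match confusion-matrix arithmetic and the rank AUC", {
  tbl <- data.frame(
    true_label = c(rep("patient", 4), rep("control", 4)),
    predicted_label = c("patient", "patient", "patient", "control",
                        "control", "control", "patient", "patient"),
    score = c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3, 0.6, 0.75))
  m <- computeMetrics(tbl)  # TP 3, FN 1, TN 2, FP 2
  expect_equal(unname(m["accuracy"]), 0.625)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 0.5)
  # exhaustive pairwise oracle for the AUC
  isPat <- tbl$true_label == "patient"
  pairs <- expand.grid(p = tbl$score[isPat], c = tbl$score[!isPat])
  oracleAuc <- mean((pairs$p > pairs$c) + 0.5 * (pairs$p == pairs$c))
  expect_equal(unname(m["auc"]), oracleAuc)
  # reference implementation agrees
  expect_equal(unname(m["auc"]),
               as.numeric(pROC::auc(pROC::roc(isPat, tbl$score, quiet = TRUE,
                                              direction = "<"))))
  # all ties -> 0.5; monotone transforms leave the AUC unchanged
  tied <- tbl; tied$score <- 1
  expect_equal(unname(computeMetrics(tied)["auc"]), 0.5)
  mono <- tbl; mono$score <- exp(5 * tbl$score) - 3
  expect_equal(unname(computeMetrics(mono)["auc"]), unname(m["auc"]))
  expect_error(computeMetrics(tbl[tbl$true_label == "patient", ]),
               "single class")
})

test_that("LOOCV predicts each subject once, metrics recompute, all classifiers run", {
  set.seed(41)
  x <- rbind(matrix(rnorm(60, 0), 6, 10), matrix(rnorm(60, 8), 6, 10))
  dimnames(x) <- list(paste0("s", 1:12), paste0("f", 1:10))
  y <- rep(c("control", "patient"), each = 6)
  fm <- FeatureMatrix(x, "pcc")
  for (kind in c("svm", "logistic", "random_forest")) {
    res <- loocvEvaluate(fm, y, ClassifierSpec(kind, trees = 51L))
    ps <- perSubject(res)
    expect_setequal(ps$subject_id, rownames(x))
    expect_equal(nrow(ps), 12L)
    expect_equal(unname(metrics(res)), unname(computeMetrics(ps)))
    # a cleanly separable cohort is classified perfectly
    expect_equal(unname(metrics(res)), c(1, 1, 1, 1))
  }
})

test_that("held-out subjects cannot influence their own fold's selection", {
  set.seed(51)
  x <- matrix(rnorm(16 * 30), 16, 30,
              dimnames = list(paste0("s", 1:16), paste0("f", 1:30)))
  y <- rep(c("patient", "control"), 8)
  fm <- FeatureMatrix(x, "pcc")
  r1 <- loocvEvaluate(fm, y)
  k <- 5L
  x2 <- x
  x2[k, ] <- x2[k, ] + 1e6   # arbitrary corruption of the held-out row
  r2 <- loocvEvaluate(FeatureMatrix(x2, "pcc"), y)
  expect_identical(r1@nSelectedPerFold[k], r2@nSelectedPerFold[k])
  # direct check on the selection itself
  s1 <- ttestSelect(x[-k, ], y[-k])
  s2 <- ttestSelect(x2[-k, ], y[-k])
  expect_identical(selectedFeatures(s1), selectedFeatures(s2))
})

test_that("destroying the labels drives LOOCV accuracy to chance", {
  set.seed(61)
  accs <- replicate(120, {
    x <- matrix(rnorm(12 * 15), 12, 15,
                dimnames = list(paste0("s", 1:12), paste0("f", 1:15)))
    y <- sample(rep(c("patient", "control"), each = 6))
    metrics(loocvEvaluate(FeatureMatrix(x, "pcc"), y))[["accuracy"]]
  })
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("a fold that loses a class is a named error", {
  x <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
  y <- c("patient", "patient", "control", "control", "patient")
  # removing s3 or s4 leaves one control only
  expect_error(loocvEvaluate(FeatureMatrix(x, "pcc"), y),
               "fewer than 2 subjects")
})
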