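labelFactor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("patient", "control"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  factor(labels, levels = c("control", "patient"))
}

colVars <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x * x) - n * mu * mu) / (n - 1)
}

#' Two-sample t-test feature selection
#'
#' Per-feature two-sample t test between patients and controls; features
#' with two-sided p below \code{alpha} are selected. The default is
#' Student's pooled-variance test (the two groups are assumed to share a
#' variance under the null of equal means); Welch's unequal-variance test is
#' available via \code{variant}. Features with zero variance in both groups
#' carry no usable signal-to-noise information and receive p = 1, so they
#' are never selected. No multiple-testing correction is applied by default,
#' matching the plain p < 0.05 rule; set \code{fdr = TRUE} for
#' Benjamini-Hochberg adjustment.
#'
#' @param fm a \linkS4class{FeatureMatrix} (or plain matrix, subjects in
#'   rows).
#' @param labels per-subject labels, \code{"patient"} / \code{"control"}, in
#'   row order.
#' @param alpha significance level; default 0.05.
#' @param variant \code{"student"} (pooled, default) or \code{"welch"}.
#' @param fdr apply Benjamini-Hochberg to the p-values before thresholding;
#'   default FALSE.
#' @return a \linkS4class{SelectionResult}.
#' @export
ttestSelect <- function(fm, labels, alpha = 0.05,
                        variant = c("student", "welch"), fdr = FALSE) {
  variant <- match.arg(variant)
  x <- if (is(fm, "FeatureMatrix")) fm@values else as.matrix(fm)
  y <- labelFactor(labels)
  if (length(y) != nrow(x)) stop("one label per subject row required")
  n1 <- sum(y == "patient"); n0 <- sum(y == "control")
  if (n1 < 2L || n0 < 2L)
    stop("each class needs at least 2 subjects for a t test (got ",
         n1, " patients, ", n0, " controls)")
  x1 <- x[y == "patient", , drop = FALSE]
  x0 <- x[y == "control", , drop = FALSE]
  d <- colMeans(x1) - colMeans(x0)
  v1 <- colVars(x1); v0 <- colVars(x0)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep.int(n1 + n0 - 2, length(se))
  } else {
    a1 <- v1 / n1; a0 <- v0 / n0
    se <- sqrt(a1 + a0)
    df <- (a1 + a0)^2 / (a1^2 / (n1 - 1) + a0^2 / (n0 - 1))
  }
  p <- rep.int(1, ncol(x))
  ok <- se > 0
  p[ok] <- 2 * stats::pt(-abs(d[ok] / se[ok]), df[ok])
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  names(p) <- colnames(x)
  new("SelectionResult", pValues = p, selected = p < alpha, alpha = alpha)
}

# fit one classifier on a (training) matrix; foldSeed controls stochastic fits
fitClassifier <- function(x, y, spec, foldSeed = spec@seed) {
  stopifnot(nlevels(droplevels(y)) == 2L)
  fit <- switch(spec@kind,
    svm = e1071::svm(x, y,
                     kernel = if (spec@kernel == "rbf") "radial" else "linear",
                     cost = spec@cost, scale = apply(x, 2L, stats::sd) > 0),
    logistic = {
      xm <- cbind(`(Intercept)` = 1, x)
      suppressWarnings(
        stats::glm.fit(xm, as.integer(y == "patient"),
                       family = stats::binomial()))
    },
    random_forest = {
      set.seed(foldSeed)
      randomForest::randomForest(x, y, ntree = spec@trees)
    })
  structure(list(model = fit, kind = spec@kind,
                 features = colnames(x)), class = "msfcFit")
}

# score new rows: higher score = more patient-like; returns label + score
scoreClassifier <- function(fit, newx) {
  newx <- newx[, fit$features, drop = FALSE]
  if (fit$kind == "svm") {
    pr <- predict(fit$model, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    pair <- strsplit(colnames(dv)[[1L]], "/", fixed = TRUE)[[1L]]
    score <- if (pair[[1L]] == "patient") dv[, 1L] else -dv[, 1L]
    data.frame(label = as.character(pr), score = as.numeric(score),
               stringsAsFactors = FALSE)
  } else if (fit$kind == "logistic") {
    cf <- fit$model$coefficients
    cf[is.na(cf)] <- 0          # aliased columns contribute nothing
    lp <- as.numeric(cbind(1, newx) %*% cf)
    data.frame(label = ifelse(lp > 0, "patient", "control"), score = lp,
               stringsAsFactors = FALSE)
  } else {
    pr <- predict(fit$model, newx, type = "prob")
    score <- pr[, "patient"]
    data.frame(label = ifelse(score > 0.5, "patient", "control"),
               score = as.numeric(score), stringsAsFactors = FALSE)
  }
}

#' Train a classifier on a feature matrix
#'
#' Fits the classifier named by \code{spec} and returns a fitted decision
#' function. The SVM is trained by the standard soft-margin max-margin
#' solver (\pkg{e1071}/libsvm); logistic regression by iteratively
#' reweighted least squares; random forest by \pkg{randomForest} under
#' \code{spec@seed}. The returned object scores new subjects with
#' \code{\link{predictLabels}}; higher scores are more patient-like.
#'
#' @param fm a \linkS4class{FeatureMatrix} or matrix (subjects x features).
#' @param labels per-subject labels in row order.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @return an object of class \code{msfcFit}.
#' @export
trainClassifier <- function(fm, labels, spec = ClassifierSpec()) {
  x <- if (is(fm, "FeatureMatrix")) fm@values else as.matrix(fm)
  y <- labelFactor(labels)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  if (any(!is.finite(x))) stop("non-finite feature values")
  fitClassifier(x, y, spec)
}

#' Predict labels and decision scores for new subjects
#'
#' @param fit an \code{msfcFit} from \code{\link{trainClassifier}}.
#' @param fm a \linkS4class{FeatureMatrix} or matrix of new subjects; must
#'   contain the features the classifier was trained on.
#' @return data.frame with columns \code{label} and \code{score} (higher =
#'   more patient-like).
#' @export
predictLabels <- function(fit, fm) {
  stopifnot(inherits(fit, "msfcFit"))
  x <- if (is(fm, "FeatureMatrix")) fm@values else as.matrix(fm)
  scoreClassifier(fit, x)
}

#' Evaluation metrics from a per-subject prediction table
#'
#' Accuracy, sensitivity (true-positive rate among patients; patient is the
#' positive class), specificity (true-negative rate among controls) and AUC.
#' AUC is the rank-statistic form: the probability that a randomly chosen
#' patient's decision score exceeds a randomly chosen control's, with ties
#' counted one half — so it is invariant under any strictly monotone
#' transform of the scores.
#'
#' @param perSubject data.frame with columns \code{true_label},
#'   \code{predicted_label}, \code{score}.
#' @return named numeric vector \code{(accuracy, sensitivity, specificity,
#'   auc)}.
#' @export
computeMetrics <- function(perSubject) {
  truth <- as.character(perSubject$true_label)
  pred <- as.character(perSubject$predicted_label)
  if (!nrow(perSubject)) stop("empty prediction table")
  isPat <- truth == "patient"
  if (all(isPat) || !any(isPat))
    stop("sensitivity/specificity undefined: table contains a single class")
  r <- rank(perSubject$score)
  np <- sum(isPat); nc <- sum(!isPat)
  auc <- (sum(r[isPat]) - np * (np + 1) / 2) / (np * nc)
  c(accuracy = mean(pred == truth),
    sensitivity = mean(pred[isPat] == "patient"),
    specificity = mean(pred[!isPat] == "control"),
    auc = auc)
}

#' Leave-one-out cross-validated evaluation
#'
#' The full evaluation protocol: each subject in turn is held out, t-test
#' feature selection is run on the remaining subjects only (when
#' \code{selectWithinFold}, the default — the held-out subject never
#' influences its own fold's selection), the classifier is trained on the
#' selected columns, and the held-out subject is scored. The pooled
#' per-subject predictions yield accuracy, sensitivity, specificity and the
#' rank-based AUC. With \code{selectWithinFold = FALSE} selection is done
#' once on the full cohort (the leakage-prone variant, available for
#' comparison).
#'
#' A fold in which no feature clears \code{alpha} falls back to the single
#' smallest-p feature so the classifier always has an input.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param labels per-subject labels in row order, or a
#'   \linkS4class{CohortManifest} (matched by subject ID).
#' @param spec a \linkS4class{ClassifierSpec}; default linear SVM, C = 1.
#' @param alpha selection significance level; default 0.05.
#' @param selectWithinFold run selection inside each training fold (default
#'   TRUE).
#' @param variant t-test variant, \code{"student"} or \code{"welch"}.
#' @return an \linkS4class{EvalResult}.
#' @export
loocvEvaluate <- function(fm, labels, spec = ClassifierSpec(), alpha = 0.05,
                          selectWithinFold = TRUE,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is(fm, "FeatureMatrix"))
  x <- fm@values
  ids <- rownames(x)
  if (is(labels, "CohortManifest")) {
    lab <- subjectLabels(labels)
    missing <- setdiff(ids, names(lab))
    if (length(missing))
      stop("manifest lacks subject(s): ", paste(missing, collapse = ", "))
    labels <- unname(lab[ids])
  }
  y <- labelFactor(labels)
  n <- nrow(x)
  if (length(y) != n) stop("one label per subject required")
  if (n < 4L) stop("LOOCV needs a cohort of at least 4 subjects")
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  globalSel <- if (!selectWithinFold)
    ttestSelect(x, y, alpha = alpha, variant = variant) else NULL
  pickCols <- function(sel) {
    cols <- which(sel@selected)
    if (!length(cols)) cols <- which.min(sel@pValues)
    cols
  }
  perSubject <- data.frame(subject_id = ids, true_label = as.character(y),
                           predicted_label = NA_character_,
                           score = NA_real_, stringsAsFactors = FALSE)
  nSel <- integer(n)
  for (k in seq_len(n)) {
    ytr <- y[-k]
    if (min(table(ytr)) < 2L)
      stop("training fold for subject '", ids[[k]],
           "' leaves a class with fewer than 2 subjects")
    sel <- if (selectWithinFold)
      ttestSelect(x[-k, , drop = FALSE], ytr, alpha = alpha, variant = variant)
    else globalSel
    cols <- pickCols(sel)
    nSel[[k]] <- sum(sel@selected)
    fit <- fitClassifier(x[-k, cols, drop = FALSE], ytr, spec,
                         foldSeed = spec@seed + k)
    sc <- scoreClassifier(fit, x[k, cols, drop = FALSE])
    perSubject$predicted_label[[k]] <- sc$label[[1L]]
    perSubject$score[[k]] <- sc$score[[1L]]
  }
  m <- computeMetrics(perSubject)
  new("EvalResult", perSubject = perSubject, accuracy = unname(m[["accuracy"]]),
      sensitivity = unname(m[["sensitivity"]]),
      specificity = unname(m[["specificity"]]), auc = unname(m[["auc"]]),
      nSelectedPerFold = nSel)
}
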