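#' Accessors for mscalefc classes
#'
#' Slot accessors: prefer these over direct \code{@} access.
#'
#' @param x an object of the matching class.
#' @name accessors
NULL

#' @rdname accessors
setMethod("subjectID", "RoiTimeSeries", function(x) x@subjectID)
#' @rdname accessors
setMethod("subjectID", "BinaryActivity", function(x) x@subjectID)
#' @rdname accessors
setMethod("subjectID", "CoactivationTensor", function(x) x@subjectID)
#' @rdname accessors
setMethod("subjectID", "ProbabilityTensor", function(x) x@subjectID)

#' @rdname accessors
setMethod("regionLabels", "RoiTimeSeries", function(x) x@regionLabels)

#' @rdname accessors
setMethod("nRegions", "RoiTimeSeries", function(x) ncol(x@values))
#' @rdname accessors
setMethod("nRegions", "BinaryActivity", function(x) ncol(x@states))
#' @rdname accessors
setMethod("nRegions", "CoactivationTensor", function(x) dim(x@counts)[1L])

#' @rdname accessors
setMethod("nTimepoints", "RoiTimeSeries", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nTimepoints", "BinaryActivity", function(x) nrow(x@states))

#' @rdname accessors
setMethod("tsValues", "RoiTimeSeries", function(x) x@values)

#' @rdname accessors
setMethod("states", "BinaryActivity", function(x) x@states)
#' @rdname accessors
setMethod("thresholds", "BinaryActivity", function(x) x@thresholds)

#' @rdname accessors
setMethod("intervals", "LagIntervalSet", function(x) x@intervals)
#' @rdname accessors
setMethod("intervals", "CoactivationTensor", function(x) x@intervals@intervals)
#' @rdname accessors
setMethod("intervals", "ProbabilityTensor", function(x) x@intervals@intervals)

#' @rdname accessors
setMethod("counts", "CoactivationTensor", function(x) x@counts)
#' @rdname accessors
setMethod("probs", "ProbabilityTensor", function(x) x@probs)
#' @rdname accessors
setMethod("isDegenerate", "ProbabilityTensor", function(x) x@degenerate)

#' @rdname accessors
setMethod("manifestEntries", "CohortManifest", function(x) x@entries)
#' @rdname accessors
setMethod("subjectIDs", "CohortManifest", function(x) x@entries$subject_id)
#' @rdname accessors
setMethod("subjectLabels", "CohortManifest", function(x) {
  structure(x@entries$label, names = x@entries$subject_id)
})

#' @rdname accessors
setMethod("subjectIDs", "FeatureMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("featureNames", "FeatureMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("featureKind", "FeatureMatrix", function(x) x@featureKind)
#' @rdname accessors
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname accessors
setMethod("pValues", "SelectionResult", function(x) x@pValues)
#' @rdname accessors
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' @rdname accessors
setMethod("perSubject", "EvalResult", function(x) x@perSubject)
#' @rdname accessors
setMethod("metrics", "EvalResult", function(x) {
  c(accuracy = x@accuracy, sensitivity = x@sensitivity,
    specificity = x@specificity, auc = x@auc)
})

#' @rdname accessors
setMethod("cohortSubjects", "SyntheticCohort", function(x) x@subjects)
#' @rdname accessors
setMethod("cohortManifest", "SyntheticCohort", function(x) x@manifest)

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s': %d time points x %d regions\n",
              object@subjectID, nrow(object@values), ncol(object@values)))
})

setMethod("show", "BinaryActivity", function(object) {
  cat(sprintf("BinaryActivity '%s': %d x %d, %.1f%% active\n",
              object@subjectID, nrow(object@states), ncol(object@states),
              100 * mean(object@states)))
})

setMethod("show", "LagIntervalSet", function(object) {
  iv <- object@intervals
  cat("LagIntervalSet:",
      paste(sprintf("[%d,%d]", iv[, 1L], iv[, 2L]), collapse = " "), "\n")
})

setMethod("show", "CoactivationTensor", function(object) {
  d <- dim(object@counts)
  cat(sprintf("CoactivationTensor '%s': %d x %d regions x %d intervals, total %d\n",
              object@subjectID, d[1L], d[2L], d[3L], sum(object@counts)))
})

setMethod("show", "ProbabilityTensor", function(object) {
  d <- dim(object@probs)
  cat(sprintf("ProbabilityTensor '%s': %d x %d x %d%s\n", object@subjectID,
              d[1L], d[2L], d[3L],
              if (object@degenerate) " (degenerate: no co-activations)" else ""))
})

setMethod("show", "CohortManifest", function(object) {
  tab <- table(object@entries$label)
  cat(sprintf("CohortManifest: %d subjects (%s)\n", nrow(object@entries),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d subjects x %d features\n",
              object@featureKind, nrow(object@values), ncol(object@values)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d / %d features selected at alpha = %g\n",
              sum(object@selected), length(object@selected), object@alpha))
})

setMethod("show", "ClassifierSpec", function(object) {
  cat(sprintf("ClassifierSpec: %s (C = %g, kernel = %s, trees = %d, seed = %d)\n",
              object@kind, object@cost, object@kernel, object@trees,
              object@seed))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf(paste0("EvalResult (%d subjects, LOOCV)\n",
                     "  accuracy %.4f  sensitivity %.4f  specificity %.4f  auc %.4f\n"),
              nrow(object@perSubject), object@accuracy, object@sensitivity,
              object@specificity, object@auc))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d patients + %d controls, %d regions x %d",
                     " time points\n  eventRate %.3g, amplitude %.3g, noiseAR %.3g,",
                     " %d couplings, seed %d\n"),
              object@nPatients, object@nControls, object@nRegions,
              object@nTimepoints, object@eventRate, object@amplitude,
              object@noiseAR, nrow(object@couplings), object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects, %d regions x %d time points\n",
              length(object@subjects), object@truth@nRegions,
              object@truth@nTimepoints))
})
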