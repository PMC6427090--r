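#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname accessors
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))

#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname accessors
#' @export
setGeneric("manifestEntries", function(x) standardGeneric("manifestEntries"))

#' @rdname accessors
#' @export
setGeneric("subjectIDs", function(x) standardGeneric("subjectIDs"))

#' @rdname accessors
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("perSubject", function(x) standardGeneric("perSubject"))

#' @rdname accessors
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname accessors
#' @export
setGeneric("cohortSubjects", function(x) standardGeneric("cohortSubjects"))

#' @rdname accessors
#' @export
setGeneric("cohortManifest", function(x) standardGeneric("cohortManifest"))

#' Binarize a time series with the per-region dynamic threshold
#'
#' @param x a \linkS4class{RoiTimeSeries} or numeric matrix (time x regions).
#' @param eta threshold multiplier; default 1.
#' @return a \linkS4class{BinaryActivity}.
#' @export
setGeneric("binarize", function(x, eta = 1) standardGeneric("binarize"))

#' Extract a feature matrix from a cohort
#'
#' @param x a \linkS4class{SyntheticCohort}, \linkS4class{CohortManifest} or
#'   list of \linkS4class{RoiTimeSeries}.
#' @param kind feature kind: \code{"multiscale_fc"}, \code{"pcc"} or
#'   \code{"combined"}.
#' @param ... passed on to the feature extractors (\code{eta},
#'   \code{intervals}, \code{excludeDiagonal}).
#' @return a \linkS4class{FeatureMatrix}.
#' @export
setGeneric("extractFeatures",
  function(x, kind = "multiscale_fc", ...) standardGeneric("extractFeatures"))
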