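#' @import methods
NULL

#' Per-subject ROI time-series matrix
#'
#' Holds one subject's multivariate BOLD series: a numeric matrix with
#' \code{M} rows (time points) and \code{N} columns (regions of interest),
#' plus unique region labels. Values are in arbitrary BOLD units; the
#' downstream dynamic threshold is scale- and shift-equivariant so no
#' standardization is imposed here.
#'
#' @slot subjectID single subject identifier.
#' @slot values numeric matrix, time points in rows, regions in columns.
#' @slot regionLabels character vector of length \code{ncol(values)}.
#' @export
setClass("RoiTimeSeries",
  representation(subjectID = "character", values = "matrix",
                 regionLabels = "character"))

setValidity("RoiTimeSeries", function(object) {
  v <- object@values
  if (length(object@subjectID) != 1L) return("subjectID must be a single string")
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) < 2L) return("need at least 2 time points (M >= 2)")
  if (ncol(v) < 2L) return("need at least 2 regions (N >= 2)")
  if (any(!is.finite(v))) return("values contain missing or non-finite entries")
  if (length(object@regionLabels) != ncol(v))
    return("regionLabels length must equal the number of regions")
  if (anyDuplicated(object@regionLabels)) return("regionLabels must be unique")
  TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param values numeric matrix, M time points x N regions.
#' @param subjectID subject identifier.
#' @param regionLabels optional region labels; defaults to column names or
#'   \code{ROI_1 ... ROI_N}.
#' @return a \linkS4class{RoiTimeSeries}.
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(40), 10, 4), subjectID = "s1")
#' nRegions(ts)
#' @export
RoiTimeSeries <- function(values, subjectID = "subject", regionLabels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(regionLabels)) {
    regionLabels <- colnames(values)
    if (is.null(regionLabels)) regionLabels <- paste0("ROI_", seq_len(ncol(values)))
  }
  colnames(values) <- regionLabels
  new("RoiTimeSeries", subjectID = as.character(subjectID), values = values,
      regionLabels = as.character(regionLabels))
}

#' Binarized activity states for one subject
#'
#' 0/1 matrix marking supra-threshold ("active") time points per region,
#' together with the per-region dynamic thresholds that produced it.
#'
#' @slot states 0/1 integer matrix, same shape as the source series.
#' @slot thresholds numeric vector of per-region thresholds (BOLD units).
#' @slot subjectID source subject identifier.
#' @export
setClass("BinaryActivity",
  representation(states = "matrix", thresholds = "numeric",
                 subjectID = "character"))

setValidity("BinaryActivity", function(object) {
  s <- object@states
  if (!all(s %in% c(0L, 1L))) return("states must be 0/1")
  if (length(object@thresholds) != ncol(s))
    return("one threshold per region required")
  if (any(!is.finite(object@thresholds))) return("thresholds must be finite")
  TRUE
})

#' A closed lag interval set
#'
#' An ordered collection of closed integer lag intervals \code{[lo, hi]}
#' (0 <= lo <= hi) over which co-activations are accumulated. The default
#' set used throughout the package is
#' \code{[0,0], [1,1], [2,2], [3,12]}: synchronous, two short asynchronous
#' lags, and one loose long-range interval.
#'
#' @slot intervals integer matrix with columns \code{lo}, \code{hi}, one row
#'   per interval.
#' @export
setClass("LagIntervalSet", representation(intervals = "matrix"))

setValidity("LagIntervalSet", function(object) {
  iv <- object@intervals
  if (nrow(iv) < 1L) return("interval set must be non-empty")
  if (ncol(iv) != 2L) return("intervals must have lo and hi columns")
  if (any(iv < 0L)) return("lags must be non-negative")
  if (any(iv[, 1L] > iv[, 2L])) return("each interval needs lo <= hi")
  if (anyDuplicated(iv)) return("duplicate intervals are forbidden")
  TRUE
})

#' Construct a LagIntervalSet
#'
#' @param intervals a list of length-2 integer vectors \code{c(lo, hi)}, or an
#'   integer matrix with two columns.
#' @return a \linkS4class{LagIntervalSet}.
#' @examples
#' LagIntervalSet(list(c(0, 0), c(1, 1), c(2, 2), c(3, 12)))
#' @export
LagIntervalSet <- function(intervals) {
  if (is.list(intervals)) {
    stopifnot(all(lengths(intervals) == 2L))
    intervals <- do.call(rbind, lapply(intervals, as.integer))
  }
  intervals <- as.matrix(intervals)
  storage.mode(intervals) <- "integer"
  colnames(intervals) <- c("lo", "hi")
  rownames(intervals) <- NULL
  new("LagIntervalSet", intervals = intervals)
}

#' Default lag interval set
#'
#' @return the four-interval default \code{[0,0],[1,1],[2,2],[3,12]}.
#' @export
defaultIntervals <- function() {
  LagIntervalSet(list(c(0L, 0L), c(1L, 1L), c(2L, 2L), c(3L, 12L)))
}

#' Lag-interval co-activation tensor
#'
#' Non-negative integer counts \code{counts[i, j, t]} of time points at which
#' region \code{i} is active and region \code{j} is active \code{l} steps
#' later, accumulated over all lags \code{l} in interval \code{t}. The tensor
#' is directional: \code{counts[i, j, t]} and \code{counts[j, i, t]} differ
#' in general for lagged intervals.
#'
#' @slot counts numeric (integer-valued) array, N x N x T.
#' @slot intervals the \linkS4class{LagIntervalSet} used.
#' @slot subjectID source subject identifier.
#' @export
setClass("CoactivationTensor",
  representation(counts = "array", intervals = "LagIntervalSet",
                 subjectID = "character"))

setValidity("CoactivationTensor", function(object) {
  cts <- object@counts
  if (length(dim(cts)) != 3L) return("counts must be a 3-order array")
  if (dim(cts)[1L] != dim(cts)[2L]) return("first two dimensions must match")
  if (dim(cts)[3L] != nrow(object@intervals@intervals))
    return("third dimension must equal the number of intervals")
  if (any(cts < 0)) return("counts must be non-negative")
  TRUE
})

#' Normalized co-activation probability tensor
#'
#' The co-activation tensor divided by its grand total so that all entries
#' sum to one: a discrete probability distribution over ordered region pairs
#' and lag intervals. If the subject had no co-activations at all the tensor
#' is degenerate: flagged, all zeros.
#'
#' @slot probs numeric array, N x N x T, entries in [0, 1].
#' @slot intervals the \linkS4class{LagIntervalSet} used.
#' @slot subjectID source subject identifier.
#' @slot degenerate TRUE when the source counts were all zero.
#' @export
setClass("ProbabilityTensor",
  representation(probs = "array", intervals = "LagIntervalSet",
                 subjectID = "character", degenerate = "logical"))

setValidity("ProbabilityTensor", function(object) {
  p <- object@probs
  if (any(p < 0)) return("probabilities must be non-negative")
  if (object@degenerate) {
    if (any(p != 0)) return("degenerate tensor must be all zeros")
  } else if (abs(sum(p) - 1) > 1e-9) {
    return("probabilities must sum to 1 within 1e-9")
  }
  TRUE
})

#' Cohort manifest
#'
#' Maps subject identifiers to a diagnostic label (\code{patient} or
#' \code{control}) and, optionally, to the file holding that subject's ROI
#' series. The patient class is the positive class for sensitivity.
#'
#' @slot entries data.frame with columns \code{subject_id}, \code{label},
#'   \code{path} (path may be NA for in-memory cohorts).
#' @export
setClass("CohortManifest", representation(entries = "data.frame"))

setValidity("CohortManifest", function(object) {
  e <- object@entries
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(e))) return("entries need subject_id, label, path")
  if (anyDuplicated(e$subject_id))
    return(paste0("duplicate subject_id: ",
                  paste(unique(e$subject_id[duplicated(e$subject_id)]),
                        collapse = ", ")))
  if (!all(e$label %in% c("patient", "control")))
    return("labels must be 'patient' or 'control'")
  TRUE
})

#' Construct a CohortManifest
#'
#' @param subjectIDs character vector of unique subject identifiers.
#' @param labels character vector, \code{"patient"} or \code{"control"}.
#' @param paths optional file paths (NA for in-memory subjects).
#' @return a \linkS4class{CohortManifest}.
#' @export
CohortManifest <- function(subjectIDs, labels, paths = NA_character_) {
  new("CohortManifest", entries = data.frame(
    subject_id = as.character(subjectIDs),
    label = as.character(labels),
    path = rep_len(as.character(paths), length(subjectIDs)),
    stringsAsFactors = FALSE))
}

#' Subjects-by-features matrix
#'
#' Rows are subjects, columns are named features of one kind:
#' \code{multiscale_fc} (vectorized probability tensor, N*N*T entries),
#' \code{pcc} (upper-triangle Pearson correlations, N(N-1)/2 entries) or
#' \code{combined} (their concatenation).
#'
#' @slot values numeric matrix with subject IDs as rownames and feature names
#'   as colnames.
#' @slot featureKind one of \code{multiscale_fc}, \code{pcc}, \code{combined}.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", featureKind = "character"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v))) return("rownames (subject IDs) required")
  if (ncol(v) > 0L && is.null(colnames(v))) return("colnames (feature names) required")
  if (any(!is.finite(v))) return("feature values must be finite")
  if (!object@featureKind %in% c("multiscale_fc", "pcc", "combined"))
    return("featureKind must be multiscale_fc, pcc or combined")
  TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix, subjects x features; rownames = subject IDs,
#'   colnames = feature names.
#' @param featureKind feature kind string.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(values, featureKind) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("FeatureMatrix", values = values, featureKind = featureKind)
}

#' Feature-selection result
#'
#' Per-feature two-sided p-values from a two-sample t test and the selection
#' mask \code{p < alpha}.
#'
#' @slot pValues numeric vector in [0, 1], named by feature.
#' @slot selected logical mask, same length.
#' @slot alpha the significance level used.
#' @export
setClass("SelectionResult",
  representation(pValues = "numeric", selected = "logical", alpha = "numeric"))

setValidity("SelectionResult", function(object) {
  if (length(object@pValues) != length(object@selected))
    return("pValues and selected must have equal length")
  if (!isTRUE(all.equal(object@selected, object@pValues < object@alpha,
                        check.attributes = FALSE)))
    return("selected must equal pValues < alpha")
  TRUE
})

#' Classifier specification
#'
#' @slot kind one of \code{svm}, \code{logistic}, \code{random_forest}.
#' @slot cost SVM regularization parameter C (> 0).
#' @slot kernel SVM kernel, \code{linear} or \code{rbf}.
#' @slot trees number of random-forest trees.
#' @slot seed integer seed controlling stochastic classifiers.
#' @export
setClass("ClassifierSpec",
  representation(kind = "character", cost = "numeric", kernel = "character",
                 trees = "integer", seed = "integer"))

setValidity("ClassifierSpec", function(object) {
  if (!object@kind %in% c("svm", "logistic", "random_forest"))
    return("kind must be svm, logistic or random_forest")
  if (object@cost <= 0) return("C must be positive")
  if (!object@kernel %in% c("linear", "rbf")) return("kernel must be linear or rbf")
  if (object@trees < 1L) return("trees must be >= 1")
  TRUE
})

#' Construct a ClassifierSpec
#'
#' @param kind classifier kind: \code{"svm"} (default), \code{"logistic"} or
#'   \code{"random_forest"}.
#' @param C SVM soft-margin cost; default 1.
#' @param kernel SVM kernel; \code{"linear"} (default) or \code{"rbf"}.
#' @param trees random-forest tree count; default 500.
#' @param seed seed for stochastic classifiers; default 1.
#' @return a \linkS4class{ClassifierSpec}.
#' @export
ClassifierSpec <- function(kind = "svm", C = 1, kernel = "linear",
                           trees = 500L, seed = 1L) {
  new("ClassifierSpec", kind = kind, cost = as.numeric(C), kernel = kernel,
      trees = as.integer(trees), seed = as.integer(seed))
}

#' Leave-one-out evaluation result
#'
#' One prediction per subject plus the four summary metrics, all recomputable
#' from the per-subject table.
#'
#' @slot perSubject data.frame with columns \code{subject_id},
#'   \code{true_label}, \code{predicted_label}, \code{score} (higher = more
#'   patient-like).
#' @slot accuracy,sensitivity,specificity,auc summary metrics in [0, 1].
#' @slot nSelectedPerFold integer vector of selected-feature counts per fold.
#' @export
setClass("EvalResult",
  representation(perSubject = "data.frame", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 auc = "numeric", nSelectedPerFold = "integer"))

#' Synthetic cohort specification
#'
#' Generative ground truth for a BOLD-like cohort: per-region AR(1) Gaussian
#' baseline noise (unit innovation SD), spontaneous activation events that
#' add \code{amplitude}, and directed, lag-specific, probabilistic couplings
#' that can differ between the patient and control groups. Defaults describe
#' the package's reference simulation: a 60-subject cohort (31 patients + 29
#' controls) of 20 regions x 150 time points whose groups differ only in five
#' patient-only lagged couplings (lags 1-3, strength 0.8) with activation
#' amplitude 5 noise-SD units.
#'
#' @slot nPatients,nControls group sizes.
#' @slot nRegions,nTimepoints series dimensions.
#' @slot eventRate per-region per-timepoint spontaneous activation probability.
#' @slot amplitude activation bump height in noise-SD units.
#' @slot noiseAR AR(1) coefficient of the baseline noise, in [0, 1).
#' @slot couplings data.frame with columns \code{src}, \code{dst}, \code{lag},
#'   \code{strength}, \code{group} (\code{patient}, \code{control} or
#'   \code{both}).
#' @slot seed master seed; per-subject child seeds are derived from it.
#' @export
setClass("SyntheticSpec",
  representation(nPatients = "integer", nControls = "integer",
                 nRegions = "integer", nTimepoints = "integer",
                 eventRate = "numeric", amplitude = "numeric",
                 noiseAR = "numeric", couplings = "data.frame",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@nPatients < 0L || object@nControls < 0L)
    return("group sizes must be non-negative")
  if (object@nRegions < 2L) return("need at least 2 regions")
  if (object@nTimepoints < 10L) return("need at least 10 time points")
  if (object@eventRate <= 0 || object@eventRate >= 1)
    return("eventRate must be in (0, 1)")
  if (object@amplitude <= 0) return("amplitude must be positive")
  if (object@noiseAR < 0 || object@noiseAR >= 1)
    return("noiseAR must be in [0, 1)")
  cp <- object@couplings
  if (nrow(cp) > 0L) {
    need <- c("src", "dst", "lag", "strength", "group")
    if (!all(need %in% names(cp)))
      return("couplings need src, dst, lag, strength, group")
    if (any(cp$src < 1L | cp$src > object@nRegions |
            cp$dst < 1L | cp$dst > object@nRegions))
      return("coupling regions must exist")
    if (any(cp$lag < 0L)) return("coupling lags must be non-negative")
    if (any(cp$lag >= object@nTimepoints))
      return("coupling lag must be smaller than nTimepoints")
    if (any(cp$strength < 0 | cp$strength > 1))
      return("coupling strength must be in [0, 1]")
    if (!all(cp$group %in% c("patient", "control", "both")))
      return("coupling group must be patient, control or both")
  }
  TRUE
})

#' Default patient-only lagged couplings
#'
#' Five directed couplings at lags 1-3 with strength 0.8, present in the
#' patient group only, over the first ten regions. With these, the two groups
#' differ only in lagged (asynchronous) structure.
#'
#' @param strength coupling strength in [0, 1]; default 0.8.
#' @return a couplings data.frame for \code{\link{SyntheticSpec}}.
#' @export
defaultCouplings <- function(strength = 0.8) {
  data.frame(src = c(1L, 3L, 5L, 7L, 9L),
             dst = c(2L, 4L, 6L, 8L, 10L),
             lag = c(1L, 2L, 3L, 1L, 2L),
             strength = strength,
             group = "patient",
             stringsAsFactors = FALSE)
}

#' Construct a SyntheticSpec
#'
#' @param nPatients,nControls group sizes; defaults 31 and 29 (a 60-subject
#'   cohort at the scale of a typical single-site clinical study).
#' @param nRegions,nTimepoints series dimensions; defaults 20 and 150.
#' @param eventRate spontaneous activation probability; default 0.08.
#' @param amplitude activation height in noise-SD units; default 5.
#' @param noiseAR AR(1) coefficient of baseline noise; default 0.3.
#' @param couplings coupling table; default \code{\link{defaultCouplings}()}.
#' @param seed master seed; default 1.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
SyntheticSpec <- function(nPatients = 31L, nControls = 29L, nRegions = 20L,
                          nTimepoints = 150L, eventRate = 0.08, amplitude = 5,
                          noiseAR = 0.3, couplings = defaultCouplings(),
                          seed = 1L) {
  new("SyntheticSpec", nPatients = as.integer(nPatients),
      nControls = as.integer(nControls), nRegions = as.integer(nRegions),
      nTimepoints = as.integer(nTimepoints), eventRate = eventRate,
      amplitude = amplitude, noiseAR = noiseAR,
      couplings = as.data.frame(couplings), seed = as.integer(seed))
}

#' Synthetic cohort
#'
#' @slot subjects list of \linkS4class{RoiTimeSeries}, one per subject.
#' @slot manifest the matching \linkS4class{CohortManifest}.
#' @slot truth the \linkS4class{SyntheticSpec} that generated the cohort.
#' @export
setClass("SyntheticCohort",
  representation(subjects = "list", manifest = "CohortManifest",
                 truth = "SyntheticSpec"))

setValidity("SyntheticCohort", function(object) {
  n <- object@truth@nPatients + object@truth@nControls
  if (length(object@subjects) != n)
    return("subject count must equal nPatients + nControls")
  if (nrow(object@manifest@entries) != n)
    return("manifest must cover every subject")
  TRUE
})
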