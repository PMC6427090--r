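#' Multi-scale functional connectivity feature vector
#'
#' Composes the full extraction for one subject: dynamic-threshold
#' binarization, lag-interval co-activation tensor, normalization to a
#' probability distribution, and flattening to a named feature vector of
#' length N*N*T (source region outermost, target region next, interval
#' innermost). Feature names encode \code{src|dst|lo-hi}. With the default
#' AAL-116 atlas and four intervals this yields 53,824 features.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param eta threshold multiplier; default 1.
#' @param intervalSet a \linkS4class{LagIntervalSet}; default
#'   \code{\link{defaultIntervals}()}.
#' @param excludeDiagonal drop the i = j cells from the distribution and the
#'   feature vector (normalization is then over off-diagonal cells only);
#'   default FALSE, i.e. the diagonal is kept.
#' @return a named numeric feature vector; all zeros (with a warning) for a
#'   degenerate subject with no co-activations.
#' @export
multiscaleFCVector <- function(ts, eta = 1, intervalSet = defaultIntervals(),
                               excludeDiagonal = FALSE) {
  stopifnot(is(ts, "RoiTimeSeries"))
  ct <- coactivationTensor(binarize(ts, eta = eta), intervalSet)
  cts <- ct@counts
  n <- dim(cts)[1L]; nt <- dim(cts)[3L]
  keepCell <- if (excludeDiagonal) {
    k <- array(TRUE, dim(cts))
    for (i in seq_len(n)) k[i, i, ] <- FALSE
    k
  } else array(TRUE, dim(cts))
  total <- sum(cts[keepCell])
  if (total == 0) {
    warning("degenerate subject '", ts@subjectID,
            "': no co-activations, features all zero")
    probs <- cts * 0
  } else {
    probs <- cts / total
  }
  lab <- ts@regionLabels
  ivn <- dimnames(cts)[[3L]]
  nm <- paste(rep(lab, each = n * nt),
              rep(rep(lab, each = nt), n),
              rep(ivn, n * n), sep = "|")
  flat <- as.vector(aperm(probs, c(3L, 2L, 1L)))   # interval fastest, then j, then i
  names(flat) <- nm
  if (excludeDiagonal) {
    keepFlat <- as.vector(aperm(keepCell, c(3L, 2L, 1L)))
    flat <- flat[keepFlat]
  }
  flat
}

#' Pearson correlation baseline feature vector
#'
#' The classic synchronous functional-connectivity features: the Pearson
#' correlation of every unordered region pair, in i < j order with i
#' outermost, giving N(N-1)/2 features (6,670 for a 116-region atlas).
#' Synchronous by construction — lagged structure is invisible to it.
#'
#' @param ts a \linkS4class{RoiTimeSeries}; every region must have nonzero
#'   variance.
#' @return named numeric vector of correlations in [-1, 1], names
#'   \code{src|dst}.
#' @export
pccVector <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  v <- ts@values
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s), correlation undefined: ",
         paste(ts@regionLabels[sds == 0], collapse = ", "))
  cm <- stats::cor(v)
  n <- ncol(v)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]  # i outer, j inner
  out <- cm[idx]
  names(out) <- paste(ts@regionLabels[idx[, 1L]], ts@regionLabels[idx[, 2L]],
                      sep = "|")
  out
}

#' Concatenate two feature matrices column-wise
#'
#' Both matrices must cover the same subjects in the same order and have
#' disjoint feature names. The result has kind \code{combined} (unless one
#' side is empty, in which case the other is returned unchanged).
#'
#' @param a,b \linkS4class{FeatureMatrix} objects.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
combineFeatures <- function(a, b) {
  stopifnot(is(a, "FeatureMatrix"), is(b, "FeatureMatrix"))
  if (!identical(rownames(a@values), rownames(b@values)))
    stop("feature matrices cover different subjects (or a different order)")
  if (ncol(b@values) == 0L) return(a)
  if (ncol(a@values) == 0L) return(b)
  if (length(intersect(colnames(a@values), colnames(b@values))))
    stop("feature names must be disjoint")
  FeatureMatrix(cbind(a@values, b@values), featureKind = "combined")
}

extractFromList <- function(tsList, kind, eta = 1,
                            intervalSet = defaultIntervals(),
                            excludeDiagonal = FALSE) {
  kind <- match.arg(kind, c("multiscale_fc", "pcc", "combined"))
  one <- function(ts, k) {
    switch(k,
           multiscale_fc = multiscaleFCVector(ts, eta = eta,
                                              intervalSet = intervalSet,
                                              excludeDiagonal = excludeDiagonal),
           pcc = pccVector(ts))
  }
  build <- function(k) {
    rows <- lapply(tsList, one, k = k)
    nm <- names(rows[[1L]])
    bad <- which(vapply(rows, function(r) !identical(names(r), nm), TRUE))
    if (length(bad))
      stop("subject '", tsList[[bad[[1L]]]]@subjectID,
           "' yields a different feature set (region labels must match ",
           "across the cohort)")
    m <- do.call(rbind, rows)
    rownames(m) <- vapply(tsList, subjectID, "")
    FeatureMatrix(m, featureKind = k)
  }
  if (kind == "combined")
    combineFeatures(build("multiscale_fc"), build("pcc"))
  else build(kind)
}

#' @describeIn extractFeatures extract from an in-memory synthetic cohort.
setMethod("extractFeatures", "SyntheticCohort",
  function(x, kind = "multiscale_fc", ...) {
    extractFromList(x@subjects, kind, ...)
  })

#' @describeIn extractFeatures extract from a list of
#'   \linkS4class{RoiTimeSeries}.
setMethod("extractFeatures", "list",
  function(x, kind = "multiscale_fc", ...) {
    stopifnot(all(vapply(x, is, TRUE, "RoiTimeSeries")))
    extractFromList(x, kind, ...)
  })

#' @describeIn extractFeatures read every subject file named in a manifest,
#'   then extract. Unreadable subjects abort with a per-subject error summary.
setMethod("extractFeatures", "CohortManifest",
  function(x, kind = "multiscale_fc", ...) {
    e <- x@entries
    loaded <- vector("list", nrow(e))
    errs <- character(0)
    for (i in seq_len(nrow(e))) {
      res <- tryCatch(readSubjectTimeSeries(e$path[[i]],
                                            subjectID = e$subject_id[[i]]),
                      error = function(c) c)
      if (inherits(res, "error")) {
        errs <- c(errs, paste0(e$subject_id[[i]], ": ", conditionMessage(res)))
      } else loaded[[i]] <- res
    }
    if (length(errs))
      stop("failed to read ", length(errs), " subject(s):\n  ",
           paste(errs, collapse = "\n  "))
    extractFromList(loaded, kind, ...)
  })
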