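#' Per-region dynamic activation threshold
#'
#' The three-sigma rule applied to one region's series: threshold
#' \eqn{\mu + \eta\,\sigma} where \eqn{\mu} is the arithmetic mean and
#' \eqn{\sigma} the sample standard deviation (divisor \eqn{M - 1}). Time
#' points at or above the threshold are considered "active"; \code{eta}
#' tunes how selective the activity definition is (default 1).
#'
#' @param series numeric vector of at least 2 finite values.
#' @param eta threshold multiplier, finite and >= 0 in normal use.
#' @return the threshold, in the same units as \code{series}.
#' @examples
#' dynamicThreshold(c(0, 0, 0, 10))   # 2.5 + 1 * 5 = 7.5
#' @export
dynamicThreshold <- function(series, eta = 1) {
  if (length(series) < 2L)
    stop("dynamic threshold needs at least 2 time points (sd undefined)")
  if (any(!is.finite(series))) stop("series contains non-finite values")
  if (!is.finite(eta)) stop("eta must be finite")
  mean(series) + eta * stats::sd(series)
}

#' @describeIn binarize method for \linkS4class{RoiTimeSeries}: each region is
#'   thresholded independently at \eqn{\mu_i + \eta\,\sigma_i}; equality maps
#'   to active (state 1). Binarization is invariant under any positive affine
#'   rescaling of the input.
setMethod("binarize", "RoiTimeSeries", function(x, eta = 1) {
  th <- apply(x@values, 2L, dynamicThreshold, eta = eta)
  st <- 0L + (x@values >= rep(th, each = nrow(x@values)))
  colnames(st) <- x@regionLabels
  new("BinaryActivity", states = st, thresholds = unname(th),
      subjectID = x@subjectID)
})

#' @describeIn binarize method for a plain numeric matrix (time x regions).
setMethod("binarize", "matrix", function(x, eta = 1) {
  binarize(RoiTimeSeries(x), eta = eta)
})
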