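#' Lagged co-activation count for one region pair
#'
#' Counts, over all time points m and all lags l in the closed interval,
#' the events "region i active at m AND region j active at m + l". Terms
#' with m + l beyond the series end are skipped (boundary truncation: no
#' padding, so no fabricated co-activations). A positive lag means region
#' j's activity follows region i's, so the count is directional:
#' \code{coactivationCount(a, b, iv)} and \code{coactivationCount(b, a, iv)}
#' differ in general for lagged intervals.
#'
#' @param binI,binJ 0/1 vectors of equal length (source and target region).
#' @param interval length-2 integer vector \code{c(lo, hi)}, 0 <= lo <= hi.
#' @return a non-negative integer count.
#' @examples
#' coactivationCount(c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 1))  # 2
#' coactivationCount(c(0, 1, 0, 1), c(1, 0, 1, 0), c(1, 1))  # 1
#' @export
coactivationCount <- function(binI, binJ, interval) {
  if (length(binI) != length(binJ))
    stop("co-activation requires series of equal length")
  lo <- as.integer(interval[[1L]]); hi <- as.integer(interval[[2L]])
  if (lo < 0L || hi < lo) stop("interval must satisfy 0 <= lo <= hi")
  m <- length(binI)
  total <- 0L
  for (l in lo:hi) {
    if (l >= m) break
    total <- total + sum(binI[seq_len(m - l)] * binJ[seq_len(m - l) + l])
  }
  as.integer(total)
}

#' Co-activation tensor over all ordered region pairs
#'
#' For every ordered pair (i, j) — the diagonal i = j included — and every
#' lag interval t, accumulates the lagged co-activation count into the
#' 3-order tensor \code{counts[i, j, t]}. Implemented with one cross-product
#' per lag, which equals the exhaustive double loop over (m, l).
#'
#' @param bam a \linkS4class{BinaryActivity}.
#' @param intervalSet a \linkS4class{LagIntervalSet}; default
#'   \code{\link{defaultIntervals}()}.
#' @return a \linkS4class{CoactivationTensor}.
#' @export
coactivationTensor <- function(bam, intervalSet = defaultIntervals()) {
  stopifnot(is(bam, "BinaryActivity"), is(intervalSet, "LagIntervalSet"))
  b <- bam@states
  storage.mode(b) <- "double"
  m <- nrow(b); n <- ncol(b)
  if (n < 2L) stop("co-activation tensor needs at least 2 regions")
  iv <- intervalSet@intervals
  nt <- nrow(iv)
  # one N x N cross-product per lag, cached so overlapping intervals reuse it
  lagCounts <- new.env(parent = emptyenv())
  lagMatrix <- function(l) {
    key <- as.character(l)
    got <- lagCounts[[key]]
    if (!is.null(got)) return(got)
    val <- if (l >= m) matrix(0, n, n)
           else crossprod(b[seq_len(m - l), , drop = FALSE],
                          b[seq_len(m - l) + l, , drop = FALSE])
    lagCounts[[key]] <- val
    val
  }
  cts <- array(0, dim = c(n, n, nt),
               dimnames = list(colnames(b), colnames(b),
                               sprintf("%d-%d", iv[, 1L], iv[, 2L])))
  for (t in seq_len(nt)) {
    acc <- matrix(0, n, n)
    for (l in iv[t, 1L]:iv[t, 2L]) acc <- acc + lagMatrix(l)
    cts[, , t] <- acc
  }
  new("CoactivationTensor", counts = cts, intervals = intervalSet,
      subjectID = bam@subjectID)
}

#' Normalize a co-activation tensor to a probability distribution
#'
#' Divides every cell by the grand total over all (i, j, t), yielding the
#' proportion of all observed co-activations falling on each ordered region
#' pair and lag interval. An all-zero tensor (a subject with no
#' co-activations) is flagged degenerate and left at zero rather than
#' failing the run.
#'
#' @param ct a \linkS4class{CoactivationTensor}.
#' @return a \linkS4class{ProbabilityTensor}.
#' @export
normalizeTensor <- function(ct) {
  stopifnot(is(ct, "CoactivationTensor"))
  total <- sum(ct@counts)
  if (total == 0) {
    p <- ct@counts * 0
    return(new("ProbabilityTensor", probs = p, intervals = ct@intervals,
               subjectID = ct@subjectID, degenerate = TRUE))
  }
  new("ProbabilityTensor", probs = ct@counts / total, intervals = ct@intervals,
      subjectID = ct@subjectID, degenerate = FALSE)
}
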