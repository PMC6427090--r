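# simulate one subject; returns values plus the event bookkeeping used by
# tests (spontaneous events and coupling-induced activations)
simulateSubject <- function(spec, label, seed) {
  m <- spec@nTimepoints; n <- spec@nRegions
  set.seed(seed)
  # fixed draw order and fixed draw COUNT regardless of outcomes, so a
  # subject's series depends only on (spec, label, seed)
  innov <- matrix(stats::rnorm(m * n), m, n)
  eventU <- matrix(stats::runif(m * n), m, n)
  cp <- spec@couplings
  flipU <- if (nrow(cp)) matrix(stats::runif(m * nrow(cp)), m, nrow(cp))
           else matrix(0, m, 0L)
  noise <- if (spec@noiseAR > 0)
    apply(innov, 2L, function(z) as.numeric(stats::filter(z, spec@noiseAR,
                                                          method = "recursive")))
  else innov
  events <- eventU < spec@eventRate
  induced <- matrix(FALSE, m, n)
  if (nrow(cp)) {
    for (ci in seq_len(nrow(cp))) {
      if (!(cp$group[[ci]] %in% c("both", label))) next
      src <- cp$src[[ci]]; dst <- cp$dst[[ci]]; lag <- cp$lag[[ci]]
      hit <- which(events[, src] & flipU[, ci] < cp$strength[[ci]])
      hit <- hit[hit + lag <= m]
      induced[hit + lag, dst] <- TRUE
    }
  }
  values <- noise + spec@amplitude * events + spec@amplitude * induced
  list(values = values, events = events, induced = induced)
}

#' Generate one synthetic subject
#'
#' Baseline AR(1) Gaussian noise per region (unit innovation SD), spontaneous
#' activation events (probability \code{eventRate} per region per time point,
#' each adding \code{amplitude}), and — for every coupling whose group
#' matches \code{label} — an induced activation of the target region
#' \code{lag} steps after each source event, with probability
#' \code{strength} (skipped when the lagged time point falls past the end of
#' the series). Deterministic given \code{seed}.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param label \code{"patient"} or \code{"control"}.
#' @param seed integer seed for this subject.
#' @param subjectID subject identifier.
#' @return a \linkS4class{RoiTimeSeries}.
#' @export
generateSubject <- function(spec, label = "control", seed = 1L,
                            subjectID = "subject") {
  stopifnot(is(spec, "SyntheticSpec"), label %in% c("patient", "control"))
  validObject(spec)
  sim <- simulateSubject(spec, label, as.integer(seed))
  RoiTimeSeries(sim$values, subjectID = subjectID,
                regionLabels = paste0("ROI_", seq_len(spec@nRegions)))
}

#' Generate a full synthetic cohort
#'
#' Draws \code{nPatients + nControls} independent subjects. Each subject uses
#' a child seed drawn from the master \code{spec@seed}, so cohorts are
#' reproducible (same spec, same cohort, byte for byte) while subjects stay
#' independent and exchangeable.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return a \linkS4class{SyntheticCohort}; patients are named
#'   \code{P_1 ...}, controls \code{C_1 ...}.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  nTot <- spec@nPatients + spec@nControls
  if (nTot < 1L) stop("cohort must contain at least one subject")
  set.seed(spec@seed)
  childSeeds <- sample.int(.Machine$integer.max - 1L, nTot)
  ids <- c(if (spec@nPatients) paste0("P_", seq_len(spec@nPatients)),
           if (spec@nControls) paste0("C_", seq_len(spec@nControls)))
  labels <- rep(c("patient", "control"), c(spec@nPatients, spec@nControls))
  subjects <- vector("list", nTot)
  for (k in seq_len(nTot))
    subjects[[k]] <- generateSubject(spec, labels[[k]], childSeeds[[k]],
                                     subjectID = ids[[k]])
  new("SyntheticCohort", subjects = subjects,
      manifest = CohortManifest(ids, labels), truth = spec)
}

#' Write a synthetic cohort to disk
#'
#' One TSV per subject plus a \code{manifest.csv} with relative paths, in the
#' interchange formats the readers of this package consume.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  e <- cohort@manifest@entries
  files <- paste0(e$subject_id, ".tsv")
  for (k in seq_along(cohort@subjects))
    writeSubjectTimeSeries(cohort@subjects[[k]], file.path(dir, files[[k]]))
  mf <- CohortManifest(e$subject_id, e$label, files)
  writeManifest(mf, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}
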