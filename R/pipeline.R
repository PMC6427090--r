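# fetch a nested config key ("a.b.c"); required keys raise a schema error
cfgGet <- function(config, key, default = NULL, required = FALSE) {
  node <- config
  for (part in strsplit(key, ".", fixed = TRUE)[[1L]]) {
    if (!is.list(node) || is.null(node[[part]])) {
      if (required) stop("config key missing: '", key, "'")
      return(default)
    }
    node <- node[[part]]
  }
  node
}

#' Read a pipeline configuration file
#'
#' YAML with sections \code{io} (manifest, features_out, report_out),
#' \code{features} (kind, eta, intervals, exclude_diagonal),
#' \code{selection} (alpha, within_fold, variant), \code{classifier} (kind,
#' C, kernel, trees), \code{simulate} (generator parameters) and a top-level
#' \code{seed}. All sections have defaults except the paths a given command
#' needs.
#'
#' @param path YAML file.
#' @return the configuration as a nested list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

cfgIntervals <- function(config) {
  iv <- cfgGet(config, "features.intervals")
  if (is.null(iv)) return(defaultIntervals())
  if (is.matrix(iv)) iv <- lapply(seq_len(nrow(iv)), function(i) iv[i, ])
  LagIntervalSet(iv)
}

cfgClassifierSpec <- function(config) {
  ClassifierSpec(kind = cfgGet(config, "classifier.kind", "svm"),
                 C = cfgGet(config, "classifier.C", 1),
                 kernel = cfgGet(config, "classifier.kernel", "linear"),
                 trees = cfgGet(config, "classifier.trees", 500L),
                 seed = cfgGet(config, "seed", 1L))
}

cfgProvenance <- function(config) {
  # full resolved config + versions: enough to reproduce the report exactly
  list(config = config,
       seed = cfgGet(config, "seed", 1L),
       package = "mscalefc",
       package_version = as.character(utils::packageVersion("mscalefc")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

#' Simulate a synthetic cohort from a config
#'
#' Builds a \linkS4class{SyntheticSpec} from the \code{simulate} section
#' (unset fields use the generator defaults), generates the cohort, and
#' writes per-subject TSVs plus \code{manifest.csv} to
#' \code{simulate.out_dir}.
#'
#' @param config configuration list (see \code{\link{readPipelineConfig}}).
#' @return the written manifest path, invisibly.
#' @export
runSimulate <- function(config) {
  outDir <- cfgGet(config, "simulate.out_dir", required = TRUE)
  cp <- cfgGet(config, "simulate.couplings")
  spec <- SyntheticSpec(
    nPatients = cfgGet(config, "simulate.n_patients", 31L),
    nControls = cfgGet(config, "simulate.n_controls", 29L),
    nRegions = cfgGet(config, "simulate.n_regions", 20L),
    nTimepoints = cfgGet(config, "simulate.n_timepoints", 150L),
    eventRate = cfgGet(config, "simulate.event_rate", 0.08),
    amplitude = cfgGet(config, "simulate.amplitude", 5),
    noiseAR = cfgGet(config, "simulate.noise_ar", 0.3),
    couplings = if (is.null(cp)) defaultCouplings()
                else do.call(rbind, lapply(cp, as.data.frame)),
    seed = cfgGet(config, "seed", 1L))
  cohort <- generateCohort(spec)
  message("simulated ", length(cohort@subjects), " subjects -> ", outDir)
  writeCohort(cohort, outDir)
}

#' Extract a feature matrix for every subject in a manifest
#'
#' Reads the manifest and each subject file, extracts features of the
#' configured kind and writes the feature matrix to
#' \code{io.features_out}. The run log (stderr) records eta, the interval
#' set, the dimensions, and any degenerate-subject warnings.
#'
#' @param config configuration list.
#' @return the \linkS4class{FeatureMatrix}, invisibly.
#' @export
runExtract <- function(config) {
  manifestPath <- cfgGet(config, "io.manifest", required = TRUE)
  outPath <- cfgGet(config, "io.features_out", required = TRUE)
  kind <- cfgGet(config, "features.kind", "multiscale_fc")
  eta <- cfgGet(config, "features.eta", 1)
  ivs <- cfgIntervals(config)
  manifest <- readManifest(manifestPath)
  message("extracting '", kind, "' features: eta = ", eta, ", intervals ",
          paste(sprintf("[%d,%d]", ivs@intervals[, 1L], ivs@intervals[, 2L]),
                collapse = " "))
  fm <- withCallingHandlers(
    extractFeatures(manifest, kind = kind, eta = eta, intervalSet = ivs,
                    excludeDiagonal = cfgGet(config,
                                             "features.exclude_diagonal",
                                             FALSE)),
    warning = function(w) { message("warning: ", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  message("feature matrix: ", nrow(fm@values), " subjects x ",
          ncol(fm@values), " features -> ", outPath)
  writeFeatureMatrix(fm, outPath)
  invisible(fm)
}

#' Evaluate a feature matrix under LOOCV and write the report
#'
#' Aligns the stored feature matrix with the manifest, runs
#' \code{\link{loocvEvaluate}} with the configured selection and classifier
#' settings, and writes the JSON report (metrics, per-fold selection counts,
#' per-subject predictions, provenance) to \code{io.report_out}.
#'
#' @param config configuration list.
#' @return the \linkS4class{EvalResult}, invisibly.
#' @export
runEvaluate <- function(config) {
  manifest <- readManifest(cfgGet(config, "io.manifest", required = TRUE))
  fm <- readFeatureMatrix(cfgGet(config, "io.features_out", required = TRUE))
  reportPath <- cfgGet(config, "io.report_out", required = TRUE)
  res <- loocvEvaluate(fm, manifest, spec = cfgClassifierSpec(config),
                       alpha = cfgGet(config, "selection.alpha", 0.05),
                       selectWithinFold = cfgGet(config, "selection.within_fold",
                                                 TRUE),
                       variant = cfgGet(config, "selection.variant", "student"))
  message(sprintf("LOOCV: accuracy %.4f, sensitivity %.4f, specificity %.4f, auc %.4f",
                  res@accuracy, res@sensitivity, res@specificity, res@auc))
  writeEvalReport(res, reportPath, provenance = cfgProvenance(config))
  invisible(res)
}

#' Compare feature kinds on one cohort
#'
#' Runs extraction and LOOCV evaluation for the \code{pcc},
#' \code{multiscale_fc} and \code{combined} feature kinds on the same
#' cohort, and writes a comparison table (rows = feature kinds, columns =
#' accuracy, sensitivity, specificity, AUC) plus provenance to
#' \code{io.report_out}.
#'
#' @param config configuration list.
#' @param kinds feature kinds to compare.
#' @return the comparison data.frame, invisibly.
#' @export
runAll <- function(config, kinds = c("pcc", "multiscale_fc", "combined")) {
  manifest <- readManifest(cfgGet(config, "io.manifest", required = TRUE))
  reportPath <- cfgGet(config, "io.report_out", required = TRUE)
  eta <- cfgGet(config, "features.eta", 1)
  ivs <- cfgIntervals(config)
  spec <- cfgClassifierSpec(config)
  rows <- lapply(kinds, function(kind) {
    fm <- extractFeatures(manifest, kind = kind, eta = eta, intervalSet = ivs,
                          excludeDiagonal = cfgGet(config,
                                                   "features.exclude_diagonal",
                                                   FALSE))
    res <- loocvEvaluate(fm, manifest, spec = spec,
                         alpha = cfgGet(config, "selection.alpha", 0.05),
                         selectWithinFold = cfgGet(config,
                                                   "selection.within_fold", TRUE),
                         variant = cfgGet(config, "selection.variant", "student"))
    message(sprintf("%-13s accuracy %.4f  auc %.4f", kind, res@accuracy,
                    res@auc))
    data.frame(feature_kind = kind, accuracy = res@accuracy,
               sensitivity = res@sensitivity, specificity = res@specificity,
               auc = res@auc, stringsAsFactors = FALSE)
  })
  cmp <- do.call(rbind, rows)
  jsonlite::write_json(list(comparison = cmp,
                            provenance = cfgProvenance(config)),
                       reportPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(cmp)
}
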