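#' Read one subject's ROI time-series table
#'
#' Reads a plain delimited text table with time points in rows and regions in
#' columns (the orientation produced by averaging BOLD voxels per atlas
#' region). An optional single header row provides region labels; without it
#' labels are auto-generated \code{ROI_1 ... ROI_N}. Tab, comma and
#' whitespace delimiters are auto-detected; pass \code{delimiter} to force
#' one.
#'
#' @param path file to read.
#' @param delimiter optional field delimiter (\code{"\t"}, \code{","}) or
#'   \code{NULL} (default) to auto-detect; any run of blanks also splits when
#'   auto-detecting.
#' @param subjectID subject identifier; defaults to the file name without
#'   extension.
#' @return a \linkS4class{RoiTimeSeries}.
#' @export
readSubjectTimeSeries <- function(path, delimiter = NULL, subjectID = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subjectID))
    subjectID <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("need at least 2 time points in ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", lines[[1L]])) "\t"
                 else if (grepl(",", lines[[1L]])) ","
                 else "[ ]+"
  } else if (delimiter == " ") delimiter <- "[ ]+"
  fields <- strsplit(trimws(lines), delimiter)
  widths <- lengths(fields)
  if (any(widths != widths[[1L]])) {
    bad <- which(widths != widths[[1L]])[[1L]]
    stop(sprintf("ragged table in %s: line %d has %d fields, expected %d",
                 path, bad, widths[[bad]], widths[[1L]]))
  }
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  hasHeader <- anyNA(first)
  labels <- if (hasHeader) fields[[1L]] else NULL
  dataFields <- if (hasHeader) fields[-1L] else fields
  nr <- length(dataFields)
  nc <- widths[[1L]]
  vals <- suppressWarnings(as.numeric(unlist(dataFields, use.names = FALSE)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[[1L]]
    row <- ((flat - 1L) %/% nc) + 1L
    col <- ((flat - 1L) %% nc) + 1L
    stop(sprintf("non-numeric value in %s at data row %d, column %d: '%s'",
                 path, row, col, dataFields[[row]][[col]]))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (nr < 2L) stop("need at least 2 time points (got ", nr, ") in ", path)
  if (nc < 2L) stop("need at least 2 regions (got ", nc, ") in ", path)
  RoiTimeSeries(m, subjectID = subjectID, regionLabels = labels)
}

#' Write one subject's ROI time series
#'
#' Tab-separated, one header row of region labels, full double precision.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSubjectTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "RoiTimeSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ts@regionLabels, collapse = "\t"), con)
  writeLines(apply(ts@values, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

# default, case-insensitive mapping of label tokens to the internal vocabulary
defaultLabelMap <- function() {
  c(patient = "patient", ad = "patient", mdd = "patient",
    control = "control", nc = "control", hc = "control")
}

#' Read a cohort manifest
#'
#' CSV with header \code{subject_id,label,path}. Label tokens are mapped
#' case-insensitively through \code{labelMap} (default: patient/AD/MDD to
#' patient, control/NC/HC to control). Relative paths are resolved against
#' the manifest's own directory.
#'
#' @param path manifest file.
#' @param labelMap named character vector mapping lower-cased input tokens to
#'   \code{"patient"} / \code{"control"}.
#' @return a \linkS4class{CohortManifest}.
#' @export
readManifest <- function(path, labelMap = defaultLabelMap()) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns subject_id, label, path; got: ",
         paste(names(df), collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  tok <- tolower(trimws(df$label))
  unknown <- setdiff(unique(tok), names(labelMap))
  if (length(unknown))
    stop("unknown label token(s): ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(names(labelMap), collapse = ", "))
  base <- dirname(normalizePath(path))
  resolved <- ifelse(is.na(df$path) | df$path == "", NA_character_,
                     ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                            file.path(base, df$path)))
  CohortManifest(df$subject_id, unname(labelMap[tok]), resolved)
}

#' Write a cohort manifest
#'
#' @param manifest a \linkS4class{CohortManifest}.
#' @param path output CSV; subject paths are written as given.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "CohortManifest"))
  utils::write.csv(manifest@entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a feature matrix
#'
#' Tab-separated text: a leading comment line records the feature kind, the
#' header row is \code{subject_id} followed by the feature names, and values
#' are printed with 17 significant digits so a write/read round trip
#' reproduces the matrix beyond 12 significant digits.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param path file path.
#' @return \code{writeFeatureMatrix}: \code{path}, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# feature_kind=", fm@featureKind), con)
  writeLines(paste(c("subject_id", colnames(fm@values)), collapse = "\t"), con)
  ids <- rownames(fm@values)
  for (i in seq_len(nrow(fm@values))) {
    row <- fm@values[i, ]
    line <- if (length(row)) paste(c(ids[[i]], sprintf("%.17g", row)),
                                   collapse = "\t") else ids[[i]]
    writeLines(line, con)
  }
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @return \code{readFeatureMatrix}: the \linkS4class{FeatureMatrix}.
#' @export
readFeatureMatrix <- function(path) {
  if (!file.exists(path)) stop("feature matrix not found: ", path)
  lines <- readLines(path, warn = FALSE)
  kind <- "combined"
  if (length(lines) && startsWith(lines[[1L]], "#")) {
    m <- regmatches(lines[[1L]], regexec("feature_kind=(\\S+)", lines[[1L]]))[[1L]]
    if (length(m) == 2L) kind <- m[[2L]]
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("empty feature matrix file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (header[[1L]] != "subject_id")
    stop("feature matrix header must start with subject_id")
  featNames <- header[-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(body) != length(header))
  if (length(bad))
    stop(sprintf("feature matrix row %d has %d fields, header has %d",
                 bad[[1L]], lengths(body)[[bad[[1L]]]], length(header)))
  ids <- vapply(body, `[[`, "", 1L)
  vals <- matrix(0, nrow = length(body), ncol = length(featNames),
                 dimnames = list(ids, featNames))
  for (i in seq_along(body)) {
    if (length(featNames))
      vals[i, ] <- as.numeric(body[[i]][-1L])
  }
  if (anyNA(vals)) stop("non-numeric feature value in ", path)
  FeatureMatrix(vals, featureKind = kind)
}

#' Write an evaluation report
#'
#' JSON with the four metrics, per-fold selected-feature counts, the
#' per-subject prediction table, and a provenance block sufficient to
#' reproduce the run (resolved config, seed, package and R versions).
#'
#' @param result an \linkS4class{EvalResult}.
#' @param path output JSON file.
#' @param provenance optional named list recorded under \code{provenance}.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(result, path, provenance = NULL) {
  stopifnot(is(result, "EvalResult"))
  out <- list(
    metrics = list(accuracy = result@accuracy, sensitivity = result@sensitivity,
                   specificity = result@specificity, auc = result@auc),
    n_selected_per_fold = result@nSelectedPerFold,
    per_subject = result@perSubject)
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
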