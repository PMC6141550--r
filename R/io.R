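# Readers/writers for the package's plain-text interchange formats (TSV for
# tables and matrices, JSON for decompositions and metadata) and the
# end-to-end pipeline driver.

.requiredPersonalityCols <- c("subject_id", "family_id", "zygosity",
                              "gender", .factorNames)

#' Read and validate a personality table
#'
#' Reads a TSV with columns `subject_id`, `family_id`, `zygosity`, `gender`
#' and the five NEO-FFI domain scores `N`, `E`, `O`, `A`, `C`, preserving row
#' order. Duplicate subject ids, missing scores and scores outside the
#' instrument range 0-48 are rejected with row-level diagnostics.
#'
#' @param path TSV file path.
#' @return validated personality data.frame.
#' @export
readPersonalityTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validatePersonalityTable(tab)
}

#' Validate a personality table
#'
#' @param tab data.frame to validate (see [readPersonalityTable()]).
#' @return the validated data.frame, invisibly unchanged.
#' @export
validatePersonalityTable <- function(tab) {
  missingCols <- setdiff(.requiredPersonalityCols, names(tab))
  if (length(missingCols)) {
    stop("personality table lacks column(s): ",
         paste(missingCols, collapse = ", "), call. = FALSE)
  }
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup)) {
    stop("duplicate subject_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  scores <- as.matrix(tab[, .factorNames])
  if (anyNA(scores)) {
    rows <- which(rowSums(is.na(scores)) > 0)
    stop("missing scores in row(s): ", paste(rows, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(rowSums(scores < 0 | scores > 48) > 0)
  if (length(bad)) {
    stop(sprintf("score(s) outside the NEO-FFI range 0-48 in row(s) %s (subject %s)",
                 paste(bad, collapse = ", "),
                 paste(tab$subject_id[bad], collapse = ", ")),
         call. = FALSE)
  }
  tab
}

#' Write a personality table as TSV
#' @param tab personality data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePersonalityTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-subject ROI time series as one TSV per subject
#' @param ts an [ROITimeSeriesSet-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeTimeseriesDir <- function(ts, dir) {
  stopifnot(is(ts, "ROITimeSeriesSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ts@series)) {
    m <- ts@series[[i]]
    colnames(m) <- ts@regionLabels
    utils::write.table(m, file.path(dir, paste0(ts@subjectIds[i], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read per-subject ROI time series from a directory
#'
#' Expects one TSV per subject named `<subject_id>.tsv` with a header row of
#' the 12 region labels. Files are read in the given subject order; missing
#' subject files, label mismatches and unequal timepoint counts are rejected
#' with specifics, and extra unlisted files are ignored with a warning.
#'
#' @param dir directory of per-subject TSVs.
#' @param subjects character subject ids, in the personality table's order.
#' @param regionLabels expected region labels (default: taken from the first
#'   subject's header).
#' @return an [ROITimeSeriesSet-class] aligned to `subjects`.
#' @export
readTimeseriesDir <- function(dir, subjects, regionLabels = NULL) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  subjects <- as.character(subjects)
  paths <- file.path(dir, paste0(subjects, ".tsv"))
  missing <- subjects[!file.exists(paths)]
  if (length(missing)) {
    stop("missing time-series file(s) for subject(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(list.files(dir, pattern = "\\.tsv$"),
                   paste0(subjects, ".tsv"))
  if (length(extra)) {
    warning("ignoring unlisted file(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  series <- lapply(seq_along(subjects), function(i) {
    m <- as.matrix(utils::read.delim(paths[i], check.names = FALSE))
    storage.mode(m) <- "double"
    m
  })
  labels <- colnames(series[[1L]])
  if (is.null(regionLabels)) regionLabels <- labels
  for (i in seq_along(series)) {
    if (!identical(colnames(series[[i]]), regionLabels)) {
      stop(sprintf("region labels of subject %s do not match (%s)",
                   subjects[i],
                   paste(colnames(series[[i]]), collapse = ", ")),
           call. = FALSE)
    }
  }
  nts <- vapply(series, nrow, 0L)
  if (length(unique(nts)) > 1L) {
    stop("unequal timepoint counts across subjects: ",
         paste(sprintf("%s=%d", subjects, nts), collapse = ", "),
         call. = FALSE)
  }
  roiTimeSeriesSet(series, subjects, regionLabels)
}

# ---------------------------------------------------------------------------
# JSON serialisation

.decompositionToList <- function(dec) {
  list(mixing = unname(dec@mixing), unmixing = unname(dec@unmixing),
       whitener = unname(dec@whitener), nIterations = dec@nIterations,
       converged = dec@converged, tol = dec@tol, seed = dec@seed)
}

#' Serialise a ProfileSet or TemporalModeSet to JSON
#'
#' Matrices are stored as nested arrays with inline metadata so cross-run
#' comparisons (validation module) can reload decompositions exactly.
#' Source matrices are not serialised (they are recomputed by projection).
#'
#' @param object a [ProfileSet-class] or [TemporalModeSet-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeDecomposition <- function(object, path) {
  if (is(object, "ProfileSet")) {
    payload <- c(list(type = "ProfileSet",
                      center = object@center, scale = object@scale,
                      factorNames = object@factorNames,
                      trainSubjects = object@trainSubjects),
                 .decompositionToList(object@decomposition))
  } else if (is(object, "TemporalModeSet")) {
    payload <- c(list(type = "TemporalModeSet",
                      regionLabels = object@regionLabels,
                      trainSubjects = object@trainSubjects),
                 .decompositionToList(object@decomposition))
  } else stop("unsupported object", call. = FALSE)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

.listToDecomposition <- function(x) {
  new("ICADecomposition",
      mixing = do.call(rbind, lapply(x$mixing, unlist)),
      unmixing = do.call(rbind, lapply(x$unmixing, unlist)),
      sources = matrix(numeric(0), 0L, length(x$unmixing)),
      whitener = do.call(rbind, lapply(x$whitener, unlist)),
      nIterations = as.integer(x$nIterations),
      converged = as.logical(x$converged),
      tol = as.numeric(x$tol), seed = as.integer(x$seed))
}

#' Read a serialised ProfileSet or TemporalModeSet
#' @param path JSON path written by [writeDecomposition()].
#' @return a [ProfileSet-class] or [TemporalModeSet-class] (with empty
#'   source slot; sources are recomputed by projection).
#' @export
readDecomposition <- function(path) {
  x <- jsonlite::read_json(path)
  dec <- .listToDecomposition(x)
  if (x$type == "ProfileSet") {
    new("ProfileSet", decomposition = dec,
        center = unlist(x$center), scale = unlist(x$scale),
        factorNames = unlist(x$factorNames),
        trainSubjects = as.character(unlist(x$trainSubjects)))
  } else {
    new("TemporalModeSet", decomposition = dec,
        regionLabels = unlist(x$regionLabels),
        trainSubjects = as.character(unlist(x$trainSubjects)))
  }
}

#' Write a GroundTruth as JSON
#' @param truth a [GroundTruth-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  jsonlite::write_json(
    list(profileMixing = unname(truth@profileMixing),
         spatialMixing = unname(truth@spatialMixing),
         couplings = truth@couplings, sourceFamily = truth@sourceFamily,
         seed = truth@seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a GroundTruth from JSON
#' @param path JSON path written by [writeGroundTruth()].
#' @return a [GroundTruth-class].
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path)
  cp <- if (length(x$couplings)) {
    do.call(rbind, lapply(x$couplings, as.data.frame))
  } else NULL
  groundTruth(do.call(rbind, lapply(x$profileMixing, unlist)),
              do.call(rbind, lapply(x$spatialMixing, unlist)),
              couplings = cp, sourceFamily = x$sourceFamily,
              seed = as.integer(x$seed))
}

#' Write an association table as TSV
#' @param object an [AssociationResult-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAssociationResult <- function(object, path) {
  stopifnot(is(object, "AssociationResult"))
  utils::write.table(object@results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Pipeline driver

#' Assemble a pipeline configuration
#'
#' @param personalityPath personality table TSV.
#' @param timeseriesDir directory of per-subject ROI TSVs.
#' @param outputDir output directory for all artifacts.
#' @param icaSeed,tol,maxIter,fun FastICA options used for both
#'   decompositions.
#' @param nPerm,assocSeed,q,fdrScope association options.
#' @return validated named list.
#' @export
pipelineConfig <- function(personalityPath, timeseriesDir, outputDir,
                           icaSeed = 1L, tol = 1e-6, maxIter = 1000L,
                           fun = "logcosh", nPerm = 10000L, assocSeed = 1L,
                           q = 0.05, fdrScope = "global") {
  config <- list(personalityPath = personalityPath,
                 timeseriesDir = timeseriesDir, outputDir = outputDir,
                 icaSeed = .checkCount(icaSeed, "icaSeed", 0L), tol = tol,
                 maxIter = .checkCount(maxIter, "maxIter"), fun = fun,
                 nPerm = .checkCount(nPerm, "nPerm"),
                 assocSeed = .checkCount(assocSeed, "assocSeed", 0L),
                 q = q, fdrScope = fdrScope)
  stopifnot(tol > 0, q > 0, q < 1, fdrScope %in% c("global", "per-profile"))
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full profiles-modes-engagement-association pipeline
#'
#' Reads the personality table and ROI time series, derives the personality
#' profiles and temporal modes, computes per-subject engagement, runs the
#' gender-corrected family-aware association, and writes all artifacts plus a
#' run manifest (config, seeds, package version, convergence flags) to the
#' output directory. Identical configuration yields identical outputs.
#'
#' @param config list from [pipelineConfig()].
#' @return (invisibly) list with `profiles`, `loadings`, `modes`,
#'   `engagement`, `association`, `manifest`.
#' @export
runPipeline <- function(config) {
  table <- .stage("read_personality",
                  readPersonalityTable(config$personalityPath))
  ts <- .stage("read_timeseries",
               readTimeseriesDir(config$timeseriesDir, table$subject_id))
  pr <- .stage("profiles",
               deriveProfiles(table, fun = config$fun, tol = config$tol,
                              maxIter = config$maxIter,
                              seed = config$icaSeed))
  modes <- .stage("modes",
                  deriveTemporalModes(ts, fun = config$fun, tol = config$tol,
                                      maxIter = config$maxIter,
                                      seed = config$icaSeed))
  engagement <- .stage("engagement", engagementMatrix(ts, modes))
  association <- .stage("association",
                        runAssociation(engagement, pr$loadings,
                                       covariates = table$gender,
                                       blocks = table$family_id,
                                       nPerm = config$nPerm,
                                       seed = config$assocSeed,
                                       q = config$q,
                                       fdrScope = config$fdrScope))
  out <- config$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  writeDecomposition(pr$profiles, file.path(out, "profiles.json"))
  writeDecomposition(modes, file.path(out, "modes.json"))
  utils::write.table(
    data.frame(subject_id = rownames(pr$loadings), pr$loadings,
               check.names = FALSE),
    file.path(out, "loadings.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(subject_id = rownames(engagement), engagement,
               check.names = FALSE),
    file.path(out, "engagement.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeAssociationResult(association, file.path(out, "association.tsv"))
  manifest <- list(
    config = config,
    package = as.character(utils::packageVersion("tempica")),
    nSubjects = nrow(table),
    profilesConverged = pr$profiles@decomposition@converged,
    modesConverged = modes@decomposition@converged)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(profiles = pr$profiles, loadings = pr$loadings,
                 modes = modes, engagement = engagement,
                 association = association, manifest = manifest))
}

#' Re-run a pipeline from its manifest
#' @param manifestPath path to a `manifest.json` written by [runPipeline()].
#' @param outputDir optional override of the output directory.
#' @return as [runPipeline()].
#' @export
runFromManifest <- function(manifestPath, outputDir = NULL) {
  manifest <- jsonlite::read_json(manifestPath)
  config <- manifest$config
  config$icaSeed <- as.integer(config$icaSeed)
  config$maxIter <- as.integer(config$maxIter)
  config$nPerm <- as.integer(config$nPerm)
  config$assocSeed <- as.integer(config$assocSeed)
  if (!is.null(outputDir)) config$outputDir <- outputDir
  runPipeline(do.call(pipelineConfig, config))
}
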