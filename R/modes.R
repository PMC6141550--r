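# Temporal functional modes: within-subject standardisation, group temporal
# ICA of the concatenated ROI series, subject mode time series and the
# per-subject engagement matrix.

#' Construct an ROITimeSeriesSet
#'
#' @param series list of numeric timepoints x regions matrices, one per
#'   subject; all with equal dimensions.
#' @param subjectIds character subject identifiers, one per matrix.
#' @param regionLabels character region labels (defaults to the column names
#'   of the first matrix).
#' @param metadata optional list of generator ground truth.
#' @return an [ROITimeSeriesSet-class].
#' @export
roiTimeSeriesSet <- function(series, subjectIds,
                             regionLabels = colnames(series[[1L]]),
                             metadata = list()) {
  if (is.null(regionLabels)) {
    stop("regionLabels required (none given, series unlabelled)",
         call. = FALSE)
  }
  series <- lapply(series, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  new("ROITimeSeriesSet", series = series,
      subjectIds = as.character(subjectIds),
      regionLabels = as.character(regionLabels), metadata = metadata)
}

.standardizeMatrix <- function(m, subject) {
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("zero-variance region(s) %s within subject %s",
                 paste(bad, collapse = ", "), subject), call. = FALSE)
  }
  sweep(sweep(m, 2L, colMeans(m), "-"), 2L, sds, "/")
}

#' Within-subject z-scoring of ROI time series
#'
#' Standardises every region's series to mean 0 and sample SD 1 *within each
#' subject*, so that between-subject global amplitude differences do not
#' dominate the group temporal ICA or contaminate the engagement measure.
#'
#' @param ts an [ROITimeSeriesSet-class].
#' @return an [ROITimeSeriesSet-class] with standardised series.
#' @export
standardizeTimeseries <- function(ts) {
  stopifnot(is(ts, "ROITimeSeriesSet"))
  series <- mapply(function(m, id) .standardizeMatrix(m, id),
                   ts@series, ts@subjectIds, SIMPLIFY = FALSE)
  initialize(ts, series = series)
}

#' Group ROI correlation matrix
#'
#' Pearson correlation matrix of the 12 region series computed on the
#' group-concatenated, within-subject standardised time series.
#'
#' @param ts an [ROITimeSeriesSet-class].
#' @return symmetric 12 x 12 correlation matrix with unit diagonal.
#' @export
roiCorrelationMatrix <- function(ts) {
  stopifnot(is(ts, "ROITimeSeriesSet"))
  if (nrow(ts@series[[1L]]) < 2L) {
    stop("need at least 2 timepoints per subject", call. = FALSE)
  }
  std <- standardizeTimeseries(ts)
  X <- do.call(rbind, std@series)
  R <- stats::cor(X)
  dimnames(R) <- list(ts@regionLabels, ts@regionLabels)
  R
}

#' Derive temporal functional modes by group temporal ICA
#'
#' Standardises each subject's series within subject, concatenates all
#' subjects along time and runs full-rank FastICA on the resulting (total
#' timepoints x 12 regions) matrix, treating time as samples. Each of the 12
#' resulting temporal modes is a spatial weight pattern over the ROIs whose
#' associated source series is the group mode time series.
#'
#' @param ts an [ROITimeSeriesSet-class].
#' @param fun,alpha,tol,maxIter,seed,nRestarts FastICA options, see [fastICA()].
#' @return a [TemporalModeSet-class].
#' @export
deriveTemporalModes <- function(ts, fun = "logcosh", alpha = 1, tol = 1e-6,
                                maxIter = 1000L, seed = 1L, nRestarts = 4L) {
  stopifnot(is(ts, "ROITimeSeriesSet"))
  k <- length(ts@regionLabels)
  std <- standardizeTimeseries(ts)
  X <- do.call(rbind, std@series)
  if (nrow(X) < 10L * k) {
    warning("few concatenated timepoints relative to regions; modes may be unstable",
            call. = FALSE)
  }
  dec <- fastICA(X, nComponents = k, fun = fun, alpha = alpha, tol = tol,
                 maxIter = maxIter, seed = seed, nRestarts = nRestarts)
  new("TemporalModeSet", decomposition = dec, regionLabels = ts@regionLabels,
      trainSubjects = ts@subjectIds)
}

#' Spatial weight matrix of the temporal modes (regions x modes)
#'
#' @param modes a [TemporalModeSet-class].
#' @return 12 x 12 numeric matrix; rows = ROIs, columns = modes, canonical
#'   order/sign.
#' @export
spatialWeights <- function(modes) {
  stopifnot(is(modes, "TemporalModeSet"))
  W <- mixing(modes)
  dimnames(W) <- list(modes@regionLabels,
                      paste0("mode", seq_len(ncol(W))))
  W
}

#' Project a subject's ROI series onto the temporal modes
#'
#' Standardises the subject's series within subject and applies the mode
#' unmixing transform, yielding the subject-specific mode time series (the
#' engagement of each co-activation pattern at every timepoint). For a
#' training subject this reproduces the corresponding rows of the group ICA
#' source series.
#'
#' @param subjectTs numeric timepoints x 12 matrix, columns in the training
#'   region order (checked against labels when present), or an
#'   [ROITimeSeriesSet-class] (projected subject by subject).
#' @param modes a [TemporalModeSet-class].
#' @return timepoints x 12 mode time-series matrix, or a list of such
#'   matrices (named by subject) for a set.
#' @export
projectModeTimeseries <- function(subjectTs, modes) {
  stopifnot(is(modes, "TemporalModeSet"))
  if (is(subjectTs, "ROITimeSeriesSet")) {
    if (!identical(subjectTs@regionLabels, modes@regionLabels)) {
      stop("region labels/order differ from the training set", call. = FALSE)
    }
    out <- lapply(seq_along(subjectTs@series), function(i) {
      .projectOne(subjectTs@series[[i]], modes, subjectTs@subjectIds[i])
    })
    names(out) <- subjectTs@subjectIds
    return(out)
  }
  .projectOne(as.matrix(subjectTs), modes, "subject")
}

.projectOne <- function(m, modes, subject) {
  if (ncol(m) != length(modes@regionLabels)) {
    stop("subject matrix must have one column per training region",
         call. = FALSE)
  }
  if (!is.null(colnames(m)) && !identical(colnames(m), modes@regionLabels)) {
    stop("region labels/order differ from the training set", call. = FALSE)
  }
  Z <- .standardizeMatrix(m, subject)
  out <- Z %*% t(unmixing(modes))
  colnames(out) <- paste0("mode", seq_len(ncol(out)))
  out
}

#' Per-subject engagement of each temporal mode
#'
#' Engagement of mode m for subject i is the sample variance (denominator
#' n - 1) of subject i's mode-m time series over all of the subject's
#' timepoints: a non-negative scalar summary of how strongly that
#' co-activation pattern is expressed.
#'
#' @param modeTs list of timepoints x modes matrices (as from
#'   [projectModeTimeseries()] on a set), or a single matrix.
#' @return subjects x modes matrix of variances (rownames = subject ids when
#'   the input list is named).
#' @examples
#' computeEngagement(list(s1 = cbind(m1 = c(1, -1, 1, -1))))  # 4/3
#' @export
computeEngagement <- function(modeTs) {
  if (is.matrix(modeTs)) modeTs <- list(modeTs)
  if (nrow(modeTs[[1L]]) < 2L) {
    stop("need at least 2 timepoints to compute a variance", call. = FALSE)
  }
  E <- t(vapply(modeTs, function(m) apply(m, 2L, stats::var),
                numeric(ncol(modeTs[[1L]]))))
  rownames(E) <- names(modeTs)
  E
}

#' Engagement matrix straight from an ROITimeSeriesSet
#'
#' Convenience composition of [projectModeTimeseries()] and
#' [computeEngagement()].
#'
#' @param ts an [ROITimeSeriesSet-class].
#' @param modes a [TemporalModeSet-class].
#' @return subjects x modes engagement matrix aligned to `subjectIds(ts)`.
#' @export
engagementMatrix <- function(ts, modes) {
  computeEngagement(projectModeTimeseries(ts, modes))
}
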