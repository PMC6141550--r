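# Reproducibility machinery: leave-one-out and split-half stability of both
# decompositions, and fully out-of-sample projection association.

.deriveWeights <- function(data, deriver, seed, ...) {
  if (deriver == "profiles") {
    fit <- deriveProfiles(data, seed = seed, ...)
    list(weights = mixing(fit$profiles), fit = fit$profiles,
         converged = fit$profiles@decomposition@converged)
  } else {
    fit <- deriveTemporalModes(data, seed = seed, ...)
    list(weights = mixing(fit), fit = fit,
         converged = fit@decomposition@converged)
  }
}

.dropSubjects <- function(data, idx) {
  if (is.data.frame(data)) data[-idx, , drop = FALSE] else data[-idx]
}

.keepSubjects <- function(data, idx) {
  if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
}

.nSubjects <- function(data) {
  if (is.data.frame(data)) nrow(data) else length(data)
}

.foldIndices <- function(n, foldSize) {
  split(seq_len(n), ceiling(seq_len(n) / foldSize))
}

.stabilityReport <- function(corMat, scheme, nExcluded, seed,
                             halfMat = NULL) {
  if (is.null(corMat) || nrow(corMat) == 0L) {
    stop("no resampling fold converged; stability cannot be summarised",
         call. = FALSE)
  }
  stats <- data.frame(
    component = seq_len(ncol(corMat)),
    meanAbsCor = colMeans(corMat),
    sdAbsCor = apply(corMat, 2L, stats::sd))
  if (!is.null(halfMat)) {
    stats$meanHalfCor <- colMeans(halfMat)
    stats$sdHalfCor <- apply(halfMat, 2L, stats::sd)
  }
  new("ReproducibilityReport", componentStats = stats, scheme = scheme,
      nFolds = nrow(corMat), nExcluded = as.integer(nExcluded),
      seed = as.integer(seed))
}

#' Leave-one-out stability of a decomposition
#'
#' For each fold, the full derivation (standardisation + ICA) is re-run with
#' the fold's subjects removed; the fold solution is aligned to the
#' full-sample solution with [matchComponents()] and the per-component
#' matched absolute correlations are recorded. The full-sample solution is
#' the alignment reference for every fold, which prevents sign/order drift
#' across folds. Folds whose ICA fails to converge are excluded with a
#' warning.
#'
#' @param data a personality data.frame (for `deriver = "profiles"`) or an
#'   [ROITimeSeriesSet-class] (for `deriver = "modes"`).
#' @param deriver which decomposition to assess.
#' @param foldSize subjects left out per fold; 1 is strict leave-one-out,
#'   larger values give the grouped-fold (leave-k-out) approximation.
#' @param seed ICA seed used for the full and fold solutions.
#' @param ... further options passed to the deriver.
#' @return a [ReproducibilityReport-class].
#' @export
looStability <- function(data, deriver = c("profiles", "modes"),
                         foldSize = 1L, seed = 1L, ...) {
  deriver <- match.arg(deriver)
  n <- .nSubjects(data)
  if (n < 20L) stop("need at least 20 subjects", call. = FALSE)
  full <- .deriveWeights(data, deriver, seed, ...)
  folds <- .foldIndices(n, .checkCount(foldSize, "foldSize"))
  rows <- list()
  nExcluded <- 0L
  for (f in folds) {
    fit <- withCallingHandlers(
      .deriveWeights(.dropSubjects(data, f), deriver, seed, ...),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!fit$converged) {
      nExcluded <- nExcluded + 1L
      warning(sprintf("fold ICA did not converge; fold excluded (subjects %s)",
                      paste(f, collapse = ",")), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <-
      matchComponents(full$weights, fit$weights)$correlations
  }
  .stabilityReport(do.call(rbind, rows), "loo", nExcluded, seed)
}

# Assign whole family blocks to two halves of (near-)equal subject counts.
.splitBlocks <- function(blockIds) {
  pos <- split(seq_along(blockIds),
               factor(blockIds, levels = unique(blockIds)))
  ord <- sample(length(pos))
  half1 <- integer(0)
  target <- length(blockIds) / 2
  for (b in ord) {
    if (length(half1) < target) half1 <- c(half1, pos[[b]])
  }
  sort(half1)
}

#' Split-half stability of a decomposition
#'
#' For each random half-split the derivation is re-run on each half; both
#' half solutions are matched to the full-sample solution (`meanAbsCor`,
#' `sdAbsCor`) and to each other (`meanHalfCor`, `sdHalfCor`). Family blocks
#' are never split across halves, so twin dependence cannot leak between
#' the halves.
#'
#' @inheritParams looStability
#' @param nSplits number of random half-splits.
#' @param blocks family structure (data.frame with `family_id` or character
#'   vector); `NULL` treats every subject as a singleton block.
#' @param seed seed for both the splits and the ICA runs.
#' @return a [ReproducibilityReport-class].
#' @export
splitHalfStability <- function(data, deriver = c("profiles", "modes"),
                               nSplits = 20L, blocks = NULL, seed = 1L, ...) {
  deriver <- match.arg(deriver)
  n <- .nSubjects(data)
  if (n < 40L) stop("need at least 40 subjects", call. = FALSE)
  blockIds <- if (is.null(blocks)) {
    if (is.data.frame(data) && !is.null(data$family_id)) {
      as.character(data$family_id)
    } else as.character(seq_len(n))
  } else .blockIdsFrom(blocks)
  stopifnot(length(blockIds) == n)
  full <- .deriveWeights(data, deriver, seed, ...)
  nSplits <- .checkCount(nSplits, "nSplits")

  halves <- .withSeed(seed, lapply(seq_len(nSplits),
                                   function(s) .splitBlocks(blockIds)))
  fullRows <- list()
  halfRows <- list()
  nExcluded <- 0L
  for (h1 in halves) {
    fits <- lapply(list(h1, setdiff(seq_len(n), h1)), function(idx) {
      withCallingHandlers(
        .deriveWeights(.keepSubjects(data, idx), deriver, seed, ...),
        warning = function(w) invokeRestart("muffleWarning"))
    })
    if (!all(vapply(fits, `[[`, FALSE, "converged"))) {
      nExcluded <- nExcluded + 1L
      warning("half ICA did not converge; split excluded", call. = FALSE)
      next
    }
    fullRows[[length(fullRows) + 1L]] <- colMeans(rbind(
      matchComponents(full$weights, fits[[1L]]$weights)$correlations,
      matchComponents(full$weights, fits[[2L]]$weights)$correlations))
    halfRows[[length(halfRows) + 1L]] <-
      matchComponents(fits[[1L]]$weights, fits[[2L]]$weights)$correlations
  }
  .stabilityReport(do.call(rbind, fullRows), "split-half", nExcluded, seed,
                   halfMat = do.call(rbind, halfRows))
}

#' Out-of-sample projection association (leave-one-out)
#'
#' For each fold, both decompositions (personality profiles and temporal
#' modes) are learned with the fold's subjects removed, aligned to the
#' full-sample reference so loadings are comparable across folds, and the
#' held-out subjects are projected onto them: profile loadings via
#' [projectSubjects()] and engagement via [projectModeTimeseries()] +
#' [computeEngagement()]. A subject's out-of-sample values therefore never
#' use that subject's data in training. The assembled out-of-sample
#' (loading, engagement) pairs are then fed through [runAssociation()].
#'
#' @param table personality data.frame (with `family_id` for the blocks).
#' @param ts an [ROITimeSeriesSet-class] aligned to `table$subject_id`.
#' @param covariates as in [runAssociation()] (default: the table's gender).
#' @param foldSize held-out subjects per fold; 1 is strict leave-one-out,
#'   larger values give the grouped-fold approximation.
#' @param nPerm,seed,q,fdrScope passed to [runAssociation()].
#' @param ... ICA options passed to both derivers.
#' @return list with `association` (an [AssociationResult-class] on the
#'   out-of-sample values), `loadings` and `engagement` (the out-of-sample
#'   matrices).
#' @export
looProjectionAssociation <- function(table, ts, covariates = table$gender,
                                     foldSize = 1L, nPerm = 1000L,
                                     seed = 1L, q = 0.05,
                                     fdrScope = "global", ...) {
  stopifnot(is.data.frame(table), is(ts, "ROITimeSeriesSet"))
  n <- nrow(table)
  if (n < 30L) stop("need at least 30 subjects", call. = FALSE)
  if (!identical(as.character(table$subject_id), ts@subjectIds)) {
    stop("personality table and time series are not subject-aligned",
         call. = FALSE)
  }
  fullProfiles <- deriveProfiles(table, seed = seed, ...)$profiles
  fullModes <- deriveTemporalModes(ts, seed = seed, ...)

  loadings <- matrix(NA_real_, n, 5L,
                     dimnames = list(table$subject_id,
                                     paste0("profile", 1:5)))
  engagement <- matrix(NA_real_, n, nComponents(fullModes),
                       dimnames = list(table$subject_id,
                                       paste0("mode",
                                              seq_len(nComponents(fullModes)))))
  for (f in .foldIndices(n, .checkCount(foldSize, "foldSize"))) {
    trainTab <- table[-f, , drop = FALSE]
    trainTs <- ts[-f]
    foldProfiles <- withCallingHandlers(
      deriveProfiles(trainTab, seed = seed, ...)$profiles,
      warning = function(w) invokeRestart("muffleWarning"))
    foldModes <- withCallingHandlers(
      deriveTemporalModes(trainTs, seed = seed, ...),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!foldProfiles@decomposition@converged ||
        !foldModes@decomposition@converged) {
      warning(sprintf("fold ICA did not converge (subjects %s); projections kept with caution",
                      paste(f, collapse = ",")), call. = FALSE)
    }
    foldProfiles@decomposition <- .alignToReference(
      mixing(fullProfiles), foldProfiles@decomposition)
    foldModes@decomposition <- .alignToReference(
      mixing(fullModes), foldModes@decomposition)
    loadings[f, ] <- projectSubjects(table[f, , drop = FALSE], foldProfiles)
    heldOut <- projectModeTimeseries(ts[f], foldModes)
    engagement[f, ] <- computeEngagement(heldOut)
  }
  association <- runAssociation(engagement, loadings,
                                covariates = covariates,
                                blocks = table$family_id, nPerm = nPerm,
                                seed = seed, q = q, fdrScope = fdrScope)
  list(association = association, loadings = loadings,
       engagement = engagement)
}
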