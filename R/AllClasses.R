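#' @import methods
NULL

# ---------------------------------------------------------------------------
# ICADecomposition

#' ICADecomposition: result of a FastICA fit
#'
#' Container for a FastICA decomposition shared by the personality-profile and
#' temporal-mode analyses. For data X (samples x variables, centered and
#' scaled), `sources = X %*% t(unmixing)` holds the estimated independent
#' component scores and `mixing` (variables x components) the weight pattern of
#' each component, so that `X ~ sources %*% t(mixing)`. Components are stored
#' in canonical form: ordered by descending variance explained in X, each
#' mixing column signed so its largest-magnitude entry is positive.
#'
#' @slot mixing numeric matrix, variables x components.
#' @slot unmixing numeric matrix, components x variables.
#' @slot sources numeric matrix, samples x components.
#' @slot whitener numeric matrix, components x variables; the whitening
#'   transform applied before the fixed-point iteration.
#' @slot nIterations integer, fixed-point iterations used.
#' @slot converged logical, whether the weight-alignment change fell below
#'   `tol` before `maxIter`.
#' @slot tol numeric convergence tolerance.
#' @slot seed integer seed used for the random initialisation.
#'
#' @seealso [fastICA()], [matchComponents()], [amariIndex()]
#' @export
setClass("ICADecomposition",
  representation(
    mixing = "matrix",
    unmixing = "matrix",
    sources = "matrix",
    whitener = "matrix",
    nIterations = "integer",
    converged = "logical",
    tol = "numeric",
    seed = "integer"
  )
)

setValidity("ICADecomposition", function(object) {
  k <- ncol(object@mixing)
  p <- nrow(object@mixing)
  msg <- character()
  if (!identical(dim(object@unmixing), c(k, p)))
    msg <- c(msg, "unmixing must be components x variables")
  if (ncol(object@sources) != k)
    msg <- c(msg, "sources must have one column per component")
  if (!identical(dim(object@whitener), c(k, p)))
    msg <- c(msg, "whitener must be components x variables")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("mixing", "ICADecomposition", function(object) object@mixing)

#' @rdname accessors
#' @export
setMethod("unmixing", "ICADecomposition", function(object) object@unmixing)

#' @rdname accessors
#' @export
setMethod("icaSources", "ICADecomposition", function(object) object@sources)

#' @rdname accessors
#' @export
setMethod("nComponents", "ICADecomposition",
          function(object) ncol(object@mixing))

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf(
    "ICADecomposition: %d components over %d variables (%d samples)\n",
    ncol(object@mixing), nrow(object@mixing), nrow(object@sources)))
  cat(sprintf("  converged: %s after %d iterations (tol %.1e, seed %d)\n",
              object@converged, object@nIterations, object@tol, object@seed))
})

# ---------------------------------------------------------------------------
# GroundTruth / SimulationConfig

#' GroundTruth: planted parameters of the synthetic generator
#'
#' Known parameters from which synthetic personality tables and ROI time
#' series are generated, kept so downstream estimates can be scored by
#' parameter recovery.
#'
#' @slot profileMixing 5 x 5 numeric matrix, rows = NEO factors (N, E, O, A,
#'   C), columns = latent personality profiles; factor scores are linear in
#'   the latent profile sources through this mixing.
#' @slot spatialMixing 12 x 12 numeric matrix, rows = ROIs, columns = latent
#'   temporal modes; ROI series are linear in the latent mode series.
#' @slot couplings data.frame with columns `profile`, `mode`, `rho`: each row
#'   plants a linear relation (correlation `rho`) between a profile's subject
#'   loading and the log-variance (engagement) of a mode.
#' @slot sourceFamily label of the non-Gaussian latent source distribution.
#' @slot seed integer seed the truth was built from.
#'
#' @seealso [groundTruth()], [defaultGroundTruth()]
#' @export
setClass("GroundTruth",
  representation(
    profileMixing = "matrix",
    spatialMixing = "matrix",
    couplings = "data.frame",
    sourceFamily = "character",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!identical(dim(object@profileMixing), c(5L, 5L)))
    msg <- c(msg, "profileMixing must be 5 x 5")
  else if (qr(object@profileMixing)$rank < 5L)
    msg <- c(msg, "profileMixing must be full rank")
  if (!identical(dim(object@spatialMixing), c(12L, 12L)))
    msg <- c(msg, "spatialMixing must be 12 x 12")
  else if (qr(object@spatialMixing)$rank < 12L)
    msg <- c(msg, "spatialMixing must be full rank")
  cp <- object@couplings
  if (!all(c("profile", "mode", "rho") %in% names(cp)))
    msg <- c(msg, "couplings needs columns profile, mode, rho")
  else if (nrow(cp) && (any(abs(cp$rho) >= 1) ||
                        any(cp$profile < 1 | cp$profile > 5) ||
                        any(cp$mode < 1 | cp$mode > 12)))
    msg <- c(msg, "couplings must have |rho| < 1, profile in 1..5, mode in 1..12")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: 5x5 profile mixing, 12x12 spatial mixing\n")
  cat(sprintf("  source family: %s; seed %d\n",
              object@sourceFamily, object@seed))
  if (nrow(object@couplings)) {
    with(object@couplings,
         cat(sprintf("  planted coupling: profile %d ~ mode %d (rho = %.2f)\n",
                     profile, mode, rho), sep = ""))
  } else cat("  no planted couplings (null model)\n")
})

#' SimulationConfig: sample sizes and noise levels of a synthetic study
#'
#' @slot nSubjects integer number of subjects.
#' @slot nTimepoints integer timepoints per subject.
#' @slot noiseSdPersonality numeric, additive Gaussian noise SD on factor
#'   scores in latent (unit-variance source) units.
#' @slot noiseSdTimeseries numeric, additive Gaussian noise SD on ROI series
#'   in latent signal units.
#' @slot familyFractions named numeric length 3 (`singleton`, `MZ`, `DZ`):
#'   fractions of subjects in each zygosity group, summing to 1.
#' @slot genderBalance numeric fraction of female subjects.
#' @slot seed integer master seed; all generator randomness derives from it.
#'
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
  representation(
    nSubjects = "integer",
    nTimepoints = "integer",
    noiseSdPersonality = "numeric",
    noiseSdTimeseries = "numeric",
    familyFractions = "numeric",
    genderBalance = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be positive")
  if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
  if (object@noiseSdPersonality < 0 || object@noiseSdTimeseries < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  ff <- object@familyFractions
  if (length(ff) != 3L ||
      !all(c("singleton", "MZ", "DZ") %in% names(ff)) ||
      any(ff < 0) || abs(sum(ff) - 1) > 1e-8)
    msg <- c(msg, "familyFractions must be named (singleton, MZ, DZ), non-negative, summing to 1")
  if (object@genderBalance < 0 || object@genderBalance > 1)
    msg <- c(msg, "genderBalance must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d subjects x %d timepoints (seed %d)\n",
              object@nSubjects, object@nTimepoints, object@seed))
  cat(sprintf("  noise SD: personality %.2f, timeseries %.2f\n",
              object@noiseSdPersonality, object@noiseSdTimeseries))
  cat(sprintf("  family fractions: singleton %.2f, MZ %.2f, DZ %.2f; %.0f%% female\n",
              object@familyFractions["singleton"],
              object@familyFractions["MZ"], object@familyFractions["DZ"],
              100 * object@genderBalance))
})

# ---------------------------------------------------------------------------
# ROITimeSeriesSet

#' ROITimeSeriesSet: per-subject ROI time-series matrices
#'
#' Ordered collection of one timepoints x 12 matrix per subject with shared
#' region labels. All subjects must share the same regions (same order) and
#' the same number of timepoints, as required for balanced temporal
#' concatenation before the group temporal ICA.
#'
#' @slot series list of numeric matrices (timepoints x regions), one per
#'   subject, in subject order.
#' @slot subjectIds character vector of subject identifiers.
#' @slot regionLabels character vector of ROI labels (columns of each matrix).
#' @slot metadata list of optional generator ground truth (latent mode series,
#'   log-variances) carried for recovery tests.
#'
#' @seealso [roiTimeSeriesSet()], [deriveTemporalModes()]
#' @export
setClass("ROITimeSeriesSet",
  representation(
    series = "list",
    subjectIds = "character",
    regionLabels = "character",
    metadata = "list"
  )
)

setValidity("ROITimeSeriesSet", function(object) {
  msg <- character()
  n <- length(object@series)
  if (length(object@subjectIds) != n)
    msg <- c(msg, "one subject id per series matrix required")
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "subject ids must be unique")
  if (n) {
    ncols <- vapply(object@series, ncol, 0L)
    nrows <- vapply(object@series, nrow, 0L)
    if (any(ncols != length(object@regionLabels)))
      msg <- c(msg, "every series matrix must have one column per region label")
    if (length(unique(nrows)) > 1L)
      msg <- c(msg, "all subjects must have the same number of timepoints")
    if (any(vapply(object@series, function(m) anyNA(m) || any(!is.finite(m)),
                   FALSE)))
      msg <- c(msg, "series contain missing or non-finite values")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("subjectIds", "ROITimeSeriesSet", function(object) object@subjectIds)

setMethod("show", "ROITimeSeriesSet", function(object) {
  nt <- if (length(object@series)) nrow(object@series[[1L]]) else 0L
  cat(sprintf("ROITimeSeriesSet: %d subjects x %d timepoints x %d regions\n",
              length(object@series), nt, length(object@regionLabels)))
  cat("  regions:", paste(object@regionLabels, collapse = ", "), "\n")
})

#' Length of an ROITimeSeriesSet (number of subjects)
#' @param x an [ROITimeSeriesSet-class] object.
#' @return integer subject count.
#' @export
setMethod("length", "ROITimeSeriesSet", function(x) length(x@series))

#' Subset an ROITimeSeriesSet by subject
#' @param x an [ROITimeSeriesSet-class] object.
#' @param i subject indices (integer, logical or subject id character).
#' @param j,drop,... ignored.
#' @return an [ROITimeSeriesSet-class] with the selected subjects.
#' @export
setMethod("[", "ROITimeSeriesSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@subjectIds)
  if (anyNA(i)) stop("unknown subject id in subset")
  initialize(x, series = x@series[i], subjectIds = x@subjectIds[i],
             metadata = .subsetMetadata(x@metadata, i))
})

.subsetMetadata <- function(md, i) {
  if (!is.null(md$latentSeries)) md$latentSeries <- md$latentSeries[i]
  if (!is.null(md$logVariance)) md$logVariance <- md$logVariance[i, , drop = FALSE]
  if (!is.null(md$trueLoadings)) md$trueLoadings <- md$trueLoadings[i, , drop = FALSE]
  md
}

# ---------------------------------------------------------------------------
# ProfileSet / TemporalModeSet

#' ProfileSet: independent personality profiles
#'
#' A FastICA decomposition of z-scored five-factor (NEO-FFI) scores into five
#' independent personality profiles, together with the training-sample
#' standardisation parameters needed to project new subjects onto the same
#' profiles.
#'
#' @slot decomposition the underlying [ICADecomposition-class].
#' @slot center numeric(5), training means of the factor columns.
#' @slot scale numeric(5), training sample SDs of the factor columns.
#' @slot factorNames character(5), the factor column names (N, E, O, A, C).
#' @slot trainSubjects character, subject ids of the training sample.
#'
#' @seealso [deriveProfiles()], [projectSubjects()], [profileWeights()]
#' @export
setClass("ProfileSet",
  representation(
    decomposition = "ICADecomposition",
    center = "numeric",
    scale = "numeric",
    factorNames = "character",
    trainSubjects = "character"
  )
)

setValidity("ProfileSet", function(object) {
  msg <- character()
  if (nrow(object@decomposition@mixing) != 5L ||
      ncol(object@decomposition@mixing) != 5L)
    msg <- c(msg, "profile decomposition must be 5 factors x 5 profiles")
  if (length(object@center) != 5L || length(object@scale) != 5L ||
      length(object@factorNames) != 5L)
    msg <- c(msg, "center/scale/factorNames must have length 5")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("mixing", "ProfileSet", function(object) object@decomposition@mixing)

#' @rdname accessors
#' @export
setMethod("unmixing", "ProfileSet",
          function(object) object@decomposition@unmixing)

#' @rdname accessors
#' @export
setMethod("nComponents", "ProfileSet", function(object) 5L)

setMethod("show", "ProfileSet", function(object) {
  cat(sprintf("ProfileSet: 5 personality profiles from %d subjects\n",
              length(object@trainSubjects)))
  cat(sprintf("  converged: %s (%d iterations)\n",
              object@decomposition@converged,
              object@decomposition@nIterations))
  cat("  profile weights (factors x profiles):\n")
  print(round(profileWeights(object), 2))
})

#' TemporalModeSet: temporal functional modes over ROIs
#'
#' A FastICA decomposition of the group-concatenated, within-subject z-scored
#' ROI time series into 12 temporal modes. Each mode is a spatial weight
#' pattern over the 12 ROIs with an associated independent time course.
#'
#' @slot decomposition the underlying [ICADecomposition-class] (time as
#'   samples).
#' @slot regionLabels character(12) ROI labels of the training set.
#' @slot trainSubjects character, subject ids of the training sample.
#'
#' @seealso [deriveTemporalModes()], [projectModeTimeseries()],
#'   [spatialWeights()]
#' @export
setClass("TemporalModeSet",
  representation(
    decomposition = "ICADecomposition",
    regionLabels = "character",
    trainSubjects = "character"
  )
)

setValidity("TemporalModeSet", function(object) {
  msg <- character()
  if (nrow(object@decomposition@mixing) != length(object@regionLabels))
    msg <- c(msg, "one mixing row per region label required")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("mixing", "TemporalModeSet",
          function(object) object@decomposition@mixing)

#' @rdname accessors
#' @export
setMethod("unmixing", "TemporalModeSet",
          function(object) object@decomposition@unmixing)

#' @rdname accessors
#' @export
setMethod("nComponents", "TemporalModeSet",
          function(object) ncol(object@decomposition@mixing))

setMethod("show", "TemporalModeSet", function(object) {
  cat(sprintf(
    "TemporalModeSet: %d temporal modes over %d regions (%d subjects)\n",
    nComponents(object), length(object@regionLabels),
    length(object@trainSubjects)))
  cat(sprintf("  converged: %s (%d iterations)\n",
              object@decomposition@converged,
              object@decomposition@nIterations))
})

# ---------------------------------------------------------------------------
# PermutationSet

#' PermutationSet: family-block-respecting permutations
#'
#' A set of subject-index permutations restricted to the family
#' exchangeability structure: members may be reordered within a family block,
#' and whole blocks may be exchanged only with blocks of equal size. The
#' identity permutation is always the first row.
#'
#' @slot perms integer matrix, permutations x subjects; row r holds the source
#'   index for each subject position, so permuted data are `x[perms[r, ]]`.
#' @slot blockIds character, family id per subject (defines the blocks).
#' @slot exhaustive logical, whether all admissible permutations are
#'   enumerated (no duplicates) rather than sampled.
#' @slot seed integer sampling seed.
#'
#' @seealso [generateBlockPermutations()], [permutationPvalue()]
#' @export
setClass("PermutationSet",
  representation(
    perms = "matrix",
    blockIds = "character",
    exhaustive = "logical",
    seed = "integer"
  )
)

setValidity("PermutationSet", function(object) {
  msg <- character()
  n <- length(object@blockIds)
  if (ncol(object@perms) != n)
    msg <- c(msg, "perms must have one column per subject")
  if (nrow(object@perms) < 1L ||
      !identical(as.integer(object@perms[1L, ]), seq_len(n)))
    msg <- c(msg, "first permutation must be the identity")
  if (length(msg)) msg else TRUE
})

#' Number of permutations in a PermutationSet
#' @param x a [PermutationSet-class].
#' @return integer count (identity included).
#' @export
setMethod("length", "PermutationSet", function(x) nrow(x@perms))

setMethod("show", "PermutationSet", function(object) {
  sizes <- table(table(object@blockIds))
  cat(sprintf("PermutationSet: %d permutations of %d subjects (%s)\n",
              nrow(object@perms), ncol(object@perms),
              if (object@exhaustive) "exhaustive" else "sampled"))
  cat("  block sizes:",
      paste(sprintf("%sx size %s", sizes, names(sizes)), collapse = ", "),
      "\n")
})

# ---------------------------------------------------------------------------
# AssociationResult

#' AssociationResult: profile-by-mode association table
#'
#' One row per (personality profile, temporal mode) pair with the
#' gender-adjusted partial correlation, the family-aware permutation p-value,
#' the BH-adjusted p-value and the significance flag.
#'
#' @slot results data.frame with columns `profile`, `mode`, `r`, `p`, `pAdj`,
#'   `significant`.
#' @slot nPermutations integer permutations used.
#' @slot seed integer permutation seed.
#' @slot blockDigest character summary of the family-block structure used.
#' @slot qThreshold numeric FDR threshold applied.
#'
#' @seealso [runAssociation()]
#' @export
setClass("AssociationResult",
  representation(
    results = "data.frame",
    nPermutations = "integer",
    seed = "integer",
    blockDigest = "character",
    qThreshold = "numeric"
  )
)

setValidity("AssociationResult", function(object) {
  r <- object@results
  msg <- character()
  need <- c("profile", "mode", "r", "p", "pAdj", "significant")
  if (!all(need %in% names(r))) {
    msg <- c(msg, paste("results needs columns:", paste(need, collapse = ", ")))
  } else {
    if (any(r$p <= 0 | r$p > 1)) msg <- c(msg, "p must lie in (0, 1]")
    if (any(r$pAdj < r$p - 1e-12)) msg <- c(msg, "adjusted p must be >= raw p")
    if (any(abs(r$r) > 1 + 1e-12)) msg <- c(msg, "r must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AssociationResult", function(object) {
  r <- object@results
  cat(sprintf(
    "AssociationResult: %d profile x mode tests (%d permutations, seed %d)\n",
    nrow(r), object@nPermutations, object@seed))
  sig <- r[r$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat(sprintf("  %d significant at q = %.2f:\n", nrow(sig),
                object@qThreshold))
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    profile %d x mode %2d: r = %+.3f, p = %.4g, pAdj = %.4g\n",
                  sig$profile[i], sig$mode[i], sig$r[i], sig$p[i], sig$pAdj[i]))
    }
  } else {
    cat(sprintf("  no pair significant at q = %.2f\n", object@qThreshold))
  }
})

#' Extract the association table
#' @param object an [AssociationResult-class].
#' @return data.frame with one row per profile x mode pair.
#' @export
associationTable <- function(object) {
  stopifnot(is(object, "AssociationResult"))
  object@results
}

# ---------------------------------------------------------------------------
# ReproducibilityReport

#' ReproducibilityReport: decomposition stability summary
#'
#' Per-component reproducibility of a decomposition under leave-one-out or
#' split-half resampling: the mean and SD of the matched absolute correlation
#' of each component with the full-sample solution and, for split-half, the
#' half-versus-half agreement.
#'
#' @slot componentStats data.frame with columns `component`, `meanAbsCor`,
#'   `sdAbsCor` and (split-half only) `meanHalfCor`, `sdHalfCor`.
#' @slot scheme character, "loo" or "split-half".
#' @slot nFolds integer folds/splits summarised.
#' @slot nExcluded integer folds dropped for non-convergence.
#' @slot seed integer resampling seed (split-half).
#'
#' @seealso [looStability()], [splitHalfStability()]
#' @export
setClass("ReproducibilityReport",
  representation(
    componentStats = "data.frame",
    scheme = "character",
    nFolds = "integer",
    nExcluded = "integer",
    seed = "integer"
  )
)

setValidity("ReproducibilityReport", function(object) {
  cs <- object@componentStats
  msg <- character()
  if (!all(c("component", "meanAbsCor", "sdAbsCor") %in% names(cs)))
    msg <- c(msg, "componentStats needs component, meanAbsCor, sdAbsCor")
  else if (any(cs$meanAbsCor < -1e-12 | cs$meanAbsCor > 1 + 1e-12,
               na.rm = TRUE) ||
           any(cs$sdAbsCor < -1e-12, na.rm = TRUE))
    # NA SDs are legal: a single usable fold has no spread
    msg <- c(msg, "matched correlations must lie in [0, 1] with SD >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReproducibilityReport", function(object) {
  cat(sprintf("ReproducibilityReport (%s, %d folds%s):\n", object@scheme,
              object@nFolds,
              if (object@nExcluded) sprintf(", %d excluded", object@nExcluded)
              else ""))
  print(transform(object@componentStats,
                  meanAbsCor = round(meanAbsCor, 3),
                  sdAbsCor = round(sdAbsCor, 3)), row.names = FALSE)
})

#' Extract per-component stability statistics
#' @param object a [ReproducibilityReport-class].
#' @return data.frame of per-component matched-correlation summaries.
#' @export
componentStats <- function(object) {
  stopifnot(is(object, "ReproducibilityReport"))
  object@componentStats
}
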