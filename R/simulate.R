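# Synthetic-data generator with planted ground truth: correlated five-factor
# scores from non-Gaussian latent profiles, ROI time series from latent mode
# time series with subject-varying engagement, family blocks and a planted
# profile-engagement coupling.

# NEO-FFI domain means/SDs of the emulated cohort (used when scores are
# mapped onto the 0-48 instrument scale).
.neoMeans <- c(N = 16.4, E = 30.6, O = 28.1, A = 32.1, C = 34.8)
.neoSds <- c(N = 7.15, E = 6.12, O = 6.11, A = 4.89, C = 5.73)

# Within-family sharing weight of latent personality sources.
.familyWeights <- c(singleton = 0, MZ = 0.8, DZ = 0.5)

#' Construct a SimulationConfig
#'
#' Defaults describe the emulated cohort: 471 subjects with family composition
#' 237 singletons / 142 MZ twins / 92 DZ twins, 277/471 female, and one hour
#' of resting-state data (4800 timepoints). Noise SDs are in latent
#' (unit-variance source) units.
#'
#' @param nSubjects number of subjects.
#' @param nTimepoints timepoints per subject.
#' @param noiseSdPersonality additive Gaussian noise SD on factor scores.
#' @param noiseSdTimeseries additive Gaussian noise SD on ROI series.
#' @param familyFractions named fractions (`singleton`, `MZ`, `DZ`) of
#'   subjects, summing to 1.
#' @param genderBalance fraction of female subjects.
#' @param seed master seed; every random draw of the generator derives from
#'   it.
#' @return a [SimulationConfig-class].
#' @examples
#' simulationConfig(nSubjects = 100, nTimepoints = 200, seed = 7)
#' @export
simulationConfig <- function(nSubjects = 471L,
                             nTimepoints = 4800L,
                             noiseSdPersonality = 0.1,
                             noiseSdTimeseries = 0.5,
                             familyFractions = c(singleton = 237, MZ = 142,
                                                 DZ = 92) / 471,
                             genderBalance = 277 / 471,
                             seed = 1L) {
  new("SimulationConfig",
      nSubjects = .checkCount(nSubjects, "nSubjects"),
      nTimepoints = .checkCount(nTimepoints, "nTimepoints", min = 2L),
      noiseSdPersonality = noiseSdPersonality,
      noiseSdTimeseries = noiseSdTimeseries,
      familyFractions = familyFractions,
      genderBalance = genderBalance,
      seed = .checkCount(seed, "seed", min = 0L))
}

#' Construct a GroundTruth
#'
#' @param profileMixing 5 x 5 full-rank matrix (factors x profiles).
#' @param spatialMixing 12 x 12 full-rank matrix (regions x modes).
#' @param couplings data.frame with columns `profile`, `mode`, `rho`
#'   (each `|rho| < 1`), or NULL for no planted coupling.
#' @param sourceFamily label of the latent source distribution.
#' @param seed integer provenance seed.
#' @return a [GroundTruth-class].
#' @seealso [defaultGroundTruth()]
#' @export
groundTruth <- function(profileMixing, spatialMixing,
                        couplings = NULL, sourceFamily = "exponential",
                        seed = 1L) {
  if (is.null(couplings)) {
    couplings <- data.frame(profile = integer(), mode = integer(),
                            rho = numeric())
  }
  pm <- .checkMatrix(as.matrix(profileMixing), "profileMixing", 5L, 5L)
  sm <- .checkMatrix(as.matrix(spatialMixing), "spatialMixing", 12L, 12L)
  if (qr(pm)$rank < 5L) {
    stop("profileMixing is rank deficient (rank ", qr(pm)$rank,
         " < 5); latent profiles would be unidentifiable", call. = FALSE)
  }
  if (qr(sm)$rank < 12L) {
    stop("spatialMixing is rank deficient (rank ", qr(sm)$rank,
         " < 12); latent modes would be unidentifiable", call. = FALSE)
  }
  if (nrow(couplings) && any(abs(couplings$rho) >= 1)) {
    stop("coupling strengths rho must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  rownames(pm) <- .factorNames
  rownames(sm) <- .regionLabels
  new("GroundTruth", profileMixing = pm, spatialMixing = sm,
      couplings = couplings, sourceFamily = sourceFamily,
      seed = .checkCount(seed, "seed", min = 0L))
}

# Qualitative profile patterns used to orient the default mixing: 1 general
# E+C synchrony, 2 E-vs-C contrast, 3 N with E/C contrast, 4 N with O/A
# contrast, 5 O-vs-A contrast.
.profilePattern <- function() {
  A <- cbind(
    c(-0.35, 0.70, 0.60, 0.65, 0.60),
    c( 0.00, 0.65, 0.10, 0.10, -0.65),
    c( 0.80, -0.35, 0.05, -0.15, -0.35),
    c( 0.55, 0.05, 0.30, -0.20, 0.05),
    c( 0.05, 0.10, 0.55, -0.40, 0.10))
  rownames(A) <- .factorNames
  A
}

# Target population factor correlations carrying the cohort's sign pattern:
# neuroticism negative with E/A/C, agreeableness positive with O/E/C,
# extraversion positive with C, at moderate magnitudes.
.targetFactorCorrelation <- function() {
  R <- diag(5)
  dimnames(R) <- list(.factorNames, .factorNames)
  pairs <- rbind(
    c("N", "E", -0.35), c("N", "O", 0.00), c("N", "A", -0.35),
    c("N", "C", -0.35), c("E", "O", 0.25), c("E", "A", 0.30),
    c("E", "C", 0.35), c("O", "A", 0.20), c("O", "C", 0.15),
    c("A", "C", 0.30))
  for (i in seq_len(nrow(pairs))) {
    R[pairs[i, 1L], pairs[i, 2L]] <- as.numeric(pairs[i, 3L])
    R[pairs[i, 2L], pairs[i, 1L]] <- as.numeric(pairs[i, 3L])
  }
  R
}

# Factors x profiles mixing constructed so that the population factor
# correlation equals .targetFactorCorrelation() exactly at the default score
# noise: A = sqrtm(R - sigma^2 I) rotated (orthogonal Procrustes) toward the
# interpretable profile patterns. Moderate conditioning (kappa ~ 2) keeps
# every latent profile identifiable.
.defaultProfileMixing <- function(noiseSd = 0.1) {
  C <- .targetFactorCorrelation() - diag(noiseSd^2, 5L)
  e <- eigen(C, symmetric = TRUE)
  sq <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  sv <- svd(crossprod(sq, .profilePattern()))
  A <- sq %*% (sv$u %*% t(sv$v))
  rownames(A) <- .factorNames
  A
}

# Blend a structured pattern matrix toward its closest orthogonal matrix
# (polar factor) and rescale columns to unit norm; moderates conditioning
# while keeping the qualitative pattern.
.orthBlend <- function(M, beta) {
  s <- svd(M)
  B <- beta * M + (1 - beta) * (s$u %*% t(s$v))
  sweep(B, 2L, sqrt(colSums(B^2)), "/")
}

# Regions x modes spatial mixing: structured mode patterns (precuneus-led
# posterior DMN; amygdala-hippocampus-mPFC-dACC; mPFC+dACC; dlPFC
# anticorrelated with DMN; bilateral subcortical) filled to full rank with a
# fixed dense jitter, columns scaled to unit norm. Dense columns keep
# within-subject z-scoring from absorbing single-mode variance changes.
.defaultSpatialMixing <- function(seed = 20260101L) {
  M <- matrix(0, 12L, 12L, dimnames = list(.regionLabels, NULL))
  M[c("PCu", "PCC"), 1L] <- c(0.9, 0.35)
  M[c("L_amygdala", "R_amygdala", "R_hippocampus", "mPFC", "dACC"), 2L] <-
    c(0.55, 0.55, 0.45, 0.4, 0.35)
  M[c("mPFC", "dACC"), 3L] <- c(0.7, 0.6)
  M[c("dlPFC", "mPFC", "PCC", "PCu"), 4L] <- c(0.9, -0.25, -0.25, -0.2)
  M[c("L_amygdala", "R_amygdala", "L_hippocampus", "R_hippocampus"), 5L] <-
    c(0.5, 0.5, 0.5, 0.5)
  M[c("insula", "dACC"), 6L] <- c(0.8, 0.4)
  M[c("OFC", "sgACC"), 7L] <- c(0.8, 0.4)
  M[c("sgACC", "mPFC"), 8L] <- c(0.8, 0.3)
  M[c("L_hippocampus", "PCC"), 9L] <- c(0.8, 0.3)
  M[c("PCC", "PCu", "mPFC"), 10L] <- c(0.7, 0.4, 0.3)
  M[c("dlPFC", "insula"), 11L] <- c(0.5, -0.6)
  M[c("OFC", "L_amygdala", "R_amygdala"), 12L] <- c(0.5, 0.4, -0.4)
  jitter <- .withSeed(seed, matrix(stats::rnorm(144, sd = 0.15), 12L, 12L))
  M <- .orthBlend(M + jitter, 0.35)
  rownames(M) <- .regionLabels
  M
}

#' Default planted ground truth
#'
#' Fixed, full-rank mixings emulating the qualitative structure reported for
#' the cohort (factor-correlation signs; a precuneus-dominated mode, a
#' subcortical-medial-prefrontal mode, a dlPFC mode anticorrelated with
#' default-mode regions), with one planted coupling between profile 5's
#' loading and mode 2's engagement.
#'
#' @param couplings planted couplings data.frame (default: profile 5 x mode 2
#'   at rho = 0.4); pass a zero-row data.frame or `NULL` via [groundTruth()]
#'   for a null model.
#' @return a [GroundTruth-class].
#' @export
defaultGroundTruth <- function(couplings = data.frame(profile = 5L,
                                                      mode = 2L,
                                                      rho = 0.4)) {
  groundTruth(.defaultProfileMixing(), .defaultSpatialMixing(),
              couplings = couplings, sourceFamily = "exponential",
              seed = 20260101L)
}

# Centered unit-variance exponential draws: skewed, strongly non-Gaussian,
# making the latent profiles identifiable by ICA.
.rSourceExp <- function(n) stats::rexp(n) - 1

# Unit-variance Laplace draws for latent mode time series (heavy-tailed,
# zero mean).
.rLaplace <- function(n) {
  u <- stats::runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

#' Simulate family structure
#'
#' Assigns subjects to family blocks: singletons, MZ twin pairs and DZ twin
#' pairs in (to rounding) the configured proportions. If the subject count is
#' too small to honour a requested twin fraction, all subjects become
#' singletons with a warning. Deterministic given the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame with columns `subject_id`, `family_id`, `zygosity`
#'   (one row per subject; twins of a pair share `family_id`).
#' @examples
#' fam <- simulateFamilies(simulationConfig(nSubjects = 20, seed = 3))
#' table(fam$zygosity)
#' @export
simulateFamilies <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nSubjects
  ff <- config@familyFractions
  nMZpairs <- round(ff[["MZ"]] * n / 2)
  nDZpairs <- round(ff[["DZ"]] * n / 2)
  if ((ff[["MZ"]] + ff[["DZ"]]) > 0 && nMZpairs + nDZpairs == 0) {
    warning("too few subjects to honour twin fractions; all singletons",
            call. = FALSE)
    nMZpairs <- nDZpairs <- 0
  }
  while (2 * (nMZpairs + nDZpairs) > n) {
    if (nDZpairs > 0) nDZpairs <- nDZpairs - 1 else nMZpairs <- nMZpairs - 1
  }
  nSingle <- n - 2 * (nMZpairs + nDZpairs)
  zygosityByFamily <- c(rep("singleton", nSingle), rep("MZ", nMZpairs),
                        rep("DZ", nDZpairs))
  sizeByFamily <- ifelse(zygosityByFamily == "singleton", 1L, 2L)
  nFam <- length(zygosityByFamily)
  ord <- .withSeed(config@seed, sample.int(nFam))
  zygosityByFamily <- zygosityByFamily[ord]
  sizeByFamily <- sizeByFamily[ord]
  familyIds <- sprintf("F%04d", seq_len(nFam))
  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    family_id = rep(familyIds, sizeByFamily),
    zygosity = rep(zygosityByFamily, sizeByFamily),
    stringsAsFactors = FALSE)
}

#' Simulate a five-factor personality table
#'
#' Draws per-subject latent profile sources i.i.d. from a centered
#' unit-variance exponential (non-Gaussian, as ICA identifiability requires),
#' mixes them through the ground-truth `profileMixing` and adds Gaussian
#' noise. Members of a twin pair share a family-level source with weight 0.8
#' (MZ) or 0.5 (DZ), so scores correlate within family. Gender is assigned at
#' family level per the configured balance. With `neoScale = TRUE` the raw
#' scores are mapped onto the NEO-FFI 0-48 instrument scale (cohort means/SDs,
#' rounded to integers, clamped); `neoScale = FALSE` returns the raw
#' continuous scores (useful for exact algebra on the generator itself).
#' Deterministic given the config seed.
#'
#' @param config a [SimulationConfig-class] (`nSubjects >= 10`).
#' @param truth a [GroundTruth-class].
#' @param neoScale logical; map scores onto the 0-48 NEO-FFI scale.
#' @return data.frame with columns `subject_id`, `family_id`, `zygosity`,
#'   `gender`, `N`, `E`, `O`, `A`, `C`. The latent source matrix (subjects x
#'   5 profiles) is attached as `attr(, "trueLoadings")`.
#' @examples
#' tab <- simulatePersonality(simulationConfig(nSubjects = 50, seed = 2),
#'                            defaultGroundTruth())
#' head(tab)
#' @export
simulatePersonality <- function(config, truth, neoScale = TRUE) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "GroundTruth"))
  validObject(config); validObject(truth)
  n <- config@nSubjects
  if (n < 10L) {
    stop("need at least 10 subjects; ICA on fewer is unidentifiable",
         call. = FALSE)
  }
  fam <- simulateFamilies(config)
  A <- truth@profileMixing

  out <- .withSeed(config@seed + 1L, {
    famIds <- unique(fam$family_id)
    famSource <- matrix(.rSourceExp(length(famIds) * 5L), ncol = 5L,
                        dimnames = list(famIds, NULL))
    w <- .familyWeights[fam$zygosity]
    indiv <- matrix(.rSourceExp(n * 5L), ncol = 5L)
    S <- w * famSource[fam$family_id, , drop = FALSE] +
      sqrt(1 - w^2) * indiv
    noise <- matrix(stats::rnorm(n * 5L, sd = config@noiseSdPersonality),
                    ncol = 5L)
    famFemale <- stats::setNames(
      stats::runif(length(famIds)) < config@genderBalance, famIds)
    list(S = S, noise = noise, female = famFemale[fam$family_id])
  })

  scores <- out$S %*% t(A) + out$noise
  colnames(scores) <- .factorNames
  if (neoScale) {
    # population SD of each factor column (marginal variance is unaffected
    # by the within-family sharing), so scaling leaks no sample information
    popSd <- sqrt(rowSums(A^2) + config@noiseSdPersonality^2)
    scores <- sweep(scores, 2L, popSd, "/")
    scores <- sweep(scores, 2L, .neoSds, "*")
    scores <- sweep(scores, 2L, .neoMeans, "+")
    scores <- pmin(pmax(round(scores), 0), 48)
  }
  tab <- cbind(
    fam,
    data.frame(gender = ifelse(out$female, "female", "male"),
               stringsAsFactors = FALSE),
    as.data.frame(scores))
  rownames(tab) <- NULL
  attr(tab, "trueLoadings") <- structure(
    out$S, dimnames = list(fam$subject_id, NULL))
  tab
}

#' Simulate per-subject ROI time series with planted engagement coupling
#'
#' For each subject, 12 latent mode time series are drawn i.i.d. from a
#' unit-variance Laplace distribution (optionally AR(1)-filtered), given
#' subject-varying variances, and mixed through the ground-truth
#' `spatialMixing` into 12 ROI series plus Gaussian noise. Every mode's
#' log-variance is `logVarSd` times a standard-normal subject effect; for
#' each planted coupling `(k, m, rho)` the mode-m effect is
#' `rho * z_k + sqrt(1 - rho^2) * noise`, where `z_k` is the standardised
#' profile-k loading, so the correlation between loading and log-engagement
#' is `rho` in population. Deterministic given the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @param truth a [GroundTruth-class].
#' @param profileLoadings subjects x 5 matrix of (true) profile loadings,
#'   e.g. `attr(simulatePersonality(...), "trueLoadings")`; row count must
#'   equal `config@nSubjects`.
#' @param subjectIds character subject ids (default taken from
#'   `rownames(profileLoadings)`).
#' @param logVarSd SD of the per-subject log-variance of each mode.
#' @param ar1 AR(1) coefficient of the latent mode series in `[0, 1)`; 0
#'   (default) gives i.i.d. samples.
#' @param keepLatent keep latent mode series and log-variances in
#'   `metadata` for recovery tests.
#' @return an [ROITimeSeriesSet-class]; when `keepLatent = TRUE` its
#'   `metadata` holds `latentSeries` (list of timepoints x 12 matrices),
#'   `logVariance` (subjects x 12) and `trueLoadings`.
#' @export
simulateROITimeseries <- function(config, truth, profileLoadings,
                                  subjectIds = rownames(profileLoadings),
                                  logVarSd = 0.5, ar1 = 0,
                                  keepLatent = TRUE) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "GroundTruth"))
  validObject(config); validObject(truth)
  profileLoadings <- as.matrix(profileLoadings)
  n <- config@nSubjects
  if (nrow(profileLoadings) != n) {
    stop(sprintf("profileLoadings has %d rows but config has %d subjects",
                 nrow(profileLoadings), n), call. = FALSE)
  }
  .checkMatrix(profileLoadings, "profileLoadings", ncol = 5L)
  if (nrow(truth@couplings) && any(abs(truth@couplings$rho) >= 1)) {
    stop("coupling rho outside (-1, 1)", call. = FALSE)
  }
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)", call. = FALSE)
  if (is.null(subjectIds)) subjectIds <- sprintf("S%05d", seq_len(n))
  nt <- config@nTimepoints
  M <- truth@spatialMixing

  .withSeed(config@seed + 2L, {
    # per-subject log-variance of each mode: standard-normal subject effects,
    # replaced by a loading-correlated effect for planted couplings
    eta <- matrix(stats::rnorm(n * 12L), n, 12L)
    if (nrow(truth@couplings)) {
      for (i in seq_len(nrow(truth@couplings))) {
        k <- truth@couplings$profile[i]
        m <- truth@couplings$mode[i]
        rho <- truth@couplings$rho[i]
        z <- as.vector(scale(profileLoadings[, k]))
        eta[, m] <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
      }
    }
    logVar <- logVarSd * eta
    series <- vector("list", n)
    latent <- if (keepLatent) vector("list", n) else NULL
    for (i in seq_len(n)) {
      S <- matrix(.rLaplace(nt * 12L), nt, 12L)
      if (ar1 > 0) {
        S <- apply(S, 2L, function(x) {
          stats::filter(x * sqrt(1 - ar1^2), ar1, method = "recursive")
        })
      }
      S <- sweep(S, 2L, exp(logVar[i, ] / 2), "*")
      X <- S %*% t(M) +
        matrix(stats::rnorm(nt * 12L, sd = config@noiseSdTimeseries), nt, 12L)
      colnames(X) <- .regionLabels
      series[[i]] <- X
      if (keepLatent) latent[[i]] <- S
    }
    md <- list(truthSeed = truth@seed)
    if (keepLatent) {
      md$latentSeries <- latent
      md$logVariance <- structure(logVar, dimnames = list(subjectIds, NULL))
      md$trueLoadings <- structure(profileLoadings,
                                   dimnames = list(subjectIds, NULL))
    }
    new("ROITimeSeriesSet", series = series,
        subjectIds = as.character(subjectIds),
        regionLabels = .regionLabels, metadata = md)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: personality table (with family blocks and gender),
#' matched ROI time series with the planted coupling driven by the table's
#' true latent loadings.
#'
#' @inheritParams simulateROITimeseries
#' @param neoScale passed to [simulatePersonality()].
#' @return list with `personality` (data.frame), `timeseries`
#'   ([ROITimeSeriesSet-class]) and `truth`.
#' @examples
#' sim <- simulateDataset(simulationConfig(nSubjects = 20, nTimepoints = 50,
#'                                         seed = 5),
#'                        defaultGroundTruth())
#' names(sim)
#' @export
simulateDataset <- function(config, truth = defaultGroundTruth(),
                            neoScale = TRUE, logVarSd = 0.5, ar1 = 0,
                            keepLatent = TRUE) {
  personality <- simulatePersonality(config, truth, neoScale = neoScale)
  loadings <- attr(personality, "trueLoadings")
  ts <- simulateROITimeseries(config, truth, loadings,
                              subjectIds = personality$subject_id,
                              logVarSd = logVarSd, ar1 = ar1,
                              keepLatent = keepLatent)
  list(personality = personality, timeseries = ts, truth = truth)
}
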