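# Personality profiles: ICA decomposition of the five NEO-FFI factor scores
# and projection of (possibly held-out) subjects onto the profiles.

.factorMatrix <- function(table) {
  missing <- setdiff(.factorNames, names(table))
  if (length(missing)) {
    stop("personality table lacks factor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(table[, .factorNames])
  if (anyNA(m)) stop("missing factor scores in personality table",
                     call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- table$subject_id
  m
}

#' Correlation matrix of the five personality factors
#'
#' Full Pearson correlation matrix of the N, E, O, A, C score columns (the
#' empirical inter-factor dependence that motivates decomposing the factors
#' into independent profiles).
#'
#' @param table personality data.frame with columns `N`, `E`, `O`, `A`, `C`.
#' @return symmetric 5 x 5 correlation matrix with unit diagonal.
#' @export
factorCorrelations <- function(table) {
  X <- .factorMatrix(table)
  if (nrow(X) < 3L) stop("need at least 3 subjects", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant factor column(s): ",
         paste(.factorNames[sds == 0], collapse = ", "), call. = FALSE)
  }
  stats::cor(X)
}

#' Derive independent personality profiles
#'
#' Z-scores the five factor columns and runs full-rank FastICA
#' (5 components), yielding five statistically independent personality
#' profiles: each profile is a weight pattern over the original factors, and
#' each subject receives a loading per profile (the estimated source scores).
#' On the training sample the loading columns are mutually uncorrelated by
#' construction (whitening).
#'
#' @param table personality data.frame (columns `subject_id`, `N`, `E`, `O`,
#'   `A`, `C`).
#' @param fun,alpha,tol,maxIter,seed,nRestarts FastICA options, see [fastICA()].
#' @return list with `profiles` (a [ProfileSet-class]) and `loadings`
#'   (subjects x 5 matrix, rownames = subject ids).
#' @examples
#' tab <- simulatePersonality(simulationConfig(nSubjects = 200, seed = 1),
#'                            defaultGroundTruth())
#' pr <- deriveProfiles(tab, seed = 1)
#' round(profileWeights(pr$profiles), 2)
#' @export
deriveProfiles <- function(table, fun = "logcosh", alpha = 1, tol = 1e-6,
                           maxIter = 1000L, seed = 1L, nRestarts = 4L) {
  X <- .factorMatrix(table)
  if (nrow(X) < 50L) {
    warning("fewer than 10 subjects per factor; profiles may be unstable",
            call. = FALSE)
  }
  cs <- centerAndScale(X)
  dec <- fastICA(cs$Z, nComponents = 5L, fun = fun, alpha = alpha, tol = tol,
                 maxIter = maxIter, seed = seed, nRestarts = nRestarts)
  ids <- if (!is.null(table$subject_id)) as.character(table$subject_id)
         else rownames(X)
  profiles <- new("ProfileSet", decomposition = dec, center = cs$means,
                  scale = cs$sds, factorNames = .factorNames,
                  trainSubjects = ids)
  loadings <- dec@sources
  dimnames(loadings) <- list(ids, paste0("profile", 1:5))
  list(profiles = profiles, loadings = loadings)
}

#' Profile weight matrix (factors x profiles)
#'
#' @param profiles a [ProfileSet-class].
#' @return 5 x 5 numeric matrix; rows = NEO factors, columns = profiles, in
#'   canonical order/sign.
#' @export
profileWeights <- function(profiles) {
  stopifnot(is(profiles, "ProfileSet"))
  W <- mixing(profiles)
  dimnames(W) <- list(profiles@factorNames, paste0("profile", 1:5))
  W
}

#' Project subjects onto derived personality profiles
#'
#' Standardises the factor scores of (new or training) subjects with the
#' *training* means and SDs stored in the [ProfileSet-class], then applies
#' the profile unmixing transform. Applied to the training table this
#' reproduces the training loadings to machine precision, which is what makes
#' leave-one-out projection of single held-out subjects well defined.
#'
#' @param table personality data.frame with the five factor columns.
#' @param profiles a [ProfileSet-class] from [deriveProfiles()].
#' @return subjects x 5 loading matrix (rownames = subject ids).
#' @export
projectSubjects <- function(table, profiles) {
  stopifnot(is(profiles, "ProfileSet"))
  X <- .factorMatrix(table)
  Z <- sweep(sweep(X, 2L, profiles@center, "-"), 2L, profiles@scale, "/")
  L <- Z %*% t(unmixing(profiles))
  dimnames(L) <- list(rownames(X), paste0("profile", 1:5))
  L
}
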