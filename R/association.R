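# Association machinery: gender-adjusted partial correlations between profile
# loadings and mode engagement, family-block-respecting Freedman-Lane
# permutation inference, and BH false-discovery-rate control.

# Coerce covariates (NULL / vector / factor / data.frame / matrix) to a
# numeric matrix with n rows; character and factor columns become 0/1 dummies.
.covariateMatrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), n, 0L))
  if (is.data.frame(covariates)) {
    covariates <- lapply(covariates, function(col) {
      if (is.character(col) || is.factor(col)) {
        as.numeric(factor(col)) - 1
      } else as.numeric(col)
    })
    covariates <- do.call(cbind, covariates)
  }
  if (is.character(covariates) || is.factor(covariates)) {
    covariates <- as.numeric(factor(covariates)) - 1
  }
  m <- as.matrix(covariates)
  storage.mode(m) <- "double"
  if (nrow(m) != n) {
    stop(sprintf("covariates have %d rows but data have %d", nrow(m), n),
         call. = FALSE)
  }
  m
}

.designQr <- function(covariates, n) {
  X <- cbind(intercept = rep(1, n), .covariateMatrix(covariates, n))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("covariate design is rank deficient after adding an intercept",
         call. = FALSE)
  }
  qrX
}

# Residual with (numerically) no variance left: correlations undefined.
.degenerateResidual <- function(resid, original) {
  stats::sd(resid) <= 1e-10 * max(stats::sd(original), 1)
}

#' Residualize a variable on covariates
#'
#' Least-squares residuals of `y` on an intercept plus the given covariates
#' (the "correcting for gender" step of the association analysis).
#'
#' @param y numeric subject vector.
#' @param covariates subject x c covariate matrix / data.frame / vector;
#'   `NULL` residualises on the intercept only (centering).
#' @return numeric residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  qrX <- .designQr(covariates, length(y))
  as.vector(qr.resid(qrX, y))
}

#' Partial Pearson correlation
#'
#' Pearson correlation between `x` and `y` after residualising *both* on the
#' covariates (plus intercept). With no covariates this is the plain Pearson
#' correlation.
#'
#' @param x,y numeric subject vectors.
#' @param covariates as in [residualize()].
#' @return scalar correlation in `[-1, 1]`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  nc <- if (is.null(covariates)) 0L else ncol(.covariateMatrix(covariates,
                                                               length(x)))
  if (length(x) < nc + 3L) {
    stop("need at least c + 3 observations for a partial correlation",
         call. = FALSE)
  }
  qrX <- .designQr(covariates, length(x))
  xr <- qr.resid(qrX, x)
  yr <- qr.resid(qrX, y)
  if (.degenerateResidual(xr, x) || .degenerateResidual(yr, y)) {
    stop("zero-variance residual; partial correlation undefined",
         call. = FALSE)
  }
  stats::cor(xr, yr)
}

# ---------------------------------------------------------------------------
# Block-respecting permutations

.blockIdsFrom <- function(blocks) {
  if (is(blocks, "PermutationSet")) return(blocks@blockIds)
  if (is.data.frame(blocks)) {
    if (is.null(blocks$family_id)) {
      stop("blocks data.frame needs a 'family_id' column", call. = FALSE)
    }
    return(as.character(blocks$family_id))
  }
  as.character(blocks)
}

# All permutations of seq_len(k) (small k only; enumeration is guarded by the
# admissible-permutation count).
.permn <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (sub in .permn(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(sub, k, after = pos - 1L)
    }
  }
  out
}

# Build one subject-index permutation from a block-slot assignment (per size
# class) and within-block orders. pos: list of subject positions per block.
.assemblePermutation <- function(pos, classes, classAssign, withinOrder) {
  n <- sum(lengths(pos))
  idx <- integer(n)
  for (s in seq_along(classes)) {
    blocksInClass <- classes[[s]]
    sigma <- classAssign[[s]]
    for (j in seq_along(blocksInClass)) {
      src <- blocksInClass[j]
      tgt <- blocksInClass[sigma[j]]
      idx[pos[[tgt]]] <- pos[[src]][withinOrder[[src]]]
    }
  }
  idx
}

#' Generate family-block-respecting permutations
#'
#' Draws subject-index permutations composed of (i) reorderings within each
#' family block and (ii) exchanges of whole blocks between blocks of equal
#' size — the exchangeability structure implied by family dependence. If the
#' number of admissible permutations is at most `nPerm` they are enumerated
#' exhaustively (no duplicates); otherwise `nPerm - 1` are sampled uniformly
#' with the seed. The identity is always the first permutation.
#'
#' @param blocks family structure: a data.frame with a `family_id` column or
#'   a character vector of family ids (one per subject, subject order).
#' @param nPerm requested number of permutations (identity included).
#' @param seed sampling seed.
#' @return a [PermutationSet-class].
#' @examples
#' ps <- generateBlockPermutations(c("a", "a", "b"), nPerm = 100, seed = 1)
#' length(ps)  # 2: within-pair swap only; unequal blocks never exchanged
#' @export
generateBlockPermutations <- function(blocks, nPerm, seed = 1L) {
  blockIds <- .blockIdsFrom(blocks)
  nPerm <- .checkCount(nPerm, "nPerm")
  seed <- .checkCount(seed, "seed", min = 0L)
  n <- length(blockIds)
  pos <- split(seq_len(n), factor(blockIds, levels = unique(blockIds)))
  sizes <- lengths(pos)
  classes <- split(seq_along(pos), sizes)  # block indices per size class

  logTotal <- sum(lfactorial(vapply(classes, length, 0L))) +
    sum(lfactorial(sizes))
  exhaustive <- logTotal <= log(nPerm)

  if (exhaustive) {
    classChoices <- lapply(classes, function(b) .permn(length(b)))
    withinChoices <- lapply(sizes, .permn)
    grid <- expand.grid(c(lapply(classChoices, seq_along),
                          lapply(withinChoices, seq_along)),
                        KEEP.OUT.ATTRS = FALSE)
    nc <- length(classChoices)
    perms <- t(apply(grid, 1L, function(row) {
      classAssign <- lapply(seq_len(nc),
                            function(s) classChoices[[s]][[row[s]]])
      withinOrder <- lapply(seq_along(withinChoices),
                            function(b) withinChoices[[b]][[row[nc + b]]])
      .assemblePermutation(pos, classes, classAssign, withinOrder)
    }))
    idIdx <- which(apply(perms, 1L, function(p) all(p == seq_len(n))))
    perms <- rbind(seq_len(n), perms[-idIdx, , drop = FALSE])
  } else {
    perms <- matrix(0L, nPerm, n)
    perms[1L, ] <- seq_len(n)
    .withSeed(seed, {
      for (r in 2:nPerm) {
        classAssign <- lapply(classes, function(b) sample.int(length(b)))
        withinOrder <- lapply(sizes, function(s) {
          if (s == 1L) 1L else sample.int(s)
        })
        perms[r, ] <- .assemblePermutation(pos, classes, classAssign,
                                           withinOrder)
      }
    })
  }
  storage.mode(perms) <- "integer"
  dimnames(perms) <- NULL
  new("PermutationSet", perms = perms, blockIds = blockIds,
      exhaustive = exhaustive, seed = seed)
}

#' Check that every permutation preserves family blocks
#'
#' @param permSet a [PermutationSet-class].
#' @return logical vector, one entry per permutation: `TRUE` when the
#'   permutation maps every family block onto a block of the same size.
#' @export
permutationsPreserveBlocks <- function(permSet) {
  stopifnot(is(permSet, "PermutationSet"))
  ids <- permSet@blockIds
  P <- permSet@perms
  sizes <- table(ids)
  ok <- rep(TRUE, nrow(P))
  for (b in unique(ids)) {
    cols <- which(ids == b)
    src <- matrix(ids[P[, cols, drop = FALSE]], nrow(P))
    sameSource <- rowSums(src == src[, 1L]) == length(cols)
    sizeMatch <- sizes[src[, 1L]] == length(cols)
    ok <- ok & sameSource & sizeMatch
  }
  unname(ok)
}

# ---------------------------------------------------------------------------
# Freedman-Lane permutation p-values

# Core Freedman-Lane statistics: given the covariate qr, the x residuals, the
# y residuals e, and the permutation index matrix (subjects x perms), return
# the partial correlation for every permutation (first = observed).
.freedmanLaneStats <- function(qrX, xres, e, idxMat) {
  E <- matrix(e[idxMat], nrow = nrow(idxMat))
  Eres <- qr.resid(qrX, E)
  as.vector(stats::cor(xres, Eres))
}

#' Family-aware permutation p-value (Freedman-Lane)
#'
#' Tests the partial correlation between `x` and `y` given covariates by the
#' Freedman-Lane scheme: `y` is residualised on the covariates, the residuals
#' are rearranged by each block-respecting permutation, the covariate fit is
#' re-added, and the partial correlation is recomputed. The two-sided p-value
#' uses the add-one convention
#' `p = (1 + #\{permuted |r| >= observed |r|\}) / (#non-identity + 1)`,
#' so p can never be 0.
#'
#' @param x,y numeric subject vectors.
#' @param covariates as in [residualize()].
#' @param perms a [PermutationSet-class] (identity first).
#' @return list with `p`, `r` (observed partial correlation) and `nPerm`
#'   (non-identity permutations used).
#' @export
permutationPvalue <- function(x, y, covariates = NULL, perms) {
  stopifnot(is(perms, "PermutationSet"))
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n, ncol(perms@perms) == n)
  if (nrow(perms@perms) < 100L) {
    warning(sprintf(
      "only %d permutations; p-value resolution floor is 1/%d",
      nrow(perms@perms), nrow(perms@perms)), call. = FALSE)
  }
  qrX <- .designQr(covariates, n)
  xres <- as.vector(qr.resid(qrX, x))
  e <- as.vector(qr.resid(qrX, y))
  if (.degenerateResidual(xres, x) || .degenerateResidual(e, y)) {
    stop("zero-variance residual; permutation test undefined", call. = FALSE)
  }
  stats <- .freedmanLaneStats(qrX, xres, e, t(perms@perms))
  obs <- stats[1L]
  p <- (1 + sum(abs(stats[-1L]) >= abs(obs))) / length(stats)
  list(p = p, r = obs, nPerm = length(stats) - 1L)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: p-values are sorted ascending, multiplied by
#' `m / rank`, monotonicity is enforced from the largest down, values are
#' capped at 1 and the original order restored.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values, same length and order.
#' @examples
#' fdrAdjust(c(0.005, 0.03, 0.04))  # 0.015 0.040 0.040
#' @export
fdrAdjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# ---------------------------------------------------------------------------
# Full profile x mode association

.alignRownames <- function(a, b, what) {
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    bad <- union(setdiff(rownames(a), rownames(b)),
                 setdiff(rownames(b), rownames(a)))
    stop(sprintf("subject ids of %s are misaligned%s", what,
                 if (length(bad)) paste0(": ",
                                         paste(utils::head(bad, 5L),
                                               collapse = ", "))
                 else " (same ids, different order)"),
         call. = FALSE)
  }
}

.blockDigest <- function(blockIds) {
  sizes <- table(table(blockIds))
  paste(sprintf("%dx size %s", as.integer(sizes), names(sizes)),
        collapse = ", ")
}

#' Profile-by-mode association with permutation inference and FDR
#'
#' Computes the gender-adjusted (or general covariate-adjusted) partial
#' correlation between every personality-profile loading and every temporal-
#' mode engagement, a family-aware Freedman-Lane permutation p-value for each
#' pair using one shared [PermutationSet-class], and BH-adjusted p-values
#' across all pairs (`fdrScope = "global"`, default) or within each profile.
#'
#' @param engagement subjects x modes engagement matrix.
#' @param loadings subjects x profiles loading matrix.
#' @param covariates as in [residualize()] (typically gender).
#' @param blocks family structure as in [generateBlockPermutations()], or a
#'   ready [PermutationSet-class].
#' @param nPerm permutations (identity included).
#' @param seed permutation sampling seed.
#' @param q FDR significance threshold.
#' @param fdrScope `"global"` (across all profile x mode tests) or
#'   `"per-profile"` (across the modes within each profile).
#' @return an [AssociationResult-class].
#' @export
runAssociation <- function(engagement, loadings, covariates = NULL, blocks,
                           nPerm = 10000L, seed = 1L, q = 0.05,
                           fdrScope = c("global", "per-profile")) {
  fdrScope <- match.arg(fdrScope)
  engagement <- as.matrix(engagement)
  loadings <- as.matrix(loadings)
  n <- nrow(engagement)
  if (nrow(loadings) != n) {
    stop("engagement and loadings have different subject counts",
         call. = FALSE)
  }
  .alignRownames(engagement, loadings, "engagement vs loadings")

  permSet <- if (is(blocks, "PermutationSet")) blocks
             else generateBlockPermutations(blocks, nPerm, seed)
  if (ncol(permSet@perms) != n) {
    stop("permutation set does not match the subject count", call. = FALSE)
  }
  qrX <- .designQr(covariates, n)
  idxMat <- t(permSet@perms)

  xresList <- lapply(seq_len(ncol(loadings)), function(k) {
    as.vector(qr.resid(qrX, loadings[, k]))
  })
  nProfiles <- ncol(loadings)
  nModes <- ncol(engagement)
  res <- expand.grid(profile = seq_len(nProfiles), mode = seq_len(nModes))
  res <- res[order(res$profile, res$mode), ]
  res$r <- NA_real_
  res$p <- NA_real_
  nNonId <- nrow(permSet@perms) - 1L
  for (m in seq_len(nModes)) {
    e <- as.vector(qr.resid(qrX, engagement[, m]))
    for (k in seq_len(nProfiles)) {
      stats <- .freedmanLaneStats(qrX, xresList[[k]], e, idxMat)
      row <- which(res$profile == k & res$mode == m)
      res$r[row] <- stats[1L]
      res$p[row] <- (1 + sum(abs(stats[-1L]) >= abs(stats[1L]))) /
        (nNonId + 1L)
    }
  }
  res$pAdj <- if (fdrScope == "global") {
    fdrAdjust(res$p)
  } else {
    stats::ave(res$p, res$profile, FUN = fdrAdjust)
  }
  res$significant <- res$pAdj < q
  rownames(res) <- NULL
  new("AssociationResult", results = res,
      nPermutations = nrow(permSet@perms), seed = permSet@seed,
      blockDigest = .blockDigest(permSet@blockIds), qThreshold = q)
}

#' Correlate profile loadings with a nuisance scalar
#'
#' Motion-style nuisance check: Pearson correlation of every profile loading
#' column with a per-subject nuisance scalar (e.g. root-mean-squared relative
#' displacement), with BH adjustment across the profiles.
#'
#' @param loadings subjects x profiles loading matrix.
#' @param nuisance numeric subject vector.
#' @return data.frame with columns `profile`, `r`, `p`, `pAdj`.
#' @export
correlateNuisance <- function(loadings, nuisance) {
  loadings <- as.matrix(loadings)
  nuisance <- as.numeric(nuisance)
  if (length(nuisance) != nrow(loadings)) {
    stop("nuisance vector does not match the number of subjects",
         call. = FALSE)
  }
  tests <- lapply(seq_len(ncol(loadings)), function(k) {
    ct <- stats::cor.test(loadings[, k], nuisance)
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(profile = seq_len(ncol(loadings)),
                    r = vapply(tests, `[[`, 0, "r"),
                    p = vapply(tests, `[[`, 0, "p"))
  # parametric p-values can underflow to exactly 0 (e.g. a self-correlation)
  out$pAdj <- fdrAdjust(pmax(out$p, .Machine$double.xmin))
  out
}
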