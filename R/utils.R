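# Internal helpers shared across modules.

#' @importFrom withr with_seed
.withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}

.checkCount <- function(x, name, min = 1L) {
  if (!.isWholeNumber(x) || x < min) {
    stop(sprintf("'%s' must be a whole number >= %d", name, min), call. = FALSE)
  }
  as.integer(round(x))
}

.checkMatrix <- function(x, name, nrow = NULL, ncol = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' contains missing or non-finite values", name),
         call. = FALSE)
  }
  if (!is.null(nrow) && nrow(x) != nrow) {
    stop(sprintf("'%s' must have %d rows (has %d)", name, nrow, nrow(x)),
         call. = FALSE)
  }
  if (!is.null(ncol) && ncol(x) != ncol) {
    stop(sprintf("'%s' must have %d columns (has %d)", name, ncol, ncol(x)),
         call. = FALSE)
  }
  invisible(x)
}

# Numerical rank via relative eigenvalue floor of the covariance spectrum.
.covRank <- function(eigenvalues, relFloor = 1e-10) {
  sum(eigenvalues > relFloor * max(eigenvalues))
}

.factorNames <- c("N", "E", "O", "A", "C")

.regionLabels <- c("L_amygdala", "R_amygdala", "L_hippocampus",
                   "R_hippocampus", "sgACC", "mPFC", "dACC", "PCC", "PCu",
                   "dlPFC", "insula", "OFC")
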