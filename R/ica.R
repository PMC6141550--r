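# FastICA core: eigen-whitening + symmetric fixed-point updates with
# symmetric decorrelation, shared by the personality-profile and
# temporal-mode decompositions.

#' Column-wise centering and scaling with reusable parameters
#'
#' Standardises each column to mean 0 and sample SD 1 (denominator n - 1) and
#' returns the transform parameters so held-out observations can be
#' standardised with the *training* parameters.
#'
#' @param X numeric matrix, samples x variables.
#' @return list with `Z` (standardised matrix), `means` and `sds` (numeric
#'   vectors of length `ncol(X)`).
#' @examples
#' cs <- centerAndScale(cbind(a = c(1, 2, 3), b = c(2, 0, 4)))
#' colMeans(cs$Z)  # ~0
#' apply(cs$Z, 2, sd)  # 1
#' @export
centerAndScale <- function(X) {
  X <- as.matrix(X)
  .checkMatrix(X, "X")
  if (nrow(X) < 2L) stop("need at least 2 rows to scale", call. = FALSE)
  means <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  Z <- sweep(sweep(X, 2L, means, "-"), 2L, sds, "/")
  list(Z = Z, means = means, sds = sds)
}

.contrast <- function(fun, alpha) {
  switch(fun,
    logcosh = list(
      g = function(u) tanh(alpha * u),
      gPrime = function(u) alpha * (1 - tanh(alpha * u)^2),
      G = function(u) log(cosh(alpha * u)) / alpha,
      # E[G(nu)] for nu ~ N(0,1), used by the negentropy proxy that ranks
      # restarts (value for alpha = 1; rescaled inside for other alpha)
      EGgauss = function() 0.3745672966),
    exp = list(
      g = function(u) u * exp(-u^2 / 2),
      gPrime = function(u) (1 - u^2) * exp(-u^2 / 2),
      G = function(u) -exp(-u^2 / 2),
      EGgauss = function() -1 / sqrt(2)),
    cube = list(
      g = function(u) u^3,
      gPrime = function(u) 3 * u^2,
      G = function(u) u^4 / 4,
      EGgauss = function() 0.75),
    stop("unknown nonlinearity: ", fun, call. = FALSE))
}

# Negentropy proxy sum_j (E[G(s_j)] - E[G(nu)])^2 used to pick the best of
# several fixed-point restarts (FastICA can converge to local optima).
.negentropyProxy <- function(S, ct, alpha, fun) {
  eg <- if (fun == "logcosh" && alpha != 1) {
    mean(log(cosh(alpha * stats::qnorm((1:2000 - 0.5) / 2000))) / alpha)
  } else ct$EGgauss()
  sum((colMeans(ct$G(S)) - eg)^2)
}

# Symmetric decorrelation: W <- (W W^T)^{-1/2} W
.symDecorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  if (min(e$values) < .Machine$double.eps * max(e$values)) {
    stop("degenerate unmixing matrix during decorrelation", call. = FALSE)
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values)) %*% W
}

#' Canonicalise ICA components (sign and order convention)
#'
#' ICA is ambiguous in component sign and order. The package's canonical form
#' orders components by descending variance explained in the input (sum of
#' squared mixing weights, sources having unit variance) and signs each mixing
#' column so its largest-magnitude entry is positive. Canonicalising twice is
#' a no-op.
#'
#' @param mixing variables x components matrix.
#' @param unmixing components x variables matrix.
#' @param sources samples x components matrix (optional).
#' @param whitener components x variables matrix (optional, reordered only).
#' @return list with the canonicalised `mixing`, `unmixing`, `sources`,
#'   `whitener`, plus the applied `order` and `signs`.
#' @export
canonicalizeComponents <- function(mixing, unmixing, sources = NULL,
                                   whitener = NULL) {
  ord <- order(colSums(mixing^2), decreasing = TRUE)
  mixing <- mixing[, ord, drop = FALSE]
  unmixing <- unmixing[ord, , drop = FALSE]
  signs <- vapply(seq_len(ncol(mixing)), function(j) {
    col <- mixing[, j]
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  }, 0)
  mixing <- sweep(mixing, 2L, signs, "*")
  unmixing <- unmixing * signs
  if (!is.null(sources)) {
    sources <- sweep(sources[, ord, drop = FALSE], 2L, signs, "*")
  }
  if (!is.null(whitener)) whitener <- whitener[ord, , drop = FALSE]
  list(mixing = mixing, unmixing = unmixing, sources = sources,
       whitener = whitener, order = ord, signs = signs)
}

#' FastICA by symmetric fixed-point iteration
#'
#' Self-contained FastICA (Hyvarinen fixed-point algorithm): the input is
#' whitened by eigendecomposition of its sample covariance, all component
#' weight vectors are updated in parallel with the chosen contrast
#' nonlinearity, and the weight matrix is symmetrically decorrelated via the
#' inverse matrix square root after every update. Iteration stops when the
#' maximum absolute change in weight-vector alignment (`1 - |<w_new, w_old>|`)
#' falls below `tol`, or at `maxIter` with `converged = FALSE` and a warning
#' (never silently). The result is canonicalised with
#' [canonicalizeComponents()] and is deterministic given `seed`.
#'
#' @param X numeric matrix, samples x variables; columns are centered
#'   internally (callers standardise as appropriate for their data).
#' @param nComponents number of components to extract (default full rank).
#' @param fun contrast nonlinearity: `"logcosh"` (default), `"exp"` or
#'   `"cube"`.
#' @param alpha logcosh slope parameter in `[1, 2]`.
#' @param tol convergence tolerance on weight alignment.
#' @param maxIter maximum fixed-point iterations.
#' @param seed integer seed for the random initial unmixing matrix; restart
#'   r uses `seed + r - 1`.
#' @param nRestarts number of seeded random restarts; the converged solution
#'   with the largest negentropy proxy is kept (the fixed-point iteration can
#'   converge to local optima).
#' @return an [ICADecomposition-class].
#' @examples
#' S <- cbind(runif(500, -sqrt(3), sqrt(3)), runif(500, -sqrt(3), sqrt(3)))
#' X <- S %*% matrix(c(1, 1, 0, 2), 2)
#' d <- fastICA(X, 2, seed = 1)
#' nComponents(d)
#' @export
fastICA <- function(X, nComponents = NULL, fun = c("logcosh", "exp", "cube"),
                    alpha = 1, tol = 1e-6, maxIter = 1000L, seed = 1L,
                    nRestarts = 4L) {
  X <- as.matrix(X)
  .checkMatrix(X, "X")
  fun <- match.arg(fun)
  maxIter <- .checkCount(maxIter, "maxIter")
  seed <- .checkCount(seed, "seed", min = 0L)
  nRestarts <- .checkCount(nRestarts, "nRestarts")
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more samples than variables (n > p)", call. = FALSE)
  if (is.null(nComponents)) nComponents <- p
  k <- .checkCount(nComponents, "nComponents")

  Xc <- sweep(X, 2L, colMeans(X), "-")
  covX <- stats::cov(Xc)
  e <- eigen(covX, symmetric = TRUE)
  rank <- .covRank(e$values)
  if (k > rank) {
    stop(sprintf(
      "requested %d components but input has numerical rank %d", k, rank),
      call. = FALSE)
  }
  d <- e$values[seq_len(k)]
  E <- e$vectors[, seq_len(k), drop = FALSE]
  whitener <- t(E) / sqrt(d)            # k x p
  Z <- Xc %*% t(whitener)               # n x k, cov(Z) = I

  ct <- .contrast(fun, alpha)
  best <- NULL
  for (restart in seq_len(nRestarts)) {
    W <- .withSeed(seed + restart - 1L, matrix(stats::rnorm(k * k), k, k))
    W <- .symDecorrelate(W)
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
      iter <- iter + 1L
      U <- Z %*% t(W)                   # n x k projections
      G <- ct$g(U)
      W1 <- crossprod(G, Z) / n - diag(colMeans(ct$gPrime(U)), k) %*% W
      W1 <- .symDecorrelate(W1)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    objective <- .negentropyProxy(Z %*% t(W), ct, alpha, fun)
    if (is.null(best) || (converged && !best$converged) ||
        (converged == best$converged && objective > best$objective)) {
      best <- list(W = W, converged = converged, iter = iter,
                   objective = objective)
    }
  }
  W <- best$W
  converged <- best$converged
  iter <- best$iter
  if (!converged) {
    warning(sprintf(
      "fastICA did not converge in %d iterations (all %d restarts)",
      maxIter, nRestarts), call. = FALSE)
  }

  unmix <- W %*% whitener                        # k x p on centered data
  sources <- Z %*% t(W)                          # n x k
  mix <- E %*% (sqrt(d) * t(W))                  # p x k
  can <- canonicalizeComponents(mix, unmix, sources)
  dimnames(can$mixing) <- list(colnames(X), NULL)

  new("ICADecomposition",
      mixing = can$mixing, unmixing = can$unmixing, sources = can$sources,
      whitener = whitener, nIterations = iter, converged = converged,
      tol = tol, seed = seed)
}
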