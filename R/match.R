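# Component-comparison utilities: Amari index, Hungarian assignment and
# sign/permutation matching of ICA components.

#' Amari performance index between two mixing matrices
#'
#' Computes the Amari index of `P = solve(A) %*% B`: rows and columns of
#' `|P|` are normalised by their maxima and the excess mass off the dominant
#' entry is summed, scaled by `1 / (2 k (k - 1))` so the index lies in
#' `[0, 1]`. It is 0 exactly when `P` is a scaled permutation, i.e. when the
#' two mixings agree up to component order, sign and scale.
#'
#' @param A,B square numeric matrices of equal size; `A` must be invertible.
#' @return non-negative scalar.
#' @examples
#' A <- diag(3)
#' amariIndex(A, A[, c(2, 3, 1)] %*% diag(c(-2, 1, 5)))  # 0
#' @export
amariIndex <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  k <- nrow(A)
  if (ncol(A) != k || !identical(dim(A), dim(B))) {
    stop("A and B must be square matrices of equal size", call. = FALSE)
  }
  if (rcond(A) < .Machine$double.eps * 100) {
    stop("A is numerically singular", call. = FALSE)
  }
  P <- abs(solve(A, B))
  rowPart <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  colPart <- sum(colSums(sweep(P, 2L, apply(P, 2L, max), "/")) - 1)
  (rowPart + colPart) / (2 * k * (k - 1))
}

# Hungarian algorithm (Kuhn-Munkres with potentials, O(k^3)) for a square
# cost matrix; returns for each row the assigned column, minimising total
# cost. Hand-rolled because no linear-assignment solver is among the
# package's dependencies; verified against brute-force enumeration in tests.
.solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}

.weightMatrix <- function(x) {
  if (is(x, "ICADecomposition")) return(x@mixing)
  if (is(x, "ProfileSet") || is(x, "TemporalModeSet")) return(mixing(x))
  as.matrix(x)
}

#' Match components between two decompositions
#'
#' Finds the one-to-one assignment of `other`'s components to `ref`'s that
#' maximises the summed absolute Pearson correlation between mixing columns
#' (Hungarian algorithm on `-|cor|`), together with the signs that make the
#' matched correlations non-negative. Used to undo ICA's inherent
#' permutation/sign ambiguity when comparing runs (e.g. resampling folds
#' against the full-sample solution).
#'
#' @param ref,other [ICADecomposition-class], [ProfileSet-class],
#'   [TemporalModeSet-class], or plain weight matrices (variables x
#'   components) with equal dimensions.
#' @return list with `permutation` (index into `other`'s components for each
#'   reference component), `signs` (+1/-1 per reference component) and
#'   `correlations` (matched absolute correlations).
#' @examples
#' W <- matrix(rnorm(25), 5)
#' m <- matchComponents(W, W[, 5:1] %*% diag(c(1, -1, 1, 1, -1)))
#' m$permutation  # 5:1
#' @export
matchComponents <- function(ref, other) {
  A <- .weightMatrix(ref)
  B <- .weightMatrix(other)
  if (!identical(dim(A), dim(B))) {
    stop("component weight matrices must have equal dimensions", call. = FALSE)
  }
  sdA <- apply(A, 2L, stats::sd)
  sdB <- apply(B, 2L, stats::sd)
  if (any(sdA == 0) || any(sdB == 0)) {
    stop("zero-variance weight column; components are degenerate",
         call. = FALSE)
  }
  C <- stats::cor(A, B)
  assignment <- .solveAssignment(-abs(C))
  matched <- C[cbind(seq_len(ncol(A)), assignment)]
  list(permutation = assignment,
       signs = ifelse(matched >= 0, 1, -1),
       correlations = abs(matched))
}

# Reorder/resign a decomposition so its components line up with a reference
# (per matchComponents against the reference's mixing).
.alignToReference <- function(refWeights, decomp) {
  m <- matchComponents(refWeights, decomp@mixing)
  initialize(decomp,
    mixing = sweep(decomp@mixing[, m$permutation, drop = FALSE], 2L,
                   m$signs, "*"),
    unmixing = decomp@unmixing[m$permutation, , drop = FALSE] * m$signs,
    sources = sweep(decomp@sources[, m$permutation, drop = FALSE], 2L,
                    m$signs, "*"))
}
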