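# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Benjamini-Hochberg step-up by direct application of the definition:
# sort ascending, multiply by m/rank, running minimum from the largest down,
# cap at 1, restore order.
bruteForceBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# All permutations of 1..k (recursive, independent of the package internals).
allPerms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in allPerms(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# Exhaustive best assignment maximising sum of |cor| between matched columns.
bruteForceAssignment <- function(A, B) {
  C <- abs(stats::cor(A, B))
  k <- ncol(A)
  best <- NULL
  bestVal <- -Inf
  for (p in allPerms(k)) {
    val <- sum(C[cbind(seq_len(k), p)])
    if (val > bestVal) {
      bestVal <- val
      best <- p
    }
  }
  best
}

# Exhaustive minimum-cost assignment (for checking the Hungarian solver).
bruteForceMinCost <- function(cost) {
  k <- nrow(cost)
  best <- NULL
  bestVal <- Inf
  for (p in allPerms(k)) {
    val <- sum(cost[cbind(seq_len(k), p)])
    if (val < bestVal) {
      bestVal <- val
      best <- p
    }
  }
  list(assignment = best, cost = bestVal)
}

# All subject-index permutations that preserve a family-block structure:
# filter the full symmetric group (tiny n only).
bruteForceBlockPerms <- function(blockIds) {
  n <- length(blockIds)
  sizes <- table(blockIds)
  keep <- Filter(function(p) {
    mapped <- blockIds[p]
    all(vapply(unique(blockIds), function(b) {
      src <- mapped[blockIds == b]
      length(unique(src)) == 1L && sizes[[src[1L]]] == sum(blockIds == b)
    }, FALSE))
  }, allPerms(n))
  keep
}

# Canonical string form of a permutation matrix for set comparison.
permKey <- function(perms) {
  apply(perms, 1L, paste, collapse = ",")
}

# Truth profile mixing expressed in the z-scored score space of a generated
# table (undoes the NEO instrument rescaling), for Amari / matching checks.
truthMixingStandardized <- function(tab, truth, noiseSd = 0.1) {
  neoSds <- c(N = 7.15, E = 6.12, O = 6.11, A = 4.89, C = 5.73)
  A <- truth@profileMixing
  popSd <- sqrt(rowSums(A^2) + noiseSd^2)
  D <- apply(as.matrix(tab[, c("N", "E", "O", "A", "C")]), 2L, stats::sd)
  A / (D * popSd / neoSds)
}

# Small valid personality table built by hand (scores inside 0-48).
tinyPersonalityTable <- function(n = 6L, seed = 42L) {
  withr::with_seed(seed, {
    data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      family_id = sprintf("F%02d", seq_len(n)),
      zygosity = "singleton",
      gender = rep(c("female", "male"), length.out = n),
      N = sample(5:40, n, replace = TRUE), E = sample(5:40, n, replace = TRUE),
      O = sample(5:40, n, replace = TRUE), A = sample(5:40, n, replace = TRUE),
      C = sample(5:40, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}
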