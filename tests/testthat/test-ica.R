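# FastICA core: standardisation, whitening/decorrelation invariants,
# recovery of non-Gaussian sources, canonical form.

test_that("centerAndScale standardises columns and returns reusable parameters", {
  cs <- centerAndScale(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
  expect_equal(cs$Z[, "a"], c(-1, 0, 1))
  expect_equal(unname(cs$means), c(2, 20))
  expect_equal(apply(cs$Z, 2L, sd), c(a = 1, b = 1))

  # hand-computed oracle: mean 5, sample SD sqrt(sum((x-5)^2)/7)
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  sdHand <- sqrt(sum((x - 5)^2) / 7)
  cs2 <- centerAndScale(cbind(x = x))
  expect_equal(cs2$means[["x"]], 5)
  expect_equal(cs2$sds[["x"]], sdHand)
  expect_equal(unname(cs2$Z[1L, "x"]), (2 - 5) / sdHand)
  expect_lt(abs(cs2$Z[1L, "x"] - (-1.403)), 1e-3)

  # idempotence on already-standardised input
  expect_equal(centerAndScale(cs$Z)$Z, cs$Z, tolerance = 1e-12)
})

test_that("centerAndScale rejects constant and missing columns by name", {
  X <- cbind(ok = c(1, 2, 3), flat = c(4, 4, 4))
  expect_error(centerAndScale(X), "flat")
  X2 <- cbind(a = c(1, NA, 3))
  expect_error(centerAndScale(X2), "missing")
})

test_that("fastICA recovers independent uniform sources (identity mixing)", {
  S <- withr::with_seed(7, matrix(runif(2000 * 2, -sqrt(3), sqrt(3)), 2000))
  d <- fastICA(S, 2, seed = 1)
  expect_true(d@converged)
  expect_lt(amariIndex(diag(2), d@mixing), 0.05)

  # independent oracle: brute-force grid over rotation angles of the
  # whitened data; the least-Gaussian orientation (max |excess kurtosis|)
  # must align with an estimated unmixing direction (mod 90 degrees)
  Z <- scale(S) %*% solve(chol(cov(scale(S))))
  angles <- seq(0, pi / 2, length.out = 361)
  kurt <- vapply(angles, function(a) {
    s <- Z %*% c(cos(a), sin(a))
    abs(mean(s^4) / mean(s^2)^2 - 3)
  }, 0)
  bestAngle <- angles[which.max(kurt)]
  west <- d@unmixing[1L, ] / sqrt(sum(d@unmixing[1L, ]^2))
  angEst <- atan2(west[2L], west[1L]) %% (pi / 2)
  diff <- min(abs(angEst - bestAngle), pi / 2 - abs(angEst - bestAngle))
  expect_lt(diff, 5 * pi / 180)
})

test_that("fastICA is deterministic given the seed", {
  X <- withr::with_seed(3, matrix(rexp(300 * 3) - 1, 300) %*%
                          matrix(c(1, .5, 0, .2, 1, .3, 0, .4, 1), 3))
  d1 <- fastICA(X, 3, seed = 11)
  d2 <- fastICA(X, 3, seed = 11)
  expect_identical(d1@mixing, d2@mixing)
  expect_identical(d1@unmixing, d2@unmixing)
  expect_identical(d1@sources, d2@sources)
})

test_that("estimated sources are decorrelated and mixing inverts unmixing", {
  X <- withr::with_seed(5, matrix(rexp(500 * 4) - 1, 500) %*%
                          (diag(4) + 0.3))
  d <- fastICA(X, 4, seed = 2)
  expect_true(d@converged)
  expect_equal(unname(cov(d@sources)), diag(4), tolerance = 1e-8)
  expect_equal(unname(d@unmixing %*% d@mixing), diag(4), tolerance = 1e-8)
})

test_that("pure Gaussian input is flagged unidentifiable or near-arbitrary", {
  X <- withr::with_seed(9, matrix(rnorm(1500 * 2), 1500))
  d <- suppressWarnings(fastICA(X, 2, seed = 1, maxIter = 200L))
  # either non-convergence is reported, or an (arbitrary) rotation returned;
  # sources must still be decorrelated
  expect_s4_class(d, "ICADecomposition")
  expect_equal(unname(cov(d@sources)), diag(2), tolerance = 1e-8)
})

test_that("rank-deficient input is rejected with the measured rank", {
  X <- withr::with_seed(1, matrix(rnorm(100 * 2), 100))
  X3 <- cbind(X, X[, 1L] + X[, 2L])
  expect_error(fastICA(X3, 3, seed = 1), "rank 2")
})

test_that("canonicalisation is idempotent and fixes sign/order", {
  X <- withr::with_seed(13, matrix(rexp(400 * 3) - 1, 400) %*%
                          matrix(rnorm(9), 3))
  d <- fastICA(X, 3, seed = 4)
  can <- canonicalizeComponents(d@mixing, d@unmixing, d@sources)
  expect_identical(can$order, 1:3)
  expect_identical(can$signs, c(1, 1, 1))
  expect_equal(can$mixing, d@mixing)
  # variance explained is non-increasing and top-magnitude entries positive
  expect_true(all(diff(colSums(d@mixing^2)) <= 1e-12))
  tops <- apply(d@mixing, 2L, function(col) col[which.max(abs(col))])
  expect_true(all(tops > 0))
})

test_that("five non-Gaussian sources are recovered across seeds", {
  A <- withr::with_seed(21, {
    M <- matrix(rnorm(25), 5)
    sv <- svd(M)
    sv$u %*% diag(seq(1.4, 0.7, length.out = 5)) %*% t(sv$v)
  })
  amaris <- vapply(1:20, function(i) {
    S <- withr::with_seed(500 + i, matrix(rexp(500 * 5) - 1, 500))
    d <- fastICA(S %*% t(A), 5, seed = i)
    amariIndex(A, d@mixing)
  }, 0)
  expect_gte(sum(amaris < 0.1), 18)
})
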