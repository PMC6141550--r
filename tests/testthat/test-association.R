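# Association machinery: residualisation, block permutations, Freedman-Lane
# p-values, BH-FDR, full profile x mode table, nuisance checks.

test_that("residualize matches hand-solved normal equations", {
  # 6-subject case solved independently via explicit normal equations
  y <- c(3.1, 4.5, 2.2, 6.0, 5.1, 3.9)
  z <- c(1.0, 2.0, 0.5, 3.0, 2.5, 1.5)
  X <- cbind(1, z)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize(y, z), as.vector(y - X %*% beta),
               tolerance = 1e-12)

  # covariate orthogonal to the centered outcome -> residuals = y - mean(y)
  y2 <- c(1, 2, 3, 4)
  z2 <- c(1, -1, -1, 1)
  expect_equal(residualize(y2, z2), y2 - mean(y2), tolerance = 1e-12)

  # outcome exactly linear in the covariate -> zero residuals
  expect_equal(residualize(2 * z + 1, z), rep(0, 6), tolerance = 1e-12)

  expect_error(residualize(y, cbind(z, z)), "rank deficient")
})

test_that("partialCorrelation reduces to Pearson r and removes shared variance", {
  x <- c(0.3, -1.2, 0.8, 2.1, -0.5, 1.4, 0.2, -0.9)
  y <- c(1.0, -0.8, 0.2, 1.9, -0.2, 1.1, 0.4, -1.2)
  expect_equal(partialCorrelation(x, x), 1)
  expect_equal(partialCorrelation(x, y), cor(x, y), tolerance = 1e-12)

  withr::with_seed(11, {
    g <- rnorm(500)
    x2 <- g + rnorm(500)
    y2 <- g + rnorm(500)
    expect_gt(cor(x2, y2), 0.3)
    expect_lt(abs(partialCorrelation(x2, y2, g)), 0.1)
  })
  expect_error(partialCorrelation(x, rep(1, 8)), "zero-variance")
})

test_that("block permutation sets match exhaustive enumeration", {
  cases <- list(
    list(blocks = c("a", "b", "c"), count = 6L),       # 3 singletons: 3!
    list(blocks = c("a", "a", "b", "b"), count = 8L),  # [2,2]: 2!*2!*2!
    list(blocks = c("a", "a", "b"), count = 2L))       # [2,1]: within swap only
  for (cs in cases) {
    ps <- generateBlockPermutations(cs$blocks, nPerm = 1000, seed = 1)
    expect_true(ps@exhaustive)
    expect_identical(nrow(ps@perms), cs$count)
    expect_identical(ps@perms[1L, ], seq_along(cs$blocks))
    expect_false(anyDuplicated(permKey(ps@perms)) > 0)
    oracle <- bruteForceBlockPerms(cs$blocks)
    expect_setequal(permKey(ps@perms),
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("sampled permutation sets respect blocks and are seed-stable", {
  blocks <- rep(sprintf("F%02d", 1:40), times = rep(c(1L, 2L), 20))
  ps <- generateBlockPermutations(blocks, nPerm = 200, seed = 7)
  expect_false(ps@exhaustive)
  expect_identical(nrow(ps@perms), 200L)
  expect_true(all(permutationsPreserveBlocks(ps)))
  ps2 <- generateBlockPermutations(blocks, nPerm = 200, seed = 7)
  expect_identical(ps@perms, ps2@perms)
  ps3 <- generateBlockPermutations(blocks, nPerm = 200, seed = 8)
  expect_false(identical(ps@perms, ps3@perms))
})

test_that("permutation p-values follow the add-one counting formula", {
  withr::with_seed(3, {
    x <- rnorm(40)
    y <- x + rnorm(40, sd = 0.1)        # overwhelming signal
  })
  blocks <- sprintf("s%02d", 1:40)
  ps <- generateBlockPermutations(blocks, nPerm = 100, seed = 2)
  res <- permutationPvalue(x, y, NULL, ps)
  expect_equal(res$p, 1 / 100)          # beats all 99 non-identity draws
  expect_gt(res$p, 0)                   # add-one: never exactly zero

  small <- generateBlockPermutations(c("a", "b", "c"), nPerm = 10, seed = 1)
  expect_warning(permutationPvalue(x[1:3], y[1:3], NULL, small),
                 "resolution")
})

test_that("Freedman-Lane observed statistic equals the partial correlation", {
  withr::with_seed(5, {
    x <- rnorm(60)
    y <- 0.4 * x + rnorm(60)
    g <- rep(0:1, 30)
  })
  ps <- generateBlockPermutations(sprintf("s%d", 1:60), nPerm = 500, seed = 3)
  res <- permutationPvalue(x, y, g, ps)
  expect_equal(res$r, partialCorrelation(x, y, g), tolerance = 1e-12)
})

test_that("fdrAdjust implements BH step-up (hand case and brute force)", {
  expect_equal(fdrAdjust(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(fdrAdjust(rep(1, 7)), rep(1, 7))
  expect_equal(fdrAdjust(0.2), 0.2)
  expect_error(fdrAdjust(c(0.1, 0)), "0, 1")
  for (i in 1:200) {
    p <- withr::with_seed(1000 + i, runif(sample(2:80, 1)))
    expect_equal(fdrAdjust(p), bruteForceBH(p), tolerance = 1e-12,
                 info = paste("vector", i))
  }
})

test_that("runAssociation produces a 5 x 12 table with valid inference fields", {
  withr::with_seed(9, {
    n <- 80
    L <- matrix(rnorm(n * 5), n, dimnames = list(sprintf("S%02d", 1:n), NULL))
    E <- matrix(rexp(n * 12), n, dimnames = list(sprintf("S%02d", 1:n), NULL))
    g <- rep(c("m", "f"), n / 2)
  })
  blocks <- rep(sprintf("F%02d", 1:50), times = c(rep(1L, 20), rep(2L, 30)))
  a <- runAssociation(E, L, covariates = g, blocks = blocks, nPerm = 300,
                      seed = 4)
  tab <- associationTable(a)
  expect_identical(nrow(tab), 60L)
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_true(all(tab$pAdj >= tab$p - 1e-12))
  expect_true(all(abs(tab$r) <= 1))
  # determinism
  a2 <- runAssociation(E, L, covariates = g, blocks = blocks, nPerm = 300,
                       seed = 4)
  expect_identical(associationTable(a2), tab)
})

test_that("misaligned subject ids are rejected with the offending ids", {
  L <- matrix(rnorm(40 * 5), 40, dimnames = list(sprintf("S%02d", 1:40), NULL))
  E <- matrix(rexp(40 * 12), 40,
              dimnames = list(sprintf("X%02d", 1:40), NULL))
  expect_error(runAssociation(E, L, blocks = sprintf("F%d", 1:40),
                              nPerm = 100),
               "misaligned")
})

test_that("correlateNuisance returns one BH-adjusted test per profile", {
  withr::with_seed(13, {
    L <- matrix(rnorm(400 * 5), 400)
    nuis <- rnorm(400)
  })
  out <- correlateNuisance(L, nuis)
  expect_identical(nrow(out), 5L)
  expect_true(all(abs(out$r) < 0.15))      # independent nuisance
  self <- correlateNuisance(L, L[, 3L])
  expect_equal(self$r[3L], 1)
  expect_error(correlateNuisance(L, nuis[1:10]), "does not match")
})
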