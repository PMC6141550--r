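# Personality profiles: factor correlations, ICA derivation, projection.

test_that("factorCorrelations has unit diagonal and flags degenerate input", {
  tab <- tinyPersonalityTable(8)
  R <- factorCorrelations(tab)
  expect_equal(unname(diag(R)), rep(1, 5))
  expect_equal(R, t(R))
  dup <- tab
  dup$E <- dup$N
  expect_equal(factorCorrelations(dup)["N", "E"], 1)
  flat <- tab
  flat$O <- 20
  expect_error(factorCorrelations(flat), "O")
})

test_that("synthetic cohort reproduces the observed correlation signs", {
  cfg <- simulationConfig(nSubjects = 500, seed = 14)
  tab <- simulatePersonality(cfg, defaultGroundTruth())
  R <- factorCorrelations(tab)
  expect_gt(R["E", "C"], 0)   # extraversion positively related to conscientiousness
  expect_gt(R["A", "O"], 0)
  expect_gt(R["A", "E"], 0)
  expect_gt(R["A", "C"], 0)
  expect_lt(R["N", "E"], 0)   # neuroticism negative with E, A, C
  expect_lt(R["N", "A"], 0)
  expect_lt(R["N", "C"], 0)
})

test_that("deriveProfiles recovers planted profiles at n = 500", {
  truth <- defaultGroundTruth()
  cfg <- simulationConfig(nSubjects = 500, seed = 25)
  tab <- simulatePersonality(cfg, truth)
  fit <- deriveProfiles(tab, seed = 2)
  expect_identical(ncol(fit$loadings), 5L)
  Atrue <- truthMixingStandardized(tab, truth)
  m <- matchComponents(Atrue, mixing(fit$profiles))
  expect_true(all(m$correlations >= 0.95))
  expect_lt(amariIndex(Atrue, mixing(fit$profiles)), 0.1)
  # training loadings are pairwise uncorrelated (whitening)
  C <- cor(fit$loadings)
  expect_true(all(abs(C[upper.tri(C)]) < 0.05))
})

test_that("each recovered profile loads on multiple factors when truth does", {
  truth <- defaultGroundTruth()
  # planted check: every truth profile has at least two sizeable weights
  expect_true(all(colSums(abs(truth@profileMixing) > 0.25) >= 2))
  cfg <- simulationConfig(nSubjects = 500, seed = 33)
  tab <- simulatePersonality(cfg, truth)
  fit <- deriveProfiles(tab, seed = 3)
  W <- profileWeights(fit$profiles)
  expect_true(all(colSums(abs(W) > 0.25 * apply(abs(W), 2, max)) >= 2))
})

test_that("projection reproduces training loadings and respects centering", {
  cfg <- simulationConfig(nSubjects = 120, seed = 6)
  tab <- simulatePersonality(cfg, defaultGroundTruth())
  fit <- deriveProfiles(tab, seed = 1)
  expect_equal(projectSubjects(tab, fit$profiles), fit$loadings,
               tolerance = 1e-12)
  # a subject sitting exactly at the training means projects to zero
  meanTab <- tab[1L, ]
  meanTab[, c("N", "E", "O", "A", "C")] <- as.list(fit$profiles@center)
  expect_equal(unname(projectSubjects(meanTab, fit$profiles))[1L, ],
               rep(0, 5), tolerance = 1e-12)
})

test_that("projection is row-wise consistent (affine map)", {
  cfg <- simulationConfig(nSubjects = 80, seed = 41)
  tab <- simulatePersonality(cfg, defaultGroundTruth())
  fit <- suppressWarnings(deriveProfiles(tab, seed = 1))
  whole <- projectSubjects(tab, fit$profiles)
  oneAtATime <- t(vapply(seq_len(nrow(tab)), function(i) {
    projectSubjects(tab[i, , drop = FALSE], fit$profiles)[1L, ]
  }, numeric(5)))
  expect_equal(unname(whole), unname(oneAtATime), tolerance = 1e-12)
})

test_that("held-out subjects project onto the true latent sources", {
  truth <- defaultGroundTruth()
  cfg <- simulationConfig(nSubjects = 700, seed = 55)
  tab <- simulatePersonality(cfg, truth)
  train <- tab[1:500, ]
  test <- tab[501:700, ]
  fit <- deriveProfiles(train, seed = 4)
  proj <- projectSubjects(test, fit$profiles)
  Strue <- attr(tab, "trueLoadings")[501:700, ]
  m <- matchComponents(Strue, proj)
  expect_true(all(m$correlations >= 0.9))
})

test_that("tables without the factor columns are rejected", {
  tab <- tinyPersonalityTable()
  tab$C <- NULL
  expect_error(deriveProfiles(tab), "C")
  fitTab <- tinyPersonalityTable(60)
  fit <- suppressWarnings(deriveProfiles(fitTab, seed = 1))
  expect_error(projectSubjects(tab, fit$profiles), "C")
})
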