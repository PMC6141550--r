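# Synthetic-data generator: family blocks, personality tables, ROI series,
# planted couplings, determinism.

identityTruth <- function(couplings = NULL) {
  groundTruth(diag(5), diag(12), couplings = couplings, seed = 1L)
}

test_that("family structure honours requested proportions", {
  cfgAllSingle <- simulationConfig(nSubjects = 50,
                                   familyFractions = c(singleton = 1, MZ = 0,
                                                       DZ = 0), seed = 1)
  fam <- simulateFamilies(cfgAllSingle)
  expect_equal(nrow(fam), 50L)
  expect_equal(length(unique(fam$family_id)), 50L)
  expect_true(all(fam$zygosity == "singleton"))

  # cohort composition: 237 singletons, 71 MZ pairs, 46 DZ pairs of 471
  cfg <- simulationConfig(nSubjects = 471, seed = 2)
  fam2 <- simulateFamilies(cfg)
  sizes <- table(table(fam2$family_id))
  expect_equal(unname(sizes[["1"]]), 237L)
  expect_equal(unname(sizes[["2"]]), 117L)
  expect_equal(sum(fam2$zygosity == "MZ"), 142L)
  expect_equal(sum(fam2$zygosity == "DZ"), 92L)
  # MZ/DZ labels only in blocks of size 2
  twinFam <- fam2$family_id[fam2$zygosity != "singleton"]
  expect_true(all(table(twinFam) == 2L))
})

test_that("family simulation is deterministic and warns when twins are infeasible", {
  cfg <- simulationConfig(nSubjects = 471, seed = 9)
  expect_identical(simulateFamilies(cfg), simulateFamilies(cfg))
  tiny <- simulationConfig(nSubjects = 12,
                           familyFractions = c(singleton = 0.92, MZ = 0.04,
                                               DZ = 0.04), seed = 1)
  expect_warning(fam <- simulateFamilies(tiny), "singleton")
  expect_true(all(fam$zygosity == "singleton"))
})

test_that("identity mixing with zero noise reproduces the latent sources", {
  cfg <- simulationConfig(nSubjects = 100, noiseSdPersonality = 0,
                          familyFractions = c(singleton = 1, MZ = 0, DZ = 0),
                          seed = 5)
  tab <- simulatePersonality(cfg, identityTruth(), neoScale = FALSE)
  S <- attr(tab, "trueLoadings")
  expect_equal(unname(as.matrix(tab[, c("N", "E", "O", "A", "C")])),
               unname(S), tolerance = 1e-12)
})

test_that("personality simulation is deterministic given the seed", {
  cfg <- simulationConfig(nSubjects = 60, seed = 77)
  t1 <- simulatePersonality(cfg, defaultGroundTruth())
  t2 <- simulatePersonality(cfg, defaultGroundTruth())
  expect_identical(t1, t2)
})

test_that("sample factor correlations match the closed-form covariance", {
  # cov(scores) = A A^T + sigma^2 I for unit-variance independent sources;
  # computed here independently from the truth slots
  truth <- defaultGroundTruth()
  sigma <- 0.1
  cfg <- simulationConfig(nSubjects = 500, noiseSdPersonality = sigma,
                          seed = 31)
  tab <- simulatePersonality(cfg, truth)
  A <- truth@profileMixing
  expectedR <- stats::cov2cor(A %*% t(A) + diag(sigma^2, 5))
  got <- factorCorrelations(tab)
  offDiag <- upper.tri(got)
  expect_true(all(abs(got[offDiag] - expectedR[offDiag]) < 0.1))
})

test_that("twin pairs have correlated scores, singletons less so", {
  cfg <- simulationConfig(nSubjects = 400, seed = 12)
  tab <- simulatePersonality(cfg, defaultGroundTruth())
  S <- attr(tab, "trueLoadings")
  mzFams <- unique(tab$family_id[tab$zygosity == "MZ"])
  prs <- t(vapply(mzFams, function(f) which(tab$family_id == f),
                  integer(2L)))
  withinCor <- cor(as.vector(S[prs[, 1L], ]), as.vector(S[prs[, 2L], ]))
  expect_gt(withinCor, 0.4)  # planted MZ sharing weight 0.8 -> cor 0.64
})

test_that("ROI series equal latent modes under identity mixing and no noise", {
  cfg <- simulationConfig(nSubjects = 12, nTimepoints = 40,
                          noiseSdTimeseries = 0, seed = 8)
  L <- withr::with_seed(1, matrix(rnorm(12 * 5), 12))
  ts <- simulateROITimeseries(cfg, identityTruth(), L)
  lat <- ts@metadata$latentSeries
  for (i in seq_len(12L)) {
    expect_equal(unname(ts@series[[i]]), unname(lat[[i]]), tolerance = 1e-12)
  }
})

test_that("ROI series have the contracted shape and subject alignment", {
  cfg <- simulationConfig(nSubjects = 15, nTimepoints = 200, seed = 3)
  tab <- simulatePersonality(cfg, defaultGroundTruth())
  ts <- simulateROITimeseries(cfg, defaultGroundTruth(),
                              attr(tab, "trueLoadings"),
                              subjectIds = tab$subject_id)
  expect_length(ts, 15L)
  expect_identical(dim(ts@series[[1L]]), c(200L, 12L))
  expect_identical(subjectIds(ts), tab$subject_id)
  expect_identical(ts@regionLabels[c(6, 9, 10)], c("mPFC", "PCu", "dlPFC"))
})

test_that("planted coupling links loadings to latent log-engagement", {
  truth <- defaultGroundTruth(data.frame(profile = 5L, mode = 2L, rho = 0.4))
  cfg <- simulationConfig(nSubjects = 400, nTimepoints = 120, seed = 21)
  L <- withr::with_seed(2, matrix(rexp(400 * 5) - 1, 400))
  ts <- simulateROITimeseries(cfg, truth, L)
  latentEng <- vapply(ts@metadata$latentSeries,
                      function(m) stats::var(m[, 2L]), 0)
  expect_lt(abs(cor(L[, 5L], log(latentEng)) - 0.4), 0.12)
})

test_that("generator rejects invalid inputs with clear diagnostics", {
  cfg <- simulationConfig(nSubjects = 20, seed = 1)
  expect_error(groundTruth(matrix(1, 5, 5), diag(12)), "rank deficient")
  expect_error(groundTruth(diag(5), diag(12),
                           couplings = data.frame(profile = 1L, mode = 1L,
                                                  rho = 1.2)),
               "rho")
  expect_error(
    simulatePersonality(simulationConfig(nSubjects = 5, seed = 1),
                        defaultGroundTruth()),
    "at least 10")
  L <- matrix(0, 7, 5)
  expect_error(simulateROITimeseries(cfg, defaultGroundTruth(), L),
               "7 rows")
})

test_that("the whole synthetic study is reproducible from one seed", {
  cfg <- simulationConfig(nSubjects = 20, nTimepoints = 30, seed = 99)
  s1 <- simulateDataset(cfg, defaultGroundTruth())
  s2 <- simulateDataset(cfg, defaultGroundTruth())
  expect_identical(s1$personality, s2$personality)
  expect_identical(s1$timeseries@series, s2$timeseries@series)
})
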