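# Temporal modes: standardisation, group ICA, projection, engagement.

# Time-series-only fixture: latent loadings drawn directly so tiny subject
# counts are allowed (no personality ICA involved).
smallTsSet <- function(nSubjects = 20, nTimepoints = 300, seed = 17) {
  truth <- defaultGroundTruth(NULL)
  cfg <- simulationConfig(nSubjects = nSubjects, nTimepoints = nTimepoints,
                          seed = seed)
  L <- withr::with_seed(seed + 1L,
                        matrix(rexp(nSubjects * 5) - 1, nSubjects))
  rownames(L) <- sprintf("S%05d", seq_len(nSubjects))
  list(timeseries = simulateROITimeseries(cfg, truth, L), truth = truth)
}

identityModeSet <- function(k = 12L) {
  dec <- new("ICADecomposition", mixing = diag(k), unmixing = diag(k),
             sources = matrix(numeric(0), 0, k), whitener = diag(k),
             nIterations = 0L, converged = TRUE, tol = 1e-6, seed = 1L)
  new("TemporalModeSet", decomposition = dec,
      regionLabels = tempica:::.regionLabels, trainSubjects = character())
}

test_that("within-subject standardisation gives exact unit variance", {
  sim <- smallTsSet(5, 50)
  std <- standardizeTimeseries(sim$timeseries)
  for (m in std@series) {
    expect_equal(unname(colMeans(m)), rep(0, 12), tolerance = 1e-12)
    expect_equal(unname(apply(m, 2, sd)), rep(1, 12), tolerance = 1e-12)
  }
  expect_equal(standardizeTimeseries(std)@series, std@series,
               tolerance = 1e-12)
  m3 <- matrix(c(1, 2, 3), 3, 12)
  expect_equal(
    tempica:::.standardizeMatrix(m3, "s")[, 1L], c(-1, 0, 1))
})

test_that("zero-variance regions are rejected naming subject and region", {
  sim <- smallTsSet(3, 30)
  sim$timeseries@series[[2L]][, 4L] <- 7
  expect_error(standardizeTimeseries(sim$timeseries),
               "R_hippocampus.*S00002")
})

test_that("ROI correlation matrix is a correlation matrix with the planted signs", {
  sim <- smallTsSet(30, 400, seed = 23)
  R <- roiCorrelationMatrix(sim$timeseries)
  expect_equal(unname(diag(R)), rep(1, 12))
  expect_equal(R, t(R))
  # default-mode regions couple positively; dlPFC anticorrelates with them
  expect_gt(R["mPFC", "PCC"], 0)
  expect_lt(R["dlPFC", "PCC"], 0)
  # duplicated region series correlate at 1
  dup <- sim$timeseries
  for (i in seq_along(dup@series)) dup@series[[i]][, 2L] <- dup@series[[i]][, 1L]
  expect_equal(roiCorrelationMatrix(dup)["L_amygdala", "R_amygdala"], 1)
})

test_that("deriveTemporalModes returns 12 canonical modes deterministically", {
  sim <- smallTsSet(15, 250, seed = 29)
  m1 <- deriveTemporalModes(sim$timeseries, seed = 2)
  m2 <- deriveTemporalModes(sim$timeseries, seed = 2)
  expect_identical(nComponents(m1), 12L)
  expect_identical(spatialWeights(m1), spatialWeights(m2))
  expect_identical(m1@decomposition@sources, m2@decomposition@sources)
})

test_that("rank-deficient region sets are rejected", {
  sim <- smallTsSet(10, 100, seed = 3)
  dup <- sim$timeseries
  for (i in seq_along(dup@series)) dup@series[[i]][, 2L] <- dup@series[[i]][, 1L]
  expect_error(deriveTemporalModes(dup, seed = 1), "rank")
})

test_that("projection reproduces group sources for training subjects", {
  sim <- smallTsSet(10, 150, seed = 31)
  modes <- deriveTemporalModes(sim$timeseries, seed = 1)
  proj <- projectModeTimeseries(sim$timeseries, modes)
  stacked <- do.call(rbind, proj)
  expect_equal(unname(stacked), unname(modes@decomposition@sources),
               tolerance = 1e-10)
})

test_that("identity mode weights return the standardised input", {
  sim <- smallTsSet(3, 60, seed = 37)
  modes <- identityModeSet()
  std <- standardizeTimeseries(sim$timeseries)
  out <- projectModeTimeseries(sim$timeseries@series[[1L]], modes)
  expect_equal(unname(out), unname(std@series[[1L]]), tolerance = 1e-12)
})

test_that("projection rejects mismatched region labels", {
  sim <- smallTsSet(3, 60, seed = 41)
  modes <- suppressWarnings(deriveTemporalModes(sim$timeseries, seed = 1))
  m <- sim$timeseries@series[[1L]]
  colnames(m) <- rev(colnames(m))
  expect_error(projectModeTimeseries(m, modes), "region labels")
})

test_that("engagement is the sample variance with denominator n - 1", {
  expect_equal(unname(computeEngagement(cbind(c(1, -1, 1, -1)))[1L, ]), 4 / 3)
  expect_equal(unname(computeEngagement(cbind(rep(2, 5)))[1L, ]), 0)
  m <- cbind(rnorm(20), rnorm(20))
  expect_equal(computeEngagement(m), computeEngagement(m + 10),
               tolerance = 1e-12)
})

test_that("subjects with amplified modes show higher engagement", {
  # doubled mode-1 amplitude for half the subjects, known mixing
  truth <- defaultGroundTruth(NULL)
  nt <- 250L
  series <- withr::with_seed(43, lapply(1:16, function(i) {
    S <- matrix(tempica:::.rLaplace(nt * 12L), nt, 12L)
    if (i <= 8L) S[, 1L] <- 2 * S[, 1L]
    X <- S %*% t(truth@spatialMixing) + matrix(rnorm(nt * 12L, sd = 0.5), nt)
    colnames(X) <- tempica:::.regionLabels
    X
  }))
  ts <- roiTimeSeriesSet(series, sprintf("S%02d", 1:16))
  modes <- deriveTemporalModes(ts, seed = 5)
  est1 <- matchComponents(truth@spatialMixing,
                          spatialWeights(modes))$permutation[1L]
  E <- engagementMatrix(ts, modes)
  expect_lt(stats::wilcox.test(E[1:8, est1], E[9:16, est1],
                               alternative = "greater")$p.value, 0.01)
})

test_that("permuting subject order permutes engagement rows identically", {
  sim <- smallTsSet(8, 120, seed = 47)
  modes <- deriveTemporalModes(sim$timeseries, seed = 1)
  E <- engagementMatrix(sim$timeseries, modes)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  Eperm <- engagementMatrix(sim$timeseries[perm], modes)
  expect_equal(Eperm, E[perm, ], tolerance = 1e-12)
})
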