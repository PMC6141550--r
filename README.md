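# tempica

Dual-ICA brain–behavior analysis in R: independent **personality profiles**
from five-factor (NEO-FFI) scores, **temporal functional modes** from
resting-state ROI time series, per-subject **engagement** of each mode, and
family-aware permutation inference linking the two — with leave-one-out /
split-half reproducibility machinery and a synthetic-data generator with
planted ground truth.

## The scientific problem

The five-factor model scores personality on neuroticism (N), extraversion
(E), openness (O), agreeableness (A) and conscientiousness (C). The factors
are conceptually distinct but empirically correlated, which muddies
interpretation when single factors are related to brain measures. The
approach implemented here decomposes the *joint* factor structure instead:

1. **Personality profiles.** Z-score the subjects × 5 score matrix X and run
   full-rank FastICA: X ≈ S Aᵀ, with A the 5 × 5 profile weight matrix and
   S the subjects × 5 loading matrix. Each profile is a weight pattern over
   all five factors (e.g. an O-vs-A contrast); each subject gets a loading
   per profile. New or held-out subjects are projected with the *training*
   standardisation and unmixing: s = W (x − μ)/σ.
2. **Temporal functional modes.** Z-score each subject's 12-region ROI time
   series within subject, concatenate all subjects along time, and run
   full-rank temporal ICA (time as samples): each mode is a spatial weight
   pattern over the ROIs with an independent time course.
3. **Engagement.** A subject's engagement of mode *m* is the sample variance
   of their mode-*m* time series — how strongly that co-activation pattern
   is expressed over the whole scan.
4. **Association.** For each (profile k, mode m) pair, the partial Pearson
   correlation between loading and engagement after residualising both on
   gender; significance by Freedman–Lane permutation (y-residuals permuted,
   covariate fit re-added) restricted to **family-exchangeable blocks**
   (members reorder within a family; only equal-size families exchange), and
   Benjamini–Hochberg FDR across the 5 × 12 = 60 tests.
5. **Validation.** Leave-one-out and split-half stability of both
   decompositions (components aligned with Hungarian matching on absolute
   weight correlations), and a fully out-of-sample association in which each
   subject's loading and engagement come from decompositions learned without
   that subject.

Real cohort data of this kind (e.g. Human Connectome Project resting-state
fMRI plus NEO-FFI) are access-controlled, so the package ships a generator
(`simulateDataset()`) that emulates the study: non-Gaussian latent profiles
mixed into correlated factor scores, Laplace latent mode series mixed into
ROI signals, twin-family blocks in realistic proportions, and a planted
log-linear coupling between one profile's loading and one mode's engagement.
Every stage is tested by recovering that ground truth.

## Worked example

```r
library(tempica)

cfg   <- simulationConfig(nSubjects = 300, nTimepoints = 300, seed = 42)
truth <- defaultGroundTruth()   # plants profile 5 ~ mode 2 at rho = 0.4
sim   <- simulateDataset(cfg, truth)

fit   <- deriveProfiles(sim$personality, seed = 1)
fit$profiles
#> ProfileSet: 5 personality profiles from 300 subjects
#>   converged: TRUE (33 iterations)
#>   profile weights (factors x profiles):
#>   profile1 profile2 profile3 profile4 profile5
#> N    -0.13     0.64     0.02     0.00     0.76
#> E     0.42    -0.62     0.65     0.07     0.06
#> O     0.70     0.28     0.16     0.62    -0.14
#> A     0.77     0.02     0.04    -0.57    -0.29
#> C     0.47    -0.57    -0.64     0.12     0.18

modes <- deriveTemporalModes(sim$timeseries, seed = 1)
E     <- engagementMatrix(sim$timeseries, modes)
assoc <- runAssociation(E, fit$loadings,
                        covariates = sim$personality$gender,
                        blocks     = sim$personality$family_id,
                        nPerm = 2000, seed = 1)
assoc
#> AssociationResult: 60 profile x mode tests (2000 permutations, seed 1)
#>   1 significant at q = 0.05:
#>     profile 4 x mode  1: r = +0.316, p = 0.0005, pAdj = 0.03
```

Reading the output: estimated profile 4 is (up to ICA's inherent sign/order
ambiguity) the planted O-vs-A-contrast profile, and estimated mode 1 is the
planted mode — `matchComponents()` against the ground truth confirms the
correspondence. The observed r = 0.32 is the planted ρ = 0.4 attenuated by
estimation noise, the exp-nonlinearity of the variance coupling, and the
within-subject normalisation. One flagged pair among 60 tests at q = 0.05 is
exactly the planted coupling.

Column-wise weights of each profile are read like the description above:
profile 4 contrasts O (+0.62) against A (−0.57); a subject with a strongly
positive loading is high-O/low-A, a negative loading the reverse.

## Layout

- `R/` — S4 classes (`ICADecomposition`, `ProfileSet`, `TemporalModeSet`,
  `ROITimeSeriesSet`, `PermutationSet`, `AssociationResult`, …) and the
  analysis functions.
- `tests/testthat/` — unit, property and acceptance tests (brute-force
  oracles for BH, assignment and block enumeration included).
- `vignettes/personality-modes.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical decisions, limitations.
- `inst/scripts/tempica.R` — thin command-line front end
  (`simulate` / `run` / `validate`).
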