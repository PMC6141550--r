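---
title: "Personality profiles, temporal functional modes, and their association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personality profiles, temporal functional modes, and their association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempica)
```

# The model

`tempica` implements a two-sided independent component analysis of
brain–behavior data. On the behavioral side, the five NEO-FFI domain scores
(neuroticism, extraversion, openness, agreeableness, conscientiousness) of a
cohort are treated as linear mixtures of five statistically independent
latent *personality profiles*: after per-factor z-scoring, the subjects × 5
score matrix is decomposed at full rank with FastICA, so each profile is a
5-vector of factor weights and each subject has one loading per profile. On
the imaging side, the mean time series of 12 regions of interest (amygdala
and hippocampus bilaterally, sgACC, mPFC, dACC, PCC, precuneus, dlPFC,
insula, OFC) are z-scored within subject, concatenated over subjects along
time, and decomposed at full rank with the same FastICA core — *temporal*
ICA, with timepoints as samples — yielding 12 *temporal functional modes*:
spatial weight patterns whose associated source series are maximally
independent over time.

A subject's *engagement* of a mode is the sample variance (denominator
n − 1) of that subject's mode time series, obtained by applying the group
unmixing transform to the subject's standardised data. Engagement is a
non-negative scalar per (subject, mode) summarising how strongly that
co-activation pattern was expressed over the subject's whole scan; it
deliberately ignores *when* the pattern was active (temporal dynamics such
as hidden-Markov state modeling are out of scope).

The association step asks, for each of the 5 × 12 profile–mode pairs,
whether subjects' profile loadings co-vary with their mode engagement. The
statistic is the partial Pearson correlation after residualising **both**
variables on gender (the symmetric reading of "corrected for gender").
Inference is by Freedman–Lane permutation: engagement is residualised on the
covariates, the residuals are rearranged by a family-structure-respecting
permutation, the covariate fit is re-added, and the statistic recomputed.
Two-sided p-values use the add-one convention
p = (1 + #{|r\*| ≥ |r|}) / (#non-identity + 1), so p is never exactly 0.
Benjamini–Hochberg FDR is then applied across all 60 tests (the stricter,
global reading; a per-profile scope is available via `fdrScope`).

## Family exchangeability blocks

Twin cohorts violate subject exchangeability: scores of monozygotic (MZ) and
dizygotic (DZ) twins are correlated within family. `generateBlockPermutations()`
therefore draws only permutations composed of (i) reorderings within a
family block and (ii) exchanges of whole blocks between families of equal
size. When the admissible set is small it is enumerated exhaustively
(e.g. blocks of sizes [2, 2] admit 2!·2!·2! = 8 permutations); otherwise
permutations are sampled uniformly under a seed, with the identity always
first. Finer multi-level schemes distinguishing MZ from DZ exchanges exist;
the size-preserving scheme used here is the conservative simplification and
is asserted (per permutation) in the tests.

# FastICA numerics

The FastICA core is self-contained and shared by both decompositions:

* **Whitening** by eigendecomposition of the sample covariance, retaining
  all requested components, with a relative eigenvalue floor of 1e-10 to
  detect numerically rank-deficient input (the measured rank is reported in
  the error).
* **Symmetric (parallel) fixed-point updates** with contrast `logcosh`
  (α = 1, the standard default; `exp` and `cube` are available), followed by
  symmetric decorrelation W ← (WWᵀ)^{-1/2} W after every update.
* **Convergence** when the maximum change in weight-vector alignment
  (1 − |⟨w_new, w_old⟩|) drops below `tol` (default 1e-6) within `maxIter`
  (default 1000); otherwise the result is returned with
  `converged = FALSE` and a warning — never silently.
* **Seeded restarts.** The unmixing matrix is initialised from a seeded
  standard normal. Fixed-point iteration with symmetric decorrelation can
  land in local optima or limit cycles — small skewed-source samples
  genuinely cycle, a behavior we reproduced with an independent reference
  implementation on identical input — so `nRestarts` (default 4)
  deterministic restarts are run (seeds `seed`, `seed + 1`, …) and the
  converged solution with the largest negentropy proxy
  Σ_j (E[G(s_j)] − E[G(ν)])² is kept.
* **Canonical form.** ICA leaves component sign and order undefined, so
  every decomposition is canonicalised: components sorted by descending
  variance explained, each mixing column signed so its largest-magnitude
  entry is positive. Canonicalisation is idempotent (tested).

Comparisons between decompositions use the Amari index (normalised to
[0, 1]; exactly 0 iff the two mixings differ by a scaled permutation) and
Hungarian assignment maximising summed absolute Pearson correlation between
mixing columns, with signs chosen to make matched correlations non-negative.
The Hungarian solver is written in-package and verified against exhaustive
enumeration for k ≤ 5.

# The synthetic cohort

Because the motivating data (HCP resting-state fMRI + NEO-FFI) are
access-controlled, the generator is a first-class module with planted ground
truth; all tests are parameter-recovery tests against it.

**What it emulates.** A cohort of 471 subjects (237 singletons, 71 MZ pairs,
46 DZ pairs; 59% female — the emulated cohort's composition), NEO-FFI scores
on the 0–48 instrument scale with the published cohort means/SDs, an hour of
resting-state data per subject (4800 timepoints) reduced to 12 ROI series.
Test and acceptance runs use smaller sizes (typically 40–500 subjects,
100–600 timepoints), chosen so the full suite runs in minutes on one core
while every recovery criterion remains comfortably identifiable.

**Latent structure.**

* Personality sources are i.i.d. centered unit-variance exponential draws —
  strongly skewed, since ICA identifiability requires non-Gaussianity and
  the real latent constructs are unobservable. Twins share a family-level
  source with weight 0.8 (MZ) or 0.5 (DZ) (conventional
  heritability-flavored defaults), giving within-pair score correlations of
  0.64 / 0.25 and making the family-block machinery consequential.
* The default 5 × 5 profile mixing is constructed from a *target* factor
  correlation matrix carrying the cohort's qualitative sign pattern (N
  negative with E/A/C; A positive with O/E/C; E positive with C) at moderate
  magnitudes: A = sqrtm(R − σ²I) rotated by orthogonal Procrustes toward
  interpretable profile patterns (E+C synchrony, E−C contrast, N with E/C
  contrast, N with O/A contrast, O−A contrast). This guarantees the
  population factor correlations equal the target exactly and keeps the
  mixing's condition number ≈ 1.9. A fundamental design tension is worth
  stating: inter-factor correlation *is* non-orthogonality of the mixing, so
  stronger correlations mean a worse-conditioned, harder-to-recover mixing;
  the chosen magnitudes balance the two.
* Score noise is additive Gaussian with σ = 0.1 (latent units). The method's
  own model — full-rank ICA on exactly five variables — is noise-free by
  construction, so the generator stays close to that model; the small noise
  term avoids an exactly singular idealisation.
* Latent mode series are i.i.d. unit-variance Laplace (heavy-tailed; an
  AR(1) option exists but temporal ICA does not rely on autocorrelation, and
  i.i.d. keeps variance targets analytic). The 12 × 12 spatial mixing embeds
  recognisable patterns — a precuneus-dominated posterior mode, an
  amygdala–hippocampus–mPFC–dACC mode, mPFC+dACC, a dlPFC mode opposed to
  default-mode regions, a bilateral subcortical mode — plus a fixed dense
  jitter, blended toward its polar orthogonal factor (condition number
  ≈ 2.4). Dense columns matter: with a sparse (near-identity) mixing,
  within-subject z-scoring would absorb any single-mode variance difference
  and engagement would be unrecoverable by construction.
* Every mode's per-subject log-variance is 0.5 × a standard-normal subject
  effect. A planted coupling (k, m, ρ) replaces the mode-m effect by
  ρ · z_k + √(1 − ρ²) · ε with z_k the standardised profile-k loading, so
  corr(loading, log-engagement) = ρ in population while engagement stays
  positive. The default truth plants profile 5 × mode 2 at ρ = 0.4. ROI
  noise is Gaussian with σ = 0.5 — a substantial noise floor, as ROI-mean
  fMRI series carry considerable scanner noise.

**What it does not emulate.** No hemodynamics, no autocorrelated BOLD
spectra by default, no motion artifacts (only an optional scalar nuisance
for `correlateNuisance()`), no voxel-level data, no site/run structure.
Passing recovery tests on this generator shows the pipeline's estimators and
inference behave correctly under the stated model — not that real fMRI
preprocessing choices are handled, which is upstream of this package's
interface.

# Normalisation decisions

* **"Normalized" scores** are per-factor z-scores (mean 0, sample SD 1,
  denominator n − 1). Held-out subjects are standardised with the *training*
  parameters — without this, projecting a single left-out subject would be
  undefined.
* **Subject projection** is standardised data × unmixingᵀ, i.e. the
  estimated source scores; on training data this reproduces the ICA sources
  exactly, which is the only reading that makes leave-one-out projection
  consistent.
* **ROI series** are z-scored within subject before concatenation. The
  alternative (raw concatenation) lets between-subject amplitude differences
  dominate the group ICA and contaminates engagement with global amplitude.
  The cost is a mild, quantifiable attenuation: a subject's elevated mode
  variance slightly inflates every region's SD, so z-scoring reclaims part
  of the signal (≈ 1/12 per region with a dense mixing) and the observed
  planted correlation lands near 0.33–0.36 rather than 0.40. A subtler
  consequence is *compensatory coupling*: inflating one mode's variance
  slightly deflates every other mode's normalised engagement, so with many
  strong planted couplings the nominally-null cells acquire weak negative
  associations. These are real features of the observables — the permutation
  test correctly detects them — which is why the FDR-control experiments
  plant effects at the observable level (exactly-null null cells) when the
  question is calibration of the inference machinery rather than generator
  physics.
* **Engagement** is computed over each subject's full series (one matrix per
  subject is the interface; per-run handling is the caller's concern), with
  denominator n − 1 fixed for test determinism.

# Inference decisions

* Freedman–Lane rather than raw-data shuffling, matching standard
  permutation-analysis practice for linear models with nuisance covariates.
* Two-sided tests; add-one p-values (p can never be 0; with N permutations
  the resolution floor is 1/N).
* FDR across all 60 tests by default. Note an interaction worth knowing
  when choosing `nPerm`: with m tests the smallest BH threshold is
  q/m (0.05/60 ≈ 0.00083), so a single true effect can only survive global
  BH if the permutation resolution 1/N reaches below it — N ≥ 1200 at these
  settings. With several true effects the step-up thresholds are larger and
  1000 permutations suffice. The association default is
  `nPerm = 10000` (configurable), which resolves well past the global
  BH floor.
* The 60 tests are univariate (each profile × mode pair tested separately);
  a multivariate per-profile regression is a possible alternative reading,
  not implemented.

# Reproducibility machinery

`looStability()` re-runs the full derivation (normalisation + ICA) with each
subject (or grouped fold) removed and matches every fold's components to the
full-sample solution; the full solution is the alignment reference for every
fold, preventing sign/order drift across hundreds of folds.
`splitHalfStability()` derives on two random halves — family blocks are
never split across halves, so twin dependence cannot leak — and reports both
half-vs-full and half-vs-half matched correlations (the latter is naturally
lower: each half has half the subjects). `looProjectionAssociation()` learns
both decompositions without the held-out subjects, aligns them to the
full-sample reference, projects the held-out subjects' scores and series,
and runs the association on the assembled out-of-sample values; a subject's
out-of-sample loading and engagement never use that subject's data in
training. Strict leave-one-out is the default; `foldSize > 1` gives the
grouped-fold approximation used in the test suite for speed.

Folds whose ICA does not converge are excluded with a warning (never
silently); small skewed-source samples can genuinely cycle, and a
decomposition that did not converge has no stable components to match.

# Known limitations

* FastICA on five variables with ~100 or fewer subjects is fragile: limit
  cycles and component splitting occur in a noticeable fraction of random
  cohorts even with restarts. The stability reports surface this honestly
  (excluded folds, lower matched correlations) rather than papering over it.
* Engagement, being a variance, cannot distinguish a mode that is
  moderately active throughout from one that alternates between strongly
  active and silent; temporal dynamics are explicitly out of scope.
* The generator's log-linear coupling between loading and engagement is a
  modeling choice (it keeps engagement positive and the coupling analytic);
  the underlying study motivating this pipeline specifies only that
  engagement correlates with loadings.
* Associations are correlational; nothing here supports directional or
  causal claims.

# Session info

```{r}
sessionInfo()
```
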