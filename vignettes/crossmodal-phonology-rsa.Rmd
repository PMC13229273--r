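---
title: "Cross-modal phonological RSA: models, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal phonological RSA: models, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonorsa)
```

## The scientific question and the analysis it requires

Does visual speech (speechreading) evoke neural representations of spoken
language *phonology* that are shared with other language forms — auditory
speech in hearing people, written text in deaf people — and does the strength
of that cross-modal alignment track reading ability? `phonorsa` implements
the full analysis pipeline needed to ask this question with multivariate
fMRI pattern analysis, plus a synthetic-data generator that plants known
representational structure so that every stage can be validated against a
recoverable ground truth.

The design rests on eight consonant-vowel-consonant words (`beam`, `beat`,
`boom`, `boot`, `real`, `reef`, `rule`, `roof`) forming a factorial phoneme
grid: initial consonant (/b/, /r/) crossed with vowel (/i:/, /u:/), final
consonant nested within initial. Each word appears in two stimulus types
(visual speech plus auditory speech for a hearing group, visual speech plus
letter-by-letter dynamic text for a deaf group) and two surface forms
(speakers or fonts), giving 32 conditions and 64 unique stimuli per group.

## Representational models

Three theoretical dissimilarity models are defined over all 496 unordered
condition pairs (`shared_phonemes_model()`, `sublexical_model()`,
`lexical_model()`):

* **Shared Phonemes** — dissimilarity = number of phoneme positions at which
  the two words differ (0-3). Mixes lexical identity and partial phoneme
  overlap.
* **Sublexical** (Shared Phonemes given Lexical) — same predictions, but all
  pairs carrying the same word (any form, any stimulus type) are excluded
  from evaluation, so a fit can only be driven by partial phoneme overlap
  between *different* words.
* **Lexical** — 0 for same-word pairs, 1 otherwise: purely identity-based
  similarity.

Model scale is irrelevant: model-data agreement uses Kendall tau-a, which
sees only ranks (an affine-invariance property the test suite asserts).
Integer predictions keep fixtures exact. We deliberately read "each word
with itself" in the Sublexical exclusion as *lexical* identity rather than
stimulus identity — the model's purpose is to remove all identity-driven
similarity, including across forms and modalities. `position_model()`
isolates single segment positions (initial/vowel/final), excluding same-word
pairs so position effects cannot ride on identity.

Distances are partitioned with `partition_mask()` into within-type pairs
(120 per stimulus type), combined within-type pairs (240) and across-type
pairs (256, treated as unordered). Evidence for *shared* representations
requires fits both within and across stimulus types.

## The crossnobis estimator

The quantitative core is the cross-validated Mahalanobis (crossnobis)
distance. Per run, condition patterns (GLM betas) are whitened by
`Sigma^(-1/2)`, where `Sigma` is the voxel noise covariance estimated from
GLM residuals and shrunk toward its diagonal
(`Sigma = (1 - lambda) S + lambda diag(S)`); the analytic optimal shrinkage
intensity (Schafer-Strimmer, diagonal target) is used unless fixed. The
distance for a condition pair is the mean over all ordered run pairs
`(m, n), m != n` of the inner product of the pair's whitened pattern
differences from the two runs, divided by the voxel count. Crossing
independent runs removes the positive bias of naive pattern distances: the
estimator has an interpretable zero, may go negative, and can be tested
against zero directly. Per-voxel normalisation makes values comparable
across searchlight spheres of different sizes (e.g. at mask edges).

The compiled searchlight core computes this with a Gram-matrix identity
(`sum_{m != n} B_m Sigma^-1 B_n' = T Sigma^-1 T' - sum_m B_m Sigma^-1 B_m'`
with `T = sum_m B_m`), which is algebraically exact; the test suite pins the
compiled path to the plain R implementation at 1e-10 and both to a literal
fold-pair loop.

## First-level model

`build_design_matrix()` models each run with 36 task regressors: 32
condition regressors (each the HRF-convolved boxcar of that condition's 4
stimulus trials), one target regressor per stimulus type (so every condition
regressor holds exactly 4 trials), a decision-cue regressor and a
button-press regressor; motion parameters and a session mean complete the
design. Null trials are unmodelled (implicit baseline). Events are convolved
on a 0.1 s microtime grid with a double-gamma HRF (response peak 6 s,
undershoot 16 s, peak:undershoot 6) and sampled at acquisition midpoints of
the sparse sequence (TR 3.95 s, 2.45 s acquisition, stimuli presented in the
silent gap). `fit_glm()` projects a discrete-cosine basis (periods > 350 s)
out of design and data, estimates a single pooled lag-1 residual
autocorrelation, prewhitens both sides with the AR(1) operator
(Cochrane-Orcutt, one iteration) and refits. A pooled scalar AR coefficient
is the simplest faithful choice where no more detailed convention is pinned
down; the whitening identity is tested on planted AR(1) noise.

## Searchlight mapping and cluster inference

`build_spheres()` enumerates a sphere (default radius 9 mm, about 3 voxels —
the radius is an exposed free parameter) around every in-mask voxel. For
each subject and sphere, the local residuals drive noise normalisation and
the full crossnobis RDM is computed. The cluster-defining statistic for
"regions carrying information" is the *conjunction* of the two stimulus
types: at every centre a one-sample t across subjects of the mean
within-type distance, per type, thresholded one-tailed at p < 0.001, with
both types required suprathreshold (minimum statistic). Suprathreshold
centres form 26-connectivity clusters. Cluster-level p-values come from a
subject sign-flip permutation (exhaustive `2^n` flips when below the cap,
else 10,000 random flips; the same flip is applied to both type maps to
preserve within-subject dependence) using the maximal-cluster-size null, and
are Benjamini-Hochberg corrected across clusters at q < 0.05. Sign flipping
is valid here because crossnobis values are symmetric about zero under the
null. One-tailed thresholds are used throughout: distances and model fits
are predicted positive.

`model_fit_searchlight()` implements the single-step variant: per centre,
Kendall tau-a between masked empirical distances and a model, Fisher-z
transformed.

## Group inference: the conditional two-step procedure

Within clusters surviving the searchlight stage, per-centre RDMs are
averaged over cluster members per subject (`cluster_average_rdms()`), and
`run_two_step()` executes the gated sequence: (1) Shared Phonemes fit in the
combined within-type distances, in every cluster; (2) only in clusters
passing step 1, the Shared Phonemes fit in the across-type distances; (3)
only in clusters passing step 2, the Sublexical and Lexical fits across
types; (4) for clusters with a significant across-type Sublexical fit,
per-type follow-ups. Each fit is tau-a per subject, Fisher-z transformed,
tested with a one-tailed one-sample t; the Bonferroni family at each step is
the number of clusters in which that model is tested at that step, not the
number of models. `d_z = t / sqrt(n)` is reported for every test (an exact
identity the suite asserts). Paired model comparisons are two-tailed.
`brain_behavior_corr()` correlates per-subject across-type Shared Phonemes
fits with reading scores (Pearson, one-tailed positive, `df = n - 2`).
`classical_mds()` (Torgerson double-centring via `stats::cmdscale`)
visualises the group-average representational space; negative crossnobis
estimates are clamped to zero with a warning, and only relative distances
within one solution are interpretable.

A note on tau-a and ties: a model predicting tied dissimilarities (all three
word-level models do) caps tau-a strictly below 1 even for data in perfect
rank agreement, because tied pairs stay in the denominator. Tests of
"perfect" agreement therefore assert agreement with the model's *maximal
achievable* tau-a (equivalently, tau-b = 1), not tau-a = 1.

## The synthetic-data generator

`generate_run_sequence()` reproduces the trial grammar of the paradigm: 170
trials of 3.95 s per run — 128 stimulus trials in two blocks of 64 (each
block a permutation of all 64 unique stimuli, no lexical word on consecutive
trials, enforced across the whole sequence including targets), 10 null
trials and 16 target-decision pairs. The first null opens the run; gaps
between successive nulls are drawn from a discretised normal (mean 17, sd 3)
truncated to [8, 26] — the observed spacing summary of the original design
is used as the generative rule, since the original sampler itself is not
documented; the bounds stay exposed in `paradigm_spec()`. Conditioning on
fitting inside the run biases the realised mean gap down by less than 0.15
of a trial. Target-pair spacing (mean 11, sd 2, clipped to [7, 14]) is a
soft constraint: collisions shift a pair forward. A session-wide Latin
square allocation makes every unique stimulus a target exactly once over the
four runs, balanced per run over words, forms and exemplars. An independent
validator (`check_run_sequence()`, `validate_session()`) re-checks every
invariant without sharing generator code.

`plant_condition_patterns()` composes true patterns in a spherical ROI from
independent standard-normal basis patterns: a shared phoneme basis (the
abstract-phonology signal, identical across stimulus types), per-modality
phoneme bases, a word-identity basis and a form basis, with weights in units
of the noise sd. The key analytic property — the expected squared distance
between two words is `2 w^2 (3 - shared) x ROI voxels` for the shared
component — is verified by Monte Carlo. Noise is AR(1) in time, spatially
smoothed with a variance-preserving Gaussian kernel, with an optional
low-rank shared component. `simulate_timeseries()` produces full sparse-
sampled 4D runs (HRF-convolved condition patterns, cosine drift, simulated
motion nuisance); `generate_cohort()` additionally supports a beta-level
mode that plants patterns plus correlated noise directly at the run x
condition level with matched synthetic residuals — the entry point the
replicate validation suites use, since it preserves everything the
searchlight consumes while skipping the (separately tested) GLM layer.

Between-subject structure: each subject draws an effect scale `g_s` from a
positive-truncated normal multiplying the shared-phonology weight, and a
reading score `alpha + beta g_s + e_s`; the convenience parameterisation
fixes the population correlation rho between effect scale and reading
(default 0.5) and the reading test's marginal mean and sd (34 and 4). Basis
patterns are drawn independently per subject: group inference generalises
over subjects, not over a shared pattern layout.

### Choosing the default effect size

The defaults `w_shared_phon = 0.05` and `effect_sd = 0.15` were fixed by
pilot simulation before the validation suites were frozen. Two desiderata
compete. Detection (the conjunction of mean within-type distances at
p < 0.001 with 12 subjects) must be reliable in a planted region; but the
same configuration drives the rank-based model fits, which are roughly
twice as sensitive and whose group t is further ceilinged only by
between-subject heterogeneity. No configuration makes detection reliable
while holding model-fit t near the low single digits; we chose reliable
detection (detection t about 8-11 at n = 12), accepting model-fit t
statistics (about 20 at n = 22) that are larger than those typical of real
data, where pattern noise, inter-subject anatomical variability and model
misspecification all shrink fits. This is the main sense in which passing
tests do *not* certify real-data behaviour: the generator emulates the
geometry, covariance structure and between-subject linkage of the design,
not the absolute signal-to-noise of BOLD data. It also does not emulate
anatomical variability, non-Gaussian artefacts, motion-correlated signal,
or misalignment between runs.

## Problem sizes used by the validation suites

The replicate suites run at desk scale, chosen once: recovery/dissociation
uses 50 shared-phonology and 20 lexical-only cohorts of 12 subjects on a
10^3 grid (ROI radius 2, searchlight radius 2 voxels); specificity uses 100
signal-free cohorts of 10 subjects on an 8^3 grid with 1,024 sign flips;
brain-behaviour recovery uses 20 cohorts of 25 subjects on a 6^3 grid with
an ROI-centred sphere; estimator correctness uses 1,000 random small
instances against a literal fold-pair oracle and 10^4 signal-free
replicates; spacing reproduction uses 1,000 generated runs. The default
20^3 geometry exercises the same code paths at the scale of the worked
examples.

## Numerical choices and degenerate inputs

* Shrinkage guarantees a positive-definite local covariance for any
  `lambda > 0`; exact zero-variance voxels fail loudly with the voxel named.
* The whitening operator is the symmetric inverse square root via
  eigendecomposition; non-positive-definite input is an error, not a silent
  pseudo-inverse.
* Correlations of exactly +-1 are clamped inward by machine epsilon before
  Fisher z, with a warning.
* `paired_t()` on identical samples returns t = 0, p = 1 by convention
  (the 0/0 limit); a constant nonzero one-sample vector is an error.
* Tau-a on constant model predictions is undefined in direction and is
  rejected explicitly.
* Rejection sampling in the sequence generator is bounded
  (`paradigm_spec(max_attempts = )`) and fails naming the constraint.
* All randomness flows through explicit seeds; identical seeds give
  bit-identical runs, cohorts and pipeline outputs, and sign-flip
  permutations are exhaustive (hence deterministic) whenever `2^n` is below
  the cap.

## Known limitations

Beyond the effect-size realism discussed above: the AR(1) coefficient is
pooled over voxels per run rather than voxel-wise or hyperparameterised;
cluster inference uses sign-flip permutation rather than random-field
theory, so p-values are resolution-limited at small n; the conjunction
statistic is the minimum of two t maps, which is conservative under
dependence; dynamic-text and auditory stimuli are modelled only through
their duration ranges; and the pipeline's real-data entry point expects
already-estimated per-run betas and residuals in standard volumetric format
(`read_beta_set()`) — raw-data preprocessing is out of scope.
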