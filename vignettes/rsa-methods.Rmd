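---
title: "Methods: second-order analysis of word-reading patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: second-order analysis of word-reading patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery:
the models, the estimators, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices a maintainer would want
written down.

## The question and the statistic

A region's multi-voxel response to each of $n$ word stimuli defines a
point cloud whose *pairwise geometry* — the representational
dissimilarity matrix (RDM) — can be compared against theoretical
geometries. Two theories are built in: orthographic form (edit
distance between letter strings) and meaning (distance between word
embedding coordinates). The comparison statistic is a second-order
correlation: the Spearman correlation between the vectorized neural
and model RDMs, with lexical-frequency and word-length dissimilarities
partialled out. Rank correlation is used because nothing links the two
dissimilarity scales linearly; the partialling removes nuisance
structure (short words are both visually similar and frequent) that
would otherwise masquerade as orthographic or semantic coding.

Vectorization takes the strictly lower triangle in row-major order —
a fixed convention so that every correlation in the package is
reproducible bit-for-bit. Partialling operates on ranks (average ranks
for ties): both rank vectors are residualized on the confound ranks by
least squares with an intercept, and the partial $\rho$ is the Pearson
correlation of the residuals. With no confounds this reduces exactly
to the textbook Spearman coefficient.

## Theoretical RDMs

**Orthographic distance.** The Levenshtein distance is generalized
with position-dependent costs: any insertion, deletion, or
substitution that consumes the *first or last* character position of
either string costs `w_edge` (default 2) instead of 1; matches cost 0.
The rationale is the robust finding that exterior letters dominate
visual word recognition, so words sharing initial and final letters
should count as closer than words sharing the same number of interior
letters. The weighting is a monotone generalization: at `w_edge = 1`
it is exactly the plain edit distance, and it never falls below it.
The exact functional form of edge-weighted edit distances varies
across the literature; this one was chosen because it is the minimal
dynamic-programming generalization with the stated properties, and it
is exposed as a single tunable cost.

**Semantic distance.** Embedding vectors are consumed as input (one
row per token); the package does not train embeddings. Euclidean
distance is the default reading of low-dimensional embedding spaces;
cosine distance is available for raw high-dimensional vectors whose
norms carry frequency rather than meaning.

**Confounds.** Frequency enters as $|\log_{10} f_i - \log_{10} f_j|$
(frequency effects in reading are approximately logarithmic), length
as $|l_i - l_j|$. When a single combined nuisance matrix is wanted,
`combine_confounds()` min-max scales each matrix to $[0,1]$ over its
off-diagonal entries before averaging — an average of raw matrices
would be dominated by whichever variable has the larger spread. The
default analysis instead partials the two confound RDMs individually,
which is strictly more flexible (two regression columns rather than
one).

**Design check.** `design_check()` tests the stimulus-selection
constraint that the orthographic and semantic model matrices be
uncorrelated: Spearman correlation plus a permutation p-value obtained
by relabeling conditions of one matrix (the exchangeable unit is the
condition, not the pair — pairs sharing a word are dependent). The
design passes when the correlation is *not* significant.

## Neural RDMs

Condition patterns are estimated per run by an ordinary least-squares
GLM: one canonical-HRF regressor per condition (pooling its
within-run repetitions), an intercept, and a discrete-cosine drift
basis realizing a 128 s high-pass cutoff
(`floor(2 * n_scans * TR / highpass)` columns). The HRF is the
conventional double-gamma (peak 6 s, undershoot 16 s, unit
dispersions, ratio 6, 32 s kernel), peak-normalized; regressors are
built on a TR/16 microtime grid and sampled at scan onsets. Baseline
(hash-mark) trials are deliberately left unmodeled: condition
estimates are converted to t-values against this implicit baseline,
which serves as the per-run noise normalization. No autocorrelation
model is applied — a stated limitation, acceptable here because the
estimator feeds a rank-based second-order analysis rather than
univariate inference.

The cross-validated Euclidean distance between conditions $a, b$ uses
independent runs for the two difference vectors, normalized by voxel
count so values are comparable across regions of different size.
Averaging over all ordered pairs of distinct runs (12 partitions for 4
runs) keeps the estimator unbiased: self-distances are zero in
expectation and entries can legitimately be negative. The `all_pairs`
scheme (16 partitions for 4 runs) additionally includes train==test
pairs; it is provided because some analyses count partitions that way,
but it reintroduces the positive bias of within-run distances and is
not the default. Voxels with zero variance across all samples
("dead" voxels) are removed first; the diagonal is stored as 0 and
never enters any correlation. No noise-covariance whitening is
applied; a multivariate-noise-normalized variant is a possible
extension, not a current feature.

## Group inference

Within each group and region, per-subject partial correlations are
tested against zero median with two-sided Wilcoxon signed-rank tests
(exact null for $n \le 25$ without ties in $|\rho|$, normal
approximation with continuity correction otherwise; exact zeros are
dropped — Wilcoxon's original rule — and reported). P-values are
converted to q-values by Benjamini–Hochberg FDR within each
(group, region) family across the model dimension — the family is
deliberately small (the tested theories), with a `pooled` option for
users who prefer one family per test type. Between-group contrasts
default to the pooled-variance t-test, with Wilcoxon rank-sum as an
alternative.

Factorial questions (does the group difference depend on the model?
is there a posterior-to-anterior gradient?) use `fit_factorial()`:
ordinary least squares with Type II sums of squares, which test each
term after every other term at its level and do not depend on term
order — the appropriate choice for mildly unbalanced group sizes.
Tukey-adjusted pairwise cell contrasts come from the fitted model's
residual variance via `tukey_posthoc()`. The mixed repetition ANOVA
(`repetition_anova()`) uses the classical univariate decomposition —
Group against subjects-within-group, Repetition and the interaction
against the repetition-by-subject stratum — with no sphericity
correction, and reports its own degrees of freedom.

Behavioral utilities follow the published conventions: efficiency
score $(\text{accuracy}/\text{RT}) \times 10$; single-pass per-subject
RT trimming at mean $\pm\,2.5$ SD (no re-iteration, since trimming
rules that iterate remove progressively more data); Cohen's d and the
t statistic from group summaries with the pooled-SD definition, signed
as (clinical group − control) so deficits are negative.

## The synthetic-data generator

The generator exists to answer one question: *if* a region's geometry
were a known mixture of the orthographic and semantic models, would
the pipeline recover it, and does it stay silent when a component is
absent? It emulates the structure of a word-reading experiment: 33
words in 2 semantic categories, 4 runs, 3 repetitions per word per run
plus as many baseline trials (136 trials per run at 34 words), TR
1.23 s, and per-region pattern matrices of 150 voxels.

Construction proceeds in four steps:

1. **Word set.** Random letter strings with lengths drawn around a
   mean of 6.85 (SD 1.7, clipped to 2–10) and log-normal frequencies
   (meanlog 2.7, sdlog 1.1, clipped to 1–150 per million) — matching
   the descriptive statistics typical of word-reading stimulus sets.
   Orthographic neighbour pairs (single interior-letter substitutions)
   are planted *across* category boundaries so orthographic and
   semantic similarity cut across each other. Embeddings are
   category-centered Gaussian clusters (centers SD 2, within-cluster
   SD 1, dimension 2), giving the semantic RDM category structure.
   Embeddings are redrawn until the confound-partialled orth–sem
   Spearman correlation satisfies $|\rho| \le$ `rho_max` (default
   0.01) — the generator's realization of the stimulus-selection
   constraint that the two model matrices be uncorrelated. The
   threshold is deliberately an order of magnitude below subject-level
   sampling variability of $\rho$ (about 0.09 SD at the default noise),
   so that residual model overlap cannot masquerade as a group-level
   effect; with looser thresholds the null-model test becomes visibly
   anticonservative.
2. **Geometry.** The target RDM is
   $D^\* = w_\text{sem}\,D_\text{sem}/\max(D_\text{sem}) + w_\text{orth}\,D_\text{orth}/\max(D_\text{orth})$,
   embedded in `latent_dim` = 8 dimensions by classical (Torgerson)
   MDS and rescaled to unit mean squared row norm. Components are
   scaled by their *maximum* dissimilarity rather than min-max:
   subtracting the minimum shifts all distances and destroys Euclidean
   embeddability even for a perfectly embeddable component, and the
   resulting eigenvalue clipping distorts the planted geometry; pure
   scaling reproduces a single-component mixture exactly. Negative
   eigenvalue mass of genuinely mixed targets is clipped — by design,
   not by accident — and latent distances rank-correlate with $D^\*$
   above 0.95 at these settings.
3. **Patterns.** One fixed random linear map per subject sends the
   latent coordinates to voxel space; the map is shared across runs so
   cross-validated distances estimate the latent geometry without
   bias. Independent Gaussian noise (SD `noise_sd`) is added per run.
4. **BOLD (optional).** `simulate_bold()` generates scan-by-voxel
   series as HRF-convolved condition regressors weighted by amplitude
   patterns plus white noise — exactly the forward model the GLM
   inverts, so the noiseless round trip through `fit_glm()` recovers
   amplitudes to machine precision.

`noise_sd = 8` (relative to per-voxel signal variance of roughly 1) is
the package's definition of a realistic regime: it yields subject-level
second-order correlations of about 0.1–0.4 against the planted model
with an across-subject SD near 0.09, the magnitude such analyses
produce in practice. Much cleaner settings make every test trivially
significant and — more subtly — let wordset-level residual model
overlap dominate subject noise, which inflates false positives.

All randomness flows from a single seed; subject and replicate seeds
are derived deterministically (a fixed large-prime stride modulo
$2^{31}-1$), so a configuration reproduces its dataset byte-for-byte.

## Calibration, recovery, and power

Three canned experiments (`null_calibration()`, `recovery_grid()`,
`separation_power()`) each simulate replicate groups with fresh word
sets. The package's own test suite runs them at the following sizes,
chosen to make Monte-Carlo error small relative to the quantities
checked: 500 replicate groups of 20 subjects for the type-I rate of
the orthographic null, 50 replicate grids over
$w_\text{sem} \in \{0.2, 0.5, 0.8\}$ for monotone recovery, and 40
replicates for group-separation power.

The recovery grid is *paired*: within a replicate, one word set is
shared by all three mixture weights, so the comparison is made at
fixed stimulus conditions and between-wordset variability does not
blur the ordering (unpaired grids are strictly ordered only ~90% of
the time; paired grids essentially always).

The power threshold for the two-group design ($w_\text{sem}$ 0.8 vs
0.4, n = 20 per group) is frozen at 0.65, set from a 100-replicate
pilot estimate of 0.77 minus three Monte-Carlo standard errors.

## Known limitations

- **Mild type-I anticonservatism.** Even with the decorrelation
  constraint, wordset-level couplings between the neural-RDM noise
  distortion and the orthographic model leave a replicate-level bias
  of SD ≈ 0.005 on the $\rho$ scale; the empirical null rejection
  rate at $\alpha = 0.05$ is about 0.05–0.07 rather than exactly 0.05.
  Analyses that need exact control should permute condition labels.
- The generator's noise is white: no temporal autocorrelation, drift,
  or motion structure, no spatial noise correlations, and no
  anatomical ROI geometry. Passing calibration here shows the
  *estimators* behave; it does not certify behaviour under structured
  fMRI noise.
- Baseline trials are a nuisance condition only; their content is not
  modeled.
- The GLM has no prewhitening and no nuisance regressors beyond drift;
  it is a pattern estimator, not a univariate inference engine.
- `classical_mds()` clips negative eigenvalues; for strongly
  non-Euclidean RDMs the embedded geometry is an approximation (the
  mixture targets used here stay above 0.95 rank agreement).
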