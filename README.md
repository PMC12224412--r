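# lexrsa

Representational similarity analysis (RSA) of word-reading multi-voxel
patterns, built for studies that ask *what kind* of word information —
orthographic form or meaning — a brain region encodes, and whether that
differs between reader groups (e.g. adults with dyslexia vs typical
readers).

Activation-based analyses say how *much* a region responds; RSA asks
whether the *geometry* of its responses matches a theory. For a set of
$n$ word stimuli, each candidate representation is summarized as an
$n \times n$ representational dissimilarity matrix (RDM):

- **OrthModel** — position-weighted Levenshtein distance between
  letter strings, with edits at the first/last letter position costing
  `w_edge` (default 2) instead of 1, so shared initial/final letters
  count extra;
- **SemModel** — Euclidean distance between low-dimensional word
  embedding coordinates;
- **confound RDMs** — absolute pairwise differences in log lexical
  frequency and word length.

On the neural side, per-condition response patterns (t-maps from an
event-related GLM with canonical-HRF regressors, or simulated
patterns) yield a **cross-validated Euclidean distance** RDM: for runs
$T \neq S$,

$$d(a,b) = \frac{(\hat x_a^{T} - \hat x_b^{T})\cdot(\hat x_a^{S} - \hat x_b^{S})}{n_\text{voxels}},$$

averaged over ordered run pairs. Because train- and test-run noise are
independent this estimator is unbiased (it can go negative), unlike the
naive distance, which noise inflates.

The second-order statistic is the **confound-partialled Spearman
correlation** $\rho$ between the vectorized neural RDM and each model
RDM. Group inference uses two-sided Wilcoxon signed-rank tests against
zero median, Benjamini–Hochberg FDR across the model dimension
(q-values), pooled-variance t-tests between groups, and Type II
ANCOVA / Tukey post hocs on the $\rho$ values. A synthetic-data
generator plants a known mixture geometry
$D^\* = w_\text{sem}\,\mathrm{scale}(D_\text{sem}) + w_\text{orth}\,\mathrm{scale}(D_\text{orth})$
in simulated subjects so the whole chain can be calibrated and
power-tested. Behavioral utilities (efficiency scores, RT trimming,
Cohen's d, pooled t, mixed repetition ANOVA) round out the workflow.

## Worked example

Simulate two groups of 12 subjects whose planted geometry differs only
in semantic weight (0.8 vs 0.4), then run the full second-order
analysis:

```r
library(lexrsa)

cfg <- sim_config(
  n_subjects = 12, seed = 42,
  groups = list(control = list(w_sem = 0.8), dyslexic = list(w_sem = 0.4))
)
ds <- simulate_dataset(cfg)
ds
#> <lexrsa_dataset: 33 words, 4 runs, 24 subjects (control, dyslexic)>
#>   orth~sem model correlation: 0.007

res <- run_rsa(ds)
glance(res)
#> # A tibble: 6 x 10
#>   roi   model     group                   n median_rho statistic  p_value  q_value test        significant
#>   <chr> <chr>     <chr>               <int>      <dbl>     <dbl>    <dbl>    <dbl> <chr>       <lgl>
#> 1 sim   OrthModel control                12     0.0786    77     0.000977 0.000977 signed_rank TRUE
#> 2 sim   SemModel  control                12     0.239     78     0.000488 0.000977 signed_rank TRUE
#> 3 sim   OrthModel control vs dyslexic    24    -0.0422    -0.575 0.571    0.571    ttest       FALSE
#> 4 sim   SemModel  control vs dyslexic    24     0.0675     1.90  0.0706   0.141    ttest       FALSE
#> 5 sim   OrthModel dyslexic               12     0.121     67     0.0269   0.0269   signed_rank TRUE
#> 6 sim   SemModel  dyslexic               12     0.171     78     0.000488 0.000977 signed_rank TRUE
```

Both groups carry significant semantic and orthographic structure
(both weights are positive in both groups), the control group's
semantic correlation is descriptively higher (median 0.239 vs 0.171),
and at this small sample the between-group contrast does not reach
significance — power analyses with `separation_power()` show n = 20
per group detects a 0.8 vs 0.4 semantic-weight difference in roughly
three quarters of experiments. `tidy(res)` returns the per-subject
correlations, `autoplot(res)` the box/jitter summary, and
`run_pipeline(cfg, out_dir)` writes all tables (TSV) plus a resolved
configuration sidecar (JSON) to disk.

Published summary statistics travel with the package:

```r
compare_groups(assessment_summaries())
# reading fluency: Cohen's d = -1.85, t(40) = -5.99
```

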