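---
title: "Methods: modelling the maturation of pain-connectome connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the maturation of pain-connectome connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

The pain connectome is the network of brain regions that together encode
the sensory-discriminative, affective-motivational and cognitive-evaluative
aspects of pain. In newborns this network is still being built: functional
connections between its regions strengthen rapidly over the developmental
window equivalent to the third gestational trimester (roughly 26–42 weeks
postmenstrual age, PMA). `painconn` implements a complete analysis chain
for quantifying that maturation from resting-state BOLD fMRI:

1. **ROI extraction** — mean gray-matter BOLD signal for 12 bilateral
   pain-related regions (thalamus, SI, SII, aI, pI, ACC, MCC, amygdala,
   BG, OFC, vlPFC, dlPFC) from a labelled 4D volume.
2. **Connectivity** — absolute Pearson partial correlations between all 66
   region pairs, hemisphere-averaged.
3. **Normalisation and presence** — Cook's-distance / 3-SD outlier
   screens, division by adult per-connection means (`r_norm`, 1 =
   adult-like), and presence calling against a thalamus–SI reference in
   the youngest infants.
4. **Maturation statistics** — PMA regressions, Dunnett group-vs-adult
   comparisons, age × subnetwork ANOVA with Tukey pairwise tests, and
   FDR-corrected per-connection t-tests.

Because the source imaging cohorts cannot ship with a package, a
first-class synthetic generator produces cohorts whose ground-truth
partial-correlation structure follows designed growth curves, making every
stage testable end to end.

# The connectivity model

For one subject, the 12 ROI signals within a hemisphere are modelled as a
zero-mean multivariate Gaussian with precision matrix $P$. The partial
correlation between regions $i$ and $j$ given all others is

$$\rho_{ij} = -\frac{P_{ij}}{\sqrt{P_{ii}P_{jj}}},$$

which is also what `partial_correlation_matrix()` computes from data by
inverting the empirical correlation matrix. The estimator is exactly
equivalent to correlating the residuals of $i$ and $j$ after regressing
each on the remaining 10 regions; the test suite checks the two routes
against each other to machine precision. No ridge or shrinkage is applied:
an ill-conditioned correlation matrix (condition number above $10^{12}$)
is an error, because silent regularisation would change the estimand.

**Conditioning set.** The analysis reports 66 connections, which is the
number of pairs among 12 region *types*, not among 24 bilateral regions.
The default (`conditioning = "per_hemisphere"`) therefore computes a
12 × 12 partial-correlation matrix separately within each hemisphere,
takes absolute values, and averages the two homologous entries — the
absolute value is taken *before* averaging. A `"joint"` option conditions
each pair on all other 22 regions instead; it is provided because the
choice is genuinely open, but the per-hemisphere default matches the
66-connection bookkeeping and keeps the conditioning set small relative
to the number of time points. Cross-hemisphere pairs are never emitted,
and no Fisher z-transform is used anywhere — the pipeline operates on raw
absolute correlations throughout.

# Quality control

Spurious connectivity values are screened per connection, with different
rules for the two cohorts because infants have a strong age trend:

* **Infants** (`infant_outlier_mask()`): ordinary least squares of the
  connection value on PMA; points whose Cook's distance exceeds three
  times the connection's mean Cook's distance are discarded. Cook's
  distance uses the standard leverage form with $p = 2$ parameters
  (intercept and PMA); the suite verifies it against the leave-one-out
  refit definition to $10^{-10}$. An age-blind z-screen would flag
  legitimate very young or very old subjects; screening against the trend
  targets genuinely aberrant values.
* **Adults** (`adult_outlier_mask()`): values deviating from the
  connection mean by more than three sample standard deviations are
  discarded, in a single pass (no iterative refitting).

Boundary conventions are strict everywhere: a value at exactly three
times the mean Cook's distance, or at exactly mean ± 3 SD, survives.
Discarded values become *missing* — they are excluded from every
downstream mean and denominator, never imputed and never zeroed. Missing
(QC-discarded) is a different state from absent (below the presence
threshold).

On clean synthetic cohorts the infant screen discards roughly 6–8 % of
values. The logistic growth curves are not exactly linear in PMA, so the
linear Cook screen concentrates its discards at the age extremes, where
leverage is highest; this is a faithful property of the screen, not a
bug, and it is why group means downstream skip subjects left with no
non-missing values in scope.

# Normalisation and presence

Each surviving infant value is divided by the post-QC adult mean for that
connection (`adult_reference_means()`, `normalize_connectome()`):
$r\text{-}norm = r / \bar r_{\text{adult}}$. By construction the adult
per-connection mean of `r_norm` is exactly 1, which the suite asserts to
$10^{-12}$ — it is the pipeline's internal consistency identity.

Presence is then called against a biological anchor: the thalamus–SI
connection is already functional in the youngest preterm infants, so the
mean thalamus–SI `r_norm` across infants below 32 weeks PMA defines the
presence threshold. Every `r_norm` strictly below it is set to 0 and
marked absent; ties survive. The threshold is applied globally — to every
infant *and* every adult — so that "present in neonates but not adults"
is a checkable outcome rather than an artefact of asymmetric processing.
Whether adults should also be thresholded is an interpretation; applying
it globally is the package's choice because it makes infant and adult
presence proportions directly comparable.

# Summary metrics and statistics

Per subject, `subject_summary()` reports the proportion of present
connections (present / non-missing) and the mean $\log_{10}(r\text{-}norm)$
over *present* connections only. Absent connections would contribute
$-\infty$ on the log scale; restricting the strength average to present
connections is the only usable convention and matches a
strength-of-present-connections reading. Subnetwork-scoped summaries use
the subnetwork's own connection count as denominator (10 sensory, 10
affective, 15 cognitive).

* `fit_pma_regression()` — OLS of each metric on PMA, infants only.
* `groups_vs_adult()` — many-to-one Dunnett-corrected comparisons of the
  six PMA bins (<32, 32–34, 34–36, 36–38, 38–40, 40–42 weeks; half-open
  on the left, last bin closed at 42) against adults, via the
  multivariate-t formulation in **multcomp**. The quasi-Monte-Carlo
  integration is seeded for reproducibility. Null simulations in the
  suite confirm family-wise error control at the nominal 5 % level.
* `subnetwork_anova()` — two-way fixed-effects ANOVA (age group ×
  subnetwork) with interaction on the unbalanced layout, Type II sums of
  squares (**car**). Each subject contributes three rows (one per
  subnetwork) treated as independent — the convention common in
  connectome group analyses, and the one whose degrees of freedom the
  package reports; a repeated-measures model is an explicit non-goal. The interaction's explained variance is its SS
  over the total SS. Tukey-adjusted pairwise comparisons (**emmeans**)
  are reported for subnetworks within age group and age groups within
  subnetwork.
* `connection_level_tests()` — Welch two-sample t-tests per connection
  between late-term infants (40–42 weeks) and adults on `r_norm`, with
  Benjamini–Hochberg correction *within each subnetwork's connection
  family* (a single 66-connection family is a config switch, as is
  testing $\log_{10}$ values). Welch is used because equal variances are
  not plausible across cohorts scanned on different hardware.

# The synthetic generator

`simulate_cohort()` emulates the structure of the source data: six infant
PMA bins between 26 and 42 weeks plus an adult group (default sizes 8, 8,
34, 40, 100, 182 and 98 — 470 subjects), 2300 time points per infant and
1200 per adult, matching the 15-minute acquisitions the analysis is
designed for.

Each connection follows a logistic growth curve
$t(\text{PMA}) = \text{floor} + (\text{adult\_target} - \text{floor})
\cdot \sigma(\text{rate} \cdot (\text{PMA} - \text{onset}))$,
nondecreasing in PMA and asymptoting at the adult target. The defaults
stagger the onsets by subnetwork — sensory (31 weeks) before affective
(34.5) before cognitive (38), with a weak intermediate "background" curve
(onset 36) for connections outside all three subnetworks, and an early
(onset 28) curve for thalamus–SI since it anchors the presence threshold.
Connections in several subnetworks take the earliest-maturing
assignment. Adult targets are 0.30 (thalamus–SI), 0.22 (sensory), 0.18
(affective), 0.15 (cognitive) and 0.10 (background): values in the range
typical of absolute partial correlations between cortical ROI signals,
and chosen once so that the implied precision matrix is positive definite
without repair (see below). No established effect-size scale exists for
these curves; they are designed for testability, not calibrated to any
real cohort, so quantitative outputs of synthetic runs (R², F values,
discard fractions) are properties of the generator, not estimates of
real-data quantities. What the design does reproduce is the qualitative
pattern: sensory-first maturation, affective intermediate, cognitive
last, and term-age hyperconnectivity in the earliest subnetworks.

**From targets to data.** `build_precision_matrix()` solves the inverse
problem: given target absolute partial correlations, it sets
$P_{ii} = 1$, $P_{ij} = -s_{ij} t_{ij}$ with a fixed mixed-sign pattern
$s_{ij}$. Partial correlations in resting fMRI are mixed-sign and the
analysis takes absolute values, so the sign pattern is free; a fixed
pseudo-random pattern is used because a dense all-positive pattern at
these magnitudes is not positive definite, whereas the chosen pattern
keeps the smallest eigenvalue near 0.3 at the asymptotic defaults. If a
user-supplied target set is still not positive definite, uniform diagonal
loading is applied and every realised target shrinks by the same factor,
which is recorded — the ground-truth table always contains the realised
values. The subject's series is then drawn from the implied covariance
(Cholesky), left and right 12-region blocks independently
(block-diagonal precision), since only within-hemisphere pairs are
analysed. Left and right targets are jittered independently
(SD 0.02, clipped to [0, 0.9]) so hemisphere averaging is exercised
nontrivially.

The latent signal is stationary white Gaussian by default: partial
correlation estimation is the object of interest, and temporal
autocorrelation affects only the effective sample size. An optional AR(1)
coefficient (default 0) is available for sensitivity analyses. The
generator does *not* simulate motion, physiological noise, scanner drift
or any preprocessing artefacts — passing tests on synthetic cohorts shows
the estimators and statistics are correct on data satisfying the model's
assumptions, not that real preprocessed fMRI satisfies them.

**Determinism.** Per-subject seeds derive from the master seed by a fixed
multiplicative counter scheme; RNG draw order within a subject is fixed
(left jitter, right jitter, postnatal age, sex, innovations). Identical
spec and seed give bit-identical cohorts, and the pipeline writes a
manifest with MD5 hashes of every output so reruns are verifiable.

# Numerical choices and degenerate inputs

* Partial correlations: condition-number guard $10^{12}$, error not
  ridge; zero-variance columns are named in the error.
* Cook screen: fewer than 4 complete points → no screening plus a
  warning; an exactly perfect fit (machine-zero residuals) keeps all
  points with zero distances.
* Adult screen: zero variance keeps everything; fewer than 3 values →
  no screening plus a warning.
* Adult reference: a connection with no surviving adult values is an
  error — there is no defensible imputation for a normalising
  denominator.
* Presence: an empty reference group is an error; `r_norm` exactly at
  the threshold stays present.
* ROI extraction: grids must match exactly (no resampling); an ROI with
  fewer than `min_voxels` eligible gray-matter voxels is an error naming
  the ROI; the gray-matter threshold is a strict `> 0.5`, which handles
  binary masks and is the package's reading of an unstated thresholding
  convention for probabilistic segmentations.

# Problem sizes used in the tests

The shipped tests and the acceptance script run the full pipeline on
cohorts with the study's bin structure and full series lengths (2300 /
1200 volumes) but smaller groups (8, 8, 12, 12, 12, 12 infants and 16
adults), a size at which every stage's behaviour — QC fractions,
threshold, trajectory ordering — is already stable across seeds. The
designed-effect experiment uses 100 subjects per group, the null
calibration of the Dunnett procedure 1000 simulated datasets. These sizes
are the package's choice of a convincing-but-compact demonstration;
nothing in the code depends on them.

# Known limitations

* The subnetwork partition is a simplified model; several regions (aI,
  BG, thalamus) belong to more than one subnetwork and their shared
  connections are counted in each.
* Treating the three subnetwork rows per subject as independent in the
  ANOVA ignores within-subject correlation; a mixed model would be more
  efficient but is out of scope.
* The Cook screen assumes a linear value–PMA trend; against logistic
  growth it over-discards at the age extremes.
* The generator's growth curves are a design instrument. Synthetic
  cohorts demonstrate correctness of the machinery, not properties of
  any real cohort.
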