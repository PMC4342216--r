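---
title: "Fuzzy molecular grading: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy molecular grading: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzygrade)
```

## The grading problem

Histologic grade 1 and grade 3 breast tumors carry clearly different
recurrence risks, but the intermediate grade 2 — about half of all cases —
is uninformative for treatment decisions. `fuzzygrade` treats molecular
grading as a two-class fuzzy classification problem: grade 1 and grade 3
tumors define the fMG1 and fMG3 expression archetypes, and every tumor
belongs to *both* classes simultaneously with membership degrees that sum to
one. Grade 2 tumors are then placed on this continuum, and a narrow score
band is reported as equivocal rather than forced into a class. The fuzzy
representation is the point: tumor heterogeneity and intermediate biology
are expressed as partial memberships instead of being discarded by a hard
threshold.

## Model

### Standardization and fuzzification

Each probe is linearly rescaled to $[0,1]$ using its minimum and maximum
over the *training* samples only (grade 1 and 3). Deployment values outside
the training range are clipped to $[0,1]$: extrapolating the membership
functions outside their calibrated domain is not meaningful, and clipping
keeps all memberships well defined. Probes that are constant on training
carry no grading information; their standardized value is pinned at 0.5 so
they are neutral for every class, and they are flagged.

Two membership families are available, and both are tried during selection
(`family = "auto"`):

* **fuzzy-binomial** $\mu_c(x) = \rho_c^{\,x}(1-\rho_c)^{1-x}$ with
  $\rho_c$ the class mean of standardized values. It behaves well when
  standardized values concentrate near 0 or 1, but the power form is
  unstable when a prototype reaches the ends of the interval; $\rho$ is
  therefore clamped to $[\varepsilon, 1-\varepsilon]$ with
  $\varepsilon = 10^{-6}$, which also keeps every membership strictly
  positive. The exponent $x$ needs no clamp: the power form is exact on
  $[0,1]$ (at $x=1$ the membership is exactly $\rho$).
* **Gaussian** $\mu_c(x) = \exp(-(x-\mu_c)^2 / 2\sigma_c^2)$ with the class
  mean and standard deviation. $\sigma_c$ is floored at 0.01 (unit-interval
  scale) so that a class with (near-)constant values does not become an
  infinitely sharp spike that zeroes every other sample.

Missing entries are excluded from prototype estimation and from
aggregation; classification refuses a sample only when more than 20% of the
signature probes are absent (configurable `max_missing`).

### MEMBAS feature weighting

For a training sample, the margin of probe $i$ is its membership to the
sample's own class minus its membership to the competing class. MEMBAS
maximizes the total membership margin $w \cdot m$ over weight vectors with
$\lVert w\rVert_2 = 1$, $w \ge 0$, where $m_i$ is probe $i$'s margin summed
over all training samples. The analytical solution is
$w \propto \max(m, 0)$: anti-informative margin sums are clipped to zero
rather than allowed to enter with negative weight. Probes are ranked by
descending weight with ties broken by ascending probe identifier, making the
ranking fully deterministic. Margins are summed unnormalized over samples;
per-sample normalization would only rescale $m$ by a constant when class
sizes are balanced and was not adopted.

The ranking is computed once on the full training set before the size loop
(the selector precedes the cross-validated classification stage). This
resubstitution ranking carries a mild selection bias; a strictly
leakage-free mode (`per_fold_ranking = TRUE`) re-derives the ranking inside
every fold and is used in the test suite to verify chance-level error under
label permutation. Empirically the bias is visible exactly where theory
predicts: with permuted labels the default mode's LOOCV error drops well
below 0.5 while the per-fold mode stays at chance.

### LAMDA classification and the molecular grade score

The marginal adequacy degrees (MADs) of a sample to a class are its
per-probe memberships; they are aggregated into a global adequacy degree by
a mixed fuzzy connective
$\mathrm{GAD} = \alpha\, T(\mathrm{MADs}) + (1-\alpha)\, S(\mathrm{MADs})$
with $(T, S) = (\min, \max)$ by default, or (product, probabilistic sum)
via `connective = "prodprobsum"`. The exigency $\alpha \in [0,1]$
interpolates between strict (every probe must fit) and lenient (one probe
suffices) aggregation.

The molecular grade score is the normalized fMG3 membership
$s = \mathrm{GAD}_3 / (\mathrm{GAD}_1 + \mathrm{GAD}_3)$, so the two
displayed memberships sum to one (a tumor with 0.8 membership to fMG1 has
score 0.2). Decision rules, boundary conventions included:

* $s \ge 0.5$ → fMG3 (boundary inclusive), $s < 0.5$ → fMG1;
* $0.48 \le s \le 0.52$ → equivocal (both ends inclusive; the band is a
  reporting convention for genuinely intermediate profiles, not a third
  class);
* if both GADs are zero (possible only with underflowed Gaussian
  memberships) the score degrades to 0.5, equivocal, with a warning.

A non-informative class (the flat all-0.5 MAD profile, classic in the LAMDA
literature) is implemented but off by default: when enabled, calls whose
GADs both fall below the NIC's GAD are flagged low-confidence. It does not
change labels or scores.

### Signature sizing by LOOCV

For each candidate size $k$ along the ranking, every training sample is held
out once; bounds, prototypes and $\alpha$ are re-estimated from scratch on
the remaining samples restricted to the top-$k$ probes, and the held-out
sample is classified. $\alpha$ is chosen per fold and per $k$ from the grid
$\{0.5, 0.6, \ldots, 1.0\}$ by resubstitution accuracy on the retained
samples — the grid's lower half is omitted because $\alpha < 0.5$ weights
the lenient t-conorm more than the strict t-norm, degrading the aggregation
toward single-probe behavior. Ties are broken toward the larger (stricter)
$\alpha$. The same rule, applied to the full training set, fixes the final
model's $\alpha$, so a fold's model and a full refit without that sample
coincide exactly — the property the no-leakage tests assert.

The chosen size is the smallest $k$ with maximal sensitivity among sizes
whose specificity reaches `min_specificity` (default 0.67, the lowest
specificity historically accepted for such grade signatures). Sensitivity is
privileged over specificity: missing a high-risk (grade 3-like) tumor is
the costlier error in this setting. If no size reaches the floor, the
maximal-sensitivity size is used with a warning. The default size grid
evaluates every $k \le 200$ and then log-spaced sizes up to the full probe
count; analyses in this package's tests and acceptance script use
`c(1:25, 30, 40, 50)`, ample for cohorts whose informative structure is a
few dozen probes.

With `er_mode = "auto"` the training set is built both from all grade 1/3
tumors and from the ER-positive ones only, and with `family = "auto"` both
membership families are tried; the configuration with the lowest LOOCV
error (ties to higher sensitivity) wins. The deployment set is never
ER-filtered.

### Cross-platform adaptation

When a signature moves to a platform with several probes per gene, each
gene's candidate probes are ranked by MEMBAS weight on the new cohort's
grade 1/3 samples and the top probe is kept; prototypes, bounds and
$\alpha$ are refitted on the new cohort. Genes without any probe are
dropped with a warning, and adaptation is refused below 80% gene coverage
(configurable).

## The synthetic generator

`simulate_cohort()` emulates the statistical structure the method assumes,
on the log2-intensity scale where microarray data are approximately
Gaussian within class:

| parameter | default | meaning |
|---|---|---|
| `n_grade1`, `n_grade3`, `n_grade2` | 60 / 60 / 60 | cohort composition |
| `n_informative`, `n_noise` | 20 / 980 | planted vs null probes |
| `effect` | 2 | grade-3 shift on informative probes, in within-class SDs |
| `noise_sd` | 0.5 | within-class SD (log2 units) |
| `baseline_mean`, `baseline_sd` | 8 / 1.5 | per-probe baseline intensities |
| `grade2_mix` | 0.5 | fraction of grade 2 tumors from the grade-3 archetype |
| `equivocal_fraction` | 0.1 | grade 2 tumors generated midway between archetypes |
| `er_positive_fraction` | 0.7 | ER+ prevalence |

`noise_sd = 0.5` and baselines around 8 ± 1.5 are typical of log2 microarray
intensities; a 2-SD shift on a minority of probes reflects the strong
proliferation-driven separation of grade 1 vs grade 3 expression; 70% ER
positivity matches the usual prevalence in breast cancer cohorts; and a 10%
midpoint fraction places the generator inside the single-digit-to-30%
equivocal ranges typically observed. Grade 2 tumors carry a latent archetype
(recorded in the ground truth) so that deployment calls can be scored;
midpoint samples are the designed-to-be-equivocal cases.

`make_two_platform_pair()` re-measures the same tumors on a second platform
with several probes per gene, each probe an affine-distorted
($a \sim U(0.8, 1.25)$, $b \sim N(0, 0.3)$), noise-jittered replicate of the
gene signal — supporting the cross-platform tests, where noisier probes must
receive lower MEMBAS weights.

What the generator deliberately does *not* emulate: platform-specific
artifacts (spatial effects, dye bias), probe saturation, correlated gene
modules, batch structure, or ER-linked expression differences. Passing the
synthetic benchmark therefore shows that the selector recovers independent
planted signal at realistic noise and that the classifier's decision
geometry behaves as specified — it does not certify performance on real
cohorts, where correlated biology and batch effects can be substantially
harder. Because the planted structure is ER-independent, the acceptance
experiments run with `er_mode = "all"` and the binomial family rather than
the `"auto"` comparisons.

## Numerical conventions

* Binomial prototypes clamped at $\varepsilon = 10^{-6}$; Gaussian
  $\sigma$ floor 0.01; degenerate (constant) probes standardized to 0.5.
* MEMBAS ties: ascending probe identifier. Exigency ties: larger $\alpha$.
  Probe-per-gene ties in cross-platform adaptation: first by ascending
  probe id.
* Displayed percentages are rounded half-up to the integer (94.5% prints as
  95%); raw fractions are always retained in the returned objects.
* Heatmap row standardization divides by the population SD (divisor $n$),
  so a displayed row has SD exactly 1; a row already standardized this way
  is unchanged.
* Reference-probe stability is the across-sample variance of
  sample-centered values, making the ranking invariant to global per-sample
  shifts; this operationalizes "expression stability" when selecting
  housekeeping probes. The complementary correlation criterion sometimes
  used for housekeeping selection is not implemented.
* The LOOCV fast path aggregates memberships with running minima/maxima
  down the ranking and requires complete values on the ranked probes;
  missing-value tolerance lives in `classify_samples()`.

## Problem sizes

The test suite and `scripts/acceptance.R` run entirely on generated data:
planted-probe recovery over 50 seeded cohorts of 1,000 probes × 120
training samples; end-to-end selection over 25 seeds; grade-2 splitting
over 50 seeds; and a 100-permutation null experiment at 30 samples × 100
probes. The acceptance script reports means over 10 seeded end-to-end runs
derived from its `--seed`.

## Known limitations

* Two classes only; multi-class grading and the unsupervised/online LAMDA
  variants are out of scope.
* The margin objective assumes two classes; with more, the maximum over
  competing classes would replace the single other-class membership.
* Survival analysis is intentionally excluded: `calls.tsv` (sample, GADs,
  score, label, equivocal flag) is designed as input to external survival
  tooling.
* GEO/SOFT and CEL parsing are out of scope; expression is exchanged as
  TSV.
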