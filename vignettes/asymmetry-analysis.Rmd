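---
title: "Voxel-based asymmetry analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based asymmetry analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbmasym)
```

## The model

`vbmasym` analyses hemispheric asymmetry of tissue distribution from
spatially normalized, Jacobian-modulated gray- and white-matter
probability maps. The pipeline assumes segmentation, normalization to a
*symmetric* template, and modulation have already happened; its inputs are
per-subject 3D volumes on a common grid.

The central statistic is the voxel-wise asymmetry index

$$AI = \frac{\mathrm{orig} - \mathrm{flip}}{\tfrac12(\mathrm{orig} + \mathrm{flip})},$$

the left–right tissue difference normalized by the local mean. Because the
denominator is the mean of the two sides, $AI$ is scale-free (invariant to
global tissue scaling), antisymmetric about the midline, and bounded by
$\pm 2$ for nonnegative input — the bounds are attained when one side has
tissue and the other has none. Under the RAS+ world convention used
throughout (world $x$ grows toward the right hemisphere), positive $AI$ at
$x > 0$ is a rightward asymmetry, so each real asymmetry effect appears
once, on its dominant hemisphere.

Mirroring is implemented as index reversal along the first voxel axis —
exact, interpolation-free — which is geometrically valid only when the
grid is symmetric about the mid-sagittal plane $x = 0$.
`check_grid_symmetry()` verifies this from the affine (worst-case
$|x_i + x_{N-1-i}|$ over the grid; default tolerance 0.1 mm) and `flip_x()`
refuses non-mirrorable grids rather than silently resampling. Data
normalized to a symmetric template satisfy this by construction. On a
mirrorable grid, index reversal already sends content at world $x$ to
world $-x$, so the affine is left untouched and a double flip is
bit-identical to the input.

$AI$ maps are smoothed (default 10 mm FWHM) *after* the index is formed,
not before; smoothing an antisymmetric map with a symmetric kernel
preserves antisymmetry to numerical precision, which the tests assert.

### Statistical inference

Smoothed AI maps enter a mass-univariate GLM (`fit_glm_t()`), always with
mean-centered nuisance covariates (age, gender by default):

* **one-sample** (per group): contrast on the intercept — is asymmetry
  nonzero;
* **two-sample** (cell-means coding): contrast control − patient — does
  asymmetry differ between groups;
* **covariate**: contrast on a behavioral score — does asymmetry track
  behavior.

Family-wise error control is by permutation (`permutation_fwe()`): each of
$B$ permutations yields a full t map, and the null distributions of the
maximum t (voxel-level FWE) and of the maximum suprathreshold cluster
statistic (cluster-level FWE) calibrate the corrected p-values
$p = (b+1)/(B+1)$, the add-one convention that counts the observed
statistic as a member of its own null sample and makes the test exact at
any $B$. Cluster inference built on a permutation null of the maximum
statistic is intrinsically robust to non-stationary smoothness of VBM-style
maps — no random-field stationarity assumption is invoked; this is the
role that parametric non-stationarity corrections play in toolbox
pipelines. Cluster *mass* (the sum of $t$ in excess of the cluster-forming
threshold) is the default statistic because it is less sensitive to the
local smoothness that drives pure extent; extent remains available.

Permutation schemes, by design:

* `sign_flip` (one-sample): under "no asymmetry" the AI map is symmetric
  about zero *by construction of the index*, so subject-wise sign flips
  are exchangeable.
* `label_permute` (two-sample): group labels are permuted while each
  subject keeps their own covariate row. With small samples and a binary
  covariate a permuted labeling can coincide exactly with the covariate,
  making the contrast inestimable; such permutations carry no statistic
  and are excluded from the null set (redrawn, or dropped from the
  exhaustive enumeration).
* `freedman_lane` (covariate): residuals from the nuisance-only model are
  permuted and the full model refit — the standard
  exchangeability-preserving scheme for designs with nuisance.

When `B` reaches the number of distinct non-identity rearrangements
($2^n$ sign patterns, $\binom{n}{n_1}$ label assignments, $n!$ residual
orders), the test switches to exhaustive enumeration with a warning.

One-sided positive contrasts are the default on AI maps: antisymmetry
means a leftward effect is exactly the mirrored rightward effect, so the
positive contrast already surfaces every asymmetry once, on its own
hemisphere, which is how asymmetry tables are conventionally split into
left and right panels. Two-sided testing remains available
(`alternative = "two.sided"`, with positive and negative suprathreshold
sets clustered separately).

### Regions of interest and small-volume correction

Correlation analyses are restricted a priori to a symmetric ROI
(`small_volume_correct()`): all permutation maxima are taken inside the
ROI only, which is the standard way to keep focused hypotheses powered.
ROIs come from integer-label volumes (`combine_labels()`) and are made
flip-invariant by `symmetrize()`. The default rule is **union**: averaging
a binary mask with its mirror leaves non-overlapping voxels at exactly
0.5, so a mean-then-threshold rule turns on a knife-edge tie; union avoids
the ambiguity and keeps full bilateral coverage (the tie-inclusive
`mean_threshold` rule coincides with union on binary input, and
`intersection` is available when only bilaterally present voxels are
wanted). No anatomical atlas is bundled; the synthetic generator's truth
label volume plays that role, and real parcellation volumes are read
through the same interface.

### Post-hoc characterization at peaks

`extract_peak_values()` samples each subject's *smoothed tissue maps* (not
AI) at a significant peak and its mirror coordinate, nearest-voxel — peaks
are reported voxel locations, so no interpolation is applied; a
sphere-average option exists for users who prefer a neighbourhood value.
`anova_group_by_hemisphere()` runs the mixed Group × Hemisphere ANOVA
(hemisphere within-subject) with LSD post-hoc contrasts: unadjusted
pairwise t tests on the ANOVA error strata, which is what LSD means —
within-group hemisphere contrasts use the within-subject mean square;
between-group contrasts at a fixed hemisphere pool both strata. With a
two-level within factor there is no sphericity to correct.
`levene_test()` uses the original mean-centered deviations (the test is
reported as "Levene" wherever it appears here; the median-centered
Brown–Forsythe variant is an option, and the choice is recorded in the
output).

### Behavioral stage

`score_intelligibility()` turns per-trial correctness into proportion
scores. `mixed_anova_group_by_config()` is the Group × Configuration
mixed ANOVA on complete score tables — between-subject group, within-subject
listening configuration — with per-configuration group contrasts
Bonferroni-multiplied by the number of configurations. No sphericity
correction is applied (a documented limitation; with three configurations
the plain df are reported, e.g. an interaction on 2 and 52 df for two
groups of 14). `table1_compare()` runs pooled-variance Student t tests
from raw vectors or printed (mean, sd, n) summaries — the pooled form is
the one that reproduces conventional summary-table p-values; Welch is an
option.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `eps` (AI denominator floor) | 0.05 | tissue probability | voxels with mean tissue below 5% have an unstable ratio; they are masked (set to 0 and excluded), not clamped. The mask is symmetric because the denominator is flip-invariant. |
| `fwhm_mm` (AI smoothing) | 10 | mm | the conventional kernel for this analysis scale |
| `cluster_forming_p` | 0.001 | probability | conventional voxel-level cluster-forming threshold |
| `cluster_alpha` | 0.05 | probability | cluster-level FWE level |
| `statistic` | mass | — | robust to non-stationary smoothness; `extent` available |
| `B` | 999 | permutations | analysis default; tests use 199 for runtime |
| `connectivity` | 18 | — | faces+edges, the convention of the major VBM toolchains |
| flip tolerance | 0.1 | mm | sub-voxel guard for grid mirror-symmetry |

## The synthetic cohort generator

`phantom_spec()` / `simulate_cohort()` generate the study conditions the
analysis expects: two groups of 14 subjects (6 females each; ages
normal with means 26.07 / 23.29 years, SDs 6.19 / 6.08), tissue maps on a
49³ grid of 2 mm voxels built as

*symmetric template* (sum of compact quartic blob bumps, exactly
flip-invariant) + *effect blobs* (one-sided additive amplitude per group,
optional per-subject jitter) + *smooth Gaussian noise* (white noise
smoothed at 8 mm and rescaled to marginal SD 0.04), clipped at zero.

Additive injection was chosen over multiplicative because it gives the
injected AI in closed form — template value $T$, amplitude $a$ give
$AI = a/(T + a/2)$ at the blob centre — which the unit tests exploit.
The default effects emulate the study pattern: a rightward GM blob at a
mid-temporal analogue location, amplitude 0.18 in controls and 0 in
patients (the calibration effect size, frozen after a pilot showed it
detectable with margin at these noise levels — amplitude 0.12 sits at the
80% power boundary), and a left posterior WM blob present in both groups
(amplitude 0.08, per-subject SD 0.05) whose per-subject asymmetry drives
the patients' monaural score through
`score = 0.62 + 0.48 · meanAI + N(0, 0.02)`, calibrated so patient
monaural scores have mean ≈ 0.71 and SD ≈ 0.10 while controls score
≈ 0.80 ± 0.03; dichotic and spatialized scores sit at their ceiling
values. Age and gender are generated but given no true effect on tissue,
so covariate adjustment is testable as a no-harm property.

The phantom world is desk-scale: the 49³ × 2 mm grid spans ±48 mm, so the
effect loci are scaled analogues, not MNI coordinates; 1 mm paper-scale
grids run through the same code, just slower. What the phantom does *not*
emulate: cortical folding and anatomy, partial-volume structure, scanner
artifacts, registration error, and spatially varying (non-stationary)
smoothness. Passing tests therefore demonstrate that the statistical
machinery is correct and well calibrated under the generative model — not
that any particular real-data effect will replicate.

Reproducibility: each cohort is drawn from a single seeded RNG with a
documented stream order (ages; then per-subject effect amplitudes and
noise fields in table order; then behavioral scores), so a seed pins every
output bit-for-bit.

## Numerical choices

* **Smoothing** is separable Gaussian convolution with **zero padding**
  (the dominant convention in this field's toolchains; reflect padding
  changes near-edge values), kernels truncated at 6σ and renormalized, so
  interior mass is conserved to ~1e-9 and the discrete kernel matches the
  continuous normalization closely. Anisotropic voxels get per-axis
  σ = FWHM / (voxel size · √(8 ln 2)).
* **Zero-variance voxels** in the GLM: a voxel whose residual variance is
  numerically zero has no t; if its contrast estimate is also zero it is a
  null voxel (t = 0), otherwise it is excluded from the analysis mask.
  The voxel set is frozen from the observed fit before permutation.
* **Degenerate ANOVA strata**: a zero-SS effect over a zero error stratum
  is reported as F = 0; a nonzero effect over a zero error stratum is an
  error, not a number. Zero is judged against a relative tolerance so
  `aov`'s ~1e-32 rounding noise on constant data does not masquerade as
  signal.
* **p-value convention**: (b+1)/(B+1) everywhere; the attainable floor is
  1/(B+1). Note that corrected p-values under nested permutation subsets
  are not pointwise monotone in B — only the floor is — so determinism and
  the floor are what the tests assert.
* **NIfTI geometry**: sform is preferred when qform and sform disagree
  (with a warning); volumes are written with the sform only.
* **Ties and sides**: cluster peak = first maximum in column-major order;
  a peak at x ≥ 0 is labelled "right".

## Problem sizes in tests and the acceptance script

The test suite validates type-I error with 200 null cohorts (49³ grid,
2 mm, 14 per group, B = 199) against the exact binomial 95% acceptance
region around 0.05, and recovery with 50 seeded cohorts at the frozen
calibration effect (two-sample Dice > 0.2 with the truth blob; significant
ROI-restricted correlation cluster overlapping the linked blob;
control-only LSD pattern — each required in ≥ 80% of runs).
`scripts/acceptance.R` recomputes the same families of quantities with 100
null simulations and 25 recovery runs — sizes chosen so a full
reproduction stays in the minutes range on one CPU.

## Known limitations

* Index-reversal flipping requires a mirror-symmetric grid; data on
  asymmetric grids must be resampled upstream.
* No random-field-theory p-values, F contrasts, or TFCE; inference is
  permutation-only, one t contrast at a time.
* The behavioral ANOVA assumes complete data and applies no sphericity
  correction.
* Whether the original correlation analyses kept age and gender alongside
  the behavioral covariate is not specified in the source methodology;
  both are kept by default here (set `covariates = character()` to drop
  them).
* Peak "volumes" are single-voxel reads by default; a sphere-average
  option is exposed because the alternative convention exists.
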