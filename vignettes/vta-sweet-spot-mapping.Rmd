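---
title: "Sweet-spot mapping of DBS volumes of tissue activated: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweet-spot mapping of DBS volumes of tissue activated: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtamap)
```

## The problem

Subthalamic deep brain stimulation (STN-DBS) improves motor symptoms of
advanced Parkinson's disease, but outcomes — motor, cognitive and
behavioral — vary between patients, and part of that variance tracks
*where* current actually spreads. Given each patient's binary volume of
tissue activated (VTA) in a common stereotactic space and their clinical
change between baseline and follow-up, sweet-spot mapping asks: which
voxels, when stimulated, are associated with improvement, and which with
worsening?

`vtamap` implements this as a mass-univariate, lesion–symptom-mapping
style analysis (VLSM applied to stimulation volumes rather than lesions),
together with the two stages around it: a closed-form electric-field
model that turns stimulation current into a VTA, and a distance-based
rule that predicts whether a *new* patient will follow the mapped
pattern. A synthetic-cohort generator with planted voxel effects makes
the whole pipeline testable without clinical data.

## The VTA field model

The stimulating contact is treated as a monopolar point source of
current $I$ in a homogeneous, isotropic medium of conductivity $\sigma$.
The field magnitude at distance $r$ is $|E|(r) = I / (4\pi\sigma r^2)$;
tissue is "activated" where $|E|$ exceeds a threshold $E_t$, so the VTA
is a sphere of radius

$$ r = \sqrt{\frac{I}{4\pi\,\sigma\,E_t}} . $$

Defaults are $E_t = 0.19$ V/mm and $\sigma = 0.1$ S/m. The unit of the
conductivity deserves a note: with $\sigma = 0.1$ S/**mm** the model
would predict sub-0.2 mm radii at clinical currents, which is physically
implausible; $0.1$ S/**m** gives $\approx 3.3$ mm at 2.58 mA, in line
with the DBS modelling literature. The package therefore defaults to
S/m, and the YAML configuration requires an explicit unit string
(`"S/m"` or `"S/mm"`) so the choice is always visible.

```{r radius}
vta_radius(2.58)           # mm, at the default threshold and conductivity
vta_radius(c(1, 2.6, 5))   # grows with the square root of the current
```

The sphere is rasterized by a voxel-center-in-sphere test (no
partial-volume weighting): downstream stages only consume binary masks.
At 1 mm resolution a 3 mm sphere centered on a voxel covers 123 voxels
versus a continuum volume of 113; worst-case alignment (center on a
voxel corner) can inflate the discrete count by about 20%, which is why
volume-accuracy checks in the test suite use voxel-centered spheres.
Assumptions deliberately *not* modelled: tissue heterogeneity and
anisotropy, axon-cable activation, voltage-mode stimulation, directional
lead segments, multi-contact settings. The model sits behind a small
interface (`field_settings()`, `vta_radius()`, `rasterize_vta()`) so a
finite-element or precomputed-field backend could replace it without
touching the statistics.

## Outcome changes

Each clinical scale's baseline and follow-up scores are standardized
against the **baseline** cohort mean and SD, and the analysis outcome is
the difference of the two Z-scores. Standardizing both timepoints
against baseline makes the change score a pure shift in baseline-SD
units: it is invariant to adding a constant to both timepoints, to
rescaling both by a positive factor, and to variance changes at
follow-up. Scales where a lower raw score is better (timed tests,
symptom inventories) are declared `higher_is_better = FALSE` and their
change is sign-flipped, so a positive change always means clinical
improvement and cluster labels ("improvement"/"worsening") are
comparable across scales.

Only scales whose cohort change is itself significant (two-sided paired
t test, $p \le 0.05$, ties at the threshold included) proceed to
voxel-wise mapping — mapping a scale that did not change would invite
noise-driven clusters.

## The voxel-wise engine

At every voxel covered by at least one VTA, patients split into a
stimulated group (VTA contains the voxel) and a non-stimulated group.
The engine fits the linear model

$$ \Delta z_i = \beta_0 + \beta_g\,g_i(v) + \mathbf{x}_i^\top\gamma + \varepsilon_i $$

where $g_i(v)$ is the group indicator at voxel $v$ and $\mathbf{x}_i$
are nuisance covariates (age, sex, disease duration for all analyses;
additionally medication change and motor change for cognitive and
behavioral scales, to absorb the dopaminergic contribution to non-motor
change). The reported statistic is the t of $\beta_g$ with
$n - p - 1$ degrees of freedom. With no covariates this reduces exactly
to the classical pooled-variance two-sample t — an identity the test
suite asserts at $10^{-10}$ against an independent implementation, and
against `lm()` when covariates are present.

Voxels where either group has fewer than 4 patients
(`min_group_n`) are discarded: with a handful of patients on one side
the test is hopelessly underpowered and its t values would only feed
noise into cluster formation. Raising the threshold can only remove
eligible voxels, never add them. Voxels whose group indicator is
collinear with the covariates are likewise flagged ineligible (reason
codes 1 and 2 in `ineligible_reason`).

Implementation note: the group indicator and the outcome are both
residualized against the covariate design once per fit
(Frisch–Waugh), after which every voxel's t is a ratio of
cross-products. This makes a full-map recomputation a single matrix
product, so one permutation of a 25-patient, ~700-eligible-voxel map
costs well under a millisecond. Outcomes that are numerically constant
after covariate adjustment are detected by comparing residual to total
sum of squares (relative tolerance $10^{-14}$) and given $t = 0$ rather
than the catastrophic-cancellation garbage a naive ratio would produce.

## Cluster formation and permutation correction

Eligible voxels with $|t|$ above the two-sided critical value at
`cluster_forming_p` (default voxel-level $p < 0.01$, a common
mass-univariate default — the sensitivity of results to this choice is
real, so it is a visible configuration knob) are grouped into connected
components under 26-connectivity (6 and 18 available). Each observed
cluster is assigned a family-wise-error-corrected p value by
permutation: the outcome vector is permuted across patients
(`"manly"`; a Freedman–Lane variant that permutes covariate-adjusted
residuals is available), the full voxel-wise map is recomputed, and the
maximum cluster statistic (extent by default, mass optionally) is
recorded per permutation. The add-one estimator
$p = (1 + \#\{M^{null} \ge s^{obs}\}) / (B + 1)$ never returns exactly
zero; its floor is $1/(B+1)$.

One design choice deserves its own paragraph. Improvement and worsening
clusters are reported separately, but by default (`tail = "both"`) each
observed cluster — of either sign — is compared against the permutation
distribution of the maximum cluster statistic **over both signs**.
Correcting each direction separately at $\alpha$ (available as
`tail = "separate"`) would put the probability of reporting *any*
spurious cluster near $1-(1-\alpha)^2 \approx 2\alpha$; the shared-null
default keeps that probability at $\alpha$, which is what the package's
own calibration checks measure (the suite runs 200 null cohorts and the
acceptance script 100, expecting the empirical rate to sit near 0.05).

Every fit records its RNG seed; identical seed and configuration
reproduce the results byte-for-byte, including the CSV written by
`run_vlsm_analysis()`.

## Motor-side flipping

Motor control is predominantly contralateral, and pooling patients
whose most affected body side differs would split any lateralized motor
sweet spot across hemispheres. For motor-domain scales the masks of
patients whose most affected side is the *right* are mirrored across
the midline ($x \mapsto -x$), so the most affected side is treated as
the left in every subject. Flipping is an involution and conserves
voxel counts on x-symmetric grids; the package refuses to flip a mask
whose nonzero voxels have no mirror voxel. Cognitive and behavioral
analyses are never flipped — hemispheric specialization makes left and
right non-interchangeable for higher functions.

## Single-subject prediction

For each significant cluster, the rule computes the Euclidean distance
from a new patient's VTA center (restricted to the cluster's
hemisphere — a right-hemisphere cluster cannot meaningfully be
distanced from a left VTA) to the cluster center, splits the new cohort
at the median distance (ties go to the *closer* group, making the
cutoff deterministic), and compares mean percentage outcome changes
between the closer and farther groups. Percentage change is oriented so
positive = improvement; magnitudes beyond ±100% are expected for large
worsenings on small baselines. The prediction is *concordant* when the
closer group's mean change is strictly more in the cluster's direction
than the farther group's; exactly equal means are non-concordant.

## The synthetic cohort generator

`simulate_cohort()` emulates the data-generating situation the analysis
assumes: bilateral electrodes with active contacts jittered (SD 1.5 mm
per axis) around ($\pm$12, −14, −7) mm; currents drawn from a normal
distribution with mean 2.6 and SD 0.6 mA, truncated at 0.5 mA; age
$\sim N(62.3, 8.0)$ years, disease duration $\sim N(11.7, 4.5)$ years,
a 21:4 male:female ratio; spherical VTAs from the field model; and
per-scale outcome changes built as cohort shift + covariate loadings +
planted voxel effects + unit-SD Gaussian noise, back-constructed into
raw baseline/follow-up scores honoring each scale's orientation. The
default scale set (a strongly improving motor score, a mildly changing
memory score, a worsening apathy score, with cohort shifts of +1.2,
+0.1 and −0.5 SD) mirrors the typical 1-year pattern after subthalamic
stimulation: large motor benefit, mixed cognitive picture, apathy
worsening. The medication-change covariate is drawn as
$N(-560, 287)$ mg and the motor-change covariate is derived from the
simulated motor scale itself.

Planted effects couple a spherical "sweet spot" to the outcome in one
of two ways. The default, `coupling = "fraction"`, scales the effect by
the fraction of the sphere the patient's VTA overlaps — a smooth
dose-response that is deliberately *harder* than the binary group model
the voxel test assumes. `coupling = "binary"` gives the full effect iff
the VTA covers the sphere's center voxel, matching the test's own
model; it is the configuration under which recovery operating
characteristics are measured. The default planted center,
(13.5, −12.5, −8.5) mm, lies ~2.6 mm dorsolateral-posterior to the mean
contact, where the probability that a simulated VTA covers it is close
to one half — a balanced, identifiable planted contrast; planting at
the mean contact position would make the coverage indicator nearly
constant and the "effect" unmappable by construction.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: registration and
normalization error, brain-shift, non-spherical field spread in
heterogeneous tissue, directional leads, floor/ceiling effects and
non-Gaussian noise in clinical scales, practice effects at retest, and
correlated outcomes across scales.

## Numerical and interface choices

* Voxel indices are 1-based (R array convention); `origin_mm` is the mm
  coordinate of voxel (1, 1, 1). Grids must span the $x = 0$ midline.
* Grid compatibility uses a 1e-3 mm tolerance on voxel size and origin,
  absorbing float32 NIfTI headers.
* The default working grid is 48 × 48 × 40 voxels at 1 mm, centered on
  (0, −14, −7) mm: both subthalamic regions fit, and a 25-patient,
  500-permutation fit runs in ~0.3 s, keeping the calibration suites
  (hundreds of fitted cohorts) at desk scale. These are the problem
  sizes used throughout validation: 200 null cohorts for the
  family-wise-error check, 100 replicates each for recovery and
  prediction operating characteristics, 500 permutations per fit.
* Connected components are labelled by a union-find over the sparse
  supra-threshold set only; no dense volume pass is ever needed.
* Cluster centers are unweighted means of member-voxel mm coordinates;
  a cluster's hemisphere is the sign of its center's x.

## Known limitations

The headline limitation is statistical power, and it is intrinsic to
the design, not an implementation artifact. With 25 patients whose
~3.3 mm spherical VTAs overlap heavily, the coverage patterns of
neighbouring voxels are strongly correlated: under a null permutation,
an outcome that happens to align with one patient's pattern pushes tens
of voxels over the cluster-forming threshold at once, so the null
distribution of the maximum cluster extent is heavy (95th percentile
around 20 voxels of ~700 eligible). A planted 1.5 SD binary effect
produces observed clusters of comparable size, and the acceptance
script's measured detection rate under these conditions is roughly
20–30% — even though empirical family-wise error is nominal and, when
a cluster *is* detected, its center lands within ~1.5 mm of the planted
center (median). Detection improves with larger cohorts, larger or
stronger effects, or less electrode-placement variability; users should
treat a negative map at $n \approx 25$ as weak evidence of absence.
Similarly, the closer/farther prediction comparison on a 6-patient
validation cohort succeeds in only about three quarters of replicates
under a strong planted effect (group means of three patients are
noisy); its value at that scale is demonstrative, not confirmatory.

Other limitations: voxel-level inference is not provided (cluster-level
only — no max-t voxel FWE, no TFCE); the field model ignores anatomy
entirely; percentage changes are undefined at zero baselines and those
patients are excluded per scale; and cluster-extent correction is known
to be sensitive to the cluster-forming threshold, which is surfaced as
configuration rather than solved.
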