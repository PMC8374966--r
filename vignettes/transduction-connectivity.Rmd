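---
title: "Mapping putaminal gene-therapy transduction onto cortico-putaminal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping putaminal gene-therapy transduction onto cortico-putaminal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(putaparc)
```

## The problem

Intraputaminal AAV gene therapy for AADC (aromatic l-amino acid
decarboxylase) deficiency restores local dopamine synthesis. AADC activity
can be imaged with the PET tracer FMT, so the spatial extent of successful
transduction is visible as a supra-baseline uptake region around the
injection tracks. The scientific question this package operationalizes is
*which cortico-putaminal network the transduced tissue belongs to*, and
whether transduction of a particular network's putaminal territory predicts
motor improvement.

The quantification chain is:

1. **SUV**: voxel radioactivity concentration (MBq/g) divided by injected
   dose per body weight — removes dosing differences.
2. **Region-to-occipital ratio**: division by the mean uptake of an
   occipital reference region — removes session-scale differences; the
   resulting maps are invariant under any global rescaling of the input.
3. **Transduction masks**: putaminal voxels whose post-treatment ratio
   strictly exceeds the patient's own baseline putaminal maximum (a
   conservative mask) or baseline 95th percentile (a liberal one). The
   masks are expressed as percent of the whole bilateral putamen, and the
   spread of the supra-max region is summarized as the maximum distance to
   the nearest same-side injection point.
4. **Connectivity-based parcellation**: each putamen voxel is assigned to
   the cortical target ROI receiving its largest streamline count
   (winner-take-all over probabilistic-tractography output), targets are
   aggregated into seven cortical networks and structural motor-system
   regions (PFC, PMC, SMA, M1), and connection-area volume fractions are
   computed with the whole bilateral putamen as denominator.
5. **Statistics**: age-adjusted partial Spearman correlation of the motor
   score against the transduced connection-area fractions; one-sample and
   paired t tests with Holm step-down adjustment; a voxel-wise paired
   contrast with sign-flip permutation cluster-level correction.

Patient images for the motivating study are not publicly deposited, so the
package ships a synthetic phantom cohort generator with known ground truth;
every stage is exercised and tested end to end on phantoms.

## The phantom generator

`phantom_spec()` fixes the study conditions; `simulate_cohort()` produces a
cohort. The generator emulates, on a 64³ grid of 2 mm voxels (the PET
acquisition voxel size):

- **Anatomy**: bilateral putamen ellipsoids (semi-axes 8 × 18 × 10 mm,
  ≈ 6 cm³ per side, ≈ 1500 voxels bilaterally) and an occipital reference
  box, disjoint by construction.
- **Baseline PET**: background and occipital intensity near 1 (ratio
  units), putamen slightly higher (1.05), additive Gaussian noise
  (sd 0.02). Background sits at occipital level so ratios hover near 1
  outside transduced tissue.
- **Post-treatment PET**: one Gaussian hotspot per injection track
  (two tracks per side: anterior and posterior), width σ = 3.5 mm,
  truncated to the putamen; 2Y amplitudes decay by 0.9 relative to 6M.
  The Gaussian spread is a modeling assumption — no quantitative spatial
  model of AAV diffusion is available — and is flagged as such in the
  stored truth.
- **Ground-truth parcellation**: structural regions are anterior-posterior
  bands (anterior = PFC-like, posterior = sensorimotor), subdivided per
  region by nearest-centroid (Voronoi) fields among that region's targets;
  K = 60 targets spread over the seven networks. K = 60 rather than the
  atlas-scale 1000 keeps the hierarchy aggregation fully exercised while
  tests stay fast; K is configurable.
- **Streamline counts**: per putamen voxel, 5000 multinomial draws with
  probability κ on the true label and the rest spread evenly (κ = 0.5 by
  default, i.e. moderately noisy tractography).
- **Motor scores**: ΔAIMS = intercept + β·(prefrontal transduced %) +
  γ·age + noise, rounded and clipped to the AIMS range 0–58 (the ceiling
  is configurable). Defaults β = 1.5 points per percent, γ = −0.4
  points/year, noise sd 1.5 give a strong but noisy designed effect,
  qualitatively matching a cohort where the prefrontal association
  dominates.

**The designed independence structure.** Per-patient variability enters
through two *independent* track amplitudes drawn uniformly on
[0.4, 1.6]× the base amplitude: the anterior track sits inside the PFC
band (reachable supra-threshold radius always below the distance to the
band edge), the posterior track inside the motor bands. The prefrontal
transduced fraction is therefore driven by the anterior amplitude and the
PMC/SMA/M1 fractions by the posterior one, so a motor score designed on
the prefrontal fraction is, by construction, uncorrelated with the motor
territories (up to the small shared variability of the per-patient
baseline-maximum threshold). This is what makes the region-specificity
check meaningful. The geometric side effect is that the hotspot width had
to stay small (σ = 3.5 mm) relative to the putamen, so the phantom's mean
supra-threshold spread (~8–10 mm) sits below the ~11.6 mm scale reported
for real patients; the transduced volume fractions (~45–55% supra-max,
~60–70% supra-p95) land in the reported range.

What the phantom does *not* emulate: registration error between modalities
(all inputs share one grid per patient), scanner differences, kinetic
effects, partial-volume effects, spatially structured tractography error
(count noise is exchangeable across targets), and real AIMS psychometrics.
A passing suite therefore validates the computational chain and its
statistical calibration, not robustness to those real-data effects.

## Numerical conventions

- **Percentiles** use linear interpolation between order statistics
  (`quantile(type = 7)`), fixed so the 95th-percentile threshold is
  reproducible.
- **Supra-threshold membership** is strict (`>`): at float resolution ties
  have measure zero, but the choice is pinned for determinism.
- **Winner-take-all ties** go to the smallest target id; voxels with zero
  streamlines everywhere stay unlabeled and are excluded from numerators
  but never from the whole-putamen denominator (the printed volume-fraction
  formulas keep the whole putamen as denominator).
- **Coordinates**: 0-based voxel indices, world = origin + index·spacing,
  axis-aligned only; all registration is out of scope. Distances use voxel
  centers; voxel laterality for the distance profile is decided by the
  nearer side's injection-point centroid, which keeps the profile invariant
  under joint rigid translation.
- **Seeds**: every stochastic stage consumes
  `seed_stream(master, i, j) = (master + 7919 i + 104729 j) mod 2147483647`.
  The two multipliers are coprime primes so patient and stage streams do
  not collide; a whole run is a pure function of the master seed. The run
  manifest contains no wall-clock timestamps, so identical configs rerun to
  byte-identical manifests.

## Cluster-level inference: mass, not extent, by default

The longitudinal voxel-wise contrast regresses each voxel's paired
difference (post − baseline, smoothed at 3 mm FWHM) on an intercept plus
centered age and tests the intercept — the standard paired-ANCOVA reading
of an age-adjusted paired contrast. Clusters are formed at two-sided
uncorrected p < 0.001, and family-wise error at the cluster level is
controlled by sign-flipping the patient difference maps (all 2ⁿ
combinations when feasible, making the test exact) and comparing each
observed cluster against the null distribution of the per-flip maximum
cluster summary.

The published convention summarizes clusters by *extent* (voxel count).
Measured on null phantoms at this resolution (2 mm voxels, 3 mm FWHM), the
null maximum-extent distribution is supported on only a handful of integers
— P(max ≥ 3) ≈ 0.08 and P(max ≥ 4) ≈ 0.008 — so no cutoff achieves a 5%
level and the test is forced to operate at ≈1%. The package therefore
defaults to cluster *mass* (the sum over the cluster of |t| in excess of
the cluster-forming threshold), a continuous statistic with a long pedigree
in the permutation literature, which calibrates to the nominal level
(measured ≈ 0.055 over 200 null cohorts, within the binomial band of 0.05).
`cluster_stat = "extent"` remains available for comparability.

The partial Spearman p value uses the t approximation on n − 3 degrees of
freedom by default; at the study size of n = 8 this approximation is rough,
and the permutation option (`method = "permutation"`) is the preferable
one there. The approximation is the default for comparability with common
practice; its null calibration at n = 50 is verified by simulation in the
test suite.

## Pairing scheme for transduced connection areas

Transduced connection areas pair the *baseline* parcellation with the *6M*
transduction mask (networks presumed functionally restored at 6M) and the
*2Y* parcellation with the *2Y* mask (networks still functioning at 2Y).
This pairing is encoded as the pipeline default. Left and right putamen are
parcellated within one bilateral map and all fractions use the bilateral
putamen denominator.

## Problem sizes used by the checks

The verification suite runs at sizes chosen to make the statistical
properties measurable while remaining desk-scale: the family-wise error of
the cluster correction is measured over 500 null cohorts of 8 patients on
the reduced 32³ grid; the null calibration of the partial correlation over
2000 simulated datasets of n = 50; designed-effect recovery on one
200-patient phantom cohort against a 10⁵-replicate score-model oracle; and
determinism on the default 8-patient, 64³ pipeline run twice.

## Known limitations

- The transduction masks inherit the per-patient baseline-maximum
  threshold, an extreme-value statistic; its sampling variability couples
  weakly into *all* fraction estimates of a patient (a shared multiplicative
  factor). On phantoms this induces a small positive correlation (~0.1)
  between otherwise independent territory fractions.
- Winner-take-all ignores the margin between the top counts; near-tied
  voxels are assigned with false confidence. The κ-sweep in the tests
  quantifies recovery as a function of count concentration.
- The AIMS model is linear-with-clipping; ceiling effects at high scores
  compress the designed effect, which is why effect-recovery checks avoid
  the ceiling.
- One anatomy template is shared across phantom patients; between-patient
  anatomical variability is not modeled.
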