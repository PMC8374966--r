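# putaparc

Quantifying where in the putamen a gene therapy took hold, and which
cortico-putaminal network that tissue serves.

In AADC (aromatic l-amino acid decarboxylase) deficiency, AAV-mediated
delivery of the missing enzyme into the bilateral putamen restores local
dopamine synthesis. PET with an AADC tracer (FMT) makes the transduced
tissue visible as a supra-baseline uptake region around the injection
tracks. `putaparc` implements the full quantification chain that links that
imaging signal to structural connectivity and motor outcome, for
researchers analyzing intraputaminal gene-therapy imaging or building
phantom-validated pipelines of this kind:

- **PET quantification** — standardized uptake value
  `SUV = C (MBq/g) / (dose (MBq) / weight (g))`, region-to-occipital
  normalization, median ROI uptake tables.
- **Transduction mapping** — per-patient masks of putaminal voxels whose
  post-treatment ratio exceeds the patient's own baseline maximum (or 95th
  percentile), volume fractions of the whole bilateral putamen
  (`100·|mask|/|putamen|`), and the maximal spread from the injection
  points.
- **Connectivity-based parcellation** — winner-take-all assignment of each
  putamen voxel to the cortical target with the largest streamline count,
  aggregation into seven cortical networks and structural regions
  (PFC/PMC/SMA/M1), connection-area fractions
  `100·|voxels labeled t ∩ mask|/|putamen|`, and cosine similarity of
  network profiles across patients.
- **Statistics** — partial Spearman correlation adjusted for age at
  treatment (`ρ_xy·z` on average ranks, t or permutation p), paired and
  one-sample t tests with 95% CIs, Holm step-down adjustment, and a
  voxel-wise paired contrast with sign-flip permutation cluster-level
  correction.
- **Synthetic phantom cohort** — because the motivating study's patient
  images are not publicly deposited, a generator produces phantoms with
  known ground truth (anatomy, hotspots, parcellation, scores), and every
  stage is validated against that truth.

## Worked example

The `analysis/` scripts run the full workflow on the default 8-patient
phantom cohort (64³ grid, 2 mm voxels) and write all outputs under
`results/run/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_petquant.R
Rscript analysis/03_parcellate.R
Rscript analysis/04_analyze.R
```

`02_petquant.R` prints the transduced volume summary:

```
supra-max transduced fraction at 6M: 47.8% +/- 1.6% (mean +/- SEM, n = 8)
max spread from injection tracks: 10.6 mm (mean)
```

i.e. about half of the phantom putamen exceeds the baseline maximum at six
months, spreading ~10 mm from the delivery tracks. `04_analyze.R` prints
the headline correlations:

```
age-adjusted partial Spearman, 6M motor score vs transduced fraction:
                   unit n statistic      p
                    PFC 8    0.8040 0.0293
                    PMC 8    0.0159 0.9731
                    SMA 8    0.0159 0.9731
                     M1 8    0.2259 0.6262
 PFC in control network 8    0.7746 0.0409
```

The motor score tracks the prefrontal transduced fraction (the phantom's
designed effect) and not the premotor/primary-motor fractions — the
region-specificity the pipeline is built to detect. Equivalent programmatic
entry points are `simulate_cohort()`, `transduction_mask()`,
`winner_take_all()`, `connection_fractions()` and
`run_headline_analyses()`; `run_pipeline()` drives all stages from one YAML
config with a deterministic seed ledger and an MD5 run manifest.

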