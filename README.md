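# trmspatial

Spatial proximity analysis of tissue-resident CD8⁺ T cells in multiplex
immunofluorescence (mIHC) data.

## The problem

In many solid tumours — cholangiocarcinoma among them — the prognostic
value of CD8⁺ tissue-resident memory (T_RM) T cells depends not only on
how many of them infiltrate a sample but on *where they sit relative to
the tumour cells*, and on their functional state (PD-1⁻ "naive" T_RM vs
PD-1⁺ exhausted T_RM, both CD103⁺CD8⁺). `trmspatial` provides, for
segmented mIHC cell tables (per-cell coordinates in µm plus mean
fluorescence intensities for PanCK, CD8, CD103, PD-1, CD69, TCF-1), the
full analysis chain that turns such tables into survival-ready spatial
features:

1. **Phenotyping** — hierarchical intensity gating (`gate_phenotypes()`):
   PanCK⁺ tumour first, then CD8⁺ subsets split by CD103/PD-1/CD69/TCF-1;
   plus the companion scRNA quality filter (`qc_filter()`: features in
   [200, 3000], mitochondrial fraction < 10%, erythroid fraction < 1%)
   and mean-expression signature scoring (`signature_score()`).
2. **Compartments** — `build_tumor_region()` dilates PanCK⁺ positions
   into a tumour region (union of disks, default radius 15 µm, debris
   components dropped) and `assign_compartments()` labels every cell
   intra-tumour or stromal with a signed boundary distance.
3. **Spatial statistics** — per-compartment densities (cells/mm²) and
   fractions of the CD8⁺ population, 10-µm distance-band infiltration
   profiles within 100 µm of the boundary, counts of immune cells within
   a 10-µm interaction radius of each tumour cell, mean tumour→T-cell
   nearest distances, and the **G-cross** function with its proximity
   score.
4. **Survival** — Wilcoxon/paired-t group comparisons, median-split
   Kaplan–Meier with log-rank tests, and uni-/multivariate Cox
   proportional-hazards models adjusted for age group, sex and TNM stage.

The central statistic is the cross-type nearest-neighbour distribution

&nbsp;&nbsp;&nbsp;&nbsp;Ĝ(r) = (1/n_tumour) · #{ tumour cells whose nearest target-phenotype cell is within r },

evaluated on a 0.5-µm grid up to r_max = 30 µm; the **proximity score**
is AUC₀₋₃₀ / 30 ∈ [0, 1] (trapezoid rule). Under complete spatial
randomness of the targets, E[Ĝ(r)] = 1 − exp(−λπr²), which the test
suite uses as a closed-form oracle.

Because patient imaging data cannot ship with a package, `trmspatial`
includes a first-class synthetic-cohort generator: tumour islets from a
Thomas (Neyman–Scott) cluster process, immune phenotypes with a tunable
attraction-to-tumour fraction ρ (exponential distance kernel), log-normal
marker-intensity mixtures with known ground-truth labels, and
exponential proportional-hazards survival whose hazard depends on the
standardised PD-1⁻ T_RM proximity score. Every stage of the pipeline is
validated against this ground truth.

## Worked example

```r
library(trmspatial)

cfg <- simulation_config(seed = 3)      # one 1 mm^2 core, ~2000 cells
sim <- simulate_sample(cfg)

thr <- estimate_gating_thresholds(sim$cells)   # or calibrated thresholds
gated  <- gate_phenotypes(sim$cells, gating_config(thr))
region <- build_tumor_region(gated)
print(region)
#> Tumour region: 1467 disk(s) of radius 15 um in 5 component(s)
#>   area 175461 um^2 (0.1755 mm^2), built from 1475 tumour cells (min component 5)

gated <- assign_compartments(gated, region)
print(gcross(gated, "trm_pd1neg"))
#> G-cross: tumour -> trm_pd1neg (1475 reference, 60 target cells)
#>   AUC[0-30 um] = 6.25 um, proximity score = 0.208

summ <- spatial_summary(gated, region)
summ[, c("phenotype", "n_intra", "n_stroma", "density_intra", "gcross_score")]
#>    phenotype n_intra n_stroma density_intra gcross_score
#> 1 trm_pd1neg      29       31     165.27883   0.20842373
#> 2 trm_pd1pos      20       40     113.98540   0.11641243
#> 3    cd8_pd1      29       31     165.27883   0.15798305
#> 4   cd8_cd69      17       23      96.88759   0.09722599
#> 5   cd8_tcf1      17       23      96.88759   0.11948023
#> 6        cd8      57       93     324.85839   0.29088701
```

A proximity score of 0.208 for the PD-1⁻ T_RM subset means that,
averaged over radii up to 30 µm, about a fifth of tumour cells already
have their nearest PD-1⁻ T_RM cell within that radius — the sample shows
moderate tumour-directed T_RM accumulation (this sample was generated
with attraction ρ = 0.3).

Cohort-level association with outcome:

```r
co <- simulate_cohort(simulation_config(seed = 11, n_patients = 500),
                      keep_cells = FALSE)
cox_model(co$cohort, "score_trm_pd1neg_z")
#> Cox proportional hazards (261 events)
#>             feature               term    HR         95% CI         p
#>  score_trm_pd1neg_z score_trm_pd1neg_z 0.497 [0.437, 0.565] 1.082e-26
#>  score_trm_pd1neg_z      age_group>=65 1.151 [0.896, 1.479]    0.2713
#>  score_trm_pd1neg_z               sexM 1.017 [0.795, 1.301]    0.8932
#>  score_trm_pd1neg_z          tnm_stage 1.040 [0.929, 1.165]    0.4938
```

The generator's true effect was a hazard ratio of 0.5 per standard
deviation of the proximity score; the multivariate fit recovers it, and
the clinical covariates (simulated independently of the score) stay
null. `run_pipeline()` chains all stages over a cohort and writes
per-stage tables plus a hash manifest; `make_report()` assembles CSV
summaries. A thin CLI over the same functions ships as `inst/cli.R`
(`simulate | gate | compartments | spatial | survival | run | report`).

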