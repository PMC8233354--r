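# psfBEF

Plant–soil feedback (PSF) analysis for biodiversity–productivity research.

Plants train the soil they grow in, and trained soil changes the growth of
the next plant. Because these feedbacks are mostly negative (species-
specific soil pathogens accumulate), plants in diverse communities — which
are mostly surrounded by *other*-trained soil — can escape their own
pathogens, offering a mechanistic explanation for why species-rich
grassland communities overyield. `psfBEF` is aimed at community ecologists
who run (or simulate) two-phase factorial soil-training experiments
alongside biodiversity–productivity experiments and want one tested
pipeline from plot records to mechanism attribution.

The package implements:

* **PSF index estimation** — for species *i* on soil trained by species
  *j*, `PSF_ij = (S − O) / max(S, O)` with `S` mean biomass on self-trained
  and `O` on other-trained soil, bounded in [−1, 1]; percentile bootstrap
  confidence intervals from raw replicate resampling; species-level means,
  between-year paired tests, functional-group tests, and distance
  regressions.
* **Community growth simulation** — a discrete logistic model in which soil
  composition `f` is trained by plant biomass (`f_j ← f_j + c·B_j`,
  renormalized) and each species grows at the soil-weighted rate
  `r̂_i = Σ_j f_j r_ij`, limited by community-level or species-level
  carrying capacities (five data-derived definitions). Feedback ensembles
  (per-soil rates × 5 capacities) versus null ensembles (control- or
  self-soil rates, one soil type, × 5 capacities).
* **Loreau–Hector additive partitioning** —
  `ΔY = N·mean(ΔRY)·mean(M) + N·cov(ΔRY, M)` (complementarity +
  selection, population covariance so the identity is exact), with
  twice-biculture monoculture imputation and a 5×IQR outlier screen.
* **Reporting layer** — log-linear richness fits, predicted-vs-observed
  OLS with RMSE, through-origin cover-to-biomass calibration, and
  overyielding arithmetic.
* **Synthetic-data generator** — a 16-species, 4-functional-group pool
  under the factorial field layout (27–35 self / 5–9 other replicates, 63
  communities in 232 plots), with a configurable true feedback matrix and
  lognormal plot noise, calibrated so defaults reproduce field-scale
  summary statistics (mean |PSF| ≈ 0.27, net ≈ −0.10).

## Worked example

```r
library(psfBEF)

design <- default_design()            # 63 communities, factorial PSF layout
truth  <- true_psf_model(seed = 1)    # ground-truth feedbacks + base biomass
psf    <- generate_psf_experiment(truth, design)
comm   <- generate_community_experiment(truth, design)

mat <- psf_matrix(psf, year = 2018, n_boot = 1000, seed = 1)
round(unlist(psf_summary(mat)), 3)
#> mean_abs_psf net_mean_psf      n_cells
#>        0.262       -0.088      240.000
```

Soils trained for two years changed subsequent growth by 26% on average
(mean absolute index), but because positive and negative feedbacks partly
cancel, the net effect is a 9% growth reduction — the signature of
predominantly negative feedback. Of the 240 species×soil cells, 109 have
bootstrap intervals excluding zero here.

```r
ens  <- run_ensemble(design, "psf", psf, comm)   # 5-member feedback ensemble
part <- partition_by_richness(ens$mean)
subset(part$richness, richness == 16)
#>   richness n  net complementarity selection
#> 5       16 1 37.7              32      5.71
```

The feedback ensemble predicts 37.7 g per plot of overyielding in the
16-species community, attributed mainly to complementarity (32.0 g) —
species escape their self-trained soil in mixture — rather than selection
(5.7 g).

```r
loreau_hector(M = c(100, 100), Y = c(60, 60))
#> Net biodiversity effect: 20.000 (complementarity 20.000 + selection 0.000), N = 2

subset(overyielding_report(), dataset == "psf_model")
#>     dataset difference percent_increase share_of_observed_pct
#> 3 psf_model         16             26.6                  13.5
```

The last call reruns the published summary arithmetic: the feedback model's
16 g m⁻² predicted gain is a 27% increase over predicted monocultures and
accounts for ~14% of the overyielding observed in the field experiments.

The whole chain (generate → index → simulate → partition → report) runs as
one seeded, manifest-checked pipeline:

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "psf-run")
```

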