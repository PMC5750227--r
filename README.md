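# netspread

Network-spread modeling of longitudinal cortical thinning in early
Parkinson's disease.

## The problem

Neurodegenerative disease is hypothesized to propagate along the brain's
connectome: cortical regions strongly connected to already-affected
territory should deteriorate faster. In de novo Parkinson's disease,
baseline atrophy concentrates in a subcortical "disease reservoir"
(thalamus, basal ganglia, hippocampus, amygdala, brainstem). `netspread`
tests whether one-year cortical thinning follows connectivity to that
reservoir. For each cortical parcel *i* it computes the **disease
exposure**

    exposure(i) = Σ_j Conn_ij · Atrophy(j)

— reservoir atrophy z-values weighted by the parcel's connectivity to each
reservoir region *j* — and relates it to the longitudinal thinning contrast
(the per-vertex group-difference t-statistic of Δt = t₁ − t₂, positive =
more thinning in PD, averaged into parcels) by Spearman correlation, with a
permutation test that keeps the connectivity structure intact and permutes
thinning across parcels, and a percentile bootstrap CI over parcels.
Functional, structural (tractography), and pure Euclidean-distance
connectomes are compared; the reservoir can be restricted to the basal
ganglia. The package also provides the vertex-wise longitudinal contrast
with permutation cluster-extent correction, intrinsic-network (Yeo-7)
summaries, clinical/CSF group statistics, partial correlations, and a
cognition (MoCA) regression — plus a synthetic-data generator that emulates
the statistical structure of a two-group, two-timepoint, multi-site
cortical-thickness study so the entire pipeline is testable without
patient data.

It is aimed at researchers who want a tested, reproducible reference
implementation of the exposure statistic and its inference, or a harness
for power/calibration experiments on connectome-spread analyses.

## Worked example

A complete seeded run on a small synthetic brain (40 cortical + 6
subcortical parcels, 30 PD vs 20 controls, thinning driven through the
functional connectome):

```r
library(netspread)

cfg <- list(synth = list(n_cortical = 40, n_subcortical = 6,
                         vertices_per_parcel = 4, n_pd = 30, n_hc = 20),
            n_perm = 999, n_boot = 999, t_threshold = 2, seed = 7)
res <- run_pipeline(cfg, out_dir = "netspread-demo")

res$associations[["functional.all.whole"]]
#> association (functional, scope whole, n = 40): rho = 0.507,
#>   95% CI [0.192, 0.734], p_perm = 0.001 (two.sided, n_perm = 999)

res$associations[["distance.all.whole"]]
#> association (distance, scope whole, n = 40): rho = -0.489,
#>   95% CI [-0.712, -0.200], p_perm = 0.004 (two.sided, n_perm = 999)

res$associations[["functional.basal_ganglia.whole"]]
#> association (functional, scope whole, n = 40): rho = 0.459,
#>   95% CI [0.102, 0.714], p_perm = 0.003 (two.sided, n_perm = 999)

wb <- res$whole_brain$PD
sprintf("PD whole-brain: %.3f -> %.3f mm (paired t = %.1f)",
        wb$mean_t1, wb$mean_t2, wb$t)
#> "PD whole-brain: 3.094 -> 3.066 mm (paired t = 30.6)"
```

Reading the output: thinning correlates positively with functional
exposure (parcels more connected to the reservoir thin more; rho = 0.51,
permutation p = 0.001) and negatively with the distance-weighted comparator
(parcels *nearer* the reservoir thin more), exactly the planted spread
mechanism; whole-brain mean thickness declines in the PD group across the
follow-up interval. `run_pipeline()` writes delimited reports
(`associations.tsv`, `clusters.tsv`, `networks.tsv`, …), a JSON summary,
and a run log to the output directory; identical config + seed reproduces
the outputs byte for byte. Every stage is also callable directly
(`disease_exposure()`, `associate()`, `longitudinal_contrast()`,
`cluster_correction_permutation()`, `network_summary()`,
`multivariate_fit()`, `chi2_2x2()`, …) and all file formats are plain
delimited text with documented schemas.

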