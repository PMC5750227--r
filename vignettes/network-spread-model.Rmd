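---
title: "Modeling network spread of cortical thinning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling network spread of cortical thinning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netspread)
```

## The model

The network-spread hypothesis holds that neurodegeneration propagates along
the brain's connectome: cortical regions that are strongly connected to
already-affected territory should deteriorate faster. `netspread`
operationalizes this for early Parkinson's disease, where baseline atrophy
is concentrated in a subcortical "disease reservoir" (thalamus, basal
ganglia, hippocampus, amygdala, brainstem). For each cortical parcel $i$ the
**disease exposure** is

$$\mathrm{exposure}(i) \;=\; \sum_{j \in \mathrm{reservoir}}
  \mathrm{Conn}_{ij}\,\cdot\,\mathrm{Atrophy}(j),$$

the reservoir's atrophy burden (baseline z-values; zero outside the
reservoir) weighted by the connectivity $\mathrm{Conn}_{ij}$ of parcel $i$
to each reservoir parcel $j$. Connectivity can be functional (resting-state
correlation), structural (tractography-derived), or — as a geometric null
model — the raw Euclidean centroid distance, in which case the hypothesized
association is negative (parcels *nearer* the reservoir thin more).

Disease progression is the longitudinal thinning contrast: per vertex,
$\Delta t = t_1 - t_2$ (positive = thinning) is regressed on a group
indicator plus covariates (acquisition site by default), and the group
coefficient's t-statistic — positive when PD thins more than controls — is
averaged into parcels. The spread hypothesis is then a Spearman rank
correlation $\rho$ between per-parcel thinning and exposure, with

* a **permutation p-value** that keeps the connectivity structure and the
  atrophy fixed and permutes the thinning values across parcels within the
  analysis scope (whole cortex, left, or right hemisphere; the reservoir
  always spans both hemispheres), using the add-one estimator
  $(k+1)/(n_\mathrm{perm}+1)$; and
* a **percentile bootstrap 95% CI** resampling parcels — the correlation's
  sampling unit — with replacement.

The permutation test is two-sided by default with an `alternative` argument
for directional hypotheses; published analyses of this kind do not always
state sidedness, so we keep the conservative default and expose the switch.
Spearman uses average ranks for ties. A multivariate variant regresses
parcel thinning on functional and structural exposures jointly to weigh the
two modalities' contributions.

## What the synthetic generator emulates

Because the motivating study's MRI data cannot be redistributed, the
package ships a generator whose *defaults are the study conditions* and
whose planted effect makes parameter recovery the testing surface:

| parameter | default | meaning |
|---|---|---|
| `n_cortical`, `n_subcortical` | 448, 15 | parcel counts of the 463-region scheme |
| `n_pd`, `n_hc` | 105, 57 | group sizes |
| `baseline_mean` | 3.055 mm | mean baseline cortical thickness |
| `aging_thinning` | 0.019 mm | common thinning over the 1-year interval |
| `b` | 0.009 mm | mean PD-specific extra thinning |
| `noise_sd` | 0.03 mm | vertex-level measurement noise |
| `subject_sd` | 0.13 mm | between-subject baseline spread |
| `n_sites`, `site_sd` | 3, 0.005 mm | additive per-site offsets at follow-up |
| `distance_decay` | 30 mm | connectivity decay length $\lambda$ |
| `interhemi_attenuation` | 0.2 | cross-hemisphere structural weight multiplier |
| `conn_noise_sd` | 0.05 | functional-weight measurement noise |

The cohort-level values (group sizes, 3.055 mm baseline, 0.019 mm aging
thinning, and `b` = 0.028 − 0.019 = 0.009 mm PD excess) are taken directly
from the published cohort; the remaining magnitudes are field-typical
choices: a ~0.13 mm between-subject SD reproduces the reported ±0.013
standard error of whole-brain thickness at n = 105, a 30 mm decay length is
a conventional scale for distance-dependent connectivity, and 0.03 mm
vertex noise is of the order of surface-pipeline measurement error after
smoothing.

Geometry is deliberately stylized: two mirrored hemispheric shells of
cortical centroids, a medial subcortical block with named bilateral
structures plus a midline brainstem, and vertices jittered around their
parcel centroid with a within-hemisphere k-nearest-neighbour adjacency.
Follow-up thickness subtracts aging, a site offset, and — in the PD group
only — `b` times the parcel's disease exposure, plus noise. The generator
normalizes the exposure vector to mean 1 before applying `b`, so `b` stays
interpretable in millimetres regardless of connectome scaling; all
downstream rank-based inference is invariant to this normalization.

What the generator does *not* emulate: real cortical folding and
registration error, spatial autocorrelation of measurement noise along the
surface, medication effects, dropout, or any tractography biases beyond a
single interhemispheric attenuation factor and a lognormal weight noise.
Passing tests therefore demonstrate that the statistical machinery recovers
a planted connectivity-mediated effect under idealized conditions — not
that the hypothesis is true of any real cohort.

## Cluster inference

Vertex-wise group differences are corrected for the familywise error by a
cluster-extent permutation scheme: group labels are permuted within
acquisition-site strata, the vertex-wise contrast is recomputed, and the
null distribution of the maximum supra-threshold cluster size calibrates
each observed cluster's p-value. This replaces random-field-theory cluster
inference (used with full-resolution surfaces in the motivating study),
which depends on resel machinery that is out of scope here; permutation is
assumption-light and exactly valid under within-stratum exchangeability.
Consequences: resel counts and the study's cluster vertex counts are not
reproduced, and on small synthetic surfaces the extent statistic is
discrete — cluster sizes are small integers with heavy ties — so realized
familywise rates sit at or below the nominal level. For that reason the
calibration checks use a cluster-forming threshold of t = 2 on the reduced
surface, which keeps the null maximum-size distribution non-degenerate;
with stricter thresholds almost every null dataset has no supra-threshold
vertex at all and the test becomes conservative rather than invalid.

## Numerical and design choices

* **Vertex-to-parcel mapping** is nearest cortical centroid by Euclidean
  distance, restricted to the vertex's hemisphere, with exact ties broken
  toward the lower parcel id — deterministic and order-invariant. The
  original study "interpolated" vertices to parcels without stating the
  scheme; nearest-centroid is our stand-in.
* **Sign conventions**: $\Delta t = t_1 - t_2$ everywhere, so positive
  values mean thinning and a positive group effect means more thinning in
  PD. The distance comparator's hypothesized direction is negative.
* **Zero-variance guards**: constant exposure or thinning aborts
  association with an explicit error; a perfectly fit vertex reports t = 0
  for a null effect rather than a ratio of rounding noise; a whole-brain
  panel with no change at all reports a paired t of 0, while a nonzero
  constant change is flagged degenerate instead of returning ±Inf.
* **Negative functional correlations are retained** in exposure sums by
  default (the least-intervention reading of the published procedure);
  zeroing them is one transform away in user code since exposure is linear
  in the connectome.
* **Multivariate fit** refuses predictor pairs with |r| > 0.99 and reports
  unstandardized coefficients by default (`standardize` switch available);
  degrees of freedom are the actual n − 3.
* **Permutation defaults** are n = 10,000 for both permutation and
  bootstrap, matching common practice at full scale; every stochastic
  routine takes an explicit seed and restores the caller's RNG state, so
  generators and inference are pure functions of (arguments, seed).

## Hemisphere mixing and the structural connectome

A finding from this package's own simulations worth recording: attenuating
interhemispheric structural weights does not by itself degrade whole-brain
rank correlations in a mirror-symmetric brain, because both the thinning
and the measured exposure then separate the hemispheres in the same
direction, and Spearman only sees ranks. The published pattern — positive
per-hemisphere structural associations with a near-zero whole-brain one —
emerges in simulation only when hemisphere-scale differences in measured
connectivity (e.g., tractography sensitivity differing between
hemispheres) interact with the *absence* of cross-hemisphere terms that
could anchor the two hemispheres on a common scale. Per-hemisphere
associations are untouched by any hemisphere-wide rescaling since Spearman
is scale-invariant within scope. The corresponding property test plants
exactly this mechanism.

## Problem sizes used in testing

The test-suite simulations run at reduced scale: a 40 cortical + 6
subcortical parcel brain with 3 vertices per parcel for calibration
(500 null replicates at $n_\mathrm{perm}$ = 199), recovery (200 replicates
at the cohort's 105 + 57 group sizes), and cluster calibration
(200 replicates); a 100 + 10 parcel brain for the functional-versus-
distance model comparison, where sharper rho estimates let the comparison
reflect the generating mechanism rather than estimation noise; and 300
bivariate-normal replicates for bootstrap coverage, where the population
Spearman correlation has the closed form $(6/\pi)\arcsin(r/2)$ and so
provides an exact external truth. These sizes are the package's choices
for desk-scale verification; all scale up through `synth_config()`.

## Known limitations

Exposure is a one-step linear projection of baseline atrophy through the
connectome — there is no dynamic accumulation, clearance, or multi-hop
spread kinetics. Cluster inference assumes exchangeability within site
strata and ignores spatial autocorrelation beyond the surface adjacency.
The synthetic atlas's geometry is a caricature; absolute effect sizes on
it do not transfer to real parcellations, only the statistical operating
characteristics do. Reported multivariate coefficients are internally
sign-consistent but not comparable to published betas whose predictor
scaling is unknown.

## A minimal run

```{r example, eval = FALSE}
cfg <- list(synth = list(n_cortical = 40, n_subcortical = 6,
                         vertices_per_parcel = 4, n_pd = 30, n_hc = 20),
            n_perm = 999, n_boot = 999, t_threshold = 2, seed = 7)
res <- run_pipeline(cfg, out_dir = "netspread-demo")
res$associations[["functional.all.whole"]]
```
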