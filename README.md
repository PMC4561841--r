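# pondscape

Landscape genetics of wetland networks: does the spatial and temporal
structure of breeding habitat explain how genes move through an amphibian
metapopulation? `pondscape` implements the full analysis chain for
pond-breeding, dispersal-limited species such as the boreal chorus frog
(*Pseudacris maculata*): microsatellite genetic distances, habitat graphs
under a calibrated dispersal kernel, probability-of-connectivity node
importance, terrain covariates, and singly-constrained gravity models —
plus a synthetic-data generator that reproduces the statistical structure of
an 18-wetland montane study system so that every stage is testable without
field data.

## The models

**Functional connectivity.** Gene flow between wetlands *i* and *j* is
proxied by `T_ij = 1 − D_ps(i, j)`, where `D_ps` is the proportion-of-
shared-alleles distance computed from multilocus microsatellite genotypes
(with full-sib larval clusters subsampled to the smallest cluster per site
to avoid allele-frequency bias). Nei's `G_ST = (H_T − H_S) / H_T`
summarizes hierarchical differentiation.

**Gravity model.** Flows follow the power-law gravity equation

```
T_ij = k · v_i^mu · w_ij^alpha · c_ij^-beta
```

with origin production terms `v`, distance `w` and edge resistance terms
`c`. Taking natural logs linearizes it; the singly-constrained form is fit
as a linear mixed model with an independent random intercept `k` per origin
site (maximum likelihood, so AIC is comparable across fixed-effect
structures). Candidate models always contain geographic distance; models
within 2 ΔAIC form the top set, and the corridor bandwidth of between-site
covariates (30/60/120/240 m) is itself selected by AIC.

**Habitat graphs and dPC.** Wetlands are nodes with habitat attribute
`a_i` (area, optionally scaled by the fraction of years a snowpack category
keeps the wetland productive); edges carry dispersal probabilities
`p_ij = exp(−θ d_ij)` from a negative-exponential kernel calibrated so that
the species' ~600 m maximum dispersal distance retains a 5% exceedance
probability. With `p*_ij` the best product-probability path, the
probability-of-connectivity numerator is `Σ_i Σ_j a_i a_j p*_ij`, and each
node's importance `dPC_k` (percent loss on removal) splits exactly into
**Intra** (own area), **Flux** (direct area-weighted exchange) and
**Connector** (irreplaceable stepping-stone role). Three constructions are
provided: the spatial-breeding network (occupied wetlands), the
temporal-breeding network (availability-weighted attributes from a
snowpack-depth threshold of 63.5 cm), and the stepping-stone network
(occupied wetlands plus all unoccupied candidates above 400 m²).

**Terrain covariates.** From ESRI ASCII grids: compound topographic index
`ln(a / tan β)` (Horn slope, strict-descent D8 accumulation), surface
relief ratio, relative slope position, precipitation ratio, meadow:forest
and impervious cover — within 100 m wetland buffers and along straight
between-wetland corridors at multiple bandwidths, with topographically
corrected distances and a pairwise-R²/VIF collinearity screen.

## Worked example

```r
library(pondscape)

kernel <- calibrate_kernel(d_ref = 600, p_ref = 0.05)
round(kernel_prob(kernel, c(0, 300, 600, 1200)), 4)
#> [1] 1.0000 0.2236 0.0500 0.0025

wetlands <- generate_wetlands(landscape_spec(seed = 42))   # 18 + 110 wetlands
snow     <- generate_snow_series(snow_series_spec(seed = 42))
classify_availability(snow$depth_cm, threshold_cm = 63.5)
#>   category available_years total_years
#> 1      low              15          33
#> 2     high              18          33
#> 3  neutral              33          33

stepping <- build_network(wetlands, kernel, "stepping_stone", min_area = 400)
stepping
#> wetland_network (stepping_stone): 128 nodes, 8128 edges, theta = 0.004993

spatial <- build_network(wetlands, kernel, "spatial")
res <- dpc_decomposition(spatial)
connectivity_report(res, spatial$nodes$id[1:4])
#>    id   dpc_pct intra_pct  flux_pct connector_pct network_kind
#> 1 B01 0.5693094 0.4246425 0.1446670             0      spatial
#> 2 B02 3.5733455 1.5564509 2.0168947             0      spatial
#> 3 B03 2.7183245 1.7172537 1.0010708             0      spatial
#> 4 B04 1.3392117 1.2317719 0.1074397             0      spatial
```

`kernel_prob` drops to exactly 0.05 at 600 m (the calibration constraint);
the stepping-stone graph has the full 18 + 110 = 128 nodes because every
generated candidate passes the >400 m² filter. Each wetland's `dpc_pct` is
the percent of total connectivity lost if it were removed, and equals
`intra + flux + connector` to machine precision; on a complete
exponential-kernel graph the Connector fraction is identically zero, since
no indirect route can beat a direct edge.

The whole pipeline — simulate genotypes structured by the kernel, compute
`D_ps`/`G_ST`, build the three networks, extract raster covariates, and run
bandwidth + gravity model selection — is one call:

```r
cfg <- pipeline_config(seed = 42, extent = c(3000, 3000), cellsize = 50,
                       n_breeding = 12, n_stepping = 60,
                       genotype_spec = genotype_sim_spec(
                         n_loci = 12, generations = 120, deme_size = 120,
                         n_adults = 6, n_clusters = 3))
run_pipeline(cfg, "demo")
read.csv("demo/selection.csv", comment.char = "#")
#>                                  model n_params logLik     AIC delta_aic  top
#> 1 dist+pratio_bet+pratio_at+pc_step_at        4  62.18 -110.37      0.00 TRUE
#> 2               dist+srr_bet+pratio_at        3  46.38  -80.76     29.61 FALSE
#> ...
read.csv("demo/gst.csv", comment.char = "#")
#>    statistic     value
#> 1 global_gst 0.2044798
```

The simulated system lands in the empirical regime of the real one: global
`G_ST` ≈ 0.20 and between-site `D_ps` between 0.54 and 0.89. The selection
table lists each candidate gravity model with its ML log-likelihood, AIC
and ΔAIC; the top set (ΔAIC < 2) here is the model that generated most of
the signal.

## Layout

| Path | Contents |
|---|---|
| `R/` | genotypes & distances, terrain, networks, connectivity, gravity, synthetic data, pipeline |
| `tests/testthat/` | unit + property tests with brute-force oracles |
| `vignettes/pondscape-methods.Rmd` | methods: models, assumptions, numerical choices |
| `inst/extdata/` | published reference tables for the 18-wetland study system |
| `scripts/acceptance.R` | recomputes headline quantities as JSON |
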