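---
title: "Methods: wetland connectivity, genetic distance and gravity models in pondscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wetland connectivity, genetic distance and gravity models in pondscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondscape)
```

`pondscape` links the genetic connectivity of a pond-breeding amphibian
metapopulation to the spatial and temporal connectivity of its wetland
habitat. This vignette is the package's own account of the methods: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
conventions adopted where the methodology left choices open.

## 1. Genetic distances

### Proportion of shared alleles (D_ps)

For two diploid individuals, the shared proportion at a locus is
`sum_a min(c_x(a), c_y(a)) / 2` over allele counts `c`, and `ps(x, y)`
averages this over the loci scored in **both** individuals
(pairwise deletion; a locus missing in either member of a pair drops out of
that pair's denominator, which keeps the measure inside `[0, 1]`). The
individual distance is `1 − ps`. Because the measure is individual-based
while the gravity model needs site pairs, the between-site `D_ps` is one
minus the mean shared proportion over all inter-site individual pairs;
`dps_individual()` exposes the individual matrix for testing.

Sites with no scored locus at all are rejected by name rather than silently
propagating `NaN`.

### Full-sib subsampling

Larval samples arrive as full-sib clusters, and unequal family sizes bias
allele-frequency estimates. `subsample_siblings()` implements the standard
correction: within each site, every cluster is randomly subsampled without
replacement to the size of that site's smallest cluster. Adults are never
touched, clusters may not span sites, and the draw is seeded. When every
cluster is a singleton the operation is the identity.

### G_ST

Nei's `G_ST = (H_T − H_S) / H_T` uses the **unweighted** mean of site
allele frequencies for `H_T` and the unweighted mean of within-site
expected heterozygosities for `H_S`; loci are combined by summing both
heterozygosities across loci before taking the ratio. Data monomorphic
everywhere would make the ratio 0/0; the package defines this case as 0.
A seeded permutation test (`gst_permutation()`, default 999 permutations)
is provided for global and pairwise significance with a Bonferroni flag.
Reproducing any particular empirical share of significant pairs requires
the original genotypes, so the test suite checks only its type-I behavior
on exchangeable synthetic data. Locus counts are data-driven throughout;
monomorphic loci contribute nothing to either heterozygosity sum rather
than being hard-coded away. Hardy–Weinberg and linkage-disequilibrium
screening are considered upstream quality control and are out of scope.

## 2. The dispersal kernel and the three habitat graphs

The kernel family is the negative exponential used by
probability-of-connectivity methods, `p(d) = exp(−θ d)`. The methodology
fixes it by one constraint: at the species' maximum observed dispersal
distance (`d_ref = 600` m for the boreal chorus frog) a fraction
`p_ref = 0.05` of individuals still disperse farther, read as
`p(d_ref) = p_ref` exactly, so `θ = −ln(p_ref)/d_ref ≈ 0.005` per meter.
`calibrate_kernel()` enforces `exp(−θ d_ref) = p_ref` to 1e-12.

Wetlands are nodes with a habitat attribute `a_i` and Euclidean
inter-wetland distances as edges. Three constructions share this skeleton:

* **spatial**: the occupied breeding wetlands, `a_i` = area (m²);
* **temporal**: the same nodes, with `a_i` = area × (available years /
  total years) for the wetland's snowpack category. The availability
  fractions come from `classify_availability()`: years with snowpack depth
  strictly below the 63.5 cm threshold count for "low"-permanence
  wetlands, years at or above it for "high", and every year for
  "neutral" (15, 18 and 33 of 33 under the default synthetic series);
* **stepping_stone**: occupied wetlands plus every unoccupied candidate
  with area **strictly** greater than 400 m² (the smallest
  snowpack-neutral breeding wetland), all treated as neutral. Under the
  default landscape this yields 18 + 110 = 128 nodes. The ambiguity of
  whether the sampled non-neutral wetlands should carry availability
  weights in this graph is resolved by treating all 128 nodes as neutral,
  which is the construction's stated premise.

The temporal attribution rule — attribute = area × availability fraction —
is this package's explicit choice; the source methodology says availability
was "attributed" without giving the algebra, and its published temporal
Intra values are not reproducible from any simple area-scaling we could
identify. The rule here is documented, tested, and makes temporal
attributes provably bounded by spatial ones (equality exactly for neutral
wetlands).

Edges default to the complete graph. This matters: with a complete graph
and an exponential kernel, a two-leg route can never carry more probability
than the direct edge (`exp(−θ(d1 + d2)) ≤ exp(−θ d)` by the triangle
inequality), so the Connector fraction is identically zero. A finite
`edge_cutoff` (in meters) prunes long edges and is what lets stepping-stone
routing contribute; it is exposed rather than defaulted because the
complete graph is the construction the PC metrics are defined on.

## 3. Probability of connectivity and its decomposition

`p*_ij` is the maximum over paths of the product of edge probabilities,
computed as a Dijkstra shortest path under edge weights `−ln p = θ d`
(igraph supplies the shortest-path machinery; working in log space avoids
underflow). `p*_ii = 1`; unreachable pairs get 0. The connectivity
numerator is the ordered-pair sum including `i = j`:

`pc_num = Σ_i Σ_j a_i a_j p*_ij`,

optionally normalized by `A_L²` (defaulting to `A_L = Σ a_i`). For each
node `k`, with `PC′_k` the numerator after removing `k` and recomputing all
best paths:

* `dPC_k = 100 (pc_num − PC′_k)/pc_num`
* `Intra_k = 100 a_k² / pc_num`
* `Flux_k = 100 · 2 Σ_{j≠k} a_k a_j p*_kj / pc_num`
* `Connector_k = 100 Σ_{i,j≠k} a_i a_j (p*_ij − p*′_ij) / pc_num`

The identity `dPC = Intra + Flux + Connector` is exact by construction
because these are precisely the three groups of terms the ordered-pair sum
loses when node `k` leaves. The implementation removes each node and
recomputes `p*` honestly — `O(n · n² log n)`, perfectly affordable at
n = 128 — rather than caching shortcuts; an exhaustive path-enumeration
oracle in the test suite guards every quantity to 1e-12 on all graphs with
up to 6 nodes, and the identity is checked to 1e-9 on 200 random pruned
graphs. Percent scaling follows the conventional presentation of per-node
PC tables, and `connectivity_report()` restricts output to a node subset
(the sampled wetlands, for the stepping-stone graph). Whether published
per-wetland "PC (%)" columns are removal importances or shares of the
numerator is ambiguous in this literature — the rows sum either way — and
the package reports removal importances (dPC).

## 4. Terrain covariates

Rasters are plain ESRI ASCII grids held in a minimal `raster_grid`
container (values matrix plus lower-left corner and cell size); no
projection handling is attempted, and wetlands are treated as points
(centroids) since polygon outlines are not part of the data model — areas
enter only as node attributes.

* **Slope** is Horn's 3×3 finite difference with replicated edges;
* **Flow accumulation** is strict-descent D8: each cell drains to the
  neighbor with the greatest positive drop per unit distance, ties broken
  deterministically clockwise from north; cells with no strictly lower
  neighbor are sinks. The strictness is deliberate: it guarantees acyclic
  routing, and it makes a flat DEM accumulate exactly one cell everywhere,
  so the CTI of a flat world is a constant — the natural degenerate
  behavior;
* **CTI** `= ln(a / tan β)` with specific catchment area
  `a = accumulation × cellsize` and `tan β` floored at `tan(0.001)`;
* **SRR** `= (mean − min)/(max − min)` over a zone and **RSP**
  `= (z_center − min)/(max − min)` over a circular window, both defined as
  0.5 on flat zones (midpoint convention, avoiding spurious extremes on
  synthetic flat patches);
* **Buffers** are the cells whose centers fall within 100 m (default) of
  the wetland centroid; **corridors** are the cells whose centers fall
  within `bandwidth/2` of the straight inter-wetland segment — a "60 m
  bandwidth" spans 60 m total, a reading the source tooling leaves
  unspecified — united with the cells the segment itself traverses so a
  corridor narrower than a cell is never empty (the union preserves
  bandwidth nesting);
* **Meadow:forest ratios** are smoothed as `(meadow + 1)/(forest + 1)` to
  stay finite in forest-free zones; a message is emitted whenever the
  smoothing moves the ratio by more than 10%;
* **Topographic distance** samples the DEM along the straight segment at
  one cell-size spacing (bilinear interpolation) and sums 3-D segment
  lengths, hence is never below the Euclidean distance;
* **Collinearity screening** first drops, from any pair with `R² > 0.7`,
  the member with the larger mean absolute correlation to the remaining
  variables, then iteratively drops the largest-VIF variable while any
  VIF exceeds 5 (`VIF_k = 1/(1 − R²_k)`); ties break alphabetically
  (keeping the earlier name) and constant variables are dropped with a
  warning up front.

Field conductivity is a pass-through measurement with no computation.
Least-cost corridors and hydrological sink filling are out of scope; the
straight-segment corridor is the package's replacement for GIS corridor
mapping.

## 5. The gravity model

`build_flow_table()` assembles one record per **ordered** site pair:
response `ln(max(1 − D_ps, ε))` with `ε = 1e-6` guarding the (warned)
degenerate case `D_ps = 1`, and `ln(x + ε)` transforms of the distance, the
origin site's at-site covariates, and the pair's between-site covariates.
Including both orientations, grouped by origin, is what makes the model
singly constrained: each origin gets its own intercept while every slope is
global. Whether site-level connectivity metrics attach to the origin, the
destination, or the pair mean is genuinely underdetermined; the default is
the origin (production-side) reading with `at_site_role` as the switch.
Predictors are ln-transformed, not standardized, preserving the power-law
reading of the coefficients; standardization remains available to the user
before table assembly if conditioning demands it.

`fit_gravity()` fits `ln T = Xβ + u_origin + ε`, `u ~ N(0, σ_u²)`, by
**maximum likelihood** (lme4, `REML = FALSE`) because candidate models
differ in their fixed effects and only ML likelihoods are AIC-comparable
across them. The boundary `σ_u = 0` is permitted (singular-fit checks are
silenced); rank-deficient designs fail fast with the aliased columns named.

Two AIC parameter-count conventions coexist deliberately. `full` counts
every estimated parameter (fixed effects including intercept, plus two
variance components) and is the statistically defensible default.
`printed_k` counts only the named predictors, because selection tables in
this literature print predictor counts — it exists to let readers reproduce
published ΔAIC arithmetic, whose single-predictor rows are in fact mutually
inconsistent under any single convention (only the multi-predictor rows
reproduce). `model_selection()` appends a distance-only null, ranks by AIC
with lexicographic tie-breaks, flags the ΔAIC < 2 top set, and records
non-converging candidates without ranking them. `bandwidth_selection()`
refits one specification per corridor bandwidth and returns the
minimum-AIC bandwidth, breaking ties toward the smallest.

## 6. The synthetic study system

The generator's defaults are the study conditions, not tuning knobs:

* 18 occupied breeding wetlands plus 110 candidates over a 5 × 5 km
  extent, coordinates uniform, areas log-uniform on 200–20,000 m²;
  snowpack categories drawn 3:11:4 (low:high:neutral) across the 18.
  Candidate areas sit above 400 m² by default so the stepping-stone filter
  passes all 110 (the post-filter situation of the emulated system); a
  `frac_below_min` parameter exists purely to exercise the filter.
* A 33-year snowpack series with exactly 15 years strictly below the
  63.5 cm threshold; depths are uniform multiples of the threshold
  (0.30–0.98 below, 1.02–2.20 above), which matches the binary way the
  series is consumed — no quantitative depth–hydroperiod link beyond the
  threshold is modeled because none is specified.
* Rasters by filtered Gaussian noise (separable kernel, 250 m default
  correlation length): a DEM with configurable relief, land cover by
  quantile-slicing a second field (45% meadow, 45% forest, 10% water, 5%
  impervious), and precipitation grids with `0 < summer ≤ annual`
  enforced cellwise by construction.
* Genotypes by forward migration–drift on allele frequencies over the
  occupied wetlands: 12 loci with 7–26 alleles each; per generation
  `p_i ← (1 − m_i) p_i + Σ_j M_ij p_j` with `M ∝ p*` row-scaled to the
  total migration rate (default 0.05), then multinomial drift at
  `deme_size = 200` chromosomes for 200 generations from a common
  Dirichlet ancestral frequency. Adults are drawn under within-deme
  random mating; larvae as full-sib clusters (two multilocus parents,
  Mendelian offspring, truncated-geometric sibship sizes capped at 10).
  Tying migration to `p*` makes the simulated genetic structure an
  expression of the same connectivity model the analysis estimates.
* Flow tables with known coefficients, `ln T = Xβ + u_origin + ε`, as the
  recovery harness for the mixed-model fit.

Every generator draws from one root seed through a documented
stream-splitting scheme (`stream_seed()`: an affine map of root seed and a
small per-component stream index, mod 2³¹ − 1), so pipelines are
reproducible end to end and components never perturb each other's streams.

What the generator does **not** emulate: coalescent genealogies, mutation,
null alleles or genotyping error; real hydrology or seasonal network
dynamics; map projections; spatially autocorrelated sampling effort.
Passing tests therefore demonstrate that the estimators recover the
structure *this* model family generates — kernel-structured migration,
threshold-driven availability, log-linear flows — not that the ecological
claims hold for any particular field system.

## 7. Numerical conventions and test scale

* Kernel calibration invariant to 1e-12; decomposition identity asserted
  to 1e-9 on 200 random graphs; brute-force equivalence to 1e-12 on all
  ≤ 6-node test graphs.
* Flats: slope 0, accumulation 1, SRR/RSP 0.5; CTI slope floor
  `tan(0.001)`.
* Log guards: `ε = 1e-6` in responses and predictors.
* Tie-breaks: D8 clockwise from north; model names lexicographic;
  bandwidth ties toward the smallest.
* The test suite runs the full pipeline at a reduced scale chosen for a
  thorough-but-quick default run (8 breeding + 20 candidate wetlands,
  1.5 km extent, 50 m cells, 6 loci) and the statistical suites at the
  analysis scale of 306 ordered pairs with 100 seeded replicates for
  coefficient recovery — sizes at which the checks are already stringent.

## 8. Known limitations

* Wetland polygons are not modeled; buffers and corridors are
  centroid-based.
* The temporal attribution rule is one defensible reading of an
  underspecified construction (Section 2); published temporal
  decomposition columns are not reproducible from it and are not targets.
* The permutation test addresses exchangeability of individuals among
  sites, not family structure within larval samples — subsample first.
* ML variance estimates at the boundary (`σ_u = 0`) make the `full`
  parameter count conservative for those fits.
* Corridors are straight; resistance-weighted or least-cost corridors are
  intentionally out of scope.
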