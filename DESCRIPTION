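Package: pondscape
Title: Landscape Genetics of Wetland Networks: Connectivity Graphs,
    Genetic Distances and Gravity Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links amphibian genetic connectivity to spatio-temporal wetland
    connectivity. Computes microsatellite genetic distances (proportion of
    shared alleles D_ps, Nei's G_ST) with full-sib larval subsampling, builds
    spatial-, temporal- and stepping-stone habitat graphs under a calibrated
    negative-exponential dispersal kernel, decomposes probability-of-
    connectivity node importance (dPC = Intra + Flux + Connector), extracts
    terrain covariates (CTI, surface relief ratio, relative slope position,
    precipitation ratio, land-cover ratios) within wetland buffers and along
    between-wetland corridors, and fits singly-constrained gravity models with
    per-origin random intercepts selected by AIC. A synthetic-data generator
    reproduces the statistical structure of the study system (wetland
    landscapes, rasters, snowpack series, kernel-structured genotypes) so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
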