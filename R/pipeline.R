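## End-to-end orchestration: simulate -> {distances, networks, covariates}
## -> connectivity -> gravity, with flat CSV artifacts, provenance comments
## and a single root seed.

#' Configuration of a full pipeline run
#'
#' Collects every tunable of the analysis in one object: landscape and
#' genotype simulation specs, kernel calibration, snow threshold,
#' stepping-stone area filter, corridor bandwidths, candidate gravity
#' models, AIC convention and edge cutoff. All randomness derives from
#' `seed` via [stream_seed()].
#'
#' @param seed integer root seed.
#' @param extent landscape extent (m).
#' @param cellsize raster cell size (m); must divide the extent.
#' @param n_breeding,n_stepping wetland counts (see [landscape_spec()]).
#' @param kernel_d_ref,kernel_p_ref dispersal-kernel calibration
#'   (see [calibrate_kernel()]).
#' @param snow_threshold_cm wetland-permanence snowpack threshold.
#' @param min_area stepping-stone area filter (m2).
#' @param edge_cutoff optional edge pruning distance (m) for the networks.
#' @param bandwidths corridor bandwidths (m) for between-site covariates.
#' @param buffer_radius at-site buffer radius (m).
#' @param genotype_spec a [genotype_sim_spec()]; its seed is overridden by
#'   the root seed.
#' @param candidate_models list of [gravity_model_spec()]s; a default
#'   candidate set over distance, terrain and connectivity predictors is
#'   supplied.
#' @param aic_convention `"full"` or `"printed_k"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            extent = c(3000, 3000),
                            cellsize = 50,
                            n_breeding = 18,
                            n_stepping = 110,
                            kernel_d_ref = 600,
                            kernel_p_ref = 0.05,
                            snow_threshold_cm = 63.5,
                            min_area = 400,
                            edge_cutoff = Inf,
                            bandwidths = c(30, 60, 120, 240),
                            buffer_radius = 100,
                            genotype_spec = genotype_sim_spec(),
                            candidate_models = NULL,
                            aic_convention = c("full", "printed_k")) {
  aic_convention <- match.arg(aic_convention)
  if (is.null(candidate_models)) {
    candidate_models <- list(
      gravity_model_spec("dist", "dist"),
      gravity_model_spec("dist+srr_bet", c("dist", "srr_bet")),
      gravity_model_spec("dist+srr_bet+pratio_at",
                         c("dist", "srr_bet", "pratio_at")),
      gravity_model_spec("dist+srr_bet+pratio_at+pc_step_at",
                         c("dist", "srr_bet", "pratio_at", "pc_step_at")),
      gravity_model_spec("dist+pratio_bet+pratio_at+pc_step_at",
                         c("dist", "pratio_bet", "pratio_at", "pc_step_at")),
      gravity_model_spec("dist+cti_at+pc_step_at",
                         c("dist", "cti_at", "pc_step_at")))
  }
  structure(list(seed = seed, extent = extent, cellsize = cellsize,
                 n_breeding = n_breeding, n_stepping = n_stepping,
                 kernel_d_ref = kernel_d_ref, kernel_p_ref = kernel_p_ref,
                 snow_threshold_cm = snow_threshold_cm, min_area = min_area,
                 edge_cutoff = edge_cutoff, bandwidths = bandwidths,
                 buffer_radius = buffer_radius, genotype_spec = genotype_spec,
                 candidate_models = candidate_models,
                 aic_convention = aic_convention),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

write_artifact <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pondscape stage=%s seed=%d config=%s",
                     stage, as.integer(config$seed), config_hash(config)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_artifact <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
           check.names = FALSE)
}

## Artifacts produced by each stage, used for dependency checking.
stage_outputs <- function(outdir) {
  list(simulate = file.path(outdir, c("wetlands.csv", "snow.csv", "dem.asc",
                                      "landcover.asc", "ppt_summer.asc",
                                      "ppt_annual.asc", "impervious.asc",
                                      "genotypes.gen", "clusters.csv")),
       distances = file.path(outdir, c("dps.csv", "gst.csv")),
       networks = file.path(outdir, sprintf("network_%s_nodes.csv",
                                            c("spatial", "temporal",
                                              "stepping_stone"))),
       connectivity = file.path(outdir, sprintf("connectivity_%s.csv",
                                                c("spatial", "temporal",
                                                  "stepping_stone"))),
       covariates = file.path(outdir, c("at_site.csv", "between_site.csv",
                                        "topo_dist.csv")),
       gravity = file.path(outdir, c("flow_table.csv", "bandwidth_table.csv",
                                     "selection.csv")))
}

stage_deps <- list(simulate = character(0),
                   distances = "simulate",
                   networks = "simulate",
                   covariates = "simulate",
                   connectivity = "networks",
                   gravity = c("distances", "covariates", "connectivity"))

check_deps <- function(stage, outdir) {
  outs <- stage_outputs(outdir)
  for (dep in stage_deps[[stage]]) {
    missing <- !file.exists(outs[[dep]])
    if (any(missing))
      stopf("stage '%s' requires artifact(s) %s; run stage '%s' first",
            stage, paste(basename(outs[[dep]][missing]), collapse = ", "), dep)
  }
}

pipe_kernel <- function(config)
  calibrate_kernel(config$kernel_d_ref, config$kernel_p_ref)

pipe_landscape_spec <- function(config)
  landscape_spec(seed = config$seed, extent = config$extent,
                 n_breeding = config$n_breeding,
                 n_stepping = config$n_stepping,
                 min_area = config$min_area)

read_wetlands <- function(outdir) {
  w <- read_artifact(file.path(outdir, "wetlands.csv"))
  w$occupied <- as.logical(w$occupied)
  w
}

read_stack <- function(outdir) {
  nm <- c("dem", "landcover", "ppt_summer", "ppt_annual", "impervious")
  setNames(lapply(nm, function(n) read_asc(file.path(outdir,
                                                     paste0(n, ".asc")))), nm)
}

read_matrix_csv <- function(path) {
  df <- read_artifact(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

write_matrix_csv <- function(m, path, config, stage) {
  df <- data.frame(site_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write_artifact(df, path, config, stage)
}

build_all_networks <- function(wetlands, snow, config) {
  kern <- pipe_kernel(config)
  attribution <- classify_availability(snow$depth_cm, config$snow_threshold_cm)
  list(spatial = build_network(wetlands, kern, "spatial",
                               edge_cutoff = config$edge_cutoff),
       temporal = build_network(wetlands, kern, "temporal",
                                attribution = attribution,
                                edge_cutoff = config$edge_cutoff),
       stepping_stone = build_network(wetlands, kern, "stepping_stone",
                                      min_area = config$min_area,
                                      edge_cutoff = config$edge_cutoff))
}

#' Run one pipeline stage
#'
#' Stages form a DAG: `simulate` -> (`distances`, `networks`,
#' `covariates`) -> `connectivity` -> `gravity`. Each stage reads the flat
#' CSV/ASC artifacts of its dependencies from `outdir` and writes its own;
#' every CSV carries a provenance comment with the stage, seed and a hash of
#' the configuration. Running a stage before its dependencies raises an
#' error naming the producing stage.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @param outdir artifact directory (created if needed).
#' @return invisibly, the paths written by the stage.
#' @export
run_stage <- function(stage = c("simulate", "distances", "networks",
                                "connectivity", "covariates", "gravity"),
                      config, outdir) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  check_deps(stage, outdir)
  outs <- stage_outputs(outdir)[[stage]]
  switch(stage,
    simulate = {
      lspec <- pipe_landscape_spec(config)
      wetlands <- generate_wetlands(lspec)
      snow <- generate_snow_series(snow_series_spec(
        threshold_cm = config$snow_threshold_cm, seed = config$seed))
      rasters <- generate_rasters(lspec, cellsize = config$cellsize)
      write_artifact(wetlands, file.path(outdir, "wetlands.csv"), config, stage)
      write_artifact(snow, file.path(outdir, "snow.csv"), config, stage)
      for (nm in names(rasters))
        write_asc(rasters[[nm]], file.path(outdir, paste0(nm, ".asc")))
      gspec <- config$genotype_spec
      gspec$seed <- config$seed
      net <- build_network(wetlands, pipe_kernel(config), "spatial",
                           edge_cutoff = config$edge_cutoff)
      sim <- simulate_genotypes(net, gspec)
      write_genepop(sim$genotypes, file.path(outdir, "genotypes.gen"))
      write_artifact(sim$clusters, file.path(outdir, "clusters.csv"),
                     config, stage)
    },
    distances = {
      gt <- read_genepop(file.path(outdir, "genotypes.gen"))
      clusters <- read_artifact(file.path(outdir, "clusters.csv"))
      gt$life_stage <- ifelse(gt$individual_id %in% clusters$individual_id,
                              "larva", "adult")
      gt <- subsample_siblings(gt, clusters, seed = config$seed)
      dps <- dps_matrix(gt)
      g <- gst(gt)
      write_matrix_csv(dps, file.path(outdir, "dps.csv"), config, stage)
      write_artifact(data.frame(statistic = "global_gst", value = g$global),
                     file.path(outdir, "gst.csv"), config, stage)
    },
    networks = {
      wetlands <- read_wetlands(outdir)
      snow <- read_artifact(file.path(outdir, "snow.csv"))
      nets <- build_all_networks(wetlands, snow, config)
      for (nm in names(nets))
        write_artifact(nets[[nm]]$nodes,
                       file.path(outdir, sprintf("network_%s_nodes.csv", nm)),
                       config, stage)
    },
    connectivity = {
      wetlands <- read_wetlands(outdir)
      snow <- read_artifact(file.path(outdir, "snow.csv"))
      nets <- build_all_networks(wetlands, snow, config)
      occ <- wetlands$id[wetlands$occupied]
      for (nm in names(nets)) {
        rep_tab <- connectivity_report(dpc_decomposition(nets[[nm]]), occ)
        write_artifact(rep_tab,
                       file.path(outdir, sprintf("connectivity_%s.csv", nm)),
                       config, stage)
      }
    },
    covariates = {
      wetlands <- read_wetlands(outdir)
      occ <- wetlands[wetlands$occupied, ]
      rasters <- read_stack(outdir)
      cti_grid <- cti(rasters$dem)
      at <- do.call(rbind, lapply(seq_len(nrow(occ)), function(i)
        data.frame(site_id = occ$id[i],
                   t(buffer_stats(rasters, occ[i, ], config$buffer_radius,
                                  cti_grid)))))
      bet <- list()
      topo <- matrix(0, nrow(occ), nrow(occ),
                     dimnames = list(occ$id, occ$id))
      for (i in seq_len(nrow(occ) - 1)) for (j in (i + 1):nrow(occ)) {
        p1 <- c(occ$x[i], occ$y[i]); p2 <- c(occ$x[j], occ$y[j])
        topo[i, j] <- topo[j, i] <- topo_distance(rasters$dem, p1, p2)
        for (bwv in config$bandwidths) {
          st <- corridor_stats(rasters, p1, p2, bwv, cti_grid)
          bet[[length(bet) + 1L]] <-
            data.frame(site_i = occ$id[i], site_j = occ$id[j],
                       bandwidth_m = bwv, t(st))
        }
      }
      write_artifact(at, file.path(outdir, "at_site.csv"), config, stage)
      write_artifact(do.call(rbind, bet),
                     file.path(outdir, "between_site.csv"), config, stage)
      write_matrix_csv(topo, file.path(outdir, "topo_dist.csv"), config, stage)
    },
    gravity = {
      dps <- read_matrix_csv(file.path(outdir, "dps.csv"))
      at <- read_artifact(file.path(outdir, "at_site.csv"))
      bet_all <- read_artifact(file.path(outdir, "between_site.csv"))
      topo <- read_matrix_csv(file.path(outdir, "topo_dist.csv"))
      for (nm in c("spatial", "temporal", "stepping_stone")) {
        cn <- read_artifact(file.path(outdir,
                                      sprintf("connectivity_%s.csv", nm)))
        key <- c(spatial = "pc_spatial_at", temporal = "pc_temporal_at",
                 stepping_stone = "pc_step_at")[[nm]]
        at[[key]] <- cn$dpc_pct[match(at$site_id, cn$id)]
      }
      tables <- lapply(config$bandwidths, function(bwv)
        build_flow_table(dps, at,
                         bet_all[bet_all$bandwidth_m == bwv, ], topo))
      names(tables) <- config$bandwidths
      base_spec <- gravity_model_spec("bandwidth_probe",
                                      c("dist", "srr_bet", "pratio_bet"))
      bw_sel <- bandwidth_selection(tables, base_spec,
                                    convention = config$aic_convention)
      flow <- tables[[as.character(bw_sel$bandwidth)]]
      sel <- model_selection(flow, config$candidate_models,
                             convention = config$aic_convention)
      write_artifact(as.data.frame(flow),
                     file.path(outdir, "flow_table.csv"), config, stage)
      write_artifact(bw_sel$table,
                     file.path(outdir, "bandwidth_table.csv"), config, stage)
      write_artifact(as.data.frame(sel),
                     file.path(outdir, "selection.csv"), config, stage)
    })
  invisible(outs)
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order:
#' simulate, distances, networks, connectivity, covariates, gravity.
#'
#' @param config a [pipeline_config()].
#' @param outdir artifact directory.
#' @return invisibly, the vector of all artifact paths.
#' @export
run_pipeline <- function(config, outdir) {
  for (stage in c("simulate", "distances", "networks", "connectivity",
                  "covariates", "gravity"))
    run_stage(stage, config, outdir)
  invisible(unlist(stage_outputs(outdir)))
}
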