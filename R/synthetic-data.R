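## Synthetic study-system generator: wetland landscapes, snowpack series,
## environmental rasters, and gravity-model flow tables. The genotype
## simulator lives in simulate-genotypes.R.

#' Specification of a synthetic wetland landscape
#'
#' Describes the study system emulated by the generators: a set of occupied
#' breeding wetlands plus candidate (unoccupied) stepping-stone wetlands
#' scattered over a rectangular extent, with areas between 200 and 20,000 m2
#' and a snowpack-response category per breeding wetland.
#'
#' @param seed integer root seed; all landscape randomness derives from it.
#' @param extent numeric length-2, width and height of the extent in meters.
#' @param n_breeding number of occupied breeding wetlands (>= 2).
#' @param n_stepping number of candidate stepping-stone wetlands.
#' @param area_range numeric length-2, min and max wetland area in m2.
#' @param snow_weights named proportions over categories `low`, `high`,
#'   `neutral`; must sum to 1. The default reflects a system with 3 low,
#'   11 high and 4 snowpack-neutral wetlands out of 18.
#' @param frac_below_min fraction of stepping-stone areas drawn below
#'   `min_area` (to exercise the stepping-stone area filter; 0 by default so
#'   every candidate passes it, matching the 18 + 110 = 128-node system).
#' @param min_area stepping-stone area filter threshold in m2.
#' @return an object of class `landscape_spec`.
#' @export
landscape_spec <- function(seed = 1,
                           extent = c(5000, 5000),
                           n_breeding = 18,
                           n_stepping = 110,
                           area_range = c(200, 20000),
                           snow_weights = c(low = 3 / 18, high = 11 / 18, neutral = 4 / 18),
                           frac_below_min = 0,
                           min_area = 400) {
  if (any(!is.finite(extent)) || length(extent) != 2 || any(extent <= 0))
    stopf("extent must be two positive lengths in meters, got (%s)",
          paste(extent, collapse = ", "))
  if (n_breeding < 2) stopf("n_breeding must be >= 2")
  if (n_stepping < 0) stopf("n_stepping must be >= 0")
  if (length(area_range) != 2 || area_range[1] <= 0 || area_range[1] >= area_range[2])
    stopf("area_range must satisfy 0 < min < max")
  if (!all(c("low", "high", "neutral") %in% names(snow_weights)))
    stopf("snow_weights must name low, high and neutral")
  if (abs(sum(snow_weights) - 1) > 1e-9)
    stopf("snow_weights must sum to 1 (got %.12f)", sum(snow_weights))
  if (frac_below_min < 0 || frac_below_min > 1)
    stopf("frac_below_min must lie in [0, 1]")
  structure(list(seed = seed, extent = extent, n_breeding = n_breeding,
                 n_stepping = n_stepping, area_range = area_range,
                 snow_weights = snow_weights[c("low", "high", "neutral")],
                 frac_below_min = frac_below_min, min_area = min_area),
            class = "landscape_spec")
}

#' Generate a synthetic wetland table
#'
#' Coordinates are uniform over the extent; breeding-wetland areas are
#' log-uniform over `area_range`; stepping-stone areas are log-uniform above
#' `min_area` except for a configurable fraction drawn below it. Output is
#' byte-identical for a fixed spec.
#'
#' @param spec a [landscape_spec()].
#' @return data.frame with columns `id`, `x`, `y`, `area_m2`,
#'   `snow_category`, `occupied`; breeding rows first.
#' @export
generate_wetlands <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_stream(spec$seed, 1L, {
    nb <- spec$n_breeding
    ns <- spec$n_stepping
    n <- nb + ns
    x <- runif(n, 0, spec$extent[1])
    y <- runif(n, 0, spec$extent[2])
    b_area <- exp(runif(nb, log(spec$area_range[1]), log(spec$area_range[2])))
    b_cat <- sample(names(spec$snow_weights), nb, replace = TRUE,
                    prob = spec$snow_weights)
    s_area <- numeric(0)
    if (ns > 0) {
      n_below <- round(spec$frac_below_min * ns)
      lo <- exp(runif(n_below, log(spec$area_range[1]),
                      log(min(spec$min_area, spec$area_range[2]))))
      hi <- exp(runif(ns - n_below,
                      log(spec$min_area * 1.0001), log(spec$area_range[2])))
      s_area <- c(lo, hi)
    }
    data.frame(
      id = c(sprintf("B%02d", seq_len(nb)),
             if (ns > 0) sprintf("S%03d", seq_len(ns))),
      x = x, y = y,
      area_m2 = c(b_area, s_area),
      snow_category = c(b_cat, rep("neutral", ns)),
      occupied = c(rep(TRUE, nb), rep(FALSE, ns)),
      stringsAsFactors = FALSE
    )
  })
}

#' Specification of a synthetic snowpack depth series
#'
#' @param n_years number of years in the series (default 33).
#' @param n_below_threshold number of years with depth strictly below
#'   `threshold_cm` (default 15, the low-snowpack years of the 33-year
#'   record the temporal network is built from).
#' @param threshold_cm depth threshold in cm (default 63.5, the long-term
#'   mean snowpack depth used as the wetland-permanence threshold).
#' @param seed integer seed.
#' @return an object of class `snow_series_spec`.
#' @export
snow_series_spec <- function(n_years = 33, n_below_threshold = 15,
                             threshold_cm = 63.5, seed = 1) {
  if (n_years < 1) stopf("n_years must be >= 1")
  if (n_below_threshold < 0 || n_below_threshold > n_years)
    stopf("n_below_threshold must lie in [0, n_years]")
  if (threshold_cm <= 0) stopf("threshold_cm must be positive")
  structure(list(n_years = n_years, n_below_threshold = n_below_threshold,
                 threshold_cm = threshold_cm, seed = seed),
            class = "snow_series_spec")
}

#' Generate a synthetic annual snowpack depth series
#'
#' Exactly `n_below_threshold` years fall strictly below the threshold and
#' the remainder strictly above; the assignment of depths to years is
#' shuffled under the seed.
#'
#' @param spec a [snow_series_spec()].
#' @return data.frame with columns `year`, `depth_cm`.
#' @export
generate_snow_series <- function(spec) {
  stopifnot(inherits(spec, "snow_series_spec"))
  with_stream(spec$seed, 2L, {
    nb <- spec$n_below_threshold
    na <- spec$n_years - nb
    th <- spec$threshold_cm
    depths <- c(th * runif(nb, 0.30, 0.98), th * runif(na, 1.02, 2.20))
    depths <- depths[sample.int(spec$n_years)]
    data.frame(year = seq(1978, length.out = spec$n_years), depth_cm = depths)
  })
}

## Separable Gaussian smoothing with replicated edges; sigma in cells.
smooth_gauss <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + length(v))]
  }
  mat <- apply(mat, 2, conv1)
  t(apply(mat, 1, conv1))
}

#' Generate synthetic environmental rasters over a landscape extent
#'
#' Produces a coregistered stack: a smooth correlated DEM (filtered Gaussian
#' noise with configurable relief and correlation length), a categorical
#' land-cover grid (meadow/forest/water/impervious, see [landcover_codes]),
#' summer and annual precipitation grids with `0 < summer <= annual`
#' cellwise, and a 0/1 impervious grid derived from land cover.
#'
#' @param spec a [landscape_spec()] (supplies extent and seed).
#' @param cellsize cell size in meters; must divide both extent dimensions.
#' @param relief total DEM relief in meters (0 gives a flat DEM).
#' @param correlation_length Gaussian correlation length of the synthesized
#'   fields, in meters.
#' @param base_elevation elevation added to the DEM, in meters.
#' @return named list of [raster_grid()]s: `dem`, `landcover`,
#'   `ppt_summer`, `ppt_annual`, `impervious`.
#' @export
generate_rasters <- function(spec, cellsize = 30, relief = 100,
                             correlation_length = 250, base_elevation = 2500) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (cellsize <= 0) stopf("cellsize must be positive")
  dims <- spec$extent / cellsize
  if (any(abs(dims - round(dims)) > 1e-9))
    stopf("cellsize %g does not divide extent (%g, %g)",
          cellsize, spec$extent[1], spec$extent[2])
  nc <- as.integer(round(dims[1])); nr <- as.integer(round(dims[2]))
  sig <- correlation_length / cellsize
  field <- function(stream) {
    with_stream(spec$seed, stream, smooth_gauss(matrix(rnorm(nr * nc), nr, nc), sig))
  }
  grid <- function(v) raster_grid(v, xllcorner = 0, yllcorner = 0,
                                  cellsize = cellsize)

  dem <- base_elevation + relief * matrix(unit01(field(3L)), nr, nc)

  lc_field <- field(4L)
  qs <- quantile(lc_field, c(0.10, 0.55, 0.95))  # water | meadow | forest | impervious
  lc <- matrix(landcover_codes[["meadow"]], nr, nc)
  lc[lc_field <= qs[1]] <- landcover_codes[["water"]]
  lc[lc_field > qs[2]] <- landcover_codes[["forest"]]
  lc[lc_field > qs[3]] <- landcover_codes[["impervious"]]

  annual <- 400 + 250 * matrix(unit01(field(5L)), nr, nc)
  ratio <- 0.2 + 0.6 * matrix(unit01(field(6L)), nr, nc)
  summer <- annual * ratio

  list(dem = grid(dem),
       landcover = grid(lc),
       ppt_summer = grid(summer),
       ppt_annual = grid(annual),
       impervious = grid((lc == landcover_codes[["impervious"]]) * 1))
}

#' Simulate a gravity-model flow table with known coefficients
#'
#' Generates `ln T = X beta + u_origin + eps` with iid Normal origin
#' intercepts `u ~ N(0, sigma_u^2)` and residuals `eps ~ N(0, sigma_e^2)`.
#' Used as the recovery harness for [fit_gravity()].
#'
#' @param X numeric design matrix or data.frame; columns are predictors.
#' @param beta coefficient vector, one per column of `X`.
#' @param origin factor or character vector of origin site ids, length
#'   `nrow(X)`.
#' @param sigma_u origin-intercept standard deviation (>= 0).
#' @param sigma_e residual standard deviation (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `origin`, `response` and the columns
#'   of `X`.
#' @export
simulate_flow_table <- function(X, beta, origin, sigma_u = 0, sigma_e = 0.05,
                                seed = 1) {
  X <- as.matrix(X)
  if (ncol(X) != length(beta))
    stopf("beta has length %d but X has %d columns", length(beta), ncol(X))
  if (nrow(X) != length(origin))
    stopf("origin must have one entry per row of X")
  if (sigma_u < 0 || sigma_e < 0) stopf("standard deviations must be >= 0")
  origin <- as.character(origin)
  with_stream(seed, 8L, {
    lev <- unique(origin)
    u <- setNames(rnorm(length(lev), 0, sigma_u), lev)
    eps <- rnorm(nrow(X), 0, sigma_e)
    out <- data.frame(origin = origin,
                      response = drop(X %*% beta) + u[origin] + eps,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(X))
  })
}
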