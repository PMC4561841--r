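## Raster terrain covariates: ESRI ASCII grids, Horn slope + D8 flow
## accumulation, CTI, surface relief ratio, relative slope position,
## wetland-buffer and corridor zonal statistics, collinearity screening.

#' Land-cover class codes used by the synthetic rasters
#'
#' Named integer codes for the categorical land-cover grid:
#' meadow = 1, forest = 2, water = 3, impervious = 4.
#' @export
landcover_codes <- c(meadow = 1L, forest = 2L, water = 3L, impervious = 4L)

#' Construct a raster grid
#'
#' Minimal in-memory raster: a values matrix whose first row is the
#' northernmost row, plus ESRI ASCII georeferencing (lower-left corner and
#' square cell size in meters).
#'
#' @param values numeric matrix (row 1 = north).
#' @param xllcorner,yllcorner lower-left corner coordinates in meters.
#' @param cellsize cell size in meters (> 0).
#' @param nodata no-data marker used on disk.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, xllcorner = 0, yllcorner = 0, cellsize = 30,
                        nodata = -9999) {
  values <- as.matrix(values)
  if (cellsize <= 0) stopf("cellsize must be > 0")
  structure(list(values = values, nrows = nrow(values), ncols = ncol(values),
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, cellsize %g m, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cellsize, x$xllcorner, x$yllcorner))
  invisible(x)
}

## Cell-center coordinates. Row r (1 = north): y = yll + (nrows - r + 0.5) * cs.
cell_xy <- function(g) {
  list(x = g$xllcorner + (seq_len(g$ncols) - 0.5) * g$cellsize,
       y = g$yllcorner + (g$nrows - seq_len(g$nrows) + 0.5) * g$cellsize)
}

## Matrix indices of cell centers within `radius` of point (x0, y0).
cells_in_radius <- function(g, x0, y0, radius) {
  cc <- cell_xy(g)
  dx2 <- outer(rep(1, g$nrows), (cc$x - x0)^2)
  dy2 <- outer((cc$y - y0)^2, rep(1, g$ncols))
  which(dx2 + dy2 <= radius^2)
}

#' Read an ESRI ASCII grid (.asc)
#' @param path file path.
#' @return a [raster_grid()]; nodata cells become NA.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (grepl("^[[:space:]]*[[:alpha:]]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stopf("%s: incomplete ASC header", path)
  xll <- hdr$xllcorner %||% (hdr$xllcenter - hdr$cellsize / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - hdr$cellsize / 2)
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stopf("%s: expected %d values, found %d", path,
          hdr$ncols * hdr$nrows, length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  raster_grid(m, xll, yll, hdr$cellsize, nodata)
}

#' Write a raster grid as ESRI ASCII (.asc)
#' @param g a [raster_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(g, path) {
  m <- g$values
  m[is.na(m)] <- g$nodata
  hdr <- c(sprintf("ncols %d", g$ncols), sprintf("nrows %d", g$nrows),
           sprintf("xllcorner %.10g", g$xllcorner),
           sprintf("yllcorner %.10g", g$yllcorner),
           sprintf("cellsize %.10g", g$cellsize),
           sprintf("NODATA_value %g", g$nodata))
  body <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## Pad a matrix by replicating its edges.
pad_edge <- function(z) {
  z <- rbind(z[1, ], z, z[nrow(z), ])
  cbind(z[, 1], z, z[, ncol(z)])
}

#' Slope and D8 flow accumulation from a DEM
#'
#' Slope by Horn's 3x3 finite differences (radians, edges padded by
#' replication). Flow routing is strict-descent D8: each cell drains to the
#' neighbor with the greatest positive drop per unit distance, ties broken
#' clockwise starting north; cells with no strictly lower neighbor (flats,
#' pits, draining edges) are sinks. Accumulation counts upslope cells
#' including the cell itself.
#'
#' @param dem a [raster_grid()] with no interior NA cells.
#' @return list with `slope` and `facc` raster grids.
#' @export
slope_and_flowacc <- function(dem) {
  z <- dem$values
  if (all(is.na(z))) stopf("DEM is entirely nodata")
  if (anyNA(z)) stopf("DEM has nodata holes inside the analysis extent")
  nr <- nrow(z); nc <- ncol(z); cs <- dem$cellsize
  zp <- pad_edge(z)
  sub <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  a <- sub(0, 0); b <- sub(0, 1); cc_ <- sub(0, 2)
  d <- sub(1, 0);                  f <- sub(1, 2)
  g <- sub(2, 0); h <- sub(2, 1); i9 <- sub(2, 2)
  dzdx <- ((cc_ + 2 * f + i9) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + i9) - (a + 2 * b + cc_)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2))

  # D8 receivers: offsets clockwise from north
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  best_drop <- matrix(0, nr, nc)
  recv <- matrix(NA_integer_, nr, nc)
  ridx <- matrix(rep(seq_len(nr), nc), nr, nc)
  cidx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    nbr <- ridx + o[1]; nbc <- cidx + o[2]
    inb <- nbr >= 1 & nbr <= nr & nbc >= 1 & nbc <= nc
    zn <- matrix(Inf, nr, nc)
    zn[inb] <- z[cbind(nbr[inb], nbc[inb])]
    drop <- (z - zn) / (cs * sqrt(sum(o^2)))
    upd <- is.finite(drop) & drop > best_drop  # strict: first offset wins ties
    best_drop[upd] <- drop[upd]
    recv[upd] <- (nbc[upd] - 1L) * nr + nbr[upd]
  }
  acc <- rep(1, nr * nc)
  ord <- order(as.vector(z), decreasing = TRUE)
  rv <- as.vector(recv)
  for (cell in ord) {
    r <- rv[cell]
    if (!is.na(r)) acc[r] <- acc[r] + acc[cell]
  }
  mk <- function(v) raster_grid(matrix(v, nr, nc), dem$xllcorner,
                                dem$yllcorner, cs, dem$nodata)
  list(slope = mk(slope), facc = mk(acc))
}

#' Compound topographic index
#'
#' `CTI = ln(a / tan(beta))` with specific catchment area
#' `a = flow accumulation x cellsize` and `tan(beta)` floored at
#' `tan(slope_floor)` so flat cells stay finite.
#'
#' @param dem a [raster_grid()].
#' @param slope_floor minimum slope in radians used in the denominator.
#' @return a [raster_grid()] of CTI values.
#' @export
cti <- function(dem, slope_floor = 0.001) {
  sf <- slope_and_flowacc(dem)
  a <- sf$facc$values * dem$cellsize
  tanb <- pmax(tan(sf$slope$values), tan(slope_floor))
  raster_grid(log(a / tanb), dem$xllcorner, dem$yllcorner,
              dem$cellsize, dem$nodata)
}

#' Surface relief ratio over a zone
#'
#' `(mean - min) / (max - min)` of the DEM values in a zone; a flat zone
#' returns 0.5 (midpoint convention).
#'
#' @param dem a [raster_grid()].
#' @param cells integer cell indices (into the values matrix) defining the
#'   zone; must be nonempty.
#' @return scalar in `[0, 1]`.
#' @export
srr <- function(dem, cells) {
  if (length(cells) == 0) stopf("srr: empty zone")
  v <- dem$values[cells]
  rng <- range(v)
  if (diff(rng) == 0) return(0.5)
  (mean(v) - rng[1]) / diff(rng)
}

#' Relative slope position of a point
#'
#' Position of the DEM value at `center` between the valley floor (0) and
#' ridge top (1) of a circular window; a flat window returns 0.5.
#'
#' @param dem a [raster_grid()].
#' @param center numeric `(x, y)` in map units; must fall on the grid.
#' @param radius window radius in meters.
#' @return scalar in `[0, 1]`.
#' @export
rsp <- function(dem, center, radius) {
  cc <- cell_xy(dem)
  col <- findInterval(center[1], dem$xllcorner + dem$cellsize * (0:dem$ncols),
                      rightmost.closed = TRUE)
  row <- dem$nrows + 1 -
    findInterval(center[2], dem$yllcorner + dem$cellsize * (0:dem$nrows),
                 rightmost.closed = TRUE)
  if (col < 1 || col > dem$ncols || row < 1 || row > dem$nrows)
    stopf("rsp: center (%g, %g) is off-grid", center[1], center[2])
  cells <- cells_in_radius(dem, center[1], center[2], radius)
  if (length(cells) == 0) cells <- (col - 1L) * dem$nrows + row
  zc <- dem$values[row, col]
  rng <- range(dem$values[cells])
  if (diff(rng) == 0) return(0.5)
  min(1, max(0, (zc - rng[1]) / diff(rng)))
}

## Shared smoothing rule for meadow:forest ratios; +1 in both counts keeps
## the ratio finite when a zone lacks forest. A message is emitted when the
## smoothing moves the ratio by more than 10%.
mf_ratio <- function(n_meadow, n_forest) {
  sm <- (n_meadow + 1) / (n_forest + 1)
  if (n_forest > 0) {
    raw <- n_meadow / n_forest
    if (raw > 0 && abs(sm - raw) / raw > 0.10)
      message(sprintf("meadow:forest smoothing changed %.3g to %.3g", raw, sm))
  }
  sm
}

check_stack <- function(rasters) {
  need <- c("dem", "landcover", "ppt_summer", "ppt_annual", "impervious")
  if (!all(need %in% names(rasters)))
    stopf("raster stack must contain %s", paste(need, collapse = ", "))
  ref <- rasters$dem
  for (nm in need) {
    g <- rasters[[nm]]
    if (g$nrows != ref$nrows || g$ncols != ref$ncols ||
        g$cellsize != ref$cellsize ||
        abs(g$xllcorner - ref$xllcorner) > 1e-6 ||
        abs(g$yllcorner - ref$yllcorner) > 1e-6)
      stopf("raster '%s' is not coregistered with the DEM", nm)
  }
  invisible(rasters)
}

#' At-site covariates within a wetland buffer
#'
#' Zonal statistics over cells whose centers lie within `radius` of the
#' wetland centroid (wetlands are treated as points): smoothed
#' meadow:forest ratio, impervious cell count, mean CTI, mean precipitation
#' ratio (summer / annual), and relative slope position at the centroid.
#'
#' @param rasters named list with `dem`, `landcover`, `ppt_summer`,
#'   `ppt_annual`, `impervious` grids (coregistered).
#' @param wetland list or one-row data.frame with `x` and `y` (meters).
#' @param radius buffer radius in meters (default 100).
#' @param cti_grid optional precomputed [cti()] grid.
#' @return named numeric: `mf_at`, `imperv_at`, `cti_at`, `pratio_at`,
#'   `rsp_at`.
#' @export
buffer_stats <- function(rasters, wetland, radius = 100, cti_grid = NULL) {
  check_stack(rasters)
  cells <- cells_in_radius(rasters$dem, wetland$x, wetland$y, radius)
  if (length(cells) == 0)
    stopf("buffer at (%g, %g) misses the grid entirely", wetland$x, wetland$y)
  if (is.null(cti_grid)) cti_grid <- cti(rasters$dem)
  lc <- rasters$landcover$values[cells]
  pr <- rasters$ppt_summer$values[cells] / rasters$ppt_annual$values[cells]
  c(mf_at = mf_ratio(sum(lc == landcover_codes[["meadow"]]),
                     sum(lc == landcover_codes[["forest"]])),
    imperv_at = sum(rasters$impervious$values[cells] > 0),
    cti_at = mean(cti_grid$values[cells]),
    pratio_at = mean(pr),
    rsp_at = rsp(rasters$dem, c(wetland$x, wetland$y), radius))
}

## Cells of the straight corridor between two points: centers within
## halfwidth of the segment, plus the cells the segment itself traverses
## (so narrow corridors are never empty).
corridor_cells <- function(g, p1, p2, halfwidth) {
  cc <- cell_xy(g)
  X <- outer(rep(1, g$nrows), cc$x)
  Y <- outer(cc$y, rep(1, g$ncols))
  ax <- p1[1]; ay <- p1[2]
  vx <- p2[1] - ax; vy <- p2[2] - ay
  L2 <- vx^2 + vy^2
  t <- pmin(1, pmax(0, ((X - ax) * vx + (Y - ay) * vy) / L2))
  d2 <- (X - (ax + t * vx))^2 + (Y - (ay + t * vy))^2
  within <- which(d2 <= halfwidth^2)
  # traversed cells, sampled at sub-cell spacing
  L <- sqrt(L2)
  ts <- seq(0, 1, length.out = max(2L, ceiling(L / (g$cellsize / 2)) + 1L))
  px <- ax + ts * vx; py <- ay + ts * vy
  col <- pmin(g$ncols, pmax(1, ceiling((px - g$xllcorner) / g$cellsize)))
  row <- pmin(g$nrows, pmax(1, g$nrows - floor((py - g$yllcorner) / g$cellsize)))
  sort(unique(c(within, (col - 1L) * g$nrows + row)))
}

#' Between-site covariates along a straight corridor
#'
#' The corridor is the set of cells whose centers lie within `bandwidth / 2`
#' of the straight segment joining the two sites (the bandwidth is the total
#' corridor width). Reports the smoothed meadow:forest ratio, mean
#' impervious cover, mean CTI, mean precipitation ratio, and the surface
#' relief ratio of the corridor; symmetric in the two sites.
#'
#' @param rasters coregistered raster stack, as in [buffer_stats()].
#' @param p1,p2 numeric `(x, y)` site coordinates in meters.
#' @param bandwidth corridor width in meters (one of 30, 60, 120, 240 in the
#'   standard analysis).
#' @param cti_grid optional precomputed [cti()] grid.
#' @return named numeric: `mf_bet`, `imperv_bet`, `cti_bet`, `pratio_bet`,
#'   `srr_bet`.
#' @export
corridor_stats <- function(rasters, p1, p2, bandwidth = 30, cti_grid = NULL) {
  check_stack(rasters)
  if (all(p1 == p2)) {
    warnf("zero-length corridor at (%g, %g); using at-site buffer", p1[1], p1[2])
    cells <- cells_in_radius(rasters$dem, p1[1], p1[2], bandwidth / 2)
  } else {
    cells <- corridor_cells(rasters$dem, p1, p2, bandwidth / 2)
  }
  if (length(cells) == 0) stopf("corridor misses the grid entirely")
  if (is.null(cti_grid)) cti_grid <- cti(rasters$dem)
  lc <- rasters$landcover$values[cells]
  pr <- rasters$ppt_summer$values[cells] / rasters$ppt_annual$values[cells]
  c(mf_bet = mf_ratio(sum(lc == landcover_codes[["meadow"]]),
                      sum(lc == landcover_codes[["forest"]])),
    imperv_bet = mean(rasters$impervious$values[cells]),
    cti_bet = mean(cti_grid$values[cells]),
    pratio_bet = mean(pr),
    srr_bet = srr(rasters$dem, cells))
}

## Bilinear interpolation of cell-center values; coordinates are clamped to
## the cell-center bounding box.
bilinear <- function(g, x, y) {
  cc <- cell_xy(g)
  x <- pmin(max(cc$x), pmax(min(cc$x), x))
  # y grid descends; interpolate on ascending copy
  ys <- rev(cc$y)
  y <- pmin(max(ys), pmax(min(ys), y))
  ix <- pmin(g$ncols - 1L, pmax(1L, findInterval(x, cc$x)))
  iy <- pmin(g$nrows - 1L, pmax(1L, findInterval(y, ys)))
  if (g$ncols == 1L) { ix <- 1L; fx <- 0 } else
    fx <- (x - cc$x[ix]) / g$cellsize
  if (g$nrows == 1L) { iy <- 1L; fy <- 0 } else
    fy <- (y - ys[iy]) / g$cellsize
  row_lo <- g$nrows + 1L - iy       # row of ys[iy] (lower y)
  row_hi <- pmax(1L, row_lo - 1L)
  v00 <- g$values[cbind(row_lo, ix)]
  v10 <- g$values[cbind(row_lo, pmin(g$ncols, ix + 1L))]
  v01 <- g$values[cbind(row_hi, ix)]
  v11 <- g$values[cbind(row_hi, pmin(g$ncols, ix + 1L))]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

#' Topographically corrected distance between two points
#'
#' Samples the DEM along the straight segment at `step` spacing (default:
#' one cellsize) and sums the 3-D lengths `sqrt(dxy^2 + dz^2)`; always at
#' least the Euclidean distance.
#'
#' @param dem a [raster_grid()].
#' @param p1,p2 numeric `(x, y)` endpoints in meters.
#' @param step sampling step in meters.
#' @return distance in meters.
#' @export
topo_distance <- function(dem, p1, p2, step = NULL) {
  if (all(p1 == p2)) return(0)
  step <- step %||% dem$cellsize
  L <- sqrt(sum((p2 - p1)^2))
  n <- max(1L, ceiling(L / step))
  ts <- seq(0, 1, length.out = n + 1)
  xs <- p1[1] + ts * (p2[1] - p1[1])
  ys <- p1[2] + ts * (p2[2] - p1[2])
  zs <- bilinear(dem, xs, ys)
  sum(sqrt((diff(ts) * L)^2 + diff(zs)^2))
}

#' Screen covariates for collinearity
#'
#' Two-stage greedy screen used before gravity-model fitting. Stage one:
#' while any variable pair has squared correlation above `r2_cut`, drop from
#' the worst pair the variable with the larger mean absolute correlation to
#' all other variables. Stage two: iteratively drop the variable with the
#' largest variance inflation factor (`VIF_k = 1 / (1 - R^2_k)` from
#' regressing variable k on the rest) while any VIF exceeds `vif_cut`.
#' Constant variables are dropped with a warning before screening.
#'
#' @param covariates numeric data.frame (rows = records).
#' @param r2_cut pairwise squared-correlation threshold (default 0.7).
#' @param vif_cut VIF threshold (default 5).
#' @return character vector of retained variable names, in input order.
#' @export
collinearity_screen <- function(covariates, r2_cut = 0.7, vif_cut = 5) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2 || nrow(covariates) < 3)
    stopf("need >= 2 variables and >= 3 records")
  sds <- vapply(covariates, sd, numeric(1))
  if (any(sds == 0)) {
    warnf("dropping constant variable(s): %s",
          paste(names(covariates)[sds == 0], collapse = ", "))
    covariates <- covariates[, sds > 0, drop = FALSE]
  }
  vars <- names(covariates)
  drop_later <- function(cand) cand[order(cand)][length(cand)]  # alphabetical tie-break
  repeat {
    if (length(vars) < 2) break
    C <- cor(covariates[vars])
    diag(C) <- 0
    if (max(C^2) <= r2_cut) break
    idx <- which(C^2 == max(C^2), arr.ind = TRUE)[1, ]
    pair <- vars[idx]
    mac <- vapply(pair, function(v) mean(abs(C[v, setdiff(vars, v)])), numeric(1))
    victim <- if (abs(diff(mac)) > 1e-12) pair[which.max(mac)] else drop_later(pair)
    vars <- setdiff(vars, victim)
  }
  repeat {
    if (length(vars) < 2) break
    vifs <- vapply(vars, function(v) {
      r2 <- summary(lm(reformulate(setdiff(vars, v), v), covariates))$r.squared
      1 / max(1 - r2, 1e-12)
    }, numeric(1))
    if (max(vifs) <= vif_cut) break
    worst <- vifs == max(vifs)
    vars <- setdiff(vars, drop_later(names(vifs)[worst]))
  }
  names(covariates)[names(covariates) %in% vars]
}
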