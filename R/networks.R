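## Habitat graphs: dispersal-kernel calibration, snowpack availability
## classification, and the spatial-, temporal- and stepping-stone wetland
## networks.

#' Calibrate a negative-exponential dispersal kernel
#'
#' The kernel assigns each inter-wetland distance a dispersal probability
#' `p(d) = exp(-theta d)`. It is calibrated so that the reference distance
#' (by default 600 m, the maximum observed dispersal distance of the boreal
#' chorus frog) retains an exceedance probability `p_ref` (by default 0.05:
#' 5% of individuals surpass the maximum), giving
#' `theta = -ln(p_ref) / d_ref`.
#'
#' @param d_ref reference distance in meters (> 0).
#' @param p_ref dispersal probability at `d_ref`, in (0, 1).
#' @return object of class `dispersal_kernel` with fields `theta`,
#'   `d_ref`, `p_ref`.
#' @export
calibrate_kernel <- function(d_ref = 600, p_ref = 0.05) {
  if (!is.finite(d_ref) || d_ref <= 0) stopf("d_ref must be > 0")
  if (!is.finite(p_ref) || p_ref <= 0 || p_ref >= 1)
    stopf("p_ref must lie strictly in (0, 1)")
  structure(list(theta = -log(p_ref) / d_ref, d_ref = d_ref, p_ref = p_ref),
            class = "dispersal_kernel")
}

#' Dispersal probability at a distance
#' @param kernel a [calibrate_kernel()] object.
#' @param d distance(s) in meters.
#' @return `exp(-theta d)`.
#' @export
kernel_prob <- function(kernel, d) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  exp(-kernel$theta * d)
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat(sprintf("dispersal_kernel: theta = %.6g per m (p(%g m) = %g)\n",
              x$theta, x$d_ref, x$p_ref))
  invisible(x)
}

#' Classify wetland availability from a snowpack depth series
#'
#' Counts, over the observed years, how many years each snowpack category of
#' wetland is productive: "low"-permanence wetlands in years with depth
#' strictly below the threshold, "high" wetlands in years at or above it,
#' and "neutral" wetlands in every year.
#'
#' @param depths numeric vector of annual snowpack depths (cm).
#' @param threshold_cm depth threshold (default 63.5 cm, the long-term mean).
#' @return object of class `temporal_attribution`: data.frame with columns
#'   `category`, `available_years`, `total_years`.
#' @export
classify_availability <- function(depths, threshold_cm = 63.5) {
  if (length(depths) == 0) stopf("empty snowpack series")
  n <- length(depths)
  n_low <- sum(depths < threshold_cm)
  out <- data.frame(category = c("low", "high", "neutral"),
                    available_years = c(n_low, n - n_low, n),
                    total_years = n, stringsAsFactors = FALSE)
  class(out) <- c("temporal_attribution", "data.frame")
  out
}

#' Availability fraction per snowpack category
#' @param attribution a [classify_availability()] result.
#' @param categories character vector of categories.
#' @return numeric fractions `available_years / total_years`.
#' @export
availability_fraction <- function(attribution, categories) {
  stopifnot(inherits(attribution, "temporal_attribution"))
  m <- match(categories, attribution$category)
  if (anyNA(m)) stopf("unknown snowpack category: %s",
                      paste(unique(categories[is.na(m)]), collapse = ", "))
  attribution$available_years[m] / attribution$total_years[m]
}

#' Build a wetland habitat network
#'
#' Three constructions share one graph structure (nodes = wetlands with a
#' habitat attribute, edges = Euclidean distances under a dispersal kernel):
#'
#' * `spatial`: occupied wetlands only, attribute = area.
#' * `temporal`: occupied wetlands, attribute = area scaled by the fraction
#'   of years the wetland's snowpack category is available.
#' * `stepping_stone`: occupied wetlands plus every unoccupied candidate
#'   with area strictly greater than `min_area`; all nodes treated as
#'   snowpack-neutral, attribute = area.
#'
#' Edges form the complete graph unless `edge_cutoff` (meters) prunes pairs
#' farther apart; with a complete graph and an exponential kernel no
#' indirect path can beat a direct edge, so a finite cutoff is what lets
#' stepping-stone routing matter.
#'
#' @param wetlands data.frame with columns `id`, `x`, `y`, `area_m2`,
#'   `snow_category`, `occupied`.
#' @param kernel a [calibrate_kernel()] object.
#' @param kind one of "spatial", "temporal", "stepping_stone".
#' @param attribution a [classify_availability()] result; required for the
#'   temporal network.
#' @param min_area stepping-stone area filter in m2 (default 400, the
#'   smallest snowpack-neutral breeding wetland).
#' @param edge_cutoff prune edges longer than this (meters); `Inf` keeps the
#'   complete graph.
#' @return object of class `wetland_network`: list with `nodes` (data.frame
#'   incl. the habitat attribute `attr`), `dist` (symmetric matrix, NA =
#'   pruned), `kernel`, `kind`.
#' @export
build_network <- function(wetlands, kernel, kind = c("spatial", "temporal",
                                                     "stepping_stone"),
                          attribution = NULL, min_area = 400,
                          edge_cutoff = Inf) {
  kind <- match.arg(kind)
  need <- c("id", "x", "y", "area_m2", "snow_category", "occupied")
  if (!all(need %in% names(wetlands)))
    stopf("wetlands must have columns %s", paste(need, collapse = ", "))
  stopifnot(inherits(kernel, "dispersal_kernel"))
  if (kind == "temporal" && is.null(attribution))
    stopf("temporal network requires a snowpack attribution")
  nodes <- switch(kind,
    spatial = ,
    temporal = wetlands[wetlands$occupied, , drop = FALSE],
    stepping_stone = {
      if (!any(!wetlands$occupied))
        stopf("stepping-stone network requires candidate wetlands")
      wetlands[wetlands$occupied |
                 (!wetlands$occupied & wetlands$area_m2 > min_area), ,
               drop = FALSE]
    })
  if (nrow(nodes) < 2) stopf("fewer than 2 nodes after filtering")
  if (anyDuplicated(nodes$id)) stopf("duplicate wetland ids")
  nodes$attr <- switch(kind,
    spatial = nodes$area_m2,
    temporal = nodes$area_m2 *
      availability_fraction(attribution, nodes$snow_category),
    stepping_stone = nodes$area_m2)
  rownames(nodes) <- NULL
  D <- as.matrix(dist(cbind(nodes$x, nodes$y)))
  dimnames(D) <- list(nodes$id, nodes$id)
  if (is.finite(edge_cutoff)) {
    D[D > edge_cutoff] <- NA
    diag(D) <- 0
  }
  structure(list(nodes = nodes, dist = D, kernel = kernel, kind = kind),
            class = "wetland_network")
}

#' @export
print.wetland_network <- function(x, ...) {
  n <- nrow(x$nodes)
  ne <- sum(!is.na(x$dist[upper.tri(x$dist)]))
  cat(sprintf("wetland_network (%s): %d nodes, %d edges, theta = %.4g\n",
              x$kind, n, ne, x$kernel$theta))
  invisible(x)
}

#' Export a network in Conefor-style node and connection files
#'
#' Writes the plain-text `nodes` (id, attribute) and `connections`
#' (id1, id2, distance) files used by patch-connectivity software.
#'
#' @param network a [build_network()] result.
#' @param nodes_path,connections_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_conefor <- function(network, nodes_path, connections_path) {
  stopifnot(inherits(network, "wetland_network"))
  nd <- network$nodes
  writeLines(sprintf("%s\t%.10g", nd$id, nd$attr), nodes_path)
  ut <- which(upper.tri(network$dist) & !is.na(network$dist), arr.ind = TRUE)
  writeLines(sprintf("%s\t%s\t%.10g", nd$id[ut[, 1]], nd$id[ut[, 2]],
                     network$dist[ut]), connections_path)
  invisible(list(nodes = nodes_path, connections = connections_path))
}
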