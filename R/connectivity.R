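## Probability of connectivity (PC), node importance dPC, and its exact
## Intra / Flux / Connector decomposition.

## igraph over the network's existing edges; weight = -ln p = theta * d.
network_graph <- function(network) {
  D <- network$dist
  if (any(D < 0, na.rm = TRUE)) stopf("negative distance in network")
  ut <- which(upper.tri(D) & !is.na(D), arr.ind = TRUE)
  ids <- network$nodes$id
  edges <- data.frame(from = ids[ut[, 1]], to = ids[ut[, 2]],
                      weight = network$kernel$theta * D[ut])
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = ids))
}

pstar_from_graph <- function(g) {
  sp <- igraph::distances(g, algorithm = "dijkstra")
  P <- exp(-sp)            # Inf distance -> 0
  diag(P) <- 1
  P
}

#' Maximum-probability dispersal matrix p*
#'
#' Each existing edge carries probability `p_ij = exp(-theta d_ij)`;
#' `p*_ij` is the maximum over paths of the product of edge probabilities,
#' computed as a shortest path under edge weights `-ln p`. `p*_ii = 1`;
#' unreachable pairs get 0.
#'
#' @param network a [build_network()] result.
#' @return symmetric matrix with unit diagonal, ordered as
#'   `network$nodes`.
#' @export
pstar_matrix <- function(network) {
  stopifnot(inherits(network, "wetland_network"))
  P <- pstar_from_graph(network_graph(network))
  P[network$nodes$id, network$nodes$id]
}

#' Probability of connectivity of a network
#'
#' `pc_num = sum_i sum_j a_i a_j p*_ij` over ordered node pairs including
#' `i = j`; the normalized PC divides by `A_L^2` where `A_L` defaults to the
#' total habitat attribute (configurable to a fixed landscape attribute).
#'
#' @param network a [build_network()] result.
#' @param a_l optional landscape attribute `A_L` for normalization.
#' @return list with `pc_num`, `pc` (normalized), and the `pstar` matrix.
#' @export
prob_connectivity <- function(network, a_l = NULL) {
  stopifnot(inherits(network, "wetland_network"))
  a <- network$nodes$attr
  if (all(a == 0)) stopf("all node attributes are zero")
  P <- pstar_matrix(network)
  pc_num <- drop(t(a) %*% P %*% a)
  A_L <- a_l %||% sum(a)
  list(pc_num = pc_num, pc = pc_num / A_L^2, pstar = P)
}

#' Node-importance decomposition dPC = Intra + Flux + Connector
#'
#' For each node k, with `PC'_k` the connectivity numerator of the network
#' with node k removed (and all best paths recomputed):
#' * `dPC_k = 100 (pc_num - PC'_k) / pc_num`,
#' * `Intra_k = 100 a_k^2 / pc_num` (habitat area alone),
#' * `Flux_k = 100 * 2 sum_{j != k} a_k a_j p*_kj / pc_num` (area-weighted
#'   direct exchange),
#' * `Connector_k = 100 sum_{i,j != k} a_i a_j (p*_ij - p*'_ij) / pc_num`
#'   (irreplaceable stepping-stone role).
#'
#' The identity `dPC = Intra + Flux + Connector` holds exactly because the
#' ordered-pair sum including `i = j` splits into precisely these three
#' groups of terms.
#'
#' @param network a [build_network()] result with >= 2 nodes.
#' @return object of class `connectivity_result`: list with `pc_num`,
#'   `a_total`, `network_kind` and `table` (columns `id`, `dpc_pct`,
#'   `intra_pct`, `flux_pct`, `connector_pct`).
#' @export
dpc_decomposition <- function(network) {
  stopifnot(inherits(network, "wetland_network"))
  nodes <- network$nodes
  n <- nrow(nodes)
  if (n < 2) stopf("need >= 2 nodes")
  a <- nodes$attr
  if (all(a == 0)) stopf("all node attributes are zero")
  g <- network_graph(network)
  P <- pstar_from_graph(g)[nodes$id, nodes$id]
  pc_num <- drop(t(a) %*% P %*% a)
  intra <- flux <- conn <- numeric(n)
  for (k in seq_len(n)) {
    keep <- setdiff(seq_len(n), k)
    ids_keep <- nodes$id[keep]
    gk <- igraph::delete_vertices(g, nodes$id[k])
    Pk <- pstar_from_graph(gk)[ids_keep, ids_keep, drop = FALSE]
    ak <- a[keep]
    intra[k] <- a[k]^2
    flux[k] <- 2 * sum(a[k] * ak * P[k, keep])
    conn[k] <- drop(t(ak) %*% (P[keep, keep, drop = FALSE] - Pk) %*% ak)
  }
  pct <- function(v) 100 * v / pc_num
  structure(list(
    pc_num = pc_num,
    a_total = sum(a),
    network_kind = network$kind,
    table = data.frame(id = nodes$id,
                       dpc_pct = pct(intra + flux + conn),
                       intra_pct = pct(intra),
                       flux_pct = pct(flux),
                       connector_pct = pct(conn),
                       stringsAsFactors = FALSE)),
    class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("connectivity_result (%s): pc_num = %.6g over %d nodes\n",
              x$network_kind, x$pc_num, nrow(x$table)))
  print(head(x$table, 10), ...)
  invisible(x)
}

#' Per-node connectivity report restricted to a subset of wetlands
#'
#' Restricts the decomposition table to a subset of node ids (e.g., the 18
#' sampled, occupied wetlands of a stepping-stone network), preserving the
#' subset order.
#'
#' @param result a [dpc_decomposition()] result.
#' @param subset character vector of node ids (may be empty).
#' @return data.frame with columns `id`, `dpc_pct`, `intra_pct`,
#'   `flux_pct`, `connector_pct`, `network_kind`.
#' @export
connectivity_report <- function(result, subset) {
  stopifnot(inherits(result, "connectivity_result"))
  unknown <- setdiff(subset, result$table$id)
  if (length(unknown) > 0)
    stopf("unknown node id(s): %s", paste(unknown, collapse = ", "))
  out <- result$table[match(subset, result$table$id), , drop = FALSE]
  out$network_kind <- rep(result$network_kind, nrow(out))
  rownames(out) <- NULL
  out
}
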