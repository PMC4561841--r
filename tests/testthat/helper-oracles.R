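# Independent brute-force oracles and fixture builders. The oracles never
# call the graph/network code paths they are used to check.

# Construct a wetland_network object directly from coordinates, attributes
# and an optional logical pruning matrix (TRUE = edge removed).
make_network <- function(x, y, attr, kernel = calibrate_kernel(),
                         pruned = NULL, kind = "spatial",
                         occupied = rep(TRUE, length(x))) {
  n <- length(x)
  ids <- sprintf("n%02d", seq_len(n))
  D <- as.matrix(dist(cbind(x, y)))
  dimnames(D) <- list(ids, ids)
  if (!is.null(pruned)) {
    D[pruned] <- NA
    diag(D) <- 0
  }
  nodes <- data.frame(id = ids, x = x, y = y, area_m2 = attr,
                      snow_category = "neutral", occupied = occupied,
                      attr = attr, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, dist = D, kernel = kernel, kind = kind),
            class = "wetland_network")
}

random_test_network <- function(n, seed, prune_frac = 0.3, extent = 1500) {
  withr::with_seed(seed, {
    x <- runif(n, 0, extent); y <- runif(n, 0, extent)
    a <- runif(n, 100, 5000)
    pruned <- matrix(FALSE, n, n)
    if (n > 2 && prune_frac > 0) {
      ut <- which(upper.tri(pruned))
      cut <- sample(ut, floor(prune_frac * length(ut)))
      pruned[cut] <- TRUE
      pruned <- pruned | t(pruned)
    }
    make_network(x, y, a, pruned = pruned)
  })
}

# Edge probability matrix of a network (NA edges -> 0).
edge_prob <- function(net) {
  p <- exp(-net$kernel$theta * net$dist)
  p[is.na(net$dist)] <- 0
  diag(p) <- 0
  p
}

# Exhaustive maximum-product path probability over all simple paths.
bf_pstar <- function(p_edge) {
  n <- nrow(p_edge)
  best <- diag(n)
  walk <- function(at, target, visited, prob) {
    if (at == target) {
      best[visited[1], target] <<- max(best[visited[1], target], prob)
      return()
    }
    for (nb in seq_len(n)) {
      if (p_edge[at, nb] > 0 && !(nb %in% visited))
        walk(nb, target, c(visited, nb), prob * p_edge[at, nb])
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) walk(i, j, i, 1)
  }
  best
}

bf_pc_num <- function(a, p_edge) {
  P <- bf_pstar(p_edge)
  drop(t(a) %*% P %*% a)
}

# Full brute-force dPC decomposition for small graphs.
bf_dpc <- function(a, p_edge) {
  n <- length(a)
  P <- bf_pstar(p_edge)
  pc <- drop(t(a) %*% P %*% a)
  out <- data.frame(dpc = numeric(n), intra = numeric(n),
                    flux = numeric(n), connector = numeric(n))
  for (k in seq_len(n)) {
    keep <- setdiff(seq_len(n), k)
    Pk <- bf_pstar(p_edge[keep, keep, drop = FALSE])
    pck <- drop(t(a[keep]) %*% Pk %*% a[keep])
    out$dpc[k] <- 100 * (pc - pck) / pc
    out$intra[k] <- 100 * a[k]^2 / pc
    out$flux[k] <- 100 * 2 * sum(a[k] * a[keep] * P[k, keep]) / pc
    out$connector[k] <- 100 *
      drop(t(a[keep]) %*% (P[keep, keep, drop = FALSE] - Pk) %*% a[keep]) / pc
  }
  list(pstar = P, pc_num = pc, table = out)
}

# Brute-force D8 flow accumulation: re-derive each cell's receiver from the
# DEM, then count path visits by walking every cell's flow path.
bf_flowacc <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); cs <- dem$cellsize
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  recv <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    best <- 0; bk <- NA
    for (k in seq_along(offs)) {
      rr <- r + offs[[k]][1]; cc <- c + offs[[k]][2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      drop_k <- (z[r, c] - z[rr, cc]) / (cs * sqrt(sum(offs[[k]]^2)))
      if (drop_k > best) { best <- drop_k; bk <- (cc - 1) * nr + rr }
    }
    recv[r, c] <- bk
  }
  acc <- matrix(0, nr, nc)
  for (cell in seq_len(nr * nc)) {
    at <- cell
    repeat {
      acc[at] <- acc[at] + 1
      at <- recv[at]
      if (is.na(at)) break
    }
  }
  acc
}

# Tiny genotype table from a list of per-individual allele vectors.
tiny_gt <- function(sites, alleles, loci = NULL,
                    stage = rep("adult", length(sites))) {
  alleles <- do.call(rbind, alleles)
  n_loci <- ncol(alleles) / 2
  loci <- loci %||% sprintf("L%02d", seq_len(n_loci))
  genotype_table(sprintf("i%02d", seq_along(sites)), sites, stage,
                 alleles, loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_fixture <- function(name) {
  read.csv(system.file("extdata", name, package = "pondscape"),
           stringsAsFactors = FALSE)
}
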