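## Forward migration-drift genotype simulator structured by the dispersal
## kernel of a wetland network.

#' Specification of a genotype simulation
#'
#' @param n_loci number of microsatellite loci (default 12).
#' @param allele_range integer length-2: min and max alleles per locus
#'   (default 7-26; minimum must be >= 2).
#' @param deme_size number of chromosomes (2N) per deme subject to drift.
#' @param generations number of migration-drift generations.
#' @param total_migration_rate per-generation fraction of each deme
#'   replaced by immigrants, in `[0, 1)`; apportioned among sources in
#'   proportion to the network's `p*` dispersal probabilities.
#' @param n_adults adults sampled per deme.
#' @param n_clusters full-sib larval clusters sampled per deme.
#' @param sibship_p success parameter of the truncated geometric sibship
#'   size distribution (`size = min(1 + Geom(p), sibship_max)`).
#' @param sibship_max maximum sibship size (default 10).
#' @param seed integer seed.
#' @return object of class `genotype_sim_spec`.
#' @export
genotype_sim_spec <- function(n_loci = 12, allele_range = c(7, 26),
                              deme_size = 200, generations = 200,
                              total_migration_rate = 0.05,
                              n_adults = 6, n_clusters = 4,
                              sibship_p = 0.45, sibship_max = 10, seed = 1) {
  if (n_loci < 1) stopf("n_loci must be >= 1")
  if (length(allele_range) != 2 || allele_range[1] < 2 ||
      allele_range[1] > allele_range[2])
    stopf("allele_range must satisfy 2 <= min <= max")
  if (total_migration_rate < 0 || total_migration_rate >= 1)
    stopf("total_migration_rate must lie in [0, 1)")
  if (deme_size < 2) stopf("deme_size must be >= 2 chromosomes")
  if (sibship_max < 1) stopf("sibship_max must be >= 1")
  structure(list(n_loci = n_loci, allele_range = allele_range,
                 deme_size = deme_size, generations = generations,
                 total_migration_rate = total_migration_rate,
                 n_adults = n_adults, n_clusters = n_clusters,
                 sibship_p = sibship_p, sibship_max = sibship_max,
                 seed = seed),
            class = "genotype_sim_spec")
}

#' Simulate kernel-structured multilocus genotypes on a wetland network
#'
#' Runs a forward migration-drift simulation of allele frequencies on the
#' occupied wetlands of a network. Each generation,
#' `p_i <- (1 - m_i) p_i + sum_j M_ij p_j` with the migration matrix
#' `M_ij` proportional to the network's maximum-probability dispersal
#' `p*_ij` and row sums scaled to the total migration rate, followed by
#' multinomial drift at `deme_size` chromosomes. Adults are then sampled
#' under within-deme random mating; larvae are generated as full-sib
#' clusters (two multilocus parents per cluster, Mendelian offspring) with
#' recorded cluster labels.
#'
#' @param network a [build_network()] result with >= 2 occupied nodes.
#' @param spec a [genotype_sim_spec()].
#' @return list with `genotypes` (a [genotype_table()]) and `clusters`
#'   (data.frame `individual_id`, `site_id`, `cluster_id` for the larvae).
#' @export
simulate_genotypes <- function(network, spec) {
  stopifnot(inherits(network, "wetland_network"),
            inherits(spec, "genotype_sim_spec"))
  occ <- which(network$nodes$occupied)
  if (length(occ) < 2) stopf("network must have >= 2 occupied nodes")
  sites <- network$nodes$id[occ]
  nd <- length(occ)

  S <- pstar_matrix(network)[sites, sites]
  diag(S) <- 0
  rs <- rowSums(S)
  M <- matrix(0, nd, nd)
  nz <- rs > 0
  M[nz, ] <- spec$total_migration_rate * S[nz, , drop = FALSE] / rs[nz]
  if (any(rowSums(M) >= 1))
    stopf("migration matrix row sum >= 1; lower total_migration_rate")
  A <- diag(1 - rowSums(M)) + M

  with_stream(spec$seed, 7L, {
    freqs <- lapply(seq_len(spec$n_loci), function(l) {
      K <- sample(spec$allele_range[1]:spec$allele_range[2], 1)
      p0 <- rgamma(K, 1)
      p0 <- p0 / sum(p0)
      matrix(rep(p0, each = nd), nd, K)
    })
    for (gen in seq_len(spec$generations)) {
      for (l in seq_len(spec$n_loci)) {
        P <- A %*% freqs[[l]]
        for (d in seq_len(nd))
          P[d, ] <- rmultinom(1, spec$deme_size, P[d, ]) / spec$deme_size
        freqs[[l]] <- P
      }
    }
    draw_genotype <- function(d) {
      unlist(lapply(freqs, function(P) {
        k <- ncol(P)
        sort(sample.int(k, 2, replace = TRUE, prob = P[d, ])) + 100L
      }))
    }
    ids <- site_v <- stage <- character(0)
    rows <- list()
    cl_ids <- cl_ind <- cl_site <- character(0)
    for (d in seq_len(nd)) {
      s <- sites[d]
      for (ad in seq_len(spec$n_adults)) {
        ids <- c(ids, sprintf("%s-a%02d", s, ad))
        site_v <- c(site_v, s); stage <- c(stage, "adult")
        rows[[length(rows) + 1L]] <- draw_genotype(d)
      }
      for (cl in seq_len(spec$n_clusters)) {
        size <- min(1L + rgeom(1, spec$sibship_p), spec$sibship_max)
        par1 <- matrix(draw_genotype(d), ncol = 2, byrow = TRUE)
        par2 <- matrix(draw_genotype(d), ncol = 2, byrow = TRUE)
        for (off in seq_len(size)) {
          g <- t(vapply(seq_len(spec$n_loci), function(l) {
            sort(c(par1[l, sample.int(2, 1)], par2[l, sample.int(2, 1)]))
          }, integer(2)))
          id <- sprintf("%s-c%02d-%02d", s, cl, off)
          ids <- c(ids, id); site_v <- c(site_v, s); stage <- c(stage, "larva")
          rows[[length(rows) + 1L]] <- as.vector(t(g))
        }
        cl_ind <- c(cl_ind, sprintf("%s-c%02d-%02d", s, cl, seq_len(size)))
        cl_site <- c(cl_site, rep(s, size))
        cl_ids <- c(cl_ids, rep(sprintf("%s-c%02d", s, cl), size))
      }
    }
    list(genotypes = genotype_table(
           ids, site_v, stage,
           alleles = do.call(rbind, rows),
           loci = sprintf("L%02d", seq_len(spec$n_loci))),
         clusters = data.frame(individual_id = cl_ind, site_id = cl_site,
                               cluster_id = cl_ids, stringsAsFactors = FALSE))
  })
}
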