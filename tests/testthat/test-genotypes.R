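genepop_text <- function() {
  c("two ponds, two loci",
    "locA", "locB",
    "Pop",
    "p1_i01 ,  101101 202203",
    "p1_i02 ,  101102 202202",
    "Pop",
    "p2_i01 ,  103103 204204",
    "p2_i02 ,  000000 202204")
}

test_that("read_genepop parses pops, loci and missing codes", {
  f <- withr::local_tempfile(lines = genepop_text())
  gt <- read_genepop(f)
  expect_equal(nrow(gt), 4)
  expect_equal(gt_loci(gt), c("locA", "locB"))
  expect_equal(unique(gt$site_id), c("p1", "p2"))
  expect_equal(gt$individual_id, c("i01", "i02", "i01", "i02"))
  expect_equal(unlist(gt[1, c("locA_1", "locA_2")], use.names = FALSE), c(101L, 101L))
  expect_true(all(is.na(gt[4, c("locA_1", "locA_2")])))
})

test_that("missing genotypes are excluded from shared-allele denominators", {
  f <- withr::local_tempfile(lines = genepop_text())
  gt <- read_genepop(f)
  d <- dps_individual(gt)
  # p2 individuals (rows 3, 4): locA missing in i02 so the pair is scored
  # over locB alone, where they share one copy of allele 204 out of two.
  expect_equal(d[4, 3], 0.5, tolerance = 1e-12)
})

test_that("malformed GENEPOP files fail with the offending line", {
  bad <- c("t", "locA", "locB", "Pop", "x ,  101101")
  f <- withr::local_tempfile(lines = bad)
  expect_error(read_genepop(f), "line 5")
  bad2 <- c("t", "locA", "Pop", "x ,  10A101")
  f2 <- withr::local_tempfile(lines = bad2)
  expect_error(read_genepop(f2), "unknown")
})

test_that("write -> read round trip preserves the table", {
  gt <- tiny_gt(c("s1", "s1", "s2"),
                list(c(101L, 102L, 210L, 210L),
                     c(NA, NA, 211L, 210L),
                     c(103L, 103L, 212L, 213L)))
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(gt, f)
  back <- read_genepop(f)
  expect_identical(as.data.frame(back), as.data.frame(gt))
  expect_identical(gt_loci(back), gt_loci(gt))
})

test_that("sibling clusters are subsampled to the smallest cluster per site", {
  sizes <- c(1, 3, 5)
  ids <- unlist(lapply(seq_along(sizes), function(k)
    sprintf("c%d_%d", k, seq_len(sizes[k]))))
  n <- length(ids)
  alleles <- matrix(rep(c(101L, 102L), n), ncol = 2, byrow = TRUE)
  gt <- genotype_table(ids, rep("s1", n), rep("larva", n), alleles, "L1")
  clusters <- data.frame(individual_id = ids, site_id = "s1",
                         cluster_id = sub("_.*", "", ids))
  kept <- subsample_siblings(gt, clusters, seed = 1)
  expect_equal(nrow(kept), 3)          # one per cluster
  expect_equal(as.vector(table(sub("_.*", "", kept$individual_id))[c("c1", "c2", "c3")]),
               c(1L, 1L, 1L))

  # site with clusters {2, 2} keeps all four
  gt2 <- genotype_table(sprintf("i%d", 1:4), rep("s1", 4), rep("larva", 4),
                        matrix(101L, 4, 2), "L1")
  cl2 <- data.frame(individual_id = sprintf("i%d", 1:4), site_id = "s1",
                    cluster_id = c("a", "a", "b", "b"))
  expect_equal(nrow(subsample_siblings(gt2, cl2, seed = 1)), 4)
})

test_that("subsampling leaves adults and singleton clusters untouched", {
  gt <- tiny_gt(c("s1", "s1", "s1"),
                list(c(101L, 101L), c(102L, 102L), c(103L, 103L)),
                stage = c("adult", "larva", "larva"))
  cl <- data.frame(individual_id = c("i02", "i03"), site_id = "s1",
                   cluster_id = c("a", "b"))
  sub <- subsample_siblings(gt, cl, seed = 1)
  expect_identical(as.data.frame(sub), as.data.frame(gt))

  cl_bad <- data.frame(individual_id = c("i02", "i03"),
                       site_id = c("s1", "s1"), cluster_id = c("a", "a"))
  cl_bad$site_id <- c("s1", "s2")
  expect_error(subsample_siblings(gt, cl_bad, seed = 1), "spanning")
})

test_that("subsampling property: cluster caps hold over many seeds", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n_cl <- sample(2:4, 1)
      sizes <- sample(1:5, n_cl, replace = TRUE)
      ids <- unlist(lapply(seq_len(n_cl), function(k)
        sprintf("c%d_%d", k, seq_len(sizes[k]))))
      stage <- rep("larva", length(ids))
      gt <- genotype_table(c(ids, "ad1"), rep("s1", length(ids) + 1),
                           c(stage, "adult"),
                           matrix(101L, length(ids) + 1, 2), "L1")
      cl <- data.frame(individual_id = ids, site_id = "s1",
                       cluster_id = sub("_.*", "", ids))
      out <- subsample_siblings(gt, cl, seed = rep)
      expect_true("ad1" %in% out$individual_id)
      kept <- table(sub("_.*", "", setdiff(out$individual_id, "ad1")))
      expect_true(all(kept == min(sizes)))
    }
  })
})

test_that("D_ps matches hand-worked shared-allele proportions", {
  # one locus: (101/101) vs (101/102) share one allele of two
  gt <- tiny_gt(c("s1", "s2"), list(c(101L, 101L), c(101L, 102L)))
  d <- dps_matrix(gt)
  expect_equal(d["s1", "s2"][[1]], 0.5, tolerance = 1e-12)

  # identical individuals across sites -> 0
  same <- tiny_gt(c("s1", "s2"), list(c(101L, 102L), c(101L, 102L)))
  expect_equal(dps_matrix(same)["s1", "s2"][[1]], 0)

  # disjoint allele sets at every locus -> 1
  disj <- tiny_gt(c("s1", "s2"),
                  list(c(101L, 102L, 201L, 202L), c(103L, 104L, 203L, 204L)))
  expect_equal(dps_matrix(disj)["s1", "s2"][[1]], 1)
})

test_that("D_ps is a bounded symmetric dissimilarity", {
  net <- make_network(c(0, 400, 900), c(0, 300, 100), rep(800, 3))
  sim <- simulate_genotypes(net, genotype_sim_spec(
    n_loci = 5, generations = 50, deme_size = 40, n_adults = 6,
    n_clusters = 0, seed = 14))
  d <- dps_matrix(sim$genotypes)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("duplicating a site reproduces its within-site dissimilarity structure", {
  gt <- tiny_gt(c("s1", "s1", "s1"),
                list(c(101L, 102L), c(101L, 103L), c(104L, 104L)))
  dup <- genotype_table(c(gt$individual_id, paste0(gt$individual_id, "x")),
                        c(gt$site_id, rep("s1copy", 3)),
                        rep("adult", 6),
                        rbind(as.matrix(gt[, 4:5]), as.matrix(gt[, 4:5])),
                        gt_loci(gt))
  d_ind <- dps_individual(gt)
  within_mean <- mean(d_ind[upper.tri(d_ind)])
  n <- 3
  expected <- (1 - 1 / n) * within_mean    # diagonal zeros dilute the block mean
  d <- dps_matrix(dup)
  expect_equal(d["s1", "s1copy"][[1]], expected, tolerance = 1e-12)
})

test_that("G_ST matches hand computations and boundary cases", {
  # freqs 0.8 vs 0.2 at one biallelic locus: H_S = 0.32, H_T = 0.5
  make_site <- function(p, site, n = 10) {
    n1 <- round(2 * n * p)
    alleles <- c(rep(101L, n1), rep(102L, 2 * n - n1))
    lapply(seq_len(n), function(i) c(alleles[2 * i - 1], alleles[2 * i]))
  }
  gt <- tiny_gt(c(rep("s1", 10), rep("s2", 10)),
                c(make_site(0.8, "s1"), make_site(0.2, "s2")))
  g <- gst(gt)
  expect_equal(g$global, 0.36, tolerance = 1e-12)
  expect_equal(g$pairwise["s1", "s2"][[1]], 0.36, tolerance = 1e-12)

  eq <- tiny_gt(c("s1", "s1", "s2", "s2"),
                list(c(101L, 102L), c(101L, 102L),
                     c(101L, 102L), c(101L, 102L)))
  expect_equal(gst(eq)$global, 0)

  fixed <- tiny_gt(c("s1", "s2"), list(c(101L, 101L), c(102L, 102L)))
  expect_equal(gst(fixed)$global, 1)

  mono <- tiny_gt(c("s1", "s2"), list(c(101L, 101L), c(101L, 101L)))
  expect_equal(gst(mono)$global, 0)  # H_T = 0 guard
})

test_that("G_ST is invariant to allele relabeling", {
  net <- make_network(c(0, 700), c(0, 0), c(400, 400))
  sim <- simulate_genotypes(net, genotype_sim_spec(
    n_loci = 4, generations = 60, deme_size = 40, n_adults = 8,
    n_clusters = 0, seed = 15))
  gt <- sim$genotypes
  g1 <- gst(gt)$global
  relab <- gt
  for (cn in names(relab)[-(1:3)]) relab[[cn]] <- 1000L - relab[[cn]]
  attr(relab, "loci") <- gt_loci(gt)
  class(relab) <- class(gt)
  expect_equal(gst(relab)$global, g1, tolerance = 1e-12)
})

test_that("G_ST permutation test is well-behaved on exchangeable data", {
  # one panmictic pool split arbitrarily into two sites: no true structure
  withr::with_seed(31, {
    alleles <- matrix(sample(101:106, 2 * 60, replace = TRUE), ncol = 2)
  })
  gt <- genotype_table(sprintf("i%02d", 1:60),
                       rep(c("s1", "s2"), each = 30),
                       alleles = cbind(alleles, alleles[, 2:1]),
                       loci = c("L1", "L2"))
  res <- gst_permutation(gt, n_perm = 199, seed = 5)
  expect_gt(res$p_value, 0.05)
  pw <- gst_permutation(gt, n_perm = 99, seed = 5, pairwise = TRUE)
  expect_equal(nrow(pw), 1)
  expect_false(pw$significant_bonferroni[1])
})

test_that("degenerate genotype tables are rejected informatively", {
  expect_error(genotype_table("i1", "", alleles = matrix(101L, 1, 2),
                              loci = "L1"), "site ids")
  expect_error(tiny_gt(c("s1", "s2"), list(c(0L, 1L), c(1L, 1L))), "positive")
  all_na <- genotype_table(c("i1", "i2"), c("s1", "s2"),
                           alleles = matrix(c(NA, NA, 101L, 101L), 2, 2,
                                            byrow = TRUE), loci = "L1")
  expect_error(dps_matrix(all_na), "s1")
})
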