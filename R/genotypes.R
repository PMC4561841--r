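## Multilocus microsatellite genotypes: container, GENEPOP IO, full-sib
## subsampling, D_ps and G_ST.

#' Construct a multilocus genotype table
#'
#' A genotype table is a data.frame with one row per individual: columns
#' `individual_id`, `site_id`, `life_stage` ("adult" or "larva"), then two
#' integer allele columns per locus named `<locus>_1` and `<locus>_2`
#' (NA = missing). The ordered locus names are kept in the `"loci"`
#' attribute.
#'
#' @param individual_id,site_id,life_stage character vectors, one entry per
#'   individual.
#' @param alleles integer matrix with `2 * length(loci)` columns: the two
#'   alleles of locus 1, then locus 2, etc. Allele codes are positive
#'   integers; use NA for missing.
#' @param loci ordered character vector of locus names.
#' @return object of class `genotype_table` (also a data.frame).
#' @export
genotype_table <- function(individual_id, site_id,
                           life_stage = rep("adult", length(individual_id)),
                           alleles, loci) {
  n <- length(individual_id)
  alleles <- as.matrix(alleles)
  if (any(!nzchar(site_id)) || anyNA(site_id)) stopf("site ids must be nonempty")
  if (ncol(alleles) != 2 * length(loci))
    stopf("alleles must have 2 columns per locus (%d loci, %d columns)",
          length(loci), ncol(alleles))
  if (nrow(alleles) != n) stopf("alleles must have one row per individual")
  if (any(alleles <= 0, na.rm = TRUE)) stopf("allele codes must be positive integers")
  if (!all(life_stage %in% c("adult", "larva")))
    stopf("life_stage must be 'adult' or 'larva'")
  colnames(alleles) <- paste(rep(loci, each = 2), 1:2, sep = "_")
  out <- data.frame(individual_id = as.character(individual_id),
                    site_id = as.character(site_id),
                    life_stage = life_stage, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(alleles))
  attr(out, "loci") <- as.character(loci)
  class(out) <- c("genotype_table", "data.frame")
  out
}

#' Locus names of a genotype table
#' @param x a `genotype_table`.
#' @return character vector of locus names, in order.
#' @export
gt_loci <- function(x) attr(x, "loci")

## n x 2 allele matrix for one locus.
gt_alleles <- function(x, locus) {
  as.matrix(x[, paste(locus, 1:2, sep = "_"), drop = FALSE])
}

## Row subset preserving class and loci attribute.
gt_subset <- function(x, idx) {
  out <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "loci") <- gt_loci(x)
  class(out) <- c("genotype_table", "data.frame")
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d loci, %d sites\n",
              nrow(x), length(gt_loci(x)), length(unique(x$site_id))))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read a GENEPOP genotype file
#'
#' Supports the common dialect: a title line; one locus name per line (or a
#' single comma-separated line); `Pop` separators; individual lines
#' `id , codes` where each code concatenates the two alleles as fixed-width
#' (2- or 3-digit) integers, with an all-zero code meaning missing. Sites
#' appear in file order; a site is named by the shared `<site>_` prefix of
#' its individual ids when one exists, else `pop<k>`.
#'
#' @param path file path.
#' @return a [genotype_table()].
#' @export
read_genepop <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (length(lines) < 3) stopf("%s: not a GENEPOP file (too short)", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stopf("%s: no 'Pop' separator found", path)
  locus_lines <- trimws(lines[2:(first_pop - 1)])
  loci <- if (length(locus_lines) == 1 && grepl(",", locus_lines)) {
    trimws(strsplit(locus_lines, ",")[[1]])
  } else locus_lines
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stopf("%s: no locus names", path)

  ids <- sites <- character(0)
  alleles <- NULL
  pop_k <- 0L
  pop_ids <- character(0)
  pop_rows <- list()
  flush_pop <- function() {
    if (length(pop_ids) == 0) return()
    pre <- sub("_.*$", "", pop_ids)
    if (all(grepl("_", pop_ids)) && length(unique(pre)) == 1) {
      site <- pre[1]
      pop_ids <- sub("^[^_]*_", "", pop_ids)
    } else {
      site <- sprintf("pop%d", pop_k)
    }
    sites <<- c(sites, rep(site, length(pop_ids)))
    ids <<- c(ids, pop_ids)
    alleles <<- rbind(alleles, do.call(rbind, pop_rows))
  }
  for (ln in seq(first_pop, length(lines))) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (toupper(line) == "POP") {
      flush_pop()
      pop_k <- pop_k + 1L
      pop_ids <- character(0); pop_rows <- list()
      next
    }
    if (!grepl(",", line))
      stopf("%s line %d: expected 'id , genotypes'", path, ln)
    id <- trimws(sub(",.*$", "", line))
    codes <- strsplit(trimws(sub("^[^,]*,", "", line)), "[[:space:]]+")[[1]]
    if (length(codes) != length(loci))
      stopf("%s line %d: %d genotype codes for %d loci",
            path, ln, length(codes), length(loci))
    w <- nchar(codes)
    if (any(w != w[1]) || !(w[1] %in% c(4L, 6L)) || any(grepl("[^0-9]", codes)))
      stopf("%s line %d: unknown genotype token(s)", path, ln)
    half <- w[1] / 2
    a1 <- as.integer(substr(codes, 1, half))
    a2 <- as.integer(substr(codes, half + 1, w[1]))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    pop_ids <- c(pop_ids, id)
    pop_rows[[length(pop_rows) + 1L]] <- as.vector(rbind(a1, a2))
  }
  flush_pop()
  if (length(ids) == 0) stopf("%s: no individuals", path)
  genotype_table(ids, sites, alleles = alleles, loci = loci)
}

#' Write a genotype table as a GENEPOP file
#'
#' Alleles are written as 3-digit codes (so codes must be < 1000); missing
#' pairs become `000000`. Individual ids are written as
#' `<site_id>_<individual_id>` so that [read_genepop()] recovers site
#' membership.
#'
#' @param x a [genotype_table()].
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "pondscape genotypes") {
  loci <- gt_loci(x)
  out <- c(title, loci)
  for (site in unique(x$site_id)) {
    out <- c(out, "Pop")
    rows <- which(x$site_id == site)
    for (i in rows) {
      codes <- vapply(loci, function(l) {
        a <- gt_alleles(x, l)[i, ]
        if (anyNA(a)) "000000" else {
          if (any(a >= 1000)) stopf("allele code >= 1000 at locus %s", l)
          sprintf("%03d%03d", a[1], a[2])
        }
      }, character(1))
      clean <- function(s) gsub("[ ,_]", "-", s)
      out <- c(out, paste0(clean(site), "_", clean(x$individual_id[i]), " ,  ",
                           paste(codes, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Subsample full-sib larval clusters to the smallest cluster size per site
#'
#' Varying full-sib family sizes bias allele-frequency estimates from larval
#' samples. For each site, every sibling cluster is randomly subsampled
#' without replacement to n*, the size of the smallest cluster at that site.
#' Adults pass through untouched.
#'
#' @param x a [genotype_table()].
#' @param clusters data.frame with columns `individual_id`, `site_id`,
#'   `cluster_id` covering every larva in `x`. Clusters must not span sites.
#' @param seed integer seed for the random draws.
#' @return a [genotype_table()] in the original row order.
#' @export
subsample_siblings <- function(x, clusters, seed = 1) {
  stopifnot(inherits(x, "genotype_table"))
  need <- c("individual_id", "site_id", "cluster_id")
  if (!all(need %in% names(clusters)))
    stopf("clusters must have columns %s", paste(need, collapse = ", "))
  span <- tapply(clusters$site_id, clusters$cluster_id,
                 function(s) length(unique(s)))
  if (any(span > 1))
    stopf("cluster(s) spanning multiple sites: %s",
          paste(names(span)[span > 1], collapse = ", "))
  larvae <- which(x$life_stage == "larva")
  m <- match(x$individual_id[larvae], clusters$individual_id)
  if (anyNA(m))
    stopf("larva(e) missing from clusters: %s",
          paste(x$individual_id[larvae][is.na(m)], collapse = ", "))
  keep <- rep(TRUE, nrow(x))
  cl <- clusters$cluster_id[m]
  site <- x$site_id[larvae]
  with_stream(seed, 9L, {
    for (s in unique(site)) {
      in_site <- larvae[site == s]
      cl_s <- cl[site == s]
      n_star <- min(table(cl_s))
      for (cc in unique(cl_s)) {
        members <- in_site[cl_s == cc]
        if (length(members) > n_star) {
          drop <- sample(members, length(members) - n_star)
          keep[drop] <- FALSE
        }
      }
    }
  })
  gt_subset(x, keep)
}

## Pairwise proportion-of-shared-alleles between all individuals.
## Returns list(ps = n x n shared proportion, scored = loci scored in both).
ps_individual <- function(x) {
  n <- nrow(x)
  loci <- gt_loci(x)
  shared <- matrix(0, n, n)
  nloc <- matrix(0L, n, n)
  for (l in loci) {
    al <- gt_alleles(x, l)
    a1 <- al[, 1]; a2 <- al[, 2]
    ok <- !(is.na(a1) | is.na(a2))
    # count of x's first/second allele within y's genotype (rows = x, cols = y)
    cnt1 <- outer(a1, a1, "==") + outer(a1, a2, "==")
    cnt2 <- outer(a2, a1, "==") + outer(a2, a2, "==")
    hom <- matrix(a1 == a2, n, n)
    sh <- ifelse(hom, cnt1, pmin(cnt1, 1) + pmin(cnt2, 1))
    both <- outer(ok, ok, "&")
    sh[!both] <- 0
    sh[is.na(sh)] <- 0
    shared <- shared + sh
    nloc <- nloc + both
  }
  ps <- ifelse(nloc > 0, shared / (2 * nloc), NA_real_)
  diag(ps) <- 1
  list(ps = ps, scored = nloc)
}

#' Individual-level proportion-of-shared-alleles distance matrix
#'
#' `D = 1 - ps` where `ps` sums, over loci scored in both individuals, the
#' minimum allele counts shared by the two genotypes, divided by twice the
#' number of jointly scored loci.
#'
#' @param x a [genotype_table()].
#' @return symmetric n x n matrix of individual dissimilarities in `[0, 1]`.
#' @export
dps_individual <- function(x) {
  d <- 1 - ps_individual(x)$ps
  dimnames(d) <- list(x$individual_id, x$individual_id)
  d
}

#' Between-site D_ps genetic distance matrix
#'
#' The proportion-of-shared-alleles distance between two sites is one minus
#' the mean shared proportion over all inter-site individual pairs.
#'
#' @param x a [genotype_table()] with at least 2 sites.
#' @return symmetric site x site matrix, zero diagonal, entries in
#'   `[0, 1]`, with per-site sample sizes in attribute `"n"`.
#' @export
dps_matrix <- function(x) {
  sites <- unique(x$site_id)
  if (length(sites) < 2) stopf("need >= 2 sites for D_ps")
  zero <- tapply(rowSums(!is.na(as.matrix(
    x[, -(1:3), drop = FALSE]))), x$site_id, max)
  if (any(zero == 0))
    stopf("site(s) with zero scored loci: %s",
          paste(names(zero)[zero == 0], collapse = ", "))
  ps <- ps_individual(x)$ps
  k <- length(sites)
  out <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    block <- ps[x$site_id == sites[i], x$site_id == sites[j], drop = FALSE]
    out[i, j] <- out[j, i] <- 1 - mean(block, na.rm = TRUE)
  }
  attr(out, "n") <- as.integer(table(factor(x$site_id, levels = sites)))
  names(attr(out, "n")) <- sites
  out
}

## Allele frequency list: per locus, a sites x alleles matrix (NA row when a
## site has no scored alleles at that locus).
allele_freqs <- function(x) {
  sites <- unique(x$site_id)
  lapply(gt_loci(x), function(l) {
    al <- gt_alleles(x, l)
    codes <- sort(unique(as.vector(al[!is.na(al)])))
    f <- matrix(NA_real_, length(sites), max(1, length(codes)),
                dimnames = list(sites, codes))
    for (s in sites) {
      a <- as.vector(al[x$site_id == s, ])
      a <- a[!is.na(a)]
      if (length(a) > 0 && length(codes) > 0)
        f[s, ] <- tabulate(match(a, codes), length(codes)) / length(a)
    }
    f
  })
}

## Summed-heterozygosity G_ST over a set of per-locus frequency matrices.
gst_from_freqs <- function(freqs) {
  ht_sum <- hs_sum <- 0
  for (f in freqs) {
    f <- f[stats::complete.cases(f), , drop = FALSE]
    if (nrow(f) == 0) next
    hs <- mean(1 - rowSums(f^2))
    pbar <- colMeans(f)
    ht <- 1 - sum(pbar^2)
    hs_sum <- hs_sum + hs
    ht_sum <- ht_sum + ht
  }
  if (ht_sum <= 0) 0 else (ht_sum - hs_sum) / ht_sum
}

#' Nei's G_ST differentiation: global and pairwise
#'
#' `G_ST = (H_T - H_S) / H_T` with `H_S` the unweighted mean of within-site
#' expected heterozygosities and `H_T` the expected heterozygosity of the
#' unweighted mean allele frequencies; loci are combined by summing the
#' heterozygosities across loci before taking the ratio. Data monomorphic
#' everywhere yield 0.
#'
#' @param x a [genotype_table()] with at least 2 sites.
#' @return list with elements `global` (scalar) and `pairwise`
#'   (site x site matrix, zero diagonal).
#' @export
gst <- function(x) {
  sites <- unique(x$site_id)
  if (length(sites) < 2) stopf("need >= 2 sites for G_ST")
  freqs <- allele_freqs(x)
  k <- length(sites)
  pw <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sub <- lapply(freqs, function(f) f[c(sites[i], sites[j]), , drop = FALSE])
    pw[i, j] <- pw[j, i] <- gst_from_freqs(sub)
  }
  list(global = gst_from_freqs(freqs), pairwise = pw)
}

#' Permutation test for G_ST
#'
#' Permutes individuals among sites and recomputes G_ST to obtain a null
#' distribution; reports the one-sided p-value `(1 + #perm >= obs) /
#' (n_perm + 1)`. For the pairwise mode, each site pair is tested separately
#' and a Bonferroni-adjusted significance flag is added.
#'
#' @param x a [genotype_table()].
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param pairwise if TRUE, test every site pair; otherwise the global value.
#' @param alpha familywise significance level for the Bonferroni flag.
#' @return for the global test a list `(gst, p_value)`; for pairwise a
#'   data.frame `(site_i, site_j, gst, p_value, significant_bonferroni)`.
#' @export
gst_permutation <- function(x, n_perm = 999, seed = 1, pairwise = FALSE,
                            alpha = 0.05) {
  perm_gst <- function(tab) {
    obs <- gst(tab)$global
    null <- with_stream(seed, 10L, vapply(seq_len(n_perm), function(b) {
      tab2 <- tab
      tab2$site_id <- sample(tab2$site_id)
      gst(tab2)$global
    }, numeric(1)))
    list(gst = obs, p_value = (1 + sum(null >= obs)) / (n_perm + 1))
  }
  if (!pairwise) return(perm_gst(x))
  sites <- unique(x$site_id)
  pairs <- utils::combn(sites, 2)
  res <- apply(pairs, 2, function(p) {
    sub <- gt_subset(x, x$site_id %in% p)
    unlist(perm_gst(sub))
  })
  out <- data.frame(site_i = pairs[1, ], site_j = pairs[2, ],
                    gst = res["gst", ], p_value = res["p_value", ],
                    stringsAsFactors = FALSE)
  out$significant_bonferroni <- out$p_value < alpha / nrow(out)
  rownames(out) <- NULL
  out
}
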