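# Shared toy inputs: n sites on a line with simple covariates.
toy_inputs <- function(n_sites = 6, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("s%02d", seq_len(n_sites))
    d <- abs(outer(seq_len(n_sites), seq_len(n_sites), "-")) * 250
    dimnames(d) <- list(ids, ids)
    dps <- 1 - exp(-d / 2000) * runif(1, 0.9, 1)   # distance-driven distances
    diag(dps) <- 0
    at <- data.frame(site_id = ids, pratio_at = runif(n_sites, 0.2, 0.8),
                     cti_at = runif(n_sites, 5, 12))
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    bet <- data.frame(site_i = ids[pairs[, 1]], site_j = ids[pairs[, 2]],
                      srr_bet = runif(nrow(pairs), 0.1, 0.9),
                      pratio_bet = runif(nrow(pairs), 0.2, 0.8))
    list(dps = dps, at = at, bet = bet, dist = d)
  })
}

test_that("flow tables cover both orientations of every site pair", {
  inp <- toy_inputs(18)
  fl <- build_flow_table(inp$dps, inp$at, inp$bet, inp$dist)
  expect_s3_class(fl, "flow_table")
  expect_equal(nrow(fl), 18 * 17)
  expect_false(any(fl$origin == fl$destination))
  key <- paste(fl$origin, fl$destination)
  rev_key <- paste(fl$destination, fl$origin)
  expect_true(all(rev_key %in% key))
  # symmetric response for the two orientations of a pair
  m <- match(rev_key, key)
  expect_equal(fl$response, fl$response[m])
  expect_true(all(c("ln_dist", "ln_pratio_at", "ln_srr_bet") %in% names(fl)))
})

test_that("flow-table responses and guards follow the log rules", {
  inp <- toy_inputs(4)
  inp$dps[1, 2] <- inp$dps[2, 1] <- 0
  fl <- build_flow_table(inp$dps, inp$at, inp$bet, inp$dist)
  expect_equal(fl$response[fl$origin == "s01" & fl$destination == "s02"], 0)

  inp2 <- toy_inputs(4)
  inp2$dps[3, 4] <- inp2$dps[4, 3] <- 1
  expect_warning(build_flow_table(inp2$dps, inp2$at, inp2$bet, inp2$dist),
                 "floored")

  inp3 <- toy_inputs(4)
  inp3$at$pratio_at[2] <- NA
  expect_error(build_flow_table(inp3$dps, inp3$at, inp3$bet, inp3$dist),
               "pratio_at.*s02")
  inp4 <- toy_inputs(4)
  inp4$bet <- inp4$bet[-1, ]
  expect_error(build_flow_table(inp4$dps, inp4$at, inp4$bet, inp4$dist),
               "between-site")
})

test_that("at-site covariates can attach to origin, destination or pair mean", {
  inp <- toy_inputs(4)
  fo <- build_flow_table(inp$dps, inp$at, inp$bet, inp$dist)
  fd <- build_flow_table(inp$dps, inp$at, inp$bet, inp$dist,
                         at_site_role = "destination")
  fm <- build_flow_table(inp$dps, inp$at, inp$bet, inp$dist,
                         at_site_role = "mean")
  i <- which(fo$origin == "s01" & fo$destination == "s03")
  v <- function(s) inp$at$pratio_at[inp$at$site_id == s]
  eps <- 1e-6
  expect_equal(fo$ln_pratio_at[i], log(v("s01") + eps))
  expect_equal(fd$ln_pratio_at[i], log(v("s03") + eps))
  expect_equal(fm$ln_pratio_at[i], log((v("s01") + v("s03")) / 2 + eps))
})

test_that("the mixed fit collapses to OLS when origins carry no variance", {
  org <- rep(sprintf("s%02d", 1:18), each = 17)
  withr::with_seed(5, {
    X <- cbind(x1 = rnorm(306), x2 = runif(306))
    eps <- rnorm(306, 0, 0.05)
  })
  # remove every between-origin difference so the origin variance is truly 0
  Xc <- apply(X, 2, function(v) v - ave(v, org))
  eps <- eps - ave(eps, org)
  fl <- data.frame(origin = org, response = drop(Xc %*% c(-0.5, 0.3)) + eps,
                   x1 = Xc[, 1], x2 = Xc[, 2], stringsAsFactors = FALSE)
  fit <- fit_gravity(fl, c("x1", "x2"))
  ols <- lm(response ~ x1 + x2, data = fl)
  expect_lt(fit$sigma_u, 1e-6)
  expect_equal(unname(fit$coef), unname(coef(ols)), tolerance = 1e-6)

  # record order is irrelevant
  perm <- fl[withr::with_seed(1, sample(nrow(fl))), ]
  fit2 <- fit_gravity(perm, c("x1", "x2"))
  expect_equal(fit$coef, fit2$coef, tolerance = 1e-9)
  expect_equal(fit$logLik, fit2$logLik, tolerance = 1e-9)
})

test_that("rank-deficient designs fail with the aliased columns named", {
  withr::with_seed(6, {
    X <- cbind(x1 = rnorm(60))
  })
  X <- cbind(X, dup = 2 * X[, "x1"])
  org <- rep(c("a", "b", "c"), each = 20)
  fl <- simulate_flow_table(X, c(1, 0), org, sigma_u = 0.1, sigma_e = 0.1,
                            seed = 1)
  expect_error(fit_gravity(fl, c("x1", "dup")), "aliased.*dup")
})

test_that("the fit tracks affine predictor rescaling exactly", {
  withr::with_seed(9, {
    X <- cbind(x1 = rnorm(120), x2 = rnorm(120))
  })
  org <- rep(sprintf("o%d", 1:6), each = 20)
  fl <- simulate_flow_table(X, c(0.8, -0.4), org, sigma_u = 0.2,
                            sigma_e = 0.1, seed = 2)
  fit <- fit_gravity(fl, c("x1", "x2"))
  fl2 <- fl
  fl2$x1 <- 10 * fl2$x1 + 3
  fit2 <- fit_gravity(fl2, c("x1", "x2"))
  expect_equal(fit2$coef[["x1"]], fit$coef[["x1"]] / 10, tolerance = 1e-8)
  expect_equal(fit2$coef[["x2"]], fit$coef[["x2"]], tolerance = 1e-8)
  expect_equal(fit2$logLik, fit$logLik, tolerance = 1e-8)
})

test_that("AIC conventions reproduce selection-table arithmetic", {
  expect_equal(aic_from_loglik(-6.04, 4), 20.08)
  expect_equal(aic_from_loglik(-5.39, 5) - aic_from_loglik(-6.04, 4), 0.70)
  expect_equal(aic_from_loglik(-4.85, 6) - aic_from_loglik(-6.04, 4), 1.62)

  withr::with_seed(3, {
    X <- cbind(x1 = rnorm(60))
  })
  org <- rep(c("a", "b", "c"), each = 20)
  fl <- simulate_flow_table(X, 0.5, org, sigma_u = 0.1, sigma_e = 0.1, seed = 4)
  fit <- fit_gravity(fl, "x1")
  printed <- aic_gravity(fit, "printed_k")
  full <- aic_gravity(fit, "full")
  expect_equal(printed$n_params, 1)
  expect_equal(full$n_params, 4)      # intercept + slope + 2 variances
  expect_equal(printed$aic, 2 * 1 - 2 * fit$logLik)
  expect_equal(full$aic, 2 * 4 - 2 * fit$logLik)
})

test_that("a noise predictor cannot reduce the likelihood or win by AIC", {
  org <- rep(sprintf("o%d", 1:6), each = 12)
  for (seed in 1:5) {
    withr::with_seed(100 + seed, {
      X <- cbind(x1 = rnorm(72), junk = rnorm(72))
    })
    fl <- simulate_flow_table(X, c(0.7, 0), org, sigma_u = 0.1,
                              sigma_e = 0.2, seed = seed)
    f1 <- fit_gravity(fl, "x1")
    f2 <- fit_gravity(fl, c("x1", "junk"))
    expect_gte(f2$logLik, f1$logLik - 1e-6)
    dAIC <- aic_gravity(f2, "printed_k")$aic - aic_gravity(f1, "printed_k")$aic
    expect_lte(dAIC, 2 + 1e-6)
  }
})

test_that("model selection ranks by AIC with a distance-only null appended", {
  inp <- toy_inputs(8, seed = 2)
  fl <- build_flow_table(inp$dps, inp$at, inp$bet, inp$dist)
  specs <- list(gravity_model_spec("dist+srr", c("dist", "srr_bet")),
                gravity_model_spec("dist+pratio", c("dist", "pratio_at")))
  tab <- model_selection(fl, specs)
  expect_s3_class(tab, "selection_table")
  expect_true("null_distance" %in% tab$model)
  expect_equal(min(tab$delta_aic), 0)
  expect_false(is.unsorted(tab$AIC))
  expect_true(all(tab$top == (tab$delta_aic < 2)))

  one <- model_selection(fl, list(gravity_model_spec("null_distance", "dist")))
  expect_equal(one$delta_aic, 0)
  expect_true(all(one$top))

  # identical specs tie; order is stabilized by name
  twins <- model_selection(fl, list(
    gravity_model_spec("zeta", c("dist", "srr_bet")),
    gravity_model_spec("alpha", c("dist", "srr_bet"))))
  tied <- twins[twins$model %in% c("alpha", "zeta"), ]
  expect_equal(tied$AIC[1], tied$AIC[2], tolerance = 1e-9)
  expect_equal(tied$model, c("alpha", "zeta"))

  expect_error(gravity_model_spec("no_dist", "srr_bet"), "distance")
})

test_that("the generating model lands in the AIC top set in most replicates", {
  org <- rep(sprintf("s%02d", 1:18), each = 17)
  hits <- 0
  n_rep <- 50
  for (seed in seq_len(n_rep)) {
    withr::with_seed(200 + seed, {
      X <- cbind(ln_dist = rnorm(306), ln_a = rnorm(306), ln_b = rnorm(306))
    })
    fl <- simulate_flow_table(X, c(-0.4, 0.5, 0), org, sigma_u = 0.1,
                              sigma_e = 0.1, seed = seed)
    fl$origin <- org
    specs <- list(gravity_model_spec("true", c("ln_dist", "ln_a")),
                  gravity_model_spec("extra", c("ln_dist", "ln_a", "ln_b")),
                  gravity_model_spec("wrong", c("ln_dist", "ln_b")))
    tab <- model_selection(fl, specs)
    if (tab$top[tab$model == "true"]) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_rep)
})

test_that("bandwidth selection minimizes AIC and breaks ties downward", {
  inp <- toy_inputs(8, seed = 3)
  fl <- build_flow_table(inp$dps, inp$at, inp$bet, inp$dist)
  same <- list("30" = fl, "60" = fl, "120" = fl, "240" = fl)
  spec <- gravity_model_spec("probe", c("dist", "srr_bet"))
  sel <- bandwidth_selection(same, spec)
  expect_equal(sel$bandwidth, 30)
  expect_equal(sel$table$delta_aic, rep(0, 4))

  solo <- bandwidth_selection(list("120" = fl), spec)
  expect_equal(solo$bandwidth, 120)

  broken <- list("30" = fl, "60" = NULL)
  expect_error(bandwidth_selection(broken, spec), "missing")
})

test_that("the bandwidth carrying the true covariate usually wins", {
  org <- rep(sprintf("s%02d", 1:12), each = 11)
  n <- length(org)
  wins <- 0
  n_rep <- 20
  for (seed in seq_len(n_rep)) {
    withr::with_seed(300 + seed, {
      truth <- rnorm(n)
      lnd <- rnorm(n)
      resp <- -0.3 * lnd + 0.6 * truth + rnorm(n, 0, 0.1)
      # one shared response; covariate measured cleanly only at 30 m
      tables <- lapply(c(0, 0.8, 1.2, 1.6), function(noise)
        data.frame(origin = org, response = resp, ln_dist = lnd,
                   ln_srr_bet = truth + noise * rnorm(n),
                   stringsAsFactors = FALSE))
      names(tables) <- c(30, 60, 120, 240)
    })
    spec <- gravity_model_spec("probe", c("ln_dist", "ln_srr_bet"),
                               require_distance = FALSE)
    sel <- bandwidth_selection(tables, spec)
    if (sel$bandwidth == 30) wins <- wins + 1
  }
  expect_gte(wins, 0.75 * n_rep)
})
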