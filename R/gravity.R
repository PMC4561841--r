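## Singly-constrained gravity models of genetic connectivity:
## flow-table assembly, mixed-model ML fit with per-origin intercepts,
## AIC conventions, and model / bandwidth selection.

#' Assemble a gravity-model flow table
#'
#' One record per ordered site pair (i, j), i != j. The response is
#' `ln T_ij` with `T_ij = 1 - D_ps(i, j)` (functional connectivity); the
#' predictors are the natural logs of the between-site distance, the at-site
#' covariates of one site per pair, and the between-site covariates of the
#' pair. Zeros are guarded by `ln(x + epsilon)`; a `D_ps` of exactly 1 is
#' floored at `epsilon` with a warning.
#'
#' @param dps site x site genetic distance matrix ([dps_matrix()]).
#' @param at_site data.frame: `site_id` plus numeric covariate columns.
#' @param between_site data.frame: `site_i`, `site_j` plus numeric
#'   covariate columns, one row per unordered pair.
#' @param distances site x site matrix of between-site distances (meters),
#'   typically topographically corrected.
#' @param epsilon log-guard constant.
#' @param at_site_role how at-site covariates attach to an ordered pair:
#'   the `"origin"` site's value (default), the `"destination"`'s, or the
#'   pair `"mean"`.
#' @return data.frame of class `flow_table` with columns `origin`,
#'   `destination`, `response`, `ln_dist` and `ln_<covariate>` columns.
#' @export
build_flow_table <- function(dps, at_site, between_site, distances,
                             epsilon = 1e-6,
                             at_site_role = c("origin", "destination", "mean")) {
  at_site_role <- match.arg(at_site_role)
  sites <- rownames(dps)
  if (is.null(sites)) stopf("dps matrix must carry site ids as dimnames")
  if (!all(sites %in% at_site$site_id))
    stopf("at_site is missing site(s): %s",
          paste(setdiff(sites, at_site$site_id), collapse = ", "))
  if (!all(sites %in% rownames(distances)))
    stopf("distances matrix is missing site(s): %s",
          paste(setdiff(sites, rownames(distances)), collapse = ", "))
  at_vars <- setdiff(names(at_site), "site_id")
  bet_vars <- setdiff(names(between_site), c("site_i", "site_j", "bandwidth_m"))
  for (v in at_vars) {
    bad <- at_site$site_id[is.na(at_site[[v]])]
    bad <- intersect(bad, sites)
    if (length(bad) > 0)
      stopf("missing at-site covariate '%s' for site %s", v, bad[1])
  }
  pairs <- expand.grid(origin = sites, destination = sites,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$origin != pairs$destination, ]
  rownames(pairs) <- NULL
  i <- pairs$origin; j <- pairs$destination

  tij <- 1 - dps[cbind(i, j)]
  if (any(tij <= epsilon))
    warnf("%d pair(s) with D_ps at or above 1 - epsilon; response floored",
          sum(tij <= epsilon))
  out <- data.frame(origin = i, destination = j,
                    response = log(pmax(tij, epsilon)),
                    ln_dist = log(distances[cbind(i, j)] + epsilon),
                    stringsAsFactors = FALSE)

  ai <- match(i, at_site$site_id); aj <- match(j, at_site$site_id)
  for (v in at_vars) {
    val <- switch(at_site_role,
                  origin = at_site[[v]][ai],
                  destination = at_site[[v]][aj],
                  mean = (at_site[[v]][ai] + at_site[[v]][aj]) / 2)
    out[[paste0("ln_", v)]] <- log(val + epsilon)
  }
  key <- pair_key(between_site$site_i, between_site$site_j)
  bm <- match(pair_key(i, j), key)
  for (v in bet_vars) {
    val <- between_site[[v]][bm]
    if (anyNA(val)) {
      miss <- which(is.na(val))[1]
      stopf("missing between-site covariate '%s' for pair %s-%s",
            v, i[miss], j[miss])
    }
    out[[paste0("ln_", v)]] <- log(val + epsilon)
  }
  attr(out, "sites") <- sites
  attr(out, "epsilon") <- epsilon
  class(out) <- c("flow_table", "data.frame")
  out
}

#' Define a candidate gravity model
#'
#' Names the predictor subset of a candidate model. Predictors are covariate
#' names as they appear in the flow table (a bare name `v` resolves to the
#' `ln_v` column if present). Geographic distance is part of every candidate
#' by default; the distance-only model is the isolation-by-distance null.
#'
#' @param name model label (used for deterministic tie-breaking).
#' @param predictors character vector of predictor names.
#' @param require_distance enforce inclusion of `dist` (default TRUE).
#' @return object of class `gravity_model_spec`.
#' @export
gravity_model_spec <- function(name, predictors, require_distance = TRUE) {
  predictors <- unique(as.character(predictors))
  if (require_distance && !any(predictors %in% c("dist", "ln_dist")))
    stopf("model '%s' must include distance ('dist')", name)
  structure(list(name = name, predictors = predictors,
                 require_distance = require_distance),
            class = "gravity_model_spec")
}

resolve_columns <- function(flow, predictors) {
  vapply(predictors, function(p) {
    if (p %in% names(flow)) return(p)
    lp <- paste0("ln_", p)
    if (lp %in% names(flow)) return(lp)
    stopf("predictor '%s' not found in flow table", p)
  }, character(1))
}

#' Fit a singly-constrained gravity model
#'
#' Fits the log-linearized gravity equation
#' `ln T = X beta + u_origin + eps` by maximum likelihood (not REML, so AIC
#' is comparable across fixed-effect structures), with an independent
#' intercept per origin site (`u ~ N(0, sigma_u^2)`, boundary `sigma_u = 0`
#' permitted). The fixed-effect exponents are the production (`mu`),
#' distance-decay (`alpha`) and resistance (`beta`) parameters of the
#' power-law gravity model.
#'
#' @param flow a [build_flow_table()] result (or any data.frame with
#'   `response`, `origin` and the predictor columns).
#' @param spec a [gravity_model_spec()], or a character vector of predictor
#'   names.
#' @return object of class `gravity_fit` with elements `spec`,
#'   `predictors`, `coef`, `se`, `sigma_u`, `sigma_e`, `logLik`,
#'   `n_obs`, `n_origins`, `model` (the underlying lme4 fit).
#' @export
fit_gravity <- function(flow, spec) {
  if (is.character(spec))
    spec <- gravity_model_spec(paste(spec, collapse = "+"), spec,
                               require_distance = FALSE)
  stopifnot(inherits(spec, "gravity_model_spec"))
  if (length(unique(flow$origin)) < 2) stopf("need >= 2 origin sites")
  cols <- resolve_columns(flow, spec$predictors)
  X <- model.matrix(reformulate(cols), flow)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient design; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }
  f <- stats::as.formula(paste("response ~", paste(cols, collapse = " + "),
                               "+ (1 | origin)"))
  fit <- lme4::lmer(f, data = flow, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  fe <- lme4::fixef(fit)
  se <- coef(summary(fit))[, "Std. Error"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == "origin"][1]
  structure(list(spec = spec, predictors = cols, coef = fe, se = se,
                 sigma_u = sigma_u, sigma_e = sigma(fit),
                 logLik = as.numeric(logLik(fit)),
                 n_obs = nrow(flow),
                 n_origins = length(unique(flow$origin)),
                 model = fit),
            class = "gravity_fit")
}

#' @export
print.gravity_fit <- function(x, ...) {
  cat(sprintf("gravity_fit '%s': logLik = %.4f, sigma_u = %.4g, sigma_e = %.4g\n",
              x$spec$name, x$logLik, x$sigma_u, x$sigma_e))
  print(round(cbind(estimate = x$coef, se = x$se), 4))
  invisible(x)
}

#' AIC from a log-likelihood under an explicit parameter-count convention
#' @param logLik log-likelihood.
#' @param n_params parameter count `k`.
#' @return `2 k - 2 logLik`.
#' @export
aic_from_loglik <- function(logLik, n_params) 2 * n_params - 2 * logLik

#' AIC of a gravity fit
#'
#' Two parameter-count conventions are supported. `"full"` (the
#' statistically defensible default) counts every estimated parameter:
#' fixed effects including the intercept plus the two variance components.
#' `"printed_k"` counts only the named predictors, mirroring how selection
#' tables in this literature print "number of parameters".
#'
#' @param fit a [fit_gravity()] result.
#' @param convention `"full"` or `"printed_k"`.
#' @return list with `aic`, `n_params`, `convention`.
#' @export
aic_gravity <- function(fit, convention = c("full", "printed_k")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fit, "gravity_fit"))
  k <- switch(convention,
              full = length(fit$coef) + 2,
              printed_k = length(fit$predictors))
  list(aic = aic_from_loglik(fit$logLik, k), n_params = k,
       convention = convention)
}

#' Fit and rank candidate gravity models by AIC
#'
#' Every candidate is fit to the same flow table by ML; the table is sorted
#' by AIC (ties broken by model name) and candidates within `delta_cut` of
#' the best are flagged as the top set. A distance-only null model is
#' appended when absent. Candidates that fail to fit are recorded with
#' `converged = FALSE` and excluded from the ranking.
#'
#' @param flow a [build_flow_table()] result.
#' @param specs list of [gravity_model_spec()]s.
#' @param delta_cut top-set threshold on delta AIC (default 2).
#' @param convention AIC parameter-count convention (see [aic_gravity()]).
#' @return object of class `selection_table`: data.frame with columns
#'   `model`, `n_params`, `logLik`, `AIC`, `delta_aic`, `top`,
#'   `converged`, plus the fits in attribute `"fits"`.
#' @export
model_selection <- function(flow, specs, delta_cut = 2,
                            convention = c("full", "printed_k")) {
  convention <- match.arg(convention)
  if (length(specs) < 1) stopf("need >= 1 candidate model")
  if (inherits(specs, "gravity_model_spec")) specs <- list(specs)
  has_null <- any(vapply(specs, function(s)
    identical(sort(s$predictors), "dist") ||
      identical(sort(s$predictors), "ln_dist"), logical(1)))
  if (!has_null)
    specs <- c(specs, list(gravity_model_spec("null_distance", "dist")))
  fits <- lapply(specs, function(s) tryCatch(fit_gravity(flow, s),
                                             error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  rows <- lapply(seq_along(specs), function(k) {
    s <- specs[[k]]
    if (!ok[k]) {
      data.frame(model = s$name, n_params = length(s$predictors),
                 logLik = NA_real_, AIC = NA_real_, stringsAsFactors = FALSE)
    } else {
      a <- aic_gravity(fits[[k]], convention)
      data.frame(model = s$name, n_params = length(s$predictors),
                 logLik = fits[[k]]$logLik, AIC = a$aic,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab$converged <- ok
  if (!any(ok)) stopf("no candidate model converged")
  tab$delta_aic <- tab$AIC - min(tab$AIC[ok])
  tab$top <- ok & tab$delta_aic < delta_cut
  ord <- order(!tab$converged, tab$AIC, tab$model)
  tab <- tab[ord, c("model", "n_params", "logLik", "AIC", "delta_aic",
                    "top", "converged")]
  rownames(tab) <- NULL
  attr(tab, "fits") <- setNames(fits[ord], tab$model)
  attr(tab, "convention") <- convention
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' Select the between-site covariate bandwidth by AIC
#'
#' Fits the same model specification to one flow table per corridor
#' bandwidth and returns the bandwidth with the lowest AIC (ties broken by
#' the smallest bandwidth).
#'
#' @param flow_tables named list of flow tables, names = bandwidths in
#'   meters (e.g. `"30"`, `"60"`, `"120"`, `"240"`).
#' @param spec a [gravity_model_spec()] fit at every bandwidth.
#' @param convention AIC convention (see [aic_gravity()]).
#' @return list with `bandwidth` (numeric) and `table` (data.frame with
#'   `bandwidth_m`, `logLik`, `AIC`, `delta_aic`).
#' @export
bandwidth_selection <- function(flow_tables, spec,
                                convention = c("full", "printed_k")) {
  convention <- match.arg(convention)
  if (length(flow_tables) == 0) stopf("no flow tables supplied")
  bw <- suppressWarnings(as.numeric(names(flow_tables)))
  if (anyNA(bw)) stopf("flow_tables must be named by numeric bandwidths")
  if (any(vapply(flow_tables, is.null, logical(1))))
    stopf("missing flow table for bandwidth %s",
          paste(names(flow_tables)[vapply(flow_tables, is.null, logical(1))],
                collapse = ", "))
  res <- lapply(flow_tables, fit_gravity, spec = spec)
  aics <- vapply(res, function(f) aic_gravity(f, convention)$aic, numeric(1))
  tab <- data.frame(bandwidth_m = bw,
                    logLik = vapply(res, `[[`, numeric(1), "logLik"),
                    AIC = aics, delta_aic = aics - min(aics))
  tab <- tab[order(tab$AIC, tab$bandwidth_m), ]
  rownames(tab) <- NULL
  list(bandwidth = tab$bandwidth_m[1], table = tab)
}
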