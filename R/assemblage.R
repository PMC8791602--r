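#' Length-weight body-mass conversion
#'
#' Allometric mass = a * length^b with published length-weight
#' coefficients (a in g cm^-b, b unitless). Lengths below the 8 cm survey
#' cutoff are still converted but flagged with a warning.
#'
#' @param length total length in cm
#' @param a,b length-weight coefficients
#' @return body mass in g
#' @export
length_to_mass <- function(length, a = 0.01, b = 3) {
  stopifnot(a > 0, b > 0)
  if (any(length < 8))
    warning("length below the 8 cm survey protocol cutoff")
  a * length^b
}

#' Site-level biomass density from UVC point counts
#'
#' Per species and site-year: body masses are summed within each replicate
#' point count (area 154 m^2), divided by the count area, and averaged
#' across all replicates — replicates where the species was absent
#' contribute zero — then converted to kg ha^-1.
#'
#' @param uvc UVC table (`site`, `year`, `point_count`, `species`,
#'   `length`, `abundance`)
#' @param lw_table optional data frame (`species`, `a`, `b`) of
#'   species-specific length-weight coefficients; species not listed use
#'   `a`/`b`
#' @param a,b default length-weight coefficients
#' @param area_m2 area of one point count
#' @param n_replicates replicates per site-year; defaults to the number of
#'   distinct point-count ids observed in that site-year
#' @return data frame (`site`, `year`, `species`, `biomass_kg_ha`)
#' @export
biomass_density <- function(uvc, lw_table = NULL, a = 0.01, b = 3,
                            area_m2 = 154, n_replicates = NULL) {
  if (!is.null(n_replicates) && n_replicates < 1)
    stop("n_replicates must be >= 1")
  if (nrow(uvc) == 0)
    return(data.frame(site = character(), year = integer(),
                      species = character(), biomass_kg_ha = numeric()))
  aa <- rep(a, nrow(uvc))
  bb <- rep(b, nrow(uvc))
  if (!is.null(lw_table)) {
    i <- match(uvc$species, lw_table$species)
    aa[!is.na(i)] <- lw_table$a[i[!is.na(i)]]
    bb[!is.na(i)] <- lw_table$b[i[!is.na(i)]]
  }
  mass_g <- aa * uvc$length^bb * uvc$abundance
  key_sy <- paste(uvc$site, uvc$year, sep = "\r")
  out <- list()
  for (sy in unique(key_sy)) {
    x <- uvc[key_sy == sy, , drop = FALSE]
    m <- mass_g[key_sy == sy]
    reps <- if (is.null(n_replicates)) length(unique(x$point_count))
            else n_replicates
    if (reps < 1) stop("zero replicates for site-year ", sy)
    # sum within point count, average over all replicates (absences = 0)
    per_sp <- tapply(m, x$species, sum) / area_m2 / reps   # g m^-2
    out[[sy]] <- data.frame(site = x$site[1], year = x$year[1],
                            species = names(per_sp),
                            biomass_kg_ha = as.numeric(per_sp) * 10,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Biomass-weighted assemblage nutrient concentration and availability
#'
#' For each site-year and nutrient, the mean micronutrient concentration
#' of the target fish assemblage weighted by fishable biomass: per
#' posterior draw, sum(biomass_s * conc_s,draw) / sum(biomass_s) over the
#' target species present, summarised as median and 50%/95% HDIs. Total
#' availability (nutrient quantity per hectare) is
#' sum(biomass_s * conc_s,draw) with 1 kg = 10 portions of 100 g, so a
#' concentration in mg 100 g^-1 yields mg ha^-1. Non-target species are
#' excluded from the weighting; their biomass share is reported.
#'
#' @param biomass output of [biomass_density()]
#' @param draws_by_nutrient named list (per nutrient) of draw matrices,
#'   species x draws (e.g. `attr(predict_species(...), "draws")` with
#'   species rownames)
#' @param target_species species in the target assemblage; defaults to all
#'   species with draws
#' @return data frame of class `reef_profile`: per site-year-nutrient the
#'   weighted-mean summaries, availability summaries and target biomass
#'   share; per-draw weighted means kept in attribute `"draws"`
#' @export
weighted_assemblage_concentration <- function(biomass, draws_by_nutrient,
                                              target_species = NULL) {
  if (is.null(target_species))
    target_species <- rownames(draws_by_nutrient[[1]])
  key_sy <- paste(biomass$site, biomass$year, sep = "\r")
  out <- list()
  draw_store <- list()
  for (sy in unique(key_sy)) {
    x <- biomass[key_sy == sy, , drop = FALSE]
    in_target <- x$species %in% target_species
    share <- if (sum(x$biomass_kg_ha) > 0)
      sum(x$biomass_kg_ha[in_target]) / sum(x$biomass_kg_ha) else NA_real_
    xt <- x[in_target, , drop = FALSE]
    for (nu in names(draws_by_nutrient)) {
      cd <- draws_by_nutrient[[nu]]
      missing_sp <- setdiff(xt$species, rownames(cd))
      if (length(missing_sp) > 0)
        stop("no posterior draws for target species: ",
             paste(missing_sp, collapse = ", "))
      tot_b <- sum(xt$biomass_kg_ha)
      if (tot_b == 0) {
        warning("zero target biomass for site-year ", gsub("\r", " ", sy))
        wm <- rep(NA_real_, ncol(cd))
        avail <- rep(0, ncol(cd))
      } else {
        cmat <- cd[xt$species, , drop = FALSE]
        num <- colSums(cmat * xt$biomass_kg_ha)
        wm <- num / tot_b
        avail <- num * 10          # kg ha^-1 x (per 100 g) -> per ha
      }
      s_wm <- if (all(is.na(wm))) rep(NA_real_, 5) else summarise_draws(wm)
      s_av <- summarise_draws(avail)
      out[[paste(sy, nu)]] <- data.frame(
        site = x$site[1], year = x$year[1], nutrient = nu,
        median = s_wm[[1]], lower50 = s_wm[[2]], upper50 = s_wm[[3]],
        lower95 = s_wm[[4]], upper95 = s_wm[[5]],
        availability_median = s_av[[1]],
        availability_lower95 = s_av[[4]], availability_upper95 = s_av[[5]],
        target_share = share, stringsAsFactors = FALSE)
      draw_store[[paste(sy, nu)]] <- wm
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "draws") <- draw_store
  class(res) <- c("reef_profile", class(res))
  res
}

#' Benthic coral-to-macroalgae gradient (PC1)
#'
#' First principal component of standardized hard-coral cover, macroalgae
#' cover and structural complexity across site-years. The axis sign is
#' fixed so that macroalgae loads positively: the gradient reads
#' coral-dominated (negative) to macroalgal-dominated (positive).
#'
#' @param benthic benthic table (`site`, `year`, `hard_coral`,
#'   `macroalgae`, `complexity`)
#' @return object of class `benthic_gradient`: `scores` data frame
#'   (`site`, `year`, `pc1`), unit-norm `loadings` and `var_explained`
#'   (fraction of variance on PC1)
#' @export
benthic_pca <- function(benthic) {
  covars <- c("hard_coral", "macroalgae", "complexity")
  stopifnot(all(covars %in% names(benthic)))
  if (nrow(benthic) < 3) stop("need at least 3 site-year rows")
  M <- as.matrix(benthic[, covars])
  if (any(apply(M, 2, stats::sd) == 0))
    stop("constant benthic covariate: zero variance")
  pca <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  flip <- if (pca$rotation["macroalgae", 1] < 0) -1 else 1
  scores <- data.frame(site = benthic$site, year = benthic$year,
                       pc1 = flip * pca$x[, 1], stringsAsFactors = FALSE)
  out <- list(scores = scores,
              loadings = flip * pca$rotation[, 1],
              var_explained = pca$sdev[1]^2 / sum(pca$sdev^2))
  class(out) <- "benthic_gradient"
  out
}

#' @export
print.benthic_gradient <- function(x, ...) {
  cat(sprintf("Benthic gradient: PC1 explains %.1f%% of variance\n",
              100 * x$var_explained))
  print(round(x$loadings, 3))
  invisible(x)
}

# ---------------------------------------------------------------------------

benthic_jags_code <- function(likelihood, quadratic) {
  lik <- if (likelihood == "normal")
    "    y[i] ~ dnorm(mu[i], tau_obs)\n    mu[i] <- lp[i]"
  else
    "    y[i] ~ dgamma(k, k / mu[i])\n    log(mu[i]) <- lp[i]"
  quad <- if (quadratic) " + b2 * x[i] * x[i]" else ""
  obs <- if (likelihood == "normal")
    "  sigma_obs ~ dexp(1)\n  tau_obs <- pow(sigma_obs, -2)\n"
  else
    "  k ~ dexp(0.05)\n"
  # year intercepts are hierarchically centred on the global intercept so
  # that abar stays identified as the overall mean (predictions along the
  # gradient exclude year and site effects)
  paste0(
    "model {\n  for (i in 1:N) {\n", lik, "\n",
    sprintf("    lp[i] <- ayear[yr[i]] + asite[site[i]] + b1 * x[i]%s\n",
            quad),
    "  }\n",
    "  abar ~ dnorm(0, 1.0E-4)\n",
    "  b1 ~ dnorm(0, 0.01)\n",
    if (quadratic) "  b2 ~ dnorm(0, 0.01)\n" else "",
    "  for (j in 1:NY) { ayear[j] ~ dnorm(abar, tau_year) }\n",
    "  for (s in 1:NS) { asite[s] ~ dnorm(0, tau_site) }\n",
    "  sigma_year ~ dexp(1)\n  tau_year <- pow(sigma_year, -2)\n",
    "  sigma_site ~ dexp(1)\n  tau_site <- pow(sigma_site, -2)\n",
    obs, "}\n")
}

#' Regression of a site-year response on the benthic gradient
#'
#' Bayesian regression of a per-site-year response (a nutrient
#' concentration, normal likelihood; or a biomass proportion, gamma
#' likelihood with log link) on benthic PC1, with random intercepts for
#' survey year and reef site. Priors: intercept Normal(0, 100), PC1
#' coefficients Normal(0, 10), scale parameters Exponential(1). With
#' `quadratic = "select"` both the linear and quadratic forms are fitted
#' and the lower-WAIC form returned.
#'
#' @param response data frame (`site`, `year`, `value`)
#' @param gradient a [benthic_pca()] result
#' @param quadratic `FALSE`, `TRUE` or `"select"`
#' @param likelihood `"normal"` or `"gamma"`
#' @param mcmc an [mcmc_config()]
#' @return object of class `benthic_fit`: draws, WAIC, data and (when
#'   selecting) the WAIC of both forms
#' @export
fit_benthic_regression <- function(response, gradient, quadratic = FALSE,
                                   likelihood = c("normal", "gamma"),
                                   mcmc = mcmc_config()) {
  likelihood <- match.arg(likelihood)
  if (identical(quadratic, "select")) {
    f1 <- fit_benthic_regression(response, gradient, FALSE, likelihood, mcmc)
    f2 <- fit_benthic_regression(response, gradient, TRUE, likelihood, mcmc)
    chosen <- if (f2$waic$waic < f1$waic$waic) f2 else f1
    chosen$waic_linear <- f1$waic$waic
    chosen$waic_quadratic <- f2$waic$waic
    return(chosen)
  }
  stopifnot(all(c("site", "year", "value") %in% names(response)))
  key_g <- paste(gradient$scores$site, gradient$scores$year)
  key_r <- paste(response$site, response$year)
  i <- match(key_r, key_g)
  if (any(is.na(i))) stop("response site-years missing from the gradient")
  if (nrow(response) < 6)
    stop("fewer than 6 site-years: unidentifiable with year+site intercepts")
  x <- gradient$scores$pc1[i]
  yr_levels <- sort(unique(response$year))
  site_levels <- sort(unique(response$site))
  jdata <- list(N = nrow(response), y = response$value, x = x,
                yr = match(response$year, yr_levels), NY = length(yr_levels),
                site = match(response$site, site_levels),
                NS = length(site_levels))
  code <- benthic_jags_code(likelihood, isTRUE(quadratic))
  inits <- lapply(seq_len(mcmc$n_chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(mcmc$seed, 2000L + ch)))
  jm <- rjags::jags.model(textConnection(code), data = jdata, inits = inits,
                          n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
                          quiet = TRUE)
  if (mcmc$n_warmup > mcmc$n_adapt)
    stats::update(jm, mcmc$n_warmup - mcmc$n_adapt, progress.bar = "none")
  monitors <- c("abar", "b1", if (isTRUE(quadratic)) "b2", "ayear", "asite",
                if (likelihood == "normal") "sigma_obs" else "k")
  post <- rjags::coda.samples(jm, monitors, n.iter = mcmc$n_iter - mcmc$n_warmup,
                              thin = mcmc$thin, progress.bar = "none")
  draws <- do.call(rbind, lapply(post, as.matrix))

  # pointwise log-likelihood for WAIC
  yr_cols <- if (jdata$NY == 1) rep("ayear", jdata$N)
             else sprintf("ayear[%d]", jdata$yr)
  site_cols <- if (jdata$NS == 1) rep("asite", jdata$N)
               else sprintf("asite[%d]", jdata$site)
  lp <- outer(draws[, "b1"], x) +
    (if (isTRUE(quadratic)) outer(draws[, "b2"], x^2) else 0) +
    draws[, yr_cols, drop = FALSE] +
    draws[, site_cols, drop = FALSE]
  y <- jdata$y
  if (likelihood == "normal") {
    sig <- draws[, "sigma_obs"]
    ll <- -sweep((sweep(lp, 2, y))^2, 1, 2 * sig^2, "/") - log(sig) -
      0.5 * log(2 * pi)
  } else {
    k <- draws[, "k"]
    mu <- exp(lp)
    ll <- k * log(k) - k * lp + outer(k - 1, log(y)) -
      sweep(sweep(1 / mu, 2, y, "*"), 1, k, "*") - lgamma(k)
  }
  waic <- compute_waic(unname(ll))

  rhat <- rep(NA_real_, ncol(post[[1]]))
  if (mcmc$n_chains >= 2) {
    gd <- try(coda::gelman.diag(post, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- gd$psrf[, 1]
  }
  fit <- list(draws = draws, waic = waic, likelihood = likelihood,
              quadratic = isTRUE(quadratic),
              data = list(response = response, x = x),
              levels = list(year = yr_levels, site = site_levels),
              diagnostics = list(rhat = rhat,
                                 max_rhat = suppressWarnings(
                                   max(rhat, na.rm = TRUE))))
  class(fit) <- "benthic_fit"
  fit
}

#' Percent change along the coral-to-macroalgae gradient
#'
#' Posterior predictions at the observed extremes of the benthic gradient
#' (hard-coral end = minimum PC1, macroalgal end = maximum PC1), excluding
#' year and site effects; percent change = 100 (pred_MA - pred_HC) /
#' pred_HC per draw. The PC1 slope is summarised with a flag for whether
#' its 95% HDI spans zero, and predictions can be rescaled to a
#' pre-disturbance baseline.
#'
#' @param fit a `benthic_fit`
#' @param gradient the [benthic_pca()] result used in fitting
#' @param baseline optional pre-disturbance mean for rescaling
#' @return list: `percent_change` (summary of the per-draw percent
#'   change), `slope` summary, `slope_spans_zero`, predictions at both
#'   ends (and rescaled to baseline when given)
#' @export
gradient_percent_change <- function(fit, gradient, baseline = NULL) {
  stopifnot(inherits(fit, "benthic_fit"))
  x_hc <- min(gradient$scores$pc1)
  x_ma <- max(gradient$scores$pc1)
  pred_at <- function(x) {
    lp <- fit$draws[, "abar"] + fit$draws[, "b1"] * x +
      (if (fit$quadratic) fit$draws[, "b2"] * x^2 else 0)
    if (fit$likelihood == "gamma") exp(lp) else lp
  }
  p_hc <- pred_at(x_hc)
  p_ma <- pred_at(x_ma)
  if (stats::median(p_hc) <= 0)
    stop("prediction at the hard-coral end is nonpositive; ",
         "percent change undefined")
  pct <- 100 * (p_ma - p_hc) / p_hc
  slope <- summarise_draws(fit$draws[, "b1"])
  out <- list(percent_change = summarise_draws(pct),
              slope = slope,
              slope_spans_zero = slope[["lower95"]] <= 0 && slope[["upper95"]] >= 0,
              pred_hc = summarise_draws(p_hc),
              pred_ma = summarise_draws(p_ma))
  if (!is.null(baseline)) {
    out$pred_hc_rescaled <- out$pred_hc / baseline
    out$pred_ma_rescaled <- out$pred_ma / baseline
  }
  out
}
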