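#' Default prior table for the trait models
#'
#' One row per sampled parameter: distribution family and hyperparameters
#' (`p1`/`p2` are mean/sd for `normal`, rate for `exponential`), plus a
#' provenance tag. Trait-coefficient priors default to weakly informative
#' Normal(0, 1); an informative prior set (e.g. posteriors of a global
#' marine-fish model) can be supplied through the same table, read from
#' YAML with [read_prior_table()]. The habitat-effect prior is
#' Normal(0, 1); intercept-hierarchy scale priors are Exponential(1); the
#' OU kernel hyperpriors are Exponential(1) for the marginal variance and
#' Exponential(0.5) for the decay rate.
#'
#' @param covariates trait covariate names needing coefficient priors
#' @return data frame with columns `parameter`, `dist`, `p1`, `p2`,
#'   `provenance`
#' @export
default_priors <- function(covariates = c("K", "TL", "AM", "PEL", "LMX")) {
  beta_rows <- data.frame(parameter = paste0("beta_", covariates),
                          dist = "normal", p1 = 0, p2 = 1,
                          provenance = "weak_default",
                          stringsAsFactors = FALSE)
  other <- data.frame(
    parameter = c("beta6", "intercept", "sigma_family", "sigma_site",
                  "sigma_species", "sigma_b6", "sigma_obs", "shape",
                  "eta2", "rho"),
    dist = c("normal", "normal", "exponential", "exponential", "exponential",
             "exponential", "exponential", "exponential", "exponential",
             "exponential"),
    p1 = c(0, 0, 1, 1, 1, 1, 1, 0.05, 1, 0.5),
    p2 = c(1, 5, NA, NA, NA, NA, NA, NA, NA, NA),
    provenance = c("stated", "weak_default", "weak_default", "weak_default",
                   "weak_default", "weak_default", "weak_default",
                   "weak_default", "weak_default", "weak_default"),
    stringsAsFactors = FALSE)
  rbind(beta_rows, other)
}

#' Read a prior table from YAML
#'
#' The YAML file holds a list of entries with fields `parameter`, `dist`,
#' `p1`, `p2` (optional) and `provenance`; entries override the defaults of
#' [default_priors()].
#'
#' @param path YAML file path
#' @param covariates covariates of the model the priors are for
#' @return prior table data frame
#' @export
read_prior_table <- function(path, covariates = c("K", "TL", "AM", "PEL", "LMX")) {
  entries <- yaml::read_yaml(path)
  tab <- default_priors(covariates)
  for (e in entries) {
    i <- match(e$parameter, tab$parameter)
    row <- data.frame(parameter = e$parameter, dist = e$dist,
                      p1 = as.numeric(e$p1),
                      p2 = if (!is.null(e$p2)) as.numeric(e$p2) else NA_real_,
                      provenance = if (!is.null(e$provenance)) e$provenance
                                   else "user",
                      stringsAsFactors = FALSE)
    if (is.na(i)) tab <- rbind(tab, row) else tab[i, ] <- row
  }
  tab
}

prior_row <- function(priors, parameter) {
  i <- match(parameter, priors$parameter)
  if (is.na(i)) stop("no prior declared for parameter: ", parameter)
  priors[i, ]
}

#' Specification of a trait-based nutrient model
#'
#' Describes one model fit: the nutrient, its likelihood (gamma with log
#' link, or log-normal — the calcium convention), the ordered trait
#' covariates, covariate scaling, the intercept structure (taxonomic
#' family + site, phylogenetic species + site, or plain species + site),
#' and an optional varying slope on the macroalgal-habitat indicator
#' (the habitat model), with a per-parameter prior table.
#'
#' @param nutrient one of calcium, iron, selenium, zinc, omega3
#' @param likelihood `"gamma"` or `"lognormal"`; defaults to lognormal for
#'   calcium and gamma otherwise
#' @param covariates ordered trait covariate names
#' @param scaling `"centered_scaled"` (default) or `"unscaled"` (used for
#'   the out-of-sample prediction refit)
#' @param intercept_structure `"family+site"`, `"phylo_species+site"` or
#'   `"species+site"`
#' @param varying_slope_on `NULL` or `"HAB"`; `"HAB"` requires the
#'   species+site structure (the habitat varying-slopes model)
#' @param priors prior table, see [default_priors()]
#' @param nugget diagonal jitter for the phylogenetic covariance
#' @return an object of class `model_spec`
#' @export
model_spec <- function(nutrient,
                       likelihood = NULL,
                       covariates = c("K", "TL", "AM", "PEL", "LMX"),
                       scaling = c("centered_scaled", "unscaled"),
                       intercept_structure = c("family+site",
                                               "phylo_species+site",
                                               "species+site"),
                       varying_slope_on = NULL,
                       priors = default_priors(covariates),
                       nugget = 1e-6) {
  nutrient <- match.arg(nutrient, NUTRIENTS)
  scaling <- match.arg(scaling)
  intercept_structure <- match.arg(intercept_structure)
  if (is.null(likelihood))
    likelihood <- if (nutrient == "calcium") "lognormal" else "gamma"
  likelihood <- match.arg(likelihood, c("gamma", "lognormal"))
  if (!is.null(varying_slope_on)) {
    if (!identical(varying_slope_on, "HAB"))
      stop("the only supported varying slope is on HAB")
    if (intercept_structure != "species+site")
      stop("a HAB varying slope requires the species+site intercept structure")
  }
  spec <- list(nutrient = nutrient, likelihood = likelihood,
               covariates = covariates, scaling = scaling,
               intercept_structure = intercept_structure,
               varying_slope_on = varying_slope_on,
               priors = priors, nugget = nugget)
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Trait model spec: %s ~ %s, %s intercepts%s (%s likelihood, %s)\n",
              x$nutrient, paste(x$covariates, collapse = " + "),
              x$intercept_structure,
              if (!is.null(x$varying_slope_on)) " + varying HAB slope" else "",
              x$likelihood, x$scaling))
  invisible(x)
}

#' MCMC settings
#'
#' Defaults follow the study convention of 3 chains of 5,000 iterations
#' with a warmup of 1,500. `rhat_tol` is the maximum allowed deviation of
#' the potential-scale-reduction factor from 1 before draws are released
#' for downstream use.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics)
#' @param n_iter total iterations per chain (including warmup)
#' @param n_warmup warmup iterations discarded per chain
#' @param thin thinning interval
#' @param n_adapt sampler adaptation steps (within warmup)
#' @param seed RNG seed for the sampler
#' @param rhat_tol convergence tolerance on |Rhat - 1|
#' @param on_fail `"error"` (default), `"warn"` or `"none"` when the
#'   convergence check fails
#' @return list of class `mcmc_config`
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 5000, n_warmup = 1500,
                        thin = 1, n_adapt = min(500, n_warmup), seed = 1,
                        rhat_tol = 0.01,
                        on_fail = c("error", "warn", "none")) {
  stopifnot(n_iter > n_warmup, n_warmup >= n_adapt, n_chains >= 1)
  out <- list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
              n_warmup = as.integer(n_warmup), thin = as.integer(thin),
              n_adapt = as.integer(n_adapt), seed = as.integer(seed),
              rhat_tol = rhat_tol, on_fail = match.arg(on_fail))
  class(out) <- "mcmc_config"
  out
}

#' Ornstein-Uhlenbeck phylogenetic covariance matrix
#'
#' S_ij = eta2 * exp(-rho * d_ij) + nugget * 1[i = j], for a symmetric
#' zero-diagonal phylogenetic distance matrix d. Positive definiteness is
#' verified by Cholesky factorisation.
#'
#' @param dist symmetric nonnegative distance matrix with zero diagonal
#' @param eta2 marginal variance (> 0)
#' @param rho decay rate (> 0)
#' @param nugget small diagonal jitter
#' @return covariance matrix S
#' @export
ou_covariance <- function(dist, eta2, rho, nugget = 1e-6) {
  dist <- as.matrix(dist)
  if (!isSymmetric(dist, tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(diag(dist) != 0)) stop("distance matrix must have zero diagonal")
  if (any(dist < 0)) stop("distances must be nonnegative")
  stopifnot(eta2 > 0, rho > 0, nugget >= 0)
  S <- eta2 * exp(-rho * dist) + diag(nugget, nrow(dist))
  ch <- try(chol(S), silent = TRUE)
  if (inherits(ch, "try-error"))
    stop("OU covariance is not positive definite; increase the nugget")
  dimnames(S) <- dimnames(dist)
  S
}

# ---------------------------------------------------------------------------
# JAGS model code assembly

jags_prior <- function(priors, parameter) {
  r <- prior_row(priors, parameter)
  switch(r$dist,
         normal = sprintf("dnorm(%.10g, %.10g)", r$p1, r$p2^-2),
         exponential = sprintf("dexp(%.10g)", r$p1),
         gamma = sprintf("dgamma(%.10g, %.10g)", r$p1, r$p2),
         stop("unsupported prior family: ", r$dist))
}

build_jags_model <- function(spec) {
  pri <- spec$priors
  lik <- if (spec$likelihood == "gamma") {
    "    y[i] ~ dgamma(k, k / mu[i])\n    log(mu[i]) <- lmu[i]"
  } else {
    "    y[i] ~ dlnorm(lmu[i], tau_obs)"
  }
  # hierarchical centering: group intercepts are centred on the global
  # mean abar (better Gibbs mixing than the additive parameterisation);
  # the phylogenetic MVN intercept stays zero-centred with abar explicit
  group_term <- switch(spec$intercept_structure,
    "family+site" = "afam[fam[i]] + asite[site[i]]",
    "phylo_species+site" = "abar + asp[sp[i]] + asite[site[i]]",
    "species+site" = "asp[sp[i]] + asite[site[i]]")
  hab_term <- if (!is.null(spec$varying_slope_on)) " + b6[sp[i]] * hab[i]" else ""
  linpred <- sprintf("    lmu[i] <- %s + inprod(X[i, ], beta)%s",
                     group_term, hab_term)
  group_block <- switch(spec$intercept_structure,
    "family+site" = paste0(
      "  for (j in 1:J) { afam[j] ~ dnorm(abar, tau_fam) }\n",
      sprintf("  sigma_fam ~ %s\n", jags_prior(pri, "sigma_family")),
      "  tau_fam <- pow(sigma_fam, -2)\n"),
    "species+site" = paste0(
      "  for (q in 1:Q) { asp[q] ~ dnorm(abar, tau_sp) }\n",
      sprintf("  sigma_sp ~ %s\n", jags_prior(pri, "sigma_species")),
      "  tau_sp <- pow(sigma_sp, -2)\n"),
    "phylo_species+site" = paste0(
      "  for (r in 1:Q) { for (c in 1:Q) {\n",
      sprintf("    SS[r, c] <- eta2 * exp(-rho * D[r, c]) + equals(r, c) * %.10g\n",
              spec$nugget),
      "  } }\n",
      "  asp[1:Q] ~ dmnorm(zeroQ, inverse(SS))\n",
      sprintf("  eta2 ~ %s\n", jags_prior(pri, "eta2")),
      sprintf("  rho ~ %s\n", jags_prior(pri, "rho"))))
  hab_block <- if (!is.null(spec$varying_slope_on)) paste0(
    sprintf("  b6bar ~ %s\n", jags_prior(pri, "beta6")),
    "  for (q in 1:Q) { b6[q] ~ dnorm(b6bar, tau_b6) }\n",
    sprintf("  sigma_b6 ~ %s\n", jags_prior(pri, "sigma_b6")),
    "  tau_b6 <- pow(sigma_b6, -2)\n") else ""
  obs_block <- if (spec$likelihood == "gamma") {
    sprintf("  k ~ %s\n", jags_prior(pri, "shape"))
  } else {
    paste0(sprintf("  sigma_obs ~ %s\n", jags_prior(pri, "sigma_obs")),
           "  tau_obs <- pow(sigma_obs, -2)\n")
  }
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n", lik, "\n", linpred, "\n  }\n",
    "  for (p in 1:P) { beta[p] ~ dnorm(beta_mu[p], beta_tau[p]) }\n",
    sprintf("  abar ~ %s\n", jags_prior(pri, "intercept")),
    group_block,
    "  for (s in 1:S) { asite[s] ~ dnorm(0, tau_site) }\n",
    sprintf("  sigma_site ~ %s\n", jags_prior(pri, "sigma_site")),
    "  tau_site <- pow(sigma_site, -2)\n",
    hab_block, obs_block,
    "}\n")
}

# ---------------------------------------------------------------------------

#' Fit a trait-based nutrient model by MCMC
#'
#' Fits the hierarchical regression described by a [model_spec()] to
#' QC-filtered nutrient samples, joined to species traits. Covariates are
#' centred and scaled (divided by one standard deviation) across the
#' distinct species in the data unless `spec$scaling == "unscaled"`.
#' Convergence (|Rhat - 1| <= `rhat_tol` on every monitored parameter) is
#' enforced before draws are released; failures raise an error carrying
#' the diagnostics (configurable via `mcmc$on_fail`).
#'
#' @param samples nutrient-sample data frame (all nutrients; the spec's
#'   nutrient is selected internally)
#' @param traits species trait table covering every sampled species
#' @param spec a [model_spec()]
#' @param mcmc an [mcmc_config()]
#' @param phylo_dist phylogenetic distance matrix (required for the
#'   phylo_species+site structure)
#' @return an object of class `nutrient_fit`: pooled draw matrix with
#'   chain labels, convergence diagnostics, the model data and scaling
#' @export
fit_model <- function(samples, traits, spec, mcmc = mcmc_config(),
                      phylo_dist = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_config"))
  dat <- samples[samples$nutrient == spec$nutrient, , drop = FALSE]
  if (nrow(dat) < 2) stop("too few samples for nutrient ", spec$nutrient)
  missing_sp <- setdiff(unique(dat$species), traits$species)
  if (length(missing_sp) > 0)
    stop("traits missing for sampled species: ",
         paste(missing_sp, collapse = ", "))

  sp_levels <- sort(unique(dat$species))
  fam_levels <- sort(unique(traits$family[match(sp_levels, traits$species)]))
  site_levels <- sort(unique(dat$site))
  tr_idx <- match(dat$species, traits$species)

  # centre/scale over distinct species, not observations, so that species
  # sampled more heavily do not drag the covariate scale
  sp_rows <- traits[match(sp_levels, traits$species), , drop = FALSE]
  Xsp <- as.matrix(sp_rows[, spec$covariates, drop = FALSE])
  if (spec$scaling == "centered_scaled") {
    centers <- colMeans(Xsp)
    scales <- apply(Xsp, 2, stats::sd)
    scales[scales == 0 | !is.finite(scales)] <- 1
  } else {
    centers <- stats::setNames(rep(0, ncol(Xsp)), colnames(Xsp))
    scales <- stats::setNames(rep(1, ncol(Xsp)), colnames(Xsp))
  }
  X <- sweep(sweep(as.matrix(traits[tr_idx, spec$covariates, drop = FALSE]),
                   2, centers), 2, scales, "/")

  beta_pr <- do.call(rbind, lapply(spec$covariates, function(cv)
    prior_row(spec$priors, paste0("beta_", cv))))
  if (any(beta_pr$dist != "normal"))
    stop("trait-coefficient priors must be normal")
  if (spec$scaling == "unscaled") {
    # express the per-SD coefficient priors in raw covariate units so the
    # unscaled refit is the same model in a different parameterisation
    sds <- apply(Xsp, 2, stats::sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    beta_pr$p1 <- beta_pr$p1 / sds
    beta_pr$p2 <- beta_pr$p2 / sds
  }
  if (any(beta_pr$provenance == "weak_default"))
    message("weak default Normal(0, 1) trait priors in use; supply an ",
            "informative prior table to reproduce an informative-prior fit")

  jdata <- list(N = nrow(dat), P = length(spec$covariates),
                y = dat$concentration, X = X,
                site = match(dat$site, site_levels), S = length(site_levels),
                beta_mu = beta_pr$p1, beta_tau = beta_pr$p2^-2)
  monitors <- c("abar", "beta", "asite", "sigma_site")
  if (spec$intercept_structure == "family+site") {
    jdata$fam <- match(traits$family[tr_idx], fam_levels)
    jdata$J <- length(fam_levels)
    monitors <- c(monitors, "afam", "sigma_fam")
  } else {
    jdata$sp <- match(dat$species, sp_levels)
    jdata$Q <- length(sp_levels)
    monitors <- c(monitors, "asp")
    if (spec$intercept_structure == "phylo_species+site") {
      if (is.null(phylo_dist))
        stop("phylo_dist required for the phylo_species+site structure")
      dd <- as.matrix(phylo_dist)[sp_levels, sp_levels]
      jdata$D <- dd
      jdata$zeroQ <- rep(0, length(sp_levels))
      monitors <- c(monitors, "eta2", "rho")
    } else {
      monitors <- c(monitors, "sigma_sp")
    }
  }
  if (!is.null(spec$varying_slope_on)) {
    hab <- dat$habitat
    if (any(!hab %in% c("coral", "macroalgal")))
      stop("habitat must be coral or macroalgal for the habitat model")
    jdata$hab <- as.numeric(hab == "macroalgal")
    monitors <- c(monitors, "b6", "b6bar", "sigma_b6")
  }
  monitors <- c(monitors,
                if (spec$likelihood == "gamma") "k" else "sigma_obs")

  code <- build_jags_model(spec)
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(mcmc$seed, 1000L + ch))
  })
  jm <- rjags::jags.model(textConnection(code), data = jdata, inits = inits,
                          n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
                          quiet = TRUE)
  extra_burn <- mcmc$n_warmup - mcmc$n_adapt
  if (extra_burn > 0) stats::update(jm, n.iter = extra_burn, progress.bar = "none")
  post <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = mcmc$n_iter - mcmc$n_warmup,
                              thin = mcmc$thin, progress.bar = "none")

  rhat <- rep(NA_real_, ncol(post[[1]]))
  names(rhat) <- colnames(post[[1]])
  if (mcmc$n_chains >= 2) {
    gd <- try(coda::gelman.diag(post, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- gd$psrf[, 1]
  }
  ess <- coda::effectiveSize(post)
  diagnostics <- list(rhat = rhat, ess = ess, divergences = NA_integer_,
                      max_rhat = suppressWarnings(max(rhat, na.rm = TRUE)))
  if (mcmc$n_chains >= 2 && mcmc$on_fail != "none") {
    bad <- names(rhat)[!is.na(rhat) & abs(rhat - 1) > mcmc$rhat_tol]
    if (length(bad) > 0) {
      msg <- sprintf("convergence check failed (|Rhat - 1| > %.3g) for: %s",
                     mcmc$rhat_tol, paste(utils::head(bad, 10), collapse = ", "))
      if (mcmc$on_fail == "error") {
        cond <- simpleError(msg)
        cond$diagnostics <- diagnostics
        stop(cond)
      } else warning(msg)
    }
  }

  draws <- do.call(rbind, lapply(post, as.matrix))
  chain <- rep(seq_along(post), each = nrow(post[[1]]))
  draws <- rename_draws(draws, spec, sp_levels, fam_levels, site_levels)

  fit <- list(draws = draws, chain = chain, diagnostics = diagnostics,
              spec = spec, mcmc = mcmc,
              data = list(y = dat$concentration, X = X,
                          species = dat$species, family = traits$family[tr_idx],
                          site = dat$site,
                          hab = if (!is.null(spec$varying_slope_on))
                                  jdata$hab else NULL),
              levels = list(species = sp_levels, family = fam_levels,
                            site = site_levels),
              scaling = list(centers = centers, scales = scales),
              n_obs = nrow(dat))
  class(fit) <- "nutrient_fit"
  fit
}

rename_draws <- function(draws, spec, sp_levels, fam_levels, site_levels) {
  nm <- colnames(draws)
  nm[nm == "abar"] <- "alpha_bar"
  nm[nm == "k"] <- "shape"
  nm[nm == "b6bar"] <- "beta6_bar"
  nm[nm == "sigma_fam"] <- "sigma_family"
  nm[nm == "sigma_sp"] <- "sigma_species"
  if (length(spec$covariates) == 1) {
    nm[nm == "beta"] <- paste0("beta_", spec$covariates)
  } else {
    for (p in seq_along(spec$covariates))
      nm[nm == sprintf("beta[%d]", p)] <- paste0("beta_", spec$covariates[p])
  }
  relabel <- function(nm, prefix, newpre, levels) {
    if (length(levels) == 1) {
      nm[nm == prefix] <- sprintf("%s[%s]", newpre, levels)
      return(nm)
    }
    for (j in seq_along(levels))
      nm[nm == sprintf("%s[%d]", prefix, j)] <-
        sprintf("%s[%s]", newpre, levels[j])
    nm
  }
  nm <- relabel(nm, "afam", "alpha_family", fam_levels)
  nm <- relabel(nm, "asite", "alpha_site", site_levels)
  nm <- relabel(nm, "asp", "alpha_species", sp_levels)
  nm <- relabel(nm, "b6", "beta6", sp_levels)
  colnames(draws) <- nm
  draws
}

#' @export
print.nutrient_fit <- function(x, ...) {
  cat(sprintf("Trait model fit: %s (%s, %s intercepts%s)\n", x$spec$nutrient,
              x$spec$likelihood, x$spec$intercept_structure,
              if (!is.null(x$spec$varying_slope_on)) " + HAB slope" else ""))
  cat(sprintf("  %d observations, %d species, %d draws (%d chains), max Rhat %.4f\n",
              x$n_obs, length(x$levels$species), nrow(x$draws),
              length(unique(x$chain)), x$diagnostics$max_rhat))
  betas <- grep("^beta_", colnames(x$draws), value = TRUE)
  for (b in betas)
    cat(sprintf("  %-10s median %7.3f  95%% HDI [%7.3f, %7.3f]\n", b,
                stats::median(x$draws[, b]),
                posterior_hdi(x$draws[, b])[1], posterior_hdi(x$draws[, b])[2]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pointwise log-likelihood and WAIC

# Linear predictor (link scale) for the fitted observations: draws x N.
fitted_lmu <- function(fit) {
  d <- fit$draws
  X <- fit$data$X
  betas <- d[, paste0("beta_", fit$spec$covariates), drop = FALSE]
  lmu <- betas %*% t(X)
  site_cols <- sprintf("alpha_site[%s]", fit$data$site)
  lmu <- lmu + d[, site_cols, drop = FALSE]
  # family/species intercepts are hierarchically centred (they include the
  # global mean); only the phylogenetic MVN intercept is a deviation
  if (fit$spec$intercept_structure == "family+site") {
    lmu <- lmu + d[, sprintf("alpha_family[%s]", fit$data$family), drop = FALSE]
  } else {
    lmu <- lmu + d[, sprintf("alpha_species[%s]", fit$data$species),
                   drop = FALSE]
    if (fit$spec$intercept_structure == "phylo_species+site")
      lmu <- lmu + d[, "alpha_bar"]
  }
  if (!is.null(fit$spec$varying_slope_on)) {
    b6 <- d[, sprintf("beta6[%s]", fit$data$species), drop = FALSE]
    lmu <- lmu + sweep(b6, 2, fit$data$hab, "*")
  }
  lmu
}

#' Pointwise log-likelihood matrix of a fitted model
#'
#' One row per posterior draw, one column per observation; the input to
#' WAIC. For the gamma likelihood this is the mean-shape gamma density at
#' the observed concentration; for the log-normal likelihood, the
#' log-normal density.
#'
#' @param fit a `nutrient_fit`
#' @return numeric matrix, draws x observations
#' @export
loglik_matrix <- function(fit) {
  lmu <- fitted_lmu(fit)
  y <- fit$data$y
  if (fit$spec$likelihood == "gamma") {
    k <- fit$draws[, "shape"]
    # gamma(shape k, rate k/mu): ll = k log(k/mu) + (k-1) log y - (k/mu) y - lgamma(k)
    mu <- exp(lmu)
    ll <- k * log(k) - k * lmu + outer(k - 1, log(y)) -
      sweep(sweep(1 / mu, 2, y, "*"), 1, k, "*") - lgamma(k)
  } else {
    sigma <- fit$draws[, "sigma_obs"]
    ll <- -sweep((sweep(lmu, 2, log(y)))^2, 1, 2 * sigma^2, "/") -
      log(sigma) - 0.5 * log(2 * pi)
    ll <- sweep(ll, 2, log(y))   # Jacobian: density of y, not log y
  }
  unname(ll)
}

#' Watanabe-Akaike information criterion
#'
#' WAIC = -2 (lppd - p_waic) with lppd = sum_i log mean_d exp(loglik_id)
#' and p_waic = sum_i var_d(loglik_id). Lower values indicate better
#' out-of-sample predictive accuracy without overfitting.
#'
#' @param x a pointwise log-likelihood matrix (draws x observations) or a
#'   `nutrient_fit`
#' @param ... unused
#' @return list with `waic`, `lppd`, `p_waic`, `se` (standard error of
#'   WAIC from the pointwise contributions) and `pointwise` data frame
#' @export
compute_waic <- function(x, ...) UseMethod("compute_waic")

#' @export
compute_waic.nutrient_fit <- function(x, ...) compute_waic(loglik_matrix(x))

#' @export
compute_waic.matrix <- function(x, ...) {
  if (nrow(x) < 2) stop("WAIC requires at least 2 posterior draws")
  # column-wise log-mean-exp, numerically stable
  mx <- apply(x, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(x, 2, mx))))
  p_i <- apply(x, 2, stats::var)
  elpd_i <- lppd_i - p_i
  waic_i <- -2 * elpd_i
  list(waic = sum(waic_i), lppd = sum(lppd_i), p_waic = sum(p_i),
       se = sqrt(length(waic_i) * stats::var(waic_i)),
       pointwise = data.frame(lppd = lppd_i, p_waic = p_i, waic = waic_i))
}

#' Choose the intercept structure for prediction
#'
#' Compares the family-intercept and phylogenetic-species-intercept fits by
#' WAIC. Under the default policy the simpler family-intercept structure is
#' always returned for prediction — phylogenetic intercepts tend to win
#' WAIC only for some nutrients and carry overfitting risk — with both WAIC
#' values recorded. `strict = TRUE` instead returns the WAIC winner; ties
#' favour the family structure.
#'
#' @param waic_family WAIC of the family-intercept fit (number or
#'   [compute_waic()] result)
#' @param waic_phylo WAIC of the phylogenetic fit
#' @param strict follow WAIC strictly instead of the default policy
#' @return list with `chosen` (`"family+site"` or `"phylo_species+site"`),
#'   both WAIC values, `waic_winner` and a `tie` flag
#' @export
select_intercept_structure <- function(waic_family, waic_phylo,
                                       strict = FALSE) {
  wf <- if (is.list(waic_family)) waic_family$waic else waic_family
  wp <- if (is.list(waic_phylo)) waic_phylo$waic else waic_phylo
  tie <- isTRUE(all.equal(wf, wp))
  winner <- if (!tie && wp < wf) "phylo_species+site" else "family+site"
  chosen <- if (strict) winner else "family+site"
  list(chosen = chosen, waic_family = wf, waic_phylo = wp,
       waic_winner = winner, tie = tie)
}

# ---------------------------------------------------------------------------
# Prediction

#' Posterior nutrient concentration for a species
#'
#' Draws posterior concentration samples for one or more species from a
#' fitted trait model, according to the species' life-history traits and
#' (optionally) taxonomic family; hierarchical site effects are always
#' excluded. For a macroalgal habitat context under the habitat model, the
#' species' own varying slope is used when the species was fitted,
#' otherwise the average habitat effect. Unknown families fall back to the
#' population level with a warning.
#'
#' @param fit a `nutrient_fit`
#' @param traits trait table rows for the species to predict (must include
#'   the fitted covariates, plus `species` and `family`)
#' @param include_family include the family (or species) intercept when the
#'   level was observed in fitting
#' @param habitat `"none"`, `"coral"` or `"macroalgal"`
#' @param n_draws number of posterior draws to use
#' @param seed seed for the draw subsample
#' @return data frame, one row per species: median, 50% and 95% HDIs of
#'   the posterior concentration, and the draw matrix as attribute
#'   `"draws"` (species x draw)
#' @export
predict_species <- function(fit, traits, include_family = TRUE,
                            habitat = c("none", "coral", "macroalgal"),
                            n_draws = 1000, seed = 1) {
  habitat <- match.arg(habitat)
  stopifnot(inherits(fit, "nutrient_fit"))
  d <- fit$draws
  idx <- with_seed(derive_seed(seed, 17L),
                   sample(nrow(d), n_draws, replace = n_draws > nrow(d)))
  d <- d[idx, , drop = FALSE]

  X <- sweep(sweep(as.matrix(traits[, fit$spec$covariates, drop = FALSE]), 2,
                   fit$scaling$centers), 2, fit$scaling$scales, "/")
  betas <- d[, paste0("beta_", fit$spec$covariates), drop = FALSE]
  lmu <- tcrossprod(X, betas)              # species x draws
  phylo <- fit$spec$intercept_structure == "phylo_species+site"

  for (i in seq_len(nrow(traits))) {
    # centred hierarchies: the group intercept already contains the global
    # mean, so the population level (abar) is the fallback
    intercept <- d[, "alpha_bar"]
    if (include_family) {
      if (fit$spec$intercept_structure == "family+site") {
        famcol <- sprintf("alpha_family[%s]", traits$family[i])
        if (famcol %in% colnames(d)) {
          intercept <- d[, famcol]
        } else {
          warning("family ", traits$family[i],
                  " not observed in fit; using population level")
        }
      } else {
        spcol <- sprintf("alpha_species[%s]", traits$species[i])
        if (spcol %in% colnames(d)) {
          intercept <- if (phylo) d[, "alpha_bar"] + d[, spcol] else d[, spcol]
        }
      }
    }
    lmu[i, ] <- lmu[i, ] + intercept
  }
  if (habitat == "macroalgal") {
    if (!is.null(fit$spec$varying_slope_on)) {
      for (i in seq_len(nrow(traits))) {
        b6col <- sprintf("beta6[%s]", traits$species[i])
        lmu[i, ] <- lmu[i, ] +
          if (b6col %in% colnames(d)) d[, b6col] else d[, "beta6_bar"]
      }
    } else {
      warning("fit has no habitat effect; macroalgal context ignored")
    }
  }
  conc <- exp(lmu)
  summ <- t(apply(conc, 1, summarise_draws))
  out <- data.frame(species = traits$species, nutrient = fit$spec$nutrient,
                    habitat = habitat, summ, n_draws = n_draws,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "draws") <- conc
  out
}

#' Summarise the macroalgal habitat effect of the habitat model
#'
#' Reports the posterior of the average habitat effect (link scale and its
#' multiplicative back-transform) and, per species, the deviation of the
#' species-level slope from the average, flagging species whose deviation
#' posterior excludes zero (95% HDI).
#'
#' @param fit a `nutrient_fit` with a HAB varying slope
#' @return list with `average` (summary of the link-scale effect),
#'   `multiplicative_median` and `species` (data frame of deviations)
#' @export
habitat_effect_summary <- function(fit) {
  stopifnot(inherits(fit, "nutrient_fit"))
  if (is.null(fit$spec$varying_slope_on))
    stop("fit has no habitat varying slope")
  d <- fit$draws
  avg <- summarise_draws(d[, "beta6_bar"])
  species <- fit$levels$species
  dev <- lapply(species, function(sp) {
    dd <- d[, sprintf("beta6[%s]", sp)] - d[, "beta6_bar"]
    s <- summarise_draws(dd)
    data.frame(species = sp, t(s),
               excludes_zero = s[["lower95"]] > 0 | s[["upper95"]] < 0,
               stringsAsFactors = FALSE)
  })
  species_df <- do.call(rbind, dev)
  rownames(species_df) <- NULL
  list(average = avg,
       multiplicative_median = exp(avg[["median"]]),
       species = species_df)
}
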