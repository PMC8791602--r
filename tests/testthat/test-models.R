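# Reduced-MCMC fits: unit tests run 2 chains and short iteration counts;
# full-length convergence settings are exercised in the acceptance tests.

recovery_config <- function(seed = 31) {
  nutrients <- names(nutrient_units())
  zero <- c(K = 0, TL = 0, AM = 0, PEL = 0, LMX = 0)
  synthetic_config(
    n_species = 25, n_families = 5, n_sites = 6, n_per_species = 8,
    n_dual_species = 0, loq_prob = 0,
    true_betas = list(calcium = zero, selenium = zero, omega3 = zero,
                      iron = c(K = 0.3, TL = 0, AM = 0, PEL = 0.2,
                               LMX = -0.3),
                      zinc = zero),
    true_habitat_effect = c(calcium = 0, iron = 0, selenium = 0, zinc = 0,
                            omega3 = 0),
    species_sd = 0, ou_eta2 = 0, seed = seed)
}

model1_fit <- function() cache_fixture("model1_fit", {
  cfg <- recovery_config()
  ds <- generate_nutrient_samples(generate_traits(cfg), cfg)
  tr <- generate_traits(cfg)$traits
  quiet_fit(ds$samples, tr, model_spec("iron"),
            test_mcmc(seed = 2, n_iter = 2600, n_warmup = 800))
})

test_that("trait effects are recovered and nulls stay null", {
  fit <- model1_fit()
  hdi_tl <- posterior_hdi(fit$draws[, "beta_TL"], 0.95)
  expect_lt(hdi_tl["lower"], 0)
  expect_gt(hdi_tl["upper"], 0)
  expect_lt(abs(median(fit$draws[, "beta_K"]) - 0.3), 0.15)
  expect_lt(abs(median(fit$draws[, "beta_LMX"]) - (-0.3)), 0.15)
  expect_lt(fit$diagnostics$max_rhat, 1.2)
})

test_that("predictions are deterministic, family-aware and monotone", {
  fit <- model1_fit()
  cfg <- recovery_config()
  tr <- generate_traits(cfg)$traits
  # identical traits, same family -> identical posterior summaries
  two <- tr[c(1, 1), ]
  two$species <- c("a", "b")
  p <- predict_species(fit, two, n_draws = 500)
  expect_equal(p$median[1], p$median[2])
  expect_equal(p$lower95[1], p$lower95[2])
  # unknown family falls back to population level with a warning
  ghost <- tr[1, ]; ghost$family <- "familyXX"
  expect_warning(predict_species(fit, ghost, n_draws = 200), "population")
  # monotonicity in a covariate with positive posterior-median coefficient
  lo <- tr[1, ]; hi <- tr[1, ]
  hi$K <- hi$K + sd(tr$K)
  p2 <- predict_species(fit, rbind(lo, hi), include_family = FALSE,
                        n_draws = 500)
  expect_gt(p2$median[2], p2$median[1])
  # intervals nested, median inside, concentrations positive
  expect_true(all(p2$lower95 <= p2$lower50 & p2$upper50 <= p2$upper95))
  expect_true(all(p2$median >= p2$lower50 & p2$median <= p2$upper50))
  expect_true(all(p2$lower95 > 0))
})

test_that("scaled and unscaled fits give matching in-sample predictions", {
  cfg <- recovery_config(seed = 8)
  tr <- generate_traits(cfg)$traits
  ds <- generate_nutrient_samples(generate_traits(cfg), cfg)
  m <- test_mcmc(seed = 3, n_iter = 3200, n_warmup = 1200)
  f_scaled <- quiet_fit(ds$samples, tr, model_spec("iron"), m)
  f_unscaled <- quiet_fit(ds$samples, tr,
                          model_spec("iron", scaling = "unscaled"), m)
  p_s <- predict_species(f_scaled, tr[1:5, ], n_draws = 800)
  p_u <- predict_species(f_unscaled, tr[1:5, ], n_draws = 800)
  expect_true(all(abs(p_s$median / p_u$median - 1) < 0.02))
})

habitat_fits <- function() cache_fixture("habitat_fits", {
  nutrients <- names(nutrient_units())
  zero <- c(K = 0, TL = 0, AM = 0, PEL = 0, LMX = 0)
  cfg <- synthetic_config(
    n_species = 10, n_families = 5, n_sites = 8, n_dual_species = 10,
    n_dual_per_species = 11, loq_prob = 0,
    true_betas = lapply(stats::setNames(nutrients, nutrients),
                        function(n) zero),
    true_habitat_effect = c(calcium = 0, iron = log(1.3), selenium = 0,
                            zinc = 0, omega3 = 0),
    species_sd = 0.05, ou_eta2 = 0, seed = 77)
  ds <- generate_nutrient_samples(generate_traits(cfg), cfg)
  tr <- generate_traits(cfg)$traits
  m <- test_mcmc(seed = 4, n_iter = 2600, n_warmup = 800)
  spec2 <- function(nu) model_spec(nu, intercept_structure = "species+site",
                                   varying_slope_on = "HAB")
  list(iron = quiet_fit(ds$samples, tr, spec2("iron"), m),
       selenium = quiet_fit(ds$samples, tr, spec2("selenium"), m),
       traits = tr)
})

test_that("habitat model recovers the enrichment and keeps nulls null", {
  hf <- habitat_fits()
  # null nutrient: average effect interval includes zero
  se_avg <- habitat_effect_summary(hf$selenium)$average
  expect_lt(se_avg[["lower95"]], 0)
  expect_gt(se_avg[["upper95"]], 0)
  # enriched nutrient: multiplicative effect near the generative 1.3
  fe <- habitat_effect_summary(hf$iron)
  expect_gt(fe$multiplicative_median, 1.1)
  expect_lt(fe$multiplicative_median, 1.6)
  expect_equal(nrow(fe$species), 10)
})

test_that("intraspecific differences rank enriched nutrients first", {
  hf <- habitat_fits()
  preds <- function(fit) {
    cc <- predict_species(fit, hf$traits, habitat = "coral", n_draws = 600)
    ma <- predict_species(fit, hf$traits, habitat = "macroalgal",
                          n_draws = 600)
    intraspecific_differences(cc, ma)
  }
  v_fe <- preds(hf$iron)
  v_se <- preds(hf$selenium)
  expect_gt(v_fe$median_pct, v_se$median_pct)
  # an iron effect of x1.3 implies within-species differences near 26% of
  # the pair mean ( |1.3c - c| / (1.15c) )
  expect_gt(v_fe$median_pct, 10)
})

test_that("phylogenetic intercept structure fits and is comparable by WAIC", {
  cfg <- synthetic_config(n_species = 10, n_families = 3, n_sites = 4,
                          n_per_species = 6, n_dual_species = 0,
                          loq_prob = 0, ou_eta2 = 0.1, ou_rho = 2,
                          species_sd = 0, seed = 5)
  tr <- generate_traits(cfg)
  ds <- generate_nutrient_samples(tr, cfg)
  m <- test_mcmc(seed = 6, n_iter = 1400, n_warmup = 600)
  f_fam <- quiet_fit(ds$samples, tr$traits, model_spec("zinc"), m)
  f_phy <- quiet_fit(ds$samples, tr$traits,
                     model_spec("zinc",
                                intercept_structure = "phylo_species+site"),
                     m, phylo_dist = tr$phylo_dist)
  expect_true(all(c("eta2", "rho") %in% colnames(f_phy$draws)))
  expect_true(all(f_phy$draws[, "eta2"] > 0))
  w_fam <- compute_waic(f_fam)
  w_phy <- compute_waic(f_phy)
  expect_true(is.finite(w_fam$waic) && is.finite(w_phy$waic))
  sel <- select_intercept_structure(w_fam, w_phy)
  expect_equal(sel$chosen, "family+site")
})

test_that("lognormal back-transform returns median-unbiased concentrations", {
  cfg <- recovery_config(seed = 12)
  tr <- generate_traits(cfg)$traits
  ds <- generate_nutrient_samples(generate_traits(cfg), cfg)
  fit <- quiet_fit(ds$samples, tr, model_spec("calcium"),
                   test_mcmc(seed = 9, n_iter = 1400, n_warmup = 600))
  expect_equal(fit$spec$likelihood, "lognormal")
  # average fish (traits at the scaled centre), no family: median of
  # exp(alpha_bar) over the same seeded draw subsample
  avg <- tr[1, ]
  avg[, c("K", "TL", "AM", "PEL", "LMX")] <-
    as.list(fit$scaling$centers)
  p <- predict_species(fit, avg, include_family = FALSE, n_draws = 400,
                       seed = 2)
  draws <- attr(p, "draws")
  expect_equal(p$median, median(draws[1, ]))
  expect_equal(unname(exp(median(log(draws[1, ])))), p$median,
               tolerance = 1e-4)
})

test_that("gamma model posterior means and variances respect mean-shape", {
  # moment property of the generative parameterisation used by the models
  set.seed(2)
  mu <- 2; k <- 4
  y <- rgamma(2e5, shape = k, rate = k / mu)
  expect_equal(mean(y), mu, tolerance = 0.02)
  expect_equal(var(y), mu^2 / k, tolerance = 0.05)
})

test_that("simulation-based calibration ranks are approximately uniform", {
  # reduced SBC: a small gamma trait model refit to prior-predictive draws;
  # the rank of the true coefficient among thinned posterior draws should
  # be uniform
  n <- 36
  set.seed(99)
  base <- data.frame(
    fish_id = sprintf("f%03d", 1:n),
    species = rep(sprintf("sp%02d", 1:6), each = n / 6),
    family = rep(c("famA", "famB"), each = n / 2),
    site = rep(c("s1", "s2"), times = n / 2),
    habitat = "coral", year = 2019L, nutrient = "iron",
    below_loq = FALSE, stringsAsFactors = FALSE)
  traits <- data.frame(
    species = sprintf("sp%02d", 1:6),
    family = rep(c("famA", "famB"), each = 3),
    TL = c(2.2, 2.8, 3.4, 2.5, 3.1, 3.9), stringsAsFactors = FALSE)
  pri <- default_priors("TL")
  pri[pri$parameter == "intercept", c("p1", "p2")] <- list(0.7, 0.4)
  pri[pri$parameter == "beta_TL", c("p1", "p2")] <- list(0, 0.5)
  pri[pri$parameter == "shape", c("dist", "p1", "p2")] <-
    list("gamma", 2, 0.5)
  pri[pri$parameter == "sigma_family", "p1"] <- 2
  pri[pri$parameter == "sigma_site", "p1"] <- 2
  spec <- model_spec("iron", covariates = "TL", priors = pri)
  tl_s <- scale(traits$TL)[, 1]
  n_rep <- 200
  ranks <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    beta <- rnorm(1, 0, 0.5)
    abar <- rnorm(1, 0.7, 0.4)
    afam <- rnorm(2, 0, rexp(1, 2))
    asite <- rnorm(2, 0, rexp(1, 2))
    k <- rgamma(1, 2, 0.5)
    i_sp <- match(base$species, traits$species)
    lmu <- abar + beta * tl_s[i_sp] +
      afam[match(base$family, c("famA", "famB"))] +
      asite[match(base$site, c("s1", "s2"))]
    base$concentration <- rgamma(n, shape = k, rate = k / exp(lmu))
    fit <- quiet_fit(base, traits, spec,
                     mcmc_config(n_chains = 1, n_iter = 1100,
                                 n_warmup = 400, thin = 7,
                                 seed = 2000 + r, on_fail = "none"))
    ranks[r] <- sum(fit$draws[, "beta_TL"] < beta)
  }
  L <- 100
  bins <- table(cut(ranks, breaks = seq(-0.5, L + 0.5, length.out = 11)))
  p <- chisq.test(as.vector(bins))$p.value
  expect_gt(p, 0.01)
})
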