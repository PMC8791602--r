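#' Configuration for the synthetic reef-fishery data generator
#'
#' Bundles every ground-truth parameter of the generative model that the
#' analysis assumes: a trait-based hierarchical model for fish tissue
#' micronutrient concentrations (gamma-distributed, log link; log-normal for
#' calcium), divergent benthic trajectories after a mass-bleaching
#' disturbance, and replicate underwater-visual-census (UVC) point counts.
#'
#' Defaults emulate a western Indian Ocean reef-fishery system: 44 target
#' species in 11
#' families, 12 survey sites, 6 survey years (one pre-disturbance), 8
#' replicate 154 m^2 point counts per site-year, ~40% of sites on a
#' macroalgal regime-shift trajectory after 1998, ten species sampled in
#' both habitat regimes (~110 tissue samples for the habitat model), and a
#' macroalgal habitat effect concentrated on iron and zinc.
#'
#' @param n_species number of fish species
#' @param n_families number of taxonomic families (<= n_species)
#' @param n_sites number of reef sites
#' @param years survey years; must include at least one year before
#'   `disturbance_year`
#' @param disturbance_year year of the mass-bleaching disturbance
#' @param n_pointcounts replicate point counts per site-year
#' @param n_per_species tissue samples per single-habitat species
#' @param n_dual_species number of species sampled in both habitat regimes
#' @param n_dual_per_species tissue samples per dual-habitat species
#' @param sampling_year nominal year of tissue sampling
#' @param trait_means_sds list of per-trait location/scale parameters
#' @param lmx_pel_r target Pearson correlation between maximum length and
#'   the binary pelagic-pathway indicator
#' @param pel_prob marginal probability of a pelagic feeding pathway
#' @param intercepts named per-nutrient intercept on the log scale
#'   (log mean concentration for an average fish in coral habitat)
#' @param true_betas named list: per nutrient, coefficients for the five
#'   scaled traits (K, TL, AM, PEL, LMX) on the log-link scale
#' @param true_habitat_effect named per-nutrient additive log-scale effect
#'   of macroalgal habitat (beta6 ground truth)
#' @param gamma_shape named per-nutrient gamma shape k (mean-shape
#'   parameterisation: Var = mu^2 / k)
#' @param family_sd,site_sd,species_sd standard deviations of the
#'   log-scale random intercepts
#' @param ou_eta2,ou_rho Ornstein-Uhlenbeck kernel parameters for the
#'   phylogenetic component of species intercepts
#' @param regime_split fraction of sites assigned the macroalgal
#'   regime-shift trajectory
#' @param loq_prob probability a tissue measurement falls below the limit
#'   of quantification
#' @param mean_count mean number of fish per point count pre-disturbance
#' @param post_growth_max multiplier on fish abundance reached in the final
#'   survey year (long-term post-bleaching biomass increase)
#' @param seed master RNG seed; all submodule seeds are derived from it
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(n_species = 44,
                             n_families = 11,
                             n_sites = 12,
                             years = c(1994, 2005, 2008, 2011, 2014, 2017),
                             disturbance_year = 1998,
                             n_pointcounts = 8,
                             n_per_species = 4,
                             n_dual_species = 10,
                             n_dual_per_species = 11,
                             sampling_year = 2019,
                             trait_means_sds = list(
                               K = c(meanlog = log(0.35), sdlog = 0.45),
                               TL = c(mean = 3.0, sd = 0.55),
                               AM = c(meanlog = log(2.5), sdlog = 0.45),
                               LMX = c(meanlog = log(45), sdlog = 0.5)
                             ),
                             lmx_pel_r = 0.65,
                             pel_prob = 0.3,
                             intercepts = c(calcium = log(30), iron = log(0.67),
                                            selenium = log(50), zinc = log(1.15),
                                            omega3 = log(0.3)),
                             true_betas = list(
                               calcium = c(K = 0.1, TL = 0, AM = 0, PEL = 0, LMX = -0.1),
                               iron = c(K = 0, TL = -0.1, AM = 0, PEL = 0.1, LMX = 0),
                               selenium = c(K = 0, TL = 0.3, AM = 0, PEL = 0, LMX = -0.05),
                               zinc = c(K = 0.2, TL = -0.15, AM = 0, PEL = 0, LMX = 0),
                               omega3 = c(K = 0, TL = 0.3, AM = 0, PEL = 0.1, LMX = 0)
                             ),
                             true_habitat_effect = c(calcium = 0, iron = log(1.5),
                                                     selenium = 0, zinc = log(1.2),
                                                     omega3 = 0),
                             gamma_shape = c(calcium = 10, iron = 10, selenium = 10,
                                             zinc = 10, omega3 = 10),
                             family_sd = 0.2,
                             site_sd = 0.1,
                             species_sd = 0.1,
                             ou_eta2 = 0.04,
                             ou_rho = 3,
                             regime_split = 0.4,
                             loq_prob = 0.02,
                             mean_count = 70,
                             post_growth_max = 3.2,
                             seed = 1) {
  cfg <- list(n_species = as.integer(n_species),
              n_families = as.integer(n_families),
              n_sites = as.integer(n_sites),
              years = as.integer(sort(years)),
              disturbance_year = as.integer(disturbance_year),
              n_pointcounts = as.integer(n_pointcounts),
              n_per_species = as.integer(n_per_species),
              n_dual_species = min(as.integer(n_dual_species),
                                   as.integer(n_species)),
              n_dual_per_species = as.integer(n_dual_per_species),
              sampling_year = as.integer(sampling_year),
              trait_means_sds = trait_means_sds,
              lmx_pel_r = lmx_pel_r, pel_prob = pel_prob,
              intercepts = intercepts, true_betas = true_betas,
              true_habitat_effect = true_habitat_effect,
              gamma_shape = gamma_shape,
              family_sd = family_sd, site_sd = site_sd, species_sd = species_sd,
              ou_eta2 = ou_eta2, ou_rho = ou_rho,
              regime_split = regime_split, loq_prob = loq_prob,
              mean_count = mean_count, post_growth_max = post_growth_max,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  counts <- c(cfg$n_species, cfg$n_families, cfg$n_sites, cfg$n_pointcounts,
              cfg$n_per_species)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (cfg$n_dual_species < 0 || cfg$n_dual_species > cfg$n_species)
    stop("n_dual_species must be in [0, n_species]")
  if (any(cfg$gamma_shape <= 0)) stop("gamma_shape must be > 0")
  if (cfg$regime_split < 0 || cfg$regime_split > 1)
    stop("regime_split must be in [0, 1]")
  scales <- c(vapply(cfg$trait_means_sds, function(p) p[[2]], numeric(1)),
              cfg$family_sd, cfg$site_sd, cfg$species_sd)
  if (any(scales < 0) || any(vapply(cfg$trait_means_sds,
                                    function(p) p[[2]], numeric(1)) <= 0))
    stop("trait scales must be > 0 and random-effect sds >= 0")
  if (cfg$ou_eta2 < 0 || cfg$ou_rho <= 0) stop("ou_eta2 >= 0 and ou_rho > 0 required")
  stopifnot(length(cfg$years) >= 1)
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic reef-fishery data configuration\n")
  cat(sprintf("  %d species in %d families; %d sites x %d years; %d point counts\n",
              x$n_species, x$n_families, x$n_sites, length(x$years),
              x$n_pointcounts))
  cat(sprintf("  regime split: %.0f%% of sites macroalgal after %d; seed %d\n",
              100 * x$regime_split, x$disturbance_year, x$seed))
  invisible(x)
}

# Deterministic regime trajectory assignment shared by the sample and
# survey generators: round(regime_split * n_sites) sites, chosen by a
# seeded shuffle, follow the macroalgal trajectory.
site_regimes <- function(config) {
  n_shift <- round(config$regime_split * config$n_sites)
  sites <- sprintf("site%02d", seq_len(config$n_sites))
  shuffled <- with_seed(derive_seed(config$seed, 7L), sample(sites))
  regime <- ifelse(sites %in% shuffled[seq_len(n_shift)],
                   "macroalgal", "recovering_coral")
  stats::setNames(regime, sites)
}

#' Generate species life-history traits and a phylogenetic distance matrix
#'
#' Traits follow FishBase-like marginals: log-normal growth coefficient K,
#' age at maturity and maximum length; normal trophic level clipped to
#' [2, 4.5]; Bernoulli pelagic-pathway indicator. Maximum length and the
#' pelagic indicator are moderately correlated (target Pearson r =
#' `lmx_pel_r`), induced by thresholding a latent bivariate normal.
#' Phylogenetic distances come from a random coalescent tree over families
#' with species nested inside, normalised to a maximum of 1.
#'
#' @param config a `synthetic_config`
#' @return list with `traits` (data frame, one row per species) and
#'   `phylo_dist` (symmetric distance matrix, zero diagonal, max 1)
#' @export
generate_traits <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_species < config$n_families)
    stop("n_species must be >= n_families")
  ns <- config$n_species
  nf <- config$n_families
  tp <- config$trait_means_sds

  with_seed(derive_seed(config$seed, 101L), {
    # family sizes: every family gets at least one species
    extra <- if (ns > nf) as.vector(stats::rmultinom(1, ns - nf, rep(1, nf))) else rep(0, nf)
    fam_sizes <- extra + 1L
    family <- rep(sprintf("family%02d", seq_len(nf)), fam_sizes)
    species <- sprintf("species%03d", seq_len(ns))

    K <- stats::rlnorm(ns, tp$K[["meanlog"]], tp$K[["sdlog"]])
    TL <- pmin(4.5, pmax(2, stats::rnorm(ns, tp$TL[["mean"]], tp$TL[["sd"]])))
    AM <- stats::rlnorm(ns, tp$AM[["meanlog"]], tp$AM[["sdlog"]])

    # latent bivariate normal; LMX from z1, PEL by thresholding z2.
    # The latent correlation is back-solved so the observed point-biserial
    # correlation between LMX and PEL hits the target.
    s <- tp$LMX[["sdlog"]]
    p <- config$pel_prob
    f_lmx <- s / sqrt(exp(s^2) - 1)
    f_pel <- stats::dnorm(stats::qnorm(1 - p)) / sqrt(p * (1 - p))
    rho_lat <- min(0.98, max(0, config$lmx_pel_r / (f_lmx * f_pel)))
    z1 <- stats::rnorm(ns)
    z2 <- rho_lat * z1 + sqrt(1 - rho_lat^2) * stats::rnorm(ns)
    LMX <- exp(tp$LMX[["meanlog"]] + s * z1)
    PEL <- as.integer(z2 > stats::qnorm(1 - p))

    feeding_group <- vapply(seq_len(ns), function(i) {
      if (TL[i] < 2.5) sample(c("browser", "scraper", "grazer"), 1)
      else if (TL[i] < 3.0) sample(c("invertivore", "corallivore"), 1, prob = c(0.85, 0.15))
      else if (TL[i] < 3.6) {
        if (PEL[i] == 1 && stats::runif(1) < 0.5) "planktivore"
        else "mixed invertivore-piscivore"
      } else "piscivore"
    }, character(1))

    # joint gear coverage leaves a non-target residual while keeping the
    # target assemblage at a majority of fishable biomass
    trap <- TL < 3.4 & stats::runif(ns) < 0.75
    handline <- TL >= 3.0 & stats::runif(ns) < 0.75
    target_gears <- ifelse(trap & handline, "trap,handline",
                           ifelse(trap, "trap", ifelse(handline, "handline", "")))

    traits <- data.frame(species = species, family = family,
                         K = K, TL = TL, AM = AM, PEL = PEL, LMX = LMX,
                         feeding_group = feeding_group,
                         target_gears = target_gears,
                         stringsAsFactors = FALSE)

    # Phylogeny: coalescent tree over families, species nested at shallow
    # within-family depths (ultrametric two-level construction).
    if (nf >= 2) {
      fam_tree <- ape::rcoal(nf, tip.label = sprintf("family%02d", seq_len(nf)))
      Dfam <- ape::cophenetic.phylo(fam_tree)
      min_cross <- min(Dfam[upper.tri(Dfam)])
    } else {
      Dfam <- matrix(0, 1, 1, dimnames = list("family01", "family01"))
      min_cross <- 1
    }
    h_fam <- stats::runif(nf, 0.15, 0.45) * min_cross / 2
    names(h_fam) <- sprintf("family%02d", seq_len(nf))
    d <- matrix(0, ns, ns, dimnames = list(species, species))
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (i == j) next
      d[i, j] <- if (family[i] == family[j]) 2 * h_fam[family[i]]
                 else Dfam[family[i], family[j]]
    }
    d <- d / max(d)

    list(traits = traits, phylo_dist = d)
  })
}

# Centre and scale the five trait covariates across species; returns the
# design matrix plus the centres/scales used (needed to reproduce the
# generative linear predictor during recovery tests).
scale_trait_matrix <- function(traits) {
  X <- as.matrix(traits[, c("K", "TL", "AM", "PEL", "LMX")])
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  scales[scales == 0 | !is.finite(scales)] <- 1
  Xs <- sweep(sweep(X, 2, centers), 2, scales, "/")
  rownames(Xs) <- traits$species
  list(X = Xs, centers = centers, scales = scales)
}

#' Generate fish tissue micronutrient samples from the trait model
#'
#' Draws one concentration per fish per nutrient from the generative form of
#' the hierarchical trait model: log mean = intercept + scaled traits x
#' true betas + family + site + species (phylogenetic OU + independent)
#' random effects + macroalgal habitat effect; gamma observation noise in
#' the mean-shape parameterisation (log-normal for calcium, matched
#' coefficient of variation). Species sampled in both habitat regimes
#' (`n_dual_species` of them) supply the data for the habitat
#' varying-slopes model.
#'
#' @param traits result of [generate_traits()]
#' @param config the `synthetic_config` used to generate `traits`
#' @return list with `samples` (long data frame, one row per fish x
#'   nutrient) and `truth` (realized parameters and random effects)
#' @export
generate_nutrient_samples <- function(traits, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(config$gamma_shape <= 0)) stop("gamma_shape must be > 0")
  tr <- traits$traits
  d <- traits$phylo_dist
  ns <- nrow(tr)
  nutrients <- names(config$intercepts)
  regimes <- site_regimes(config)
  sites <- names(regimes)
  coral_sites <- sites[regimes == "recovering_coral"]
  ma_sites <- sites[regimes == "macroalgal"]
  if (length(coral_sites) == 0) coral_sites <- sites
  sc <- scale_trait_matrix(tr)

  with_seed(derive_seed(config$seed, 211L), {
    n_dual <- min(config$n_dual_species, ns)
    if (length(ma_sites) == 0 && n_dual > 0) {
      warning("no macroalgal sites under this regime_split; ",
              "dual-habitat sampling disabled")
      n_dual <- 0L
    }
    dual_species <- if (n_dual > 0) sort(sample(tr$species, n_dual)) else character(0)

    # per-nutrient random effects
    fams <- unique(tr$family)
    eff <- list()
    for (nu in nutrients) {
      a_fam <- stats::setNames(stats::rnorm(length(fams), 0, config$family_sd), fams)
      a_site <- stats::setNames(stats::rnorm(length(sites), 0, config$site_sd), sites)
      a_phy <- rep(0, ns)
      if (config$ou_eta2 > 0 && ns > 1) {
        S <- config$ou_eta2 * exp(-config$ou_rho * d) + diag(1e-8, ns)
        a_phy <- as.vector(t(chol(S)) %*% stats::rnorm(ns))
      }
      a_sp <- a_phy + stats::rnorm(ns, 0, config$species_sd)
      names(a_sp) <- tr$species
      eff[[nu]] <- list(family = a_fam, site = a_site, species = a_sp)
    }

    # sampling design: fish x (site, habitat)
    rows <- list()
    fish_counter <- 0L
    for (i in seq_len(ns)) {
      sp <- tr$species[i]
      if (sp %in% dual_species) {
        n_c <- ceiling(config$n_dual_per_species / 2)
        n_m <- config$n_dual_per_species - n_c
        plan <- data.frame(
          habitat = c(rep("coral", n_c), rep("macroalgal", n_m)),
          site = c(sample(coral_sites, n_c, replace = TRUE),
                   sample(ma_sites, n_m, replace = TRUE)),
          stringsAsFactors = FALSE)
      } else {
        plan <- data.frame(
          habitat = rep("coral", config$n_per_species),
          site = sample(coral_sites, config$n_per_species, replace = TRUE),
          stringsAsFactors = FALSE)
      }
      plan$species <- sp
      plan$fish_id <- sprintf("fish%04d", fish_counter + seq_len(nrow(plan)))
      fish_counter <- fish_counter + nrow(plan)
      rows[[i]] <- plan
    }
    design <- do.call(rbind, rows)

    out <- list()
    for (nu in nutrients) {
      b <- config$true_betas[[nu]]
      hab_eff <- config$true_habitat_effect[[nu]]
      k <- config$gamma_shape[[nu]]
      idx <- match(design$species, tr$species)
      lmu <- config$intercepts[[nu]] +
        as.vector(sc$X[idx, , drop = FALSE] %*% b[colnames(sc$X)]) +
        eff[[nu]]$family[tr$family[idx]] +
        eff[[nu]]$site[design$site] +
        eff[[nu]]$species[design$species] +
        hab_eff * (design$habitat == "macroalgal")
      mu <- exp(lmu)
      y <- if (nu == "calcium") {
        sdlog <- sqrt(log(1 + 1 / k))
        stats::rlnorm(nrow(design), log(mu) - sdlog^2 / 2, sdlog)
      } else {
        stats::rgamma(nrow(design), shape = k, rate = k / mu)
      }
      out[[nu]] <- data.frame(
        fish_id = design$fish_id, species = design$species,
        family = tr$family[idx], site = design$site,
        habitat = design$habitat, year = config$sampling_year,
        nutrient = nu, concentration = y,
        below_loq = stats::runif(nrow(design)) < config$loq_prob,
        stringsAsFactors = FALSE)
    }
    samples <- do.call(rbind, out)
    rownames(samples) <- NULL

    truth <- list(intercepts = config$intercepts,
                  true_betas = config$true_betas,
                  true_habitat_effect = config$true_habitat_effect,
                  gamma_shape = config$gamma_shape,
                  effects = eff,
                  trait_centers = sc$centers, trait_scales = sc$scales,
                  site_regimes = regimes,
                  dual_species = dual_species,
                  seed = config$seed)
    list(samples = samples, truth = truth)
  })
}

#' Generate UVC fish surveys, benthic trajectories and gear target lists
#'
#' Emulates the long-term reef monitoring design: `n_pointcounts` replicate
#' 154 m^2 point counts per site-year recording species, total length
#' (>= 8 cm) and abundance; benthic cover trajectories that start
#' coral-dominated everywhere and, after the disturbance year, diverge into
#' coral-recovery versus macroalgal regimes (macroalgal cover reaching the
#' 33-75% band on shifted reefs); and trap/handline target-species lists
#' drawn from the trait table. Fish abundance composition follows a
#' Dirichlet-multinomial with a post-disturbance boost to herbivore share,
#' and total abundance grows post-disturbance up to `post_growth_max`.
#'
#' @param traits result of [generate_traits()]
#' @param config the `synthetic_config`
#' @return list with `uvc`, `benthic`, `gear_lists` and `truth`
#'   (site regime assignments and abundance growth multipliers)
#' @export
generate_surveys <- function(traits, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!any(config$years < config$disturbance_year))
    stop("years must include at least one pre-disturbance year")
  tr <- traits$traits
  ns <- nrow(tr)
  regimes <- site_regimes(config)
  sites <- names(regimes)
  years <- config$years
  post_years <- years[years > config$disturbance_year]

  with_seed(derive_seed(config$seed, 307L), {
    # --- benthic trajectories -------------------------------------------
    progress <- function(y) {
      if (length(post_years) <= 1) return(1)
      (y - min(post_years)) / (max(post_years) - min(post_years))
    }
    benthic <- do.call(rbind, lapply(sites, function(s) {
      do.call(rbind, lapply(years, function(y) {
        if (y < config$disturbance_year) {
          coral <- min(30, max(8, stats::rnorm(1, 18, 4)))
          ma <- stats::runif(1, 0, 3)
          cx <- stats::rnorm(1, 3.2, 0.25)
        } else if (regimes[s] == "recovering_coral") {
          coral <- min(35, max(5, stats::rnorm(1, 11 + 8 * progress(y), 3)))
          ma <- stats::runif(1, 0, 6)
          cx <- stats::rnorm(1, 3.0, 0.25)
        } else {
          coral <- min(10, max(0.2, stats::rnorm(1, 4, 2)))
          ma <- min(75, max(20, stats::rnorm(1, 28 + 24 * progress(y), 4)))
          cx <- stats::rnorm(1, 2.1, 0.2)
        }
        data.frame(site = s, year = y, hard_coral = coral, macroalgae = ma,
                   complexity = max(0.5, cx), stringsAsFactors = FALSE)
      }))
    }))
    rownames(benthic) <- NULL

    # --- UVC point counts -----------------------------------------------
    herb <- tr$TL < 2.5
    base_w <- stats::rlnorm(ns, 0, 0.8)
    growth <- function(y) {
      if (y < config$disturbance_year || length(post_years) == 0) return(1)
      1.2 + (config$post_growth_max - 1.2) * progress(y)
    }
    uvc_rows <- list()
    for (s in sites) for (y in years) {
      boost <- if (y < config$disturbance_year) 1
               else if (regimes[s] == "macroalgal") 2.5 else 1.6
      w_sy <- base_w * ifelse(herb, boost, 1)
      for (pc in seq_len(config$n_pointcounts)) {
        n_fish <- max(5L, stats::rnbinom(1, size = 10,
                                         mu = config$mean_count * growth(y)))
        # Dirichlet-multinomial species composition
        g <- stats::rgamma(ns, shape = w_sy * 2, rate = 1)
        probs <- g / sum(g)
        counts <- as.vector(stats::rmultinom(1, n_fish, probs))
        present <- which(counts > 0)
        for (i in present) {
          lmax_eff <- max(9, 0.7 * tr$LMX[i])
          lens <- pmax(8, round(8 + (lmax_eff - 8) *
                                  stats::rbeta(counts[i], 2, 3.5)))
          tab <- table(lens)
          uvc_rows[[length(uvc_rows) + 1L]] <- data.frame(
            site = s, year = y, point_count = pc,
            species = tr$species[i],
            length = as.numeric(names(tab)),
            abundance = as.integer(tab), stringsAsFactors = FALSE)
        }
      }
    }
    uvc <- do.call(rbind, uvc_rows)
    rownames(uvc) <- NULL

    gear_lists <- list(
      trap = tr$species[grepl("trap", tr$target_gears)],
      handline = tr$species[grepl("handline", tr$target_gears)])

    truth <- list(site_regimes = regimes,
                  growth = stats::setNames(vapply(years, growth, numeric(1)),
                                           years),
                  herbivore_species = tr$species[herb])
    list(uvc = uvc, benthic = benthic, gear_lists = gear_lists, truth = truth)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_traits()],
#' [generate_nutrient_samples()] and [generate_surveys()] under one config.
#'
#' @param config a `synthetic_config`
#' @return list with `traits`, `phylo_dist`, `samples`, `uvc`, `benthic`,
#'   `gear_lists` and `truth`
#' @export
generate_dataset <- function(config) {
  tr <- generate_traits(config)
  ns <- generate_nutrient_samples(tr, config)
  sv <- generate_surveys(tr, config)
  list(traits = tr$traits, phylo_dist = tr$phylo_dist,
       samples = ns$samples, uvc = sv$uvc, benthic = sv$benthic,
       gear_lists = sv$gear_lists,
       truth = c(ns$truth, sv$truth[c("growth", "herbivore_species")]))
}

#' Write a synthetic dataset to delimited text files
#'
#' Writes each table as CSV, the configuration as YAML and the ground truth
#' as a JSON sidecar, so a generated study can be re-read through the
#' package's input loaders.
#'
#' @param dataset result of [generate_dataset()]
#' @param config the `synthetic_config` used
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_synthetic_inputs <- function(dataset, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(traits = file.path(dir, "traits.csv"),
             phylo = file.path(dir, "phylo_dist.csv"),
             samples = file.path(dir, "nutrient_samples.csv"),
             uvc = file.path(dir, "uvc.csv"),
             benthic = file.path(dir, "benthic.csv"),
             gears = file.path(dir, "gear_lists.csv"),
             config = file.path(dir, "config.yaml"),
             truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(dataset$traits, paths["traits"], row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$phylo_dist), paths["phylo"],
                   row.names = TRUE)
  utils::write.csv(dataset$samples, paths["samples"], row.names = FALSE)
  utils::write.csv(dataset$uvc, paths["uvc"], row.names = FALSE)
  utils::write.csv(dataset$benthic, paths["benthic"], row.names = FALSE)
  gears <- do.call(rbind, lapply(names(dataset$gear_lists), function(g) {
    data.frame(gear = g, species = dataset$gear_lists[[g]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(gears, paths["gears"], row.names = FALSE)
  cfg <- unclass(config)
  cfg$true_betas <- lapply(cfg$true_betas, as.list)
  yaml::write_yaml(cfg, paths["config"])
  jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(paths)
}
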