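#' Assign habitat regimes to site-years along the benthic gradient
#'
#' Pre-disturbance site-years are labelled `pre_bleaching`. Post-disturbance
#' site-years are split by empirical quantiles of PC1 pooled across
#' post-disturbance years: the top 20% are `macroalgal`, the bottom 20%
#' `recovering_coral`, and the middle 60% `intermediate` (never enriched —
#' no intraspecific effect is inferred on reefs with low coral or
#' macroalgal cover).
#'
#' @param gradient a [benthic_pca()] result
#' @param disturbance_year year of the disturbance; surveys before it are
#'   pre-bleaching
#' @param quantiles lower/upper quantile cut fractions (default 0.2/0.8)
#' @return data frame (`site`, `year`, `pc1`, `quantile_rank`, `regime`)
#' @export
assign_regimes <- function(gradient, disturbance_year = 1998,
                           quantiles = c(0.2, 0.8)) {
  sc <- gradient$scores
  pre <- sc$year < disturbance_year
  post <- sc[!pre, , drop = FALSE]
  if (nrow(post) < 5) stop("fewer than 5 post-disturbance site-years")
  if (stats::sd(post$pc1) == 0) stop("degenerate gradient: all PC1 equal")
  qs <- stats::quantile(post$pc1, quantiles, type = 7)
  regime <- ifelse(post$pc1 > qs[2], "macroalgal",
                   ifelse(post$pc1 < qs[1], "recovering_coral",
                          "intermediate"))
  rank_post <- stats::ecdf(post$pc1)(post$pc1)
  out <- rbind(
    if (any(pre)) data.frame(site = sc$site[pre], year = sc$year[pre],
                             pc1 = sc$pc1[pre], quantile_rank = NA_real_,
                             regime = "pre_bleaching",
                             stringsAsFactors = FALSE),
    data.frame(site = post$site, year = post$year, pc1 = post$pc1,
               quantile_rank = rank_post, regime = regime,
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Enrich species posterior draws with the macroalgal habitat effect
#'
#' Applies the posterior of the average macroalgal habitat effect (beta6 of
#' the habitat model) to species concentration draws, per draw on the link
#' scale (multiplicative on the response scale), so that the uncertainty in
#' the effect size propagates. The average effect is treated as
#' representative of all targeted species. A response-scale additive mode
#' is available for sensitivity analysis. Nutrients without a beta6 draw
#' vector pass through unchanged with a warning; with beta6 identically
#' zero the draws are returned bit-identical.
#'
#' @param draws_by_nutrient named list of species x draw matrices
#' @param beta6_draws named list/vector set: per nutrient, posterior draws
#'   of the link-scale habitat effect
#' @param regime enrichment applies only when `"macroalgal"`
#' @param mode `"link"` (default, multiplicative) or `"response"`
#'   (additive on the concentration scale)
#' @return list of enriched draw matrices, same shape as the input
#' @export
apply_enrichment <- function(draws_by_nutrient, beta6_draws,
                             regime = "macroalgal",
                             mode = c("link", "response")) {
  mode <- match.arg(mode)
  if (!identical(regime, "macroalgal")) return(draws_by_nutrient)
  out <- draws_by_nutrient
  for (nu in names(draws_by_nutrient)) {
    b6 <- beta6_draws[[nu]]
    if (is.null(b6)) {
      warning("no habitat-effect draws for ", nu, "; passed through unchanged")
      next
    }
    cd <- draws_by_nutrient[[nu]]
    b6 <- rep_len(b6, ncol(cd))
    out[[nu]] <- if (mode == "link") sweep(cd, 2, exp(b6), "*")
                 else sweep(cd, 2, b6, "+")
  }
  out
}

# Profile where macroalgal-regime site-years use enriched species draws and
# all other site-years the unenriched draws.
profile_with_enrichment <- function(biomass, draws_by_nutrient, regimes,
                                    beta6_draws = NULL,
                                    target_species = NULL) {
  if (is.null(beta6_draws))
    return(weighted_assemblage_concentration(biomass, draws_by_nutrient,
                                             target_species))
  key_r <- paste(regimes$site, regimes$year)
  key_b <- paste(biomass$site, biomass$year)
  is_ma <- key_b %in% key_r[regimes$regime == "macroalgal"]
  enriched <- apply_enrichment(draws_by_nutrient, beta6_draws)
  parts <- list()
  if (any(!is_ma))
    parts$plain <- weighted_assemblage_concentration(
      biomass[!is_ma, , drop = FALSE], draws_by_nutrient, target_species)
  if (any(is_ma))
    parts$ma <- weighted_assemblage_concentration(
      biomass[is_ma, , drop = FALSE], enriched, target_species)
  res <- do.call(rbind, lapply(unname(parts), as.data.frame))
  attr(res, "draws") <- c(attr(parts$plain, "draws"), attr(parts$ma, "draws"))
  class(res) <- c("reef_profile", class(res))
  res
}

#' Regime contrasts of assemblage nutrient concentration
#'
#' For macroalgal-regime reefs, the percent change of the biomass-weighted
#' assemblage concentration relative to the across-reef pre-bleaching mean,
#' reported separately for species composition only (`interspecific`) and
#' for composition plus tissue enrichment (`intraspecific`), with medians
#' across reefs per nutrient.
#'
#' @param profile_plain `reef_profile` without enrichment
#' @param profile_enriched `reef_profile` with macroalgal enrichment
#'   applied (e.g. from [profile_with_enrichment()])
#' @param regimes output of [assign_regimes()]
#' @return list with `per_reef` (one row per macroalgal reef x nutrient)
#'   and `summary` (per-nutrient median percent changes and the baseline)
#' @export
regime_contrast <- function(profile_plain, profile_enriched, regimes) {
  pre_keys <- with(regimes[regimes$regime == "pre_bleaching", ],
                   paste(site, year))
  if (length(pre_keys) == 0) stop("no pre-bleaching surveys")
  ma_keys <- with(regimes[regimes$regime == "macroalgal", ],
                  paste(site, year))
  key <- function(p) paste(p$site, p$year)
  out <- list()
  for (nu in unique(profile_plain$nutrient)) {
    pp <- profile_plain[profile_plain$nutrient == nu, ]
    pe <- profile_enriched[profile_enriched$nutrient == nu, ]
    base <- mean(pp$median[key(pp) %in% pre_keys])
    ma_p <- pp[key(pp) %in% ma_keys, ]
    ma_e <- pe[match(key(ma_p), key(pe)), ]
    if (nrow(ma_p) == 0) next
    out[[nu]] <- data.frame(
      nutrient = nu, site = ma_p$site, year = ma_p$year, baseline = base,
      interspecific_pct = 100 * (ma_p$median - base) / base,
      intraspecific_pct = 100 * (ma_e$median - base) / base,
      stringsAsFactors = FALSE)
  }
  per_reef <- do.call(rbind, out)
  rownames(per_reef) <- NULL
  summary <- do.call(rbind, lapply(split(per_reef, per_reef$nutrient),
    function(x) data.frame(
      nutrient = x$nutrient[1], baseline = x$baseline[1],
      interspecific_median_pct = stats::median(x$interspecific_pct),
      intraspecific_median_pct = stats::median(x$intraspecific_pct),
      n_reefs = nrow(x), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(per_reef = per_reef, summary = summary)
}

#' Gear micronutrient selectivity
#'
#' Biomass-weighted micronutrient concentration restricted to each fishing
#' gear's target species, per site-year (enriched on macroalgal-regime
#' site-years when habitat-effect draws are supplied), summarised by
#' regime-year stratum as mean +/- 2 SEM across reef sites.
#'
#' @param biomass output of [biomass_density()]
#' @param draws_by_nutrient named list of species x draw matrices
#' @param gear_lists named list of target-species vectors (e.g. `trap`,
#'   `handline`)
#' @param regimes output of [assign_regimes()]
#' @param beta6_draws optional per-nutrient habitat-effect draws for
#'   enrichment on macroalgal site-years
#' @return list with `per_site` (gear x site-year x nutrient medians with
#'   regime) and `strata` (gear x regime x year x nutrient: mean, sem,
#'   n_sites)
#' @export
gear_selectivity <- function(biomass, draws_by_nutrient, gear_lists,
                             regimes, beta6_draws = NULL) {
  per_site <- list()
  for (g in names(gear_lists)) {
    targets <- gear_lists[[g]]
    if (length(targets) == 0) stop("empty target list for gear ", g)
    prof <- profile_with_enrichment(biomass, draws_by_nutrient, regimes,
                                    beta6_draws, target_species = targets)
    prof$gear <- g
    prof$regime <- regimes$regime[match(paste(prof$site, prof$year),
                                        paste(regimes$site, regimes$year))]
    per_site[[g]] <- as.data.frame(
      prof[, c("gear", "site", "year", "regime", "nutrient", "median")])
  }
  per_site <- do.call(rbind, per_site)
  rownames(per_site) <- NULL
  strata <- do.call(rbind, lapply(
    split(per_site, list(per_site$gear, per_site$regime, per_site$year,
                         per_site$nutrient), drop = TRUE),
    function(x) data.frame(
      gear = x$gear[1], regime = x$regime[1], year = x$year[1],
      nutrient = x$nutrient[1], mean = mean(x$median),
      sem = stats::sd(x$median) / sqrt(nrow(x)), n_sites = nrow(x),
      stringsAsFactors = FALSE)))
  rownames(strata) <- NULL
  strata$lower_2sem <- strata$mean - 2 * strata$sem
  strata$upper_2sem <- strata$mean + 2 * strata$sem
  list(per_site = per_site, strata = strata)
}

#' Total micronutrient availability and its long-term trend
#'
#' Availability per site-year and nutrient is the total fishable nutrient
#' quantity per hectare: sum over target species of biomass (kg ha^-1)
#' times concentration (per 100 g), with 1 kg = 10 portions of 100 g
#' (concentrations in mg 100 g^-1 give mg ha^-1). The trend compares
#' each post-disturbance year's mean availability within a regime group
#' (sites grouped by their final-year regime assignment) with the
#' pre-bleaching mean, as a percent change.
#'
#' @param biomass output of [biomass_density()]
#' @param draws_by_nutrient named list of species x draw matrices
#' @param regimes output of [assign_regimes()]
#' @param beta6_draws optional per-nutrient enrichment draws
#' @param target_species target assemblage (default: all species with
#'   draws)
#' @return list with `profile` (the `reef_profile`, availability columns
#'   included) and `trend` (per regime-group x year x nutrient mean
#'   availability and percent change vs the pre-bleaching mean)
#' @export
availability <- function(biomass, draws_by_nutrient, regimes,
                         beta6_draws = NULL, target_species = NULL) {
  prof <- profile_with_enrichment(biomass, draws_by_nutrient, regimes,
                                  beta6_draws, target_species)
  last_year <- max(regimes$year)
  site_group <- with(regimes[regimes$year == last_year, ],
                     stats::setNames(regime, site))
  pre_keys <- with(regimes[regimes$regime == "pre_bleaching", ],
                   paste(site, year))
  prof_key <- paste(prof$site, prof$year)
  trend <- list()
  for (nu in unique(prof$nutrient)) {
    p <- prof[prof$nutrient == nu, ]
    pk <- paste(p$site, p$year)
    base <- mean(p$availability_median[pk %in% pre_keys])
    post <- p[!(pk %in% pre_keys), ]
    post$group <- site_group[post$site]
    for (grp in unique(stats::na.omit(post$group))) {
      x <- post[post$group %in% grp, ]
      for (y in sort(unique(x$year))) {
        m <- mean(x$availability_median[x$year == y])
        trend[[paste(nu, grp, y)]] <- data.frame(
          nutrient = nu, group = grp, year = y, mean_availability = m,
          baseline = base, pct_change = 100 * (m - base) / base,
          stringsAsFactors = FALSE)
      }
    }
  }
  trend <- do.call(rbind, trend)
  rownames(trend) <- NULL
  list(profile = prof, trend = trend)
}

#' Default recommended dietary allowances
#'
#' RDA values for children under 5 years used in the dietary-contribution
#' metric: iron 8.4 mg day^-1 and zinc 3.6 mg day^-1. No other RDAs are
#' assumed.
#'
#' @return named numeric vector (per-day requirements)
#' @export
default_rda <- function() c(iron = 8.4, zinc = 3.6)

#' Dietary contribution of a 100 g portion
#'
#' Percent of the recommended dietary allowance provided by a single 100 g
#' portion at a given concentration, with the international "source of
#' nutrients" classification at the 15% threshold.
#'
#' @param concentration concentration per 100 g (same unit as the RDA)
#' @param nutrient nutrient name(s), matched against `rda_table`
#' @param rda_table named per-day requirements, see [default_rda()]
#' @return data frame (`nutrient`, `concentration`, `rda`, `pct_rda`,
#'   `is_source`)
#' @export
dietary_contribution <- function(concentration, nutrient,
                                 rda_table = default_rda()) {
  rda <- rda_table[nutrient]
  if (any(is.na(rda))) stop("no RDA for nutrient(s): ",
                            paste(nutrient[is.na(rda)], collapse = ", "))
  if (any(rda <= 0)) stop("RDA must be > 0")
  pct <- 100 * concentration / rda
  data.frame(nutrient = nutrient, concentration = concentration,
             rda = as.numeric(rda), pct_rda = as.numeric(pct),
             is_source = as.numeric(pct) >= 15, stringsAsFactors = FALSE)
}
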