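post_gradient <- function(pc1, year = 2017L) {
  fake_gradient(c(0.1, 0.2, pc1), c(1994L, 1994L, rep(year, length(pc1))),
                c("pre1", "pre2", sprintf("s%02d", seq_along(pc1))))
}

test_that("regime assignment follows the 20% PC1 quantiles", {
  g <- post_gradient(1:10)
  reg <- assign_regimes(g, disturbance_year = 1998)
  post <- reg[reg$regime != "pre_bleaching", ]
  expect_equal(post$site[post$regime == "macroalgal"], c("s09", "s10"))
  expect_equal(post$site[post$regime == "recovering_coral"], c("s01", "s02"))
  expect_equal(sum(post$regime == "intermediate"), 6)
  expect_equal(sum(reg$regime == "pre_bleaching"), 2)
})

test_that("degenerate or tiny gradients are refused", {
  expect_error(assign_regimes(post_gradient(rep(2, 10))), "degenerate")
  expect_error(assign_regimes(post_gradient(1:3)), "fewer than 5")
})

test_that("the partition is 20/60/20 within rounding on larger gradients", {
  set.seed(9)
  g <- post_gradient(rnorm(60))
  reg <- assign_regimes(g)
  post <- reg[reg$regime != "pre_bleaching", ]
  tab <- table(post$regime)
  expect_equal(as.vector(tab[c("recovering_coral", "intermediate",
                               "macroalgal")]) / nrow(post),
               c(0.2, 0.6, 0.2), tolerance = 0.05)
})

test_that("regime assignment lands on the generator's shifted sites", {
  ds <- small_dataset()
  g <- benthic_pca(ds$benthic)
  reg <- assign_regimes(g, disturbance_year = small_config()$disturbance_year)
  truth <- ds$truth$site_regimes
  ma <- reg[reg$regime == "macroalgal", ]
  expect_gte(mean(truth[ma$site] == "macroalgal"), 0.95)
})

test_that("zero habitat effect leaves everything bit-identical", {
  set.seed(10)
  sp <- sprintf("sp%02d", 1:4)
  draws <- list(iron = matrix(rlnorm(4 * 100), 4, 100,
                              dimnames = list(sp, NULL)))
  b6_zero <- list(iron = rep(0, 100))
  enr <- apply_enrichment(draws, b6_zero)
  expect_identical(enr$iron, draws$iron)
  # and downstream profiles are bit-identical too
  bm <- data.frame(site = rep(c("s01", "pre1"), each = 4),
                   year = rep(c(2017L, 1994L), each = 4),
                   species = rep(sp, 2), biomass_kg_ha = rep(1:4, 2),
                   stringsAsFactors = FALSE)
  g <- post_gradient(c(3, 0, 0, 0, 0, -1))   # s01 is macroalgal
  reg <- assign_regimes(g)
  p_plain <- weighted_assemblage_concentration(bm, draws)
  p_enr <- reefnutr:::profile_with_enrichment(bm, draws, reg, b6_zero)
  i <- order(p_enr$site, p_enr$year)
  j <- order(p_plain$site, p_plain$year)
  expect_identical(p_enr$median[i], p_plain$median[j])
  expect_identical(p_enr$availability_median[i],
                   p_plain$availability_median[j])
})

test_that("link-scale enrichment is multiplicative with closed form", {
  draws <- list(iron = const_draws(c(sp1 = 2), n_draws = 10))
  enr <- apply_enrichment(draws, list(iron = rep(log(2), 10)))
  expect_equal(as.vector(enr$iron), rep(4, 10))
  # response-scale additive mode
  add <- apply_enrichment(draws, list(iron = rep(0.27, 10)),
                          mode = "response")
  expect_equal(as.vector(add$iron), rep(2.27, 10))
  # nutrients without an effect pass through unchanged, with a warning
  expect_warning(
    out <- apply_enrichment(c(draws, list(zinc = draws$iron)),
                            list(iron = rep(0, 10))), "zinc")
  expect_identical(out$zinc, draws$iron)
})

test_that("regime contrasts are zero under identity conditions", {
  prof <- data.frame(site = c("pre1", "s01"), year = c(1994L, 2017L),
                     nutrient = "iron", median = c(1, 1),
                     stringsAsFactors = FALSE)
  regimes <- data.frame(site = c("pre1", "s01"), year = c(1994L, 2017L),
                        regime = c("pre_bleaching", "macroalgal"),
                        stringsAsFactors = FALSE)
  rc <- regime_contrast(prof, prof, regimes)
  expect_equal(rc$summary$interspecific_median_pct, 0)
  expect_equal(rc$summary$intraspecific_median_pct, 0)
  # arithmetic mirroring a +57% enrichment contrast
  prof_e <- transform(prof, median = c(1, 1.57))
  rc2 <- regime_contrast(prof, prof_e, regimes)
  expect_equal(rc2$summary$interspecific_median_pct, 0)
  expect_equal(rc2$summary$intraspecific_median_pct, 57)
  expect_error(regime_contrast(prof, prof, regimes[2, , drop = FALSE]),
               "pre-bleaching")
})

test_that("gear selectivity is a restricted weighted mean", {
  sp <- c("lowTL1", "lowTL2", "hiTL1", "hiTL2")
  bm <- data.frame(site = "s01", year = 2017L, species = sp,
                   biomass_kg_ha = 1, stringsAsFactors = FALSE)
  regimes <- data.frame(site = c("pre1", "s01"), year = c(1994L, 2017L),
                        regime = c("pre_bleaching", "intermediate"),
                        stringsAsFactors = FALSE)
  draws <- list(iron = const_draws(c(lowTL1 = 1, lowTL2 = 3,
                                     hiTL1 = 5, hiTL2 = 7)))
  gs <- gear_selectivity(bm, draws,
                         list(trap = c("lowTL1", "lowTL2"),
                              handline = c("hiTL1", "hiTL2")),
                         regimes)
  expect_equal(gs$per_site$median[gs$per_site$gear == "trap"], 2)
  expect_equal(gs$per_site$median[gs$per_site$gear == "handline"], 6)
  # identical target lists give identical selectivity
  gs2 <- gear_selectivity(bm, draws, list(trap = sp, handline = sp), regimes)
  expect_equal(gs2$per_site$median[gs2$per_site$gear == "trap"],
               gs2$per_site$median[gs2$per_site$gear == "handline"])
  # a gear targeting all species equals the assemblage concentration
  p_all <- weighted_assemblage_concentration(bm, draws)
  expect_equal(gs2$per_site$median[1], p_all$median)
  expect_error(gear_selectivity(bm, draws, list(trap = character(0)),
                                regimes), "empty")
})

test_that("selectivity orders gears by the nutrient-trait gradient", {
  # selenium rises with trophic level; handline targets high-TL species
  sp <- sprintf("sp%02d", 1:8)
  TL <- seq(2, 4, length.out = 8)
  conc <- 20 + 15 * (TL - 3)
  names(conc) <- sp
  bm <- data.frame(site = "s01", year = 2017L, species = sp,
                   biomass_kg_ha = runif(8, 0.5, 2), stringsAsFactors = FALSE)
  regimes <- data.frame(site = c("pre1", "s01"), year = c(1994L, 2017L),
                        regime = c("pre_bleaching", "intermediate"),
                        stringsAsFactors = FALSE)
  gs <- gear_selectivity(bm, list(selenium = const_draws(conc)),
                         list(trap = sp[TL < 3.2], handline = sp[TL >= 3]),
                         regimes)
  sel <- gs$per_site
  expect_gt(sel$median[sel$gear == "handline"],
            sel$median[sel$gear == "trap"])
})

test_that("availability arithmetic and unit invariance hold", {
  sp <- "sp1"
  bm <- data.frame(site = rep(c("pre1", "s01"), 2),
                   year = rep(c(1994L, 2017L), 2), species = sp,
                   biomass_kg_ha = c(100, 100, 100, 100),
                   stringsAsFactors = FALSE)
  bm <- bm[1:2, ]
  regimes <- data.frame(site = c("pre1", "s01"), year = c(1994L, 2017L),
                        regime = c("pre_bleaching", "recovering_coral"),
                        stringsAsFactors = FALSE)
  draws <- list(iron = const_draws(c(sp1 = 1)))
  av <- availability(bm, draws, regimes)
  # 100 kg/ha at 1 mg/100 g -> 1,000 mg/ha
  expect_equal(unique(av$profile$availability_median), 1000)
  # doubling biomass doubles availability
  bm2 <- transform(bm, biomass_kg_ha = biomass_kg_ha * 2)
  av2 <- availability(bm2, draws, regimes)
  expect_equal(unique(av2$profile$availability_median), 2000)
  # +218% style change
  bm3 <- bm; bm3$biomass_kg_ha[2] <- 318
  av3 <- availability(bm3, draws, regimes)
  expect_equal(av3$trend$pct_change, 218)
  # percent change invariant to the nutrient unit
  draws_ug <- list(iron = const_draws(c(sp1 = 1000)))
  av4 <- availability(bm3, draws_ug, regimes)
  expect_equal(av4$trend$pct_change, av3$trend$pct_change)
})

test_that("dietary contribution implements the RDA and source rules", {
  expect_equal(dietary_contribution(8.4, "iron")$pct_rda, 100)
  z <- dietary_contribution(0, "zinc")
  expect_equal(z$pct_rda, 0)
  expect_false(z$is_source)
  # the zinc concentration matching a 32% RDA share
  z32 <- dietary_contribution(1.152, "zinc")
  expect_equal(z32$pct_rda, 32)
  expect_true(z32$is_source)
  expect_error(dietary_contribution(1, "selenium"), "no RDA")
  expect_error(dietary_contribution(1, "iron", rda_table = c(iron = -1)),
               "RDA must be")
})
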