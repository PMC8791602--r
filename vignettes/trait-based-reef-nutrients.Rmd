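---
title: "Trait-based models of reef-fish micronutrients and their propagation to fishery scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based models of reef-fish micronutrients and their propagation to fishery scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`reefnutr` models concentrations of five nutrients in coral-reef fish
tissue — calcium, iron, selenium, zinc and omega-3 fatty acids — from
species life-history traits, and propagates those posteriors to the scale
at which small-scale fisheries experience them: the biomass-weighted
nutrient concentration of a reef's target assemblage, the total fishable
nutrient quantity per hectare, gear-specific selectivity, and dietary
contributions per 100 g portion. The scientific setting is a reef system
that suffered mass coral mortality after a marine heatwave and whose reefs
then diverged into coral-recovery and macroalgal regime-shift trajectories;
the central question is how that habitat divergence changes the
micronutrients a reef fishery can deliver.

## The trait model

For each nutrient, sample $i$ (one concentration per fish, standardised
per 100 g wet tissue) is modelled with a gamma likelihood in the
mean-shape parameterisation, $y_i \sim \mathrm{Gamma}(\mu_i, k)$ with
$\mathrm{Var}(y_i) = \mu_i^2 / k$. Calcium behaves closer to log-normal
and is modelled as $y_i \sim \mathrm{LogNormal}(\log\mu_i, \sigma)$. The
mean is driven by five traits:

$$\log \mu_i = \alpha_{family(i), site(i)} + \beta_1 K_i + \beta_2 TL_i +
  \beta_3 AM_i + \beta_4 PEL_i + \beta_5 LMX_i$$

where $K$ is the von Bertalanffy growth coefficient, $TL$ trophic level,
$AM$ age at maturity, $PEL$ a binary pelagic-feeding-pathway indicator
and $LMX$ maximum length. Family and site enter as exchangeable random
intercepts. A second structure replaces the family intercept with a
species-level intercept drawn from a multivariate normal whose covariance
is an Ornstein-Uhlenbeck function of phylogenetic distance,
$S_{ij} = \eta^2 e^{-\rho d_{ij}}$ (plus a fixed $10^{-6}$ diagonal
nugget); the two structures are compared by WAIC. The habitat model adds
a varying slope on a macroalgal-habitat indicator,
$\beta_{6,sp} HAB_i$, fitted to the species sampled in both habitat
regimes; $\beta_6$ (the across-species average) is the tissue-level
enrichment effect of macroalgal habitat on the log scale.

Choices the likelihood leaves open, and how this package resolves them:

* **Link function.** The gamma models use a log link: it keeps $\mu_i > 0$
  for any covariate combination and makes the habitat effect
  multiplicative on the response scale, which is how enrichment is
  propagated downstream. Response-scale contrasts are always computed by
  differencing back-transformed predictions, never by transforming a
  coefficient alone.
* **Calcium back-transform.** Predictions exponentiate the draws of
  $\log\mu$ without a half-variance correction; the reported medians are
  therefore median-unbiased rather than mean-unbiased, matching how all
  posterior summaries here are medians with highest-density intervals.
* **Covariate scaling.** Covariates are centred and divided by one
  standard deviation computed *across the distinct species in the data*,
  not across observations, so unevenly sampled species do not drag the
  scale. An unscaled refit is available for out-of-sample prediction; its
  trait-coefficient priors are the scaled-space priors divided by the
  empirical covariate SD, which makes the two fits the same model in
  different parameterisations (their in-sample predictions agree within
  MCMC error, checked to 2% in the tests).
* **Intercept parameterisation.** Group intercepts are hierarchically
  centred ($\alpha_{family} \sim N(\bar\alpha, \sigma_{fam})$, and
  likewise for species), which mixes far better under Gibbs sampling than
  the zero-centred additive form. The phylogenetic intercept stays a
  zero-mean deviation because the OU covariance is defined around zero.
* **Priors.** Trait coefficients default to weakly informative
  $N(0, 1)$ on the per-SD scale; an informative prior table (for example
  the posteriors of a global marine-fish trait model) can be supplied as
  YAML and is used verbatim. The habitat effect prior is $N(0, 1)$.
  Intercept-hierarchy scales are Exponential(1); the gamma shape has an
  Exponential(0.05) prior; the OU hyperpriors are
  $\eta^2 \sim \mathrm{Exp}(1)$, $\rho \sim \mathrm{Exp}(0.5)$.
* **Sampling.** Models are estimated by MCMC in JAGS, by default 3
  chains of 5,000 iterations with 1,500 warmup. Convergence is enforced
  before draws are released: every monitored parameter must have
  $|\hat R - 1| \le 0.01$ (configurable; reduced-length test fits relax
  enforcement and state so). JAGS has no divergence diagnostic, so that
  field of the diagnostics is reported as missing rather than zero.
* **Model choice for prediction.** Even where the phylogenetic structure
  wins WAIC, the default policy predicts from the simpler family-intercept
  model (less overfitting risk for out-of-sample species); a strict-WAIC
  flag overrides this. Both WAIC values are always recorded.
* **WAIC.** $\mathrm{WAIC} = -2(\mathrm{lppd} - p_{WAIC})$ with
  $\mathrm{lppd} = \sum_i \log \tfrac1D \sum_d e^{\ell_{id}}$ and
  $p_{WAIC} = \sum_i \mathrm{Var}_d(\ell_{id})$, computed from the
  pointwise log-likelihood matrix with a log-sum-exp stabilisation; the
  tests pin it to a literal two-loop reference at $10^{-10}$.
* **Intervals.** All uncertainty intervals are highest-density intervals
  (50% and 95%) computed from pooled chains by the shortest-window scan
  over sorted draws.

## Sample exclusion

Tissue samples below the limit of quantification are removed first. Then,
per nutrient, any value greater than `mean + 2 × SD` of the remaining
values is excluded — a one-sided upper filter, because the failure mode
being guarded against (foreign contamination during dissection) only
inflates concentrations. The filter runs in a single pass: the threshold
is computed once and not recomputed after removals. The spread statistic
is the standard deviation by default. The standard *error* reading of the
rule is available behind a flag, but with realistic per-nutrient sample
sizes (~180) an SEM-based threshold would remove an implausibly large
fraction of samples, which is inconsistent with a removal rate of a few
percent; SD is therefore the default and the choice is logged in the QC
report.

## From species posteriors to reef metrics

UVC point counts (154 m², eight replicates per site-year) are converted
to biomass with allometric length-weight relationships
($m = aL^b$, defaulting to $a = 0.01$, $b = 3$ in g/cm unless a
species-specific table is supplied). Within a site-year, body masses are
summed within each replicate, divided by the count area, averaged across
*all* replicates (absences contribute zero) and scaled to kg ha⁻¹.

The assemblage concentration for a site-year is, per posterior draw, the
biomass-weighted mean over target species; availability is the unweighted
sum of biomass × concentration with 1 kg = 10 portions of 100 g, so a
concentration in mg 100 g⁻¹ yields mg ha⁻¹. Draws are taken
independently per species (the joint posterior across species is not
preserved); this widens assemblage intervals slightly relative to using
correlated draws and is the documented default.

The benthic gradient is the first principal component of standardised
hard-coral cover, macroalgae cover and structural complexity. The sign of
PC1 is fixed so that macroalgae loads positively — the axis always reads
coral → macroalgae. Regressions of site-year responses on PC1 use a
normal likelihood for concentrations and a gamma likelihood (log link)
for biomass proportions, with year and site random intercepts and the
stated priors ($\alpha \sim N(0, 100)$, $\beta \sim N(0, 10)$,
scales Exponential(1)); a quadratic PC1 term is adopted when it lowers
WAIC. Percent changes along the gradient are evaluated at the observed
minimum and maximum of PC1, not at ±2 SD.

Post-disturbance site-years are classified by PC1 quantiles pooled across
post-disturbance years (per-year quantiles are the plausible alternative;
pooling is the default because the regime concept is a property of the
reef's state, not of the survey year): top 20% macroalgal, bottom 20%
recovering coral, middle 60% intermediate. Enrichment — multiplying each
concentration draw by $e^{\beta_6^{(d)}}$ using draws of the average
habitat effect — is applied only on macroalgal site-years; intermediate
reefs are never enriched. With $\beta_6 \equiv 0$ the enriched pipeline
is bit-identical to the plain one, which the tests assert literally.

Gear selectivity restricts the biomass weighting to a gear's target list
and summarises strata (regime × year) as mean ± 2 SEM across reef sites.
Dietary contribution divides a 100 g portion's content by the RDA for
children under five (iron 8.4 mg day⁻¹, zinc 3.6 mg day⁻¹ — the only two
RDAs shipped; others must be supplied) and applies the 15%-of-daily-intake
"source" rule.

## The synthetic-data generator

The generator is first-class, tested code: it draws complete studies from
the generative structure the models assume, with known ground truth, and
is what the recovery and calibration tests run against. Its defaults are
the study conditions: 44 species in 11 families, 12 sites surveyed in
1994 and 2005–2017 (one pre-disturbance year, disturbance in 1998), 8
point counts of 154 m² per site-year, 40% of sites on the macroalgal
trajectory, ten species sampled in both habitat regimes at ~110 tissue
samples (the habitat-model scale), and a macroalgal effect concentrated
on iron (×1.5) and zinc (×1.2) with the other nutrients unaffected.

Where the generative form is not dictated by the analysis, the choices
are: log-normal marginals for $K$, $AM$ and $LMX$ and a clipped normal
for $TL$ (FishBase-style skew); the moderate correlation between maximum
length and pelagic feeding (target Pearson r = 0.65) induced by
thresholding a latent bivariate normal whose latent correlation is
back-solved analytically from the target; phylogenetic distances from a
random coalescent tree over families with species nested at shallow
within-family depths (ultrametric, normalised to max 1); species
intercepts with both an OU-kernel component and an independent component;
Dirichlet-multinomial point-count compositions with a post-disturbance
boost to herbivore share (stronger on shifted reefs) and total abundance
growing to ×3.2 of the pre-disturbance mean by the final survey year,
emulating the long-term post-bleaching biomass increase; benthic
trajectories in which shifted reefs reach 33–75% macroalgae cover while
recovering reefs stay below ~6%; and baseline concentrations (iron
0.67 mg, zinc 1.15 mg, calcium 30 mg, selenium 50 µg, omega-3 0.3 g per
100 g) chosen so the average fish sits at realistic dietary-contribution
levels. Within-fish residual noise defaults to gamma shape 10 (CV ≈ 32%)
per nutrient — no empirical residual variance was available to anchor
this, so it is explicitly configurable.

What the generator does *not* emulate: a real species list or phylogeny,
observer error in the UVC counts, spatial structure beyond site labels,
detectability, or the browser/scraper split that can make compositional
change push individual nutrients in opposite directions on real reefs.
Passing tests therefore demonstrate that the estimation and propagation
machinery is correct under the assumed generative structure — not that
the structure captures every feature of field data.

## Problem sizes and numerical tolerances

The test suite runs reduced problem sizes chosen to exercise each
property at adequate power: parameter recovery uses 20 replicate studies
of n = 500 samples with 3 chains × 2,000 iterations (95% HDI coverage of
the five trait coefficients ≥ 90% across 100 intervals); habitat-effect
recovery uses 20 replicates at the habitat-model scale (10 species, ~110
samples), requiring the posterior multiplicative iron effect in
[1.2, 1.9] in at least 18; simulation-based calibration runs 200
prior-predictive refits of a reduced trait model and requires a χ² test
on the rank histogram not to reject at α = 0.01; gamma moment checks run
at n = 10⁵ within three standard errors; WAIC is pinned at 10⁻¹⁰.
Reduced-length fits relax the R̂ enforcement (the full-length default
remains 0.01) — that relaxation is always explicit at the call site.

## Known limitations

Gamma likelihoods for biomass *proportions* are supported because that is
the stated modelling convention, but a proportion support of (0, 1] sits
awkwardly in a gamma model; a beta-likelihood alternative is available
behind a flag and off by default. The QC filter's SD-versus-SEM ambiguity
is resolved by default, not eliminated. Enrichment extrapolates the
average habitat effect to all target species, including those never
sampled in both habitats; the species-level deviations the habitat model
estimates are reported so that assumption can be inspected. No catch or
effort dynamics, detectability correction, or projection under future
disturbance scenarios is included.
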