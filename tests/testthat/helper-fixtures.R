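# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cache_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# a small but complete study for structural tests
small_config <- function(...) {
  synthetic_config(n_species = 12, n_families = 4, n_sites = 6,
                   years = c(1994, 2005, 2011, 2017), n_pointcounts = 4,
                   n_per_species = 3, n_dual_species = 4,
                   n_dual_per_species = 6, mean_count = 25, seed = 11, ...)
}

small_dataset <- function() cache_fixture("small_dataset",
                                          generate_dataset(small_config()))

# quiet, reduced MCMC for unit tests (documented as reduced runs)
test_mcmc <- function(seed = 5, n_iter = 1800, n_warmup = 600, ...) {
  mcmc_config(n_chains = 2, n_iter = n_iter, n_warmup = n_warmup,
              seed = seed, on_fail = "none", ...)
}

quiet_fit <- function(...)
  suppressWarnings(suppressMessages(fit_model(...)))

# constant-concentration draw matrices keyed by species
const_draws <- function(values, n_draws = 50) {
  m <- matrix(rep(values, each = n_draws), nrow = length(values),
              ncol = n_draws, byrow = TRUE,
              dimnames = list(names(values), NULL))
  m
}

# minimal benthic gradient object for arithmetic tests
fake_gradient <- function(pc1, years, sites = NULL) {
  if (is.null(sites)) sites <- sprintf("s%02d", seq_along(pc1))
  g <- list(scores = data.frame(site = sites, year = years, pc1 = pc1,
                                stringsAsFactors = FALSE),
            loadings = c(hard_coral = -0.6, macroalgae = 0.6,
                         complexity = -0.5),
            var_explained = 0.7)
  class(g) <- "benthic_gradient"
  g
}

# minimal benthic_fit with fixed coefficient draws
fake_benthic_fit <- function(abar, b1, b2 = NULL, n = 200,
                             likelihood = "normal") {
  draws <- cbind(abar = rep(abar, n), b1 = rep(b1, n))
  quadratic <- !is.null(b2)
  if (quadratic) draws <- cbind(draws, b2 = rep(b2, n))
  fit <- list(draws = draws, likelihood = likelihood, quadratic = quadratic)
  class(fit) <- "benthic_fit"
  fit
}
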