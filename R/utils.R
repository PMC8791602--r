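#' @keywords internal
"_PACKAGE"

NUTRIENTS <- c("calcium", "iron", "selenium", "zinc", "omega3")

#' Measurement unit for each nutrient (per 100 g wet tissue)
#'
#' Calcium, iron and zinc are reported in mg 100 g^-1, selenium in
#' ug 100 g^-1 and omega-3 fatty acids in g 100 g^-1.
#'
#' @param nutrient character vector of nutrient names
#' @return character vector of unit labels
#' @export
nutrient_units <- function(nutrient = NUTRIENTS) {
  units <- c(calcium = "mg", iron = "mg", selenium = "ug",
             zinc = "mg", omega3 = "g")
  unknown <- setdiff(nutrient, names(units))
  if (length(unknown) > 0) {
    stop("unknown nutrient(s): ", paste(unknown, collapse = ", "))
  }
  stats::setNames(units[nutrient], nutrient)
}

# Derive a reproducible sub-seed from a master seed and a fixed stream
# offset, kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483629L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Highest-density interval of a sample of draws
#'
#' Shortest contiguous interval containing a given probability mass,
#' computed from sorted draws (the convention used for all uncertainty
#' intervals in this package).
#'
#' @param x numeric vector of posterior draws
#' @param prob probability mass of the interval (e.g. 0.95)
#' @return named numeric vector with elements `lower` and `upper`
#' @export
posterior_hdi <- function(x, prob = 0.95) {
  stopifnot(is.numeric(x), length(x) >= 2, prob > 0, prob < 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# Summarise draws into median + 50%/95% HDIs (long used downstream).
summarise_draws <- function(x) {
  h50 <- posterior_hdi(x, 0.50)
  h95 <- posterior_hdi(x, 0.95)
  c(median = stats::median(x),
    lower50 = h50[["lower"]], upper50 = h50[["upper"]],
    lower95 = h95[["lower"]], upper95 = h95[["upper"]])
}
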