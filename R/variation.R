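#' Interspecific micronutrient variation
#'
#' Pairwise Euclidean differences in posterior-median concentration among
#' species, per nutrient. Each unordered pair contributes
#' |c_a - c_b| expressed as a percentage of the pair mean, making the
#' measure invariant to the nutrient's unit. With n species there are
#' C(n, 2) pairs (e.g. 43 species give 903 pairs).
#'
#' @param species_posteriors data frame with columns `species`, `nutrient`,
#'   `median` (one row per species per nutrient, e.g. from
#'   [predict_species()])
#' @return data frame of class `variation_summary`: per nutrient the
#'   median and quartiles of the percent differences and `n_pairs`, with
#'   the full long table as attribute `"pairs"`
#' @export
interspecific_differences <- function(species_posteriors) {
  stopifnot(all(c("species", "nutrient", "median") %in%
                  names(species_posteriors)))
  out <- list()
  pairs_long <- list()
  for (nu in unique(species_posteriors$nutrient)) {
    x <- species_posteriors[species_posteriors$nutrient == nu, ]
    if (nrow(x) < 2) stop("need >= 2 species per nutrient (", nu, ")")
    cmb <- utils::combn(nrow(x), 2)
    a <- x$median[cmb[1, ]]
    b <- x$median[cmb[2, ]]
    pct <- ifelse(a + b == 0, 0, 100 * abs(a - b) / ((a + b) / 2))
    q <- stats::quantile(pct, c(0.25, 0.5, 0.75))
    out[[nu]] <- data.frame(nutrient = nu, scope = "interspecific",
                            median_pct = q[[2]], q25_pct = q[[1]],
                            q75_pct = q[[3]], n_pairs = ncol(cmb),
                            stringsAsFactors = FALSE)
    pairs_long[[nu]] <- data.frame(nutrient = nu,
                                   species_a = x$species[cmb[1, ]],
                                   species_b = x$species[cmb[2, ]],
                                   diff = abs(a - b), pct_of_mean = pct,
                                   stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, out)
  rownames(summary) <- NULL
  attr(summary, "pairs") <- do.call(rbind, pairs_long)
  class(summary) <- c("variation_summary", class(summary))
  summary
}

#' Intraspecific (habitat-driven) micronutrient variation
#'
#' For species predicted in both recovering-coral and macroalgal habitat
#' regimes, the within-species Euclidean difference
#' |c_MA - c_coral| as a percentage of the mean of the two, per nutrient.
#' The signed response-scale difference is retained for reporting
#' concentration-scale contrasts. Species missing one habitat are excluded
#' with a warning.
#'
#' @param coral_posteriors,macroalgal_posteriors data frames with columns
#'   `species`, `nutrient`, `median` (habitat-specific predictions from the
#'   habitat model)
#' @return data frame of class `variation_summary` with attribute
#'   `"pairs"` holding the per-species table (including signed
#'   `diff_signed` = c_MA - c_coral)
#' @export
intraspecific_differences <- function(coral_posteriors,
                                      macroalgal_posteriors) {
  key <- function(x) paste(x$species, x$nutrient)
  common <- intersect(key(coral_posteriors), key(macroalgal_posteriors))
  dropped <- union(setdiff(unique(coral_posteriors$species),
                           unique(macroalgal_posteriors$species)),
                   setdiff(unique(macroalgal_posteriors$species),
                           unique(coral_posteriors$species)))
  if (length(dropped) > 0)
    warning("species missing one habitat, excluded: ",
            paste(dropped, collapse = ", "))
  cc <- coral_posteriors[key(coral_posteriors) %in% common, ]
  mm <- macroalgal_posteriors[match(key(cc), key(macroalgal_posteriors)), ]
  pct <- ifelse(cc$median + mm$median == 0, 0,
                100 * abs(mm$median - cc$median) /
                  ((cc$median + mm$median) / 2))
  pairs <- data.frame(nutrient = cc$nutrient, species = cc$species,
                      coral = cc$median, macroalgal = mm$median,
                      diff = abs(mm$median - cc$median),
                      diff_signed = mm$median - cc$median,
                      pct_of_mean = pct, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(pairs, pairs$nutrient), function(x) {
    q <- stats::quantile(x$pct_of_mean, c(0.25, 0.5, 0.75))
    data.frame(nutrient = x$nutrient[1], scope = "intraspecific",
               median_pct = q[[2]], q25_pct = q[[1]], q75_pct = q[[3]],
               n_pairs = nrow(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "pairs") <- pairs
  class(out) <- c("variation_summary", class(out))
  out
}
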