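#' Required columns for each input table
#'
#' @keywords internal
table_schemas <- function() {
  list(
    samples = c("fish_id", "species", "family", "site", "habitat", "year",
                "nutrient", "concentration", "below_loq"),
    traits = c("species", "family", "K", "TL", "AM", "PEL", "LMX",
               "feeding_group", "target_gears"),
    uvc = c("site", "year", "point_count", "species", "length", "abundance"),
    benthic = c("site", "year", "hard_coral", "macroalgae", "complexity"),
    gears = c("gear", "species")
  )
}

read_table_checked <- function(path, required, what, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  }
  x
}

#' Load and validate the input tables of a study
#'
#' Reads the nutrient-sample, trait, UVC, benthic and gear tables from
#' delimited text, checks required columns, types the fields, and
#' cross-references species names. Species observed in the UVC surveys but
#' absent from the trait table are flagged with a warning (exact string
#' matching; no fuzzy name resolution).
#'
#' @param paths named list/vector with elements `samples`, `traits`, `uvc`,
#'   `benthic`, `gears` (any subset; only named tables are read)
#' @param delim field delimiter, default comma
#' @param schema optional named list overriding required-column sets, e.g.
#'   from a YAML schema file read with [yaml::read_yaml()]
#' @return named list of validated data frames plus a `report` data frame
#'   of row counts
#' @export
load_tables <- function(paths, delim = ",", schema = NULL) {
  schemas <- table_schemas()
  if (!is.null(schema)) schemas[names(schema)] <- schema
  out <- list()
  for (what in intersect(names(schemas), names(paths))) {
    out[[what]] <- read_table_checked(paths[[what]], schemas[[what]], what,
                                      delim)
  }
  if (!is.null(out$samples)) {
    s <- out$samples
    s$concentration <- as.numeric(s$concentration)
    s$below_loq <- as.logical(s$below_loq)
    s$year <- as.integer(s$year)
    bad <- setdiff(unique(s$nutrient), NUTRIENTS)
    if (length(bad) > 0)
      stop("unknown nutrient(s) in samples: ", paste(bad, collapse = ", "))
    dup <- duplicated(s[, c("fish_id", "nutrient")])
    if (any(dup))
      stop("duplicate fish_id x nutrient rows: ",
           paste(utils::head(s$fish_id[dup]), collapse = ", "))
    if (any(s$concentration <= 0 & !s$below_loq, na.rm = TRUE))
      stop("nonpositive concentration in rows not flagged below_loq")
    out$samples <- s
  }
  if (!is.null(out$traits)) {
    tr <- out$traits
    for (cl in c("K", "TL", "AM", "LMX")) tr[[cl]] <- as.numeric(tr[[cl]])
    tr$PEL <- as.integer(tr$PEL)
    with_neg <- with(tr, K <= 0 | TL < 2 | AM <= 0 | LMX <= 0 | !PEL %in% 0:1)
    if (any(with_neg))
      stop("invalid trait values for species: ",
           paste(tr$species[with_neg], collapse = ", "))
    out$traits <- tr
  }
  if (!is.null(out$uvc)) {
    u <- out$uvc
    u$length <- as.numeric(u$length)
    u$abundance <- as.integer(u$abundance)
    u$year <- as.integer(u$year)
    if (any(u$abundance < 1)) stop("UVC abundance must be >= 1")
    if (!is.null(out$traits)) {
      unknown <- setdiff(unique(u$species), out$traits$species)
      if (length(unknown) > 0)
        warning("UVC species absent from traits table: ",
                paste(unknown, collapse = ", "))
    }
    out$uvc <- u
  }
  out$report <- data.frame(
    table = setdiff(names(out), "report"),
    rows = vapply(out[setdiff(names(out), "report")], nrow, integer(1)))
  out
}

#' Apply the sample-exclusion rules to a nutrient-sample table
#'
#' Two filters, applied once (single pass, no iteration): first, samples
#' flagged below the limit of quantification are removed; then, per
#' nutrient, any value greater than mean + `multiplier` x spread of the
#' post-LOQ values is removed (one-sided upper filter — suspected tissue
#' contamination only inflates concentrations). The spread statistic is the
#' standard deviation by default; the standard error of the mean is
#' available via `spread = "sem"`.
#'
#' @param samples nutrient-sample data frame (see [load_tables()])
#' @param multiplier number of spread units above the mean, default 2
#' @param spread `"sd"` (default) or `"sem"`
#' @return list with `samples` (filtered table) and `report` (per-nutrient
#'   QC counts: input, below-LOQ removals, outlier removals, retained,
#'   removal fraction)
#' @export
apply_qc <- function(samples, multiplier = 2, spread = c("sd", "sem")) {
  spread <- match.arg(spread)
  stopifnot(is.data.frame(samples), multiplier >= 0)
  nutrients <- unique(samples$nutrient)
  kept <- list()
  rep_rows <- list()
  for (nu in nutrients) {
    x <- samples[samples$nutrient == nu, , drop = FALSE]
    n_in <- nrow(x)
    loq <- x$below_loq %in% TRUE
    n_loq <- sum(loq)
    x <- x[!loq, , drop = FALSE]
    if (nrow(x) == 0)
      stop("all samples below LOQ for nutrient: ", nu)
    if (nrow(x) < 2)
      stop("fewer than 2 retained samples for nutrient: ", nu)
    m <- mean(x$concentration)
    s <- stats::sd(x$concentration)
    if (spread == "sem") s <- s / sqrt(nrow(x))
    thr <- m + multiplier * s
    out <- x$concentration > thr
    n_out <- sum(out)
    kept[[nu]] <- x[!out, , drop = FALSE]
    rep_rows[[nu]] <- data.frame(
      nutrient = nu, n_input = n_in, n_below_loq = n_loq,
      n_outlier = n_out, n_retained = n_in - n_loq - n_out,
      threshold = thr,
      removal_fraction = (n_loq + n_out) / n_in,
      stringsAsFactors = FALSE)
  }
  filtered <- do.call(rbind, kept)
  rownames(filtered) <- NULL
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  stopifnot(all(report$n_retained ==
                  report$n_input - report$n_below_loq - report$n_outlier))
  list(samples = filtered, report = report)
}

#' Write a QC report as JSON
#'
#' @param report the `report` element returned by [apply_qc()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
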