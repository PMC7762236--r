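# Core data model: per-plot trial records, daily weather, experiment metadata,
# and the entity x environment cell-mean matrix feeding the stability indices.

.date_cols <- c("date_emergence", "date_double_ridge", "date_terminal_spikelet",
                "date_heading", "date_flowering", "date_maturity")
.num_cols <- c("gy_g_m2", "gw_mg", "spikes_m2", "grains_per_spike",
               "spikelets_per_spike", "fertile_florets_per_spike")
.derived_cols <- c("gn_m2", "grains_per_spikelet", "grain_setting",
                   "days_ef", "days_fm")

# full-precision numeric formatting so CSV round-trips are value-identical
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

.env_id <- function(site, year) paste(site, year, sep = "-")

.plot_label <- function(p, i) {
  sprintf("row %d (site %s, year %s, block %s, genotype %s)",
          i, p$site[i], p$year[i], p$block[i], p$genotype[i])
}

.check_date_order <- function(plots) {
  ord <- .date_cols  # canonical developmental order
  for (i in seq_len(nrow(plots))) {
    d <- as.numeric(unlist(plots[i, ord]))
    d <- d[!is.na(d)]
    if (length(d) > 1 && any(diff(d) < 0))
      stop("phenology dates out of order at ", .plot_label(plots, i))
  }
  invisible(plots)
}

#' Read a per-plot trial table
#'
#' Reads `plots.csv` (one row per experimental plot: design labels, phenology
#' dates in ISO-8601, trait values; empty string = absent) and validates each
#' row: genotype ids must resolve against the genotype metadata, phenology
#' dates must be non-decreasing in the developmental order emergence, double
#' ridge, terminal spikelet, heading, flowering, maturity, and GY/GW must be
#' positive when present.
#'
#' @param path CSV file path.
#' @param genotypes genotype metadata (see [genotype_meta()]); when supplied,
#'   every `genotype` value must occur in it.
#' @return data frame of validated plot records, dates as `Date`.
#' @export
read_plot_table <- function(path, genotypes = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("site", "year", "block", "genotype", "date_emergence",
            "date_flowering", "date_maturity", "gy_g_m2", "gw_mg")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("plot table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("plot table ", path, " has a header but no rows")
  }
  plots <- data.frame(site = raw$site,
                      year = as.integer(raw$year),
                      block = as.integer(raw$block),
                      genotype = raw$genotype,
                      stringsAsFactors = FALSE)
  for (dc in .date_cols) {
    v <- if (dc %in% names(raw)) raw[[dc]] else rep("", nrow(raw))
    v[!nzchar(v)] <- NA_character_
    plots[[dc]] <- as.Date(v)
  }
  for (nc in .num_cols) {
    v <- if (nc %in% names(raw)) raw[[nc]] else rep("", nrow(raw))
    v[!nzchar(v)] <- NA_character_
    plots[[nc]] <- as.numeric(v)
  }
  if (!is.null(genotypes)) {
    bad <- which(!(plots$genotype %in% genotypes$genotype))
    if (length(bad))
      stop("unknown genotype id at ", .plot_label(plots, bad[1]))
  }
  .check_date_order(plots)
  for (v in c("gy_g_m2", "gw_mg")) {
    bad <- which(!is.na(plots[[v]]) & plots[[v]] <= 0)
    if (length(bad))
      stop(v, " must be > 0; violated at ", .plot_label(plots, bad[1]))
  }
  plots
}

#' Write a per-plot trial table
#'
#' Dates are written ISO-8601 and numerics at full precision, so
#' write-then-read is value-identical.
#'
#' @param plots plot record data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(plots, path) {
  out <- data.frame(site = plots$site, year = plots$year, block = plots$block,
                    genotype = plots$genotype, stringsAsFactors = FALSE)
  for (dc in .date_cols) {
    v <- if (dc %in% names(plots)) format(plots[[dc]], "%Y-%m-%d") else ""
    v[is.na(v)] <- ""
    out[[dc]] <- v
  }
  for (nc in .num_cols) {
    v <- if (nc %in% names(plots)) plots[[nc]] else NA_real_
    out[[nc]] <- .fmt_num(v)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily weather table
#'
#' Expects columns `site, year, date, tmin_c, tmax_c, tmean_c, rad_mj_m2` and
#' checks `tmin <= tmean <= tmax` on every day.
#'
#' @param path CSV file path.
#' @return data frame with `date` as `Date`.
#' @export
read_weather_table <- function(path) {
  wx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "date", "tmin_c", "tmax_c", "tmean_c", "rad_mj_m2")
  miss <- setdiff(need, names(wx))
  if (length(miss))
    stop("weather table missing column(s): ", paste(miss, collapse = ", "))
  wx$date <- as.Date(wx$date)
  wx$year <- as.integer(wx$year)
  bad <- which(wx$tmin_c > wx$tmean_c | wx$tmean_c > wx$tmax_c)
  if (length(bad))
    stop("tmin <= tmean <= tmax violated at ", wx$site[bad[1]], " ",
         wx$date[bad[1]])
  wx
}

#' Write a daily weather table
#' @param weather weather data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather_table <- function(weather, path) {
  out <- weather[c("site", "year", "date", "tmin_c", "tmax_c", "tmean_c",
                   "rad_mj_m2")]
  out$date <- format(out$date, "%Y-%m-%d")
  for (v in c("tmin_c", "tmax_c", "tmean_c", "rad_mj_m2"))
    out[[v]] <- .fmt_num(out[[v]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experiment (site-year) metadata table
#'
#' Expects columns `site, year, latitude_deg, sowing_date`; (site, year) pairs
#' must be unique and latitudes within \[-90, 90\].
#'
#' @param path CSV file path.
#' @return data frame with `sowing_date` as `Date`.
#' @export
read_experiment_table <- function(path) {
  ex <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "latitude_deg", "sowing_date")
  miss <- setdiff(need, names(ex))
  if (length(miss))
    stop("experiment table missing column(s): ", paste(miss, collapse = ", "))
  ex$year <- as.integer(ex$year)
  ex$sowing_date <- as.Date(ex$sowing_date)
  if (anyDuplicated(ex[c("site", "year")]))
    stop("duplicated (site, year) pairs in experiment table")
  if (any(abs(ex$latitude_deg) > 90))
    stop("latitude outside [-90, 90]")
  ex
}

#' Write an experiment metadata table
#' @param experiments experiment data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_experiment_table <- function(experiments, path) {
  out <- experiments[c("site", "year", "latitude_deg", "sowing_date")]
  out$sowing_date <- format(out$sowing_date, "%Y-%m-%d")
  out$latitude_deg <- .fmt_num(out$latitude_deg)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive definitional traits on plot records
#'
#' Adds (or recomputes, idempotently) the derived traits:
#' grain number `gn_m2 = 1000 * GY / GW` (GY in g/m2 dry weight, GW in
#' mg/grain), `grains_per_spikelet = grains_per_spike / spikelets_per_spike`,
#' `grain_setting = grains_per_spike / fertile_florets_per_spike`, and the
#' phase durations `days_ef` (emergence to flowering) and `days_fm` (flowering
#' to maturity) in whole days.  Inputs are never mutated; an enriched copy is
#' returned.  Derived values are absent (NA) where an input is absent.
#'
#' @param plots plot record data frame.
#' @return copy of `plots` with derived trait columns.
#' @export
derive_traits <- function(plots) {
  out <- plots
  gw0 <- which(!is.na(out$gw_mg) & out$gw_mg == 0)
  if (length(gw0))
    stop("gw_mg is zero at ", .plot_label(out, gw0[1]), "; GN undefined")
  out$gn_m2 <- 1000 * out$gy_g_m2 / out$gw_mg

  gps <- if ("grains_per_spike" %in% names(out)) out$grains_per_spike else
    rep(NA_real_, nrow(out))
  sps <- if ("spikelets_per_spike" %in% names(out)) out$spikelets_per_spike else
    rep(NA_real_, nrow(out))
  ff <- if ("fertile_florets_per_spike" %in% names(out))
    out$fertile_florets_per_spike else rep(NA_real_, nrow(out))
  bad <- which(!is.na(gps) & gps > 0 & !is.na(sps) & sps == 0)
  if (length(bad))
    stop("spikelets_per_spike is zero with positive grains/spike at ",
         .plot_label(out, bad[1]))
  gpsl <- gps / sps
  gset <- gps / ff
  zero <- !is.na(gps) & gps == 0   # zero numerator: ratio defined as 0
  gpsl[zero] <- 0
  gset[zero & !is.na(ff)] <- 0
  out$grains_per_spikelet <- gpsl
  out$grain_setting <- gset
  out$days_ef <- as.integer(out$date_flowering - out$date_emergence)
  out$days_fm <- as.integer(out$date_maturity - out$date_flowering)
  out
}

#' Entity x environment cell-mean matrix
#'
#' Builds the complete two-way means table feeding the stability indices:
#' cell (i, j) is the arithmetic mean over blocks (and over member genotypes
#' when `entity_level = "allele_combination"`) of the trait in environment j.
#' Environments are the site-year pairs, identified as `"SITE-YEAR"`.
#'
#' @param plots plot record data frame (run [derive_traits()] first for
#'   derived traits).
#' @param entity_level `"genotype"` or `"allele_combination"`.
#' @param trait trait column name.
#' @param genotypes genotype metadata; required for the allele-combination
#'   level (excluded combinations are dropped).
#' @param strict when `TRUE` (default) any cell with fewer observations than
#'   the modal count is an error; when `FALSE`, available-count means are used.
#'   Empty cells are always an error.
#' @return object of class `two_way_means`: list with `values` and `counts`
#'   matrices (entities x environments), `entity_ids`, `environment_ids`,
#'   `trait`, `entity_level`.
#' @export
cell_means <- function(plots, entity_level = c("genotype", "allele_combination"),
                       trait, genotypes = NULL, strict = TRUE) {
  entity_level <- match.arg(entity_level)
  if (!trait %in% names(plots)) stop("trait column not found: ", trait)
  if (entity_level == "allele_combination") {
    if (is.null(genotypes))
      stop("genotype metadata required at allele_combination level")
    keep <- genotypes[!genotypes$excluded, ]
    idx <- match(plots$genotype, keep$genotype)
    plots <- plots[!is.na(idx), ]
    entity <- keep$allele_combination[idx[!is.na(idx)]]
  } else {
    entity <- plots$genotype
  }
  env <- .env_id(plots$site, plots$year)
  y <- plots[[trait]]
  ok <- !is.na(y)
  entity <- factor(entity[ok], levels = sort(unique(entity)))
  env <- factor(env[ok], levels = sort(unique(env)))
  y <- y[ok]
  values <- tapply(y, list(entity, env), mean)
  counts <- table(entity, env)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(values))
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)
    pairs <- apply(empty, 1, function(ij)
      paste0("(", rownames(values)[ij[1]], ", ", colnames(values)[ij[2]], ")"))
    stop("empty cells in ", entity_level, " x environment table: ",
         paste(pairs, collapse = ", "))
  }
  if (strict) {
    # strict balance: within each entity, every environment must contribute
    # the same number of plots
    rng <- apply(counts, 1, function(r) diff(range(r)))
    if (any(rng > 0)) {
      bad <- rownames(counts)[which(rng > 0)[1]]
      stop("unbalanced cell counts for entity ", bad,
           " (use strict = FALSE for available-count means)")
    }
  }
  structure(list(values = values, counts = counts,
                 entity_ids = rownames(values),
                 environment_ids = colnames(values),
                 trait = trait, entity_level = entity_level),
            class = "two_way_means")
}

#' @export
print.two_way_means <- function(x, ...) {
  cat("Two-way cell means (", x$entity_level, " x environment) for trait ",
      x$trait, ": ", nrow(x$values), " x ", ncol(x$values), "\n", sep = "")
  print(round(x$values, 2))
  invisible(x)
}
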