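# Synthetic multi-environment trial generator with known ground truth.
# Emulates a 3-site x 5-year x 23-genotype randomised complete block design
# (3 blocks) with photoperiod allele-combination flowering shifts of up to
# 9 days, within-combination earliness-per-se variation, a negative
# flowering-time -> grain-weight association, grain number / grain weight
# compensation, and per-genotype environment-responsiveness so that true
# joint-regression slopes are known.

.default_sites <- function() {
  data.frame(
    site = c("Spain", "Mexico-North", "Mexico-South"),
    latitude_deg = c(41.63, 27.35, 19.52),
    sowing_month = c(11L, 12L, 5L),
    sowing_day = c(25L, 5L, 20L),
    sown_previous_year = c(TRUE, TRUE, FALSE),  # autumn vs spring planting
    base_days_flowering = c(160, 110, 75),
    grain_fill_days = c(38, 45, 38),
    emergence_days = c(12L, 12L, 10L),
    stringsAsFactors = FALSE)
}

.default_weather_params <- function() {
  data.frame(
    site = c("Spain", "Mexico-North", "Mexico-South"),
    tmean_annual = c(14, 22, 16),
    tmean_amplitude = c(8, 7, 3),
    tmean_phase_doy = c(110, 110, 110),  # sinusoid peaks ~day 201 (late July)
    half_range = c(6, 7, 6),
    ar1_rho = c(0.7, 0.7, 0.7),
    ar1_sd = c(1.5, 1.5, 1.5),
    rad_scale = c(16, 20, 18),
    cloud_sd = c(0.15, 0.10, 0.20),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Assembles the full configuration of the synthetic trial.  Defaults state
#' the emulated design: 3 sites at latitudes 41.63 / 27.35 / 19.52 degrees N,
#' years 2007, 2008, 2010, 2011, 2012, the 24-genotype roster of
#' [default_genotypes()] (23 retained), 3 blocks, allele-combination flowering
#' shifts spanning 9 days (I0I 0 ... SI +9), within-combination
#' earliness-per-se SD of 3 days, grain weight declining 0.5 mg per day of
#' flowering delay, and a grain number / grain weight compensation
#' coefficient of 0.4.
#'
#' @param seed master RNG seed (integer); all randomness derives from it.
#' @param sites per-site data frame (latitude, sowing rule, base phenology).
#' @param years trial years.
#' @param genotypes genotype metadata roster.
#' @param n_blocks blocks per experiment (default 3).
#' @param include_excluded simulate genotypes of excluded (singleton) allele
#'   combinations too (default FALSE, giving 23 genotypes).
#' @param ac_flowering_effect named days added to flowering per combination.
#' @param sigma_eps_days SD of the per-genotype earliness-per-se shift (days).
#' @param sigma_flower_year,sigma_flower_plot year and plot flowering noise SD
#'   (days).
#' @param grain_fill_sd per-plot grain filling duration noise SD (days).
#' @param gw_base baseline grain weight (mg/grain).
#' @param gw_per_day_late grain weight change per day of flowering delay
#'   (mg/day; negative).
#' @param sigma_gw_genotype,sigma_gw_block,sigma_gw_plot grain weight effect
#'   SDs (mg).
#' @param gn_base baseline grain number (grains/m2).
#' @param gn_ac_effect named grain number shift per allele combination.
#' @param gn_gw_compensation unitless compensation coefficient: a genotype
#'   whose grain weight sits d mg above baseline loses
#'   `gn_gw_compensation * (d / gw_base) * gn_base` grains/m2.
#' @param sigma_gn_genotype,sigma_gn_block,sigma_gn_plot grain number SDs.
#' @param sigma_gy_block,sigma_gy_plot residual yield SDs (g/m2).
#' @param slope_sd SD of the per-genotype environment-sensitivity multiplier
#'   around 1 (drives true joint-regression slopes).
#' @param env_quality named per-site mean of the shared environment quality
#'   term added to yield (g/m2).
#' @param sigma_env_quality SD of the per-experiment quality deviation (g/m2).
#' @param stage_years years in which double ridge / terminal spikelet /
#'   heading are recorded (3 of the 5 years).
#' @param spike_years years in which spike components are sampled.
#' @param weather per-site weather generator parameters.
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(seed = 1L,
                       sites = .default_sites(),
                       years = c(2007L, 2008L, 2010L, 2011L, 2012L),
                       genotypes = default_genotypes(),
                       n_blocks = 3L,
                       include_excluded = FALSE,
                       ac_flowering_effect = c(I0I = 0, I0S = 1, I5I = 2,
                                               I5S = 5, SS = 7, SI = 9),
                       sigma_eps_days = 3,
                       sigma_flower_year = 2,
                       sigma_flower_plot = 1.5,
                       grain_fill_sd = 2,
                       gw_base = 40,
                       gw_per_day_late = -0.5,
                       sigma_gw_genotype = 4,
                       sigma_gw_block = 0.5,
                       sigma_gw_plot = 1.5,
                       gn_base = 15000,
                       gn_ac_effect = c(I0I = 0, I0S = 0, I5I = 0, I5S = 1500,
                                        SS = 800, SI = 0),
                       gn_gw_compensation = 0.4,
                       sigma_gn_genotype = 800,
                       sigma_gn_block = 250,
                       sigma_gn_plot = 600,
                       sigma_gy_block = 15,
                       sigma_gy_plot = 20,
                       slope_sd = 0.12,
                       env_quality = c(Spain = 150, `Mexico-North` = 50,
                                       `Mexico-South` = -200),
                       sigma_env_quality = 60,
                       stage_years = c(2010L, 2011L, 2012L),
                       spike_years = c(2010L, 2011L, 2012L),
                       weather = .default_weather_params()) {
  cfg <- as.list(environment())
  sds <- cfg[grep("^sigma_|_sd$", names(cfg))]
  if (any(unlist(sds) < 0)) stop("all SDs must be >= 0")
  if (!all(cfg$sites$site %in% cfg$weather$site))
    stop("weather parameters missing for some site")
  if (!all(unique(genotype_meta(cfg$genotypes)$allele_combination) %in%
           names(cfg$ac_flowering_effect)))
    stop("ac_flowering_effect must name every allele combination in roster")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# per-experiment RNG stream derived from the master seed and (site, year),
# so adding an experiment never perturbs the others
.exp_seed <- function(seed, site, year, offset = 0L) {
  h <- sum(utf8ToInt(site)) * 1013L + as.integer(year) * 17L
  (as.integer(seed) * 7919L + h + offset) %% 2147483647L
}

#' Experiment metadata implied by a simulation configuration
#' @param config a [sim_config()].
#' @return data frame site, year, latitude_deg, sowing_date, ordered by site
#'   then year.
#' @export
sim_experiments <- function(config) {
  s <- config$sites
  ex <- expand.grid(site = s$site, year = config$years,
                    stringsAsFactors = FALSE)
  ex <- ex[order(ex$site, ex$year), ]
  i <- match(ex$site, s$site)
  sow_year <- ifelse(s$sown_previous_year[i], ex$year - 1L, ex$year)
  ex$latitude_deg <- s$latitude_deg[i]
  ex$sowing_date <- as.Date(sprintf("%d-%02d-%02d", sow_year,
                                    s$sowing_month[i], s$sowing_day[i]))
  rownames(ex) <- NULL
  ex
}

#' Simulate one site-year's daily weather
#'
#' Daily mean temperature is an annual sinusoid plus AR(1) noise; daily max
#' and min are the mean plus/minus a fixed half-range; radiation is a
#' clear-sky scale times a day-length-driven seasonal factor times a cloud
#' attenuation, truncated at zero.  Deterministic given the configuration
#' seed and the experiment identity.
#'
#' @param config a [sim_config()].
#' @param experiment one-row data frame with `site`, `year`, `latitude_deg`,
#'   `sowing_date` (see [sim_experiments()]).
#' @return daily weather data frame covering sowing - 10 to sowing + 340 days.
#' @export
simulate_weather <- function(config, experiment) {
  wp <- config$weather[config$weather$site == experiment$site, ]
  if (nrow(wp) != 1) stop("no weather parameters for site ", experiment$site)
  set.seed(.exp_seed(config$seed, experiment$site, experiment$year))
  dates <- seq(experiment$sowing_date - 10, experiment$sowing_date + 340,
               by = "day")
  n <- length(dates)
  doy <- .doy(dates)
  e <- numeric(n)
  innov <- stats::rnorm(n, 0, wp$ar1_sd)
  for (t in seq_len(n))
    e[t] <- if (t == 1) innov[1] else wp$ar1_rho * e[t - 1] + innov[t]
  tmean <- wp$tmean_annual +
    wp$tmean_amplitude * sin(2 * pi * (doy - wp$tmean_phase_doy) / 365) + e
  cloud <- pmin(abs(stats::rnorm(n, 0, wp$cloud_sd)), 0.6)
  rad <- pmax(wp$rad_scale * (day_length(experiment$latitude_deg, doy, 0) / 12) *
                (1 - cloud), 0)
  data.frame(site = experiment$site, year = experiment$year, date = dates,
             tmin_c = tmean - wp$half_range, tmax_c = tmean + wp$half_range,
             tmean_c = tmean, rad_mj_m2 = rad, stringsAsFactors = FALSE)
}

#' Simulate a complete multi-environment trial
#'
#' Generates plot records, daily weather and the ground truth for the whole
#' design.  Flowering time is built additively in days (site baseline +
#' allele-combination shift + per-genotype earliness-per-se shift + year
#' effect + plot noise, rounded to whole days); grain weight declines with
#' flowering delay; grain number carries combination effects and compensates
#' genotype grain-weight deviations; yield adds a per-genotype
#' sensitivity-scaled shared environment-quality term so that true
#' joint-regression slopes are known; grain number is then derived as
#' 1000*GY/GW, its definitional identity.  Blocks add shared offsets within a
#' site-year.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_trial`: list with `plots`, `weather`,
#'   `experiments`, `genotypes` and `truth` (per-genotype earliness-per-se
#'   shifts, effect sizes, variance components, true slopes, per-experiment
#'   quality).
#' @export
simulate_trial <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  geno <- genotype_meta(config$genotypes)
  if (!config$include_excluded) geno_used <- geno[!geno$excluded, ]
  else geno_used <- geno
  ng <- nrow(geno_used)

  # genotype-level truth from the master seed (fixed roster order)
  set.seed(config$seed)
  eps <- stats::rnorm(nrow(geno), 0, config$sigma_eps_days)
  gw_eff <- stats::rnorm(nrow(geno), 0, config$sigma_gw_genotype)
  gn_eff <- stats::rnorm(nrow(geno), 0, config$sigma_gn_genotype)
  s_raw <- pmin(pmax(1 + stats::rnorm(nrow(geno), 0, config$slope_sd),
                     0.6), 1.4)
  used <- geno$genotype %in% geno_used$genotype
  sens <- s_raw / mean(s_raw[used])   # true FW slopes average 1 over roster
  names(eps) <- names(gw_eff) <- names(gn_eff) <- names(sens) <- geno$genotype

  exps <- sim_experiments(config)
  sites <- config$sites
  ac_used <- geno_used$allele_combination
  # expected site mean flowering (baseline + roster-average AC shift)
  ac_mean_shift <- mean(config$ac_flowering_effect[ac_used])

  wx_list <- vector("list", nrow(exps))
  plot_list <- vector("list", nrow(exps))
  q_all <- numeric(nrow(exps))
  n_clipped <- 0L
  for (k in seq_len(nrow(exps))) {
    ex <- exps[k, ]
    wx_list[[k]] <- simulate_weather(config, ex)
    st <- sites[sites$site == ex$site, ]
    set.seed(.exp_seed(config$seed, ex$site, ex$year, offset = 1L))
    year_fl <- stats::rnorm(1, 0, config$sigma_flower_year)
    q <- config$env_quality[[ex$site]] +
      stats::rnorm(1, 0, config$sigma_env_quality)
    q_all[k] <- q
    nb <- config$n_blocks
    blk_gw <- stats::rnorm(nb, 0, config$sigma_gw_block)
    blk_gn <- stats::rnorm(nb, 0, config$sigma_gn_block)
    blk_gy <- stats::rnorm(nb, 0, config$sigma_gy_block)
    idx <- expand.grid(g = seq_len(ng), b = seq_len(nb))
    np <- nrow(idx)
    fl_noise <- stats::rnorm(np, 0, config$sigma_flower_plot)
    fill_noise <- stats::rnorm(np, 0, config$grain_fill_sd)
    gw_noise <- stats::rnorm(np, 0, config$sigma_gw_plot)
    gn_noise <- stats::rnorm(np, 0, config$sigma_gn_plot)
    gy_noise <- stats::rnorm(np, 0, config$sigma_gy_plot)
    gid <- geno_used$genotype[idx$g]
    ac <- geno_used$allele_combination[idx$g]

    fl_days <- round(st$base_days_flowering +
                       config$ac_flowering_effect[ac] + eps[gid] + year_fl +
                       fl_noise)
    emergence <- ex$sowing_date + st$emergence_days
    flowering <- emergence + fl_days
    maturity <- flowering + round(st$grain_fill_days + fill_noise)
    fl_dev <- fl_days - (st$base_days_flowering + ac_mean_shift)
    gw <- config$gw_base + config$gw_per_day_late * fl_dev + gw_eff[gid] +
      blk_gw[idx$b] + gw_noise
    # genotype-expected grain weight (photoperiod + earliness-per-se shifts
    # only): feeding this, not the realised gw, into yield keeps the shared
    # environment term out of the genotype x environment structure, so the
    # recorded true joint-regression slopes are exact
    gw_geno <- config$gw_base + config$gw_per_day_late *
      (config$ac_flowering_effect[ac] + eps[gid] - ac_mean_shift) +
      gw_eff[gid]
    gn_core <- config$gn_base + config$gn_ac_effect[ac] + gn_eff[gid] -
      config$gn_gw_compensation * (gw_eff[gid] / config$gw_base) *
        config$gn_base + blk_gn[idx$b] + gn_noise
    # negative draws: reflect once about the positive mean, then clip (logged)
    for (v in c("gw", "gn_core")) {
      x <- get(v)
      bad <- which(x <= 0)
      if (length(bad)) {
        x[bad] <- abs(2 * mean(x[-bad]) - x[bad])
        x[x <= 0] <- 1e-3
        n_clipped <- n_clipped + length(bad)
        assign(v, x)
      }
    }
    gy <- gn_core * gw_geno / 1000 + sens[gid] * q + blk_gy[idx$b] + gy_noise
    bad <- which(gy <= 0)
    if (length(bad)) {
      gy[bad] <- abs(2 * mean(gy[-bad]) - gy[bad])
      gy[gy <= 0] <- 1e-3
      n_clipped <- n_clipped + length(bad)
    }

    pl <- data.frame(site = ex$site, year = ex$year, block = idx$b,
                     genotype = gid,
                     date_emergence = emergence,
                     date_double_ridge = as.Date(NA),
                     date_terminal_spikelet = as.Date(NA),
                     date_heading = as.Date(NA),
                     date_flowering = flowering,
                     date_maturity = maturity,
                     gy_g_m2 = gy, gw_mg = gw,
                     spikes_m2 = NA_real_, grains_per_spike = NA_real_,
                     spikelets_per_spike = NA_real_,
                     fertile_florets_per_spike = NA_real_,
                     stringsAsFactors = FALSE)
    if (ex$year %in% config$stage_years) {
      pl$date_double_ridge <- emergence + round(0.45 * fl_days)
      pl$date_terminal_spikelet <- emergence + round(0.62 * fl_days)
      pl$date_heading <- flowering - 5
    }
    if (ex$year %in% config$spike_years) {
      spikes <- pmax(stats::rnorm(np, 450, 35), 50)
      gn_stored <- 1000 * pl$gy_g_m2 / pl$gw_mg
      pl$spikes_m2 <- spikes
      pl$grains_per_spike <- gn_stored / spikes
      pl$spikelets_per_spike <- pmax(12 + 0.04 * fl_days +
                                       stats::rnorm(np, 0, 0.8), 5)
      if (ex$site == "Spain")
        pl$fertile_florets_per_spike <-
          pl$grains_per_spike / pmin(pmax(stats::rnorm(np, 0.78, 0.04),
                                          0.5), 0.95)
    }
    plot_list[[k]] <- pl
  }
  if (n_clipped > 0)
    warning(n_clipped, " negative generated values resampled/clipped")

  truth <- list(
    genotype = data.frame(
      genotype = geno$genotype,
      allele_combination = geno$allele_combination,
      included = used,
      eps_days = unname(eps),
      gw_effect_mg = unname(gw_eff),
      gn_effect_m2 = unname(gn_eff),
      true_slope = unname(sens),
      stringsAsFactors = FALSE),
    ac_flowering_effect = as.list(config$ac_flowering_effect),
    gn_ac_effect = as.list(config$gn_ac_effect),
    gw_per_day_late = config$gw_per_day_late,
    gn_gw_compensation = config$gn_gw_compensation,
    variance_components = list(
      sigma2_eps_days = config$sigma_eps_days^2,
      sigma2_flower_plot = config$sigma_flower_plot^2,
      sigma2_gw_genotype = config$sigma_gw_genotype^2,
      sigma2_gw_plot = config$sigma_gw_plot^2,
      sigma2_gy_plot = config$sigma_gy_plot^2),
    environment = data.frame(site = exps$site, year = exps$year,
                             quality = q_all, stringsAsFactors = FALSE),
    seed = config$seed)

  structure(list(plots = do.call(rbind, plot_list),
                 weather = do.call(rbind, wx_list),
                 experiments = exps,
                 genotypes = geno,
                 truth = truth),
            class = "sim_trial")
}

#' Write all simulation outputs to a directory
#'
#' Emits `plots.csv`, `genotypes.csv`, `weather.csv`, `experiments.csv` and
#' `truth.json` (the ground truth, for scoring recovery).
#'
#' @param sim a [simulate_trial()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plot_table(sim$plots, file.path(dir, "plots.csv"))
  write_genotype_table(sim$genotypes, file.path(dir, "genotypes.csv"))
  write_weather_table(sim$weather, file.path(dir, "weather.csv"))
  write_experiment_table(sim$experiments, file.path(dir, "experiments.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
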