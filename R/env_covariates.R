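# Phenology-windowed environmental covariates: day length including twilight
# (CBM model), photo-thermal units, and temperature/radiation aggregates over
# developmental windows.  All windows are closed intervals including both
# stage dates, so a one-day window is never empty.

.covariate_cols <- c("tmean_ef", "tmean_fm", "tmax_f", "rmean_ef", "rmean_drf",
                     "rmean_fm", "rac_ef", "dlmean_ef", "dlmean_fm", "ptu_tsf")

#' Day length including twilight (CBM model)
#'
#' Photoperiod in hours for a latitude and day of year under the CBM
#' (Forsythe-style) model.  The tunable `daylength_coef_deg` is the solar
#' depression angle below the horizon at which the day is considered to start
#' and end; 0 gives sunrise/sunset day length, the default 6 includes civil
#' twilight.
#'
#' The model is
#' \deqn{\theta = 0.2163108 + 2\,\mathrm{atan}(0.9671396\,\tan(0.00860(J-186)))}
#' \deqn{\phi = \mathrm{asin}(0.39795 \cos\theta)}
#' \deqn{D = 24 - \frac{24}{\pi}\,\mathrm{acos}\!\left[\frac{\sin(p\pi/180) +
#'   \sin(L\pi/180)\sin\phi}{\cos(L\pi/180)\cos\phi}\right]}
#' with the acos argument clamped to \[-1, 1\] (continuous day or night; a
#' warning is raised when clamping triggers, which happens only beyond about
#' 66 degrees of latitude for the default coefficient).
#'
#' @param latitude_deg latitude in signed decimal degrees.
#' @param day_of_year integer day of year, 1..366.
#' @param daylength_coef_deg twilight coefficient p in degrees (default 6,
#'   civil twilight).
#' @return day length in hours (vectorised over the inputs).
#' @examples
#' day_length(0, 80, 0)        # equator, no twilight: exactly 12 h
#' day_length(41.63, 172, 6)   # Lleida around the June solstice
#' @export
day_length <- function(latitude_deg, day_of_year, daylength_coef_deg = 6) {
  if (any(day_of_year < 1 | day_of_year > 366))
    stop("day_of_year must be in 1..366")
  theta <- 0.2163108 +
    2 * atan(0.9671396 * tan(0.00860 * (day_of_year - 186)))
  phi <- asin(0.39795 * cos(theta))
  L <- latitude_deg * pi / 180
  p <- daylength_coef_deg * pi / 180
  a <- (sin(p) + sin(L) * sin(phi)) / (cos(L) * cos(phi))
  if (any(a < -1 | a > 1))
    warning("day length saturated (continuous day or night) at |latitude| = ",
            max(abs(latitude_deg)))
  a <- pmin(pmax(a, -1), 1)
  24 - (24 / pi) * acos(a)
}

.doy <- function(date) as.integer(format(date, "%j"))

# closed-interval slice of one site-year's weather; hard error on gaps
.wx_window <- function(wx, start_date, end_date, what = "window") {
  days <- seq(start_date, end_date, by = "day")
  idx <- match(days, wx$date)
  if (anyNA(idx))
    stop("weather series does not cover ", what, " ",
         format(start_date), "..", format(end_date),
         " (first missing date: ", format(days[which(is.na(idx))[1]]), ")")
  wx[idx, , drop = FALSE]
}

#' Photo-thermal units over a phenology window
#'
#' Accumulated product of daily thermal forcing above a base temperature and
#' day length: \eqn{\sum_d \max(T_{mean,d} - T_{base}, 0) \times DL(L, d, p)}
#' in degree-Celsius hours, over the closed window from `start_date` to
#' `end_date`.
#'
#' @param weather daily weather data frame for one site-year (columns `date`,
#'   `tmean_c`).
#' @param start_date,end_date window endpoints (both included).
#' @param latitude_deg site latitude.
#' @param t_base base temperature in degrees C (default 0).
#' @param daylength_coef_deg twilight coefficient (default 6).
#' @return photo-thermal units in degree-C hours.
#' @export
photothermal_units <- function(weather, start_date, end_date, latitude_deg,
                               t_base = 0, daylength_coef_deg = 6) {
  w <- .wx_window(weather, start_date, end_date, "photo-thermal window")
  dl <- day_length(latitude_deg, .doy(w$date), daylength_coef_deg)
  sum(pmax(w$tmean_c - t_base, 0) * dl)
}

#' Per-plot environmental covariates from phenology windows
#'
#' Computes, for every plot, the covariates characterising the environment it
#' experienced: mean temperature emergence-flowering (`tmean_ef`) and
#' flowering-maturity (`tmean_fm`); mean daily maximum temperature over the 11
#' days centred on flowering (`tmax_f`); mean daily solar radiation
#' emergence-flowering (`rmean_ef`), double ridge-flowering (`rmean_drf`) and
#' flowering-maturity (`rmean_fm`); accumulated radiation emergence-flowering
#' (`rac_ef`); mean day length emergence-flowering (`dlmean_ef`) and
#' flowering-maturity (`dlmean_fm`); and photo-thermal units terminal
#' spikelet-flowering (`ptu_tsf`).  Covariates whose stage dates are absent
#' are returned as `NA`, never imputed.
#'
#' @param plots plot record data frame.
#' @param weather daily weather data frame covering every referenced window.
#' @param experiments experiment metadata (latitudes).
#' @param t_base base temperature for photo-thermal units (default 0).
#' @param daylength_coef_deg twilight coefficient (default 6).
#' @return data frame: plot keys (site, year, block, genotype) plus the ten
#'   covariate columns.
#' @export
window_aggregates <- function(plots, weather, experiments, t_base = 0,
                              daylength_coef_deg = 6) {
  wx_by_env <- split(weather, .env_id(weather$site, weather$year))
  lat <- experiments$latitude_deg[
    match(.env_id(plots$site, plots$year),
          .env_id(experiments$site, experiments$year))]
  if (anyNA(lat))
    stop("experiments table lacks latitude for some plot site-years")
  n <- nrow(plots)
  out <- plots[c("site", "year", "block", "genotype")]
  for (cc in .covariate_cols) out[[cc]] <- NA_real_
  for (i in seq_len(n)) {
    wx <- wx_by_env[[.env_id(plots$site[i], plots$year[i])]]
    if (is.null(wx))
      stop("no weather series for ", .env_id(plots$site[i], plots$year[i]))
    em <- plots$date_emergence[i]; fl <- plots$date_flowering[i]
    ma <- plots$date_maturity[i]; dr <- plots$date_double_ridge[i]
    ts <- plots$date_terminal_spikelet[i]
    if (!is.na(em) && !is.na(fl)) {
      w <- .wx_window(wx, em, fl, "emergence-flowering")
      out$tmean_ef[i] <- mean(w$tmean_c)
      out$rmean_ef[i] <- mean(w$rad_mj_m2)
      out$rac_ef[i] <- sum(w$rad_mj_m2)
      out$dlmean_ef[i] <-
        mean(day_length(lat[i], .doy(w$date), daylength_coef_deg))
    }
    if (!is.na(fl) && !is.na(ma)) {
      w <- .wx_window(wx, fl, ma, "flowering-maturity")
      out$tmean_fm[i] <- mean(w$tmean_c)
      out$rmean_fm[i] <- mean(w$rad_mj_m2)
      out$dlmean_fm[i] <-
        mean(day_length(lat[i], .doy(w$date), daylength_coef_deg))
    }
    if (!is.na(fl)) {
      w <- .wx_window(wx, fl - 5, fl + 5, "flowering +/- 5 days")
      out$tmax_f[i] <- mean(w$tmax_c)
    }
    if (!is.na(dr) && !is.na(fl)) {
      w <- .wx_window(wx, dr, fl, "double ridge-flowering")
      out$rmean_drf[i] <- mean(w$rad_mj_m2)
    }
    if (!is.na(ts) && !is.na(fl)) {
      out$ptu_tsf[i] <- photothermal_units(wx, ts, fl, lat[i], t_base,
                                           daylength_coef_deg)
    }
  }
  out
}
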