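#' Weather generator configuration
#'
#' Parameters of the stochastic daily forcing generator. The generator
#' produces a 365-day (no leap) calendar with a sinusoidal seasonal cycle
#' peaking in mid-July, AR(1) day-to-day temperature persistence, and
#' summer "blocking" episodes: persistent anticyclonic spells that add
#' warmth, depress humidity, suppress rain and raise clear-sky shortwave —
#' the synoptic ingredient that lets multi-day exceedance runs form.
#'
#' @param n_years Number of simulated years.
#' @param latitude_band One of `"temperate"`, `"boreal"`, `"tundra"`; sets
#'   the default seasonal amplitude when `seasonal_amplitude` is `NULL`.
#' @param mean_annual_tmax Annual mean of daily maximum temperature (C).
#' @param seasonal_amplitude Half-range of the seasonal tmax cycle (C).
#' @param ar1_coefficient Lag-1 autocorrelation of the tmax anomaly, in
#'   `[0, 1)`.
#' @param daily_noise_sd Standard deviation of the AR(1) innovations (C).
#' @param blocking_rate Expected number of blocking episodes per summer
#'   (JJA).
#' @param blocking_duration_mean Mean episode duration (days, >= 1).
#' @param blocking_warming Temperature added during an episode (C).
#' @param blocking_sw_bonus Clear-sky shortwave added during an episode
#'   (W m-2).
#' @param blocking_rh_drop Relative humidity depression during an episode
#'   (percentage points).
#' @param precip_mean Mean precipitation (mm day-1).
#' @param wet_day_prob Probability a day is wet.
#' @param rh_base Baseline daytime relative humidity (%).
#' @param rh_anomaly_slope Humidity response to the temperature anomaly
#'   (% per C); positive values dry the air on warm days.
#' @param sw_mean,sw_amplitude Mean and seasonal half-range of daily
#'   shortwave (W m-2).
#' @param diurnal_range Mean tmax - tmin (C).
#' @param warming_trend Linear trend added to tmax (C per decade); use for
#'   transient-climate experiments.
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate bit-identical forcing.
#' @return An object of class `weather_config`.
#' @export
weather_config <- function(n_years = 30,
                           latitude_band = c("boreal", "temperate",
                                             "tundra"),
                           mean_annual_tmax = 8,
                           seasonal_amplitude = NULL,
                           ar1_coefficient = 0.7,
                           daily_noise_sd = 2.2,
                           blocking_rate = 1.2,
                           blocking_duration_mean = 6,
                           blocking_warming = 4,
                           blocking_sw_bonus = 60,
                           blocking_rh_drop = 8,
                           precip_mean = 2.2,
                           wet_day_prob = 0.35,
                           rh_base = 70,
                           rh_anomaly_slope = 2,
                           sw_mean = 180,
                           sw_amplitude = 110,
                           diurnal_range = 10,
                           warming_trend = 0,
                           seed = 1L) {
  latitude_band <- match.arg(latitude_band)
  if (is.null(seasonal_amplitude)) {
    seasonal_amplitude <- switch(latitude_band,
                                 tundra = 16, boreal = 15, temperate = 11)
  }
  cfg <- list(
    n_years = as.integer(n_years), latitude_band = latitude_band,
    mean_annual_tmax = mean_annual_tmax,
    seasonal_amplitude = seasonal_amplitude,
    ar1_coefficient = ar1_coefficient, daily_noise_sd = daily_noise_sd,
    blocking_rate = blocking_rate,
    blocking_duration_mean = blocking_duration_mean,
    blocking_warming = blocking_warming,
    blocking_sw_bonus = blocking_sw_bonus,
    blocking_rh_drop = blocking_rh_drop,
    precip_mean = precip_mean, wet_day_prob = wet_day_prob,
    rh_base = rh_base, rh_anomaly_slope = rh_anomaly_slope,
    sw_mean = sw_mean, sw_amplitude = sw_amplitude,
    diurnal_range = diurnal_range, warming_trend = warming_trend,
    seed = as.integer(seed)
  )
  num <- vapply(cfg[!(names(cfg) %in% c("latitude_band"))], is.numeric,
                logical(1))
  vals <- unlist(cfg[names(num)[num]])
  if (!all(is.finite(vals))) {
    stop("weather_config values must be finite", call. = FALSE)
  }
  if (cfg$ar1_coefficient < 0 || cfg$ar1_coefficient >= 1) {
    stop("'ar1_coefficient' must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$daily_noise_sd < 0 || cfg$blocking_duration_mean < 1 ||
      cfg$n_years < 1) {
    stop("invalid weather_config: SDs must be >= 0, durations >= 1",
         call. = FALSE)
  }
  structure(cfg, class = "weather_config")
}

# Deterministic seasonal tmax cycle, peaking on day 196 (mid-July).
seasonal_tmax <- function(doy, cfg) {
  cfg$mean_annual_tmax +
    cfg$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365)
}

#' Generate daily meteorological forcing
#'
#' Simulates `n_years` of daily weather on a 365-day calendar:
#' `tmax = seasonal cycle + warming trend + AR(1) anomaly + blocking`.
#' Midday vapour pressure deficit is derived from `tmax` through a
#' Magnus-type saturation vapour pressure and a relative humidity that
#' decreases with the temperature anomaly (warm anomalies are dry).
#' Blocking episodes arrive as a Poisson count per summer with geometric
#' durations; while one is active, tmax and shortwave are elevated,
#' humidity is depressed and rain is suppressed.
#'
#' Blocking episodes are drawn from an RNG stream seeded independently of
#' the base weather (from `seed + 101`), so switching blocking off (or
#' rescaling its warming) leaves the underlying weather untouched — the
#' paired-comparison property the tests rely on.
#'
#' @param config A [weather_config()].
#' @return A data frame (class `daily_forcing`) with one row per day:
#'   `year`, `doy`, `date` (ISO string, nominal years starting at 2001),
#'   `tmax`, `tmin` (C), `shortwave` (W m-2), `vpd_midday` (kPa),
#'   `precip` (mm day-1), `blocked` (logical).
#' @export
#' @examples
#' f <- generate_forcing(weather_config(n_years = 2, seed = 42))
#' head(f)
generate_forcing <- function(config) {
  stopifnot(inherits(config, "weather_config"))
  cfg <- config
  n_days <- cfg$n_years * 365L
  doy <- rep(1:365, cfg$n_years)
  year <- rep(seq_len(cfg$n_years), each = 365L)

  base <- with_seed(cfg$seed, {
    # AR(1) anomaly initialised from the stationary distribution.
    phi <- cfg$ar1_coefficient
    innov <- rnorm(n_days, 0, cfg$daily_noise_sd)
    a0 <- rnorm(1, 0, cfg$daily_noise_sd / sqrt(1 - phi^2))
    anom <- if (phi > 0) {
      as.numeric(stats::filter(innov, phi, method = "recursive", init = a0))
    } else {
      innov
    }
    rh_noise <- rnorm(n_days, 0, 7)
    wet <- runif(n_days) < cfg$wet_day_prob
    amount <- rexp(n_days,
                   rate = cfg$wet_day_prob / max(cfg$precip_mean, 1e-12))
    dtr_noise <- rnorm(n_days, 0, 1.5)
    list(anom = anom, rh_noise = rh_noise, wet = wet, amount = amount,
         dtr_noise = dtr_noise)
  })

  blocked <- with_seed(cfg$seed + 101L, {
    b <- logical(n_days)
    if (cfg$blocking_rate > 0) {
      for (y in seq_len(cfg$n_years)) {
        n_ep <- stats::rpois(1, cfg$blocking_rate)
        if (n_ep > 0) {
          starts <- sample(JJA_START:JJA_END, n_ep, replace = TRUE)
          durs <- stats::rgeom(n_ep, 1 / cfg$blocking_duration_mean) + 1L
          for (k in seq_len(n_ep)) {
            idx <- (y - 1L) * 365L + seq(starts[k],
                                         min(starts[k] + durs[k] - 1L, 365L))
            b[idx] <- TRUE
          }
        }
      }
    }
    b
  })

  trend <- cfg$warming_trend * (year - 1) / 10
  tmax <- seasonal_tmax(doy, cfg) + trend + base$anom +
    ifelse(blocked, cfg$blocking_warming, 0)
  tmin <- tmax - pmax(cfg$diurnal_range + base$dtr_noise, 1)

  sw_season <- cfg$sw_mean + cfg$sw_amplitude * cos(2 * pi * (doy - 172) / 365)
  shortwave <- pmax(sw_season + ifelse(blocked, cfg$blocking_sw_bonus, 0) -
                      ifelse(base$wet & !blocked, 40, 0), 10)

  rh <- cfg$rh_base - cfg$rh_anomaly_slope * (base$anom +
          ifelse(blocked, cfg$blocking_warming, 0)) + base$rh_noise -
        ifelse(blocked, cfg$blocking_rh_drop, 0)
  rh <- pmin(pmax(rh, 15), 98)
  vpd_midday <- pmax(saturation_vp(tmax) * (1 - rh / 100), 0.05)

  precip <- ifelse(base$wet & !blocked, base$amount, 0)

  out <- data.frame(
    year = year, doy = doy,
    date = sprintf("%04d-%02d-%02d", 2000L + year, doy_to_month(doy),
                   doy - MONTH_START[doy_to_month(doy)] + 1L),
    tmax = tmax, tmin = tmin, shortwave = shortwave,
    vpd_midday = vpd_midday, precip = precip, blocked = blocked
  )
  class(out) <- c("daily_forcing", "data.frame")
  out
}

#' Write or read daily forcing as delimited text
#'
#' @param forcing A forcing data frame from [generate_forcing()].
#' @param path File path.
#' @return `read_forcing()` returns the forcing data frame.
#' @export
write_forcing <- function(forcing, path) {
  utils::write.csv(forcing, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("daily_forcing", "data.frame")
  out
}
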