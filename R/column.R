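# Physical constants for the surface energy balance.
RHO_CP <- 1204.8      # volumetric heat capacity of air (J m-3 K-1)
LAMBDA_V <- 2.45e6    # latent heat of vaporisation (J kg-1)
PSYCHRO <- 0.066      # psychrometric constant (kPa K-1)
MOL_TO_MS <- 0.0245   # mol m-2 s-1 -> m s-1 conductance at ~25 C, 101 kPa

#' Land-surface column configuration
#'
#' A single big-leaf column: prescribed monthly leaf area index, a bucket
#' soil, fixed aerodynamic resistance and albedo. Evapotranspiration is
#' canopy transpiration only (soil evaporation is neglected); the daily
#' maximum temperature proxy is a linearised local energy-balance
#' adjustment of the forcing tmax, with sensitivity
#' `aerodynamic_resistance / (rho cp)` Kelvin per W m-2 of sensible flux
#' anomaly.
#'
#' @param pft Plant functional type label.
#' @param lai_climatology 12 monthly LAI values (m2 m-2).
#' @param bucket_capacity Plant-available soil water capacity (mm).
#' @param initial_soil_water Initial store (mm), within `[0, capacity]`.
#' @param aerodynamic_resistance Aerodynamic resistance (s m-1).
#' @param albedo Surface shortwave albedo (fraction).
#' @param sensible_ref Reference sensible flux (W m-2) against which the
#'   tmax proxy anomaly is measured.
#' @param daylight_fraction Fraction of the day over which the midday
#'   gas-exchange flux is assumed to act.
#' @param par_factor Conversion from daily-mean shortwave (W m-2) to
#'   midday photosynthetically active radiation (umol m-2 s-1).
#' @return An object of class `column_config`.
#' @export
column_config <- function(pft = "evergreen_needleleaf",
                          lai_climatology = c(0.8, 0.8, 1.0, 1.5, 2.5, 3.5,
                                              3.8, 3.5, 2.5, 1.5, 1.0, 0.8),
                          bucket_capacity = 200,
                          initial_soil_water = 150,
                          aerodynamic_resistance = 50,
                          albedo = 0.15,
                          sensible_ref = 70,
                          daylight_fraction = 0.45,
                          par_factor = 8) {
  if (length(lai_climatology) != 12 || any(lai_climatology < 0)) {
    stop("'lai_climatology' must be 12 non-negative monthly values",
         call. = FALSE)
  }
  if (initial_soil_water < 0 || initial_soil_water > bucket_capacity) {
    stop("'initial_soil_water' must lie in [0, bucket_capacity]",
         call. = FALSE)
  }
  structure(list(pft = pft, lai_climatology = lai_climatology,
                 bucket_capacity = bucket_capacity,
                 initial_soil_water = initial_soil_water,
                 aerodynamic_resistance = aerodynamic_resistance,
                 albedo = albedo, sensible_ref = sensible_ref,
                 daylight_fraction = daylight_fraction,
                 par_factor = par_factor),
            class = "column_config")
}

# Vectorised daily surface computation given leaf conductance. Returns the
# potential (water-unlimited) transpiration plus the energy terms that do
# not depend on the soil store.
column_fluxes <- function(forcing, gs_leaf, config) {
  lai <- config$lai_climatology[doy_to_month(forcing$doy)]
  gc_mol <- gs_leaf * lai
  rn <- (1 - config$albedo) * forcing$shortwave
  delta <- svp_slope(forcing$tmax)
  ra <- config$aerodynamic_resistance

  gc_ms <- gc_mol * MOL_TO_MS
  open <- gc_ms > 1e-9
  rs <- ifelse(open, 1 / pmax(gc_ms, 1e-9), Inf)
  # Penman-Monteith combination equation, daytime flux (W m-2).
  le_day <- ifelse(
    open,
    (delta * rn + RHO_CP * forcing$vpd_midday / ra) /
      (delta + PSYCHRO * (1 + rs / ra)),
    0
  )
  le_day <- pmax(le_day, 0)
  et_pot <- le_day * config$daylight_fraction * 86400 / LAMBDA_V  # mm day-1
  list(et_pot = et_pot, rn = rn, lai = lai, gc_mol = gc_mol)
}

# Bucket update given potential transpiration: the slow sequential part.
bucket_run <- function(et_pot, precip, init, capacity) {
  n <- length(et_pot)
  et <- numeric(n); sw <- numeric(n); runoff <- numeric(n)
  s <- init
  for (i in seq_len(n)) {
    e <- min(et_pot[i], s)   # supply limit: no more than today's store
    s2 <- s - e + precip[i]
    r <- max(s2 - capacity, 0)
    s <- s2 - r
    et[i] <- e; sw[i] <- s; runoff[i] <- r
  }
  list(et = et, soil_water = sw, runoff = runoff)
}

finish_column <- function(forcing, fl, bk, sol, config) {
  latent <- bk$et * LAMBDA_V / 86400          # daily-mean W m-2
  sensible <- fl$rn - latent
  sens_coef <- config$aerodynamic_resistance / RHO_CP
  tmax_surface <- forcing$tmax +
    sens_coef * (sensible - config$sensible_ref)
  if (!all(is.finite(latent)) || !all(is.finite(sensible))) {
    stop("non-finite surface flux; check forcing and parameters",
         call. = FALSE)
  }
  out <- data.frame(
    year = forcing$year, doy = forcing$doy,
    et = bk$et, soil_water = bk$soil_water, runoff = bk$runoff,
    latent = latent, sensible = sensible, available_energy = fl$rn,
    tmax_surface = tmax_surface,
    gs_leaf = sol$conductance_h2o, assimilation = sol$assimilation,
    lai = fl$lai, precip = forcing$precip
  )
  class(out) <- c("column_run", "data.frame")
  out
}

#' Run the land-surface column over a forcing series
#'
#' For every day: solve the coupled leaf gas exchange at midday
#' conditions (leaf temperature = forcing tmax), scale leaf conductance to
#' the canopy with LAI, evaluate a Penman-Monteith-type combination
#' equation for potential transpiration, cap it by the available soil
#' water, update the bucket (excess above capacity leaves as runoff), and
#' partition available energy into latent and sensible flux. The daily
#' maximum temperature proxy is
#' `tmax + (ra / rho cp) (sensible - sensible_ref)`.
#'
#' The water balance closes exactly: for any run,
#' `sum(precip) - sum(et) - sum(runoff)` equals the change in soil water;
#' the energy partition satisfies `latent + sensible = available_energy`
#' every day.
#'
#' @param forcing A [generate_forcing()] data frame.
#' @param config A [column_config()].
#' @param photo A [photo_params()].
#' @param stomatal A [stomatal_params()].
#' @param ca Atmospheric CO2 (umol mol-1): a scalar, a per-year vector, or
#'   a per-day vector.
#' @return A data frame (class `column_run`) with one row per day: water
#'   (`et`, `soil_water`, `runoff`, mm), energy (`latent`, `sensible`,
#'   `available_energy`, W m-2), `tmax_surface` (C), and the leaf-level
#'   `gs_leaf`, `assimilation`.
#' @export
run_column <- function(forcing, config, photo, stomatal, ca = 400) {
  stopifnot(inherits(config, "column_config"))
  n <- nrow(forcing)
  ca_day <- if (length(ca) == 1) {
    rep(ca, n)
  } else if (length(ca) == max(forcing$year)) {
    ca[forcing$year]
  } else if (length(ca) == n) {
    ca
  } else {
    stop("'ca' must be scalar, per-year or per-day", call. = FALSE)
  }
  # Leaf temperature equals air tmax, clamped to the kinetic domain;
  # outside it (deep winter) assimilation is non-positive and gs = g0.
  sol <- solve_coupled(ca_day, forcing$vpd_midday,
                       pmin(pmax(forcing$tmax, -10), 60),
                       forcing$shortwave * config$par_factor,
                       photo, stomatal)
  fl <- column_fluxes(forcing, sol$conductance_h2o, config)
  bk <- bucket_run(fl$et_pot, forcing$precip, config$initial_soil_water,
                   config$bucket_capacity)
  finish_column(forcing, fl, bk, sol, config)
}

#' Advance the column by a single day
#'
#' The one-day transition used by [run_column()]: identical physics,
#' exposed so that single steps can be inspected or folded manually.
#'
#' @param state A list with element `soil_water` (mm).
#' @param forcing_day A single-row forcing data frame.
#' @inheritParams run_column
#' @return A list (`daily_column_state`) with `soil_water`, `et`,
#'   `runoff`, `latent`, `sensible_flux`, `available_energy`,
#'   `tmax_surface`, `gs_leaf`, `assimilation`.
#' @export
step_day <- function(state, forcing_day, config, photo, stomatal,
                     ca = 400) {
  stopifnot(nrow(forcing_day) == 1)
  sol <- solve_coupled(ca, forcing_day$vpd_midday,
                       pmin(pmax(forcing_day$tmax, -10), 60),
                       forcing_day$shortwave * config$par_factor,
                       photo, stomatal)
  fl <- column_fluxes(forcing_day, sol$conductance_h2o, config)
  bk <- bucket_run(fl$et_pot, forcing_day$precip, state$soil_water,
                   config$bucket_capacity)
  res <- finish_column(forcing_day, fl, bk, sol, config)
  structure(list(soil_water = res$soil_water, et = res$et,
                 runoff = res$runoff, latent = res$latent,
                 sensible_flux = res$sensible,
                 available_energy = res$available_energy,
                 tmax_surface = res$tmax_surface,
                 gs_leaf = res$gs_leaf, assimilation = res$assimilation),
            class = "daily_column_state")
}
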