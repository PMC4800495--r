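# Universal gas constant (J mol-1 K-1) and reference temperature (K).
RGAS <- 8.314
TREF_K <- 298.15

#' Photosynthesis parameter set
#'
#' Bundles the base rates (at 25 degrees C) and temperature-response
#' constants of a Farquhar-type C3 photosynthesis model. Kinetic constants
#' default to the widely used Bernacchi in-vivo values; the electron
#' transport light response is a non-rectangular hyperbola.
#'
#' The peaked (deactivation) response applied to `vcmax_25` and `jmax_25`
#' produces the high-temperature inhibition of photosynthesis: carboxylation
#' capacity rises with temperature to an optimum (about 28 degrees C with the
#' defaults) and collapses above it, which is what damps the difference
#' between stomatal schemes during extreme heat.
#'
#' @param vcmax_25 Maximum carboxylation rate at 25 C (umol m-2 s-1).
#' @param jmax_25 Maximum electron transport rate at 25 C (umol m-2 s-1).
#'   Defaults to `1.67 * vcmax_25`.
#' @param rd_25 Day respiration at 25 C (umol m-2 s-1). Defaults to
#'   `0.015 * vcmax_25`.
#' @param gamma_star_25 CO2 compensation point in the absence of day
#'   respiration at 25 C (umol mol-1).
#' @param kc_25 Michaelis constant of Rubisco for CO2 at 25 C (umol mol-1).
#' @param ko_25 Michaelis constant of Rubisco for O2 at 25 C (mmol mol-1).
#' @param oi Intercellular O2 concentration (mmol mol-1).
#' @param ea_vcmax,ea_jmax,ea_rd,ea_gamma_star,ea_kc,ea_ko Activation
#'   energies (J mol-1).
#' @param hd Deactivation energy of the peaked Vcmax/Jmax response
#'   (J mol-1). Set `peaked = FALSE` to disable inhibition entirely.
#' @param ds Entropy term of the peaked response (J mol-1 K-1). The
#'   default corresponds to entropy acclimated to a growth temperature
#'   near 10 C (cool/boreal vegetation): carboxylation peaks near 28 C,
#'   electron transport near 26 C, net photosynthesis near 22-23 C, and
#'   assimilation is fully inhibited by about 40 C.
#' @param theta_j Curvature of the electron transport light response (0-1).
#' @param alpha_j Quantum yield of electron transport
#'   (mol electrons mol-1 photons).
#' @param peaked Logical; apply the peaked response to Vcmax and Jmax?
#' @return An object of class `photo_params` (a named list).
#' @export
#' @examples
#' p <- photo_params(vcmax_25 = 50)
#' net_assimilation(leaf_env(leaf_temp = 25, par = 1500, ci = 280), p)
photo_params <- function(vcmax_25 = 60,
                         jmax_25 = 1.67 * vcmax_25,
                         rd_25 = 0.015 * vcmax_25,
                         gamma_star_25 = 42.75,
                         kc_25 = 404.9,
                         ko_25 = 278.4,
                         oi = 210,
                         ea_vcmax = 65330,
                         ea_jmax = 43540,
                         ea_rd = 46390,
                         ea_gamma_star = 37830,
                         ea_kc = 79430,
                         ea_ko = 36380,
                         hd = 200000,
                         ds = 657,
                         theta_j = 0.7,
                         alpha_j = 0.3,
                         peaked = TRUE) {
  p <- list(
    vcmax_25 = vcmax_25, jmax_25 = jmax_25, rd_25 = rd_25,
    gamma_star_25 = gamma_star_25, kc_25 = kc_25, ko_25 = ko_25, oi = oi,
    ea_vcmax = ea_vcmax, ea_jmax = ea_jmax, ea_rd = ea_rd,
    ea_gamma_star = ea_gamma_star, ea_kc = ea_kc, ea_ko = ea_ko,
    hd = hd, ds = ds, theta_j = theta_j, alpha_j = alpha_j,
    peaked = isTRUE(peaked)
  )
  rates <- c("vcmax_25", "jmax_25", "rd_25", "gamma_star_25", "kc_25", "ko_25")
  for (r in rates) {
    if (!is.numeric(p[[r]]) || length(p[[r]]) != 1L || !is.finite(p[[r]]) ||
        p[[r]] <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", r),
           call. = FALSE)
    }
  }
  structure(p, class = "photo_params")
}

#' Leaf environment
#'
#' Instantaneous drivers of leaf biochemistry.
#'
#' @param leaf_temp Leaf temperature (degrees C).
#' @param par Photosynthetically active radiation (umol photons m-2 s-1).
#' @param ci Intercellular CO2 mole fraction (umol mol-1).
#' @param oi Intercellular O2 (mmol mol-1); usually left to the parameter
#'   set default.
#' @return An object of class `leaf_env`.
#' @export
leaf_env <- function(leaf_temp, par, ci, oi = NULL) {
  if (any(ci < 0)) stop("'ci' must be non-negative", call. = FALSE)
  if (any(par < 0)) stop("'par' must be non-negative", call. = FALSE)
  structure(list(leaf_temp = leaf_temp, par = par, ci = ci, oi = oi),
            class = "leaf_env")
}

#' Temperature response multipliers
#'
#' `arrhenius()` is the standard exponential response, normalised so the
#' multiplier is exactly 1 at 25 degrees C. `peaked_arrhenius()` adds a
#' deactivation term giving a unimodal response with a finite optimum;
#' it is likewise exactly 1 at 25 C.
#'
#' @param leaf_temp Leaf temperature (degrees C); valid on [-10, 60].
#' @param ea Activation energy (J mol-1).
#' @param hd Deactivation energy (J mol-1).
#' @param ds Entropy term (J mol-1 K-1).
#' @return Dimensionless multiplier(s).
#' @export
arrhenius <- function(leaf_temp, ea) {
  check_leaf_temp(leaf_temp)
  tk <- leaf_temp + 273.15
  exp(ea * (tk - TREF_K) / (TREF_K * RGAS * tk))
}

#' @rdname arrhenius
#' @export
peaked_arrhenius <- function(leaf_temp, ea, hd, ds) {
  check_leaf_temp(leaf_temp)
  tk <- leaf_temp + 273.15
  arrh <- exp(ea * (tk - TREF_K) / (TREF_K * RGAS * tk))
  num <- 1 + exp((TREF_K * ds - hd) / (TREF_K * RGAS))
  den <- 1 + exp((tk * ds - hd) / (tk * RGAS))
  arrh * num / den
}

check_leaf_temp <- function(leaf_temp) {
  if (any(leaf_temp < -10 | leaf_temp > 60)) {
    stop("'leaf_temp' outside the supported range [-10, 60] C",
         call. = FALSE)
  }
  invisible(leaf_temp)
}

# Temperature-adjusted kinetic parameters at a given leaf temperature.
# Returned as a list of vectors aligned with leaf_temp; this is the single
# place where the temperature machinery touches the base rates, so the
# coupled solver can pre-compute it once per forcing series.
adjust_kinetics <- function(leaf_temp, params) {
  vc_mult <- if (params$peaked) {
    peaked_arrhenius(leaf_temp, params$ea_vcmax, params$hd, params$ds)
  } else {
    arrhenius(leaf_temp, params$ea_vcmax)
  }
  j_mult <- if (params$peaked) {
    peaked_arrhenius(leaf_temp, params$ea_jmax, params$hd, params$ds)
  } else {
    arrhenius(leaf_temp, params$ea_jmax)
  }
  list(
    vcmax = params$vcmax_25 * vc_mult,
    jmax = params$jmax_25 * j_mult,
    rd = params$rd_25 * arrhenius(leaf_temp, params$ea_rd),
    gamma_star = params$gamma_star_25 * arrhenius(leaf_temp,
                                                  params$ea_gamma_star),
    km = params$kc_25 * arrhenius(leaf_temp, params$ea_kc) *
      (1 + params$oi / (params$ko_25 * arrhenius(leaf_temp, params$ea_ko)))
  )
}

# Electron transport rate from the non-rectangular hyperbola light response.
electron_transport <- function(par, jmax, theta, alpha) {
  b <- alpha * par + jmax
  (b - sqrt(pmax(b^2 - 4 * theta * alpha * par * jmax, 0))) / (2 * theta)
}

# Vectorised core: net assimilation given pre-adjusted kinetics.
assimilation_core <- function(ci, par, kin, params) {
  jj <- electron_transport(par, kin$jmax, params$theta_j, params$alpha_j)
  ac <- kin$vcmax * (ci - kin$gamma_star) / (ci + kin$km)
  aj <- (jj / 4) * (ci - kin$gamma_star) / (ci + 2 * kin$gamma_star)
  pmin(ac, aj) - kin$rd
}

#' Net CO2 assimilation
#'
#' Farquhar-type C3 model: the minimum of the Rubisco-limited and the
#' RuBP-regeneration-limited carboxylation rate, less day respiration. A
#' hard minimum of the two limitations is used so that every value can be
#' traced to one closed-form expression.
#'
#' @param env A [leaf_env()] (fields may be vectors of equal length).
#' @param params A [photo_params()].
#' @return Net assimilation A (umol m-2 s-1), vectorised over `env`.
#' @export
#' @examples
#' p <- photo_params(vcmax_25 = 50, rd_25 = 1, peaked = FALSE)
#' # Rubisco-limited at 25 C: 50 * (300 - 42.75) / (300 + Kc(1 + Oi/Ko)) - 1
#' net_assimilation(leaf_env(25, par = 2000, ci = 300), p)
net_assimilation <- function(env, params) {
  stopifnot(inherits(env, "leaf_env"), inherits(params, "photo_params"))
  if (any(env$ci < 0)) stop("'ci' must be non-negative", call. = FALSE)
  if (!is.null(env$oi)) params$oi <- env$oi
  kin <- adjust_kinetics(env$leaf_temp, params)
  assimilation_core(env$ci, env$par, kin, params)
}
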