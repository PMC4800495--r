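# Floor applied to vapour pressure deficit before the sqrt(D) term, to
# avoid the singularity of the optimal-theory form as D -> 0.
VPD_FLOOR <- 0.05

#' Stomatal scheme parameters
#'
#' Parameters for one of the two conductance schemes:
#'
#' * `"medlyn"` — the optimal-stomatal-theory model
#'   `gs = g0 + 1.6 (1 + g1 / sqrt(D)) A / Cs`, whose slope parameter `g1`
#'   (kPa^0.5) varies by plant functional type (PFT) and is theoretically
#'   the marginal carbon cost of water. Low `g1` means conservative water
#'   use.
#' * `"default_empirical"` — a Leuning-type empirical model
#'   `gs = g0 + a1 A / ((Cs - Gamma) (1 + D / d0))` whose two fitted
#'   constants (`slope_a1`, `d0`) vary only by photosynthetic pathway,
#'   not by PFT.
#'
#' @param scheme `"medlyn"` or `"default_empirical"`.
#' @param g0 Residual conductance as A reaches zero (mol m-2 s-1).
#' @param g1 Optimal-model slope (kPa^0.5); required for `"medlyn"`.
#' @param slope_a1 Empirical slope (dimensionless); required for
#'   `"default_empirical"`.
#' @param d0 Humidity sensitivity constant (kPa) of the empirical model.
#' @param gamma CO2 compensation offset (umol mol-1) of the empirical
#'   model. `NULL` (default) means "use the temperature-adjusted
#'   Gamma-star of the photosynthesis parameters" inside the coupled
#'   solver; stand-alone calls to [default_empirical_gs()] then fall back
#'   to 42.75.
#' @param pft Optional PFT label carried along for bookkeeping.
#' @return An object of class `stomatal_params`.
#' @export
#' @examples
#' stomatal_params("medlyn", g1 = 4)
#' stomatal_params("default_empirical", slope_a1 = 9, d0 = 1.5)
stomatal_params <- function(scheme = c("medlyn", "default_empirical"),
                            g0 = 0, g1 = NULL, slope_a1 = NULL, d0 = NULL,
                            gamma = NULL, pft = NULL) {
  scheme <- match.arg(scheme)
  if (g0 < 0) stop("'g0' must be non-negative", call. = FALSE)
  if (scheme == "medlyn") {
    if (is.null(g1) || !is.finite(g1) || g1 <= 0) {
      stop("the medlyn scheme requires g1 > 0", call. = FALSE)
    }
  } else {
    if (is.null(slope_a1) || slope_a1 <= 0) {
      stop("the default empirical scheme requires slope_a1 > 0",
           call. = FALSE)
    }
    if (is.null(d0)) d0 <- 1.5
    if (d0 <= 0) stop("'d0' must be positive", call. = FALSE)
  }
  structure(list(scheme = scheme, g0 = g0, g1 = g1, slope_a1 = slope_a1,
                 d0 = d0, gamma = gamma, pft = pft),
            class = "stomatal_params")
}

#' @export
print.stomatal_params <- function(x, ...) {
  if (x$scheme == "medlyn") {
    cat(sprintf("Stomatal scheme: medlyn (g0 = %g, g1 = %g kPa^0.5%s)\n",
                x$g0, x$g1,
                if (is.null(x$pft)) "" else paste0(", pft = ", x$pft)))
  } else {
    cat(sprintf(
      "Stomatal scheme: default empirical (g0 = %g, a1 = %g, d0 = %g kPa)\n",
      x$g0, x$slope_a1, x$d0))
  }
  invisible(x)
}

#' Optimal-theory stomatal conductance
#'
#' `gs = g0 + 1.6 (1 + g1 / sqrt(D)) A / Cs`. The 1.6 factor converts the
#' CO2-side supply ratio to water vapour, so the returned conductance is
#' for water. Non-positive assimilation clamps the conductance at `g0`.
#' VPD below 0.05 kPa is clamped to the floor (not an error).
#'
#' @param assimilation Net assimilation A (umol m-2 s-1).
#' @param cs CO2 mole fraction at the leaf surface (umol mol-1).
#' @param vpd Vapour pressure deficit at the leaf surface D (kPa).
#' @param params A [stomatal_params()] with `scheme = "medlyn"`.
#' @return Stomatal conductance to water vapour (mol m-2 s-1).
#' @export
#' @examples
#' p <- stomatal_params("medlyn", g1 = 4)
#' medlyn_gs(10, cs = 400, vpd = 1, params = p) # 1.6 * 5 * 10/400 = 0.2
medlyn_gs <- function(assimilation, cs, vpd, params) {
  stopifnot(inherits(params, "stomatal_params"),
            params$scheme == "medlyn")
  if (any(cs <= 0)) stop("'cs' must be positive", call. = FALSE)
  vpd <- pmax(vpd, VPD_FLOOR)
  gs <- params$g0 + 1.6 * (1 + params$g1 / sqrt(vpd)) * assimilation / cs
  pmax(gs, params$g0)
}

#' Default empirical (Leuning-type) stomatal conductance
#'
#' `gs = g0 + a1 A / ((Cs - Gamma) (1 + D / d0))`, the pathway-level
#' empirical scheme used as the control. Non-positive assimilation clamps
#' at `g0`.
#'
#' @inheritParams medlyn_gs
#' @param params A [stomatal_params()] with `scheme = "default_empirical"`.
#' @param gamma CO2 compensation offset (umol mol-1); overrides the value
#'   stored in `params`.
#' @return Stomatal conductance to water vapour (mol m-2 s-1).
#' @export
#' @examples
#' p <- stomatal_params("default_empirical", slope_a1 = 9, d0 = 1.5)
#' default_empirical_gs(10, cs = 400, vpd = 1.5, params = p, gamma = 40)
default_empirical_gs <- function(assimilation, cs, vpd, params,
                                 gamma = NULL) {
  stopifnot(inherits(params, "stomatal_params"),
            params$scheme == "default_empirical")
  gamma <- gamma %||% params$gamma %||% 42.75
  if (any(cs <= gamma)) {
    stop("'cs' must exceed the compensation offset 'gamma'", call. = FALSE)
  }
  vpd <- pmax(vpd, 0)
  gs <- params$g0 + params$slope_a1 * assimilation /
    ((cs - gamma) * (1 + vpd / params$d0))
  pmax(gs, params$g0)
}

# Scheme dispatch used by the coupled solver. `gamma` is the
# temperature-adjusted compensation point (vector aligned with the inputs).
scheme_gs <- function(assimilation, cs, vpd, params, gamma) {
  if (params$scheme == "medlyn") {
    medlyn_gs(assimilation, cs, vpd, params)
  } else {
    default_empirical_gs(assimilation, cs, vpd, params, gamma = gamma)
  }
}

#' Coupled assimilation--conductance--Ci solution
#'
#' Solves the leaf-level closure both schemes require: find the
#' intercellular CO2 `ci` at which the diffusive supply
#' `(gs / 1.6) (Cs - ci)` equals the biochemical demand `A(ci)`, with `gs`
#' itself a function of `A` through the selected scheme. The root is
#' located by bisection on `[0, Cs]`, which is robust because supply minus
#' demand is strictly decreasing in `ci` over the bracketing interval.
#'
#' All driver arguments are vectorised; the temperature-dependent kinetics
#' are computed once, so a multi-decadal daily series solves in one call.
#'
#' @param cs CO2 at the leaf surface (umol mol-1).
#' @param vpd Vapour pressure deficit (kPa).
#' @param leaf_temp Leaf temperature (degrees C).
#' @param par Photosynthetically active radiation (umol m-2 s-1).
#' @param photo A [photo_params()].
#' @param stomatal A [stomatal_params()].
#' @param tol Convergence tolerance on the supply-demand residual
#'   (umol m-2 s-1).
#' @param max_iter Maximum bisection iterations.
#' @return A data frame of class `coupled_solution` with columns
#'   `assimilation`, `conductance_h2o`, `ci`, `residual`.
#' @details A leaf whose assimilation is non-positive even at `ci = Cs`
#'   (dark or deeply respiring) has no positive root; the solver then
#'   returns `ci = Cs`, `gs = g0` and the (non-positive) assimilation at
#'   `Cs`, the gradient-free equilibrium. Non-convergence after
#'   `max_iter` iterations raises an error.
#' @export
solve_coupled <- function(cs, vpd, leaf_temp, par, photo, stomatal,
                          tol = 1e-6, max_iter = 80L) {
  stopifnot(inherits(photo, "photo_params"),
            inherits(stomatal, "stomatal_params"))
  n <- max(length(cs), length(vpd), length(leaf_temp), length(par))
  cs <- rep_len(cs, n); vpd <- rep_len(vpd, n)
  leaf_temp <- rep_len(leaf_temp, n); par <- rep_len(par, n)
  assert_finite(cs, "cs"); assert_finite(vpd, "vpd")
  if (any(cs <= 0)) stop("'cs' must be positive", call. = FALSE)

  kin <- adjust_kinetics(leaf_temp, photo)
  # Light-dependent electron transport, the kinetic terms and the (linear
  # in A) conductance factor do not depend on ci; hoist them all out of the
  # bisection loop.
  jq <- electron_transport(par, kin$jmax, photo$theta_j, photo$alpha_j) / 4
  fac <- if (stomatal$scheme == "medlyn") {
    1.6 * (1 + stomatal$g1 / sqrt(pmax(vpd, VPD_FLOOR))) / cs
  } else {
    gam <- kin$gamma_star
    if (any(cs <= gam)) {
      stop("'cs' must exceed the compensation offset", call. = FALSE)
    }
    stomatal$slope_a1 / ((cs - gam) * (1 + pmax(vpd, 0) / stomatal$d0))
  }

  demand <- function(ci, vc, gst, km, j4, rd) {
    pmin(vc * (ci - gst) / (ci + km), j4 * (ci - gst) / (ci + 2 * gst)) - rd
  }

  a_at_cs <- demand(cs, kin$vcmax, kin$gamma_star, kin$km, jq, kin$rd)
  dark <- a_at_cs <= 0
  act <- which(!dark)

  ci <- cs
  a <- a_at_cs
  gs <- rep_len(stomatal$g0, n)
  if (length(act)) {
    # Bisection on interval width rather than residual: supply - demand has
    # a sign change only at the transpiring root (it touches zero from
    # above at the compensation point), so narrowing the bracket cannot
    # stall there.
    lo <- rep(0, length(act)); hi <- cs[act]
    csa <- cs[act]; faca <- fac[act]
    vc <- kin$vcmax[act]; gst <- kin$gamma_star[act]; km <- kin$km[act]
    j4 <- jq[act]; rd <- kin$rd[act]; g0 <- stomatal$g0
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      aa <- demand(mid, vc, gst, km, j4, rd)
      h <- ((g0 + faca * pmax(aa, 0)) / 1.6) * (csa - mid) - aa
      up <- h > 0  # supply exceeds demand: root lies above
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
      if (max(hi - lo) < 1e-10) break
    }
    ci[act] <- (lo + hi) / 2
    a[act] <- demand(ci[act], vc, gst, km, j4, rd)
    gs[act] <- scheme_gs(a[act], csa, vpd[act], stomatal,
                         gamma = gst)
  }
  residual <- (gs / 1.6) * (cs - ci) - a
  residual[dark] <- 0
  if (any(abs(residual) >= tol)) {
    stop("coupled solver failed to converge; check parameters",
         call. = FALSE)
  }
  out <- data.frame(assimilation = a, conductance_h2o = gs, ci = ci,
                    residual = residual)
  class(out) <- c("coupled_solution", "data.frame")
  out
}

#' Compare the VPD sensitivity of the two conductance schemes
#'
#' Computes the relative sensitivity `-(1/gs) d(gs)/dD` of both schemes on
#' a VPD grid, after rescaling the empirical slope so both schemes predict
#' the same conductance at a calibration VPD. For the optimal scheme the
#' relative sensitivity is `(g1 / (2 D^1.5)) / (1 + g1 / sqrt(D))`,
#' independent of A and Cs; for the empirical scheme it is `1 / (d0 + D)`.
#' Rescaling the slope does not change either relative sensitivity, but
#' makes the absolute conductance curves directly comparable.
#'
#' @param photo A [photo_params()] (used only for the compensation offset
#'   of the empirical scheme).
#' @param medlyn_params Optimal-scheme [stomatal_params()].
#' @param default_params Empirical-scheme [stomatal_params()].
#' @param calibration_vpd VPD (kPa) at which the two schemes are forced to
#'   agree.
#' @param vpd_grid VPD values (kPa) on which sensitivities are evaluated.
#' @param assimilation,cs Reference A and Cs for the absolute curves.
#' @return A list of class `vpd_sensitivity_report`: a data frame `grid`
#'   with the conductances and relative sensitivities, the rescaled
#'   `slope_a1`, and `default_more_sensitive_above_3`, TRUE when the
#'   empirical scheme's relative sensitivity exceeds the optimal scheme's
#'   at every grid VPD above 3 kPa.
#' @export
vpd_sensitivity_compare <- function(photo, medlyn_params, default_params,
                                    calibration_vpd = 1,
                                    vpd_grid = seq(0.2, 5, by = 0.1),
                                    assimilation = 10, cs = 400) {
  stopifnot(medlyn_params$scheme == "medlyn",
            default_params$scheme == "default_empirical")
  gamma <- default_params$gamma %||% photo$gamma_star_25
  gs_med_cal <- medlyn_gs(assimilation, cs, calibration_vpd, medlyn_params)
  gs_def_cal <- default_empirical_gs(assimilation, cs, calibration_vpd,
                                     default_params, gamma = gamma)
  scale <- gs_med_cal / gs_def_cal
  def2 <- default_params
  def2$slope_a1 <- default_params$slope_a1 * scale

  g1 <- medlyn_params$g1
  d0 <- default_params$d0
  d <- pmax(vpd_grid, VPD_FLOOR)
  rel_med <- (g1 / (2 * d^1.5)) / (1 + g1 / sqrt(d))
  rel_def <- 1 / (d0 + d)
  grid <- data.frame(
    vpd = vpd_grid,
    gs_medlyn = medlyn_gs(assimilation, cs, vpd_grid, medlyn_params),
    gs_default = default_empirical_gs(assimilation, cs, vpd_grid, def2,
                                      gamma = gamma),
    rel_sens_medlyn = rel_med,
    rel_sens_default = rel_def
  )
  high <- grid$vpd > 3
  structure(list(
    grid = grid,
    slope_a1_calibrated = def2$slope_a1,
    calibration_vpd = calibration_vpd,
    default_more_sensitive_above_3 =
      length(high) > 0 && all(rel_def[high] > rel_med[high])
  ), class = "vpd_sensitivity_report")
}

#' @export
print.vpd_sensitivity_report <- function(x, ...) {
  cat("VPD sensitivity comparison (relative sensitivity -(1/gs) dgs/dD)\n")
  cat(sprintf("  calibrated at %g kPa (rescaled a1 = %.3f)\n",
              x$calibration_vpd, x$slope_a1_calibrated))
  cat(sprintf("  default scheme more sensitive at every D > 3 kPa: %s\n",
              x$default_more_sensitive_above_3))
  invisible(x)
}
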