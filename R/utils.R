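#' @keywords internal
"_PACKAGE"

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards so library code never clobbers
# user-level reproducibility.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Saturation vapour pressure of water
#'
#' Magnus-type formula, suitable for air temperatures in the meteorological
#' range.
#'
#' @param temp_c Air temperature (degrees C). Vectorised.
#' @return Saturation vapour pressure (kPa).
#' @export
#' @examples
#' saturation_vp(25) # about 3.17 kPa
saturation_vp <- function(temp_c) {
  0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
}

# Slope of the saturation vapour pressure curve (kPa / K).
svp_slope <- function(temp_c) {
  4098 * saturation_vp(temp_c) / (temp_c + 237.3)^2
}

# 365-day no-leap calendar helpers -------------------------------------------

# First day-of-year of each month, 365-day calendar.
MONTH_START <- cumsum(c(1, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))
DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# JJA window in day-of-year terms (1 Jun -- 31 Aug).
JJA_START <- 152L
JJA_END <- 243L

doy_to_month <- function(doy) {
  findInterval(doy, MONTH_START)
}

is_jja <- function(doy) {
  doy >= JJA_START & doy <= JJA_END
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  }
  invisible(x)
}
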