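#' Read per-PFT parameter configuration
#'
#' Loads the YAML parameter file holding per-PFT optimal-model slopes
#' (`g1`), photosynthetic capacities and leaf-area profiles, plus the
#' pathway-level constants of the default empirical scheme. The packaged
#' file ships stand-in `g1` values spanning the range of the published
#' leaf-level synthesis (conservative needleleaf and tundra around
#' 2.2-2.4 kPa^0.5, crops near 5.8); supply your own file to override.
#'
#' @param path Path to a YAML file; `NULL` (default) reads the file
#'   shipped with the package.
#' @return A list with elements `default_scheme` (pathway-level constants)
#'   and `pfts` (named list of per-PFT parameter lists).
#' @export
#' @examples
#' cfg <- read_pft_params()
#' names(cfg$pfts)
read_pft_params <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pft_params.yaml",
                                package = "stomawave")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pfts) || is.null(cfg$default_scheme)) {
    stop("parameter file must define 'pfts' and 'default_scheme'",
         call. = FALSE)
  }
  for (p in names(cfg$pfts)) {
    if (is.null(cfg$pfts[[p]]$g1) || cfg$pfts[[p]]$g1 <= 0) {
      stop(sprintf("pft '%s' needs a positive g1", p), call. = FALSE)
    }
  }
  cfg
}

# Monthly LAI climatology from a peak value and a winter fraction:
# a smooth seasonal bell peaking in July.
lai_profile <- function(peak, winter_frac) {
  months <- 1:12
  shape <- (1 + cos(2 * pi * (months - 7) / 12)) / 2  # 1 in Jul, 0 in Jan
  winter <- winter_frac * peak
  winter + (peak - winter) * shape^1.5
}

# Stomatal parameter pair (control = default empirical, experiment =
# optimal model) for one PFT, from a configuration list.
pft_scheme_params <- function(pft, cfg = read_pft_params()) {
  pp <- cfg$pfts[[pft]]
  if (is.null(pp)) stop(sprintf("unknown pft '%s'", pft), call. = FALSE)
  d <- cfg$default_scheme$c3
  list(
    control = stomatal_params("default_empirical", g0 = d$g0 %||% 0,
                              slope_a1 = d$slope_a1, d0 = d$d0, pft = pft),
    experiment = stomatal_params("medlyn", g0 = 0, g1 = pp$g1, pft = pft),
    photo = photo_params(vcmax_25 = pp$vcmax_25),
    lai = lai_profile(pp$lai_peak, pp$lai_winter_frac %||% 0.1)
  )
}
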