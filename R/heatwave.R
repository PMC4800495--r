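#' Calendar-day percentile thresholds
#'
#' Computes, for each of the 365 calendar days, the empirical percentile of
#' daily maximum temperature pooled over a moving window across a base
#' period: for calendar day `d` the sample is every `tmax(y, d + k)` with
#' `y` in the base years and `|k| <= window_halfwidth`, wrapping at year
#' edges. With a 30-year base and a 15-day window (halfwidth 7) the pooled
#' sample is 450 values per calendar day. Quantiles use linear
#' interpolation between order statistics (type 7), fixed so results are
#' bit-reproducible.
#'
#' @param base_series Daily tmax over the base period; length must be a
#'   multiple of 365 and gap-free (no missing values).
#' @param percentile Percentile as a fraction (default 0.90).
#' @param window_halfwidth Half-width of the moving window in days
#'   (default 7, i.e. a 15-day window).
#' @return An object of class `hw_thresholds`: numeric vector of length
#'   365 with attributes `percentile`, `window_halfwidth`, `base_years`.
#' @export
#' @examples
#' th <- calendar_thresholds(rep(20, 365 * 30))
#' all(th == 20)
calendar_thresholds <- function(base_series, percentile = 0.90,
                                window_halfwidth = 7L) {
  if (anyNA(base_series) || !all(is.finite(base_series))) {
    stop("base series must be gap-free and finite", call. = FALSE)
  }
  n <- length(base_series)
  if (n == 0 || n %% 365L != 0L) {
    stop("base series length must be a positive multiple of 365",
         call. = FALSE)
  }
  if (percentile <= 0 || percentile >= 1) {
    stop("'percentile' must lie in (0, 1)", call. = FALSE)
  }
  hw <- as.integer(window_halfwidth)
  if (hw < 0) stop("'window_halfwidth' must be >= 0", call. = FALSE)
  n_years <- n %/% 365L
  m <- matrix(base_series, nrow = 365L)  # [doy, year]
  th <- vapply(1:365, function(d) {
    days <- ((d - hw):(d + hw) - 1L) %% 365L + 1L
    stats::quantile(m[days, ], probs = percentile, names = FALSE, type = 7)
  }, numeric(1))
  structure(th, class = "hw_thresholds", percentile = percentile,
            window_halfwidth = hw, base_years = n_years)
}

#' Detect heatwave events
#'
#' A heatwave is a maximal run of at least three consecutive days whose
#' daily maximum temperature strictly exceeds its calendar-day threshold.
#' Shorter exceedance runs are discarded; ties with the threshold do not
#' count. Detection runs over the full series (events may span calendar
#' years); seasonal attribution happens in [heatwave_summary()].
#'
#' @param series Daily tmax, aligned to the 365-day calendar (day 1 =
#'   1 January of year 1).
#' @param thresholds A [calendar_thresholds()] object (or any numeric
#'   vector of length 365).
#' @param min_duration Minimum run length in days (default 3).
#' @return A data frame (class `heatwave_events`), one row per event:
#'   `start_day` (index into `series`), `duration`, `year` and
#'   `start_doy` of the start day, `mean_tmax`, `max_tmax`.
#' @export
detect_events <- function(series, thresholds, min_duration = 3L) {
  if (length(thresholds) != 365L) {
    stop("'thresholds' must have length 365", call. = FALSE)
  }
  doy <- (seq_along(series) - 1L) %% 365L + 1L
  exceed <- series > as.numeric(thresholds)[doy]
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  starts <- starts[keep]
  lens <- r$lengths[keep]
  ev <- data.frame(
    start_day = starts,
    duration = lens,
    year = (starts - 1L) %/% 365L + 1L,
    start_doy = (starts - 1L) %% 365L + 1L,
    mean_tmax = vapply(seq_along(starts), function(i) {
      mean(series[starts[i]:(starts[i] + lens[i] - 1L)])
    }, numeric(1)),
    max_tmax = vapply(seq_along(starts), function(i) {
      max(series[starts[i]:(starts[i] + lens[i] - 1L)])
    }, numeric(1))
  )
  class(ev) <- c("heatwave_events", "data.frame")
  ev
}

#' Summer heatwave indices and TXx
#'
#' Summarises detected events into the four heatwave indices, per year:
#' HW-frequency (number of events), HW-duration (mean event length in
#' days), HW-intensity (mean tmax over event days), HW-max-intensity
#' (maximum tmax during events), plus TXx (warmest daily maximum of the
#' calendar year). Events are attributed to the summer of their start day;
#' only events starting in the season window count. Years without events
#' have frequency 0 and missing (NA) duration/intensity, not zero.
#'
#' @param series Daily tmax (365-day calendar).
#' @param events Events from [detect_events()].
#' @param season Integer vector `c(first_doy, last_doy)` of the season
#'   window; default JJA (days 152-243).
#' @param intensity Either `"pooled"` (mean over all event days; the
#'   default) or `"event_mean"` (mean of per-event means).
#' @return A data frame (class `heatwave_summary`), one row per year:
#'   `year`, `hw_frequency`, `hw_duration`, `hw_intensity`,
#'   `hw_max_intensity`, `txx`.
#' @export
heatwave_summary <- function(series, events,
                             season = c(JJA_START, JJA_END),
                             intensity = c("pooled", "event_mean")) {
  intensity <- match.arg(intensity)
  n_years <- ceiling(length(series) / 365)
  in_season <- events$start_doy >= season[1] & events$start_doy <= season[2]
  ev <- events[in_season, , drop = FALSE]
  out <- lapply(seq_len(n_years), function(y) {
    e <- ev[ev$year == y, , drop = FALSE]
    yr_days <- series[((y - 1) * 365 + 1):min(y * 365, length(series))]
    if (nrow(e) == 0) {
      return(data.frame(year = y, hw_frequency = 0L,
                        hw_duration = NA_real_, hw_intensity = NA_real_,
                        hw_max_intensity = NA_real_, txx = max(yr_days)))
    }
    day_values <- unlist(lapply(seq_len(nrow(e)), function(i) {
      series[e$start_day[i]:(e$start_day[i] + e$duration[i] - 1L)]
    }))
    hwi <- if (intensity == "pooled") mean(day_values) else mean(e$mean_tmax)
    data.frame(year = y, hw_frequency = nrow(e),
               hw_duration = mean(e$duration), hw_intensity = hwi,
               hw_max_intensity = max(e$max_tmax), txx = max(yr_days))
  })
  out <- do.call(rbind, out)
  class(out) <- c("heatwave_summary", "data.frame")
  out
}

#' Normalised histogram (probability distribution in percent)
#'
#' Bins values on an absolute grid (bin edges at integer multiples of
#' `bin_width`) and normalises counts to sum to 100. The absolute grid
#' means that shifting the input by an exact multiple of the bin width
#' shifts the histogram by the same number of bins.
#'
#' @param values Numeric values (at least one).
#' @param bin_width Bin width in the units of `values`.
#' @return A data frame with columns `mid` (bin midpoint) and `pct`
#'   (percentage of values in the bin).
#' @export
pdf_summary <- function(values, bin_width = 0.5) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("need at least one value", call. = FALSE)
  if (bin_width <= 0) stop("'bin_width' must be positive", call. = FALSE)
  lo <- floor(min(values) / bin_width)
  hi <- ceiling(max(values) / bin_width)
  if (hi == lo) hi <- lo + 1
  breaks <- seq(lo, hi) * bin_width
  idx <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE),
                   1L), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             pct = 100 * counts / sum(counts))
}
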