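# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with R/.

# Linear-interpolation quantile by explicit sort-and-index arithmetic.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# Calendar-day percentile thresholds by direct index arithmetic.
oracle_thresholds <- function(series, p = 0.90, hw = 7) {
  ny <- length(series) %/% 365
  th <- numeric(365)
  for (d in 1:365) {
    days <- ((d - hw):(d + hw) - 1) %% 365 + 1
    idx <- rep(days, ny) + rep((0:(ny - 1)) * 365, each = length(days))
    th[d] <- oracle_quantile(series[idx], p)
  }
  th
}

# Heatwave scanner: walk the series day by day.
oracle_events <- function(series, th, min_dur = 3) {
  n <- length(series)
  doy <- ((seq_len(n) - 1) %% 365) + 1
  out <- NULL
  i <- 1
  while (i <= n) {
    if (series[i] > th[doy[i]]) {
      j <- i
      while (j < n && series[j + 1] > th[doy[j + 1]]) j <- j + 1
      if (j - i + 1 >= min_dur) {
        out <- rbind(out, data.frame(start_day = i, duration = j - i + 1))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (is.null(out)) data.frame(start_day = integer(), duration = integer())
  else out
}

# Benjamini-Hochberg by explicit enumeration of all cutoffs.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) kmax <- i
  if (kmax == 0) return(rep(FALSE, m))
  p <= ps[kmax]
}

# Coupled-leaf solution by grid search over ci.
oracle_ci <- function(cs, vpd, leaf_temp, par, photo, stomatal,
                      step = 0.01) {
  grid <- seq(0, cs, by = step)
  a <- net_assimilation(leaf_env(leaf_temp, par, grid), photo)
  gs <- if (stomatal$scheme == "medlyn") {
    medlyn_gs(a, cs, vpd, stomatal)
  } else {
    gst <- photo$gamma_star_25 * arrhenius(leaf_temp, photo$ea_gamma_star)
    default_empirical_gs(a, cs, vpd, stomatal, gamma = gst)
  }
  h <- (gs / 1.6) * (cs - grid) - a
  if (a[length(a)] <= 0) return(cs)
  # sign change closest to cs
  idx <- which(h[-1] <= 0 & h[-length(h)] > 0)
  if (length(idx) == 0) return(cs)
  grid[max(idx)]
}

# Default-scheme params used across tests.
test_default_scheme <- function() {
  stomatal_params("default_empirical", slope_a1 = 9, d0 = 1.5)
}
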