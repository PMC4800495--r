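#' Two-sample Student's t-test for one grid cell
#'
#' Equal-variance (pooled) two-sample t-test of ensemble means, the form
#' used for control-versus-experiment differencing; Welch's unequal
#' variance correction is available as an option. Two constant samples
#' with equal means return `p = 1` (and `p = 0` when their means differ)
#' by convention, rather than an error.
#'
#' @param sample_a,sample_b Numeric vectors (at least 2 values each),
#'   typically per-ensemble-member means.
#' @param var_equal Use the pooled-variance Student form (default TRUE).
#' @return A list with `t`, `df`, `p_value`, and `difference`
#'   (`mean(sample_a) - mean(sample_b)`).
#' @export
#' @examples
#' cell_ttest(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7)) # t = -2, p ~ 0.0805
cell_ttest <- function(sample_a, sample_b, var_equal = TRUE) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("need at least 2 values per sample", call. = FALSE)
  }
  diff <- mean(sample_a) - mean(sample_b)
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    equal <- isTRUE(all.equal(mean(sample_a), mean(sample_b)))
    return(list(t = if (equal) 0 else Inf * sign(diff),
                df = length(sample_a) + length(sample_b) - 2,
                p_value = if (equal) 1 else 0,
                difference = diff))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, difference = diff)
}

#' Field significance mask by the false discovery rate
#'
#' Benjamini-Hochberg step-up over all grid cells: with sorted p-values
#' `p(1) <= ... <= p(m)`, find the largest `i` with `p(i) <= i q / m` and
#' reject every cell with `p <= p(i)`; when no `i` qualifies the rejection
#' set is empty. Implemented through [stats::p.adjust()] (`method =
#' "BH"`), whose adjusted values are below `q` exactly for the step-up
#' rejection set.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed;
#'   never rejected).
#' @param q Target false discovery rate (default 0.05, matching a 95%
#'   testing level).
#' @return Logical vector: TRUE where the cell is field-significant.
#' @export
#' @examples
#' fdr_field_mask(c(0.001, 0.01, 0.02, 0.03, 0.5), q = 0.05)
fdr_field_mask <- function(p_values, q = 0.05) {
  ok <- is.finite(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (q <= 0 || q > 1) stop("'q' must lie in (0, 1]", call. = FALSE)
  mask <- rep(FALSE, length(p_values))
  mask[ok] <- stats::p.adjust(p_values[ok], method = "BH") <= q
  mask
}
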