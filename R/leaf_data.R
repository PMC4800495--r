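#' Generate a synthetic leaf gas-exchange dataset
#'
#' Emulates a field synthesis of stomatal conductance measurements:
#' assimilation, leaf-surface CO2 and VPD are sampled over the envelope
#' typical of survey campaigns (A uniform on 2-30 umol m-2 s-1, Cs near
#' 400 umol mol-1, D lognormal and truncated to 0.3-4 kPa), conductance is
#' the optimal-theory prediction times multiplicative lognormal noise with
#' a given coefficient of variation, and species labels are nested within
#' plant functional type.
#'
#' @param g1_true Named numeric vector of true g1 values (kPa^0.5), one
#'   per PFT; names are the PFT labels.
#' @param n_obs Observations per PFT (minimum 10).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal conductance noise (0 = exact model).
#' @param n_species Species per PFT.
#' @param g1_species_sd Between-species standard deviation of g1 within a
#'   PFT (kPa^0.5); 0 by default so the PFT value is shared.
#' @param seed Integer seed.
#' @return A data frame (class `leaf_observations`) with columns
#'   `species`, `pft`, `A`, `gs`, `Cs`, `D`.
#' @export
#' @examples
#' leaf <- generate_leaf_dataset(c(enf = 2.35, crop = 5.8), n_obs = 50,
#'                               noise_cv = 0.1, seed = 1)
#' head(leaf)
generate_leaf_dataset <- function(g1_true, n_obs = 200, noise_cv = 0.1,
                                  n_species = 6, g1_species_sd = 0,
                                  seed = 1L) {
  if (is.null(names(g1_true)) || any(!nzchar(names(g1_true)))) {
    stop("'g1_true' must be a named vector (one value per PFT)",
         call. = FALSE)
  }
  if (any(g1_true <= 0)) stop("'g1_true' must be positive", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  if (n_obs < 10) {
    stop("'n_obs' must be at least 10 per PFT (fitting would be degenerate)",
         call. = FALSE)
  }

  with_seed(seed, {
    rows <- lapply(names(g1_true), function(pft) {
      a <- runif(n_obs, 2, 30)
      cs <- rnorm(n_obs, 400, 15)
      cs[cs < 300] <- 300
      d <- exp(rnorm(n_obs, log(1.2), 0.45))
      d <- pmin(pmax(d, 0.3), 4)
      sp_idx <- sample.int(n_species, n_obs, replace = TRUE)
      g1_sp <- pmax(g1_true[[pft]] + rnorm(n_species, 0, g1_species_sd),
                    0.1)
      g1 <- g1_sp[sp_idx]
      gs0 <- 1.6 * (1 + g1 / sqrt(d)) * a / cs
      noise <- if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        exp(rnorm(n_obs, -sdlog^2 / 2, sdlog))  # mean-one lognormal
      } else {
        1
      }
      data.frame(
        species = sprintf("%s_sp%02d", pft, sp_idx),
        pft = pft,
        A = a, gs = gs0 * noise, Cs = cs, D = d
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("leaf_observations", "data.frame")
    out
  })
}

#' Write or read a leaf observation table
#'
#' Delimited text with header `species,pft,A,gs,Cs,D`.
#'
#' @param obs A leaf observation data frame.
#' @param path File path.
#' @export
write_leaf_dataset <- function(obs, path) {
  utils::write.csv(obs[, c("species", "pft", "A", "gs", "Cs", "D")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_leaf_dataset
#' @export
read_leaf_dataset <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "pft", "A", "gs", "Cs", "D")
  if (!all(need %in% names(out))) {
    stop("leaf dataset must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  class(out) <- c("leaf_observations", "data.frame")
  out
}

#' Estimate the optimal-model slope g1 from leaf observations
#'
#' Fits `gs = 1.6 (1 + g1 / sqrt(D)) A / Cs` (residual conductance g0
#' fixed at zero) to measured conductance by nonlinear least squares,
#' separately per group. Three estimators are available:
#'
#' * `"nls"` — one least-squares fit per group (the default), minimising
#'   squared conductance residuals; because the model is linear in g1 the
#'   minimiser is evaluated in closed form.
#' * `"two_stage"` — species-level least-squares fits followed by a
#'   precision-weighted (inverse squared standard error) mean per PFT; a
#'   transparent stand-in for a nonlinear mixed-effects model.
#' * `"lme"` — a linear mixed-effects formulation: because the model is
#'   linear in g1, `gs - 1.6 A/Cs = g1 * 1.6 A/(Cs sqrt(D))` is fitted
#'   with a species-level random slope via [nlme::lme()].
#'
#' @param observations Data frame with columns `species`, `pft`, `A`,
#'   `gs`, `Cs`, `D` (see [generate_leaf_dataset()]).
#' @param by Grouping: `"pft"` or `"species"`.
#' @param method Estimator (see Details).
#' @return A data frame with one row per group: `group`, `g1_hat`, `se`,
#'   `n`. With `method = "lme"`, `group` is the PFT and the estimate is
#'   the fixed-effect slope.
#' @export
#' @examples
#' leaf <- generate_leaf_dataset(c(enf = 2.35), n_obs = 100, noise_cv = 0,
#'                               seed = 1)
#' fit_g1(leaf) # recovers 2.35
fit_g1 <- function(observations, by = c("pft", "species"),
                   method = c("nls", "two_stage", "lme")) {
  by <- match.arg(by)
  method <- match.arg(method)
  obs <- as.data.frame(observations)
  need <- c("species", "pft", "A", "gs", "Cs", "D")
  if (!all(need %in% names(obs))) {
    stop("observations must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (any(obs$D <= 0.05) || any(obs$Cs <= 0)) {
    stop("observations outside the fitting domain (need D > 0.05, Cs > 0)",
         call. = FALSE)
  }

  if (method == "lme") {
    return(fit_g1_lme(obs))
  }
  if (method == "two_stage") {
    return(fit_g1_two_stage(obs))
  }

  groups <- split(obs, obs[[by]])
  res <- lapply(names(groups), function(g) fit_g1_one(groups[[g]], g))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Single-group least squares. The model is linear in its one free
# parameter (g0 is fixed at zero), so the least-squares minimiser of the
# conductance residuals has a closed form: moving the intercept-free term
# to the left, gs - 1.6 A/Cs = g1 * 1.6 A/(Cs sqrt(D)), a regression
# through the origin. This is identical to what an iterative nonlinear
# fit would converge to, and is robust on zero-residual data.
fit_g1_one <- function(d, label) {
  if (nrow(d) < 10) {
    stop(sprintf("group '%s' has fewer than 10 observations", label),
         call. = FALSE)
  }
  x <- 1.6 * d$A / (d$Cs * sqrt(d$D))
  y <- d$gs - 1.6 * d$A / d$Cs
  sxx <- sum(x^2)
  if (sxx <= 0) {
    warning(sprintf("group '%s': degenerate design (no A signal)", label))
    return(data.frame(group = label, g1_hat = NA_real_, se = NA_real_,
                      n = nrow(d)))
  }
  g1_hat <- sum(x * y) / sxx
  dof <- nrow(d) - 1L
  rss <- sum((y - g1_hat * x)^2)
  se <- sqrt(rss / dof / sxx)
  data.frame(group = label, g1_hat = g1_hat, se = se, n = nrow(d))
}

# Species-within-PFT two-stage estimator: species fits, then a
# precision-weighted mean per PFT.
fit_g1_two_stage <- function(obs) {
  res <- lapply(split(obs, obs$pft), function(d) {
    sp <- do.call(rbind, lapply(split(d, d$species), function(s) {
      fit_g1_one(s, s$species[1])
    }))
    sp <- sp[is.finite(sp$g1_hat) & is.finite(sp$se) & sp$se > 0, ]
    if (nrow(sp) == 0) {
      return(data.frame(group = d$pft[1], g1_hat = NA_real_, se = NA_real_,
                        n = nrow(d)))
    }
    w <- 1 / sp$se^2
    data.frame(group = d$pft[1],
               g1_hat = sum(w * sp$g1_hat) / sum(w),
               se = sqrt(1 / sum(w)),
               n = nrow(d))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Mixed-effects route: linear in g1 after moving the g0-free intercept term
# to the left-hand side, with a random species slope.
fit_g1_lme <- function(obs) {
  res <- lapply(split(obs, obs$pft), function(d) {
    d$x <- 1.6 * d$A / (d$Cs * sqrt(d$D))
    d$y <- d$gs - 1.6 * d$A / d$Cs
    n_sp <- length(unique(d$species))
    if (n_sp < 2) return(fit_g1_one(d, d$pft[1]))
    fit <- tryCatch(
      nlme::lme(y ~ x - 1, random = ~ x - 1 | species, data = d,
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warning(sprintf("pft '%s': mixed model failed, using pooled nls",
                      d$pft[1]))
      return(fit_g1_one(d, d$pft[1]))
    }
    s <- summary(fit)$tTable
    data.frame(group = d$pft[1], g1_hat = s["x", "Value"],
               se = s["x", "Std.Error"], n = nrow(d))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
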