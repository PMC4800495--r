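test_that("optimal-model conductance matches hand-evaluated values", {
  p4 <- stomatal_params("medlyn", g1 = 4)
  expect_equal(medlyn_gs(10, 400, 1.0, p4), 1.6 * (1 + 4) * 10 / 400,
               tolerance = 1e-12)
  expect_equal(medlyn_gs(10, 400, 1.0, p4), 0.200, tolerance = 1e-12)
  p2 <- stomatal_params("medlyn", g1 = 2)
  expect_equal(medlyn_gs(20, 400, 4.0, p2), 1.6 * (1 + 1) * 20 / 400,
               tolerance = 1e-12)
  expect_equal(medlyn_gs(20, 400, 4.0, p2), 0.160, tolerance = 1e-12)
  # zero assimilation, g0 = 0 -> zero conductance
  expect_identical(medlyn_gs(0, 400, 1, p4), 0)
  expect_identical(medlyn_gs(-3, 400, 1, p4), 0)
})

test_that("optimal model is homogeneous of degree one in A", {
  p <- stomatal_params("medlyn", g1 = 3.7)
  expect_equal(medlyn_gs(24, 380, 1.7, p), 2 * medlyn_gs(12, 380, 1.7, p),
               tolerance = 1e-12)
})

test_that("default empirical scheme matches hand-evaluated values", {
  p <- stomatal_params("default_empirical", slope_a1 = 9, d0 = 1.5)
  expect_equal(default_empirical_gs(10, 400, 1.5, p, gamma = 40),
               9 * 10 / (360 * 2), tolerance = 1e-12)  # 0.125
  expect_equal(default_empirical_gs(10, 400, 0, p, gamma = 40),
               0.250, tolerance = 1e-12)
  expect_identical(default_empirical_gs(0, 400, 1.5, p, gamma = 40), 0)
  expect_error(default_empirical_gs(10, 30, 1.5, p, gamma = 40), "gamma")
})

test_that("both schemes are strictly decreasing in vpd for positive A", {
  vpd <- seq(0.2, 5, by = 0.1)
  med <- medlyn_gs(12, 400, vpd, stomatal_params("medlyn", g1 = 4))
  def <- default_empirical_gs(12, 400, vpd, test_default_scheme(),
                              gamma = 42.75)
  expect_true(all(diff(med) < 0))
  expect_true(all(diff(def) < 0))
})

test_that("limiting forms at large vpd: optimal floor vs empirical decay", {
  med <- stomatal_params("medlyn", g1 = 4)
  def <- test_default_scheme()
  big <- 1e6
  expect_equal(medlyn_gs(10, 400, big, med), 1.6 * 10 / 400,
               tolerance = 1e-2)
  expect_lt(default_empirical_gs(10, 400, big, def, gamma = 42.75), 1e-3)
})

test_that("vpd below the floor is clamped, not an error", {
  p <- stomatal_params("medlyn", g1 = 4)
  expect_equal(medlyn_gs(10, 400, 0, p), medlyn_gs(10, 400, 0.05, p))
  expect_error(medlyn_gs(10, 0, 1, p), "cs")
})

test_that("dark leaf with zero respiration returns the gradient-free equilibrium", {
  p <- photo_params(rd_25 = 1e-9)
  s <- solve_coupled(400, 1.5, 25, 0, p, stomatal_params("medlyn", g1 = 4))
  expect_equal(s$ci, 400)
  expect_equal(s$conductance_h2o, 0)
  expect_lt(abs(s$assimilation), 1e-8)
})

test_that("coupled ci matches a 0.01 grid-search oracle on random environments", {
  set.seed(71)
  photo <- photo_params()
  n <- 25  # a denser sweep runs in the acceptance suite
  cs <- runif(n, 300, 500); vpd <- runif(n, 0.2, 3.5)
  tl <- runif(n, 5, 38); par <- runif(n, 100, 2000)
  for (sp in list(stomatal_params("medlyn", g1 = 4),
                  test_default_scheme())) {
    sol <- solve_coupled(cs, vpd, tl, par, photo, sp)
    expect_true(all(abs(sol$residual) < 1e-6))
    for (i in seq_len(n)) {
      ci_star <- oracle_ci(cs[i], vpd[i], tl[i], par[i], photo, sp)
      expect_lt(abs(sol$ci[i] - ci_star), 0.1)
    }
  }
})

test_that("raising g1 raises ci and assimilation monotonically", {
  photo <- photo_params()
  out <- t(sapply(1:8, function(g) {
    s <- solve_coupled(400, 1.5, 25, 1500, photo,
                       stomatal_params("medlyn", g1 = g))
    c(ci = s$ci, a = s$assimilation)
  }))
  expect_true(all(diff(out[, "ci"]) > 0))
  expect_true(all(diff(out[, "a"]) > 0))
})

test_that("coupled solution is scheme-consistent to 1e-8", {
  photo <- photo_params()
  med <- stomatal_params("medlyn", g1 = 3)
  s <- solve_coupled(c(380, 420), c(0.8, 2.2), c(18, 30), c(800, 1600),
                     photo, med)
  expect_equal(s$conductance_h2o,
               medlyn_gs(s$assimilation, c(380, 420), c(0.8, 2.2), med),
               tolerance = 1e-8)
})

test_that("relative VPD sensitivity follows the analytic forms and ordering", {
  photo <- photo_params()
  med <- stomatal_params("medlyn", g1 = 4)
  def <- test_default_scheme()
  rep <- vpd_sensitivity_compare(photo, med, def, calibration_vpd = 1)
  g <- rep$grid
  # analytic medlyn sensitivity, checked against a finite difference
  d <- 3.5
  fd <- -(medlyn_gs(10, 400, d + 1e-6, med) -
            medlyn_gs(10, 400, d - 1e-6, med)) /
    (2e-6 * medlyn_gs(10, 400, d, med))
  expect_equal(g$rel_sens_medlyn[abs(g$vpd - d) < 1e-9], fd,
               tolerance = 1e-4)
  fd_def <- -(default_empirical_gs(10, 400, d + 1e-6, def, gamma = 42.75) -
                default_empirical_gs(10, 400, d - 1e-6, def, gamma = 42.75)) /
    (2e-6 * default_empirical_gs(10, 400, d, def, gamma = 42.75))
  expect_equal(g$rel_sens_default[abs(g$vpd - d) < 1e-9], fd_def,
               tolerance = 1e-4)
  # the default scheme is the more VPD-sensitive one beyond 3 kPa
  expect_true(rep$default_more_sensitive_above_3)
  # calibration makes the curves agree at the calibration point
  i <- which(abs(g$vpd - 1) < 1e-9)
  expect_equal(g$gs_medlyn[i], g$gs_default[i], tolerance = 1e-12)
})
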