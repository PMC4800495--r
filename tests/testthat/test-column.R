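forcing_days <- function(n = 30, tmax = 22, sw = 240, vpd = 1.2,
                         precip = 2, doy0 = 166) {
  data.frame(year = 1, doy = doy0 + seq_len(n) - 1, tmax = tmax,
             shortwave = sw, vpd_midday = vpd, precip = precip)
}

test_that("a dark canopy evaporates nothing and maximises the tmax proxy", {
  cfg <- column_config()
  photo <- photo_params(rd_25 = 1e-9)
  day <- forcing_days(1)
  day$shortwave <- 240
  dark <- day; dark$tmax <- 22
  s_dark <- step_day(list(soil_water = 150), dark, cfg, photo,
                     stomatal_params("medlyn", g1 = 4), ca = 400)
  # PAR comes from shortwave; kill light by zeroing it in a second config
  cfg0 <- column_config(par_factor = 0)
  s0 <- step_day(list(soil_water = 150), day, cfg0, photo,
                 stomatal_params("medlyn", g1 = 4), ca = 400)
  expect_equal(s0$et, 0)
  expect_equal(s0$sensible_flux, s0$available_energy)
  s_open <- step_day(list(soil_water = 150), day, cfg, photo,
                     stomatal_params("medlyn", g1 = 4), ca = 400)
  expect_gt(s_open$et, 0)
  expect_gt(s0$tmax_surface, s_open$tmax_surface)
})

test_that("water balance closes to 1e-6 mm on arbitrary runs", {
  f <- generate_forcing(weather_config(n_years = 3, mean_annual_tmax = 4,
                                       seed = 14))
  cfg <- column_config(bucket_capacity = 120, initial_soil_water = 80)
  run <- run_column(f, cfg, photo_params(), stomatal_params("medlyn",
                                                            g1 = 2.35))
  closure <- sum(f$precip) - sum(run$et) - sum(run$runoff) -
    (run$soil_water[nrow(run)] - cfg$initial_soil_water)
  expect_lt(abs(closure), 1e-6)
  expect_true(all(run$soil_water >= 0 &
                    run$soil_water <= cfg$bucket_capacity + 1e-9))
  expect_true(all(run$et >= 0))
})

test_that("energy partition closes to 1e-6 W m-2 every day", {
  f <- generate_forcing(weather_config(n_years = 2, mean_annual_tmax = 6,
                                       seed = 15))
  run <- run_column(f, column_config(), photo_params(),
                    stomatal_params("medlyn", g1 = 3))
  expect_lt(max(abs(run$latent + run$sensible - run$available_energy)),
            1e-6)
})

test_that("higher g1 gives higher daily ET and lower tmax proxy, water-unlimited", {
  f <- forcing_days(20, tmax = 24, precip = 50)  # keep the bucket full
  f <- rbind(f)
  cfg <- column_config(bucket_capacity = 500, initial_soil_water = 500)
  photo <- photo_params()
  lo <- run_column(f, cfg, photo, stomatal_params("medlyn", g1 = 2))
  hi <- run_column(f, cfg, photo, stomatal_params("medlyn", g1 = 6))
  expect_true(all(hi$et > lo$et))
  expect_true(all(hi$tmax_surface < lo$tmax_surface))
})

test_that("a rainless run cannot evaporate more than its initial store", {
  f <- forcing_days(60, tmax = 26, vpd = 2, precip = 0)
  cfg <- column_config(bucket_capacity = 100, initial_soil_water = 40)
  run <- run_column(f, cfg, photo_params(),
                    stomatal_params("medlyn", g1 = 6))
  expect_lte(sum(run$et), 40 + 1e-9)
  # and a dry-started run evaporates nothing
  cfg0 <- column_config(bucket_capacity = 100, initial_soil_water = 0)
  f0 <- f; f0$precip <- 0
  run0 <- run_column(f0, cfg0, photo_params(),
                     stomatal_params("medlyn", g1 = 6))
  expect_equal(sum(run0$et), 0)
})

test_that("run_column equals a manual fold of step_day", {
  f <- generate_forcing(weather_config(n_years = 1, mean_annual_tmax = 5,
                                       seed = 33))
  f <- f[120:200, ]
  cfg <- column_config()
  photo <- photo_params()
  sp <- stomatal_params("medlyn", g1 = 2.35)
  run <- run_column(f, cfg, photo, sp)
  sw <- cfg$initial_soil_water
  for (i in seq_len(nrow(f))) {
    st <- step_day(list(soil_water = sw), f[i, ], cfg, photo, sp)
    expect_equal(st$et, run$et[i], tolerance = 1e-12)
    expect_equal(st$tmax_surface, run$tmax_surface[i], tolerance = 1e-12)
    sw <- st$soil_water
  }
  expect_equal(sw, run$soil_water[nrow(f)], tolerance = 1e-12)
})

test_that("between-scheme ET gap shrinks from 25 C to 40 C with inhibition on", {
  # same radiation and VPD, only leaf temperature differs: isolates the
  # peaked photosynthetic response
  cfg <- column_config(bucket_capacity = 500, initial_soil_water = 500)
  photo <- photo_params(vcmax_25 = 60, peaked = TRUE)
  med <- stomatal_params("medlyn", g1 = 2.35)
  def <- stomatal_params("default_empirical", slope_a1 = 9, d0 = 1.5)
  gap_at <- function(tm) {
    f <- forcing_days(1, tmax = tm, sw = 250, vpd = 1.5, precip = 0)
    ec <- step_day(list(soil_water = 500), f, cfg, photo, def)$et
    ee <- step_day(list(soil_water = 500), f, cfg, photo, med)$et
    abs(ee - ec)
  }
  expect_lt(gap_at(40), gap_at(25))
})

test_that("configuration guards reject inconsistent stores", {
  expect_error(column_config(initial_soil_water = 300,
                             bucket_capacity = 200), "initial_soil_water")
  expect_error(column_config(lai_climatology = rep(1, 5)), "12")
})
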