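test_that("the gut-pigment power fit is exact on exact points", {
  rec <- data.frame(length_oal = c(5, 10, 20), gpig = 0.01 * c(5, 10, 20)^2)
  fit <- fit_gut_pigment_power(rec)
  expect_equal(fit$a, 0.01, tolerance = 1e-12)
  expect_equal(fit$b, 2, tolerance = 1e-12)
  # duplicating a point leaves an exact fit unchanged
  fit2 <- fit_gut_pigment_power(rbind(rec, rec[2, ]))
  expect_equal(fit2$a, fit$a, tolerance = 1e-12)
  expect_equal(fit2$b, fit$b, tolerance = 1e-12)
})

test_that("degenerate pigment data fall back or error", {
  two <- data.frame(length_oal = c(10, 20), gpig = c(1, 4))
  expect_warning(fit <- fit_gut_pigment_power(two), "mean")
  expect_equal(fit$fallback_mean, 2.5)
  expect_true(is.na(fit$a))
  expect_error(fit_gut_pigment_power(data.frame(length_oal = 1:3, gpig = 0)),
               "positive")
})

test_that("gut passage time follows the printed log-length form with Q10 scaling", {
  cfg <- q10_config(2, t_ref = 10)
  expect_equal(gut_passage_time(exp(1), 10, cfg), 0.007, tolerance = 1e-12)
  expect_equal(gut_passage_time(20, 10, cfg), 5.209874, tolerance = 1e-6)
  # a 10-degree warming halves GPT at Q10 = 2
  expect_equal(gut_passage_time(20, 20, cfg), gut_passage_time(20, 10, cfg) / 2)
  expect_equal(q10_factor(cfg, 10), 1)
  expect_error(gut_passage_time(2, 10, cfg), "non-positive")
})

test_that("GPT is increasing in length and decreasing in temperature", {
  cfg <- q10_config(2, t_ref = 12)
  L <- seq(5, 130, by = 5)
  g <- gut_passage_time(L, 12, cfg)
  expect_true(all(diff(g) > 0))
  for (tt in c(0, 6, 18)) {
    expect_true(all(gut_passage_time(L, tt, cfg) >
                      gut_passage_time(L, tt + 5, cfg)))
  }
})

test_that("population grazing weights day/night hours and is linear in abundance", {
  cfg <- q10_config(2, t_ref = 12)
  # fallback fit with mean pigment equal to GPT(20) gives rate 1 ng h^-1
  fit <- structure(list(a = NA_real_, b = NA_real_, n_points = 5,
                        fallback_mean = gut_passage_time(20, 12, cfg)),
                   class = "pigment_fit")
  pop <- one_bin_pop(mid = 20, day = 1, night = 1)
  gr <- population_grazing(pop, fit, temp = 12, q10cfg = cfg)
  expect_equal(gr$pigment_mg_m2_d, 24 * 1e-6, tolerance = 1e-12)
  pop2 <- one_bin_pop(mid = 20, day = 2, night = 2)
  gr2 <- population_grazing(pop2, fit, temp = 12, q10cfg = cfg)
  expect_equal(gr2$pigment_mg_m2_d, 2 * gr$pigment_mg_m2_d)
  # zero abundance, zero grazing
  gr0 <- population_grazing(one_bin_pop(mid = 20, day = 0, night = 0),
                            fit, 12, cfg)
  expect_equal(gr0$pigment_mg_m2_d, 0)
  expect_error(population_grazing(pop, fit, temp = NULL, q10cfg = cfg),
               "temperature")
})

test_that("population grazing matches the analytic bin sum at machine precision", {
  sc <- noiseless_scenario()
  cyc <- quiet(generate_cycle(sc, seed = 9))
  pops <- bind_tow_pops(cyc$tows)
  pop <- day_night_average(pops)
  fit <- fit_gut_pigment_power(cyc$gut_pigments)
  cfg <- q10_config(2, t_ref = sc$water_temp)
  gr <- quiet(population_grazing(pop, fit, sc$water_temp, cfg))
  ok <- pop$mid > exp(2.6 / 2.607)
  manual <- sum((14 * pop$day[ok] + 10 * pop$night[ok]) *
                  fit$a * pop$mid[ok]^fit$b /
                  ((2.607 * log(pop$mid[ok]) - 2.6)))
  expect_equal(gr$pigment_mg_m2_d, manual * 1e-6, tolerance = 1e-12)
})

test_that("pigment-based egestion is the egestion efficiency times grazing", {
  expect_equal(egestion_gpig(100), 36)
  expect_equal(egestion_gpig(0), 0)
  expect_equal(egestion_gpig(57.3, ee = 1), 57.3)
  g <- runif(20, 0, 500)
  expect_true(all(egestion_gpig(g) <= g))
  expect_error(egestion_gpig(10, ee = 1.2), "ee")
})

test_that("length-based pellet production matches its printed coefficients", {
  cfg0 <- q10_config(2, t_ref = 0)
  expect_equal(pellet_production_rate(50, temp = 0, cfg0), 0.186670,
               tolerance = 1e-5)
  expect_equal(pellet_carbon_from_length(50), 178.3546, tolerance = 1e-4)
  expect_equal(pellet_carbon_from_length(1), 0.055)
  # size -> 0+: rate tends to the 0.5388 intercept
  expect_equal(pellet_production_rate(1e-9, 0, cfg0), 0.5388, tolerance = 1e-9)
  expect_error(pellet_production_rate(-1), "positive")

  pop <- one_bin_pop(mid = 50, day = 1, night = 1)
  eg <- egestion_iversen(pop, temp = 0, q10cfg = cfg0)
  expect_equal(eg$total, 24 * 0.186670 * 178.3546 * 1e-3, tolerance = 1e-4)
  # homogeneous degree 1 in abundance
  eg2 <- egestion_iversen(one_bin_pop(mid = 50, day = 2, night = 2), 0, cfg0)
  expect_equal(eg2$total, 2 * eg$total)
})
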