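test_that("trap flux is mass over area and time, intensive in tube count", {
  s <- trap_sample(depth = 100, duration = 3, n_tubes = 1, poc_mass = 1)
  expect_equal(poc_flux(s), 86.6149, tolerance = 1e-4)
  expect_equal(poc_flux(trap_sample(100, 3, 1, 0)), 0)
  s2 <- trap_sample(100, 3, 2, 2)
  expect_equal(poc_flux(s2), poc_flux(s))
  expect_error(trap_sample(100, 0, 1, 1), "duration")
})

test_that("power-law attenuation fit matches the two-point closed form", {
  tab <- data.frame(depth = c(70, 300), flux = c(210, 119))
  fit <- fit_attenuation(tab, z0 = 70)
  expect_equal(fit$f0, 210, tolerance = 1e-9)
  expect_equal(fit$b, log(210 / 119) / log(300 / 70), tolerance = 1e-9)
  expect_equal(round(fit$b, 3), 0.390)
  # identity at the reference depth and b = 0 for constant flux
  expect_equal(flux_at_depth(fit, 70), fit$f0)
  flat <- fit_attenuation(data.frame(depth = c(70, 300), flux = c(50, 50)), 70)
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_error(fit_attenuation(data.frame(depth = 70, flux = 10), 70), ">= 2")
})

test_that("pellet carbon follows the volume allometry and is additive", {
  expect_equal(pellet_carbon(1), 26.9153, tolerance = 1e-4)
  expect_equal(pellet_carbon(10), 115.8777, tolerance = 1e-4)
  v <- sort(runif(10, 0.1, 20))
  expect_true(all(diff(pellet_carbon(v)) > 0))

  pel <- data.frame(length = c(4, 6), width = c(1.5, 2))
  s <- trap_sample(70, 5, 3, poc_mass = 50, pellets = pel)
  both <- pellet_carbon_flux(s)
  each <- vapply(1:2, function(i)
    pellet_carbon_flux(trap_sample(70, 5, 3, 50, pellets = pel[i, ]))$pellet_flux,
    0)
  expect_equal(both$pellet_flux, sum(each), tolerance = 1e-12)
  # cylinder volume rule
  expect_equal(pellet_volume(4, 1.5), pi * 0.75^2 * 4)
  expect_lt(pellet_volume(4, 1.5, "ellipsoid"), pellet_volume(4, 1.5))

  empty <- trap_sample(70, 5, 3, 50,
                       pellets = data.frame(length = numeric(), width = numeric()))
  expect_equal(pellet_carbon_flux(empty)$pellet_flux, 0)
  expect_equal(pellet_carbon_flux(empty)$fraction, 0)
})

test_that("pellet flux exceeding total POC is reported, not hidden", {
  pel <- data.frame(length = rep(20, 50), width = rep(7, 50))
  s <- trap_sample(70, 1, 1, poc_mass = 0.5, pellets = pel)
  expect_warning(p <- pellet_carbon_flux(s), "exceeds")
  expect_gt(p$fraction, 1)
})

test_that("the fitted curve interpolates noiseless fluxes; the exponential
           alternative shifts mid-depth flux by a known bounded amount", {
  z <- c(70, 100, 300); f0 <- 210; b <- 0.39
  tab <- data.frame(depth = z, flux = f0 * (z / 70)^(-b))
  pow <- fit_attenuation(tab, 70)
  expect_equal(flux_at_depth(pow, z), tab$flux, tolerance = 1e-10)
  ex <- fit_attenuation(tab, 70, form = "exponential")
  ratio <- flux_at_depth(ex, 170) / flux_at_depth(pow, 170)
  # frozen from the closed-form log-space regression on these three depths
  expect_equal(ratio, 1.082381, tolerance = 1e-5)
})

test_that("attenuation recovery from noisy traps stays within 0.1 of truth", {
  sc <- cycle_scenario()
  errs <- vapply(1:200, function(i) {
    tab <- poc_flux_table(generate_trap_samples(sc, seed = 5000 + i))
    fit_attenuation(tab, z0 = sc$euphotic_depth)$b - sc$true_params$b_true
  }, 0)
  expect_lt(median(abs(errs)), 0.1)
})
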