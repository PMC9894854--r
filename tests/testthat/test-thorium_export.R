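test_that("salinity-derived 238U follows the configured linear relation", {
  expect_equal(u238_from_salinity(35), 2.436, tolerance = 1e-12)
  expect_warning(a0 <- u238_from_salinity(0), "oceanic")
  expect_equal(a0, -0.315)
  cfg <- th_config(u_coeffs = c(slope = 0, intercept = 2.4))
  expect_equal(u238_from_salinity(c(34, 35, 36), cfg), rep(2.4, 3))
})

test_that("steady-state export integrates the 238U-234Th deficiency", {
  cfg <- th_config()
  a_u <- u238_from_salinity(35)
  depths <- c(5, 25, 50, 75, 100)
  # zero deficiency, zero flux
  p0 <- th_profile("2026-01-01", depths, rep(a_u, 5), 0.05, 35)
  expect_equal(ss_export(p0, 100, cfg)$flux, 0, tolerance = 1e-12)
  # uniform 0.5 dpm L^-1 deficiency over 100 m
  p1 <- th_profile("2026-01-01", depths, rep(a_u - 0.5, 5), 0.05, 35)
  ss <- ss_export(p1, 100, cfg)
  expect_equal(ss$flux, cfg$lambda_234 * 0.5 * 1000 * 100, tolerance = 1e-9)
  expect_equal(ss$flux, 1438.06, tolerance = 1e-4)
  expect_gt(ss$sd, 0)
  # linearity in the deficiency (kappa = 0)
  p2 <- th_profile("2026-01-01", depths, rep(a_u - 1.0, 5), 0.05, 35)
  expect_equal(ss_export(p2, 100, cfg)$flux, 2 * ss$flux, tolerance = 1e-9)
  expect_error(ss_export(p1, 150, cfg), "deepest")
})

test_that("the mixing correction vanishes on a linear profile", {
  cfg <- th_config(kappa = 10)
  depths <- seq(10, 150, by = 20)
  a_lin <- 2.4 - 0.002 * depths
  p <- th_profile("2026-01-01", depths, a_lin, 0.05, 35)
  with_mix <- ss_export(p, 130, cfg)
  expect_equal(with_mix$components$mixing, 0, tolerance = 1e-9)
  # and curvature produces a nonzero term
  a_curv <- 2.4 - 1e-5 * depths^2
  pc <- th_profile("2026-01-01", depths, a_curv, 0.05, 35)
  expect_gt(abs(ss_export(pc, 130, cfg)$components$mixing), 0)
})

test_that("NSS export collapses to SS for identical profiles and tracks inventory change", {
  depths <- c(5, 25, 50, 75, 100)
  a <- 2.436 - c(0.6, 0.6, 0.5, 0.3, 0.1)
  p1 <- th_profile("2026-01-01", depths, a, 0.05, 35)
  p2 <- th_profile("2026-01-06", depths, a, 0.05, 35)
  expect_equal(nss_export(p1, p2, 100)$flux, ss_export(p1, 100)$flux,
               tolerance = 1e-9)
  # growing inventory at fixed mean deficiency lowers the NSS estimate
  eps <- 0.05
  p1l <- th_profile("2026-01-01", depths, a - eps, 0.05, 35)
  p2h <- th_profile("2026-01-06", depths, a + eps, 0.05, 35)
  expect_lt(nss_export(p1l, p2h, 100)$flux, ss_export(p1, 100)$flux)
  expect_error(nss_export(p2, p1, 100), "after")
})

test_that("NSS inverts a forward-simulated 1D thorium balance within 5%", {
  # dA/dt = lambda (A_U - A) - P(z); closed-form solution between occupations
  cfg <- th_config()
  a_u <- u238_from_salinity(34.8)
  depths <- seq(0, 120, by = 10)
  p_z <- 0.02 * exp(-depths / 50)             # export production, dpm L^-1 d^-1
  a1 <- a_u - 0.3 * exp(-depths / 60)         # initial state, out of equilibrium
  dt <- 6
  a_inf <- a_u - p_z / cfg$lambda_234
  a2 <- a_inf + (a1 - a_inf) * exp(-cfg$lambda_234 * dt)
  p1 <- th_profile("2026-01-01", depths[-1], a1[-1], 0, 34.8)
  p2 <- th_profile("2026-01-07", depths[-1], a2[-1], 0, 34.8)
  truth <- 1000 * pracma::trapz(depths, p_z)  # dpm m^-2 d^-1 integrated to 120 m
  est <- nss_export(p1, p2, 120, cfg)$flux
  expect_lt(abs(est - truth) / truth, 0.05)
})

test_that("integration converges to the analytic integral as the grid refines", {
  cfg <- th_config()
  a_u <- 2.436
  defic <- function(z) 0.6 * (1 - (z / 100)^2)    # smooth, quadratic
  analytic <- cfg$lambda_234 * 1000 * (0.6 * (100 - 100 / 3))
  err <- vapply(c(11, 21, 41), function(n) {
    z <- seq(0.5, 100, length.out = n)
    p <- th_profile("2026-01-01", z, a_u - defic(z), 0, 35)
    abs(ss_export(p, 100, cfg)$flux - analytic)
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_gt(err[1] / err[2], 3)   # roughly second-order
})

test_that("C:234Th conversion is linear unit arithmetic", {
  expect_equal(poc_flux_from_th(0, 5), 0)
  expect_equal(poc_flux_from_th(1000, 5), 60.055)
  expect_equal(poc_flux_from_th(2000, 5), 2 * poc_flux_from_th(1000, 5))
  expect_equal(poc_flux_from_th(1000, 10), 2 * poc_flux_from_th(1000, 5))
})
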