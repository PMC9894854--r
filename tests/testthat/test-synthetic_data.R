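test_that("generation is deterministic in (scenario, seed) and varies with seed", {
  sc <- cycle_scenario()
  c1 <- quiet(generate_cycle(sc, seed = 1))
  c2 <- quiet(generate_cycle(sc, seed = 1))
  expect_identical(c1, c2)

  c3 <- quiet(generate_cycle(sc, seed = 2))
  expect_false(identical(c1$gut_pigments$gpig, c3$gut_pigments$gpig))
  expect_identical(c1$truth, c3$truth)
})

test_that("a zero-salp scenario yields empty tows but populated traps", {
  sc <- cycle_scenario(true_params = ground_truth(
    abundance_total = c(blastozooid = 0, oozooid = 0)))
  cyc <- quiet(generate_cycle(sc, seed = 4))
  counts <- vapply(cyc$tows, function(t) nrow(t$individuals), 0L)
  expect_true(all(counts == 0))
  expect_equal(nrow(cyc$gut_pigments), 0)
  expect_length(cyc$traps, 4)
  expect_true(all(vapply(cyc$traps, function(s) s$poc_mass, 0) > 0))
})

test_that("invalid scenarios fail naming the offending field", {
  expect_error(cycle_scenario(duration_days = -1), "duration_days")
  expect_error(cycle_scenario(trap_depths = c(100, 70)), "trap_depths")
  expect_error(cycle_scenario(euphotic_depth = 80,
                              trap_depths = c(70, 100)), "euphotic_depth")
  expect_error(ground_truth(abundance_total = c(blastozooid = -5, oozooid = 0)),
               "abundance")
  expect_error(cycle_scenario(salinity = 20), "salinity")
})

test_that("tow counts are Poisson around abundance * volume / tow depth", {
  # one stage at 20 ind m^-2; mean of count/volume*depth over many tows -> 20
  sc <- cycle_scenario(duration_days = 7.5, tows_per_day = 10,
                       true_params = ground_truth(
                         abundance_total = c(blastozooid = 20, oozooid = 0)))
  tows <- generate_salp_tows(sc, seed = 7)
  areal <- vapply(tows, function(t)
    nrow(t$individuals) / t$volume_filtered * t$tow_depth, 0)
  expect_equal(mean(areal), 20, tolerance = 0.05)
  expect_true(all(vapply(tows, function(t) t$volume_filtered, 0) >= 150))
  expect_true(all(vapply(tows, function(t) t$volume_filtered, 0) <= 500))
  expect_true(any(vapply(tows, function(t) t$is_night, TRUE)) &&
                any(!vapply(tows, function(t) t$is_night, TRUE)))
})

test_that("noiseless gut pigments recover the allometry exactly", {
  sc <- noiseless_scenario(true_params = ground_truth(
    pigment_power_a = 0.01, pigment_power_b = 2))
  gp <- generate_gut_pigments(sc, seed = 2)
  expect_gt(nrow(gp), 10)
  fit <- fit_gut_pigment_power(gp)
  expect_equal(fit$a, 0.01, tolerance = 1e-10)
  expect_equal(fit$b, 2, tolerance = 1e-10)
  # <= 10 individuals per stage per tow
  tab <- table(gp$tow_id, gp$stage)
  expect_true(all(tab <= 10))
})

test_that("thorium profiles encode the true steady-state export", {
  sc <- noiseless_scenario()
  prof <- generate_th_profiles(sc, seed = 3)
  ss <- ss_export(prof[[1]], z_int = sc$euphotic_depth)
  expect_equal(ss$flux, sc$true_params$th_export_true, tolerance = 1e-9)
  # identical mean profiles: NSS equals SS
  nss <- nss_export(prof[[1]], prof[[2]], z_int = sc$euphotic_depth)
  expect_equal(nss$flux, ss$flux, tolerance = 1e-9)
  expect_true(all(prof[[1]]$salinity >= 34 & prof[[1]]$salinity <= 35.5))

  # zero export: total 234Th equals salinity-derived 238U everywhere
  sc0 <- noiseless_scenario(true_params = ground_truth(th_export_true = 0))
  p0 <- generate_th_profiles(sc0, seed = 3)[[1]]
  expect_equal(p0$a_th, u238_from_salinity(p0$salinity), tolerance = 1e-12)
})

test_that("noiseless traps recover F0 and the attenuation exponent", {
  sc <- noiseless_scenario()
  traps <- generate_trap_samples(sc, seed = 5)
  tab <- poc_flux_table(traps)
  expect_equal(tab$flux[tab$depth == sc$euphotic_depth],
               sc$true_params$f0_true, tolerance = 1e-12)
  fit <- fit_attenuation(tab, z0 = sc$euphotic_depth)
  expect_equal(fit$f0, sc$true_params$f0_true, tolerance = 1e-9)
  expect_equal(fit$b, sc$true_params$b_true, tolerance = 1e-9)
})

test_that("noiseless dilution bottles invert to the true rates; g = 0 equalises treatments", {
  sc <- noiseless_scenario()
  dil <- generate_dilution_experiments(sc, seed = 6)
  r <- dilution_rates(dil$bottles)
  expect_equal(unique(round(r$g, 12)), sc$true_params$g_true)
  expect_equal(unique(round(r$mu_insitu, 12)), sc$true_params$mu_true)

  sc0 <- noiseless_scenario(true_params = ground_truth(g_true = 0))
  d0 <- generate_dilution_experiments(sc0, seed = 6)
  r0 <- dilution_rates(d0$bottles)
  expect_equal(r0$k_a, r0$k_b, tolerance = 1e-12)
})

test_that("generated quantities respect sign constraints", {
  cyc <- quiet(generate_cycle(cycle_scenario(), seed = 11))
  expect_true(all(cyc$gut_pigments$gpig >= 0))
  expect_true(all(cyc$th_profiles[[1]]$a_th >= 0))
  expect_true(all(vapply(cyc$traps, function(s) s$poc_mass, 0) >= 0))
  expect_true(all(cyc$npp$npp >= 0))
  expect_true(all(cyc$truth$abundance_by_bin$ind_m2 >= 0))
})
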