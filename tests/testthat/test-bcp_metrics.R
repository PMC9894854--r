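test_that("pump metrics obey their identities and bounds", {
  expect_equal(ez_ratio(100, 100), 1)
  expect_error(ez_ratio(10, 0), "positive")
  fit <- fit_attenuation(data.frame(depth = c(70, 300), flux = c(210, 119)), 70)
  expect_equal(t100(fit, 70), (170 / 70)^(-fit$b))
  expect_equal(round(t100(fit, 70), 3), 0.707)
  flat <- fit_attenuation(data.frame(depth = c(70, 300), flux = c(80, 80)), 70)
  expect_equal(t100(flat, 70), 1)
  # T100 in (0, 1] for non-negative attenuation
  for (b in seq(0, 2, by = 0.25)) {
    f <- structure(list(f0 = 100, b = b, z0 = 70, form = "power"),
                   class = "attenuation_fit")
    expect_true(t100(f, 70) > 0 && t100(f, 70) <= 1)
  }
  expect_equal(bcp_efficiency(0.42, 0.65), 0.273)
  expect_equal(bcp_efficiency(0, 0.9), 0)
  expect_equal(bcp_efficiency(0.3, 0.5), bcp_efficiency(0.5, 0.3))
  # all metrics invariant to a common carbon-unit rescaling
  expect_equal(ez_ratio(210, 452), ez_ratio(2.10, 4.52))
})

test_that("salp : non-salp flux ratios interpolate geometrically", {
  salp <- data.frame(depth = c(70, 300), flux = c(210, 119))
  non <- data.frame(depth = c(70, 300), flux = c(25, 19))
  r <- salp_nonsalp_ratio(list(S = salp, N = non),
                          data.frame(salp = "S", nonsalp = "N"))
  expect_equal(r$per_depth$ratio[r$per_depth$depth == 300], 119 / 19,
               tolerance = 1e-12)
  expect_equal(round(119 / 19, 2), 6.26)
  ident <- salp_nonsalp_ratio(list(A = salp, B = salp),
                              data.frame(salp = "A", nonsalp = "B"))
  expect_true(all(abs(ident$per_depth$ratio - 1) < 1e-12))
  expect_warning(
    miss <- salp_nonsalp_ratio(list(S = salp),
                               data.frame(salp = "S", nonsalp = "X")),
    "skipped")
  expect_equal(nrow(miss$per_depth), 0)
})

test_that("end-to-end synthetic metrics equal the analytic ground truth without noise", {
  sc <- noiseless_scenario()
  cyc <- quiet(generate_cycle(sc, seed = 12))
  res <- quiet(run_pipeline(pipeline_config(cycle = cyc)))
  gt <- sc$true_params
  ez_true <- gt$f0_true / cyc$truth$npp_int
  t100_true <- ((sc$euphotic_depth + 100) / sc$euphotic_depth)^(-gt$b_true)
  expect_equal(res$budget$ez, ez_true, tolerance = 1e-9)
  expect_equal(res$budget$t100, t100_true, tolerance = 1e-9)
  expect_equal(res$budget$efficiency, ez_true * t100_true, tolerance = 1e-9)
  expect_equal(res$plankton$npp_int, cyc$truth$npp_int, tolerance = 1e-9)
  expect_equal(res$thorium$poc[["ss"]],
               poc_flux_from_th(gt$th_export_true, sc$c_to_th),
               tolerance = 1e-9)
})

test_that("cycle budgets validate inputs and expose egestion:flux diagnostics", {
  fit <- fit_attenuation(data.frame(depth = c(70, 300), flux = c(210, 119)), 70)
  tab <- data.frame(depth = c(70, 300), flux = c(210, 119))
  b <- cycle_budget("C1", npp = 452, flux_table = tab, attenuation = fit,
                    z_eu = 70, grazings = c(uzoo = 100, mesozoo = 10, salp = 50),
                    egestion = c(gpig = 80, iversen = 120))
  expect_equal(b$flux_ez, 210)
  expect_equal(round(b$ez, 2), 0.46)
  f200 <- flux_at_depth(fit, 200)
  expect_equal(unname(b$egestion_to_flux200["gpig"]), 80 / f200)
  expect_error(cycle_budget("C1", npp = 0, tab, fit, 70), "positive")
  s <- budget_summary(b)
  expect_equal(s$ez, b$ez)
  expect_equal(s$f0, fit$f0)
})
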