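# Configuration-driven orchestration of the full cycle budget: demography
# -> grazing/egestion -> trap fluxes -> thorium export -> plankton rates ->
# pump metrics.  One cycle per run; deterministic given inputs and
# configuration.

# equation constants recorded in the provenance log of every run
PROVENANCE_CONSTANTS <- list(
  gpt_slope = 2.607, gpt_intercept = 2.6, egestion_efficiency = 0.36,
  fprod_coef = 0.5388, fprod_exp = 0.0212, orgc_coef = 0.055,
  orgc_exp = 2.0665, pellet_c_slope = 0.634, pellet_c_intercept = 1.43,
  lambda_234 = log(2) / 24.1)

#' Build a pipeline configuration
#'
#' @param input_dir Directory of input tables (see [read_cycle_tables()]);
#'   ignored when `cycle` is given.
#' @param cycle Optional in-memory `synthetic_cycle` bundle.
#' @param out_dir Optional directory for intermediate tables, the summary
#'   JSON and the provenance log.
#' @param cycle_id Cycle label for outputs.
#' @param water_temp Ambient temperature, deg C (required; taken from the
#'   scenario when `cycle` is given).
#' @param z_eu Euphotic depth, m (required; from the scenario when `cycle`
#'   is given).
#' @param q10_gpt [q10_config()] for gut passage time; defaults to Q10 = 2
#'   referenced at the ambient temperature (scaling factor 1 unless
#'   reconfigured).
#' @param q10_iversen [q10_config()] for the length-based pellet production
#'   model (default Q10 = 2 about 0 deg C, its cold-water reference).
#' @param c_to_chl Carbon:chl ratio for pigment-based grazing (g:g).
#' @param ee Egestion efficiency.
#' @param biomass_coeffs Length--carbon allometry for
#'   [biomass_from_length()].
#' @param c_to_th C:234Th ratio, µmol C dpm^-1.
#' @param th_kappa Mixing coefficient for the thorium model, m^2 d^-1.
#' @param mesozoo_grazing Bulk non-salp mesozooplankton grazing,
#'   mg C m^-2 d^-1 (external input).
#' @param daynight_hours Photoperiod split, hours.
#' @param pellet_shape Pellet volume shape rule.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, cycle = NULL, out_dir = NULL,
                            cycle_id = NULL, water_temp = NULL, z_eu = NULL,
                            q10_gpt = NULL,
                            q10_iversen = q10_config(2, t_ref = 0),
                            c_to_chl = 50, ee = 0.36,
                            biomass_coeffs = c(a_w = 0.006, b_w = 2.58),
                            c_to_th = 5, th_kappa = 0, mesozoo_grazing = 0,
                            daynight_hours = c(day = 14, night = 10),
                            pellet_shape = "cylinder") {
  if (!is.null(cycle)) {
    stopifnot(inherits(cycle, "synthetic_cycle"))
    water_temp <- water_temp %||% cycle$scenario$water_temp
    z_eu <- z_eu %||% cycle$scenario$euphotic_depth
    c_to_th <- cycle$scenario$c_to_th %||% c_to_th
    cycle_id <- cycle_id %||% cycle$scenario$cycle_id
  } else if (is.null(input_dir)) {
    stopf("pipeline_config needs either 'input_dir' or 'cycle'")
  } else if (!dir.exists(input_dir)) {
    stopf("config error: input_dir does not exist: %s", input_dir)
  }
  if (is.null(water_temp)) stopf("config error: 'water_temp' is required")
  if (is.null(z_eu)) stopf("config error: 'z_eu' is required")
  q10_gpt <- q10_gpt %||% q10_config(2, t_ref = water_temp)
  structure(list(input_dir = input_dir, cycle = cycle, out_dir = out_dir,
                 cycle_id = cycle_id %||% "cycle", water_temp = water_temp,
                 z_eu = z_eu, q10_gpt = q10_gpt, q10_iversen = q10_iversen,
                 c_to_chl = c_to_chl, ee = ee, biomass_coeffs = biomass_coeffs,
                 c_to_th = c_to_th, th_kappa = th_kappa,
                 mesozoo_grazing = mesozoo_grazing,
                 daynight_hours = daynight_hours, pellet_shape = pellet_shape),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config error: file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$q10_gpt)) y$q10_gpt <- q10_config(y$q10_gpt$q10, y$q10_gpt$t_ref)
  if (!is.null(y$q10_iversen))
    y$q10_iversen <- q10_config(y$q10_iversen$q10, y$q10_iversen$t_ref)
  if (!is.null(y$biomass_coeffs)) y$biomass_coeffs <- unlist(y$biomass_coeffs)
  if (!is.null(y$daynight_hours)) y$daynight_hours <- unlist(y$daynight_hours)
  do.call(pipeline_config, y)
}

# md5 hash of the configuration (cycle data excluded), for provenance
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  slim <- unclass(config)
  slim$cycle <- NULL
  slim$q10_gpt <- unclass(slim$q10_gpt); slim$q10_iversen <- unclass(slim$q10_iversen)
  slim$biomass_coeffs <- as.list(slim$biomass_coeffs)
  slim$daynight_hours <- as.list(slim$daynight_hours)
  yaml::write_yaml(slim, tf)
  unname(tools::md5sum(tf))
}

#' Run the full cycle budget pipeline
#'
#' Executes every stage over the input tables and returns the assembled
#' [cycle_budget()] with all intermediate results; any stage failure aborts
#' with the stage name prefixed to the error.  When `config$out_dir` is set,
#' intermediate tables (CSV), the budget summary (JSON) and a provenance
#' log recording all equation constants and the configuration hash are
#' written there.
#'
#' Microzooplankton grazing enters the carbon balance as
#' `(g / mu_insitu) * NPP` (grazing expressed as the grazed fraction of
#' growth applied to the production it removes); non-salp mesozooplankton
#' grazing is an external configuration input.
#'
#' @param config A [pipeline_config()] (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @return List of class `pipeline_result`: `budget`, `demography`,
#'   `grazing`, `traps`, `thorium`, `plankton`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  dat <- stage("load", {
    if (!is.null(config$cycle)) config$cycle else read_cycle_tables(config$input_dir)
  })

  demography <- stage("demography", {
    tow_pops <- do.call(rbind, lapply(dat$tows, function(t)
      cbind(areal_abundance(t), tow_id = t$tow_id, is_night = t$is_night)))
    pop <- day_night_average(tow_pops)
    list(tow_pops = tow_pops, pop = pop,
         biomass_gC_m2 = biomass_from_length(pop, config$biomass_coeffs))
  })

  grazing <- stage("grazing", {
    if (nrow(dat$gut_pigments) == 0 || !any(dat$gut_pigments$gpig > 0)) {
      # no salps caught: grazing is zero, not an estimation failure
      fit <- NULL
      gr <- list(pigment_mg_m2_d = 0, carbon_mg_m2_d = 0, by_stage = NULL)
    } else {
      fit <- fit_gut_pigment_power(dat$gut_pigments)
      gr <- population_grazing(demography$pop, fit, config$water_temp,
                               config$q10_gpt, config$daynight_hours,
                               config$c_to_chl)
    }
    list(pigment_fit = fit, grazing = gr,
         egestion_gpig = egestion_gpig(gr$carbon_mg_m2_d, config$ee),
         egestion_iversen = egestion_iversen(demography$pop, config$water_temp,
                                             config$q10_iversen,
                                             config$daynight_hours))
  })

  traps <- stage("traps", {
    tab <- poc_flux_table(dat$traps, shape = config$pellet_shape)
    fit <- fit_attenuation(tab, z0 = config$z_eu)
    list(flux_table = tab, attenuation = fit)
  })

  thorium <- stage("thorium", {
    cfg <- th_config(kappa = config$th_kappa)
    ss <- lapply(dat$th_profiles, ss_export, z_int = config$z_eu, cfg = cfg)
    ss_mean <- mean(vapply(ss, `[[`, 0, "flux"))
    nss <- if (length(dat$th_profiles) >= 2)
      nss_export(dat$th_profiles[[1]], dat$th_profiles[[2]],
                 z_int = config$z_eu, cfg = cfg)
    else NULL
    list(ss = ss, ss_mean = ss_mean, nss = nss,
         poc = c(ss = poc_flux_from_th(ss_mean, config$c_to_th),
                 nss = if (is.null(nss)) NA_real_ else
                   poc_flux_from_th(nss$flux, config$c_to_th)))
  })

  plankton <- stage("plankton", {
    rates <- dilution_rates(dat$dilution$bottles)
    phi <- photoacclimation_phi(dat$dilution$cytometry)
    rates <- merge(rates, phi, by = "depth", all.x = TRUE)
    rates$mu_corrected <- correct_growth(rates$mu_insitu,
                                         ifelse(is.na(rates$phi), 0, rates$phi))
    npp_int <- integrate_profile(rate_profile(dat$npp$depth, dat$npp$npp,
                                              config$z_eu))
    mu_bar <- mean(rates$mu_corrected)
    g_bar <- mean(rates$g)
    uzoo <- if (mu_bar > 0) g_bar / mu_bar * npp_int else NA_real_
    list(rates = rates, npp_int = npp_int, mu = mu_bar, g = g_bar,
         uzoo_grazing = uzoo)
  })

  budget <- stage("budget", {
    b <- cycle_budget(
      cycle_id = config$cycle_id, npp = plankton$npp_int,
      flux_table = traps$flux_table, attenuation = traps$attenuation,
      z_eu = config$z_eu,
      grazings = c(uzoo = plankton$uzoo_grazing,
                   mesozoo = config$mesozoo_grazing,
                   salp = grazing$grazing$carbon_mg_m2_d),
      egestion = c(gpig = grazing$egestion_gpig,
                   iversen = grazing$egestion_iversen$total),
      th_poc = thorium$poc)
    b$balance <- net_rate_of_change(plankton$npp_int, plankton$uzoo_grazing,
                                    config$mesozoo_grazing,
                                    grazing$grazing$carbon_mg_m2_d)
    b
  })

  provenance <- list(constants = PROVENANCE_CONSTANTS,
                     config_hash = config_hash(config),
                     timestamp_free = TRUE)

  result <- structure(list(budget = budget, demography = demography,
                           grazing = grazing, traps = traps, thorium = thorium,
                           plankton = plankton, provenance = provenance),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

# intermediate tables, summary JSON and provenance log for a finished run
write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(config$out_dir, name),
                                           row.names = FALSE)
  w(result$demography$pop, "binned_abundance.csv")
  w(result$traps$flux_table, "trap_fluxes.csv")
  w(result$plankton$rates, "dilution_rates.csv")
  w(result$grazing$egestion_iversen$by_bin, "egestion_by_bin.csv")
  jsonlite::write_json(budget_summary(result$budget),
                       file.path(config$out_dir, "cycle_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  jsonlite::write_json(result$provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  b <- x$budget
  cat(sprintf("Cycle budget '%s'\n", b$cycle_id))
  cat(sprintf("  NPP (euphotic):        %8.1f mg C m-2 d-1\n", b$npp))
  cat(sprintf("  POC flux at z_eu:      %8.1f mg C m-2 d-1 (F0 = %.1f, b = %.3f)\n",
              b$flux_ez, b$attenuation$f0, b$attenuation$b))
  cat(sprintf("  Ez = %.3f, T100 = %.3f, BCP efficiency = %.3f\n",
              b$ez, b$t100, b$efficiency))
  cat(sprintf("  Grazing (uzoo/meso/salp): %.1f / %.1f / %.1f mg C m-2 d-1\n",
              b$grazings[["uzoo"]], b$grazings[["mesozoo"]], b$grazings[["salp"]]))
  cat(sprintf("  Egestion (Gpig/length-based): %.1f / %.1f mg C m-2 d-1\n",
              b$egestion[["gpig"]], b$egestion[["iversen"]]))
  invisible(x)
}
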