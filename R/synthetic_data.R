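# Synthetic Lagrangian-cycle generator with recorded ground truth.
#
# Emulates the field data streams of a salp-bloom process cycle — net tows,
# gut pigments, drifting sediment traps, 234Th profiles, dilution bottles
# and depth-resolved NPP — from a scenario whose true parameters are kept
# alongside, so every downstream estimator can be checked for recovery.
# Noise models are deliberately minimal and configurable: Poisson counts,
# lognormal multiplicative noise on pigments and per-tube trap POC, Gaussian
# additive noise on 234Th activities, lognormal noise on dilution chl.

# fixed RNG stream offsets per table, so generate_cycle() and the individual
# generators agree for the same (scenario, seed)
SEED_OFFSETS <- c(tows = 11L, pigments = 22L, thorium = 33L, traps = 44L,
                  dilution = 55L, npp = 66L)

#' Ground-truth parameter set for a synthetic cycle
#'
#' @param pigment_power_a,pigment_power_b Gut-pigment allometry
#'   `Gpig(L) = a * L^b` (ng ind^-1, L in mm).
#' @param f0_true True POC flux at the euphotic base, mg C m^-2 d^-1.
#' @param b_true True power-law attenuation exponent.
#' @param th_export_true True steady-state 234Th export at the euphotic
#'   base, dpm m^-2 d^-1.
#' @param mu_true In situ phytoplankton growth rate, d^-1.
#' @param g_true Microzooplankton grazing rate, d^-1 (>= 0).
#' @param abundance_total Named vector of areal abundance per stage,
#'   ind m^-2 (spread over length bins by the scenario length distributions).
#' @param npp_surface Surface NPP, mg C m^-3 d^-1.
#' @param npp_efold NPP e-folding depth, m.
#' @param nutrient_boost Growth-rate increment from nutrient amendment, d^-1.
#' @param phi_true True photoacclimation rate, d^-1.
#' @export
ground_truth <- function(pigment_power_a = 0.08, pigment_power_b = 2.4,
                         f0_true = 210, b_true = 0.39, th_export_true = 1500,
                         mu_true = 0.6, g_true = 0.4,
                         abundance_total = c(blastozooid = 64, oozooid = 3),
                         npp_surface = 11.5, npp_efold = 55,
                         nutrient_boost = 0.1, phi_true = 0) {
  gt <- list(pigment_power_a = pigment_power_a, pigment_power_b = pigment_power_b,
             f0_true = f0_true, b_true = b_true, th_export_true = th_export_true,
             mu_true = mu_true, g_true = g_true, abundance_total = abundance_total,
             npp_surface = npp_surface, npp_efold = npp_efold,
             nutrient_boost = nutrient_boost, phi_true = phi_true)
  num <- unlist(gt[c("pigment_power_a", "pigment_power_b", "f0_true", "b_true",
                     "th_export_true", "mu_true", "g_true")])
  if (any(!is.finite(num))) stopf("ground truth rates must be finite")
  if (f0_true <= 0) stopf("f0_true must be > 0")
  if (g_true < 0) stopf("g_true must be >= 0")
  if (pigment_power_a <= 0) stopf("pigment_power_a must be > 0")
  if (any(abundance_total < 0)) stopf("abundance_total must be non-negative")
  structure(gt, class = "ground_truth")
}

#' Noise configuration for the generator
#'
#' @param pigment_sigma Lognormal sigma on gut pigments (default 0.2).
#' @param trap_sigma Lognormal sigma on per-tube trap POC mass (default 0.2).
#' @param th_sigma Gaussian sd on 234Th activities, dpm L^-1 (default 0.05).
#' @param chl_sigma Lognormal sigma on final dilution-bottle chl
#'   (default 0.05).
#' @param npp_sigma Lognormal sigma on NPP (default 0.1).
#' @param counts `"poisson"` for Poisson tow counts, `"expected"` for
#'   rounded expectations (the noise-free mode).
#' @export
noise_config <- function(pigment_sigma = 0.2, trap_sigma = 0.2, th_sigma = 0.05,
                         chl_sigma = 0.05, npp_sigma = 0.1,
                         counts = c("poisson", "expected")) {
  counts <- match.arg(counts)
  sig <- c(pigment_sigma, trap_sigma, th_sigma, chl_sigma, npp_sigma)
  if (any(sig < 0)) stopf("noise sigmas must be non-negative")
  list(pigment_sigma = pigment_sigma, trap_sigma = trap_sigma,
       th_sigma = th_sigma, chl_sigma = chl_sigma, npp_sigma = npp_sigma,
       counts = counts)
}

#' All-zero noise configuration (deterministic tables)
#' @export
noise_off <- function() {
  noise_config(pigment_sigma = 0, trap_sigma = 0, th_sigma = 0, chl_sigma = 0,
               npp_sigma = 0, counts = "expected")
}

#' Define a synthetic Lagrangian cycle scenario
#'
#' Defaults describe a salp-bloom cycle in subtropical frontal waters: a
#' 5-day occupation, 70-m euphotic zone, traps at 70/100/300/500 m, one day
#' and one night tow per day to 200 m, and *S. thompsoni* length
#' distributions with small solitary (oozooid) and abundant aggregate
#' (blastozooid) stages.
#'
#' @param cycle_id Cycle label.
#' @param duration_days Cycle length, days (3--7.5 typical; must be > 0).
#' @param water_temp Mixed-layer temperature, deg C.
#' @param euphotic_depth Euphotic-zone depth, m (must not exceed the
#'   shallowest trap).
#' @param trap_depths Trap deployment depths, m, strictly increasing.
#' @param true_params A [ground_truth()].
#' @param noise A [noise_config()].
#' @param night_day_factor Night:day abundance ratio (default 1).
#' @param tows_per_day Day tows (and night tows) per day.
#' @param tow_depth Net tow depth, m.
#' @param oal_factor OAL : total-length ratio used to synthesise
#'   `length_total`.
#' @param length_dist Per-stage truncated-normal OAL distributions,
#'   `list(stage = c(mean = , sd = ))` (mm).
#' @param n_tubes Pooled trap tubes per depth.
#' @param tube_inner_diameter Trap tube inner diameter, m.
#' @param pellet_fraction_true Fraction of the POC flux carried by intact,
#'   imaged salp pellets (sets expected pellet counts per trap).
#' @param dilution_depths Incubation depths, m.
#' @param dilution_fraction Whole-seawater fraction in the diluted bottle.
#' @param th_depths 234Th sampling depths, m.
#' @param salinity Water-column salinity, psu (34--35.5).
#' @param c_to_th C:234Th ratio on sinking particles, µmol C dpm^-1.
#' @return Validated list of class `cycle_scenario`.
#' @export
cycle_scenario <- function(cycle_id = "SYN-1", duration_days = 5,
                           water_temp = 12, euphotic_depth = 70,
                           trap_depths = c(70, 100, 300, 500),
                           true_params = ground_truth(),
                           noise = noise_config(),
                           night_day_factor = 1, tows_per_day = 1,
                           tow_depth = 200, oal_factor = 0.8,
                           length_dist = list(
                             blastozooid = c(mean = 30, sd = 10),
                             oozooid = c(mean = 70, sd = 25)),
                           n_tubes = 3, tube_inner_diameter = 0.07,
                           pellet_fraction_true = 0.3,
                           dilution_depths = c(5, 15, 25, 40, 55, 70),
                           dilution_fraction = 0.25,
                           th_depths = c(5, 20, 40, 60, 70, 85, 100, 150, 200),
                           salinity = 34.8, c_to_th = 5) {
  sc <- structure(as.list(environment()), class = "cycle_scenario")
  validate_scenario(sc)
}

#' @rdname cycle_scenario
#' @param scenario A `cycle_scenario` to validate.
#' @export
validate_scenario <- function(scenario) {
  s <- scenario
  if (!is.numeric(s$duration_days) || s$duration_days <= 0)
    stopf("invalid scenario field 'duration_days': must be > 0")
  if (is.unsorted(s$trap_depths, strictly = TRUE))
    stopf("invalid scenario field 'trap_depths': must be strictly increasing")
  if (s$euphotic_depth > min(s$trap_depths))
    stopf("invalid scenario field 'euphotic_depth': exceeds the shallowest trap")
  if (!inherits(s$true_params, "ground_truth"))
    stopf("invalid scenario field 'true_params': use ground_truth()")
  if (any(s$true_params$abundance_total < 0))
    stopf("invalid scenario field 'true_params$abundance_total': negative abundance")
  if (s$salinity < 34 || s$salinity > 35.5)
    stopf("invalid scenario field 'salinity': expected 34-35.5 psu")
  if (s$dilution_fraction <= 0 || s$dilution_fraction >= 1)
    stopf("invalid scenario field 'dilution_fraction': must be in (0, 1)")
  if (is.unsorted(s$th_depths, strictly = TRUE))
    stopf("invalid scenario field 'th_depths': must be strictly increasing")
  s
}

#' True areal abundance per 5-mm length bin and stage
#'
#' Spreads each stage's total abundance over the standard bins in proportion
#' to a truncated normal OAL density (deterministic; no RNG).
#'
#' @param scenario A [cycle_scenario()].
#' @param bins Bin table from [size_bins()].
#' @return data.frame: `bin_lo`, `bin_hi`, `mid`, `stage`, `ind_m2`.
#' @export
true_abundance_by_bin <- function(scenario, bins = size_bins()) {
  s <- validate_scenario(scenario)
  out <- do.call(rbind, lapply(names(s$length_dist), function(st) {
    pars <- s$length_dist[[st]]
    p <- stats::pnorm(bins$bin_hi, pars[["mean"]], pars[["sd"]]) -
      stats::pnorm(bins$bin_lo, pars[["mean"]], pars[["sd"]])
    tot <- stats::pnorm(max(bins$bin_hi), pars[["mean"]], pars[["sd"]]) -
      stats::pnorm(min(bins$bin_lo), pars[["mean"]], pars[["sd"]])
    data.frame(bins, stage = st,
               ind_m2 = s$true_params$abundance_total[[st] ] * p / tot)
  }))
  rownames(out) <- NULL
  out
}

#' Generate net-tow records
#'
#' One day and one night tow per cycle day (times `tows_per_day`).  Per tow,
#' the count in each length bin is Poisson around
#' `abundance * volume / tow_depth` (or the rounded expectation in the
#' noise-free count mode); individual OALs are uniform within their bin.
#'
#' @param scenario A [cycle_scenario()].
#' @param seed Integer seed.
#' @return List of [tow_record()] objects.
#' @export
generate_salp_tows <- function(scenario, seed) {
  s <- validate_scenario(scenario)
  set.seed(seed + SEED_OFFSETS[["tows"]])
  ab <- true_abundance_by_bin(s)
  n_each <- ceiling(s$duration_days) * s$tows_per_day
  tows <- list()
  for (night in c(FALSE, TRUE)) {
    fac <- if (night) s$night_day_factor else 1
    for (j in seq_len(n_each)) {
      vol <- stats::runif(1, 150, 500)
      expected <- ab$ind_m2 * fac * vol / s$tow_depth
      counts <- if (s$noise$counts == "poisson") stats::rpois(length(expected), expected)
      else round(expected)
      ind <- data.frame(species = character(), stage = character(),
                        length_total = numeric(), length_oal = numeric())
      if (sum(counts) > 0) {
        rows <- rep(seq_len(nrow(ab)), counts)
        oal <- stats::runif(length(rows), ab$bin_lo[rows], ab$bin_hi[rows])
        ind <- data.frame(species = "Salpa thompsoni", stage = ab$stage[rows],
                          length_total = oal / s$oal_factor, length_oal = oal)
      }
      tows[[length(tows) + 1]] <- tow_record(
        tow_id = sprintf("%s-%s-%02d", s$cycle_id, if (night) "N" else "D", j),
        is_night = night, volume_filtered = vol, tow_depth = s$tow_depth,
        individuals = ind)
    }
  }
  tows
}

# gut pigments for an existing set of tows (shared by generate_gut_pigments
# and generate_cycle, so the tow stream is drawn once)
gut_pigments_from_tows <- function(tows, scenario, seed, max_per_stage = 10) {
  s <- scenario
  set.seed(seed + SEED_OFFSETS[["pigments"]])
  a <- s$true_params$pigment_power_a; b <- s$true_params$pigment_power_b
  rows <- lapply(tows, function(tw) {
    ind <- tw$individuals[tw$individuals$species == "Salpa thompsoni", , drop = FALSE]
    do.call(rbind, lapply(split(ind, ind$stage), function(st) {
      if (nrow(st) == 0) return(NULL)
      take <- st[sample.int(nrow(st), min(max_per_stage, nrow(st))), , drop = FALSE]
      noise <- exp(stats::rnorm(nrow(take), 0, s$noise$pigment_sigma))
      data.frame(tow_id = tw$tow_id, stage = take$stage,
                 length_oal = take$length_oal,
                 gpig = a * take$length_oal^b * noise)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tow_id = character(), stage = character(),
                      length_oal = numeric(), gpig = numeric())
  rownames(out) <- NULL
  out
}

#' Generate per-individual gut-pigment records
#'
#' Subsamples up to 10 individuals per stage per tow and evaluates the true
#' allometry `Gpig = a * L^b` with multiplicative lognormal noise.
#'
#' @inheritParams generate_salp_tows
#' @return data.frame: `tow_id`, `stage`, `length_oal`, `gpig` (ng ind^-1).
#' @export
generate_gut_pigments <- function(scenario, seed) {
  s <- validate_scenario(scenario)
  gut_pigments_from_tows(generate_salp_tows(s, seed), s, seed)
}

#' Generate paired 234Th profiles
#'
#' Builds a deficiency profile that is constant over the euphotic zone (at
#' the level implied by `th_export_true`), decays linearly to zero 30 m
#' below it, and is zero at depth, so that the steady-state model integrated
#' to the euphotic depth returns the true export (exactly when a sample sits
#' at the euphotic depth, within discretisation otherwise).  The two
#' occupations are separated by the cycle duration and share the same mean
#' state (steady state holds in truth), differing only by measurement noise.
#'
#' @inheritParams generate_salp_tows
#' @return List of two [th_profile()] objects.
#' @export
generate_th_profiles <- function(scenario, seed) {
  s <- validate_scenario(scenario)
  set.seed(seed + SEED_OFFSETS[["thorium"]])
  cfg <- th_config()
  a_u <- u238_from_salinity(s$salinity, cfg)
  delta0 <- s$true_params$th_export_true / (cfg$lambda_234 * 1000 * s$euphotic_depth)
  taper_to <- s$euphotic_depth + 30
  deficiency <- function(z) {
    ifelse(z <= s$euphotic_depth, delta0,
           ifelse(z <= taper_to, delta0 * (taper_to - z) / 30, 0))
  }
  mk <- function(date) {
    a_th <- pmax(a_u - deficiency(s$th_depths) +
                   stats::rnorm(length(s$th_depths), 0, s$noise$th_sigma), 0)
    th_profile(date = date, depth = s$th_depths, a_th = a_th,
               a_th_sd = s$noise$th_sigma, salinity = s$salinity)
  }
  t0 <- as.Date("2026-01-01")
  list(mk(t0), mk(t0 + s$duration_days))
}

#' Generate sediment-trap samples
#'
#' Per depth, the per-tube POC mass is `F(z) * tube area * duration` with
#' multiplicative lognormal noise per tube, where
#' `F(z) = f0_true * (z/z_eu)^-b_true`; tubes are pooled by mass.  Expected
#' imaged pellet counts are set so pellet carbon is the scenario's
#' `pellet_fraction_true` of the flux; pellet lengths are lognormal around
#' 4 mm with width 0.35 x length.
#'
#' @inheritParams generate_salp_tows
#' @return List of [trap_sample()] objects.
#' @export
generate_trap_samples <- function(scenario, seed) {
  s <- validate_scenario(scenario)
  set.seed(seed + SEED_OFFSETS[["traps"]])
  gt <- s$true_params
  area_tube <- pi * (s$tube_inner_diameter / 2)^2
  lapply(s$trap_depths, function(z) {
    fz <- gt$f0_true * (z / s$euphotic_depth)^(-gt$b_true)
    tube_mass <- fz * area_tube * s$duration_days *
      exp(stats::rnorm(s$n_tubes, 0, s$noise$trap_sigma))
    # expected pellet count from the target pellet fraction of flux, using
    # the carbon of the reference 4 x 1.4 mm cylinder pellet
    c_ref_mg <- 1e-3 * pellet_carbon(pellet_volume(4, 0.35 * 4))
    area_tot <- s$n_tubes * area_tube
    lam <- s$pellet_fraction_true * fz * area_tot * s$duration_days / c_ref_mg
    n_p <- if (s$noise$counts == "poisson") stats::rpois(1, lam) else round(lam)
    pellets <- if (n_p > 0) {
      len <- if (s$noise$counts == "poisson")
        stats::rlnorm(n_p, log(4), 0.4) else rep(4, n_p)
      data.frame(length = len, width = 0.35 * len)
    } else data.frame(length = numeric(), width = numeric())
    trap_sample(depth = z, duration = s$duration_days, n_tubes = s$n_tubes,
                poc_mass = sum(tube_mass),
                tube_inner_diameter = s$tube_inner_diameter, pellets = pellets)
  })
}

#' Generate two-treatment dilution experiments
#'
#' Bottle finals follow exponential dynamics with apparent rates implied by
#' the true growth and grazing rates: `k_C = mu - g`,
#' `k_B = mu + boost - g`, `k_A = mu + boost - x * g`, with lognormal noise
#' on final chl.  Cytometric FL3:FSC trajectories encode the true
#' photoacclimation rate.
#'
#' @inheritParams generate_salp_tows
#' @return List: `bottles` and `cytometry` data.frames.
#' @export
generate_dilution_experiments <- function(scenario, seed) {
  s <- validate_scenario(scenario)
  set.seed(seed + SEED_OFFSETS[["dilution"]])
  gt <- s$true_params
  x <- s$dilution_fraction
  dur <- 1
  chl0 <- 1.5 * exp(-s$dilution_depths / 60)
  k_c <- gt$mu_true - gt$g_true
  k_b <- gt$mu_true + gt$nutrient_boost - gt$g_true
  k_a <- gt$mu_true + gt$nutrient_boost - x * gt$g_true
  n <- length(s$dilution_depths)
  noise <- function() exp(stats::rnorm(n, 0, s$noise$chl_sigma))
  bottles <- data.frame(
    depth = s$dilution_depths, duration = dur, x = x,
    chl_a0 = x * chl0, chl_af = x * chl0 * exp(k_a * dur) * noise(),
    chl_b0 = chl0, chl_bf = chl0 * exp(k_b * dur) * noise(),
    chl_c0 = chl0, chl_cf = chl0 * exp(k_c * dur) * noise())
  cyto <- rbind(
    data.frame(depth = s$dilution_depths, population = "picoeukaryote",
               biomass = 10, fl3fsc_initial = 0.5,
               fl3fsc_final = 0.5 * exp(gt$phi_true * dur), duration = dur),
    data.frame(depth = s$dilution_depths, population = "nanoeukaryote",
               biomass = 20, fl3fsc_initial = 0.8,
               fl3fsc_final = 0.8 * exp(gt$phi_true * dur), duration = dur))
  list(bottles = bottles, cytometry = cyto)
}

#' Generate a depth-resolved NPP profile
#'
#' Exponential decline `npp_surface * exp(-z / npp_efold)` with lognormal
#' noise, sampled at the dilution depths.
#'
#' @inheritParams generate_salp_tows
#' @return data.frame: `depth`, `npp` (mg C m^-3 d^-1).
#' @export
generate_npp_profile <- function(scenario, seed) {
  s <- validate_scenario(scenario)
  set.seed(seed + SEED_OFFSETS[["npp"]])
  gt <- s$true_params
  mu <- gt$npp_surface * exp(-s$dilution_depths / gt$npp_efold)
  data.frame(depth = s$dilution_depths,
             npp = mu * exp(stats::rnorm(length(mu), 0, s$noise$npp_sigma)))
}

#' Generate a complete synthetic cycle bundle
#'
#' Runs every table generator with one seed and bundles the tables with the
#' scenario and a `truth` block that also records derived quantities the
#' estimators should recover (binned abundance, the euphotic-zone NPP
#' integral of the noiseless profile, the 234Th deficiency level).
#'
#' @inheritParams generate_salp_tows
#' @return List of class `synthetic_cycle`: `scenario`, `truth`, `tows`,
#'   `gut_pigments`, `th_profiles`, `traps`, `dilution`, `npp`.
#' @export
generate_cycle <- function(scenario = cycle_scenario(), seed) {
  s <- validate_scenario(scenario)
  if (missing(seed) || !is.numeric(seed)) stopf("a fixed integer seed is required")
  tows <- generate_salp_tows(s, seed)
  npp_true <- rate_profile(
    s$dilution_depths,
    s$true_params$npp_surface * exp(-s$dilution_depths / s$true_params$npp_efold),
    s$euphotic_depth)
  cfg <- th_config()
  truth <- c(unclass(s$true_params), list(
    abundance_by_bin = true_abundance_by_bin(s),
    npp_int = integrate_profile(npp_true),
    th_deficiency = s$true_params$th_export_true /
      (cfg$lambda_234 * 1000 * s$euphotic_depth)))
  structure(list(
    scenario = s, truth = truth, tows = tows,
    gut_pigments = gut_pigments_from_tows(tows, s, seed),
    th_profiles = generate_th_profiles(s, seed),
    traps = generate_trap_samples(s, seed),
    dilution = generate_dilution_experiments(s, seed),
    npp = generate_npp_profile(s, seed)),
    class = "synthetic_cycle")
}
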