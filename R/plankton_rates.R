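# Phytoplankton growth and microzooplankton grazing from two-treatment
# dilution experiments, photoacclimation correction, and euphotic-zone
# integration of depth-resolved rates.
#
# The two-treatment dilution design incubates, at each depth, a diluted
# bottle A (fraction x of whole seawater, nutrient-amended), a whole bottle
# B (nutrient-amended) and a whole bottle C (unamended).  Assuming
# exponential dynamics, the apparent growth rates k = ln(final/initial)/t
# yield the microzooplankton grazing rate g = (kA - kB)/(1 - x), the
# nutrient-replete growth rate mu_n = kB + g and the in situ growth rate
# mu_0 = kC + g.  Changes in cell fluorescence per scatter (FL3:FSC, a
# chl:C proxy) during the incubation measure photoacclimation, which is
# subtracted from pigment-based growth.

#' Growth and grazing rates from two-treatment dilution bottles
#'
#' @param bottles data.frame, one row per depth, columns `depth`, `duration`
#'   (days), `x` (whole-seawater fraction in the diluted bottle, in (0,1)),
#'   and initial/final chl a for the three bottles: `chl_a0`, `chl_af`,
#'   `chl_b0`, `chl_bf`, `chl_c0`, `chl_cf` (all > 0).  Any other
#'   exponential tracer (e.g. cytometric cell counts) may be supplied in the
#'   same columns.
#' @return data.frame per depth: apparent rates `k_a`, `k_b`, `k_c`, raw and
#'   floored grazing `g_raw`, `g` (negative estimates floored at 0 and
#'   flagged in `g_floored`), `mu_nutrient`, `mu_insitu` (d^-1).
#' @export
dilution_rates <- function(bottles) {
  req <- c("depth", "duration", "x", "chl_a0", "chl_af", "chl_b0", "chl_bf",
           "chl_c0", "chl_cf")
  if (!all(req %in% names(bottles)))
    stopf("bottles need columns: %s", paste(req, collapse = ", "))
  chl <- as.matrix(bottles[, c("chl_a0", "chl_af", "chl_b0", "chl_bf",
                               "chl_c0", "chl_cf")])
  if (any(chl <= 0)) stopf("all chl values must be positive")
  if (any(bottles$x <= 0 | bottles$x >= 1)) stopf("dilution fraction x must be in (0, 1)")
  k_a <- log(bottles$chl_af / bottles$chl_a0) / bottles$duration
  k_b <- log(bottles$chl_bf / bottles$chl_b0) / bottles$duration
  k_c <- log(bottles$chl_cf / bottles$chl_c0) / bottles$duration
  g_raw <- (k_a - k_b) / (1 - bottles$x)
  floored <- g_raw < 0
  if (any(floored))
    warning(sum(floored), " negative grazing estimate(s) floored at 0", call. = FALSE)
  g <- pmax(g_raw, 0)
  data.frame(depth = bottles$depth, k_a = k_a, k_b = k_b, k_c = k_c,
             g_raw = g_raw, g = g, g_floored = floored,
             mu_nutrient = k_b + g, mu_insitu = k_c + g)
}

#' Photoacclimation correction factor Phi
#'
#' Per population, `phi = ln(FL3:FSC_final / FL3:FSC_initial) / duration`;
#' the combined Phi at each depth is the biomass-weighted mean over the
#' picoeukaryote and nanoeukaryote populations (populations with zero or
#' missing biomass drop out).
#'
#' @param cytometry data.frame, one row per depth x population, columns
#'   `depth`, `population`, `biomass`, `fl3fsc_initial`, `fl3fsc_final`,
#'   `duration` (days).
#' @return data.frame: `depth`, `phi` (d^-1).
#' @export
photoacclimation_phi <- function(cytometry) {
  req <- c("depth", "population", "biomass", "fl3fsc_initial", "fl3fsc_final",
           "duration")
  if (!all(req %in% names(cytometry)))
    stopf("cytometry needs columns: %s", paste(req, collapse = ", "))
  cy <- cytometry[!is.na(cytometry$biomass) & cytometry$biomass > 0, , drop = FALSE]
  cy$phi_p <- log(cy$fl3fsc_final / cy$fl3fsc_initial) / cy$duration
  out <- do.call(rbind, lapply(split(cy, cy$depth), function(d) {
    data.frame(depth = d$depth[1],
               phi = sum(d$biomass * d$phi_p) / sum(d$biomass))
  }))
  rownames(out) <- NULL
  out[order(out$depth), , drop = FALSE]
}

#' Photoacclimation-corrected growth rate
#'
#' @param mu Pigment-based instantaneous growth rate, d^-1.
#' @param phi Photoacclimation factor from [photoacclimation_phi()], d^-1.
#' @return `mu - phi`, d^-1.
#' @export
correct_growth <- function(mu, phi) mu - phi

#' Construct a depth-resolved rate profile
#'
#' @param depths Depths, m, increasing.
#' @param values Rate at each depth (e.g. NPP, mg C m^-3 d^-1).
#' @param euphotic_depth Euphotic-zone depth (0.1% surface PAR), m.
#' @export
rate_profile <- function(depths, values, euphotic_depth) {
  if (is.unsorted(depths, strictly = TRUE)) stopf("depths must be strictly increasing")
  assert_num(euphotic_depth, "euphotic_depth", lower = 0, strict = TRUE)
  structure(list(depths = depths, values = values,
                 euphotic_depth = euphotic_depth),
            class = "rate_profile")
}

#' Integrate a rate profile over the euphotic zone
#'
#' Trapezoidal integral from 0 m to the euphotic depth, with the shallowest
#' and deepest values continued as constants where the profile does not
#' reach the limits.
#'
#' @param profile A [rate_profile()].
#' @return Areal rate (e.g. mg C m^-2 d^-1).
#' @export
integrate_profile <- function(profile) {
  stopifnot(inherits(profile, "rate_profile"))
  trapz_extended(profile$depths, profile$values, 0, profile$euphotic_depth)
}

#' Net phytoplankton rate of change of the carbon budget
#'
#' @param npp Net primary production, mg C m^-2 d^-1.
#' @param uzoo_grazing Microzooplankton grazing, mg C m^-2 d^-1.
#' @param mesozoo_grazing Non-salp mesozooplankton grazing, mg C m^-2 d^-1.
#' @param salp_grazing Salp grazing, mg C m^-2 d^-1.
#' @return List: `accumulation` (NPP minus microzooplankton grazing) and
#'   `net` (after all grazing terms); both may be negative.
#' @export
net_rate_of_change <- function(npp, uzoo_grazing, mesozoo_grazing = 0,
                               salp_grazing = 0) {
  list(accumulation = npp - uzoo_grazing,
       net = npp - uzoo_grazing - mesozoo_grazing - salp_grazing)
}
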