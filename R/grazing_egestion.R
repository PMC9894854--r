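# Salp grazing from gut pigments and fecal-pellet egestion.
#
# Grazing follows the gut-fluorescence method: the pigment standing stock in
# the gut (Gpig, chl a + phaeopigment, ng ind^-1) divided by the gut passage
# time (GPT, h) gives an hourly ingestion rate.  Gpig scales allometrically
# with body length; GPT is a logarithmic function of oral-to-atrial length
# (OAL) and is temperature-corrected with a Q10.  Egestion is estimated two
# ways: as a fixed egestion efficiency times pigment-based grazing, and from
# a published length-based pellet production / pellet carbon model.

# shortest OAL (mm) for which the gut-passage-time formula is positive
GPT_MIN_OAL <- exp(2.6 / 2.607)

#' Q10 temperature-scaling configuration
#'
#' @param q10 Q10 factor (> 0), default 2.
#' @param t_ref Reference temperature (deg C) at which the scaling factor is 1.
#' @export
q10_config <- function(q10 = 2, t_ref) {
  assert_num(q10, "q10", lower = 0, strict = TRUE)
  assert_num(t_ref, "t_ref")
  structure(list(q10 = q10, t_ref = t_ref), class = "q10_config")
}

#' Q10 scaling factor at a given temperature
#' @param cfg A [q10_config()].
#' @param temp Ambient temperature, deg C.
#' @export
q10_factor <- function(cfg, temp) {
  stopifnot(inherits(cfg, "q10_config"))
  cfg$q10^((temp - cfg$t_ref) / 10)
}

#' Fit the gut-pigment allometry Gpig(L) = a * L^b
#'
#' Ordinary least squares on log(Gpig) ~ log(L) over records with positive
#' pigment.  With fewer than three distinct lengths the power law is
#' unidentifiable and the fit falls back to the mean pigment content,
#' flagged in the result.
#'
#' @param records data.frame with columns `length_oal` (mm) and `gpig`
#'   (ng pigment ind^-1).
#' @return List of class `pigment_fit`: `a`, `b`, `n_points`,
#'   `fallback_mean` (NA unless the fallback was used).
#' @export
fit_gut_pigment_power <- function(records) {
  req <- c("length_oal", "gpig")
  if (!all(req %in% names(records))) stopf("records need columns length_oal, gpig")
  pos <- records[records$gpig > 0 & records$length_oal > 0, , drop = FALSE]
  if (nrow(pos) == 0) stopf("no records with positive gut pigment; cannot fit")
  if (length(unique(pos$length_oal)) < 3) {
    warning("fewer than 3 distinct lengths; falling back to mean gut pigment",
            call. = FALSE)
    return(structure(list(a = NA_real_, b = NA_real_, n_points = nrow(pos),
                          fallback_mean = mean(pos$gpig)), class = "pigment_fit"))
  }
  fit <- stats::lm(log(gpig) ~ log(length_oal), data = pos)
  structure(list(a = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 n_points = nrow(pos), fallback_mean = NA_real_),
            class = "pigment_fit")
}

#' Predict gut pigment content at a given length
#' @param fit A `pigment_fit`.
#' @param length_oal OAL, mm (vectorised).
#' @export
predict_gpig <- function(fit, length_oal) {
  stopifnot(inherits(fit, "pigment_fit"))
  if (!is.na(fit$fallback_mean)) return(rep(fit$fallback_mean, length(length_oal)))
  fit$a * length_oal^fit$b
}

#' Gut passage time
#'
#' `GPT(h) = 2.607 * ln(OAL, mm) - 2.6`, divided by the Q10 factor so that
#' warmer water shortens gut residence.  The formula is only positive for
#' OAL above about 2.71 mm; smaller lengths are outside its domain.
#'
#' @param length_oal OAL, mm (vectorised).
#' @param temp Ambient temperature, deg C.
#' @param q10cfg A [q10_config()]; at `temp == t_ref` no scaling is applied.
#' @return GPT in hours.
#' @export
gut_passage_time <- function(length_oal, temp, q10cfg) {
  if (any(length_oal <= GPT_MIN_OAL))
    stopf("GPT formula 2.607*ln(OAL) - 2.6 is non-positive for OAL <= %.4f mm",
          GPT_MIN_OAL)
  (2.607 * log(length_oal) - 2.6) / q10_factor(q10cfg, temp)
}

#' Daily areal salp grazing from a size-binned population
#'
#' Per size bin, the individual hourly grazing rate is
#' `Gpig(midpoint) / GPT(midpoint)` (ng pigment ind^-1 h^-1).  The daily
#' areal rate weights the day and night abundances by the photoperiod split
#' (default 14 h day / 10 h night).  Bins below the GPT domain contribute
#' zero and are reported via a message.  Carbon units use a configurable
#' carbon:chl ratio applied to the chl a fraction of gut pigment; the
#' pigment-unit result is always returned alongside.
#'
#' @param pop Day/night-averaged population from [day_night_average()]
#'   (columns `mid`, `stage`, `day`, `night`).
#' @param fit Gut-pigment allometry from [fit_gut_pigment_power()].
#' @param temp Ambient temperature, deg C.
#' @param q10cfg [q10_config()] for the GPT temperature scaling.
#' @param daynight_hours Hours of day and night (sums to 24).
#' @param c_to_chl Carbon:chl a mass ratio (g:g) for carbon conversion
#'   (documented default 50).
#' @param chl_frac Fraction of gut pigment treated as chl a-equivalent for
#'   the carbon conversion (default 1: no pigment-destruction correction).
#' @return List: `pigment_mg_m2_d`, `carbon_mg_m2_d`, and `by_stage`
#'   data.frame of the pigment rate per stage.
#' @export
population_grazing <- function(pop, fit, temp, q10cfg,
                               daynight_hours = c(day = 14, night = 10),
                               c_to_chl = 50, chl_frac = 1) {
  if (missing(temp) || is.null(temp) || is.na(temp)) stopf("ambient temperature is required")
  stopifnot(inherits(fit, "pigment_fit"))
  ok <- pop$mid > GPT_MIN_OAL
  if (any(!ok))
    message(sprintf("%d bin(s) below the GPT domain (%.3f mm) contribute zero grazing",
                    sum(!ok), GPT_MIN_OAL))
  rate <- numeric(nrow(pop))  # ng pigment ind^-1 h^-1
  rate[ok] <- predict_gpig(fit, pop$mid[ok]) /
    gut_passage_time(pop$mid[ok], temp, q10cfg)
  day_ab <- ifelse(is.na(pop$day), pop$ind_m2, pop$day)
  night_ab <- ifelse(is.na(pop$night), pop$ind_m2, pop$night)
  ng_d <- daynight_hours[["day"]] * day_ab * rate +
    daynight_hours[["night"]] * night_ab * rate
  by_stage <- stats::aggregate(ng_d, list(stage = pop$stage), sum)
  names(by_stage)[2] <- "pigment_ng_m2_d"
  pig_mg <- sum(ng_d) * 1e-6
  list(pigment_mg_m2_d = pig_mg,
       carbon_mg_m2_d = pig_mg * chl_frac * c_to_chl,
       by_stage = by_stage)
}

#' Egestion from pigment-based grazing and an egestion efficiency
#'
#' @param grazing_c Grazing in carbon units, mg C m^-2 d^-1.
#' @param ee Egestion efficiency (fraction of ingested carbon egested as
#'   pellets; default 0.36, i.e. assimilation efficiency 0.64).
#' @export
egestion_gpig <- function(grazing_c, ee = 0.36) {
  assert_num(ee, "ee", lower = 0, upper = 1)
  ee * grazing_c
}

#' Egestion from the length-based pellet production model
#'
#' Pellet production rate `Fprod (pellets h^-1) = 0.5388 * exp(-0.0212 * size)`
#' and pellet carbon `OrgCpellet (µg C) = 0.055 * size^2.0665` (size = OAL,
#' mm), with the production rate Q10-scaled from its cold-water reference
#' temperature (default t_ref = 0 deg C, Antarctic source data).  Daily areal
#' egestion applies the same 14/10 day/night abundance weighting as grazing.
#'
#' @param pop Day/night-averaged population (columns `mid`, `stage`, `day`,
#'   `night`).
#' @param temp Ambient temperature, deg C.
#' @param q10cfg [q10_config()] (default Q10 = 2 about 0 deg C).
#' @param daynight_hours Hours of day and night.
#' @return List: `total` (mg C m^-2 d^-1), `by_stage` named numeric, and the
#'   per-bin table `by_bin`.
#' @export
egestion_iversen <- function(pop, temp, q10cfg = q10_config(2, t_ref = 0),
                             daynight_hours = c(day = 14, night = 10)) {
  if (any(pop$mid <= 0)) stopf("bin midpoints (sizes) must be positive")
  fprod <- 0.5388 * exp(-0.0212 * pop$mid) * q10_factor(q10cfg, temp)  # pellets h^-1
  cpellet <- 0.055 * pop$mid^2.0665                                    # µg C pellet^-1
  day_ab <- ifelse(is.na(pop$day), pop$ind_m2, pop$day)
  night_ab <- ifelse(is.na(pop$night), pop$ind_m2, pop$night)
  ug_d <- (daynight_hours[["day"]] * day_ab + daynight_hours[["night"]] * night_ab) *
    fprod * cpellet
  by_bin <- data.frame(pop[, c("bin_lo", "bin_hi", "mid", "stage")],
                       fprod_h = fprod, c_pellet_ug = cpellet,
                       egestion_mg_m2_d = ug_d * 1e-3)
  by_stage <- tapply(by_bin$egestion_mg_m2_d, by_bin$stage, sum)
  list(total = sum(by_bin$egestion_mg_m2_d), by_stage = by_stage, by_bin = by_bin)
}

#' Length-based pellet production rate (pellets per hour per individual)
#' @inheritParams egestion_iversen
#' @param size OAL, mm.
#' @export
pellet_production_rate <- function(size, temp = 0, q10cfg = q10_config(2, t_ref = 0)) {
  if (any(size <= 0)) stopf("size must be positive")
  0.5388 * exp(-0.0212 * size) * q10_factor(q10cfg, temp)
}

#' Length-based carbon content of a fecal pellet (µg C)
#' @param size OAL of the producing salp, mm.
#' @export
pellet_carbon_from_length <- function(size) {
  if (any(size <= 0)) stopf("size must be positive")
  0.055 * size^2.0665
}
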