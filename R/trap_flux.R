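# Particle-interceptor trap (PIT) fluxes and depth attenuation.
#
# Free-drifting cylindrical traps (7 cm inner diameter, 8:1 aspect) collect
# sinking particles over a deployment.  Flux is mass per collection area per
# day; depth attenuation is fit with the power law Flux(z) = F0 * (z/z0)^-b,
# with z0 the euphotic depth and F0 the flux at its base.  Intact salp fecal
# pellets photographed in the traps are converted to carbon through a
# volume--carbon allometry.

#' Construct a sediment-trap sample
#'
#' @param depth Trap depth, m.
#' @param duration Deployment length, days (> 0).
#' @param n_tubes Number of pooled collection tubes (>= 1).
#' @param poc_mass Swimmer-removed, blank-corrected POC summed over tubes, mg C.
#' @param tube_inner_diameter Tube inner diameter, m (default 0.07).
#' @param pellets Optional data.frame of intact salp pellet morphometrics,
#'   columns `length`, `width` (mm).
#' @export
trap_sample <- function(depth, duration, n_tubes, poc_mass,
                        tube_inner_diameter = 0.07, pellets = NULL) {
  assert_num(duration, "duration", lower = 0, strict = TRUE)
  if (n_tubes < 1) stopf("n_tubes must be >= 1")
  assert_num(poc_mass, "poc_mass", lower = 0)
  if (!is.null(pellets) && nrow(pellets) > 0 &&
      (any(pellets$length <= 0) || any(pellets$width <= 0)))
    stopf("pellet dimensions must be positive")
  structure(list(depth = depth, duration = duration, n_tubes = n_tubes,
                 poc_mass = poc_mass, tube_inner_diameter = tube_inner_diameter,
                 pellets = pellets),
            class = "trap_sample")
}

#' Total collection area of a trap sample (m^2)
#' @param sample A [trap_sample()].
#' @export
trap_area <- function(sample) {
  sample$n_tubes * pi * (sample$tube_inner_diameter / 2)^2
}

#' POC flux from a trap sample
#'
#' `flux = poc_mass / (n_tubes * pi * (d/2)^2 * duration)`, mg C m^-2 d^-1.
#'
#' @param sample A [trap_sample()].
#' @export
poc_flux <- function(sample) {
  stopifnot(inherits(sample, "trap_sample"))
  sample$poc_mass / (trap_area(sample) * sample$duration)
}

#' Fit depth attenuation of flux
#'
#' Default form is the power law `Flux(z) = F0 * (z/z0)^-b` fit by unweighted
#' least squares in log space; `form = "exponential"` fits
#' `Flux(z) = F0 * exp(-k (z - z0))` the same way (used to gauge sensitivity
#' to the functional form, which for trap profiles is typically modest).
#'
#' @param fluxes data.frame with columns `depth` (m) and `flux`
#'   (mg C m^-2 d^-1); at least two depths with positive flux.
#' @param z0 Reference depth (euphotic depth), m.
#' @param form `"power"` or `"exponential"`.
#' @return List of class `attenuation_fit`: `f0`, `b` (or `k`), `z0`, `form`.
#' @export
fit_attenuation <- function(fluxes, z0, form = c("power", "exponential")) {
  form <- match.arg(form)
  assert_num(z0, "z0", lower = 0, strict = TRUE)
  pos <- fluxes[fluxes$flux > 0, , drop = FALSE]
  if (nrow(pos) < 2) stopf("need >= 2 depths with positive flux to fit attenuation")
  if (form == "power") {
    fit <- stats::lm(log(flux) ~ log(depth / z0), data = pos)
    out <- list(f0 = unname(exp(stats::coef(fit)[1])),
                b = unname(-stats::coef(fit)[2]), z0 = z0, form = form)
  } else {
    fit <- stats::lm(log(flux) ~ I(depth - z0), data = pos)
    out <- list(f0 = unname(exp(stats::coef(fit)[1])),
                k = unname(-stats::coef(fit)[2]), z0 = z0, form = form)
  }
  out$residual_sd <- stats::sigma(fit)
  structure(out, class = "attenuation_fit")
}

#' Evaluate a fitted attenuation curve at depth
#' @param fit An `attenuation_fit`.
#' @param z Depth(s), m.
#' @export
flux_at_depth <- function(fit, z) {
  stopifnot(inherits(fit, "attenuation_fit"))
  if (fit$form == "power") fit$f0 * (z / fit$z0)^(-fit$b)
  else fit$f0 * exp(-fit$k * (z - fit$z0))
}

#' Pellet volume from length and width
#'
#' Salp pellets are elongated; the default shape rule is a cylinder
#' `V = pi * (width/2)^2 * length`; `"ellipsoid"` uses the prolate spheroid
#' `V = pi/6 * width^2 * length`.
#'
#' @param length,width Pellet dimensions, mm.
#' @param shape `"cylinder"` (default) or `"ellipsoid"`.
#' @return Volume, mm^3.
#' @export
pellet_volume <- function(length, width, shape = c("cylinder", "ellipsoid")) {
  shape <- match.arg(shape)
  if (any(length <= 0) || any(width <= 0)) stopf("pellet dimensions must be positive")
  if (shape == "cylinder") pi * (width / 2)^2 * length
  else pi / 6 * width^2 * length
}

#' Carbon content of a pellet from its volume
#'
#' Log-log volume--carbon allometry `C = 10^(0.634 * log10(V) + 1.43)`,
#' C in µg carbon, V in mm^3.
#'
#' @param volume Pellet volume, mm^3.
#' @export
pellet_carbon <- function(volume) {
  if (any(volume <= 0)) stopf("pellet volume must be positive")
  10^(0.634 * log10(volume) + 1.43)
}

#' Intact salp-pellet carbon flux in a trap sample
#'
#' Sums per-pellet carbon (volume from the shape rule, carbon from
#' [pellet_carbon()]) over the imaged pellets and divides by collection area
#' and duration.  Also reports the pellet fraction of the total POC flux;
#' fractions above 1 (pellet carbon exceeding bulk POC, possible with noisy
#' morphometrics) are reported with a warning, not truncated silently.
#'
#' @param sample A [trap_sample()] with a `pellets` table.
#' @param shape Shape rule passed to [pellet_volume()].
#' @param total_flux Total POC flux to compare against; defaults to
#'   [poc_flux()] of the same sample.
#' @return List: `pellet_flux` (mg C m^-2 d^-1), `fraction`, `n_pellets`.
#' @export
pellet_carbon_flux <- function(sample, shape = "cylinder", total_flux = NULL) {
  stopifnot(inherits(sample, "trap_sample"))
  total_flux <- total_flux %||% poc_flux(sample)
  if (is.null(sample$pellets) || nrow(sample$pellets) == 0)
    return(list(pellet_flux = 0, fraction = 0, n_pellets = 0L))
  v <- pellet_volume(sample$pellets$length, sample$pellets$width, shape)
  c_ug <- pellet_carbon(v)
  pf <- sum(c_ug) * 1e-3 / (trap_area(sample) * sample$duration)
  frac <- if (total_flux > 0) pf / total_flux else NA_real_
  if (!is.na(frac) && frac > 1)
    warning(sprintf("pellet flux exceeds total POC flux at %g m (fraction %.2f)",
                    sample$depth, frac), call. = FALSE)
  list(pellet_flux = pf, fraction = frac, n_pellets = nrow(sample$pellets))
}

#' Tabulate fluxes for a list of trap samples
#'
#' @param samples List of [trap_sample()] objects.
#' @param shape Pellet shape rule.
#' @return data.frame: `depth`, `flux`, `pellet_flux`, `pellet_fraction`,
#'   `n_pellets`.
#' @export
poc_flux_table <- function(samples, shape = "cylinder") {
  rows <- lapply(samples, function(s) {
    tot <- poc_flux(s)
    p <- pellet_carbon_flux(s, shape = shape, total_flux = tot)
    data.frame(depth = s$depth, flux = tot, pellet_flux = p$pellet_flux,
               pellet_fraction = p$fraction, n_pellets = p$n_pellets)
  })
  out <- do.call(rbind, rows)
  out[order(out$depth), , drop = FALSE]
}
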