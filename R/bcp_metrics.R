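# Biological-carbon-pump efficiency metrics and salp vs non-salp flux
# comparisons.
#
# Ez is the fraction of net primary production exported past the base of the
# euphotic zone; T100 is the flux transmission, the fraction of that export
# surviving an additional 100 m; their product is the pump efficiency, the
# fraction of NPP delivered 100 m below the euphotic zone.

#' Export ratio Ez
#'
#' @param flux_ez POC flux at the base of the euphotic zone, mg C m^-2 d^-1.
#' @param npp Euphotic-zone integrated NPP, mg C m^-2 d^-1 (> 0).
#' @return Ez = flux_ez / npp (fraction).
#' @export
ez_ratio <- function(flux_ez, npp) {
  if (any(npp <= 0)) stopf("npp must be positive to form the Ez ratio")
  flux_ez / npp
}

#' Flux transmission T100
#'
#' Fraction of the euphotic-zone export flux remaining 100 m deeper,
#' evaluated on a fitted attenuation curve:
#' `T100 = Flux(z_eu + 100) / Flux(z_eu)`.
#'
#' @param fit An `attenuation_fit` from [fit_attenuation()].
#' @param z_eu Euphotic depth, m.
#' @export
t100 <- function(fit, z_eu) {
  flux_at_depth(fit, z_eu + 100) / flux_at_depth(fit, z_eu)
}

#' Biological-carbon-pump efficiency
#'
#' @param ez Export ratio from [ez_ratio()].
#' @param t100 Flux transmission from [t100()].
#' @return `ez * t100` (fraction of NPP reaching z_eu + 100 m).
#' @export
bcp_efficiency <- function(ez, t100) ez * t100

#' Flux at the euphotic-zone base from trap observations
#'
#' Uses the trap at the euphotic depth when one sits there, otherwise
#' interpolates on the fitted power law.
#'
#' @param flux_table data.frame with `depth`, `flux`.
#' @param fit An `attenuation_fit`.
#' @param z_eu Euphotic depth, m.
#' @export
flux_at_ez <- function(flux_table, fit, z_eu) {
  hit <- which(flux_table$depth == z_eu)
  if (length(hit) >= 1) flux_table$flux[hit[1]] else flux_at_depth(fit, z_eu)
}

#' Per-depth salp : non-salp POC flux ratios
#'
#' For each (salp, non-salp) cycle pair within a water mass, interpolates
#' both flux profiles geometrically (log flux vs log depth, consistent with
#' the power-law attenuation model) onto their common depth range and
#' reports per-depth ratios plus the overall mean.  Pairs with a missing
#' partner are skipped with a warning.
#'
#' @param budgets Named list of flux tables (data.frame `depth`, `flux`),
#'   one per cycle.
#' @param pairing data.frame with columns `salp`, `nonsalp` (cycle names in
#'   `budgets`).
#' @return List: `per_depth` data.frame (`salp`, `nonsalp`, `depth`,
#'   `ratio`) and `mean_ratio`.
#' @export
salp_nonsalp_ratio <- function(budgets, pairing) {
  rows <- list()
  for (i in seq_len(nrow(pairing))) {
    sal <- pairing$salp[i]; non <- pairing$nonsalp[i]
    if (!(sal %in% names(budgets)) || !(non %in% names(budgets))) {
      warning(sprintf("pair %s / %s skipped: missing flux table", sal, non),
              call. = FALSE)
      next
    }
    fs <- budgets[[sal]]; fn <- budgets[[non]]
    lo <- max(min(fs$depth), min(fn$depth))
    hi <- min(max(fs$depth), max(fn$depth))
    depths <- sort(unique(c(fs$depth, fn$depth)))
    depths <- depths[depths >= lo & depths <= hi]
    if (length(depths) == 0) {
      warning(sprintf("pair %s / %s skipped: no overlapping depths", sal, non),
              call. = FALSE)
      next
    }
    ratio <- loglog_interp(fs$depth, fs$flux, depths) /
      loglog_interp(fn$depth, fn$flux, depths)
    rows[[length(rows) + 1]] <- data.frame(salp = sal, nonsalp = non,
                                           depth = depths, ratio = ratio)
  }
  per_depth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(salp = character(), nonsalp = character(),
               depth = numeric(), ratio = numeric())
  list(per_depth = per_depth,
       mean_ratio = if (nrow(per_depth)) mean(per_depth$ratio) else NA_real_)
}

#' Assemble a cycle-level carbon budget
#'
#' @param cycle_id Cycle label.
#' @param npp Integrated NPP, mg C m^-2 d^-1 (> 0).
#' @param flux_table Trap flux table from [poc_flux_table()].
#' @param attenuation `attenuation_fit` for the cycle.
#' @param z_eu Euphotic depth, m.
#' @param grazings Named list/vector: `uzoo`, `mesozoo`, `salp`
#'   (mg C m^-2 d^-1).
#' @param egestion Named list/vector: `gpig`, `iversen` (mg C m^-2 d^-1).
#' @param th_poc Optional thorium-derived POC fluxes (named vector, e.g.
#'   `ss`, `nss`).
#' @return List of class `cycle_budget` including `ez`, `t100`,
#'   `efficiency`, and egestion:flux ratios at 200 m.
#' @export
cycle_budget <- function(cycle_id, npp, flux_table, attenuation, z_eu,
                         grazings = c(uzoo = NA, mesozoo = NA, salp = NA),
                         egestion = c(gpig = NA, iversen = NA),
                         th_poc = NULL) {
  if (npp <= 0) stopf("npp must be positive")
  if (any(flux_table$flux < 0)) stopf("fluxes must be non-negative")
  f_ez <- flux_at_ez(flux_table, attenuation, z_eu)
  ez <- ez_ratio(f_ez, npp)
  t1 <- t100(attenuation, z_eu)
  flux200 <- flux_at_depth(attenuation, 200)
  structure(list(
    cycle_id = cycle_id, npp = npp, flux_table = flux_table,
    attenuation = attenuation, z_eu = z_eu, flux_ez = f_ez,
    grazings = grazings, egestion = egestion, th_poc = th_poc,
    ez = ez, t100 = t1, efficiency = bcp_efficiency(ez, t1),
    egestion_to_flux200 = c(gpig = unname(egestion[["gpig"]] / flux200),
                            iversen = unname(egestion[["iversen"]] / flux200))),
    class = "cycle_budget")
}

#' Flatten a cycle budget for serialisation
#' @param budget A [cycle_budget()].
#' @return Plain list suitable for JSON/CSV output.
#' @export
budget_summary <- function(budget) {
  stopifnot(inherits(budget, "cycle_budget"))
  list(cycle_id = budget$cycle_id, npp = budget$npp, z_eu = budget$z_eu,
       flux_ez = budget$flux_ez,
       f0 = budget$attenuation$f0, b = budget$attenuation$b,
       ez = budget$ez, t100 = budget$t100, efficiency = budget$efficiency,
       grazing = as.list(budget$grazings), egestion = as.list(budget$egestion),
       egestion_to_flux200 = as.list(budget$egestion_to_flux200),
       th_poc = if (is.null(budget$th_poc)) NULL else as.list(budget$th_poc),
       flux_by_depth = budget$flux_table)
}
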