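# Size-binned areal abundance and biomass from net-tow records.
#
# Double-oblique bongo tows (0 -> tow_depth -> 0) record every salp individual
# with species, life stage (oozooid = solitary, blastozooid = aggregate) and
# oral-to-atrial length (OAL, mm). Abundance is reported areally (ind m^-2):
# volumetric concentration in the tow times the depth of the layer sampled.

#' Standard 5-mm salp length bins
#'
#' Contiguous half-open length bins `[lo, hi)` spanning the 1--136 mm range
#' used for *Salpa thompsoni* length-frequency analysis.
#'
#' @param lo,hi Range limits in mm.
#' @param width Bin width in mm (default 5).
#' @return A data.frame with columns `bin_lo`, `bin_hi`, `mid` (mm).
#' @export
size_bins <- function(lo = 1, hi = 136, width = 5) {
  edges <- seq(lo, hi, by = width)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             mid = edges[-length(edges)] + width / 2)
}

#' Construct a net-tow record
#'
#' @param tow_id Tow label.
#' @param is_night Logical; was the tow conducted at night?
#' @param volume_filtered Volume filtered by the net, m^3 (> 0).
#' @param tow_depth Maximum tow depth, m (> 0).
#' @param individuals data.frame with columns `species`, `stage`
#'   (`"oozooid"`/`"blastozooid"`), `length_total` and `length_oal` (mm, in
#'   (0, 200]). May have zero rows.
#' @return A list of class `tow_record`.
#' @export
tow_record <- function(tow_id, is_night, volume_filtered, tow_depth, individuals) {
  assert_num(volume_filtered, "volume_filtered", lower = 0, strict = TRUE)
  assert_num(tow_depth, "tow_depth", lower = 0, strict = TRUE)
  req <- c("species", "stage", "length_total", "length_oal")
  if (!all(req %in% names(individuals)))
    stopf("individuals must have columns: %s", paste(req, collapse = ", "))
  if (nrow(individuals) > 0) {
    assert_num(individuals$length_oal, "length_oal", lower = 0, upper = 200, strict = FALSE)
    if (any(individuals$length_oal <= 0)) stopf("lengths must be in (0, 200] mm")
  }
  structure(list(tow_id = as.character(tow_id), is_night = isTRUE(is_night),
                 volume_filtered = volume_filtered, tow_depth = tow_depth,
                 individuals = individuals),
            class = "tow_record")
}

#' Convert total length to oral-to-atrial length
#'
#' Linear shrinkage/posture correction factor; the factor is study
#' configuration, not a constant of nature.
#'
#' @param length_total Total length, mm.
#' @param factor OAL:total-length ratio (default 0.8).
#' @export
oal_from_total <- function(length_total, factor = 0.8) {
  assert_num(factor, "factor", lower = 0, strict = TRUE)
  length_total * factor
}

#' Size-binned areal abundance from one tow
#'
#' Bins one species' individuals by OAL into half-open 5-mm bins and scales
#' counts to areal abundance: `ind m^-2 = count / volume_filtered * tow_depth`.
#' Individuals outside the bin range are assigned to the nearest edge bin and
#' reported via a message.
#'
#' @param tow A [tow_record()].
#' @param species Species label to tabulate.
#' @param bins Bin table from [size_bins()].
#' @param stages Stage labels always present in the output.
#' @return data.frame: `bin_lo`, `bin_hi`, `mid`, `stage`, `count`, `ind_m2`.
#' @export
areal_abundance <- function(tow, species = "Salpa thompsoni", bins = size_bins(),
                            stages = c("oozooid", "blastozooid")) {
  stopifnot(inherits(tow, "tow_record"))
  if (tow$volume_filtered <= 0) stopf("tow %s has non-positive volume", tow$tow_id)
  ind <- tow$individuals[tow$individuals$species == species, , drop = FALSE]
  out <- do.call(rbind, lapply(stages, function(st) {
    L <- ind$length_oal[ind$stage == st]
    n_low <- sum(L < bins$bin_lo[1])
    n_high <- sum(L >= bins$bin_hi[nrow(bins)])
    if (n_low + n_high > 0)
      message(sprintf("tow %s: %d individual(s) outside %g-%g mm assigned to edge bins",
                      tow$tow_id, n_low + n_high, bins$bin_lo[1], bins$bin_hi[nrow(bins)]))
    idx <- findInterval(L, c(bins$bin_lo, bins$bin_hi[nrow(bins)]),
                        rightmost.closed = FALSE)
    idx <- pmin(pmax(idx, 1L), nrow(bins))
    counts <- tabulate(idx, nbins = nrow(bins))
    data.frame(bins, stage = st, count = counts,
               ind_m2 = counts / tow$volume_filtered * tow$tow_depth)
  }))
  rownames(out) <- NULL
  out
}

#' Day/night-averaged size-binned population
#'
#' Averages per-tow areal abundances first within the day and night tow
#' groups, then across the two groups with equal weight (the standard
#' treatment for diel vertical migrators sampled day and night). Standard
#' errors come from the tow-to-tow spread within each group.
#'
#' @param tow_pops data.frame row-binding [areal_abundance()] results with
#'   added columns `tow_id` and `is_night`.
#' @return data.frame per bin x stage: `day`, `night`, `se_day`, `se_night`,
#'   `ind_m2` (the day/night mean) and `se`.
#' @export
day_night_average <- function(tow_pops) {
  req <- c("bin_lo", "bin_hi", "mid", "stage", "ind_m2", "tow_id", "is_night")
  if (!all(req %in% names(tow_pops)))
    stopf("tow_pops must have columns: %s", paste(req, collapse = ", "))
  has_day <- any(!tow_pops$is_night)
  has_night <- any(tow_pops$is_night)
  if (!has_day || !has_night)
    warning("only ", if (has_day) "day" else "night",
            " tows present; day/night average falls back to the available period",
            call. = FALSE)
  key <- interaction(tow_pops$bin_lo, tow_pops$stage, drop = FALSE)
  agg <- function(night) {
    sub <- tow_pops[tow_pops$is_night == night, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    m <- stats::aggregate(ind_m2 ~ bin_lo + bin_hi + mid + stage, data = sub, FUN = mean)
    s <- stats::aggregate(ind_m2 ~ bin_lo + bin_hi + mid + stage, data = sub,
                          FUN = function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
    m$se <- s$ind_m2
    m
  }
  d <- agg(FALSE); n <- agg(TRUE)
  base <- (d %||% n)[, c("bin_lo", "bin_hi", "mid", "stage")]
  out <- base
  out$day <- if (is.null(d)) NA_real_ else d$ind_m2
  out$night <- if (is.null(n)) NA_real_ else n$ind_m2
  out$se_day <- if (is.null(d)) NA_real_ else d$se
  out$se_night <- if (is.null(n)) NA_real_ else n$se
  out$ind_m2 <- rowMeans(cbind(out$day, out$night), na.rm = TRUE)
  out$se <- 0.5 * sqrt(ifelse(is.na(out$se_day), 0, out$se_day)^2 +
                       ifelse(is.na(out$se_night), 0, out$se_night)^2)
  if (is.null(d)) { out$ind_m2 <- out$night; out$se <- out$se_night }
  if (is.null(n)) { out$ind_m2 <- out$day; out$se <- out$se_day }
  out
}

#' Areal carbon biomass from a size-binned population
#'
#' Applies a length--carbon allometry `C(µg) = a_w * L^b_w` (L = bin midpoint,
#' mm) to the day/night-averaged abundance and sums over bins, per stage.
#' The coefficients are mandatory study configuration: supply the allometry
#' appropriate for the species and region (for *S. thompsoni* a literature
#' default of `c(a_w = 0.006, b_w = 2.58)` is documented in the package
#' vignette, but it is never assumed silently).
#'
#' @param pop Output of [day_night_average()] (or any data.frame with `mid`,
#'   `stage`, `ind_m2`).
#' @param coeffs Named vector `c(a_w = , b_w = )`; `a_w` in µg C mm^-b_w, > 0.
#' @return Named numeric, g C m^-2 per stage.
#' @export
biomass_from_length <- function(pop, coeffs) {
  if (missing(coeffs) || is.null(coeffs) || !all(c("a_w", "b_w") %in% names(coeffs)))
    stopf("length-carbon coefficients are required: coeffs = c(a_w = , b_w = )")
  if (coeffs[["a_w"]] <= 0) stopf("a_w must be > 0")
  ug <- pop$ind_m2 * coeffs[["a_w"]] * pop$mid^coeffs[["b_w"]]
  tapply(ug, pop$stage, sum) * 1e-6  # µg C m^-2 -> g C m^-2
}
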