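# Plain-text serialisation of cycle tables: CSV for data, YAML for the
# scenario, JSON for ground truth and budget summaries.  Header contracts
# match the readers below; all files are written with write.csv(row.names
# = FALSE).

#' Write the tables of a synthetic cycle to a directory
#'
#' Files written: `tows.csv` (tow metadata), `individuals.csv` (one row per
#' individual), `gut_pigments.csv`, `traps.csv` (one row per depth),
#' `pellets.csv` (one row per pellet), `th_profiles.csv` (`date`, `depth_m`,
#' `a_th_dpm_l`, `a_th_sd`, `salinity`), `dilution_bottles.csv`,
#' `dilution_cytometry.csv`, `npp.csv`, plus `scenario.yaml` and
#' `ground_truth.json`.
#'
#' @param cycle A `synthetic_cycle` from [generate_cycle()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cycle_tables <- function(cycle, dir) {
  stopifnot(inherits(cycle, "synthetic_cycle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name), row.names = FALSE)

  tow_meta <- do.call(rbind, lapply(cycle$tows, function(t)
    data.frame(tow_id = t$tow_id, is_night = t$is_night,
               volume_filtered = t$volume_filtered, tow_depth = t$tow_depth)))
  w(tow_meta, "tows.csv")
  ind <- do.call(rbind, lapply(cycle$tows, function(t)
    if (nrow(t$individuals)) cbind(tow_id = t$tow_id, t$individuals) else NULL))
  if (is.null(ind))
    ind <- data.frame(tow_id = character(), species = character(),
                      stage = character(), length_total = numeric(),
                      length_oal = numeric())
  w(ind, "individuals.csv")
  w(cycle$gut_pigments, "gut_pigments.csv")

  traps <- do.call(rbind, lapply(cycle$traps, function(s)
    data.frame(depth = s$depth, duration = s$duration, n_tubes = s$n_tubes,
               tube_inner_diameter = s$tube_inner_diameter,
               poc_mass = s$poc_mass)))
  w(traps, "traps.csv")
  pel <- do.call(rbind, lapply(cycle$traps, function(s)
    if (nrow(s$pellets)) cbind(depth = s$depth, s$pellets) else NULL))
  if (is.null(pel)) pel <- data.frame(depth = numeric(), length = numeric(),
                                      width = numeric())
  w(pel, "pellets.csv")

  th <- do.call(rbind, lapply(cycle$th_profiles, function(p)
    data.frame(date = as.character(attr(p, "date")), depth_m = p$depth,
               a_th_dpm_l = p$a_th, a_th_sd = p$a_th_sd,
               salinity = p$salinity)))
  w(th, "th_profiles.csv")

  w(cycle$dilution$bottles, "dilution_bottles.csv")
  w(cycle$dilution$cytometry, "dilution_cytometry.csv")
  w(cycle$npp, "npp.csv")

  sc <- cycle$scenario
  sc_list <- unclass(sc)
  sc_list$true_params <- lapply(unclass(sc$true_params), identity)
  sc_list$true_params$abundance_total <- as.list(sc$true_params$abundance_total)
  sc_list$length_dist <- lapply(sc$length_dist, as.list)
  yaml::write_yaml(sc_list, file.path(dir, "scenario.yaml"))
  jsonlite::write_json(cycle$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read cycle tables back from a directory
#'
#' Reconstructs the in-memory containers ([tow_record()], [trap_sample()],
#' [th_profile()]) from the CSV files written by [write_cycle_tables()] or
#' assembled by hand with the same headers.  `ground_truth.json`, when
#' present, is attached as `truth`.
#'
#' @param dir Directory of tables.
#' @return List with the same table components as [generate_cycle()].
#' @export
read_cycle_tables <- function(dir) {
  need <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stopf("required input table missing: %s", path)
    utils::read.csv(path)
  }
  tow_meta <- need("tows.csv")
  ind <- need("individuals.csv")
  tows <- lapply(seq_len(nrow(tow_meta)), function(i) {
    m <- tow_meta[i, ]
    sub <- ind[ind$tow_id == m$tow_id,
               c("species", "stage", "length_total", "length_oal"), drop = FALSE]
    tow_record(m$tow_id, m$is_night, m$volume_filtered, m$tow_depth, sub)
  })
  gut <- need("gut_pigments.csv")
  traps_df <- need("traps.csv")
  pel <- need("pellets.csv")
  traps <- lapply(seq_len(nrow(traps_df)), function(i) {
    t <- traps_df[i, ]
    trap_sample(t$depth, t$duration, t$n_tubes, t$poc_mass,
                t$tube_inner_diameter,
                pellets = pel[pel$depth == t$depth, c("length", "width"),
                              drop = FALSE])
  })
  th <- need("th_profiles.csv")
  th_profiles <- lapply(split(th, th$date), function(p) {
    p <- p[order(p$depth_m), ]
    th_profile(p$date[1], p$depth_m, p$a_th_dpm_l, p$a_th_sd, p$salinity)
  })
  th_profiles <- th_profiles[order(vapply(th_profiles,
                                          function(p) as.numeric(attr(p, "date")), 0))]
  truth <- NULL
  if (file.exists(file.path(dir, "ground_truth.json")))
    truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                 simplifyVector = TRUE)
  list(tows = tows, gut_pigments = gut, traps = traps,
       th_profiles = unname(th_profiles),
       dilution = list(bottles = need("dilution_bottles.csv"),
                       cytometry = need("dilution_cytometry.csv")),
       npp = need("npp.csv"), truth = truth)
}
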