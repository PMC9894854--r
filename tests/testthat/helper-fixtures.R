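# shared fixtures: scenarios and small hand-built tables

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

noiseless_scenario <- function(...) {
  cycle_scenario(noise = noise_off(), ...)
}

# bind per-tow areal abundances with tow metadata, as the pipeline does
bind_tow_pops <- function(tows, ...) {
  do.call(rbind, lapply(tows, function(t)
    cbind(areal_abundance(t, ...), tow_id = t$tow_id, is_night = t$is_night)))
}

# one-bin population table in the day_night_average() output layout
one_bin_pop <- function(mid = 20, day = 1, night = 1, stage = "blastozooid") {
  data.frame(bin_lo = mid - 2.5, bin_hi = mid + 2.5, mid = mid, stage = stage,
             day = day, night = night, se_day = 0, se_night = 0,
             ind_m2 = (day + night) / 2, se = 0)
}

# dilution bottle rows consistent with given apparent rates
bottles_from_rates <- function(k_a, k_b, k_c, x = 0.25, chl0 = 1, duration = 1,
                               depth = 10) {
  data.frame(depth = depth, duration = duration, x = x,
             chl_a0 = x * chl0, chl_af = x * chl0 * exp(k_a * duration),
             chl_b0 = chl0, chl_bf = chl0 * exp(k_b * duration),
             chl_c0 = chl0, chl_cf = chl0 * exp(k_c * duration))
}
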