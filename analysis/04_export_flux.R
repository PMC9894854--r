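#!/usr/bin/env Rscript
# Passive export: trap POC fluxes with power-law attenuation, intact pellet
# contribution, and the 234Th-based water-column estimates.

suppressPackageStartupMessages(library(salpflux))
z_eu <- 70

for (id in c("SALP", "NOSALP")) {
  dat <- read_cycle_tables(file.path("results/synthetic", id))
  tab <- poc_flux_table(dat$traps)
  fit <- fit_attenuation(tab, z0 = z_eu)
  ss1 <- ss_export(dat$th_profiles[[1]], z_eu)
  ss2 <- ss_export(dat$th_profiles[[2]], z_eu)
  nss <- nss_export(dat$th_profiles[[1]], dat$th_profiles[[2]], z_eu)
  th_poc <- poc_flux_from_th(mean(c(ss1$flux, ss2$flux)), c_to_th = 5)

  cat(sprintf("\n== cycle %s ==\n", id))
  print(cbind(round(tab[, c("depth", "flux", "pellet_flux")], 1),
              pellet_fraction = round(tab$pellet_fraction, 2)))
  cat(sprintf("Power-law fit: F0 = %.1f mg C m-2 d-1, b = %.3f\n", fit$f0, fit$b))
  cat(sprintf("234Th SS export %.0f +/- %.0f dpm m-2 d-1 (NSS %.0f); C:Th-derived POC %.1f mg C m-2 d-1\n",
              mean(c(ss1$flux, ss2$flux)), ss1$sd, nss$flux, th_poc))
  write.csv(tab, sprintf("results/trap_fluxes_%s.csv", id), row.names = FALSE)
}
cat("\nThorium-derived POC sits below the trap fluxes here; the conversion is\n")
cat("set entirely by the C:234Th ratio, which the study measures on trap material.\n")
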