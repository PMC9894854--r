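#!/usr/bin/env Rscript
# Phytoplankton growth, microzooplankton grazing and the production balance.

suppressPackageStartupMessages(library(salpflux))
z_eu <- 70

for (id in c("SALP", "NOSALP")) {
  dat <- read_cycle_tables(file.path("results/synthetic", id))
  rates <- dilution_rates(dat$dilution$bottles)
  phi <- photoacclimation_phi(dat$dilution$cytometry)
  rates <- merge(rates, phi, by = "depth")
  rates$mu_corrected <- correct_growth(rates$mu_insitu, rates$phi)
  npp <- integrate_profile(rate_profile(dat$npp$depth, dat$npp$npp, z_eu))

  cat(sprintf("\n== cycle %s ==\n", id))
  cat(sprintf("mu (in situ, Phi-corrected) = %.2f d-1, g (uzoo) = %.2f d-1\n",
              mean(rates$mu_corrected), mean(rates$g)))
  cat(sprintf("Integrated NPP = %.0f mg C m-2 d-1\n", npp))
  uzoo <- mean(rates$g) / mean(rates$mu_corrected) * npp
  bal <- net_rate_of_change(npp, uzoo)
  cat(sprintf("Microzooplankton remove %.0f mg C m-2 d-1; accumulation %.0f mg C m-2 d-1\n",
              uzoo, bal$accumulation))
  write.csv(rates, sprintf("results/dilution_rates_%s.csv", id), row.names = FALSE)
}
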