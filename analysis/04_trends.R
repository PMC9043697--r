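#!/usr/bin/env Rscript
# Stage 4: abundance and phenology trends at population and species level.
#
# Population trends are ordinary least squares on year; species trends
# pool populations with a site random intercept.  Classes use alpha=0.05.

library(phenowin)

abundance <- read.csv("results/abundance.csv")
phenology <- read.csv("results/phenology.csv")

ab <- estimate_trends(abundance, "log_abundance")
ph <- estimate_trends(phenology, "peak_day")

write.csv(rbind(ab$population, ph$population),
          "results/population_trends.csv", row.names = FALSE)
write.csv(rbind(ab$species, ph$species),
          "results/species_trends.csv", row.names = FALSE)

for (what in list(list("abundance", ab), list("phenology", ph))) {
  s <- trend_summary(what[[2]]$species$class)
  cat(sprintf("%s, species level: %.0f%% declining / %.0f%% stable / %.0f%% increasing\n",
              what[[1]], s$percent[1], s$percent[2], s$percent[3]))
}
pop_ab <- trend_summary(ab$population$class)
cat(sprintf("Populations with significant abundance trends: %.0f%%, of which %.0f%% negative\n",
            100 - pop_ab$percent[2],
            100 * pop_ab$n[1] / max(1, pop_ab$n[1] + pop_ab$n[3])))
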