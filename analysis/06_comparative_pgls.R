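#!/usr/bin/env Rscript
# Stage 6: phylogenetic comparative models.
#
# PGLS (Brownian covariance from the species tree) of thermal
# sensitivity, phenology trends and abundance trends on six ecological
# traits, single-trait models ranked by AICc plus a combined model of the
# significant traits; then the phenology-abundance models: does
# sensitivity drive the magnitude of phenological change, and do
# phenological variables predict abundance trends?

library(phenowin)
library(ape)

sp_tr <- read.csv("results/species_trends.csv")
sens <- read.csv("results/sensitivities.csv")
traits <- read.csv("results/data/traits.csv")
tree <- read.tree("results/data/tree.nwk")

tab <- build_comparative_table(sp_tr, sens, traits)
tree <- keep.tip(tree, tab$species_id)
write.csv(tab, "results/comparative_table.csv", row.names = FALSE)

tm <- trait_models(tab, tree)
write.csv(do.call(rbind, lapply(tm, function(x) x$summary)),
          "results/trait_model_coefficients.csv", row.names = FALSE)
rank <- compare_models(tm$abundance_trend$single)
write.csv(rank, "results/trait_model_ranking.csv", row.names = FALSE)

cat("Significant single-trait predictors of abundance trends:",
    paste(tm$abundance_trend$significant_traits, collapse = ", "), "\n")
cat("Best single-trait model by AICc:", rank$model[1], "\n")

pa <- tryCatch(
  phenology_abundance_models(tab, tree,
                             tm$abundance_trend$significant_traits),
  error = function(e) { cat("phenology-abundance models:",
                            conditionMessage(e), "\n"); NULL })
if (!is.null(pa)) {
  cat("Species excluded as positive-sensitivity outliers:",
      paste(pa$excluded_species, collapse = ", "), "\n")
  cf1 <- pa$sensitivity_vs_abs_trend$coefficients
  cat(sprintf("abs phenology trend ~ sensitivity: slope %+.3f (p = %.3f)\n",
              cf1$estimate[2], cf1$p_value[2]))
  cf2 <- pa$abundance_models$sensitivity$alone$coefficients
  cat(sprintf("abundance trend ~ sensitivity:     slope %+.4f (p = %.3f)\n",
              cf2$estimate[2], cf2$p_value[2]))
  coefs <- do.call(rbind, lapply(names(pa$abundance_models), function(p) {
    f <- pa$abundance_models[[p]]$alone
    cbind(predictor = p, f$coefficients)
  }))
  write.csv(coefs, "results/phenology_abundance_models.csv",
            row.names = FALSE)
}
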