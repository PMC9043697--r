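#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a dataset, runs temperature-trend models, flight-curve
#' estimation with the inclusion rules, population and species trend
#' models, critical-period selection and the comparative PGLS stage, and
#' writes every stage's tables plus a provenance manifest (input file
#' hashes, seed, package version) to `out_dir`.  All stages are
#' deterministic given the configuration, so re-running with the same
#' configuration reproduces every file.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param alpha Significance level used throughout.
#' @param stages Character subset of
#'   `c("simulate", "climate", "phenology", "trends", "sensitivity",
#'   "pgls", "recovery")`; later stages require the earlier ones.
#' @return A list with every stage's in-memory results.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL,
                         alpha = 0.05,
                         stages = c("simulate", "climate", "phenology",
                                    "trends", "sensitivity", "pgls",
                                    "recovery")) {
  res <- list(config = config)
  written <- character(0)
  emit <- function(obj, name) {
    if (is.null(out_dir) || is.null(obj)) return(invisible(NULL))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(obj, path, row.names = FALSE)
    written <<- c(written, path)
  }

  dataset <- simulate_dataset(config)
  res$dataset <- dataset
  if (!is.null(out_dir) && "simulate" %in% stages) {
    written <- c(written, unname(write_dataset(dataset, out_dir)))
  }
  if (!length(setdiff(stages, "simulate"))) {
    return(finish_pipeline(res, out_dir, written, config))
  }

  if ("climate" %in% stages) {
    span <- c(config$year_start, config$year_end)
    clim <- rbind(
      temperature_trend_lmm(dataset$temperature, "tmean", "annual", span),
      do.call(rbind, lapply(1:12, function(m)
        temperature_trend_lmm(dataset$temperature, "tmean", m, span))))
    res$climate_trends <- clim
    res$site_trends <- per_site_trends(dataset$temperature, "tmean", span)
    res$region_test <- region_slope_glm(res$site_trends, dataset$sites)
    emit(clim, "temperature_trends")
    emit(res$site_trends, "site_trends")
  }

  if ("phenology" %in% stages) {
    filt <- apply_dataset_filters(dataset$counts)
    est <- estimate_phenology_abundance(filt$kept)
    res$filters <- filt
    res$estimates <- est
    emit(est$abundance, "abundance")
    emit(est$phenology, "phenology")
    emit(rbind(filt$log,
               if (nrow(est$log)) est$log[, c("site_id", "species_id",
                                              "kept", "reason")]),
         "filter_log")
  }

  if ("trends" %in% stages) {
    ab_tr <- estimate_trends(res$estimates$abundance, "log_abundance", alpha)
    ph_tr <- estimate_trends(res$estimates$phenology, "peak_day", alpha)
    res$trends <- list(abundance = ab_tr, phenology = ph_tr)
    res$trend_summary <- list(
      abundance_population = trend_summary(ab_tr$population$class),
      abundance_species = trend_summary(ab_tr$species$class),
      phenology_population = trend_summary(ph_tr$population$class),
      phenology_species = trend_summary(ph_tr$species$class))
    emit(rbind(ab_tr$population[, names(ab_tr$population) != "n_populations"],
               ph_tr$population[, names(ph_tr$population) != "n_populations"]),
         "population_trends")
    emit(rbind(ab_tr$species, ph_tr$species), "species_trends")
  }

  if ("sensitivity" %in% stages) {
    sens <- species_sensitivities(res$estimates$phenology,
                                  dataset$temperature, alpha = alpha)
    res$sensitivities <- sens
    res$month_inclusion <- month_inclusion_summary(sens)
    emit(sens, "sensitivities")
    emit(res$month_inclusion, "month_inclusion")
  }

  if ("pgls" %in% stages) {
    sp_tr <- rbind(res$trends$abundance$species, res$trends$phenology$species)
    tab <- build_comparative_table(sp_tr, res$sensitivities, dataset$traits)
    tm <- trait_models(tab, dataset$tree, alpha = alpha)
    pa <- tryCatch(
      phenology_abundance_models(
        tab, dataset$tree,
        significant_traits = tm$abundance_trend$significant_traits),
      error = function(e) {
        message("phenology-abundance models skipped: ", conditionMessage(e))
        NULL
      })
    res$comparative_table <- tab
    res$trait_models <- tm
    res$phenology_abundance <- pa
    res$trait_ranking <- compare_models(tm$abundance_trend$single)
    emit(tab, "comparative_table")
    emit(do.call(rbind, lapply(tm, function(x) x$summary)),
         "trait_model_coefficients")
    emit(res$trait_ranking, "trait_model_ranking")
  }

  if ("recovery" %in% stages) {
    res$recovery <- recovery_report(res$sensitivities,
                                    res$trends$abundance$species,
                                    res$trends$phenology$species,
                                    dataset$truth, config = config)
    emit(res$recovery$summary, "recovery_summary")
  }

  finish_pipeline(res, out_dir, written, config)
}

finish_pipeline <- function(res, out_dir, written, config) {
  if (!is.null(out_dir) && length(written)) {
    manifest <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("phenowin")),
      files = as.list(tools::md5sum(sort(unique(written)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Compare pipeline estimates with simulation ground truth
#'
#' Joins recovered species-level quantities to the truth sidecar and
#' reports, per quantity: Pearson correlation with truth, root mean
#' squared error, the fraction of species whose selected critical window
#' shares at least one month slot with the true window, and 95% Wald
#' confidence-interval coverage of species abundance trends.
#'
#' @param sensitivities Table from [species_sensitivities()].
#' @param abundance_species,phenology_species Species-level trend tables
#'   (may be `NULL`).
#' @param truth Ground-truth table from [simulate_species_params()].
#' @param strong_cutoff Absolute true sensitivity above which a species
#'   counts as strong-signal for the window-overlap rate (days per
#'   degree C).
#' @param config Optional [simulation_config()]; when given, the true
#'   phenology trend is the temperature-mediated component (sensitivity
#'   times the true window's mean monthly temperature trend) plus the
#'   residual trend, instead of the residual trend alone.
#' @return List with per-quantity statistics and a tidy `summary` data
#'   frame.
#' @export
recovery_report <- function(sensitivities, abundance_species = NULL,
                            phenology_species = NULL, truth,
                            strong_cutoff = 2, config = NULL) {
  if (is.null(truth)) stop("ground truth unavailable; ",
                           "recovery reports require a synthetic run")
  out <- list()
  rows <- list()
  add <- function(quantity, value, n) {
    rows[[length(rows) + 1L]] <<- data.frame(quantity = quantity,
                                             value = value, n = n)
  }
  if (!is.null(sensitivities) && nrow(sensitivities)) {
    m <- merge(sensitivities, truth, by = "species_id")
    out$sensitivity_correlation <- stats::cor(m$sensitivity, m$sensitivity_true)
    out$sensitivity_rmse <- sqrt(mean((m$sensitivity - m$sensitivity_true)^2))
    overlap <- mapply(function(s, l, st, lt) {
      max(s, st) <= min(s + l - 1L, st + lt - 1L)
    }, m$start_month_index, m$length_months,
       m$window_start_true, m$window_length_true)
    strong <- abs(m$sensitivity_true) >= strong_cutoff
    out$window_overlap_rate <- mean(overlap)
    out$window_overlap_rate_strong <- mean(overlap[strong])
    add("sensitivity_correlation", out$sensitivity_correlation, nrow(m))
    add("sensitivity_rmse", out$sensitivity_rmse, nrow(m))
    add("window_overlap_rate_strong", out$window_overlap_rate_strong,
        sum(strong))
  }
  if (!is.null(abundance_species) && nrow(abundance_species)) {
    m <- merge(abundance_species, truth, by = "species_id")
    out$abundance_trend_correlation <- stats::cor(m$slope, m$abundance_trend_true)
    out$abundance_trend_rmse <- sqrt(mean((m$slope - m$abundance_trend_true)^2))
    covered <- abs(m$slope - m$abundance_trend_true) <= 1.96 * m$se
    out$abundance_trend_coverage <- mean(covered)
    add("abundance_trend_correlation", out$abundance_trend_correlation, nrow(m))
    add("abundance_trend_rmse", out$abundance_trend_rmse, nrow(m))
    add("abundance_trend_coverage", out$abundance_trend_coverage, nrow(m))
  }
  if (!is.null(phenology_species) && nrow(phenology_species)) {
    m <- merge(phenology_species, truth, by = "species_id")
    true_tr <- m$phenology_trend_extra
    if (!is.null(config)) {
      true_tr <- true_tr + m$sensitivity_true * vapply(seq_len(nrow(m)),
        function(i) {
          mons <- window_calendar_months(m$window_start_true[i],
                                         m$window_length_true[i])
          mean(config$monthly_trend_vector[mons])
        }, numeric(1))
    }
    out$phenology_trend_correlation <- stats::cor(m$slope, true_tr)
    out$phenology_trend_rmse <- sqrt(mean((m$slope - true_tr)^2))
    add("phenology_trend_correlation", out$phenology_trend_correlation, nrow(m))
    add("phenology_trend_rmse", out$phenology_trend_rmse, nrow(m))
  }
  out$summary <- do.call(rbind, rows)
  out
}
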