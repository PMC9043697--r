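#' Fit the phenology-temperature model for one candidate window
#'
#' Gaussian mixed model of annual peak day on the window's mean
#' temperature with a random site intercept:
#' `peak_day ~ T_window + (1 | site)`.  Fitted by maximum likelihood so
#' that AICs are comparable across windows (the fixed predictor
#' changes); the winning window is refitted by REML for the reported
#' slope.
#'
#' @param phenology Records of one species: `site_id`, `year`,
#'   `peak_day`.
#' @param temperature Monthly temperature table.
#' @param start_month_index,length_months Window definition.
#' @param element Temperature element (default `"tmean"`).
#' @param method `"ML"` or `"REML"`.
#' @param min_obs,min_sites Minimum data requirement (defaults 10
#'   records over 2 sites).
#' @return An `"lmm_fit"` (see [fit_random_intercept_lmm()]) with the
#'   window attached, or `NULL` when the requirement is not met or the
#'   fit fails.
#' @export
fit_window_model <- function(phenology, temperature, start_month_index,
                             length_months, element = "tmean",
                             method = "ML", min_obs = 10L, min_sites = 2L) {
  d <- phenology[!is.na(phenology$peak_day),
                 c("site_id", "year", "peak_day")]
  if (nrow(d) < min_obs || length(unique(d$site_id)) < min_sites) return(NULL)
  key <- unique(d[, c("site_id", "year")])
  key$t_window <- window_mean_many(temperature, key$site_id, key$year,
                                   start_month_index, length_months, element)
  d <- merge(d, key, by = c("site_id", "year"))
  fit <- tryCatch(
    suppressWarnings(
      fit_random_intercept_lmm(d$peak_day, d$t_window, d$site_id, method)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  fit$window <- list(start_month_index = start_month_index,
                     length_months = length_months,
                     label = window_label(start_month_index, length_months))
  fit
}

#' Select a species' critical period by AIC over candidate windows
#'
#' Fits every candidate window by ML, keeps the window with minimal AIC
#' (ties broken deterministically: shorter window first, then earlier
#' start), and refits the winner by REML to report the thermal
#' sensitivity slope (days per degree C), its standard error and
#' p-value.  The sign class uses `alpha`: negative significant slopes
#' are phenological advances, positive ones delays.
#'
#' @param phenology Records of one species (`site_id`, `year`,
#'   `peak_day`).
#' @param temperature Monthly temperature table.
#' @param windows Candidate table from [enumerate_windows()].
#' @param element Temperature element.
#' @param alpha Significance level for the sign class.
#' @return One-row data frame: window definition, `sensitivity`, `se`,
#'   `p_value`, `AIC`, `delta_AIC_runner_up`, `n_obs`, `sign_class`;
#'   or `NULL` when no window model converges.  The per-window AIC table
#'   is attached as attribute `"aic_table"`.
#' @export
select_critical_period <- function(phenology, temperature,
                                   windows = enumerate_windows(),
                                   element = "tmean", alpha = 0.05) {
  fits <- vector("list", nrow(windows))
  aics <- rep(NA_real_, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    f <- fit_window_model(phenology, temperature,
                          windows$start_month_index[i],
                          windows$length_months[i], element, method = "ML")
    fits[[i]] <- f
    if (!is.null(f)) aics[i] <- f$AIC
  }
  if (all(is.na(aics))) return(NULL)
  ord <- order(aics, windows$length_months, windows$start_month_index,
               na.last = TRUE)
  best <- ord[1L]
  runner <- if (sum(!is.na(aics)) >= 2L) aics[ord[2L]] - aics[best] else NA_real_
  reml <- fit_window_model(phenology, temperature,
                           windows$start_month_index[best],
                           windows$length_months[best], element,
                           method = "REML")
  if (is.null(reml)) reml <- fits[[best]]
  sign_class <- if (reml$p_value >= alpha) "nonsignificant"
                else if (reml$slope < 0) "advance" else "delay"
  out <- data.frame(
    start_month_index = windows$start_month_index[best],
    length_months = windows$length_months[best],
    label = windows$label[best],
    sensitivity = reml$slope, se = reml$se, p_value = reml$p_value,
    AIC = aics[best], delta_AIC_runner_up = runner,
    n_obs = reml$n_obs, sign_class = sign_class)
  aic_tab <- windows
  aic_tab$AIC <- aics
  attr(out, "aic_table") <- aic_tab
  out
}

#' Critical periods and sensitivities for every species
#'
#' @param phenology Phenology estimates for all species (`site_id`,
#'   `species_id`, `year`, `peak_day`).
#' @param temperature Monthly temperature table.
#' @param windows Candidate windows.
#' @param element Temperature element.
#' @param alpha Significance level.
#' @return Data frame with one row per species that could be fitted;
#'   species with no converged window model are absent (and listed in
#'   attribute `"excluded"`).
#' @export
species_sensitivities <- function(phenology, temperature,
                                  windows = enumerate_windows(),
                                  element = "tmean", alpha = 0.05) {
  sps <- split(phenology, phenology$species_id, drop = TRUE)
  rows <- list(); excluded <- character(0)
  for (sp in names(sps)) {
    res <- select_critical_period(sps[[sp]], temperature, windows,
                                  element, alpha)
    if (is.null(res)) {
      excluded <- c(excluded, sp)
      next
    }
    rows[[sp]] <- cbind(data.frame(species_id = sp), res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Temperature trend of a species' critical period
#'
#' Mixed-model yearly trend of the window's mean temperature across
#' sites — flags whether the critical period warmed or cooled over the
#' study span.
#'
#' @param temperature Monthly temperature table.
#' @param start_month_index,length_months Window definition.
#' @param years Focal flight seasons to cover.
#' @param sites Site ids to include (default: all in the table).
#' @param element Temperature element.
#' @return One-row data frame as [temperature_trend_lmm()].
#' @export
critical_period_trend <- function(temperature, start_month_index,
                                  length_months, years,
                                  sites = unique(temperature$site_id),
                                  element = "tmean") {
  grid <- expand.grid(site_id = sites, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$value <- window_mean_many(temperature, grid$site_id, grid$year,
                                 start_month_index, length_months, element)
  fit <- suppressWarnings(
    fit_random_intercept_lmm(grid$value, grid$year, grid$site_id, "REML"))
  data.frame(scope = window_label(start_month_index, length_months),
             element = element, slope = fit$slope, se = fit$se,
             stat = fit$stat, p_value = fit$p_value,
             implied_change = fit$slope * diff(range(years)),
             n_obs = fit$n_obs)
}

#' Fraction of species whose critical period includes each month
#'
#' @param sensitivities Table from [species_sensitivities()].
#' @return Data frame `month` (1--12), `month_abb`, `n_species`,
#'   `fraction`.
#' @export
month_inclusion_summary <- function(sensitivities) {
  if (is.null(sensitivities) || nrow(sensitivities) == 0L) {
    stop("no sensitivity results to summarize")
  }
  n <- nrow(sensitivities)
  counts <- integer(12)
  for (i in seq_len(n)) {
    mons <- window_calendar_months(sensitivities$start_month_index[i],
                                   sensitivities$length_months[i])
    counts[unique(mons)] <- counts[unique(mons)] + 1L
  }
  data.frame(month = 1:12, month_abb = month.abb, n_species = counts,
             fraction = counts / n)
}
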