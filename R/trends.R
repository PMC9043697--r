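#' Gaussian random-intercept mixed model of y on x
#'
#' Thin wrapper around [lme4::lmer()] fitting
#' `y ~ x + (1 | group)`.  Fixed-effect inference uses the Wald t
#' statistic with `n - p` residual degrees of freedom, where `p` is the
#' number of fixed coefficients.  With fewer than two groups the model
#' degrades to ordinary least squares with a warning; the returned
#' structure is the same.
#'
#' @param y,x Numeric response and predictor.
#' @param group Grouping factor for the random intercept.
#' @param method `"REML"` (estimation) or `"ML"` (for AIC comparison of
#'   models differing in fixed effects).
#' @return A list of class `"lmm_fit"`: `slope`, `se`, `stat`,
#'   `p_value`, `intercept`, `group_var`, `resid_var`, `logLik`, `AIC`,
#'   `method`, `converged`, `n_obs`, `n_groups`, `model`.
#' @export
fit_random_intercept_lmm <- function(y, x, group, method = c("REML", "ML")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(y, x, group)
  d <- data.frame(y = y[keep], x = x[keep], g = factor(group[keep]))
  n <- nrow(d); p <- 2L
  if (nlevels(d$g) < 2L) {
    warning("fewer than 2 groups; falling back to ordinary regression")
    fit <- stats::lm(y ~ x, data = d)
    cf <- summary(fit)$coefficients
    ll <- as.numeric(stats::logLik(fit))
    return(structure(list(
      slope = cf["x", 1], se = cf["x", 2], stat = cf["x", 3],
      p_value = cf["x", 4], intercept = cf["(Intercept)", 1],
      group_var = 0, resid_var = summary(fit)$sigma^2,
      logLik = ll, AIC = stats::AIC(fit), method = "OLS",
      converged = TRUE, n_obs = n, n_groups = nlevels(d$g), model = fit),
      class = "lmm_fit"))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (1 | g), data = d, REML = (method == "REML"))))
  # a singular (zero group variance) fit is a valid boundary estimate and
  # gradient-check messages on near-degenerate data are advisory; only a
  # nonzero optimizer return code counts as non-convergence
  conv <- isTRUE(fit@optinfo$conv$opt == 0)
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- beta[["x"]] / se[2L]
  df <- n - p
  structure(list(
    slope = beta[["x"]], se = se[2L], stat = tval,
    p_value = 2 * stats::pt(-abs(tval), df),
    intercept = beta[["(Intercept)"]],
    group_var = vc$vcov[vc$grp == "g"],
    resid_var = vc$vcov[vc$grp == "Residual"],
    logLik = as.numeric(stats::logLik(fit)), AIC = stats::AIC(fit),
    method = method, converged = conv, n_obs = n,
    n_groups = nlevels(d$g), model = fit),
    class = "lmm_fit")
}

#' Population-level trend (ordinary least squares on year)
#'
#' Slope of a linear regression of the annual response (log abundance or
#' peak day) on calendar year for one site-species population.  At least
#' three usable years are required for a reported estimate.
#'
#' @param records Data frame with columns `year` and the response.
#' @param response Column name (`"log_abundance"` or `"peak_day"`).
#' @return One-row data frame (`level`, `response`, `slope`, `se`,
#'   `stat`, `p_value`, `n_obs`, `n_years`), or `NULL` when fewer than
#'   `min_years` years are available.
#' @param min_years Minimum number of distinct years (default 3).
#' @export
population_trend <- function(records, response, min_years = 3L) {
  d <- records[!is.na(records[[response]]), ]
  if (length(unique(d$year)) < min_years) return(NULL)
  fit <- stats::lm(d[[response]] ~ d$year)
  cf <- summary(fit)$coefficients
  data.frame(level = "population", response = response,
             slope = cf[2, 1], se = cf[2, 2], stat = cf[2, 3],
             p_value = cf[2, 4], n_obs = nrow(d),
             n_years = length(unique(d$year)))
}

#' Species-level trend (random site intercept)
#'
#' Mixed model of the annual response on year across all populations of
#' a species, with site as a random intercept.  With a single population
#' the estimate reduces to the population-level regression.
#'
#' @param records All populations of one species: columns `site_id`,
#'   `year` and the response.
#' @param response Column name.
#' @return One-row data frame as [population_trend()], `level =
#'   "species"`, plus `n_populations`.
#' @export
species_trend <- function(records, response) {
  d <- records[!is.na(records[[response]]), ]
  if (length(unique(d$year)) < 3L) return(NULL)
  fit <- suppressWarnings(
    fit_random_intercept_lmm(d[[response]], d$year, d$site_id, "REML"))
  if (!fit$converged) return(NULL)
  data.frame(level = "species", response = response,
             slope = fit$slope, se = fit$se, stat = fit$stat,
             p_value = fit$p_value, n_obs = fit$n_obs,
             n_years = length(unique(d$year)),
             n_populations = length(unique(d$site_id)))
}

#' Classify a trend estimate by sign and significance
#'
#' @param slope,p_value Estimate and its p-value (vectorized).
#' @param alpha Significance level (default 0.05).
#' @return Character vector in `{"significant_negative",
#'   "nonsignificant", "significant_positive"}`.
#' @export
classify_trend <- function(slope, p_value, alpha = 0.05) {
  ifelse(p_value >= alpha | slope == 0, "nonsignificant",
         ifelse(slope < 0, "significant_negative", "significant_positive"))
}

#' Tabulate trend classes
#'
#' Counts and percentages of declining, stable and increasing units.
#'
#' @param classes Character vector from [classify_trend()].
#' @return Data frame `class`, `n`, `percent` (all three classes always
#'   present).
#' @export
trend_summary <- function(classes) {
  lev <- c("significant_negative", "nonsignificant", "significant_positive")
  tab <- table(factor(classes, levels = lev))
  data.frame(class = lev, n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(classes))
}

#' Trends for every population and species in an estimates table
#'
#' Convenience driver: applies [population_trend()] per site-species and
#' [species_trend()] per species, for one response column, and attaches
#' trend classes.
#'
#' @param estimates Table with `site_id`, `species_id`, `year` and the
#'   response column.
#' @param response Column name.
#' @param alpha Significance level for classification.
#' @return List of data frames `population` and `species` (with
#'   `site_id`/`species_id` identifiers and a `class` column).
#' @export
estimate_trends <- function(estimates, response, alpha = 0.05) {
  pops <- split(estimates, list(estimates$site_id, estimates$species_id),
                drop = TRUE)
  pop_rows <- lapply(pops, function(d) {
    tr <- population_trend(d, response)
    if (is.null(tr)) return(NULL)
    cbind(data.frame(site_id = d$site_id[1], species_id = d$species_id[1]), tr)
  })
  pop_df <- do.call(rbind, pop_rows)
  sps <- split(estimates, estimates$species_id, drop = TRUE)
  sp_rows <- lapply(sps, function(d) {
    tr <- species_trend(d, response)
    if (is.null(tr)) return(NULL)
    cbind(data.frame(species_id = d$species_id[1]), tr)
  })
  sp_df <- do.call(rbind, sp_rows)
  if (!is.null(pop_df)) {
    pop_df$class <- classify_trend(pop_df$slope, pop_df$p_value, alpha)
    rownames(pop_df) <- NULL
  }
  if (!is.null(sp_df)) {
    sp_df$class <- classify_trend(sp_df$slope, sp_df$p_value, alpha)
    rownames(sp_df) <- NULL
  }
  list(population = pop_df, species = sp_df)
}
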