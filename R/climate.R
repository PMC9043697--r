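#' Monthly temperature regression on geographic predictors
#'
#' First (global) step of the two-step temperature interpolation:
#' ordinary least squares of a station temperature element on altitude,
#' latitude, continentality and solar radiation, fitted separately per
#' month (and optionally per year).
#'
#' @param stations Long station table with columns `station_id`, `x`,
#'   `y`, `altitude`, `latitude`, `continentality`, `solar_radiation`,
#'   `month`, `element`, `value` and optionally `year`.
#' @param month Calendar month (1--12).
#' @param element One of `"tmin"`, `"tmean"`, `"tmax"`.
#' @param year Optional year filter.
#' @return List with `coefficients`, `residuals` (named by station),
#'   `stations` (the subset used) and the `lm` fit.
#' @export
fit_monthly_regression <- function(stations, month, element, year = NULL) {
  sub <- stations[stations$month == month & stations$element == element, ]
  if (!is.null(year) && "year" %in% names(stations)) {
    sub <- sub[sub$year == year, ]
  }
  if (nrow(sub) < 6L) {
    stop(sprintf("need at least 6 stations for month %d, element %s (got %d)",
                 month, element, nrow(sub)))
  }
  fit <- stats::lm(value ~ altitude + latitude + continentality + solar_radiation,
                   data = sub)
  al <- stats::alias(fit)$Complete
  if (!is.null(al)) {
    stop("rank-deficient design; collinear predictor(s): ",
         paste(rownames(al), collapse = ", "))
  }
  list(coefficients = stats::coef(fit),
       residuals = stats::setNames(stats::residuals(fit), sub$station_id),
       stations = sub, fit = fit)
}

#' Inverse-distance-weighted residual correction
#'
#' Second (local) step of the interpolation: station residuals are spread
#' to target points with weights proportional to distance to the power
#' `-power`.  The interpolator is exact: a target coinciding with a
#' station returns that station's residual.
#'
#' @param station_xy Two-column matrix of station coordinates.
#' @param residuals Residual at each station.
#' @param target_xy Two-column matrix of target coordinates.
#' @param power Positive IDW exponent (default 2).
#' @return Numeric vector of corrections, one per target.
#' @export
idw_residual_correction <- function(station_xy, residuals, target_xy,
                                    power = 2) {
  station_xy <- as.matrix(station_xy); target_xy <- as.matrix(target_xy)
  if (nrow(station_xy) < 1L) stop("no stations supplied")
  stopifnot(power > 0, nrow(station_xy) == length(residuals))
  out <- numeric(nrow(target_xy))
  for (i in seq_len(nrow(target_xy))) {
    d <- sqrt((station_xy[, 1] - target_xy[i, 1])^2 +
              (station_xy[, 2] - target_xy[i, 2])^2)
    if (any(d == 0)) {
      out[i] <- residuals[which(d == 0)[1L]]
    } else {
      w <- d^(-power)
      out[i] <- sum(w * residuals) / sum(w)
    }
  }
  out
}

#' Interpolated monthly temperatures at monitoring sites
#'
#' Combines the monthly regression prediction at each site's predictor
#' values with the IDW-interpolated residual correction, for every
#' (year,) month and element present in the station table.
#'
#' @param stations Long station table (see [fit_monthly_regression()]).
#' @param sites Site table with `site_id`, `x`, `y`, `altitude`,
#'   `latitude`, `continentality`, `solar_radiation`.
#' @param power IDW exponent.
#' @return Data frame `site_id`, (`year`,) `month`, `element`, `value`.
#' @export
site_temperature_table <- function(stations, sites, power = 2) {
  has_year <- "year" %in% names(stations)
  combos <- unique(stations[, c(if (has_year) "year", "month", "element"),
                            drop = FALSE])
  combos <- combos[do.call(order, combos), , drop = FALSE]
  res <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    yr <- if (has_year) combos$year[i] else NULL
    reg <- fit_monthly_regression(stations, combos$month[i],
                                  combos$element[i], year = yr)
    pred <- stats::predict(reg$fit, newdata = sites)
    corr <- idw_residual_correction(
      reg$stations[, c("x", "y")], reg$residuals,
      sites[, c("x", "y")], power = power)
    out <- data.frame(site_id = sites$site_id, month = combos$month[i],
                      element = combos$element[i], value = pred + corr)
    if (has_year) out$year <- yr
    res[[i]] <- out
  }
  out <- do.call(rbind, res)
  cols <- c("site_id", if (has_year) "year", "month", "element", "value")
  rownames(out) <- NULL
  out[, cols]
}

#' Regional temperature trend from a random-intercept mixed model
#'
#' Fits temperature on calendar year with a random site intercept
#' (Gaussian errors), either for the annual mean (mean of the twelve
#' monthly means) or for a single calendar month.  With a single site
#' the model degrades to ordinary regression with a warning.
#'
#' @param temperature Table with `site_id`, `year`, `month` and element
#'   columns (wide, as produced by [simulate_temperatures()]).
#' @param element Temperature element (default `"tmean"`).
#' @param scope `"annual"` or a month number 1--12.
#' @param year_range Optional `c(first, last)` restriction; the implied
#'   change is `slope * (last - first)`.
#' @return One-row data frame: `scope`, `element`, `slope`, `se`, `stat`,
#'   `p_value`, `implied_change`, `n_obs`.
#' @export
temperature_trend_lmm <- function(temperature, element = "tmean",
                                  scope = "annual", year_range = NULL) {
  stopifnot(element %in% names(temperature))
  d <- temperature
  if (!is.null(year_range)) d <- d[d$year >= year_range[1] & d$year <= year_range[2], ]
  if (identical(scope, "annual")) {
    d <- stats::aggregate(d[[element]],
                          by = list(site_id = d$site_id, year = d$year),
                          FUN = mean)
    names(d)[3] <- "value"
    # keep only complete years (12 monthly means) upstream of this call
  } else {
    scope <- as.integer(scope)
    stopifnot(scope >= 1L, scope <= 12L)
    d <- d[d$month == scope, c("site_id", "year", element)]
    names(d)[3] <- "value"
  }
  if (length(unique(d$year)) < 3L) stop("need at least 3 years")
  span <- diff(range(d$year))
  fit <- fit_random_intercept_lmm(d$value, d$year, d$site_id, method = "REML")
  data.frame(scope = as.character(scope), element = element,
             slope = fit$slope, se = fit$se, stat = fit$stat,
             p_value = fit$p_value,
             implied_change = fit$slope * span, n_obs = fit$n_obs)
}

#' Per-site trends of annual mean temperature
#'
#' Ordinary least squares of each site's annual mean on year.
#'
#' @param temperature Wide temperature table.
#' @param element Temperature element.
#' @param year_range Optional year restriction.
#' @return Data frame `site_id`, `slope`, `se`, `stat`, `p_value`,
#'   `n_years`.
#' @export
per_site_trends <- function(temperature, element = "tmean",
                            year_range = NULL) {
  d <- temperature
  if (!is.null(year_range)) d <- d[d$year >= year_range[1] & d$year <= year_range[2], ]
  ann <- stats::aggregate(d[[element]],
                          by = list(site_id = d$site_id, year = d$year),
                          FUN = mean)
  names(ann)[3] <- "value"
  out <- lapply(split(ann, ann$site_id), function(s) {
    fit <- stats::lm(value ~ year, data = s)
    cf <- summary(fit)$coefficients
    data.frame(site_id = s$site_id[1], slope = cf["year", 1],
               se = cf["year", 2], stat = cf["year", 3],
               p_value = cf["year", 4], n_years = nrow(s))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Climate-region effect on site temperature trends
#'
#' Gaussian GLM of per-site trend slopes on the three-level climate
#' region factor, with an F test of the region term.
#'
#' @param site_slopes Output of [per_site_trends()].
#' @param sites Site table with `site_id` and `climate_region`.
#' @return List with the `glm` fit, `coefficients` table and
#'   `region_test` (F statistic, df, p-value).
#' @export
region_slope_glm <- function(site_slopes, sites) {
  d <- merge(site_slopes, sites[, c("site_id", "climate_region")],
             by = "site_id")
  d$climate_region <- factor(d$climate_region)
  if (nlevels(d$climate_region) < 2L) {
    stop("need at least 2 climate regions to test a region effect")
  }
  small <- table(d$climate_region) < 2L
  if (any(small)) {
    warning("region(s) with fewer than 2 sites: ",
            paste(names(small)[small], collapse = ", "))
  }
  fit <- stats::glm(slope ~ climate_region, data = d, family = stats::gaussian())
  an <- stats::anova(fit, test = "F")
  list(fit = fit,
       coefficients = summary(fit)$coefficients,
       region_test = data.frame(F = an$F[2], df1 = an$Df[2],
                                df2 = an$`Resid. Df`[2],
                                p_value = an$`Pr(>F)`[2]))
}
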