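#' Fit a flight curve to one site-species-year of weekly counts
#'
#' A penalized regression spline of count on Julian day (Poisson family,
#' log link, smoothness chosen by restricted maximum likelihood) fitted
#' with \pkg{mgcv}.  Units with fewer than five weeks in which the
#' species was actually recorded (count > 0) are excluded as unreliable,
#' as are non-converging fits.  The curve is evaluated on a daily grid
#' from the first to the last visit of the year, so boundary artifacts
#' cannot produce spurious peaks.
#'
#' @param weekly Data frame for one site-species-year with columns
#'   `julian_day` and `count`.
#' @param k Spline basis dimension; default `min(10, n_weeks - 1)`.
#' @return A list of class `"flight_curve"`: `kept` (logical), `reason`
#'   (`NA` or one of `"too_few_weeks"`, `"no_convergence"`), `days`,
#'   `intensity` (daily predictions on the response scale), `fit`,
#'   `deviance_explained`.
#' @export
fit_flight_curve <- function(weekly, k = NULL) {
  weekly <- weekly[order(weekly$julian_day), ]
  stopifnot(all(weekly$count >= 0))
  n_pos <- sum(weekly$count > 0)
  if (n_pos < 5L) {
    return(structure(list(kept = FALSE, reason = "too_few_weeks",
                          n_positive_weeks = n_pos),
                     class = "flight_curve"))
  }
  if (is.null(k)) k <- min(10L, nrow(weekly) - 1L)
  fit <- tryCatch(
    mgcv::gam(count ~ s(julian_day, k = k), family = stats::poisson(),
              data = weekly, method = "REML"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !fit$converged) {
    return(structure(list(kept = FALSE, reason = "no_convergence",
                          n_positive_weeks = n_pos),
                     class = "flight_curve"))
  }
  days <- seq(min(weekly$julian_day), max(weekly$julian_day))
  intensity <- as.numeric(stats::predict(
    fit, newdata = data.frame(julian_day = days), type = "response"))
  structure(list(kept = TRUE, reason = NA_character_, days = days,
                 intensity = intensity, fit = fit,
                 n_positive_weeks = n_pos,
                 deviance_explained = summary(fit)$dev.expl),
            class = "flight_curve")
}

#' Detect emergence peaks of a fitted flight curve
#'
#' Strict interior local maxima of the daily intensity, retained when
#' their height reaches `prominence_fraction` of the global maximum.
#' Grid boundary points are never peaks.
#'
#' @param intensity Daily intensity values.
#' @param days Matching Julian days.
#' @param prominence_fraction Minimum peak height as a fraction of the
#'   curve maximum (default 0.05).
#' @return Numeric vector of peak days, ordered by day (possibly empty).
#' @export
detect_peaks <- function(intensity, days, prominence_fraction = 0.05) {
  stopifnot(length(intensity) == length(days))
  n <- length(intensity)
  if (n < 3L) return(numeric(0))
  i <- 2:(n - 1L)
  is_peak <- intensity[i] > intensity[i - 1L] & intensity[i] > intensity[i + 1L]
  cand <- i[is_peak]
  cand <- cand[intensity[cand] >= prominence_fraction * max(intensity)]
  days[cand]
}

#' Select the annual phenological estimate from detected peaks
#'
#' The default estimate is the earliest retained peak (the first annual
#' emergence peak).  A per-species rule can select a later brood instead
#' — e.g. species whose first spring peak reflects reactivation of
#' hibernated adults rather than emergence.
#'
#' @param peaks Ordered peak days from [detect_peaks()].
#' @param peak_rule `"first"` (default) or `"second_generation"`.
#' @return The peak Julian day, or `NA` (reason `"no_peak"`) when no
#'   usable peak exists; attribute `n_peaks` records how many were found.
#' @export
first_emergence_peak <- function(peaks, peak_rule = "first") {
  if (length(peaks) == 0L) {
    return(structure(NA_real_, n_peaks = 0L, reason = "no_peak"))
  }
  day <- switch(peak_rule,
                first = peaks[1L],
                second_generation = if (length(peaks) >= 2L) peaks[2L] else NA_real_,
                stop("unknown peak_rule: ", peak_rule))
  if (is.na(day)) {
    return(structure(NA_real_, n_peaks = length(peaks), reason = "no_peak"))
  }
  structure(day, n_peaks = length(peaks), reason = NA_character_)
}

#' Annual abundance index
#'
#' Natural logarithm of the season total count divided by the number of
#' recording events of that site-year, so that years with fewer visits
#' (bad weather) remain comparable.
#'
#' @param total_count Season total individuals (must be positive).
#' @param n_events Number of recording events (visits) of the site-year.
#' @return `log(total_count / n_events)`.
#' @export
abundance_index <- function(total_count, n_events) {
  stopifnot(n_events >= 1L)
  if (total_count <= 0) stop("abundance index undefined for zero total count")
  log(total_count / n_events)
}

#' Apply the dataset inclusion rules
#'
#' Reproduces the monitoring-scheme filtering: sites monitored for fewer
#' than 10 years are dropped; species flagged as migratory or as having
#' strongly overlapping broods are dropped; a site-species population is
#' usable when at least one year has the species recorded in five or
#' more weeks; species with fewer than three usable populations are
#' dropped.  Every removal is logged with exactly one primary reason.
#'
#' @param counts Counts table (`site_id`, `species_id`, `year`, `week`,
#'   `julian_day`, `count`).
#' @param species_config Optional data frame `species_id`, `migratory`,
#'   `overlapping_broods` (logical); missing species default to FALSE.
#' @param min_site_years Minimum years a site must be monitored (10).
#' @param min_populations Minimum usable populations per species (3).
#' @param min_weeks Minimum weeks with the species recorded for a usable
#'   site-species-year (5).
#' @return List: `kept` (counts restricted to surviving populations),
#'   `populations` (usable site-species pairs), `log` (filter decisions:
#'   `site_id`, `species_id`, `kept`, `reason`).
#' @export
apply_dataset_filters <- function(counts, species_config = NULL,
                                  min_site_years = 10L, min_populations = 3L,
                                  min_weeks = 5L) {
  log <- list()
  note <- function(site, sp, reason) {
    data.frame(site_id = site, species_id = sp, kept = FALSE, reason = reason)
  }
  site_years <- tapply(counts$year, counts$site_id,
                       function(y) length(unique(y)))
  bad_sites <- names(site_years)[site_years < min_site_years]
  if (length(bad_sites)) {
    log <- c(log, list(note(bad_sites, NA_character_, "site_under_10y")))
  }
  d <- counts[!(counts$site_id %in% bad_sites), ]

  flagged <- character(0)
  if (!is.null(species_config)) {
    mig <- species_config$species_id[isTRUE_vec(species_config$migratory)]
    ovl <- species_config$species_id[isTRUE_vec(species_config$overlapping_broods)]
    ovl <- setdiff(ovl, mig)
    if (length(mig)) log <- c(log, list(note(NA_character_, mig, "migratory")))
    if (length(ovl)) log <- c(log, list(note(NA_character_, ovl, "overlapping_broods")))
    flagged <- c(mig, ovl)
  }
  d <- d[!(d$species_id %in% flagged), ]
  if (nrow(d) == 0L) stop("no data survive the site/species flags")

  pos <- d[d$count > 0, ]
  wk <- stats::aggregate(pos$week,
                         by = list(site_id = pos$site_id,
                                   species_id = pos$species_id,
                                   year = pos$year),
                         FUN = function(w) length(unique(w)))
  usable <- wk[wk$x >= min_weeks, c("site_id", "species_id")]
  pops <- unique(usable)
  n_pop <- table(pops$species_id)
  thin <- names(n_pop)[n_pop < min_populations]
  thin <- union(thin, setdiff(unique(d$species_id), names(n_pop)))
  if (length(thin)) {
    log <- c(log, list(note(NA_character_, thin, "too_few_populations")))
  }
  pops <- pops[!(pops$species_id %in% thin), ]
  if (nrow(pops) == 0L) stop("no populations survive the filters")
  keep_key <- paste(pops$site_id, pops$species_id)
  kept <- d[paste(d$site_id, d$species_id) %in% keep_key, ]
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(site_id = character(0), species_id = character(0),
               kept = logical(0), reason = character(0))
  list(kept = kept, populations = pops, log = log_df)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Annual abundance and phenology estimates for all populations
#'
#' For every site-species-year of the filtered counts: fit the flight
#' curve, detect peaks, take the species' annual phenological estimate,
#' and compute the abundance index.  Recording events per site-year are
#' counted over all visits of that site-year (species-independent).
#'
#' @param counts Filtered counts table (from [apply_dataset_filters()]
#'   `$kept`, or raw counts for a single population).
#' @param species_config Optional data frame with `species_id` and
#'   `peak_rule` (`"first"`/`"second_generation"`).
#' @param prominence_fraction Passed to [detect_peaks()].
#' @return List of data frames: `abundance` (`site_id`, `species_id`,
#'   `year`, `log_abundance`, `total_count`, `n_events`), `phenology`
#'   (`site_id`, `species_id`, `year`, `peak_day`, `n_peaks`,
#'   `deviance_explained`), `log` (per-unit filter decisions).
#' @export
estimate_phenology_abundance <- function(counts, species_config = NULL,
                                         prominence_fraction = 0.05) {
  events <- stats::aggregate(counts$week,
                             by = list(site_id = counts$site_id,
                                       year = counts$year),
                             FUN = function(w) length(unique(w)))
  names(events)[3] <- "n_events"
  rule_for <- function(sp) {
    if (is.null(species_config) || !"peak_rule" %in% names(species_config))
      return("first")
    r <- species_config$peak_rule[species_config$species_id == sp]
    if (length(r) == 0L || is.na(r[1L])) "first" else r[1L]
  }
  ab <- list(); ph <- list(); lg <- list()
  units <- split(counts,
                 list(counts$site_id, counts$species_id, counts$year),
                 drop = TRUE)
  for (u in units) {
    site <- u$site_id[1L]; sp <- u$species_id[1L]; yr <- u$year[1L]
    ne <- events$n_events[events$site_id == site & events$year == yr][1L]
    total <- sum(u$count)
    if (total > 0) {
      ab[[length(ab) + 1L]] <- data.frame(
        site_id = site, species_id = sp, year = yr,
        log_abundance = abundance_index(total, ne),
        total_count = total, n_events = ne)
    }
    fc <- fit_flight_curve(u[, c("julian_day", "count")])
    if (!fc$kept) {
      lg[[length(lg) + 1L]] <- data.frame(site_id = site, species_id = sp,
                                          year = yr, kept = FALSE,
                                          reason = fc$reason)
      next
    }
    peaks <- detect_peaks(fc$intensity, fc$days, prominence_fraction)
    day <- first_emergence_peak(peaks, rule_for(sp))
    if (is.na(day)) {
      lg[[length(lg) + 1L]] <- data.frame(site_id = site, species_id = sp,
                                          year = yr, kept = FALSE,
                                          reason = attr(day, "reason"))
      next
    }
    ph[[length(ph) + 1L]] <- data.frame(
      site_id = site, species_id = sp, year = yr,
      peak_day = as.numeric(day), n_peaks = attr(day, "n_peaks"),
      deviance_explained = fc$deviance_explained)
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(
    abundance = bind(ab, data.frame(site_id = character(0),
                                    species_id = character(0),
                                    year = integer(0),
                                    log_abundance = numeric(0),
                                    total_count = numeric(0),
                                    n_events = integer(0))),
    phenology = bind(ph, data.frame(site_id = character(0),
                                    species_id = character(0),
                                    year = integer(0), peak_day = numeric(0),
                                    n_peaks = integer(0),
                                    deviance_explained = numeric(0))),
    log = bind(lg, data.frame(site_id = character(0),
                              species_id = character(0), year = integer(0),
                              kept = logical(0), reason = character(0))))
}
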