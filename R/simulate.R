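#' Configuration for a synthetic butterfly monitoring dataset
#'
#' The defaults emulate a north-western Mediterranean monitoring scheme:
#' 59 transect sites sampled weekly from March to September (ISO weeks
#' 10--39, about 30 recording events) over 26 seasons (1994--2019), with
#' 51 species whose emergence peak responds linearly to the mean
#' temperature of a species-specific monthly window.  Monthly temperature
#' trends are of mixed sign: cooling in February, March and May and
#' warming elsewhere, which averages to an annual trend of about
#' 0.0235 degrees C per year (0.59 degrees C over the 25-year span).
#'
#' @param n_sites Number of monitoring sites.
#' @param n_species Number of species.
#' @param year_start,year_end First and last flight season (calendar
#'   years).  Temperatures are generated from `year_start - 1` so that
#'   windows reaching into the previous autumn are always covered.
#' @param weeks Integer vector of sampled ISO weeks (default 10--39,
#'   March--September).
#' @param mean_site_temp Regional mean annual temperature, degrees C.
#' @param site_temp_sd Between-site spread of the annual mean, degrees C.
#' @param seasonal_amplitude Half-range of the within-year sinusoidal
#'   temperature cycle, degrees C (July peak).
#' @param monthly_trend_vector Twelve per-month temperature trends,
#'   degrees C per year (January first).
#' @param temp_noise_sd Independent Gaussian noise added to each
#'   site-year-month temperature, degrees C.
#' @param detection_missingness Probability that a weekly visit is
#'   skipped; skipped visits are absent rows, not zeros.
#' @param sensitivity_range Range (days per degree C) from which typical
#'   species' thermal sensitivities are drawn; negative values mean
#'   earlier flight in warmer years.
#' @param n_atypical Number of species given a positive (delaying)
#'   sensitivity.
#' @param prop_multivoltine Proportion of species with a second brood.
#' @param abundance_trend_sd Standard deviation of the Brownian residual
#'   of species abundance trends (log abundance per year).
#' @param phenology_extra_range Range of the residual peak-day trend not
#'   mediated by temperature (days per year).
#' @param seed Integer seed; the whole dataset is a deterministic
#'   function of the configuration including the seed.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_sites = 59L,
                              n_species = 51L,
                              year_start = 1994L,
                              year_end = 2019L,
                              weeks = 10:39,
                              mean_site_temp = 14,
                              site_temp_sd = 2,
                              seasonal_amplitude = 8,
                              monthly_trend_vector = default_monthly_trends(),
                              temp_noise_sd = 0.5,
                              detection_missingness = 0.1,
                              sensitivity_range = c(-8, 0),
                              n_atypical = round(n_species * 3 / 51),
                              prop_multivoltine = 0.3,
                              abundance_trend_sd = 0.015,
                              phenology_extra_range = c(-0.1, 0.1),
                              seed = 1L) {
  stopifnot(year_end > year_start,
            length(monthly_trend_vector) == 12L,
            detection_missingness >= 0, detection_missingness < 1,
            n_sites >= 1L, n_species >= 2L)
  cfg <- list(n_sites = as.integer(n_sites), n_species = as.integer(n_species),
              year_start = as.integer(year_start), year_end = as.integer(year_end),
              weeks = as.integer(weeks), mean_site_temp = mean_site_temp,
              site_temp_sd = site_temp_sd, seasonal_amplitude = seasonal_amplitude,
              monthly_trend_vector = monthly_trend_vector,
              temp_noise_sd = temp_noise_sd,
              detection_missingness = detection_missingness,
              sensitivity_range = sensitivity_range,
              n_atypical = as.integer(n_atypical),
              prop_multivoltine = prop_multivoltine,
              abundance_trend_sd = abundance_trend_sd,
              phenology_extra_range = phenology_extra_range,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default per-month temperature trends (degrees C per year)
#'
#' Cooling in February, March and May, warming in the other nine months,
#' chosen so the annual mean trend is 0.0235 degrees C per year.
#' @return Numeric vector of length 12, January first.
#' @export
default_monthly_trends <- function() {
  tr <- rep(0.038, 12L)
  tr[c(2L, 3L, 5L)] <- -0.02
  names(tr) <- month.abb
  tr
}

#' Julian day of a sampled ISO week (approximate Monday)
#' @noRd
week_to_julian <- function(week) 7L * as.integer(week) - 3L

seasonal_cycle <- function(month, amplitude) {
  amplitude * cos(2 * pi * (month - 7) / 12)
}

#' Site table for a simulation
#'
#' Draws per-site baseline temperatures and planar coordinates, and
#' assigns each site to one of three climate regions by its baseline.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return Data frame: `site_id`, `x`, `y`, `altitude`, `baseline_temp`,
#'   `climate_region`.
#' @export
simulate_sites <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_sites
  baseline <- stats::rnorm(n, config$mean_site_temp, config$site_temp_sd)
  region <- cut(baseline,
                breaks = stats::quantile(baseline, c(0, 1/3, 2/3, 1)),
                labels = c("alpine_subalpine", "mediterranean_mesic",
                           "mediterranean_xeric"),
                include.lowest = TRUE)
  data.frame(
    site_id = sprintf("site%02d", seq_len(n)),
    x = stats::runif(n, 0, 200), y = stats::runif(n, 0, 200),
    altitude = pmax(0, (config$mean_site_temp - baseline) / 0.0065),
    baseline_temp = baseline,
    climate_region = as.character(region)
  )
}

#' Expected (noise-free) monthly mean temperature
#' @noRd
expected_monthly_temp <- function(config, baseline_temp, year, month) {
  baseline_temp + seasonal_cycle(month, config$seasonal_amplitude) +
    config$monthly_trend_vector[month] * (year - config$year_start)
}

#' Simulate monthly site temperatures
#'
#' Each site-year-month value is the site baseline plus a fixed seasonal
#' sinusoid, a linear per-month trend and independent Gaussian noise.
#' Years run from `year_start - 1` through `year_end` so that climate
#' windows reaching into the previous autumn are covered.
#'
#' @param config A [simulation_config()].
#' @param sites Site table from [simulate_sites()]; generated if `NULL`.
#' @param seed Optional seed.
#' @return Data frame: `site_id`, `year`, `month`, `tmin`, `tmean`,
#'   `tmax`.
#' @export
simulate_temperatures <- function(config, sites = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sites)) sites <- simulate_sites(config)
  grid <- expand.grid(month = 1:12,
                      year = (config$year_start - 1L):config$year_end,
                      site_id = sites$site_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("site_id", "year", "month")]
  base <- sites$baseline_temp[match(grid$site_id, sites$site_id)]
  mu <- base + seasonal_cycle(grid$month, config$seasonal_amplitude) +
    config$monthly_trend_vector[grid$month] * (grid$year - config$year_start)
  grid$tmean <- mu + stats::rnorm(nrow(grid), 0, config$temp_noise_sd)
  # daily range around the mean; only tmean drives the generative model
  half_range <- 4 + stats::rnorm(nrow(grid), 0, 0.3)
  grid$tmin <- grid$tmean - half_range
  grid$tmax <- grid$tmean + half_range
  grid[, c("site_id", "year", "month", "tmin", "tmean", "tmax")]
}

#' Simulate a pure-birth species phylogeny
#'
#' @param n_species Number of tips (at least 2).
#' @param seed Optional seed.
#' @param tip_labels Optional character vector of tip labels.
#' @return An [ape::ape-package] `phylo` object with strictly positive
#'   branch lengths.
#' @export
simulate_tree <- function(n_species, seed = NULL, tip_labels = NULL) {
  if (n_species < 2L) stop("a phylogeny needs at least 2 species")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$tip.label <- if (is.null(tip_labels)) {
    sprintf("sp%02d", seq_len(n_species))
  } else tip_labels
  tree
}

#' Simulate species ecological and life-history traits
#'
#' Voltinism, overwintering stage and larval diet are categorical; the
#' habitat specialization index (SSI), open-habitat preference (TAO) and
#' host plant index (HPI, a positive count-like trophic-specialization
#' measure) are continuous.
#'
#' @param n_species Number of species.
#' @param prop_multivoltine Proportion of multivoltine species.
#' @param seed Optional seed.
#' @return Data frame with columns `species_id`, `voltinism`,
#'   `overwinter_stage`, `larval_diet`, `ssi`, `tao`, `hpi`.
#' @export
simulate_traits <- function(n_species, prop_multivoltine = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_species
  data.frame(
    species_id = sprintf("sp%02d", seq_len(n)),
    voltinism = ifelse(stats::runif(n) < prop_multivoltine,
                       "multivoltine", "univoltine"),
    overwinter_stage = sample(c("egg", "larva", "pupa", "adult"), n,
                              replace = TRUE, prob = c(0.15, 0.45, 0.3, 0.1)),
    larval_diet = sample(c("grass", "forb", "tree"), n, replace = TRUE,
                         prob = c(0.4, 0.4, 0.2)),
    ssi = stats::rlnorm(n, log(4), 0.5),
    tao = stats::rnorm(n, 0, 1),
    hpi = stats::rlnorm(n, log(9), 0.6)
  )
}

#' Species-level trends with trait effects and Brownian residuals
#'
#' Generates species values as `X beta + eps` where `X` is the model
#' matrix of `formula` evaluated on `traits` and `eps` is multivariate
#' normal with covariance `sigma2 * C`, `C` the Brownian path-length
#' matrix of the tree.  Closely related species therefore receive
#' correlated residuals.
#'
#' @param traits Trait table with a `species_id` column matching the tree
#'   tips.
#' @param tree `phylo` object whose tips cover every species.
#' @param beta Named numeric vector of effect sizes; names must match the
#'   columns of `model.matrix(formula, traits)`.
#' @param formula Right-hand-side formula over trait columns.
#' @param sigma2 Brownian rate of the residual (variance per unit branch
#'   length).
#' @param seed Optional seed.
#' @return Numeric vector of species values, named by `species_id`.
#' @export
simulate_species_effects <- function(traits, tree, beta,
                                     formula = ~1, sigma2 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(traits$species_id %in% tree$tip.label)) {
    missing <- setdiff(traits$species_id, tree$tip.label)
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  }
  X <- stats::model.matrix(formula, traits)
  if (!setequal(names(beta), colnames(X))) {
    stop("beta names do not match model matrix columns: expected ",
         paste(colnames(X), collapse = ", "))
  }
  mu <- drop(X %*% beta[colnames(X)])
  if (sigma2 > 0) {
    C <- brownian_covariance(tree)[traits$species_id, traits$species_id]
    eps <- drop(MASS::mvrnorm(1, mu = rep(0, nrow(X)), Sigma = sigma2 * C))
  } else {
    eps <- rep(0, nrow(X))
  }
  stats::setNames(mu + eps, traits$species_id)
}

#' Draw the per-species generative truth
#'
#' Assigns each species a baseline peak day, a thermal sensitivity, a
#' critical climate window (weighted towards late winter, where most
#' Mediterranean species concentrate development), an abundance trend
#' driven by its traits with Brownian phylogenetic residuals, a residual
#' phenology trend, flight-curve spread and expected season total.
#'
#' @param config A [simulation_config()].
#' @param traits Trait table from [simulate_traits()].
#' @param tree Species phylogeny.
#' @param seed Optional seed.
#' @return Data frame with one row per species (the ground-truth
#'   sidecar).
#' @export
simulate_species_params <- function(config, traits, tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_species
  sens <- stats::runif(n, config$sensitivity_range[1], config$sensitivity_range[2])
  if (config$n_atypical > 0) {
    atyp <- sample.int(n, config$n_atypical)
    sens[atyp] <- stats::runif(config$n_atypical, 0.5, 3)
  }
  win_len <- sample(1:3, n, replace = TRUE)
  # start indices favour Dec-Apr (slots 4-8); 86% of real species include
  # January in their critical period
  win_start <- integer(n)
  w <- c(1, 1, 1, 3, 6, 6, 3, 2, 1, 1, 1, 1, 1)
  for (i in seq_len(n)) {
    ok <- seq_len(13L - win_len[i] + 1L)
    win_start[i] <- sample(ok, 1L, prob = w[ok])
  }
  # trait effects on abundance trends: trophic and habitat specialists and
  # univoltine species decline more
  beta <- c("(Intercept)" = -0.035, "hpi_sqrt" = 0.009,
            "voltinismunivoltine" = -0.008, "ssi" = -0.002, "tao" = -0.004)
  tr <- traits
  tr$hpi_sqrt <- sqrt(tr$hpi)
  ab_trend <- simulate_species_effects(
    tr, tree, beta, formula = ~ hpi_sqrt + voltinism + ssi + tao,
    sigma2 = config$abundance_trend_sd^2 / mean(diag(brownian_covariance(tree))))
  multiv <- traits$voltinism == "multivoltine"
  data.frame(
    species_id = traits$species_id,
    baseline_peak_day = stats::runif(n, 105, 240),
    sensitivity_true = sens,
    window_start_true = win_start,
    window_length_true = win_len,
    abundance_trend_true = unname(ab_trend[traits$species_id]),
    phenology_trend_extra = stats::runif(n, config$phenology_extra_range[1],
                                         config$phenology_extra_range[2]),
    voltinism = traits$voltinism,
    second_brood_offset = ifelse(multiv, stats::runif(n, 45, 70), NA_real_),
    flight_sd = stats::runif(n, 8, 14),
    expected_total_count = stats::rlnorm(n, log(250), 0.4)
  )
}

#' Expected weekly count intensities for one species, site and year
#'
#' The emergence peak day is
#' `baseline_peak_day + sensitivity * (T_window - T_baseline) +
#' phenology_trend_extra * (year - year_start)`, where `T_window` is the
#' realized mean temperature of the species' critical window for that
#' site and year and `T_baseline` its noise-free value in the first study
#' year.  Weekly intensities follow a Gaussian flight curve (two Gaussian
#' broods for multivoltine species, weights 0.65/0.35) renormalized so
#' that the season total equals
#' `expected_total_count * exp(abundance_trend_true * (year - year_start))`
#' exactly.
#'
#' @param truth One row of the [simulate_species_params()] table.
#' @param site One row of the site table.
#' @param year Flight season.
#' @param temperature Temperature table covering the window months.
#' @param config The simulation configuration.
#' @return Data frame: `week`, `julian_day`, `intensity`.
#' @export
expected_weekly_intensity <- function(truth, site, year, temperature, config) {
  t_win <- window_mean_temperature(temperature, site$site_id,
                                   truth$window_start_true,
                                   truth$window_length_true, year)
  t_base <- baseline_window_temperature(config, site, truth)
  mu <- truth$baseline_peak_day +
    truth$sensitivity_true * (t_win - t_base) +
    truth$phenology_trend_extra * (year - config$year_start)
  total <- truth$expected_total_count *
    exp(truth$abundance_trend_true * (year - config$year_start))
  days <- week_to_julian(config$weeks)
  w <- stats::dnorm(days, mu, truth$flight_sd)
  if (!is.na(truth$second_brood_offset)) {
    w <- 0.65 * w +
      0.35 * stats::dnorm(days, mu + truth$second_brood_offset, truth$flight_sd)
  }
  if (sum(w) <= 0) w <- rep(1e-12, length(w))
  data.frame(week = config$weeks, julian_day = days,
             intensity = total * w / sum(w))
}

#' Noise-free critical-window temperature in the first study year,
#' evaluated at the regional mean temperature.  The reference is shared
#' by all sites so that a site that is persistently warmer (for example,
#' at lower altitude) also has a persistently earlier flight period --
#' spatial and inter-annual temperature variation shift the peak along
#' the same response slope.
#' @noRd
baseline_window_temperature <- function(config, site, truth) {
  mons <- window_months(truth$window_start_true, truth$window_length_true,
                        config$year_start)
  mean(expected_monthly_temp(config, config$mean_site_temp,
                             mons$year, mons$month))
}

#' Build the full expected-intensity table
#' @noRd
expected_intensity_table <- function(config, sites, temperature, truth) {
  years <- config$year_start:config$year_end
  pieces <- vector("list", nrow(truth) * nrow(sites) * length(years))
  k <- 0L
  for (si in seq_len(nrow(sites))) {
    site <- sites[si, ]
    for (sp in seq_len(nrow(truth))) {
      tr <- truth[sp, ]
      for (yr in years) {
        k <- k + 1L
        wi <- expected_weekly_intensity(tr, site, yr, temperature, config)
        wi$site_id <- site$site_id; wi$species_id <- tr$species_id
        wi$year <- yr
        pieces[[k]] <- wi
      }
    }
  }
  out <- do.call(rbind, pieces)
  out[, c("site_id", "species_id", "year", "week", "julian_day", "intensity")]
}

#' Draw observed counts from expected intensities
#'
#' Weekly visits are skipped independently with probability
#' `missingness`; the skip applies to the whole visit, so every species
#' shares a site-year's visit schedule.  Retained visits draw independent
#' Poisson counts with the given intensities.  Skipped visits are absent
#' rows, not zeros.
#'
#' @param intensity Table from [expected_weekly_intensity()] rows
#'   (columns `site_id`, `species_id`, `year`, `week`, `julian_day`,
#'   `intensity`).
#' @param missingness Per-visit skip probability in `[0, 1)`.
#' @param seed Optional seed.
#' @return Counts table: `site_id`, `species_id`, `year`, `week`,
#'   `julian_day`, `count`.
#' @export
simulate_counts <- function(intensity, missingness = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(intensity$intensity >= 0))
  visits <- unique(intensity[, c("site_id", "year", "week")])
  visits <- visits[order(visits$site_id, visits$year, visits$week), ]
  visits$kept <- stats::runif(nrow(visits)) >= missingness
  key <- function(d) paste(d$site_id, d$year, d$week, sep = "\r")
  keep <- visits$kept[match(key(intensity), key(visits))]
  out <- intensity[keep, , drop = FALSE]
  out$count <- stats::rpois(nrow(out), out$intensity)
  out$intensity <- NULL
  rownames(out) <- NULL
  out
}

#' Simulate a complete monitoring dataset with recorded ground truth
#'
#' Runs the whole generative model in a fixed order from the
#' configuration seed: sites, monthly temperatures, phylogeny, traits,
#' species truth, expected weekly intensities and Poisson counts with
#' missing visits.  The same configuration always yields the identical
#' dataset.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"synthetic_dataset"` with elements `sites`,
#'   `temperature`, `counts`, `traits`, `tree` (a `phylo`), `truth` and
#'   `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  set.seed(config$seed)
  sites <- simulate_sites(config)
  temperature <- simulate_temperatures(config, sites)
  tree <- simulate_tree(config$n_species)
  traits <- simulate_traits(config$n_species, config$prop_multivoltine)
  truth <- simulate_species_params(config, traits, tree)
  intensity <- expected_intensity_table(config, sites, temperature, truth)
  counts <- simulate_counts(intensity, config$detection_missingness)
  structure(list(sites = sites, temperature = temperature, counts = counts,
                 traits = traits, tree = tree, truth = truth, config = config),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Counts, temperatures, traits and sites as CSV, the phylogeny as
#' Newick, and the ground truth as a JSON sidecar.
#'
#' @param dataset A `"synthetic_dataset"` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             temperature = file.path(dir, "temperature.csv"),
             traits = file.path(dir, "traits.csv"),
             sites = file.path(dir, "sites.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(dataset$counts, paths["counts"], row.names = FALSE)
  utils::write.csv(dataset$temperature, paths["temperature"], row.names = FALSE)
  utils::write.csv(dataset$traits, paths["traits"], row.names = FALSE)
  utils::write.csv(dataset$sites, paths["sites"], row.names = FALSE)
  ape::write.tree(dataset$tree, paths["tree"])
  jsonlite::write_json(dataset$truth, paths["truth"], digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
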