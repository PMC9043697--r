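# Shared fixtures, all built in code at test time.

# Small configuration for fast end-to-end runs.
tiny_config <- function(seed = 42L, ...) {
  simulation_config(n_sites = 4L, n_species = 6L,
                    year_start = 1994L, year_end = 2008L,
                    seed = seed, ...)
}

# Constant monthly temperature table for one or more sites.
constant_temperature <- function(sites, years, value = 10) {
  g <- expand.grid(month = 1:12, year = c(min(years) - 1L, years),
                   site_id = sites, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  data.frame(site_id = g$site_id, year = g$year, month = g$month,
             tmin = value - 4, tmean = value, tmax = value + 4)
}

# Long station table on a regular grid with a pure lapse-rate field.
lapse_rate_stations <- function(n = 12, month = 1, element = "tmean",
                                lapse = -0.0065, noise_sd = 0,
                                seed = 1) {
  set.seed(seed)
  alt <- seq(0, 2200, length.out = n)
  data.frame(station_id = sprintf("st%02d", seq_len(n)),
             x = seq(0, 100, length.out = n),
             y = rep(c(0, 50), length.out = n),
             altitude = alt,
             latitude = 41 + stats::runif(n, 0, 0.5),
             continentality = stats::runif(n, 0, 1),
             solar_radiation = stats::runif(n, 0.8, 1.2),
             month = month, element = element,
             value = 20 + lapse * alt + stats::rnorm(n, 0, noise_sd))
}

# Weekly counts drawn from a Gaussian flight curve.
gaussian_weekly_counts <- function(peak_day = 150, sd = 10, total = 300,
                                   weeks = 10:39, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  days <- 7L * weeks - 3L
  w <- stats::dnorm(days, peak_day, sd)
  intensity <- total * w / sum(w)
  data.frame(julian_day = days, count = stats::rpois(length(days), intensity))
}

# One-species phenology records with an exact linear temperature response.
linear_phenology_fixture <- function(n_sites = 5, years = 1994:2013,
                                     slope = -4, intercept = 200,
                                     window_start = 5, window_length = 2,
                                     noise_sd = 0, seed = 1) {
  set.seed(seed)
  sites <- sprintf("s%02d", seq_len(n_sites))
  temps <- constant_temperature(sites, years)
  temps$tmean <- temps$tmean + stats::rnorm(nrow(temps), 0, 1)
  grid <- expand.grid(site_id = sites, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$t_window <- vapply(seq_len(nrow(grid)), function(i) {
    window_mean_temperature(temps, grid$site_id[i], window_start,
                            window_length, grid$year[i])
  }, numeric(1))
  grid$peak_day <- intercept + slope * grid$t_window +
    stats::rnorm(nrow(grid), 0, noise_sd)
  grid$species_id <- "spA"
  list(phenology = grid, temperature = temps)
}

# A small ultrametric fixture tree and a trait table aligned to it.
fixture_tree <- function(n = 8, seed = 3) {
  simulate_tree(n, seed = seed)
}
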