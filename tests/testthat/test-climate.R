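test_that("monthly regression recovers a pure lapse-rate field", {
  st <- lapse_rate_stations(n = 12, noise_sd = 0)
  reg <- fit_monthly_regression(st, month = 1, element = "tmean")
  expect_equal(unname(reg$coefficients["altitude"]), -0.0065,
               tolerance = 1e-8)
  expect_lt(max(abs(reg$residuals)), 1e-8)

  # constant field: zero slopes, intercept equal to the constant
  st$value <- 12.5
  reg <- fit_monthly_regression(st, 1, "tmean")
  expect_equal(unname(reg$coefficients[-1]), rep(0, 4), tolerance = 1e-8)
  expect_equal(unname(reg$coefficients[1]), 12.5, tolerance = 1e-6)
})

test_that("monthly regression rejects under-determined or collinear designs", {
  st <- lapse_rate_stations(n = 12)
  expect_error(fit_monthly_regression(st[1:4, ], 1, "tmean"), "at least 6")
  col <- st
  col$solar_radiation <- 2 * col$continentality  # collinear pair
  expect_error(fit_monthly_regression(col, 1, "tmean"), "solar_radiation")
})

test_that("IDW residual correction is an exact interpolator", {
  xy <- cbind(c(0, 10, 20), c(0, 0, 0))
  r <- c(1.5, -0.5, 3)
  for (p in c(0.5, 1, 2, 4)) {
    expect_equal(idw_residual_correction(xy, r, xy, power = p), r)
  }
  # equal residuals everywhere give that constant at any target
  targets <- cbind(runif(5, 0, 20), runif(5, -5, 5))
  expect_equal(idw_residual_correction(xy, rep(2, 3), targets), rep(2, 5))
  # two stations, residuals 0 and 2, equidistant target, power 2 -> 1
  expect_equal(idw_residual_correction(cbind(c(0, 2), c(0, 0)), c(0, 2),
                                       cbind(1, 5), power = 2), 1)
  expect_error(idw_residual_correction(xy[0, , drop = FALSE], numeric(0),
                                       cbind(0, 0)), "no stations")
})

test_that("site temperatures reproduce station values and shift affinely", {
  st <- lapse_rate_stations(n = 10, noise_sd = 0.3, seed = 4)
  sites <- data.frame(site_id = sprintf("site%d", 1:10),
                      x = st$x, y = st$y, altitude = st$altitude,
                      latitude = st$latitude,
                      continentality = st$continentality,
                      solar_radiation = st$solar_radiation)
  tab <- site_temperature_table(st, sites)
  # sites colocated with stations recover the station values exactly
  expect_equal(tab$value, st$value, tolerance = 1e-8)

  shifted <- st; shifted$value <- shifted$value + 3
  tab2 <- site_temperature_table(shifted, sites)
  expect_equal(tab2$value, tab$value + 3, tolerance = 1e-8)
})

test_that("leave-one-station-out errors are finite on a noisy field", {
  st <- lapse_rate_stations(n = 12, noise_sd = 0.5, seed = 8)
  errs <- vapply(seq_len(nrow(st)), function(i) {
    target <- data.frame(site_id = "loo", st[i, c("x", "y", "altitude",
                                                  "latitude", "continentality",
                                                  "solar_radiation")])
    pred <- site_temperature_table(st[-i, ], target)$value
    pred - st$value[i]
  }, numeric(1))
  rmse <- sqrt(mean(errs^2))
  expect_true(is.finite(rmse))
  expect_lt(rmse, 5)
})

test_that("regional mixed-model trend matches the generating slope", {
  # annual slope chosen to imply ~0.59 degrees over 25 years
  cfg <- simulation_config(n_sites = 20, n_species = 2, seed = 13)
  set.seed(cfg$seed)
  temps <- simulate_temperatures(cfg)
  tr <- temperature_trend_lmm(temps, "tmean", "annual",
                              c(cfg$year_start, cfg$year_end))
  true_slope <- mean(cfg$monthly_trend_vector)
  expect_lt(abs(tr$slope - true_slope), 2 * tr$se)
  expect_equal(tr$implied_change, tr$slope * 25)
  expect_lt(abs(tr$implied_change - 0.59), 0.15)

  # all sites on one exact line: slope exact, se ~ 0
  years <- 1994:2013
  exact <- expand.grid(month = 1:12, year = years,
                       site_id = c("a", "b"), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  exact$tmean <- 10 + 0.02 * (exact$year - 1994)
  tr <- suppressWarnings(temperature_trend_lmm(exact, "tmean", "annual"))
  expect_equal(tr$slope, 0.02, tolerance = 1e-8)
  expect_lt(tr$se, 1e-6)
})

test_that("zero-trend simulations rarely produce significant annual slopes", {
  cfg <- simulation_config(n_sites = 6, n_species = 2,
                           year_start = 1994, year_end = 2009,
                           monthly_trend_vector = rep(0, 12))
  set.seed(21)
  hits <- vapply(1:150, function(i) {
    temps <- simulate_temperatures(cfg)
    tr <- temperature_trend_lmm(temps, "tmean", "annual",
                                c(cfg$year_start, cfg$year_end))
    abs(tr$slope) < 2 * tr$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("per-site trends are exact on noiseless series and die under permutation", {
  years <- 1994:2019
  d <- expand.grid(month = 1:12, year = years, site_id = "s1",
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$tmean <- 5 + 0.03 * (d$year - 1994)
  tr <- per_site_trends(d)
  expect_equal(tr$slope, 0.03, tolerance = 1e-10)

  # with noise the significant trend disappears for permuted years
  set.seed(31)
  d$tmean <- d$tmean + rnorm(nrow(d), 0, 0.3)
  obs <- per_site_trends(d)
  expect_lt(obs$p_value, 0.01)
  perm_p <- vapply(1:60, function(i) {
    dp <- d
    map <- setNames(sample(years), years)
    dp$year <- map[as.character(dp$year)]
    per_site_trends(dp)$p_value
  }, numeric(1))
  expect_gte(mean(perm_p > 0.05), 0.9)
})

test_that("region GLM recovers region means and needs two regions", {
  set.seed(41)
  sites <- data.frame(site_id = sprintf("s%02d", 1:30),
                      climate_region = rep(c("alpine_subalpine",
                                             "mediterranean_mesic",
                                             "mediterranean_xeric"), each = 10))
  mu <- c(alpine_subalpine = 0.01, mediterranean_mesic = 0.02,
          mediterranean_xeric = 0.03)
  slopes <- data.frame(site_id = sites$site_id,
                       slope = mu[sites$climate_region] +
                         rnorm(30, 0, 1e-4))
  res <- region_slope_glm(slopes, sites)
  cf <- res$coefficients
  expect_lt(abs(cf[1, 1] - 0.01), 1e-4)  # reference level mean
  expect_lt(abs(cf[2, 1] - 0.01), 1e-4)  # mesic contrast
  expect_lt(abs(cf[3, 1] - 0.02), 1e-4)  # xeric contrast
  expect_lt(res$region_test$p_value, 1e-6)

  # near-identical slopes: region effect indistinguishable from zero
  flat <- slopes; flat$slope <- 0.02 + rnorm(30, 0, 1e-6)
  res <- region_slope_glm(flat, sites)
  expect_gt(res$region_test$p_value, 0.05)
  expect_lt(max(abs(res$coefficients[-1, 1])), 1e-5)

  one <- sites; one$climate_region <- "mediterranean_mesic"
  expect_error(region_slope_glm(slopes, one), "at least 2")
})
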