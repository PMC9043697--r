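test_that("the same configuration reproduces the dataset exactly", {
  cfg <- tiny_config(seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$temperature, b$temperature)
  expect_identical(a$truth, b$truth)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("zero trend and zero noise give identical monthly values every year", {
  cfg <- tiny_config(monthly_trend_vector = rep(0, 12), temp_noise_sd = 0)
  set.seed(1)
  temps <- simulate_temperatures(cfg)
  byy <- split(temps$tmean, temps$year)
  for (i in seq_along(byy)[-1]) expect_equal(byy[[i]], byy[[1]])
})

test_that("per-month OLS refits recover the generating monthly trends", {
  tr <- rep(0, 12); tr[6:11] <- 0.03; tr[c(2, 3, 5)] <- -0.03
  cfg <- simulation_config(n_sites = 20, n_species = 2,
                           year_start = 1994, year_end = 2019,
                           monthly_trend_vector = tr, temp_noise_sd = 0.5,
                           seed = 5)
  set.seed(cfg$seed)
  temps <- simulate_temperatures(cfg)
  temps <- temps[temps$year >= cfg$year_start, ]
  for (m in 1:12) {
    d <- temps[temps$month == m, ]
    fit <- lm(tmean ~ year, data = d)
    est <- coef(summary(fit))["year", ]
    expect_lt(abs(est["Estimate"] - tr[m]), 3 * est["Std. Error"])
  }
})

test_that("expected intensities respond to temperature and trends as built", {
  cfg <- tiny_config(temp_noise_sd = 0, monthly_trend_vector = rep(0, 12))
  site <- data.frame(site_id = "s1", baseline_temp = cfg$mean_site_temp)
  temps <- constant_temperature("s1", cfg$year_start:cfg$year_end, value = 0)
  # make the realized window match the noise-free baseline
  base_truth <- data.frame(species_id = "spA", baseline_peak_day = 170,
                           sensitivity_true = 0, window_start_true = 5,
                           window_length_true = 2, abundance_trend_true = 0,
                           phenology_trend_extra = 0,
                           second_brood_offset = NA_real_, flight_sd = 10,
                           expected_total_count = 200)
  for (m in 1:2) {  # every year's window months sit at the baseline value
    sel <- temps$month == m
    temps$tmean[sel] <- cfg$mean_site_temp + 8 * cos(2 * pi * (m - 7) / 12)
  }
  # zero sensitivity and trends: every year identical
  i1 <- expected_weekly_intensity(base_truth, site, cfg$year_start, temps, cfg)
  i2 <- expected_weekly_intensity(base_truth, site, cfg$year_end, temps, cfg)
  expect_equal(i1$intensity, i2$intensity)
  expect_equal(which.max(i1$intensity), which.max(i2$intensity))

  # -4 days per degree: a 1 degree warmer window shifts the mode 4 days earlier
  tr4 <- base_truth; tr4$sensitivity_true <- -4; tr4$baseline_peak_day <- 172
  warm <- temps
  mons2 <- window_months(5, 2, cfg$year_start + 1L)
  for (i in seq_len(nrow(mons2))) {
    sel <- warm$year == mons2$year[i] & warm$month == mons2$month[i]
    warm$tmean[sel] <- warm$tmean[sel] + 1
  }
  cold_mode <- with(expected_weekly_intensity(tr4, site, cfg$year_start,
                                              temps, cfg),
                    julian_day[which.max(intensity)])
  warm_mode <- with(expected_weekly_intensity(tr4, site, cfg$year_start + 1L,
                                              warm, cfg),
                    julian_day[which.max(intensity)])
  # weekly grid: a 4-day shift moves the argmax by at most one week
  expect_true(warm_mode < cold_mode)
  expect_lte(cold_mode - warm_mode, 7)

  # abundance trend log(2)/span doubles the season total by the final year
  tr2 <- base_truth
  span <- cfg$year_end - cfg$year_start
  tr2$abundance_trend_true <- log(2) / span
  first <- sum(expected_weekly_intensity(tr2, site, cfg$year_start,
                                         temps, cfg)$intensity)
  last <- sum(expected_weekly_intensity(tr2, site, cfg$year_end,
                                        temps, cfg)$intensity)
  expect_equal(last / first, 2, tolerance = 1e-10)
})

test_that("season totals follow the abundance trend exactly before noise", {
  cfg <- tiny_config(seed = 9)
  set.seed(cfg$seed)
  sites <- simulate_sites(cfg)
  temps <- simulate_temperatures(cfg, sites)
  tree <- simulate_tree(cfg$n_species)
  traits <- simulate_traits(cfg$n_species, cfg$prop_multivoltine)
  truth <- simulate_species_params(cfg, traits, tree)
  site <- sites[1, ]; tr <- truth[1, ]
  tot <- vapply(cfg$year_start:cfg$year_end, function(y) {
    sum(expected_weekly_intensity(tr, site, y, temps, cfg)$intensity)
  }, numeric(1))
  expected <- tr$expected_total_count *
    exp(tr$abundance_trend_true * (cfg$year_start:cfg$year_end - cfg$year_start))
  expect_equal(tot, expected, tolerance = 1e-10)
})

test_that("counts are Poisson around the intensities with dropped visits", {
  intensity <- data.frame(site_id = "s1", species_id = "spA", year = 2000,
                          week = 10:39, julian_day = 7 * (10:39) - 3,
                          intensity = 0)
  set.seed(1)
  zero <- simulate_counts(intensity, missingness = 0)
  expect_true(all(zero$count == 0))
  expect_equal(nrow(zero), 30L)

  # mean retained visits under 20% missingness is ~24 of 30
  set.seed(2)
  kept <- replicate(500, nrow(simulate_counts(intensity, missingness = 0.2)))
  expect_equal(mean(kept), 24, tolerance = 0.02)

  # Poisson concentration at large intensity
  intensity$intensity <- 2000
  set.seed(3)
  big <- simulate_counts(intensity, missingness = 0)
  expect_true(all(abs(big$count - 2000) / 2000 < 0.1))
})

test_that("missingness drops whole visits, shared across species", {
  intensity <- expand.grid(week = 10:39, species_id = c("spA", "spB"),
                           site_id = "s1", year = 2000,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  intensity$julian_day <- 7 * intensity$week - 3
  intensity$intensity <- 5
  set.seed(4)
  out <- simulate_counts(intensity, missingness = 0.3)
  wk <- split(out$week, out$species_id)
  expect_identical(sort(wk$spA), sort(wk$spB))
})

test_that("simulated trees are valid pure-birth phylogenies", {
  t2 <- simulate_tree(2, seed = 1)
  expect_s3_class(t2, "phylo")
  expect_equal(ape::Ntip(t2), 2L)
  rt <- ape::read.tree(text = ape::write.tree(t2))
  expect_equal(sort(rt$tip.label), sort(t2$tip.label))

  t51 <- simulate_tree(51, seed = 2)
  expect_equal(ape::Ntip(t51), 51L)
  expect_equal(t51$Nnode, 50L)
  expect_true(all(t51$edge.length > 0))

  expect_identical(ape::write.tree(simulate_tree(12, seed = 7)),
                   ape::write.tree(simulate_tree(12, seed = 7)))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("species effects are X beta plus Brownian residuals", {
  tree <- fixture_tree(n = 6)
  traits <- simulate_traits(6, seed = 2)
  beta <- c("(Intercept)" = -0.02, "ssi" = 0.005)
  exact <- simulate_species_effects(traits, tree, beta, ~ ssi, sigma2 = 0)
  expect_equal(unname(exact), unname(-0.02 + 0.005 * traits$ssi))

  # star tree: residuals are independent across species
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("sp%02d:1", 1:6), collapse = ","), ");"))
  set.seed(10)
  reps <- t(replicate(400, as.numeric(
    simulate_species_effects(traits, star, c("(Intercept)" = 0), ~ 1,
                             sigma2 = 1))))
  S <- cov(reps)
  off <- S[upper.tri(S)]
  expect_true(max(abs(off)) < 0.35)
  expect_equal(unname(diag(S)), rep(1, 6), tolerance = 0.35)

  # on a structured tree the residual covariance converges to sigma2 * C
  C <- brownian_covariance(tree)[traits$species_id, traits$species_id]
  set.seed(11)
  reps <- t(replicate(400, as.numeric(
    simulate_species_effects(traits, tree, c("(Intercept)" = 0), ~ 1,
                             sigma2 = 1))))
  expect_lt(max(abs(cov(reps) - C)), 0.5 * max(diag(C)))

  bad <- traits; bad$species_id[1] <- "missing_sp"
  expect_error(simulate_species_effects(bad, tree, beta, ~ ssi),
               "missing_sp")
})

test_that("written datasets round-trip through plain-text files", {
  cfg <- tiny_config(seed = 3)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  counts <- read.csv(file.path(dir, "counts.csv"))
  expect_equal(nrow(counts), nrow(ds$counts))
  expect_true(all(counts$count >= 0))
  expect_true(all(counts$count == round(counts$count)))
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  traits <- read.csv(file.path(dir, "traits.csv"))
  expect_setequal(traits$species_id, tree$tip.label)
  expect_setequal(unique(counts$species_id), traits$species_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$sensitivity_true, ds$truth$sensitivity_true)
})
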