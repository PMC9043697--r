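test_that("Brownian covariance matches the path-length oracle", {
  # two sisters: stem 2 shared, terminal branches 1
  sisters <- ape::read.tree(text = "((A:1,B:1):2);")
  C <- brownian_covariance(sisters)
  expect_equal(C[c("A", "B"), c("A", "B")],
               matrix(c(3, 2, 2, 3), 2, dimnames = list(c("A", "B"),
                                                        c("A", "B"))))
  # star tree with unit branches: identity
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unname(brownian_covariance(star)), diag(4))
  # larger hand-built case
  t3 <- ape::read.tree(text = "(((A:1,B:1):1.5,C:2.5):1,D:3.5);")
  C3 <- brownian_covariance(t3)
  expect_equal(unname(C3["A", "B"]), 2.5)
  expect_equal(unname(C3["A", "C"]), 1)
  expect_equal(unname(C3["A", "D"]), 0)
  expect_equal(unname(diag(C3)), rep(3.5, 4))  # ultrametric: constant diagonal
  # symmetry and positive definiteness
  expect_equal(C3, t(C3))
  expect_true(all(eigen(C3, symmetric = TRUE)$values > 0))
  expect_error(brownian_covariance(t3, c("A", "Zmissing")), "Zmissing")
})

test_that("Pagel's lambda scales off-diagonals only", {
  C <- brownian_covariance(fixture_tree(5))
  expect_equal(pagel_transform(C, 1), C)
  expect_equal(pagel_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  half <- pagel_transform(C, 0.5)
  expect_equal(half[1, 2], 0.5 * C[1, 2])
  expect_equal(diag(half), diag(C))
  expect_error(pagel_transform(C, 1.2), "lambda")
})

test_that("PGLS with identity covariance reproduces OLS inference", {
  set.seed(191)
  n <- 40
  X <- cbind(1, x1 = rnorm(n), x2 = rnorm(n))
  y <- 2 + 1.5 * X[, 2] - 0.5 * X[, 3] + rnorm(n)
  fit <- fit_pgls(y, X, diag(n))
  ols <- summary(lm(y ~ X[, 2] + X[, 3]))$coefficients
  expect_equal(fit$coefficients$estimate, unname(ols[, 1]), tolerance = 1e-8)
  expect_equal(fit$coefficients$se, unname(ols[, 2]), tolerance = 1e-8)
  expect_equal(fit$coefficients$t, unname(ols[, 3]), tolerance = 1e-8)
  expect_equal(fit$coefficients$p_value, unname(ols[, 4]), tolerance = 1e-8)

  expect_error(fit_pgls(y, cbind(X, X[, 2]), diag(n)), "rank deficient")
})

test_that("PGLS agrees with an independent GLS implementation", {
  set.seed(201)
  tree <- fixture_tree(12, seed = 7)
  d <- data.frame(species_id = tree$tip.label, x = rnorm(12))
  d$y <- 1 + 0.8 * d$x + as.numeric(
    MASS::mvrnorm(1, rep(0, 12), 0.5 * brownian_covariance(tree)))
  fit <- pgls(y ~ x, d, tree)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, tree, form = ~species_id))
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(ref$varBeta))), tolerance = 1e-6)
})

test_that("PGLS slopes cover a Brownian-simulated effect", {
  set.seed(211)
  tree <- simulate_tree(30, seed = 5)
  traits <- simulate_traits(30)
  hits <- vapply(1:60, function(i) {
    y <- simulate_species_effects(traits, tree,
                                  c("(Intercept)" = 0, "tao" = 1.5),
                                  ~ tao, sigma2 = 1)
    d <- data.frame(species_id = traits$species_id, tao = traits$tao,
                    y = as.numeric(y))
    fit <- pgls(y ~ tao, d, tree)
    cf <- fit$coefficients[fit$coefficients$term == "tao", ]
    abs(cf$estimate - 1.5) <= 2 * cf$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("trait models flag the generating trait and a constant response fits flat", {
  set.seed(221)
  tree <- simulate_tree(40, seed = 9)
  traits <- simulate_traits(40)
  tab <- data.frame(species_id = traits$species_id, traits[-1])
  tab$hpi_sqrt <- sqrt(tab$hpi)
  tab$abundance_trend <- -0.03 + 0.02 * tab$hpi_sqrt +
    as.numeric(MASS::mvrnorm(1, rep(0, 40),
                             1e-4 * brownian_covariance(tree)))
  tab$sensitivity <- rep(0.5, 40)
  tab$phenology_trend <- rep(0.1, 40)
  tm <- trait_models(tab, tree, responses = "abundance_trend")
  expect_true("hpi_sqrt" %in% tm$abundance_trend$significant_traits)
  rank <- compare_models(tm$abundance_trend$single)
  expect_equal(rank$model[1], "hpi_sqrt")

  # constant response: every slope is (numerically) zero
  tm0 <- trait_models(tab, tree, responses = "sensitivity")
  slopes <- tm0$sensitivity$summary$estimate
  expect_lt(max(abs(slopes)), 1e-8)
})

test_that("positive-sensitivity species are excluded as outliers, by id", {
  set.seed(231)
  tree <- simulate_tree(12, seed = 11)
  tab <- data.frame(species_id = tree$tip.label,
                    sensitivity = c(runif(9, -5, -1), runif(3, 0.5, 2)),
                    phenology_trend = rnorm(12, 0, 0.2),
                    abundance_trend = rnorm(12, 0, 0.02))
  tab$abs_phenology_trend_sqrt <- sqrt(abs(tab$phenology_trend))
  res <- phenology_abundance_models(tab, tree)
  expect_setequal(res$excluded_species, tree$tip.label[10:12])
  expect_equal(res$sensitivity_vs_abs_trend$n, 9)
  expect_named(res$abundance_models,
               c("sensitivity", "phenology_trend", "abs_phenology_trend_sqrt"))

  flat <- tab; flat$sensitivity <- -2
  expect_error(phenology_abundance_models(flat, tree), "zero variance")

  few <- tab; few$sensitivity <- abs(few$sensitivity)
  expect_error(phenology_abundance_models(few, tree), "fewer than 5")
})

test_that("sensitivity-driven abundance trends are detected by the adjusted models", {
  set.seed(241)
  tree <- simulate_tree(48, seed = 13)
  sens <- runif(48, -6, -0.5)
  # residuals follow the Brownian covariance assumed by the model, so the
  # null predictor (phenology trend) stays calibrated
  C <- brownian_covariance(tree)
  bm <- function(s2) as.numeric(MASS::mvrnorm(1, rep(0, 48),
                                              s2 * C / mean(diag(C))))
  tab <- data.frame(species_id = tree$tip.label,
                    sensitivity = sens,
                    phenology_trend = 0.15 * bm(1),
                    # higher sensitivity (more negative) -> steeper decline
                    abundance_trend = -0.04 - 0.006 * sens + 0.005 * bm(1))
  tab$abs_phenology_trend_sqrt <- sqrt(abs(tab$phenology_trend))
  res <- phenology_abundance_models(tab, tree)
  cf <- res$abundance_models$sensitivity$alone$coefficients
  sens_row <- cf[cf$term == "sensitivity", ]
  expect_lt(sens_row$p_value, 0.05)
  expect_lt(sens_row$estimate, 0)
  cf_ph <- res$abundance_models$phenology_trend$alone$coefficients
  expect_gt(cf_ph$p_value[cf_ph$term == "phenology_trend"], 0.05)
})

test_that("model ranking orders by AICc with deterministic tie-breaks", {
  mk <- function(aicc, k, n = 20) {
    structure(list(AICc = aicc, k = k, n = n, logLik = -aicc / 2,
                   response = "y"), class = "pgls_fit")
  }
  fits <- list(a = mk(104, 3), b = mk(100, 3))
  r <- compare_models(fits)
  expect_equal(r$model, c("b", "a"))
  expect_equal(r$delta_AICc, c(0, 4))

  ties <- list(big = mk(100, 5), small = mk(100, 3))
  expect_equal(compare_models(ties)$model, c("small", "big"))

  mixed <- list(a = mk(100, 3), b = { f <- mk(90, 3); f$response <- "z"; f })
  expect_error(compare_models(mixed), "different responses")
})
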