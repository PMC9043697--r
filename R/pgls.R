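#' Brownian-motion covariance matrix of a phylogeny
#'
#' `C[i, j]` is the shared root-to-ancestor path length of tips i and j;
#' the diagonal holds root-to-tip distances.  Under Brownian trait
#' evolution this is the expected covariance of tip values.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param species Optional tip subset/order; an error names any species
#'   missing from the tree.
#' @return Symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
brownian_covariance <- function(tree, species = NULL) {
  C <- ape::vcv(tree)
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(C))
    if (length(missing)) {
      stop("species missing from tree: ", paste(missing, collapse = ", "))
    }
    C <- C[species, species, drop = FALSE]
  }
  C
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal covariances by `lambda`, leaving the diagonal
#' unchanged; `lambda = 1` is pure Brownian motion, `lambda = 0`
#' phylogenetic independence.
#'
#' @param C Covariance matrix.
#' @param lambda Value in `[0, 1]`.
#' @return Transformed matrix.
#' @export
pagel_transform <- function(C, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

#' Phylogenetic generalized least squares
#'
#' Generalized least squares with residual covariance proportional to
#' `C`: `beta = (X' C^-1 X)^-1 X' C^-1 y`, standard errors from
#' `sigma2 * (X' C^-1 X)^-1` with `sigma2` the GLS residual variance
#' (denominator `n - p`), Wald t tests on `n - p` degrees of freedom,
#' and AICc from the Gaussian maximum likelihood (parameter count
#' `p + 1` for the residual rate).
#'
#' @param y Response vector (named by species or aligned with `C`).
#' @param X Model matrix (full rank), rows aligned with `y` and `C`.
#' @param C Phylogenetic covariance (positive definite).
#' @return A list of class `"pgls_fit"`: `coefficients` (table with
#'   `estimate`, `se`, `t`, `p_value`), `sigma2`, `logLik`, `AICc`,
#'   `AIC`, `n`, `k`, `df_residual`, `fitted`, `residuals`.
#' @export
fit_pgls <- function(y, X, C) {
  X <- as.matrix(X); n <- length(y)
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("model matrix is rank deficient")
  L <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance is not positive definite"))
  # whiten: solve L' z = v  =>  z = (L')^-1 v, cov of whitened residual = I
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  qrX <- qr(Xw)
  beta <- qr.coef(qrX, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), n - p)
  sigma2_ml <- rss / n
  logdetC <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  k <- p + 1
  aic <- -2 * ll + 2 * k
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  coefs <- data.frame(term = colnames(X), estimate = as.numeric(beta),
                      se = se, t = as.numeric(tval),
                      p_value = as.numeric(pval))
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, sigma2 = sigma2, logLik = ll,
                 AICc = aicc, AIC = aic, n = n, k = k, df_residual = n - p,
                 fitted = as.numeric(X %*% beta),
                 residuals = as.numeric(y - X %*% beta)),
            class = "pgls_fit")
}

#' PGLS regression from a species table, formula and tree
#'
#' Convenience front end to [fit_pgls()]: builds the model matrix with
#' treatment contrasts (alphabetical reference level), aligns the
#' Brownian covariance to the table's species, and optionally applies
#' Pagel's lambda.
#'
#' @param formula Model formula over columns of `data`.
#' @param data Species-level table with a `species_id` column.
#' @param tree `phylo` covering all species.
#' @param lambda Pagel's lambda (default 1, pure Brownian).
#' @return A `"pgls_fit"` with the formula and response name attached.
#' @export
pgls <- function(formula, data, tree, lambda = 1) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  C <- brownian_covariance(tree, data$species_id)
  if (lambda != 1) C <- pagel_transform(C, lambda)
  fit <- fit_pgls(y, X, C)
  fit$formula <- formula
  fit$response <- as.character(formula[[2]])
  fit
}

#' Assemble the species-level comparative table
#'
#' Joins species abundance and phenology trends, thermal sensitivities
#' and traits, adding the square-root transforms used in the comparative
#' models: `abs_phenology_trend_sqrt = sqrt(|phenology trend|)` and
#' `hpi_sqrt = sqrt(HPI)`.
#'
#' @param species_trends Species-level trend table (long; columns
#'   `species_id`, `response`, `slope`).
#' @param sensitivities Table from [species_sensitivities()].
#' @param traits Trait table.
#' @return Data frame with one row per species present in all three
#'   inputs.
#' @export
build_comparative_table <- function(species_trends, sensitivities, traits) {
  ab <- species_trends[species_trends$response == "log_abundance",
                       c("species_id", "slope")]
  names(ab)[2] <- "abundance_trend"
  ph <- species_trends[species_trends$response == "peak_day",
                       c("species_id", "slope")]
  names(ph)[2] <- "phenology_trend"
  sen <- sensitivities[, c("species_id", "sensitivity", "sign_class")]
  out <- Reduce(function(a, b) merge(a, b, by = "species_id"),
                list(ab, ph, sen, traits))
  out$abs_phenology_trend_sqrt <- sqrt(abs(out$phenology_trend))
  out$hpi_sqrt <- sqrt(out$hpi)
  out
}

trait_predictors <- c("voltinism", "overwinter_stage", "larval_diet",
                      "ssi", "tao", "hpi_sqrt")

#' Single-trait and combined PGLS models of species-level responses
#'
#' For each response (thermal sensitivity, phenology trend, abundance
#' trend) fits one PGLS per trait, then a combined model of the traits
#' that were significant singly (any coefficient of the trait with
#' `p < alpha`).  HPI enters square-root transformed; categorical traits
#' use treatment contrasts.
#'
#' @param table Comparative table from [build_comparative_table()].
#' @param tree Species phylogeny.
#' @param responses Response columns to model.
#' @param alpha Significance level used to pick traits for the combined
#'   model.
#' @param lambda Pagel's lambda.
#' @return List per response: `single` (named list of `"pgls_fit"`),
#'   `significant_traits`, `combined` (fit or `NULL`), `summary` (data
#'   frame of trait coefficients across single-trait models).
#' @export
trait_models <- function(table, tree,
                         responses = c("sensitivity", "phenology_trend",
                                       "abundance_trend"),
                         alpha = 0.05, lambda = 1) {
  out <- list()
  for (resp in responses) {
    single <- list(); sig <- character(0); rows <- list()
    for (tr in trait_predictors) {
      v <- table[[tr]]
      if (length(unique(v)) < 2L) next  # trait carries no contrast
      f <- stats::as.formula(paste(resp, "~", tr))
      fit <- pgls(f, table, tree, lambda)
      single[[tr]] <- fit
      cf <- fit$coefficients[-1, , drop = FALSE]  # drop intercept
      cf$trait <- tr; cf$response <- resp; cf$AICc <- fit$AICc
      rows[[tr]] <- cf
      if (any(cf$p_value < alpha)) sig <- c(sig, tr)
    }
    combined <- if (length(sig) >= 1L) {
      pgls(stats::as.formula(paste(resp, "~", paste(sig, collapse = " + "))),
           table, tree, lambda)
    } else NULL
    out[[resp]] <- list(single = single, significant_traits = sig,
                        combined = combined,
                        summary = do.call(rbind, rows))
  }
  out
}

#' PGLS models linking abundance trends to phenological variables
#'
#' (1) Does sensitivity drive the magnitude of phenological change?
#' `abs_phenology_trend_sqrt ~ sensitivity`, fitted only on species with
#' negative sensitivity (species that delay with warming are excluded as
#' outliers; their ids are recorded).  (2) Do phenological variables
#' predict abundance trends?  `abundance_trend` on each of sensitivity,
#' phenology trend and absolute phenology trend, first alone and then
#' together with the traits found significant for abundance trends.
#'
#' @param table Comparative table (must include `sign_class` or a
#'   `sensitivity` column; exclusion uses `sensitivity > 0`).
#' @param tree Species phylogeny.
#' @param significant_traits Traits to adjust for in step (2) (typically
#'   from [trait_models()] on `abundance_trend`).
#' @param lambda Pagel's lambda.
#' @return List: `sensitivity_vs_abs_trend` (fit), `excluded_species`,
#'   `abundance_models` (per predictor: `alone` and `adjusted` fits).
#' @export
phenology_abundance_models <- function(table, tree,
                                       significant_traits = character(0),
                                       lambda = 1) {
  excl <- table$species_id[table$sensitivity > 0]
  neg <- table[table$sensitivity <= 0, ]
  if (nrow(neg) < 5L) stop("fewer than 5 species left after excluding ",
                           "positive-sensitivity outliers")
  if (stats::var(neg$sensitivity) == 0) {
    stop("sensitivity has zero variance; its effect is undefined")
  }
  sub_tree <- ape::keep.tip(tree, neg$species_id)
  m1 <- pgls(abs_phenology_trend_sqrt ~ sensitivity, neg, sub_tree, lambda)
  preds <- c("sensitivity", "phenology_trend", "abs_phenology_trend_sqrt")
  ab <- list()
  for (p in preds) {
    alone <- pgls(stats::as.formula(paste("abundance_trend ~", p)),
                  table, tree, lambda)
    adjusted <- if (length(significant_traits)) {
      pgls(stats::as.formula(
        paste("abundance_trend ~", p, "+",
              paste(significant_traits, collapse = " + "))),
        table, tree, lambda)
    } else NULL
    ab[[p]] <- list(alone = alone, adjusted = adjusted)
  }
  list(sensitivity_vs_abs_trend = m1, excluded_species = excl,
       abundance_models = ab)
}

#' Rank PGLS fits by AICc
#'
#' @param fits Named list of `"pgls_fit"` objects sharing the same
#'   response and observations.
#' @return Data frame sorted by AICc (`model`, `AICc`, `delta_AICc`,
#'   `k`, `logLik`); AICc ties are broken by fewer parameters.
#' @export
compare_models <- function(fits) {
  resp <- unique(vapply(fits, function(f)
    if (is.null(f$response)) NA_character_ else f$response, character(1)))
  resp <- resp[!is.na(resp)]
  if (length(resp) > 1L) stop("fits model different responses: ",
                              paste(resp, collapse = ", "))
  ns <- unique(vapply(fits, function(f) f$n, numeric(1)))
  if (length(ns) > 1L) stop("fits use different numbers of observations")
  d <- data.frame(model = names(fits),
                  AICc = vapply(fits, function(f) f$AICc, numeric(1)),
                  k = vapply(fits, function(f) f$k, numeric(1)),
                  logLik = vapply(fits, function(f) f$logLik, numeric(1)))
  d <- d[order(d$AICc, d$k), ]
  d$delta_AICc <- d$AICc - d$AICc[1]
  rownames(d) <- NULL
  d[, c("model", "AICc", "delta_AICc", "k", "logLik")]
}
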