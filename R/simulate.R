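#' Scenario configuration for the simulation experiment
#'
#' One cell of the simulation design: a rate of exposure missingness, a common
#' instrument strength applied to all J instruments, and a true causal-effect
#' size. Experiment-wide constants default to the study design used for
#' calibration: a pool of 1000 individuals from which 400 are analysed, J = 15
#' instruments, and confounder loadings delta_x = delta_y = 1.
#'
#' @param missing_rate Fraction of analysed individuals whose exposure is
#'   masked, in \[0, 1).
#' @param alpha_strength Instrument-exposure coefficient shared by all
#'   instruments.
#' @param beta_true True causal effect used in generation.
#' @param n_pool Size of the simulated pool H.
#' @param n_analysis Number of individuals sampled from the pool for analysis.
#' @param J Number of instruments.
#' @param delta_x,delta_y Confounder loadings used in generation.
#' @param replicates Datasets per scenario in the full experiment.
#' @param maf_range Range of the per-instrument minor-allele frequency, drawn
#'   once per dataset from a uniform distribution over this interval.
#' @param sigma_x Exposure residual SD used in generation; `NULL` (default)
#'   draws it per dataset from its Inv-Gamma(3, 2) prior, a fixed value
#'   overrides (useful for variance-decomposition checks).
#' @param intercept Outcome-model intercept used in generation.
#' @return A list of class `mr_scenario`.
#' @examples
#' mr_scenario(missing_rate = 0.8, alpha_strength = 0.3, beta_true = 0.3)
#' @export
mr_scenario <- function(missing_rate = 0, alpha_strength = 0.3, beta_true = 0.3,
                        n_pool = 1000, n_analysis = 400, J = 15,
                        delta_x = 1, delta_y = 1, replicates = 200,
                        maf_range = c(0.1, 0.5), sigma_x = NULL,
                        intercept = 0) {
  stopifnot(missing_rate >= 0, missing_rate < 1, n_analysis <= n_pool,
            J >= 1, replicates >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] < 1)
  if (!is.null(sigma_x)) stopifnot(sigma_x > 0)
  structure(
    list(missing_rate = missing_rate, alpha_strength = alpha_strength,
         beta_true = beta_true, n_pool = n_pool, n_analysis = n_analysis,
         J = J, delta_x = delta_x, delta_y = delta_y, replicates = replicates,
         maf_range = maf_range, sigma_x = sigma_x, intercept = intercept),
    class = "mr_scenario")
}

#' Full factorial scenario grid
#'
#' Enumerates the factorial design of the calibration experiment: three rates
#' of exposure missingness (80%, 40%, 0%) by three instrument strengths
#' (0.3, 0.1, 0.05) by two causal-effect sizes (0.3, 0), i.e. 3 x 3 x 2 = 18
#' scenarios; at 200 replicates each that is 3600 datasets.
#'
#' @param missing_rates,alpha_strengths,beta_trues Factor levels of the grid.
#' @param ... Experiment-wide constants passed to [mr_scenario()].
#' @return A tibble of class `mr_scenario_grid` with one row per scenario:
#'   columns `scenario` (id), the three factors, and a list-column `config`
#'   of [mr_scenario()] objects.
#' @examples
#' build_grid()           # the 18-scenario design
#' build_grid(beta_trues = 0.3, alpha_strengths = 0.3, missing_rates = 0)
#' @export
build_grid <- function(missing_rates = c(0.8, 0.4, 0),
                       alpha_strengths = c(0.3, 0.1, 0.05),
                       beta_trues = c(0.3, 0), ...) {
  grid <- tidyr::expand_grid(
    missing_rate = missing_rates,
    alpha_strength = alpha_strengths,
    beta_true = beta_trues)
  grid <- dplyr::mutate(grid, scenario = dplyr::row_number(), .before = 1)
  grid$config <- purrr::pmap(
    grid[c("missing_rate", "alpha_strength", "beta_true")],
    function(missing_rate, alpha_strength, beta_true) {
      mr_scenario(missing_rate = missing_rate, alpha_strength = alpha_strength,
                  beta_true = beta_true, ...)
    })
  class(grid) <- c("mr_scenario_grid", class(grid))
  grid
}

#' Total dataset count of a grid
#' @param grid An `mr_scenario_grid`.
#' @return Number of scenario-replicate datasets the grid enumerates.
#' @export
n_datasets <- function(grid) {
  sum(purrr::map_int(grid$config, ~ .x$replicates))
}

#' Simulate a fully observed pool of individuals
#'
#' Draws a pool H of independent individuals from the generative model:
#' genotypes as Binomial(2, MAF) minor-allele counts in Hardy-Weinberg
#' proportions (MAF per instrument uniform over `maf_range`), standardized;
#' latent confounders U ~ N(0, 0.1); exposure X from the linear instrument
#' stage with residual SD sigma_x; binary outcome Y from the logistic stage
#' with effect `beta_true`. All instruments share the configured strength.
#'
#' @param config An [mr_scenario()].
#' @param seed Integer seed; the draw is deterministic given it.
#' @param n Pool size override (defaults to `config$n_pool`).
#' @return A standardized `mr_data` with a `truth` attribute recording the
#'   generating parameter values (including the sigma_x actually used).
#' @export
simulate_pool <- function(config, seed, n = config$n_pool) {
  stopifnot(inherits(config, "mr_scenario"))
  set.seed(seed)
  J <- config$J
  maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  z_raw <- vapply(maf, function(p) stats::rbinom(n, 2L, p), numeric(n))
  sdz <- apply(z_raw, 2L, stats::sd)
  if (any(sdz == 0)) { # monomorphic draw (tiny n only): redraw that column
    for (j in which(sdz == 0)) {
      repeat {
        z_raw[, j] <- stats::rbinom(n, 2L, maf[j])
        if (stats::sd(z_raw[, j]) > 0) break
      }
    }
  }
  z <- scale(z_raw)[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL

  sigma_x <- config$sigma_x %||% (1 / stats::rgamma(1L, shape = 3, rate = 2))
  u <- stats::rnorm(n, 0, sqrt(0.1))
  alpha <- rep(config$alpha_strength, J)
  x <- drop(z %*% alpha) + config$delta_x * u +
    stats::rnorm(n, 0, sigma_x)
  eta <- config$intercept + config$beta_true * x + config$delta_y * u
  y <- stats::rbinom(n, 1L, stats::plogis(eta))

  new_mr_data(
    genotypes = z, exposure = x, outcome = as.integer(y), standardized = TRUE,
    scaling = list(genotype_center = colMeans(z_raw),
                   genotype_scale = apply(z_raw, 2L, stats::sd),
                   exposure_center = 0, exposure_scale = 1),
    truth = list(beta = config$beta_true, alpha = alpha, sigma_x = sigma_x,
                 delta_x = config$delta_x, delta_y = config$delta_y,
                 intercept = config$intercept, maf = maf, u = u, seed = seed))
}

#' Sample the analysis set and mask exposures
#'
#' From a fully observed pool, samples `n_analysis` individuals without
#' replacement and splits them into dataset A (complete records, size
#' n_A = round(n_analysis * (1 - missing_rate)), rounding half away from
#' zero) and dataset B (size n_B = n_analysis - n_A) whose exposures are set
#' to missing. The combined dataset D1 = A u B is returned with A rows first;
#' no individual appears twice. The masked values are retained in the hidden
#' `oracle_exposure` field for imputation checks.
#'
#' @param pool An `mr_data` pool from [simulate_pool()].
#' @param config The [mr_scenario()] supplying `missing_rate`, `n_analysis`.
#' @param seed Integer seed for the two sampling steps.
#' @return An `mr_data` with `n_complete() == n_A`, `n_missing() == n_B`.
#' @export
split_and_mask <- function(pool, config, seed) {
  validate_mr_data(pool)
  stopifnot(inherits(config, "mr_scenario"))
  n <- n_total(pool)
  if (config$n_analysis > n) stop("n_analysis exceeds pool size")
  set.seed(seed)
  n_a <- round_half_away(config$n_analysis * (1 - config$missing_rate))
  n_b <- config$n_analysis - n_a
  idx_a <- sample.int(n, n_a)
  idx_b <- if (n_b > 0) sample(setdiff(seq_len(n), idx_a), n_b) else integer(0)
  idx <- c(idx_a, idx_b)
  exposure <- pool$exposure[idx]
  oracle <- exposure
  if (n_b > 0) exposure[(n_a + 1L):(n_a + n_b)] <- NA_real_
  new_mr_data(
    genotypes = pool$genotypes[idx, , drop = FALSE],
    exposure = exposure, outcome = pool$outcome[idx],
    standardized = pool$standardized, scaling = pool$scaling,
    oracle_exposure = oracle,
    truth = c(pool$truth[setdiff(names(pool$truth), "u")],
              list(u = pool$truth$u[idx], n_a = n_a, n_b = n_b,
                   pool_index = idx, split_seed = seed)))
}

# round half away from zero (round() rounds half to even)
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Simulate one analysis-ready dataset for a scenario
#'
#' Convenience wrapper: [simulate_pool()] then [split_and_mask()], using two
#' seeds derived from `seed`.
#'
#' @inheritParams simulate_pool
#' @return An `mr_data` ready for [mr_fit()].
#' @export
simulate_dataset <- function(config, seed) {
  seeds <- derive_seeds(seed, 2L)
  pool <- simulate_pool(config, seeds[1L])
  split_and_mask(pool, config, seeds[2L])
}

# deterministic substream seeds below 2^31 derived from one root seed
derive_seeds <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # multiplier kept small so a*s stays exactly representable in doubles
  a <- 69069; c <- 12345; m <- 2^31
  out <- numeric(k)
  s <- (abs(seed) %% m)
  for (i in seq_len(k)) {
    s <- (a * s + c) %% m
    out[i] <- s
  }
  as.integer(out %% (2^31 - 1)) + 1L
}
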