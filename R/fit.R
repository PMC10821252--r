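#' Fit the Bayesian MR model by MCMC under the used prior
#'
#' Draws from the posterior defined by [log_joint()]: the mixture prior for
#' the causal effect is *not* sampled directly; instead the chain targets the
#' posterior under the continuous normal "used" prior, and draws under the
#' intended mixture prior are recovered afterwards with
#' [mixture_resample()] / [posterior_odds()]. Missing exposures and the latent
#' confounder scores are sampled jointly with the parameters, so imputation
#' and causal-effect estimation happen simultaneously.
#'
#' The sampler is a blocked scheme: conjugate Gibbs updates for the
#' instrument-strength vector alpha and the exposure-side confounder loading
#' delta_x; adaptive random-walk Metropolis on log sigma_x and on the
#' three-parameter logistic block (intercept, beta, delta_y), with proposal
#' scale/covariance adapted during warmup only; and vectorized
#' independence-Metropolis updates for the latent confounder scores and the
#' missing exposures, proposing from their Gaussian full-conditional factor
#' and accepting on the Bernoulli outcome-likelihood ratio.
#'
#' @param dataset An `mr_data` object, standardized (or simulated on the
#'   model's standardized scale).
#' @param prior An [mr_prior()] configuration.
#' @param iterations Total iterations per chain (including warmup).
#' @param warmup Iterations discarded as warmup (adaptation happens here).
#' @param chains Number of chains (>= 2 recommended for diagnostics).
#' @param seed Integer seed; chains use substreams derived from it.
#' @param store_latent If `TRUE`, retained draws of the latent confounder
#'   scores and imputed exposures are stored (memory scales with n x draws).
#' @return An object of class `mr_fit` with elements `draws` (a tibble with
#'   `.chain`, `.iteration` and one column per parameter, including the
#'   identified product `delta_prod = delta_x * delta_y`), `latent` (if
#'   requested), `accept` (acceptance rates), and chain metadata. Methods:
#'   [tidy()], [glance()], [compute_rhat()], [autoplot.mr_fit()].
#' @examples
#' \donttest{
#' d <- simulate_dataset(mr_scenario(n_pool = 300, n_analysis = 120), seed = 1)
#' fit <- mr_fit(d, mr_prior(), iterations = 400, chains = 2, seed = 1)
#' generics::tidy(fit)
#' }
#' @export
mr_fit <- function(dataset, prior = mr_prior(), iterations = 2000,
                   warmup = floor(iterations / 2), chains = 4, seed = 1L,
                   store_latent = FALSE) {
  validate_mr_data(dataset)
  stopifnot(inherits(prior, "mr_prior"), iterations > warmup, warmup >= 0,
            chains >= 1)
  seeds <- derive_seeds(seed, chains)
  runs <- lapply(seq_len(chains), function(ch) {
    run_chain(dataset, prior, iterations, warmup, seeds[ch], store_latent)
  })
  draws <- dplyr::bind_rows(lapply(seq_len(chains), function(ch) {
    d <- tibble::as_tibble(runs[[ch]]$draws)
    dplyr::mutate(d, .chain = ch, .iteration = dplyr::row_number(),
                  .before = 1)
  }))
  accept <- colMeans(do.call(rbind, lapply(runs, `[[`, "accept")))
  latent <- if (store_latent) lapply(runs, `[[`, "latent") else NULL
  structure(
    list(draws = draws, latent = latent, accept = accept,
         prior = prior, chains = chains, iterations = iterations,
         warmup = warmup, seed = seed,
         n = n_total(dataset), n_missing = n_missing(dataset),
         n_instruments = n_instruments(dataset)),
    class = "mr_fit")
}

# One chain of the blocked sampler. Returns kept draws as a matrix plus
# acceptance rates and (optionally) latent-variable draws.
run_chain <- function(dataset, prior, iterations, warmup, seed, store_latent) {
  set.seed(seed)
  z <- dataset$genotypes
  y <- dataset$outcome
  n <- length(y)
  J <- ncol(z)
  miss <- is.na(dataset$exposure)
  n_b <- sum(miss)
  ztz <- crossprod(z)
  prec_alpha0 <- diag(1 / prior$alpha_prior_sd^2, J)
  b_alpha0 <- rep(prior$alpha_prior_mean / prior$alpha_prior_sd^2, J)
  v_u <- prior$u_variance
  sd_d <- prior$delta_prior_sd
  sd_w <- prior$intercept_prior_sd

  # initial state, jittered per chain for overdispersed starts
  alpha <- rep(prior$alpha_prior_mean, J) + stats::rnorm(J, 0, 0.05)
  beta <- stats::rnorm(1, 0, 0.5)
  delta_x <- stats::rnorm(1, 0.5, 0.2)
  delta_y <- stats::rnorm(1, 0.5, 0.2)
  sigma_x <- exp(stats::rnorm(1, 0, 0.3))
  intercept <- stats::rnorm(1, 0, 0.3)
  u <- stats::rnorm(n, 0, sqrt(v_u))
  x <- dataset$exposure
  zalpha <- drop(z %*% alpha)
  if (n_b > 0) x[miss] <- zalpha[miss] + stats::rnorm(n_b, 0, sigma_x)

  # Bernoulli log-likelihood of the logistic stage
  ll_bern <- function(eta) sum(y * eta - log1pexp(eta))
  ll_bern_vec <- function(eta) y * eta - log1pexp(eta)

  # adaptation state
  log_step_sigma <- log(0.3)
  log_lambda <- 0
  theta_mean <- c(intercept, beta, delta_y)
  theta_cov <- diag(c(0.04, 0.04, 0.04))
  chol_prop <- chol(theta_cov)

  kept <- iterations - warmup
  cn <- c("beta", "intercept", "delta_x", "delta_y", "delta_prod", "sigma_x",
          paste0("alpha", seq_len(J)))
  draws <- matrix(NA_real_, kept, length(cn), dimnames = list(NULL, cn))
  lat_u <- if (store_latent) matrix(NA_real_, kept, n) else NULL
  lat_x <- if (store_latent && n_b > 0) matrix(NA_real_, kept, n_b) else NULL
  acc <- c(sigma_x = 0, logistic = 0, u = 0, x_impute = 0)
  n_acc_u <- 0; n_acc_x <- 0

  for (it in seq_len(iterations)) {
    in_warmup <- it <= warmup
    gam <- min(0.25, 2 / sqrt(it))

    ## -- alpha | rest: conjugate Gaussian (linear exposure stage)
    resid_target <- x - delta_x * u
    prec <- ztz / sigma_x^2 + prec_alpha0
    bvec <- drop(crossprod(z, resid_target)) / sigma_x^2 + b_alpha0
    R <- chol(prec)
    mu_a <- backsolve(R, forwardsolve(t(R), bvec))
    alpha <- drop(mu_a + backsolve(R, stats::rnorm(J)))
    zalpha <- drop(z %*% alpha)

    ## -- delta_x | rest: conjugate Gaussian scalar
    r <- x - zalpha
    prec_d <- sum(u^2) / sigma_x^2 + 1 / sd_d^2
    mu_d <- (sum(u * r) / sigma_x^2) / prec_d
    delta_x <- stats::rnorm(1, mu_d, sqrt(1 / prec_d))

    ## -- sigma_x: random-walk Metropolis on the log scale
    ssr <- sum((r - delta_x * u)^2)
    log_post_sigma <- function(ls) {
      s <- exp(ls)
      -n * ls - ssr / (2 * s^2) +
        dinvgamma_log(s, prior$sigma_x_prior_shape, prior$sigma_x_prior_scale) +
        ls  # Jacobian of the log transform
    }
    ls_cur <- log(sigma_x)
    ls_prop <- ls_cur + stats::rnorm(1, 0, exp(log_step_sigma))
    a_sig <- min(1, exp(log_post_sigma(ls_prop) - log_post_sigma(ls_cur)))
    if (stats::runif(1) < a_sig) sigma_x <- exp(ls_prop)
    if (in_warmup) log_step_sigma <- log_step_sigma + gam * (a_sig - 0.44)
    if (!in_warmup) acc["sigma_x"] <- acc["sigma_x"] + a_sig

    ## -- (intercept, beta, delta_y): joint adaptive random-walk Metropolis
    theta <- c(intercept, beta, delta_y)
    log_post_theta <- function(th) {
      eta <- th[1] + th[2] * x + th[3] * u
      ll_bern(eta) +
        stats::dnorm(th[1], 0, sd_w, log = TRUE) +
        stats::dnorm(th[2], prior$used_prior_mean, prior$used_prior_sd,
                     log = TRUE) +
        stats::dnorm(th[3], 0, sd_d, log = TRUE)
    }
    lp_cur <- log_post_theta(theta)
    for (sub in seq_len(5L)) {  # cheap block: several MH sub-steps per sweep
      prop <- theta + exp(log_lambda) * drop(stats::rnorm(3) %*% chol_prop)
      lp_prop <- log_post_theta(prop)
      a_th <- min(1, exp(lp_prop - lp_cur))
      if (stats::runif(1) < a_th) {
        theta <- prop
        lp_cur <- lp_prop
      }
      if (in_warmup) log_lambda <- log_lambda + gam * (a_th - 0.234)
    }
    intercept <- theta[1]; beta <- theta[2]; delta_y <- theta[3]
    if (in_warmup) {
      dtheta <- theta - theta_mean
      theta_mean <- theta_mean + gam * dtheta
      theta_cov <- theta_cov + gam * (tcrossprod(dtheta) - theta_cov)
      if (it %% 25 == 0) {
        chol_prop <- chol(2.38^2 / 3 * (theta_cov + diag(1e-6, 3)))
      }
    }
    if (!in_warmup) acc["logistic"] <- acc["logistic"] + a_th

    ## -- latent confounders u_i: vectorized independence Metropolis.
    ## Proposal = prior x Gaussian exposure-stage factor; accept on the
    ## Bernoulli factor only.
    if (n > 0) {
      prec_u <- 1 / v_u + delta_x^2 / sigma_x^2
      mu_u <- (delta_x * (x - zalpha) / sigma_x^2) / prec_u
      u_prop <- stats::rnorm(n, mu_u, sqrt(1 / prec_u))
      eta_cur <- intercept + beta * x + delta_y * u
      eta_prop <- intercept + beta * x + delta_y * u_prop
      lr <- ll_bern_vec(eta_prop) - ll_bern_vec(eta_cur)
      take <- stats::runif(n) < exp(lr)
      u[take] <- u_prop[take]
      if (!in_warmup) { acc["u"] <- acc["u"] + mean(take); n_acc_u <- n_acc_u + 1 }
    }

    ## -- missing exposures: vectorized independence Metropolis.
    ## Proposal = exposure-stage Gaussian; accept on the Bernoulli factor.
    if (n_b > 0) {
      mu_b <- zalpha[miss] + delta_x * u[miss]
      x_prop <- stats::rnorm(n_b, mu_b, sigma_x)
      eta_cur <- intercept + beta * x[miss] + delta_y * u[miss]
      eta_prop <- intercept + beta * x_prop + delta_y * u[miss]
      lr <- y[miss] * (eta_prop - eta_cur) -
        log1pexp(eta_prop) + log1pexp(eta_cur)
      take <- stats::runif(n_b) < exp(lr)
      x[miss][take] <- x_prop[take]
      if (!in_warmup) { acc["x_impute"] <- acc["x_impute"] + mean(take); n_acc_x <- n_acc_x + 1 }
    }

    if (!in_warmup) {
      k <- it - warmup
      draws[k, ] <- c(beta, intercept, delta_x, delta_y, delta_x * delta_y,
                      sigma_x, alpha)
      if (store_latent) {
        lat_u[k, ] <- u
        if (n_b > 0) lat_x[k, ] <- x[miss]
      }
    }
  }

  kept_n <- max(1, kept)
  acc[c("sigma_x", "logistic")] <- acc[c("sigma_x", "logistic")] / kept_n
  if (n_acc_u > 0) acc["u"] <- acc["u"] / n_acc_u
  if (n_acc_x > 0) acc["x_impute"] <- acc["x_impute"] / n_acc_x
  list(draws = draws, accept = acc,
       latent = if (store_latent) list(u = lat_u, x_impute = lat_x))
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf(
    "<mr_fit> %d chains x %d iterations (%d warmup); n = %d (%d missing exposures), J = %d\n",
    x$chains, x$iterations, x$warmup, x$n, x$n_missing, x$n_instruments))
  s <- generics::tidy(x)
  print(as.data.frame(s[s$term %in% c("beta", "delta_prod", "sigma_x"), ]),
        row.names = FALSE)
  invisible(x)
}

#' Extract a draws matrix (iterations x chains) for one parameter
#' @param fit An `mr_fit`.
#' @param parameter Column name in `fit$draws`, default `"beta"`.
#' @return A numeric matrix with one column per chain.
#' @export
draws_matrix <- function(fit, parameter = "beta") {
  stopifnot(inherits(fit, "mr_fit"), parameter %in% names(fit$draws))
  m <- matrix(fit$draws[[parameter]],
              ncol = fit$chains)
  colnames(m) <- paste0("chain", seq_len(fit$chains))
  m
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Posterior summaries of an MR fit
#'
#' One row per model parameter (the delta loadings are reported individually
#' and through their identified product `delta_prod`), with posterior mean,
#' SD, and central 95% credible interval.
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  long <- tidyr::pivot_longer(x$draws, cols = -c(".chain", ".iteration"),
                              names_to = "term", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$term),
    estimate = mean(.data$value),
    std.error = stats::sd(.data$value),
    conf.low = stats::quantile(.data$value, 0.025, names = FALSE),
    conf.high = stats::quantile(.data$value, 0.975, names = FALSE),
    .groups = "drop")
  ord <- c("beta", "intercept", "delta_x", "delta_y", "delta_prod", "sigma_x")
  dplyr::arrange(out, match(.data$term, ord, nomatch = length(ord) + 1L),
                 .data$term)
}

#' One-line summary of an MR fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, chain settings, the split-R-hat
#'   and effective sample size of the causal effect, and the logistic-block
#'   acceptance rate.
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  dg <- tryCatch(compute_rhat(x), error = function(e) {
    list(rhat_beta = NA_real_, effective_sample_size = NA_real_)
  })
  tibble::tibble(
    n = x$n, n_missing = x$n_missing, n_instruments = x$n_instruments,
    chains = x$chains, iterations = x$iterations, warmup = x$warmup,
    rhat_beta = dg$rhat_beta, ess_beta = dg$effective_sample_size,
    accept_logistic = unname(x$accept["logistic"]))
}

#' Split-R-hat and effective sample size
#'
#' Computes the standard split-chain potential scale reduction factor: each
#' chain is split in half, and R-hat compares the between- and within-chain
#' variances of the resulting half-chains. Values near 1 indicate mixing.
#' The effective sample size uses the initial-positive-sequence estimate of
#' the autocorrelation time on the split chains.
#'
#' @param x An `mr_fit` (the causal-effect draws are used) or a numeric
#'   matrix with one column per chain.
#' @param parameter Parameter name when `x` is an `mr_fit`.
#' @return A list of class `mr_diagnostics` with `rhat_beta` and
#'   `effective_sample_size`. When all chains are constant the statistic is
#'   undefined; `rhat_beta` is `NA` with a warning.
#' @export
compute_rhat <- function(x, parameter = "beta") {
  m <- if (inherits(x, "mr_fit")) draws_matrix(x, parameter) else as.matrix(x)
  if (ncol(m) < 2L) {
    stop("split-R-hat needs draws from >= 2 chains; run more chains ",
         "(each chain is additionally split in half)")
  }
  n <- nrow(m)
  if (n < 4L) stop("chains too short to split")
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(half), j], m[(n - half + 1L):n, j])
  }))
  w <- mean(apply(splits, 2L, stats::var))
  b <- half * stats::var(colMeans(splits))
  if (!is.finite(w) || w == 0) {
    warning("zero within-chain variance: R-hat undefined (constant chains)")
    rhat <- NA_real_
    ess <- NA_real_
  } else {
    varplus <- (half - 1) / half * w + b / half
    rhat <- sqrt(varplus / w)
    ess <- ess_ips(splits, varplus)
  }
  structure(list(rhat_beta = rhat, effective_sample_size = ess),
            class = "mr_diagnostics")
}

#' @export
print.mr_diagnostics <- function(x, ...) {
  cat(sprintf("<mr_diagnostics> split R-hat = %.4f, ESS = %.0f\n",
              x$rhat_beta, x$effective_sample_size))
  invisible(x)
}

# initial-positive-sequence ESS over split chains (rho[t+1] = lag-t correlation)
ess_ips <- function(splits, varplus) {
  n <- nrow(splits); m <- ncol(splits)
  max_lag <- min(n - 2L, 200L)
  acov <- vapply(seq_len(m), function(j) {
    v <- splits[, j] - mean(splits[, j])
    vapply(0:max_lag, function(k) sum(v[seq_len(n - k)] * v[(k + 1):n]) / n,
           numeric(1))
  }, numeric(max_lag + 1L))
  w <- mean(acov[1, ]) * n / (n - 1)
  s <- rowMeans(as.matrix(acov))
  rho <- 1 - (w - s) / varplus
  tau <- -1
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / max(tau, 1), 1)
}
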