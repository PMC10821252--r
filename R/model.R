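#' Prior configuration for the Bayesian MR model
#'
#' Collects every hyperparameter of the model's prior layer together with the
#' two quantities that define the interval-null test: the ROPE half-width `T`
#' (the causal effect is "practically null" when |beta| <= T) and the prior
#' null mass `pi0`.
#'
#' The causal effect beta carries a *mixture* ("true") prior: with probability
#' `pi0` it is uniform on \[-T, T\] (the null component) and with probability
#' `1 - pi0` it is normal with mean `used_prior_mean` and SD `used_prior_sd`.
#' MCMC is run under the continuous normal ("used") prior alone; the mixture
#' is recovered afterwards by importance resampling (see [importance_weight()]).
#'
#' Defaults follow the model's stated prior layer: instrument-strength
#' coefficients alpha_j ~ N(0.5, 0.2^2) independently, sigma_x ~
#' Inv-Gamma(shape 3, scale 2) on the exposure residual SD, latent confounder
#' scores U_i ~ N(0, variance 0.1), and a locally uninformative N(0, 10^2)
#' used prior for beta. The intercept and the two confounder loadings
#' delta_x, delta_y, for which no prior is stated, get weakly informative
#' N(0, 1) priors (configurable); the loadings are identified only through
#' their product.
#'
#' @param pi0 Prior probability of the null hypothesis, in \[0, 1\].
#' @param rope_T Positive ROPE half-width T.
#' @param used_prior_mean,used_prior_sd Mean and SD of the continuous normal
#'   prior for beta (the alternative component of the mixture, and the prior
#'   actually sampled under).
#' @param alpha_prior_mean,alpha_prior_sd Normal prior for each alpha_j.
#' @param sigma_x_prior_shape,sigma_x_prior_scale Inverse-gamma prior
#'   (shape/scale) on the exposure residual SD sigma_x.
#' @param u_variance Prior variance of each latent confounder score.
#' @param delta_prior_sd SD of the zero-mean normal priors on delta_x, delta_y.
#' @param intercept_prior_sd SD of the zero-mean normal prior on the outcome
#'   intercept.
#' @return A list of class `mr_prior`.
#' @examples
#' mr_prior(pi0 = 0.5, rope_T = 0.1)
#' @export
mr_prior <- function(pi0 = 0.5, rope_T = 0.1,
                     used_prior_mean = 0, used_prior_sd = 10,
                     alpha_prior_mean = 0.5, alpha_prior_sd = 0.2,
                     sigma_x_prior_shape = 3, sigma_x_prior_scale = 2,
                     u_variance = 0.1,
                     delta_prior_sd = 1, intercept_prior_sd = 1) {
  stopifnot(pi0 >= 0, pi0 <= 1, rope_T > 0, used_prior_sd > 0,
            alpha_prior_sd > 0, sigma_x_prior_shape > 0,
            sigma_x_prior_scale > 0, u_variance > 0, delta_prior_sd > 0,
            intercept_prior_sd > 0)
  structure(
    list(pi0 = pi0, rope_T = rope_T,
         used_prior_mean = used_prior_mean, used_prior_sd = used_prior_sd,
         alpha_prior_mean = alpha_prior_mean, alpha_prior_sd = alpha_prior_sd,
         sigma_x_prior_shape = sigma_x_prior_shape,
         sigma_x_prior_scale = sigma_x_prior_scale,
         u_variance = u_variance, delta_prior_sd = delta_prior_sd,
         intercept_prior_sd = intercept_prior_sd),
    class = "mr_prior")
}

#' @export
print.mr_prior <- function(x, ...) {
  cat(sprintf(
    "<mr_prior> ROPE [-%g, %g], pi0 = %g; used prior for beta N(%g, %g^2)\n",
    x$rope_T, x$rope_T, x$pi0, x$used_prior_mean, x$used_prior_sd))
  invisible(x)
}

#' Model parameter bundle
#'
#' All unknowns of the generative model: instrument strengths `alpha` (length
#' J), causal effect `beta`, confounder loadings `delta_x` and `delta_y`,
#' exposure residual SD `sigma_x`, outcome intercept, latent confounder
#' scores `u` (length n), and imputed values `x_impute` for individuals whose
#' exposure is missing (in row order of the missing entries).
#'
#' @param alpha Numeric vector of instrument-exposure strengths.
#' @param beta Causal-effect scalar.
#' @param delta_x,delta_y Confounder loadings on exposure and outcome.
#' @param sigma_x Positive exposure residual SD.
#' @param intercept Outcome-model intercept (log-odds at X = 0, U = 0).
#' @param u Latent confounder scores, one per individual.
#' @param x_impute Imputed exposures for the missing entries (may be empty).
#' @return A list of class `mr_params`.
#' @export
mr_params <- function(alpha, beta, delta_x, delta_y, sigma_x, intercept, u,
                      x_impute = numeric(0)) {
  if (!is.numeric(sigma_x) || length(sigma_x) != 1L || sigma_x <= 0) {
    stop("sigma_x must be a positive scalar")
  }
  structure(list(alpha = as.numeric(alpha), beta = beta, delta_x = delta_x,
                 delta_y = delta_y, sigma_x = sigma_x, intercept = intercept,
                 u = as.numeric(u), x_impute = as.numeric(x_impute)),
            class = "mr_params")
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x < 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

# log density of Inv-Gamma(shape, scale) at s > 0
dinvgamma_log <- function(s, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(s) - scale / s
}

# exposure vector with imputations substituted for the missing entries
fill_exposure <- function(dataset, x_impute) {
  x <- dataset$exposure
  miss <- is.na(x)
  if (sum(miss) != length(x_impute)) {
    stop("x_impute must have one value per missing exposure entry (",
         sum(miss), " needed, ", length(x_impute), " given)")
  }
  x[miss] <- x_impute
  x
}

#' Log joint density of the MR model
#'
#' Evaluates the log of the unnormalized posterior density under the *used*
#' (continuous normal) prior for beta: the sum of the exposure-stage Gaussian
#' log-likelihood, the outcome-stage Bernoulli-logit log-likelihood, and the
#' log prior densities of every unknown (including the latent confounder
#' scores and any imputed exposures, which enter both model stages).
#'
#' @param dataset An `mr_data` object (standardized).
#' @param params An [mr_params()] bundle; `x_impute` must supply one value per
#'   missing exposure entry.
#' @param prior An [mr_prior()] configuration.
#' @return A finite numeric scalar (for finite parameters with
#'   `sigma_x > 0`).
#' @export
log_joint <- function(dataset, params, prior) {
  validate_mr_data(dataset)
  stopifnot(inherits(params, "mr_params"), inherits(prior, "mr_prior"))
  n <- n_total(dataset)
  J <- n_instruments(dataset)
  if (length(params$alpha) != J) stop("alpha must have length J = ", J)
  if (length(params$u) != n) stop("u must have length n = ", n)
  if (params$sigma_x <= 0) stop("sigma_x must be positive")

  x <- fill_exposure(dataset, params$x_impute)
  y <- dataset$outcome

  # exposure stage: X | Z, U ~ N(Z alpha + delta_x U, sigma_x^2)
  mu_x <- drop(dataset$genotypes %*% params$alpha) + params$delta_x * params$u
  ll_x <- sum(stats::dnorm(x, mu_x, params$sigma_x, log = TRUE))

  # outcome stage: Y | X, U ~ Bernoulli(expit(intercept + beta X + delta_y U))
  eta <- params$intercept + params$beta * x + params$delta_y * params$u
  ll_y <- sum(y * eta - log1pexp(eta))

  lp <- sum(stats::dnorm(params$alpha, prior$alpha_prior_mean,
                         prior$alpha_prior_sd, log = TRUE)) +
    stats::dnorm(params$beta, prior$used_prior_mean, prior$used_prior_sd,
                 log = TRUE) +
    stats::dnorm(params$delta_x, 0, prior$delta_prior_sd, log = TRUE) +
    stats::dnorm(params$delta_y, 0, prior$delta_prior_sd, log = TRUE) +
    stats::dnorm(params$intercept, 0, prior$intercept_prior_sd, log = TRUE) +
    dinvgamma_log(params$sigma_x, prior$sigma_x_prior_shape,
                  prior$sigma_x_prior_scale) +
    sum(stats::dnorm(params$u, 0, sqrt(prior$u_variance), log = TRUE))

  ll_x + ll_y + lp
}

#' Absolute-risk shift implied by a log-odds effect
#'
#' Translates a candidate causal-effect size into the change it implies in an
#' outcome probability: `expit(logit(baseline_prob) + beta)`. The intended use
#' is ROPE elicitation — judging whether a one-standard-deviation change in
#' the exposure moves the absolute risk by a negligible amount, and choosing
#' the half-width T accordingly.
#'
#' @param baseline_prob Baseline outcome probability, strictly inside (0, 1).
#'   Vectorized.
#' @param beta Log-odds shift (the causal-effect coefficient). Vectorized.
#' @return The shifted probability, in (0, 1).
#' @examples
#' risk_shift(0.524, 0.1)  # 0.549 to three decimals
#' @export
risk_shift <- function(baseline_prob, beta) {
  if (any(!is.finite(baseline_prob)) ||
      any(baseline_prob <= 0) || any(baseline_prob >= 1)) {
    stop("baseline_prob must lie strictly inside (0, 1)")
  }
  stats::plogis(stats::qlogis(baseline_prob) + beta)
}
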