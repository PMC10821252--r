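#' Importance weight converting used-prior draws to mixture-prior draws
#'
#' The MCMC runs under the continuous "used" prior for the causal effect,
#' p_used = N(mean, sd^2). The intended "true" prior is the mixture
#' (1 - pi0) * N(mean, sd^2) + pi0 * Unif(-T, T). Each posterior draw beta
#' receives the weight
#' \deqn{\omega(\beta) = \frac{(1-\pi_0)\,N(\beta \mid 0, 10^2) +
#'   \pi_0\,\mathrm{Unif}(\beta \mid -T, T)}{N(\beta \mid 0, 10^2)},}
#' where the uniform density is 1/(2T) inside \[-T, T\] and 0 outside. Draws
#' outside the ROPE all get the constant weight `1 - pi0` (0.5 when
#' `pi0 = 0.5`); draws inside get `1 - pi0 + pi0 / (2 T N(beta | 0, sd^2))`,
#' so inside draws are always upweighted relative to outside draws, the more
#' so the narrower the ROPE.
#'
#' @param beta Numeric vector of causal-effect draws.
#' @param prior An [mr_prior()] supplying `pi0`, `rope_T` and the used-prior
#'   mean/SD.
#' @return Nonnegative weights, one per draw.
#' @examples
#' importance_weight(c(-0.5, 0, 0.5), mr_prior(pi0 = 0.5, rope_T = 0.1))
#' @export
importance_weight <- function(beta, prior) {
  stopifnot(inherits(prior, "mr_prior"))
  used <- stats::dnorm(beta, prior$used_prior_mean, prior$used_prior_sd)
  unif <- ifelse(abs(beta) <= prior$rope_T, 1 / (2 * prior$rope_T), 0)
  ((1 - prior$pi0) * used + prior$pi0 * unif) / used
}

#' Recover mixture-prior posterior draws by weighted resampling
#'
#' Resamples the used-posterior draws with replacement, with probability
#' proportional to [importance_weight()], yielding draws (of the causal
#' effect and, through the retained indices, of every other unknown) from the
#' posterior under the intended mixture prior.
#'
#' @param fit An `mr_fit`, or a numeric vector of causal-effect draws.
#' @param prior An [mr_prior()].
#' @param n_out Number of resampled draws (default: the input draw count).
#' @param seed Integer seed for the resampling step.
#' @return An object of class `mr_weighted_draws`: `beta` (input draws),
#'   `weights`, `resampled_beta`, `resampled_index`, and the `prior` used.
#' @export
mixture_resample <- function(fit, prior, n_out = NULL, seed = 1L) {
  beta <- if (inherits(fit, "mr_fit")) fit$draws$beta else as.numeric(fit)
  k <- length(beta)
  if (k < 1L) stop("need at least one posterior draw")
  w <- importance_weight(beta, prior)
  if (all(w == 0)) {
    stop("all importance weights are zero (pi0 = 1 with no draw in the ROPE):",
         " the mixture posterior cannot be recovered from these draws")
  }
  n_out <- n_out %||% k
  set.seed(seed)
  idx <- sample.int(k, n_out, replace = TRUE, prob = w)
  structure(
    list(beta = beta, weights = w, resampled_beta = beta[idx],
         resampled_index = idx, prior = prior),
    class = "mr_weighted_draws")
}

#' @export
print.mr_weighted_draws <- function(x, ...) {
  cat(sprintf("<mr_weighted_draws> %d draws -> %d resampled; ROPE [-%g, %g]\n",
              length(x$beta), length(x$resampled_beta), x$prior$rope_T,
              x$prior$rope_T))
  invisible(x)
}

#' Posterior odds of the causal effect lying in the ROPE
#'
#' Computes V0, the posterior probability of |beta| <= T under the mixture
#' ("true") prior, V1 = 1 - V0, and their ratio V0/V1 — a
#' simulation-consistent approximation to the posterior odds of the interval
#' null and hence to its Bayes factor times the prior odds.
#'
#' Two estimators are available: `"weights"` (default) uses the normalized
#' importance-weight mass inside the ROPE, which has the same expectation as
#' the resampled proportion but lower Monte-Carlo variance; `"resample"` uses
#' the literal resampled-draw proportion.
#'
#' @param weighted An `mr_weighted_draws` from [mixture_resample()].
#' @param method `"weights"` or `"resample"`.
#' @return A one-row tibble of class `mr_odds`: `V0`, `V1`, `odds`
#'   (`Inf` when V1 = 0), `n_resampled`, `rope_T`, `method`.
#' @export
posterior_odds <- function(weighted, method = c("weights", "resample")) {
  stopifnot(inherits(weighted, "mr_weighted_draws"))
  method <- match.arg(method)
  T <- weighted$prior$rope_T
  if (method == "weights") {
    inside <- abs(weighted$beta) <= T
    v0 <- sum(weighted$weights[inside]) / sum(weighted$weights)
  } else {
    v0 <- mean(abs(weighted$resampled_beta) <= T)
  }
  v1 <- 1 - v0
  out <- tibble::tibble(
    V0 = v0, V1 = v1,
    odds = if (v1 == 0) Inf else v0 / v1,
    n_resampled = length(weighted$resampled_beta),
    rope_T = T, method = method)
  class(out) <- c("mr_odds", class(out))
  out
}

#' Ternary causal-discovery decision rule (CDDR)
#'
#' Maps the ROPE posterior odds V0/V1 to one of three outcomes:
#' odds > `upper` accepts the non-existence hypothesis with confidence
#' (`"accept_null"`); odds < `lower` accepts the existence hypothesis and
#' claims a causal discovery (`"discovery"`); anything in the closed interval
#' \[`lower`, `upper`\] is an uncertain outcome (`"uncertain"`). The default
#' thresholds are 10 and 0.1.
#'
#' @param odds An `mr_odds` row from [posterior_odds()], or a numeric odds
#'   value (vectorized).
#' @param upper,lower Decision thresholds, `lower < upper`.
#' @return A character vector with values `"accept_null"`, `"discovery"` or
#'   `"uncertain"`.
#' @examples
#' cddr(c(11, 10, 1, 0.05))
#' @export
cddr <- function(odds, upper = 10, lower = 0.1) {
  stopifnot(lower < upper)
  o <- if (inherits(odds, "mr_odds")) odds$odds else as.numeric(odds)
  dplyr::case_when(
    o > upper ~ "accept_null",
    o < lower ~ "discovery",
    TRUE ~ "uncertain")
}

#' Decision outcomes recognised by the loss layer
#' @return The three CDDR outcome labels.
#' @export
decision_levels <- function() c("accept_null", "discovery", "uncertain")

#' One-call ROPE decision from a fit
#'
#' Convenience pipeline: [mixture_resample()] then [posterior_odds()] then
#' [cddr()].
#'
#' @param fit An `mr_fit` (or numeric vector of causal-effect draws).
#' @param prior An [mr_prior()].
#' @param upper,lower CDDR thresholds.
#' @param method Odds estimator, see [posterior_odds()].
#' @param seed Resampling seed.
#' @return A one-row tibble: `V0`, `V1`, `odds`, `decision`, `rope_T`, `pi0`.
#' @export
mr_decide <- function(fit, prior, upper = 10, lower = 0.1,
                      method = "weights", seed = 1L) {
  wd <- mixture_resample(fit, prior, seed = seed)
  od <- posterior_odds(wd, method = method)
  tibble::tibble(V0 = od$V0, V1 = od$V1, odds = od$odds,
                 decision = cddr(od, upper = upper, lower = lower),
                 rope_T = prior$rope_T, pi0 = prior$pi0)
}
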