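#' Loss of a ternary test decision
#'
#' The six-entry loss table used for calibration: a correct confident decision
#' costs 0, a wrong confident decision costs 1, and an uncertain outcome costs
#' `a` regardless of the truth (0 <= a <= 1). Truth is `"null"` when the true
#' causal effect lies in the ROPE and `"alternative"` when it is some
#' beta* outside it.
#'
#' @param decision Character vector of [decision_levels()] outcomes.
#' @param truth Character vector, `"null"` or `"alternative"`.
#' @param a Cost of an uncertain outcome, in \[0, 1\].
#' @return Numeric losses in \{0, a, 1\}.
#' @examples
#' decision_loss("uncertain", "alternative", a = 0.3)
#' @export
decision_loss <- function(decision, truth, a) {
  stopifnot(all(a >= 0), all(a <= 1),
            all(decision %in% decision_levels()),
            all(truth %in% c("null", "alternative")))
  correct <- (decision == "accept_null" & truth == "null") |
    (decision == "discovery" & truth == "alternative")
  dplyr::case_when(
    decision == "uncertain" ~ a + 0 * seq_along(decision),
    correct ~ 0,
    TRUE ~ 1)
}

#' Expected loss of a decision procedure
#'
#' The empirical mean of per-record losses over simulated decisions sharing
#' one truth condition. This equals the four-term decision-theoretic formula
#' (uncertain-rate x a under each truth, plus the two confident-error rates)
#' with the probabilities replaced by empirical frequencies. For a binary
#' (frequentist) procedure the uncertain terms are structurally zero.
#'
#' @param records A data frame with columns `decision` and `truth` (and
#'   optionally a precomputed `loss` column, ignored here).
#' @param a Cost of an uncertain outcome. May also be a column name in
#'   `records` holding per-record values of `a`.
#' @return A numeric scalar in \[0, 1\].
#' @export
expected_loss <- function(records, a = 0.5) {
  if (nrow(records) == 0L) stop("no decision records supplied")
  if (length(unique(records$truth)) > 1L) {
    stop("expected_loss is defined under one truth condition; ",
         "split the records by truth first")
  }
  avec <- if (is.character(a) && length(a) == 1L) records[[a]] else a
  mean(decision_loss(records$decision, records$truth, avec))
}

#' Inverse-variance weighted (IVW) two-sample MR estimate
#'
#' The frequentist comparator. Per-instrument instrument-exposure
#' associations gamma_j come from simple linear regressions of X on Z_j in
#' dataset A; instrument-outcome associations Gamma_j from univariate
#' logistic regressions of Y on Z_j in dataset B. Ratio estimates
#' beta_j = Gamma_j / gamma_j are combined by fixed-effect inverse-variance
#' weighting with first-order weights w_j = gamma_j^2 / se(Gamma_j)^2, so the
#' estimate is sum(gamma_j Gamma_j / se_j^2) / sum(gamma_j^2 / se_j^2) —
#' a near-zero gamma_j simply gets near-zero weight, with no ratio blow-up.
#' The 95% confidence interval is estimate +/- 1.96 / sqrt(sum w_j).
#'
#' @param data_a An `mr_data` supplying (Z, X): rows with observed exposure.
#' @param data_b An `mr_data` supplying (Z, Y). In the experiment this is the
#'   missing-exposure subset; its Y values are all that is used.
#' @return A list of class `mr_ivw`: `estimate`, `std_error`, `ci_lower`,
#'   `ci_upper`, and a tibble `instruments` of per-instrument summaries.
#'   Methods: [tidy()], [glance()].
#' @export
ivw_fit <- function(data_a, data_b) {
  validate_mr_data(data_a); validate_mr_data(data_b)
  J <- n_instruments(data_a)
  if (n_instruments(data_b) != J) stop("instrument sets differ between datasets")
  obs <- !is.na(data_a$exposure)
  za <- data_a$genotypes[obs, , drop = FALSE]
  xa <- data_a$exposure[obs]
  zb <- data_b$genotypes
  yb <- data_b$outcome
  poly_a <- apply(za, 2L, function(v) stats::sd(v) > 0)
  poly_b <- apply(zb, 2L, function(v) stats::sd(v) > 0)
  if (!all(poly_a & poly_b)) {
    stop("monomorphic instrument in one of the datasets: ",
         paste(colnames(za)[!(poly_a & poly_b)], collapse = ", "))
  }
  per <- purrr::map_dfr(seq_len(J), function(j) {
    fx <- stats::lm(xa ~ za[, j])
    gamma_hat <- stats::coef(fx)[2L]
    gamma_se <- sqrt(diag(stats::vcov(fx))[2L])
    fy <- suppressWarnings(stats::glm(yb ~ zb[, j], family = stats::binomial()))
    big_gamma <- stats::coef(fy)[2L]
    big_se <- sqrt(diag(stats::vcov(fy))[2L])
    tibble::tibble(
      instrument = colnames(za)[j],
      gamma_hat = unname(gamma_hat), gamma_se = unname(gamma_se),
      big_gamma_hat = unname(big_gamma), big_gamma_se = unname(big_se),
      ratio = unname(big_gamma / gamma_hat),
      weight = unname(gamma_hat^2 / big_se^2))
  })
  wsum <- sum(per$weight)
  est <- sum(per$weight * per$ratio) / wsum
  se <- 1 / sqrt(wsum)
  structure(
    list(estimate = est, std_error = se,
         ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se,
         instruments = per),
    class = "mr_ivw")
}

#' @export
print.mr_ivw <- function(x, ...) {
  cat(sprintf("<mr_ivw> estimate %.4f (SE %.4f), 95%% CI (%.4f, %.4f), %d instruments\n",
              x$estimate, x$std_error, x$ci_lower, x$ci_upper,
              nrow(x$instruments)))
  invisible(x)
}

#' Per-instrument summaries of an IVW fit
#' @param x An `mr_ivw`.
#' @param ... Unused.
#' @return A tibble with one row per instrument: the instrument-exposure and
#'   instrument-outcome associations, the ratio estimate and its IVW weight.
#' @method tidy mr_ivw
#' @export
tidy.mr_ivw <- function(x, ...) x$instruments

#' One-row summary of an IVW fit
#' @param x An `mr_ivw`.
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `n_instruments`.
#' @method glance mr_ivw
#' @export
glance.mr_ivw <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, std.error = x$std_error,
                 conf.low = x$ci_lower, conf.high = x$ci_upper,
                 n_instruments = nrow(x$instruments))
}

#' Binary decision from an IVW confidence interval
#'
#' Accept the point null iff the 95% confidence interval contains 0
#' (closed-interval convention: an endpoint exactly at 0 accepts the null);
#' otherwise claim a discovery. The frequentist rule has no uncertain
#' outcome.
#'
#' @param result An `mr_ivw` from [ivw_fit()].
#' @return `"accept_null"` or `"discovery"`.
#' @export
ivw_decide <- function(result) {
  stopifnot(inherits(result, "mr_ivw"))
  if (result$ci_lower <= 0 && result$ci_upper >= 0) "accept_null" else "discovery"
}

# Build the two IVW input datasets from the combined D1. Dataset A rows keep
# (Z, X); dataset B rows keep (Z, Y). With no missingness, A is split at
# random into equal halves for the two association stages.
ivw_splits <- function(dataset, seed) {
  miss <- exposure_missing_mask(dataset)
  if (any(miss)) {
    a_idx <- which(!miss); b_idx <- which(miss)
  } else {
    set.seed(seed)
    n <- n_total(dataset)
    a_idx <- sample.int(n, floor(n / 2)); b_idx <- setdiff(seq_len(n), a_idx)
  }
  list(
    a = new_mr_data(dataset$genotypes[a_idx, , drop = FALSE],
                    dataset$exposure[a_idx], dataset$outcome[a_idx],
                    standardized = dataset$standardized),
    b = new_mr_data(dataset$genotypes[b_idx, , drop = FALSE],
                    rep(NA_real_, length(b_idx)), dataset$outcome[b_idx],
                    standardized = dataset$standardized))
}

#' Run the loss-calibration simulation experiment
#'
#' For every scenario in the grid and every replicate: simulate a dataset,
#' draw the ROPE half-width T ~ Unif over `T_range` and the uncertain-outcome
#' cost a ~ Unif over `a_range`, run the Bayesian pipeline
#' ([mr_fit()] -> [mixture_resample()] -> [cddr()]) on the combined data and
#' the IVW pipeline ([ivw_fit()] -> [ivw_decide()]) on the two-sample splits
#' (Y of the complete-data rows is discarded), and record both decisions with
#' the loss each incurs given the generating truth.
#'
#' Defaults are scaled for desk use (20 replicates, short chains); the
#' full-scale design (200 replicates) is one argument away.
#'
#' @param grid An `mr_scenario_grid` from [build_grid()].
#' @param replicates Replicates per scenario (overrides the configs').
#' @param seed Root seed; every dataset/fit/draw uses substreams derived
#'   from it.
#' @param T_range,a_range Uniform ranges for the per-replicate draws of the
#'   ROPE half-width and the uncertain cost.
#' @param pi0 Prior null mass used in the Bayesian analysis.
#' @param iterations,chains MCMC settings passed to [mr_fit()].
#' @param odds_method Posterior-odds estimator for the Bayesian pipeline:
#'   `"resample"` (default) counts resampled draws inside the ROPE, the
#'   procedure the calibration experiment is defined around (V0 is exactly 0
#'   when no draw lands in the interval); `"weights"` uses the
#'   variance-reduced normalized-weight estimator.
#' @param methods Which pipelines to run, subset of `c("bayes", "ivw")`.
#' @param progress Print a line per scenario.
#' @return A tibble of class `mr_experiment`: one row per scenario x
#'   replicate x method with columns `scenario`, `replicate`, `method`,
#'   `missing_rate`, `alpha_strength`, `beta_true`, `truth`, `T_used`,
#'   `a_used`, `V0`, `V1`, `odds`, `estimate`, `ci_lower`, `ci_upper`,
#'   `decision`, `loss`, `seed`. Failures of individual replicates are
#'   recorded with `decision = NA` and a warning, never silently dropped.
#' @export
run_experiment <- function(grid, replicates = 20, seed = 1L,
                           T_range = c(0.01, 0.1), a_range = c(0, 0.6),
                           pi0 = 0.5, iterations = 1500, chains = 2,
                           odds_method = c("resample", "weights"),
                           methods = c("bayes", "ivw"), progress = FALSE) {
  stopifnot(inherits(grid, "mr_scenario_grid"), replicates >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  odds_method <- match.arg(odds_method)
  scen_seeds <- derive_seeds(seed, nrow(grid))
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cfg <- grid$config[[i]]
    rep_seeds <- derive_seeds(scen_seeds[i], replicates * 2L)
    if (progress) {
      message(sprintf("scenario %d/%d (miss %g, alpha %g, beta %g)",
                      i, nrow(grid), cfg$missing_rate, cfg$alpha_strength,
                      cfg$beta_true))
    }
    purrr::map_dfr(seq_len(replicates), function(r) {
      ds_seed <- rep_seeds[2L * r - 1L]
      an_seed <- rep_seeds[2L * r]
      set.seed(an_seed)
      T_used <- stats::runif(1, T_range[1], T_range[2])
      a_used <- stats::runif(1, a_range[1], a_range[2])
      truth <- if (cfg$beta_true == 0) "null" else "alternative"
      one_replicate(cfg, ds_seed, an_seed, T_used, a_used, truth, pi0,
                    iterations, chains, methods, odds_method,
                    scenario = grid$scenario[i], replicate = r)
    })
  })
  class(rows) <- c("mr_experiment", class(rows))
  rows
}

one_replicate <- function(cfg, ds_seed, an_seed, T_used, a_used, truth, pi0,
                          iterations, chains, methods, odds_method,
                          scenario, replicate) {
  base <- tibble::tibble(
    scenario = scenario, replicate = replicate,
    missing_rate = cfg$missing_rate, alpha_strength = cfg$alpha_strength,
    beta_true = cfg$beta_true, truth = truth,
    T_used = T_used, a_used = a_used, seed = ds_seed)
  dataset <- tryCatch(simulate_dataset(cfg, ds_seed), error = function(e) e)
  if (inherits(dataset, "error")) {
    warning("replicate failed in simulation: ", conditionMessage(dataset))
    return(dplyr::mutate(base, method = methods, V0 = NA_real_, V1 = NA_real_,
                         odds = NA_real_, estimate = NA_real_,
                         ci_lower = NA_real_, ci_upper = NA_real_,
                         decision = NA_character_, loss = NA_real_))
  }
  out <- list()
  if ("bayes" %in% methods) {
    row <- tryCatch({
      prior <- mr_prior(pi0 = pi0, rope_T = T_used)
      fit <- mr_fit(dataset, prior, iterations = iterations, chains = chains,
                    seed = an_seed)
      dec <- mr_decide(fit, prior, method = odds_method, seed = an_seed)
      dplyr::mutate(base, method = "bayes", V0 = dec$V0, V1 = dec$V1,
                    odds = dec$odds, estimate = mean(fit$draws$beta),
                    ci_lower = stats::quantile(fit$draws$beta, 0.025, names = FALSE),
                    ci_upper = stats::quantile(fit$draws$beta, 0.975, names = FALSE),
                    decision = dec$decision,
                    loss = decision_loss(dec$decision, truth, a_used))
    }, error = function(e) {
      warning("Bayesian replicate failed: ", conditionMessage(e))
      dplyr::mutate(base, method = "bayes", V0 = NA_real_, V1 = NA_real_,
                    odds = NA_real_, estimate = NA_real_, ci_lower = NA_real_,
                    ci_upper = NA_real_, decision = NA_character_,
                    loss = NA_real_)
    })
    out <- c(out, list(row))
  }
  if ("ivw" %in% methods) {
    row <- tryCatch({
      sp <- ivw_splits(dataset, an_seed)
      iv <- ivw_fit(sp$a, sp$b)
      dec <- ivw_decide(iv)
      dplyr::mutate(base, method = "ivw", V0 = NA_real_, V1 = NA_real_,
                    odds = NA_real_, estimate = iv$estimate,
                    ci_lower = iv$ci_lower, ci_upper = iv$ci_upper,
                    decision = dec,
                    loss = decision_loss(dec, truth, a_used))
    }, error = function(e) {
      warning("IVW replicate failed: ", conditionMessage(e))
      dplyr::mutate(base, method = "ivw", V0 = NA_real_, V1 = NA_real_,
                    odds = NA_real_, estimate = NA_real_, ci_lower = NA_real_,
                    ci_upper = NA_real_, decision = NA_character_,
                    loss = NA_real_)
    })
    out <- c(out, list(row))
  }
  dplyr::bind_rows(out)
}

#' Expected-loss surface over (T, a)
#'
#' Summarises experiment records into per-scenario, per-method expected
#' losses, optionally binned over the drawn (T, a) values so the surface the
#' calibration experiment explores can be plotted.
#'
#' @param records An `mr_experiment` tibble.
#' @param bins Number of bins per axis for T and a (0 = no binning).
#' @return A tibble with `scenario`, `method`, bin midpoints `T_mid`/`a_mid`
#'   (if binned), `expected_loss` and `n`.
#' @export
loss_surface <- function(records, bins = 0) {
  ok <- dplyr::filter(records, !is.na(.data$loss))
  if (bins > 0) {
    ok <- dplyr::mutate(
      ok,
      T_mid = bin_mid(.data$T_used, bins),
      a_mid = bin_mid(.data$a_used, bins))
    grp <- dplyr::group_by(ok, .data$scenario, .data$missing_rate,
                           .data$alpha_strength, .data$beta_true,
                           .data$method, .data$T_mid, .data$a_mid)
  } else {
    grp <- dplyr::group_by(ok, .data$scenario, .data$missing_rate,
                           .data$alpha_strength, .data$beta_true,
                           .data$method)
  }
  dplyr::summarise(grp, expected_loss = mean(.data$loss), n = dplyr::n(),
                   .groups = "drop")
}

bin_mid <- function(x, bins) {
  br <- seq(min(x), max(x), length.out = bins + 1L)
  mid <- (br[-1L] + br[-length(br)]) / 2
  mid[pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), bins)]
}
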