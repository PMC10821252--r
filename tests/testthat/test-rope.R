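test_that("importance weights follow the printed mixture-over-used formula", {
  pr <- mr_prior(pi0 = 0.5, rope_T = 0.1)
  # outside the ROPE the weight is exactly 1 - pi0
  expect_equal(importance_weight(c(-5, -0.11, 0.2, 3), pr), rep(0.5, 4))
  # inside: 0.5 + 1 / (4 T N(beta | 0, 10^2)), against an independent pdf
  b <- c(-0.1, -0.03, 0, 0.05, 0.1)
  expect_equal(importance_weight(b, pr),
               0.5 + 1 / (4 * 0.1 * phi_indep(b, 0, 10)),
               tolerance = 1e-12)
  # derived spot value at beta = 0: phi(0; 0, 10^2) = 1/(10 sqrt(2 pi))
  expect_equal(importance_weight(0, pr),
               0.5 + 10 * sqrt(2 * pi) / 0.4, tolerance = 1e-12)

  # piecewise jump exactly at the ROPE boundary; inside > outside for pi0 > 0
  eps <- 1e-9
  expect_gt(importance_weight(0.1, pr), importance_weight(0.1 + eps, pr))
  for (pi0 in c(0.1, 0.5, 0.9, 1)) {
    p2 <- mr_prior(pi0 = pi0, rope_T = 0.05)
    expect_gt(importance_weight(0.04, p2), importance_weight(0.06, p2))
    expect_equal(importance_weight(0.06, p2), 1 - pi0)
  }
  # generalizes to other used-prior SDs
  p3 <- mr_prior(pi0 = 0.3, rope_T = 0.2, used_prior_sd = 2)
  expect_equal(importance_weight(0.1, p3),
               (0.7 * phi_indep(0.1, 0, 2) + 0.3 / 0.4) / phi_indep(0.1, 0, 2))
})

test_that("resampling recovers the used posterior when pi0 = 0", {
  set.seed(1)
  beta <- rnorm(20000, 0.2, 0.5)
  wd <- mixture_resample(beta, mr_prior(pi0 = 0, rope_T = 0.1), seed = 2)
  expect_true(all(wd$weights == 1))
  # resampling noise only: SE of the resampled mean is ~ sd/sqrt(K) * sqrt(2)
  expect_lt(abs(mean(wd$resampled_beta) - mean(beta)),
            6 * sd(beta) / sqrt(length(beta)))
  expect_lt(abs(sd(wd$resampled_beta) - sd(beta)), 0.02)
})

test_that("draws all outside the ROPE resample uniformly", {
  beta <- seq(0.5, 1.5, length.out = 1000)
  wd <- mixture_resample(beta, mr_prior(pi0 = 0.5, rope_T = 0.1),
                         n_out = 50000, seed = 3)
  expect_true(all(wd$weights == 0.5))
  counts <- tabulate(wd$resampled_index, 1000)
  expect_equal(mean(counts), 50, tolerance = 1e-12)
  expect_lt(max(abs(counts - 50)) / 50, 0.6)  # binomial fluctuation only
})

test_that("resampled ROPE mass matches numeric integration on a toy model", {
  # conjugate toy: y ~ N(beta, 1), n obs; used prior N(0, 10^2) gives a
  # normal used posterior we can sample exactly; the true mixture-prior
  # posterior is integrated on a fine grid (trapezoid) as the oracle.
  set.seed(4)
  n <- 30
  y <- rnorm(n, 0.05, 1)
  prior <- mr_prior(pi0 = 0.5, rope_T = 0.1)
  post_prec <- n + 1 / 100
  post_mean <- sum(y) / post_prec
  post_sd <- sqrt(1 / post_prec)
  draws <- rnorm(20000, post_mean, post_sd)
  wd <- mixture_resample(draws, prior, seed = 5)
  v0_resampled <- mean(abs(wd$resampled_beta) <= 0.1)
  v0_weighted <- posterior_odds(wd, method = "weights")$V0

  grid <- seq(-1.5, 1.5, length.out = 40001)
  lik <- exp(-n / 2 * (grid - mean(y))^2)  # beta-dependent factor only
  p_true <- 0.5 * phi_indep(grid, 0, 10) +
    0.5 * ifelse(abs(grid) <= 0.1, 1 / 0.2, 0)
  dens <- lik * p_true
  trap <- function(f, x) sum((f[-1] + f[-length(f)]) / 2 * diff(x))
  oracle <- trap(dens * (abs(grid) <= 0.1), grid) / trap(dens, grid)

  expect_equal(v0_weighted, oracle, tolerance = 0.01)
  expect_equal(v0_resampled, oracle, tolerance = 0.02)
})

test_that("posterior odds handles the boundary cases of the decision rule", {
  pr <- mr_prior(pi0 = 0.5, rope_T = 0.1)
  all_in <- mixture_resample(runif(500, -0.09, 0.09), pr, seed = 6)
  o_in <- posterior_odds(all_in)
  expect_equal(o_in$V0, 1)
  expect_equal(o_in$odds, Inf)
  expect_equal(cddr(o_in), "accept_null")

  all_out <- mixture_resample(runif(500, 0.2, 1), pr, seed = 7)
  o_out <- posterior_odds(all_out)
  expect_equal(o_out$V0, 0)
  expect_equal(o_out$odds, 0)
  expect_equal(cddr(o_out), "discovery")

  # V0 + V1 = 1 always, both estimators
  mixed <- mixture_resample(rnorm(2000, 0.1, 0.2), pr, seed = 8)
  for (m in c("weights", "resample")) {
    o <- posterior_odds(mixed, method = m)
    expect_equal(o$V0 + o$V1, 1)
    expect_gte(o$V0, 0); expect_lte(o$V0, 1)
  }
})

test_that("weight-based and resampled V0 agree within Monte-Carlo error", {
  set.seed(9)
  pr <- mr_prior(pi0 = 0.5, rope_T = 0.15)
  draws <- rnorm(50000, 0.1, 0.15)
  wd <- mixture_resample(draws, pr, seed = 10)
  ow <- posterior_odds(wd, method = "weights")$V0
  os <- posterior_odds(wd, method = "resample")$V0
  se <- sqrt(ow * (1 - ow) / 50000)
  expect_lt(abs(ow - os), 6 * se)
})

test_that("the ternary decision rule maps odds as stated", {
  expect_equal(cddr(11), "accept_null")
  expect_equal(cddr(0.05), "discovery")
  # boundaries inclusive to the uncertain outcome
  expect_equal(cddr(10), "uncertain")
  expect_equal(cddr(0.1), "uncertain")
  expect_equal(cddr(1), "uncertain")
  expect_equal(cddr(Inf), "accept_null")
  expect_equal(cddr(0), "discovery")
  expect_equal(cddr(c(0.3, 20), upper = 0.5, lower = 0.2),
               c("uncertain", "accept_null"))
  expect_error(cddr(1, upper = 0.1, lower = 10), "lower < upper")
})

test_that("degenerate weighting (pi0 = 1, nothing in ROPE) is flagged", {
  pr <- mr_prior(pi0 = 1, rope_T = 0.01)
  expect_error(mixture_resample(c(0.5, 0.9), pr), "weights are zero")
})
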