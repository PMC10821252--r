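test_that("split_and_mask reproduces the design bookkeeping", {
  cfg <- mr_scenario(missing_rate = 0.8, alpha_strength = 0.3, beta_true = 0.3)
  pool <- simulate_pool(cfg, seed = 5)
  d <- split_and_mask(pool, cfg, seed = 6)
  expect_equal(n_complete(d), 80L)
  expect_equal(n_missing(d), 320L)
  expect_equal(n_total(d), 400L)
  # masked entries keep their oracle values for imputation checks
  mask <- exposure_missing_mask(d)
  expect_true(all(is.finite(d$oracle_exposure[mask])))
  expect_equal(d$exposure[!mask], d$oracle_exposure[!mask])
  # A and B partition the selection: no pool individual twice
  expect_equal(anyDuplicated(d$truth$pool_index), 0L)

  cfg0 <- mr_scenario(missing_rate = 0, alpha_strength = 0.3, beta_true = 0.3)
  d0 <- split_and_mask(pool, cfg0, seed = 6)
  expect_equal(n_missing(d0), 0L)

  expect_error(
    split_and_mask(pool, mr_scenario(n_pool = 400, n_analysis = 400), 1),
    NA)
  small <- simulate_pool(mr_scenario(n_pool = 50, n_analysis = 50), 1, n = 10)
  expect_error(split_and_mask(small, mr_scenario(), 1), "pool size")
})

test_that("masked fraction follows the rounding rule at awkward rates", {
  # round-half-away-from-zero documented for n_A
  cfg <- mr_scenario(missing_rate = 0.4375, n_pool = 100, n_analysis = 40)
  pool <- simulate_pool(cfg, seed = 2)
  d <- split_and_mask(pool, cfg, seed = 3)
  expect_equal(n_complete(d), 23L)  # 40 * 0.5625 = 22.5 -> 23
  expect_equal(n_missing(d), 17L)
  expect_equal(ropemr:::round_half_away(2.5), 3)
  expect_equal(ropemr:::round_half_away(-2.5), -3)
})

test_that("simulation is deterministic given the seed", {
  cfg <- mr_scenario(missing_rate = 0.4, alpha_strength = 0.1, beta_true = 0)
  a <- simulate_dataset(cfg, seed = 77)
  b <- simulate_dataset(cfg, seed = 77)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$outcome, b$outcome)
  c <- simulate_dataset(cfg, seed = 78)
  expect_false(identical(a$outcome, c$outcome))
})

test_that("build_grid enumerates the factorial design", {
  g <- build_grid()
  expect_equal(nrow(g), 18L)
  expect_equal(n_datasets(g), 3600L)
  expect_setequal(unique(g$missing_rate), c(0.8, 0.4, 0))
  expect_setequal(unique(g$alpha_strength), c(0.3, 0.1, 0.05))
  expect_setequal(unique(g$beta_true), c(0.3, 0))
  g1 <- build_grid(missing_rates = 0, alpha_strengths = 0.3, beta_trues = 0,
                   replicates = 7)
  expect_equal(nrow(g1), 1L)
  expect_equal(n_datasets(g1), 7L)
})

test_that("pool generation honours the generative model", {
  # independence when beta and confounder paths are switched off
  cfg <- mr_scenario(missing_rate = 0, alpha_strength = 0, beta_true = 0,
                     delta_x = 0, delta_y = 0)
  big <- simulate_pool(cfg, seed = 9, n = 50000)
  expect_lt(abs(cor(big$exposure, big$outcome)), 0.015)

  # logistic slope recovery on a large pool with the confounder known
  cfg2 <- mr_scenario(missing_rate = 0, alpha_strength = 0.3, beta_true = 0.3)
  pool <- simulate_pool(cfg2, seed = 10, n = 20000)
  fitg <- glm(pool$outcome ~ pool$exposure + pool$truth$u, family = binomial())
  se <- sqrt(diag(vcov(fitg)))[2]
  expect_lt(abs(coef(fitg)[2] - 0.3), 3.5 * se)
  expect_lt(abs(coef(fitg)[3] - 1), 3.5 * sqrt(diag(vcov(fitg)))[3])

  # genotype columns standardized; sigma_x recorded in truth
  expect_equal(colMeans(pool$genotypes), rep(0, 15),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(apply(pool$genotypes, 2, sd), rep(1, 15),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_gt(pool$truth$sigma_x, 0)
})

test_that("exposure variance matches the closed-form decomposition", {
  # Var(X) = sum(alpha^2) + delta_x^2 * 0.1 + sigma_x^2 for standardized,
  # independent instruments; fixed sigma_x override used here
  cfg <- mr_scenario(missing_rate = 0, alpha_strength = 0.3, beta_true = 0,
                     sigma_x = 0.8)
  pool <- simulate_pool(cfg, seed = 12, n = 50000)
  v_expect <- 15 * 0.3^2 + 0.1 + 0.8^2
  expect_equal(var(pool$exposure), v_expect, tolerance = 0.05)
  # R^2 of X on Z approaches the implied variance ratio
  r2 <- summary(lm(pool$exposure ~ pool$genotypes))$r.squared
  expect_equal(r2, 15 * 0.09 / v_expect, tolerance = 0.02)
})
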