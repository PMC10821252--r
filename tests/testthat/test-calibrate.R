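test_that("the six-entry loss table is reproduced exactly", {
  expect_equal(decision_loss("accept_null", "null", a = 0.3), 0)
  expect_equal(decision_loss("uncertain", "null", a = 0.3), 0.3)
  expect_equal(decision_loss("discovery", "null", a = 0.7), 1)
  expect_equal(decision_loss("accept_null", "alternative", a = 0.3), 1)
  expect_equal(decision_loss("uncertain", "alternative", a = 0.3), 0.3)
  expect_equal(decision_loss("discovery", "alternative", a = 0.3), 0)
  # losses only ever take values in {0, a, 1}
  grid <- expand.grid(decision = decision_levels(),
                      truth = c("null", "alternative"),
                      stringsAsFactors = FALSE)
  losses <- decision_loss(grid$decision, grid$truth, a = 0.42)
  expect_true(all(losses %in% c(0, 0.42, 1)))
  expect_error(decision_loss("accept_null", "null", a = 1.5), "a")
})

test_that("expected_loss equals the four-term formula via frequencies", {
  # direct arithmetic oracle: 10 null-truth records,
  # 2 discovery (cost 1), 3 uncertain (cost 0.5), 5 accept_null (cost 0)
  rec <- tibble::tibble(
    decision = c(rep("discovery", 2), rep("uncertain", 3),
                 rep("accept_null", 5)),
    truth = "null")
  expect_equal(expected_loss(rec, a = 0.5), (2 * 1 + 3 * 0.5) / 10)
  expect_equal(expected_loss(rec, a = 0.5), 0.35)

  # all correct-and-confident -> zero loss
  good <- tibble::tibble(decision = rep("discovery", 6), truth = "alternative")
  expect_equal(expected_loss(good, a = 0.9), 0)

  # per-record a column is honoured
  rec$a_used <- rep(c(0.2, 0.4), 5)
  manual <- mean(decision_loss(rec$decision, rec$truth, rec$a_used))
  expect_equal(expected_loss(rec, a = "a_used"), manual)

  expect_error(expected_loss(rec[0, ], a = 0.5), "no decision records")
  mixed <- tibble::tibble(decision = c("discovery", "discovery"),
                          truth = c("null", "alternative"))
  expect_error(expected_loss(mixed, a = 0.5), "one truth condition")
})

test_that("IVW reduces to the ratio estimate with one instrument", {
  d <- small_dataset(seed = 21, n_pool = 500, n_analysis = 300)
  # restrict to a single instrument
  one <- ropemr:::new_mr_data(d$genotypes[, 1, drop = FALSE], d$exposure,
                              d$outcome, standardized = TRUE)
  sp <- ropemr:::ivw_splits(one, seed = 2)
  iv <- ivw_fit(sp$a, sp$b)
  per <- generics::tidy(iv)
  expect_equal(nrow(per), 1L)
  expect_equal(iv$estimate, per$big_gamma_hat / per$gamma_hat)
})

test_that("IVW equals an independent hand computation on a small fixture", {
  set.seed(31)
  n <- 200
  maf <- c(0.2, 0.3, 0.4)
  z <- vapply(maf, function(p) rbinom(n, 2, p), numeric(n))
  colnames(z) <- paste0("Z", 1:3)
  x <- 0.4 * z[, 1] + 0.25 * z[, 2] + 0.3 * z[, 3] + rnorm(n)
  y <- rbinom(n, 1, plogis(-0.2 + 0.4 * x))
  half <- 1:100
  da <- ropemr:::new_mr_data(z[half, ], x[half], as.integer(y[half]))
  db <- ropemr:::new_mr_data(z[-half, ], rep(NA_real_, 100),
                             as.integer(y[-half]))
  iv <- ivw_fit(da, db)

  # term-by-term oracle: per-instrument regressions and the weighted mean
  g <- se_g <- G <- se_G <- numeric(3)
  for (j in 1:3) {
    fx <- summary(lm(x[half] ~ z[half, j]))
    g[j] <- fx$coefficients[2, 1]
    fy <- summary(glm(y[-half] ~ z[-half, j], family = binomial()))
    G[j] <- fy$coefficients[2, 1]
    se_G[j] <- fy$coefficients[2, 2]
  }
  w <- g^2 / se_G^2
  est_oracle <- sum(w * (G / g)) / sum(w)
  se_oracle <- 1 / sqrt(sum(w))
  expect_equal(iv$estimate, est_oracle, tolerance = 1e-10)
  expect_equal(iv$std_error, se_oracle, tolerance = 1e-10)
  expect_equal(iv$ci_lower, est_oracle - 1.96 * se_oracle, tolerance = 1e-10)

  # two instruments with identical ratio estimates recover that value
  per <- generics::tidy(iv)
  w2 <- per$weight[1:2]
  r_common <- 0.37
  est2 <- sum(w2 * r_common) / sum(w2)
  expect_equal(est2, r_common)
})

test_that("ivw_decide applies the closed-interval CI convention", {
  mk <- function(lo, hi) {
    structure(list(estimate = (lo + hi) / 2, std_error = (hi - lo) / 3.92,
                   ci_lower = lo, ci_upper = hi,
                   instruments = tibble::tibble()), class = "mr_ivw")
  }
  expect_equal(ivw_decide(mk(-0.1, 0.2)), "accept_null")
  expect_equal(ivw_decide(mk(0.05, 0.4)), "discovery")
  expect_equal(ivw_decide(mk(0, 0.4)), "accept_null")   # endpoint exactly 0
  expect_equal(ivw_decide(mk(-0.4, 0)), "accept_null")
  expect_equal(ivw_decide(mk(-0.5, -0.1)), "discovery")
})

test_that("IVW splits discard Y of complete rows and halve at 0% missing", {
  d <- small_dataset(seed = 22, missing_rate = 0.4, n_pool = 500,
                     n_analysis = 200)
  sp <- ropemr:::ivw_splits(d, seed = 1)
  expect_equal(n_total(sp$a), 120L)
  expect_equal(n_total(sp$b), 80L)
  expect_true(all(is.na(sp$b$exposure)))

  d0 <- small_dataset(seed = 23, missing_rate = 0, n_pool = 500,
                      n_analysis = 200)
  sp0 <- ropemr:::ivw_splits(d0, seed = 1)
  expect_equal(n_total(sp0$a), 100L)
  expect_equal(n_total(sp0$b), 100L)
})

test_that("run_experiment produces complete, reproducible decision records", {
  g <- build_grid(missing_rates = 0.4, alpha_strengths = 0.3,
                  beta_trues = c(0.3, 0), n_pool = 400, n_analysis = 150)
  ex1 <- run_experiment(g, replicates = 2, seed = 14, iterations = 400,
                        chains = 2)
  ex2 <- run_experiment(g, replicates = 2, seed = 14, iterations = 400,
                        chains = 2)
  expect_identical(as.data.frame(ex1), as.data.frame(ex2))

  expect_equal(nrow(ex1), 2 * 2 * 2)  # scenarios x replicates x methods
  expect_setequal(unique(ex1$method), c("bayes", "ivw"))
  expect_true(all(ex1$T_used >= 0.01 & ex1$T_used <= 0.1))
  expect_true(all(ex1$a_used >= 0 & ex1$a_used <= 0.6))
  # per-row loss consistent with the table given decision and truth
  expect_equal(ex1$loss,
               decision_loss(ex1$decision, ex1$truth, ex1$a_used))
  # the frequentist rule is binary: never uncertain, loss in {0, 1}
  ivw_rows <- ex1[ex1$method == "ivw", ]
  expect_true(all(ivw_rows$decision %in% c("accept_null", "discovery")))
  expect_true(all(ivw_rows$loss %in% c(0, 1)))
  # (T, a) shared between the two methods within a replicate
  shared <- dplyr::count(ex1, scenario, replicate, T_used, a_used)
  expect_true(all(shared$n == 2))

  surf <- loss_surface(ex1)
  expect_true(all(surf$expected_loss >= 0 & surf$expected_loss <= 1))
})
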