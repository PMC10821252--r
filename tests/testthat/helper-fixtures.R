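# Shared fixtures and independent oracle helpers.

# normal pdf written out explicitly, independent of stats::dnorm
phi_indep <- function(x, m = 0, s = 1) {
  exp(-(x - m)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
}

# 5-individual, 2-instrument fixture with hand-listed values
tiny_fixture <- function() {
  ropemr:::new_mr_data(
    genotypes = cbind(Z1 = c(0.5, -1.2, 0.3, 1.1, -0.7),
                      Z2 = c(-0.4, 0.9, -1.5, 0.2, 0.8)),
    exposure = c(0.2, NA, -0.8, 1.4, 0.1),
    outcome = c(1L, 0L, 0L, 1L, 1L),
    standardized = TRUE)
}

tiny_params <- function() {
  mr_params(alpha = c(0.4, -0.1), beta = 0.25, delta_x = 0.8, delta_y = -0.6,
            sigma_x = 0.9, intercept = 0.3,
            u = c(0.1, -0.2, 0.05, 0.3, -0.15), x_impute = 0.7)
}

# small analysis-ready simulated dataset, fast to fit
small_dataset <- function(seed = 1, missing_rate = 0, alpha = 0.3, beta = 0.3,
                          n_pool = 500, n_analysis = 200) {
  simulate_dataset(
    mr_scenario(missing_rate = missing_rate, alpha_strength = alpha,
                beta_true = beta, n_pool = n_pool, n_analysis = n_analysis),
    seed = seed)
}
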