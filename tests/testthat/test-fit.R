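test_that("forward expression evaluates the additive model", {
  co <- integration_coefficients(alpha = 2.535, gamma = 4.347)  # beta absent
  expect_equal(forward_expression(1, 1, 1, co), 6.882)
  expect_equal(forward_expression(0, 5, 1, co), 0)     # A=0, beta absent -> T_B
  co2 <- integration_coefficients(alpha = 1, beta = 2, gamma = 3,
                                  basal_T_B = 7)
  b1 <- forward_expression(0.5, 0.25, 1, co2)
  b2 <- forward_expression(0.5, 0.25, 2, co2)
  expect_equal(b2 - 7, 2 * (b1 - 7))                   # linear in sigma
  expect_error(forward_expression(-1, 0, 1, co), "negative")
  # occupancy form divides by the bound-state partition
  co3 <- integration_coefficients(alpha = 1, beta = 2, gamma = 3,
                                  form = "occupancy")
  expect_equal(forward_expression(1, 1, 1, co3), (1 + 2 + 3) / 4)
})

test_that("AIC follows the Gaussian closed form and penalty structure", {
  expect_equal(compute_aic(10, 10, 2), 6)                    # 10*log(1) + 6
  expect_equal(compute_aic(5, 10, 3) - compute_aic(5, 10, 2), 2)
  expect_equal(compute_aic(4, 20, 2) - compute_aic(8, 20, 2), -20 * log(2))
  expect_warning(a0 <- compute_aic(0, 10, 2), "-Inf")
  expect_identical(a0, -Inf)
  # delta-AIC agrees with stats::AIC on nested linear models
  set.seed(3)
  d <- data.frame(x = rnorm(40), z = rnorm(40))
  d$y <- 1 + 2 * d$x + rnorm(40)
  m1 <- lm(y ~ x, d); m2 <- lm(y ~ x + z, d)
  ours <- compute_aic(sum(resid(m2)^2), 40, 3) -
    compute_aic(sum(resid(m1)^2), 40, 2)
  expect_equal(ours, AIC(m2) - AIC(m1), tolerance = 1e-10)
})

test_that("noise-free data refits to the generating coefficients exactly", {
  for (truth in ara_coefficients()) {
    tab <- make_steady_table(truth)
    fit <- fit_integration_model(tab, terms = c("alpha", "gamma"),
                                 fit_basal = FALSE)
    expect_true(fit$converged)
    expect_equal(fit$coefficients$alpha, truth$alpha, tolerance = 1e-6)
    expect_equal(fit$coefficients$gamma, truth$gamma, tolerance = 1e-6)
  }
})

test_that("additive NLS equals the closed-form OLS solution", {
  truth <- integration_coefficients(alpha = 1.5, beta = 0.4, gamma = 3,
                                    basal_T_B = 2)
  for (seed in 1:5) {
    tab <- make_steady_table(truth, noise_sdlog = 0.1, seed = seed)
    fit <- fit_integration_model(tab)          # alpha+beta+gamma+T_B
    ols <- ols_oracle(tab, c("alpha", "beta", "gamma"))
    est <- c(fit$coefficients$alpha, fit$coefficients$beta,
             fit$coefficients$gamma, fit$coefficients$basal_T_B)
    expect_equal(est, unname(ols), tolerance = 1e-8)
  }
})

test_that("significance flags follow the p-values and boundary levels", {
  tab <- make_steady_table(ara_coefficients()$ParaBAD, noise_sdlog = 0.02,
                           seed = 11)
  fit <- fit_integration_model(tab, terms = c("alpha", "gamma"),
                               fit_basal = FALSE)
  sig <- coefficient_significance(fit)
  expect_true(all(sig))                        # huge |t| on near-exact data
  expect_true(all(coefficient_significance(fit, level = 1)))
  expect_error(coefficient_significance(fit, level = 0), "level > 0")
})

test_that("an absent-input coefficient is usually insignificant and dropped", {
  truth <- ara_coefficients()$ParaBAD          # beta structurally zero
  n_rep <- 200
  insig <- logical(n_rep); reduced_wins <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    tab <- make_steady_table(truth, noise_sdlog = 0.05, seed = 5000 + s)
    full <- fit_integration_model(tab, terms = c("alpha", "beta", "gamma"),
                                  fit_basal = FALSE)
    insig[s] <- full$table["beta", "p.value"] > 0.05 &&
      abs(full$table["beta", "estimate"]) < 0.5
    cmp <- reduce_and_compare(tab, full)
    reduced_wins[s] <- length(cmp$dropped) > 0 &&
      cmp$reduced$aic <= full$aic
  }
  expect_gte(mean(insig), 0.9)
  expect_gte(mean(reduced_wins), 0.9)
})

test_that("a genuinely strong CRP-alone term is retained", {
  truth <- integration_coefficients(alpha = 2, beta = 5, gamma = 3)
  tab <- make_steady_table(truth, noise_sdlog = 0.05, seed = 77)
  full <- fit_integration_model(tab, fit_basal = FALSE)
  cmp <- reduce_and_compare(tab, full)
  expect_false("beta" %in% cmp$dropped)
  # all significant -> explicit no-reduction report
  expect_identical(cmp$selected, "no reduction")
  expect_identical(cmp$reduced, cmp$full)
})

test_that("degenerate designs raise a singular-fit error", {
  tab <- data.frame(A_star = 1, C_star = 1, sigma = 1,
                    expression = rnorm(20) + 5)
  expect_error(fit_integration_model(tab), "singular")
})

test_that("estimates tighten as noise shrinks", {
  truth <- ara_coefficients()$ParaE
  spread <- vapply(c(0.1, 0.05, 0.01), function(s) {
    est <- vapply(1:20, function(i) {
      tab <- make_steady_table(truth, noise_sdlog = s, seed = 300 * s * 1e4 + i)
      fit_integration_model(tab, terms = c("alpha", "gamma"),
                            fit_basal = FALSE)$coefficients$gamma
    }, numeric(1))
    c(sd = sd(est), bias = abs(mean(est) - truth$gamma))
  }, numeric(2))
  expect_true(all(diff(spread["sd", ]) < 0))
  expect_lt(spread["bias", 3], spread["bias", 1] + 0.02)
})

test_that("rescaling activities and coefficients leaves predictions invariant", {
  co <- integration_coefficients(alpha = 1.5, beta = 0.4, gamma = 3,
                                 basal_T_B = 2)
  cc <- 2.7
  co_scaled <- integration_coefficients(alpha = 1.5 / cc, beta = 0.4 / cc,
                                        gamma = 3 / cc^2, basal_T_B = 2)
  a <- runif(50, 0, 3); k <- runif(50, 0, 3); s <- runif(50, 0.5, 2)
  expect_equal(forward_expression(a, k, s, co),
               forward_expression(cc * a, cc * k, s, co_scaled),
               tolerance = 1e-12)
})

test_that("the occupancy form also recovers its generating parameters", {
  truth <- integration_coefficients(alpha = 6, beta = 2, gamma = 12,
                                    basal_T_B = 1, form = "occupancy")
  tab <- make_steady_table(truth)
  fit <- fit_integration_model(tab, form = "occupancy")
  expect_true(fit$converged)
  expect_equal(unname(fit$table[, "estimate"]), c(6, 2, 12, 1),
               tolerance = 1e-6)
})
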