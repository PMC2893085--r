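# Shared fixtures: a unit-span reporter calibration, a quiet default
# gradient, and a fit-ready noise-free steady-state table built from
# exact generator activities.

unit_cal <- function(cap = 50) reporter_calibration(1, 0.02, activity_cap = cap)

# Noise-free fit table for a coefficient set: exact activities from the
# dose-response map on the default 12 x 8 gradient, expression from the
# forward model (sigma = 1, basal = 0 unless the set says otherwise).
make_steady_table <- function(truth, dr = dose_response_map(),
                              design = gradient_design(),
                              noise_sdlog = 0, seed = NULL) {
  grid <- expand.grid(ara = design$arabinose_levels,
                      camp = design$camp_levels)
  act <- dr(grid$ara, grid$camp)
  df <- data.frame(A_star = act$A_star, C_star = act$C_star,
                   sigma = act$sigma)
  df$expression <- forward_expression(df$A_star, df$C_star, df$sigma, truth)
  if (noise_sdlog > 0) {
    if (!is.null(seed)) set.seed(seed)
    df$expression <- df$expression * rlnorm(nrow(df), 0, noise_sdlog)
  }
  df
}

# Closed-form OLS solution on the additive regressors (independent
# linear-algebra oracle for the NLS fit).
ols_oracle <- function(df, terms, fit_basal = TRUE) {
  reg <- list(alpha = df$sigma * df$A_star,
              beta = df$sigma * df$C_star,
              gamma = df$sigma * df$A_star * df$C_star)
  X <- do.call(cbind, reg[terms])
  if (fit_basal) X <- cbind(X, T_B = 1)
  qr.solve(crossprod(X), crossprod(X, df$expression))[, 1]
}
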