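test_that("loss rates combine dilution and degradation correctly", {
  expect_equal(loss_rate(loss_model(30)), log(2) / 30)          # ~0.02310
  expect_equal(loss_rate(loss_model(Inf)), 0)
  expect_equal(loss_rate(loss_model(30, k_deg = 0.0833,
                                    mode = "dilution_plus_degradation")),
               log(2) / 30 + 0.0833)
  # dilution_only ignores k_deg
  expect_equal(loss_rate(loss_model(30, k_deg = 5)), log(2) / 30)
  expect_error(loss_model(0), "> 0")
  expect_error(loss_model(-3), "> 0")
})

test_that("cell-cycle time is recovered from an exponential OD window", {
  t <- seq(0, 120, by = 4)
  od <- 0.05 * 2^(t / 27)
  expect_equal(estimate_tau(t, od), 27, tolerance = 1e-9)
  expect_error(estimate_tau(t, rev(od)), "non-positive growth")
})

const_profile <- function(a, c, s, times = seq(0, 200, by = 4)) {
  data.frame(time_min = times, A_star = a, C_star = c, sigma = s)
}

test_that("ODE solution matches the constant-input closed form", {
  co <- integration_coefficients(alpha = 2, beta = 1, gamma = 3,
                                 basal_T_B = 0.5)
  loss <- loss_model(30)
  mu <- loss_rate(loss)
  prof <- const_profile(1.2, 0.8, 1.5)
  prod <- forward_expression(1.2, 0.8, 1.5, co)
  bss <- prod / mu
  b0 <- 2
  traj <- integrate_expression(prof, co, loss, b0 = b0)
  closed <- bss + (b0 - bss) * exp(-mu * prof$time_min)
  expect_equal(traj$expression, closed, tolerance = 1e-6)

  # zero production, b0 > 0: pure exponential decay
  co0 <- integration_coefficients(alpha = 0, gamma = 0)
  dec <- integrate_expression(const_profile(1, 1, 1), co0, loss, b0 = 5)
  expect_equal(dec$expression, 5 * exp(-mu * dec$time_min), tolerance = 1e-6)

  # mu = 0 (infinite tau), constant production P, T_B = 0: linear growth
  coP <- integration_coefficients(alpha = 4)   # P = sigma * alpha * A = 4
  lin <- integrate_expression(const_profile(1, 0, 1), coP, loss_model(Inf),
                              b0 = 1)
  expect_equal(lin$expression, 1 + 4 * lin$time_min, tolerance = 1e-9)
})

test_that("halving the RK4 step shrinks the closed-form error at least 4-fold", {
  co <- integration_coefficients(alpha = 2, gamma = 3, basal_T_B = 0.5)
  loss <- loss_model(12)                       # faster dynamics, visible error
  mu <- loss_rate(loss)
  prof <- const_profile(1.2, 0.8, 1.5, times = seq(0, 200, by = 20))
  prod <- forward_expression(1.2, 0.8, 1.5, co)
  closed <- prod / mu + (10 - prod / mu) * exp(-mu * prof$time_min)
  err <- function(substeps) max(abs(
    integrate_expression(prof, co, loss, b0 = 10,
                         substeps = substeps)$expression - closed))
  expect_gt(err(1) / err(2), 4)
  expect_gt(err(2) / err(4), 4)
})

test_that("the integrator cross-checks against an adaptive ODE solver", {
  # time-varying drivers: a pulse plus a rise, solved independently by lsoda
  p <- pulse_params(onset_min = 40); r <- rise_params(onset_min = 50)
  times <- seq(0, 160, by = 4)
  prof <- data.frame(time_min = times,
                     A_star = arac_activity_rise(times, r),
                     C_star = crp_activity_pulse(times, p),
                     sigma = 1)
  co <- ara_coefficients()$ParaBAD
  loss <- loss_model(30)
  mu <- loss_rate(loss)
  ours <- integrate_expression(prof, co, loss, b0 = 0)
  fA <- approxfun(times, prof$A_star, rule = 2)
  fC <- approxfun(times, prof$C_star, rule = 2)
  ref <- deSolve::lsoda(
    y = c(B = 0), times = times,
    func = function(t, y, parms)
      list(1 * (co$alpha * fA(t) + co$gamma * fA(t) * fC(t)) - mu * y),
    rtol = 1e-10, atol = 1e-12)
  expect_equal(ours$expression, unname(ref[, "B"]), tolerance = 1e-6)
})

test_that("NaN driving signals are rejected with the offending time named", {
  prof <- const_profile(1, 1, 1, times = seq(0, 20, by = 4))
  prof$A_star[3] <- NaN
  co <- integration_coefficients(alpha = 1)
  expect_error(integrate_expression(prof, co, loss_model(30), b0 = 0),
               "A_star at time\\(s\\) 8")
})

test_that("CRP rise detection finds steps and is translation-equivariant", {
  t <- seq(0, 160, by = 4)
  flat <- rep(0.1, length(t))
  expect_true(is.na(detect_crp_rise(t, flat)))
  step <- ifelse(t >= 40, 2, 0.1) + 0.001 * sin(t)   # tiny baseline wiggle
  expect_equal(detect_crp_rise(t, step), 40)
  expect_equal(detect_crp_rise(t + 12, step), 52)
  expect_error(detect_crp_rise(t, rep(NA_real_, length(t))), "all-missing")
})

test_that("alignment brings jittered pulses into register and averages", {
  t <- seq(0, 200, by = 4)
  mk <- function(onset) {
    p <- pulse_params(onset_min = onset)
    data.frame(time_min = t,
               A_star = arac_activity_rise(t, rise_params(onset_min = onset + 10)),
               C_star = crp_activity_pulse(t, p),
               sigma = 1)
  }
  onsets <- c(48, 55, 62, 70, 53, 66, 58)
  reps <- lapply(onsets, mk)
  al <- align_and_average(reps)
  expect_length(al$shifts, 7)
  # peaks of the individual aligned replicates sit within one grid step
  peak_t <- vapply(seq_along(reps), function(i) {
    r <- reps[[i]]; r$time_min <- r$time_min - al$shifts[i]
    r$time_min[which.max(r$C_star)]
  }, numeric(1))
  expect_lte(diff(range(peak_t)), 4)

  # single replicate: average == shifted input on the overlapping grid
  one <- align_and_average(reps[1])
  r1 <- reps[[1]]; r1$time_min <- r1$time_min - one$shifts[1]
  keep <- r1$time_min %in% one$mean$time_min
  expect_equal(one$mean$C_star, r1$C_star[keep], tolerance = 1e-12)
  expect_true(all(one$mean$n == 1))

  # idempotence: identical replicates average to each input
  same <- align_and_average(reps[c(1, 1, 1)])
  expect_equal(same$mean$C_star, r1$C_star[keep], tolerance = 1e-12)

  # translation invariance: shifting every replicate by a constant changes nothing
  shifted <- lapply(reps, function(r) { r$time_min <- r$time_min + 36; r })
  al2 <- align_and_average(shifted)
  expect_equal(al2$mean, al$mean, tolerance = 1e-12)
})

test_that("prediction metrics behave on constructed cases", {
  t <- seq(0, 100, by = 4)
  y <- crp_activity_pulse(t, pulse_params(onset_min = 30)) + 0.5
  m <- evaluate_prediction(y, y, t)
  expect_equal(m$rmse, 0)
  expect_equal(m$peak_time_error_min, 0)
  expect_equal(m$magnitude_ratio, 1)
  m2 <- evaluate_prediction(y, 2 * y, t)       # observed two-fold higher
  expect_equal(m2$magnitude_ratio, 2)
  shift <- c(y[-(1:3)], rep(y[length(y)], 3))  # 12-min advance
  m3 <- evaluate_prediction(y, shift, t)
  expect_gt(m3$rmse, 0)
  expect_equal(m3$peak_time_error_min, 12)
  expect_equal(m3$magnitude_ratio, 1)
})
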