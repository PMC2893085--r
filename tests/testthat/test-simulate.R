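test_that("CRP pulse is baseline before onset and decays back, one peak", {
  p <- pulse_params(baseline = 0.2, amplitude = 3, onset_min = 40,
                    rise_min = 6, decay_min = 10)
  expect_equal(crp_activity_pulse(0, p), 0.2)
  expect_equal(crp_activity_pulse(40, p), 0.2)
  expect_lt(abs(crp_activity_pulse(500, p) - 0.2), 0.01 * 0.2 + 1e-9)
  expect_error(crp_activity_pulse(NaN, p), "non-finite")

  # brute-force scan: exactly one local maximum, inside (onset, onset+rise+3*decay)
  t <- seq(0, 200, by = 0.05)
  v <- crp_activity_pulse(t, p)
  d <- diff(v)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  expect_length(peaks, 1)
  expect_gt(t[peaks], 40)
  expect_lt(t[peaks], 40 + 6 + 3 * 10)
  expect_true(all(v >= 0))
})

test_that("AraC rise is monotone, bounded, and degenerate at rate 0", {
  p <- rise_params(baseline = 0.1, rate = 0.05, onset_min = 30, ceiling = 2)
  expect_equal(arac_activity_rise(c(0, 15, 30), p), rep(0.1, 3))
  t <- seq(0, 400, by = 0.5)
  v <- arac_activity_rise(t, p)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 2 + 1e-12))
  p0 <- rise_params(baseline = 0.7, rate = 0, onset_min = 10, ceiling = 2)
  expect_equal(arac_activity_rise(t, p0), rep(0.7, length(t)))
  expect_error(arac_activity_rise(Inf, p), "non-finite")
})

test_that("gradient plate has one well per combination and honours limits", {
  sim <- simulate_gradient_plate(gradient_design(), ara_coefficients()$ParaBAD,
                                 unit_cal(), unit_cal(),
                                 noise = noise_model(0, 0, seed = 1))
  expect_equal(nrow(sim$layout), 96)           # 12 arabinose x 8 cAMP
  expect_equal(length(unique(sim$plate$well)), 96)
  expect_error(gradient_design(arabinose_levels = seq(0, 0.2, length.out = 13)),
               "96")
  expect_error(gradient_design(camp_levels = c(-0.1, 0.5)), "negative")
})

test_that("noise-free gradient promoter channel equals the forward model", {
  truth <- ara_coefficients()$ParaE
  sim <- simulate_gradient_plate(gradient_design(), truth, unit_cal(),
                                 unit_cal(), noise = noise_model(0, 0, 1),
                                 promoter_id = "ParaE")
  ex <- plate_expression(sim$plate)
  prom <- ex[ex$reporter_id == "ParaE" & ex$time_min == 44, ]
  want <- forward_expression(sim$truth$A_star, sim$truth$C_star,
                             sim$truth$sigma, truth)
  got <- prom$expression[match(sim$truth$well, prom$well)]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("same seed gives identical datasets, different seeds differ", {
  args <- list(gradient_design(), ara_coefficients()$ParaBAD, unit_cal(),
               unit_cal())
  s1 <- do.call(simulate_gradient_plate, c(args, list(noise = noise_model(seed = 42))))
  s2 <- do.call(simulate_gradient_plate, c(args, list(noise = noise_model(seed = 42))))
  s3 <- do.call(simulate_gradient_plate, c(args, list(noise = noise_model(seed = 43))))
  expect_identical(s1$plate, s2$plate)
  expect_false(identical(s1$plate$value, s3$plate$value))
  # byte-for-byte after serialization
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_plate_csv(s1$plate, f1); write_plate_csv(s2$plate, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("noise-free reporter channels invert to the true activities", {
  cal <- unit_cal()
  sim <- simulate_gradient_plate(gradient_design(), ara_coefficients()$ParaBAD,
                                 cal, cal, noise = noise_model(0, 0, 1))
  tab <- steady_state_table(sim$plate, sim$layout, cal, cal, "ParaBAD")
  tab <- tab[match(sim$truth$well, tab$well), ]
  below_cap <- sim$truth$A_star < cal$activity_cap
  expect_equal(tab$A_star[below_cap], sim$truth$A_star[below_cap],
               tolerance = 1e-9)
  expect_equal(tab$C_star, sim$truth$C_star, tolerance = 1e-9)
  expect_equal(tab$sigma, sim$truth$sigma, tolerance = 1e-12)
})

test_that("diauxic replicates have distinct, jittered exhaustion times", {
  dia <- simulate_diauxic_experiment(diauxic_scenario(n_replicates = 7),
                                     noise = noise_model(0, 0, seed = 5))
  ex <- vapply(dia$replicates, `[[`, numeric(1), "exhaustion_min")
  expect_length(ex, 7)
  expect_equal(length(unique(ex)), 7)
  expect_true(all(abs(ex - 60) <= 12))
  expect_error(diauxic_scenario(exhaustion_time_min = 5, jitter_min = 10),
               "non-positive")
})

test_that("flat scenario relaxes each promoter to its basal steady state", {
  scn <- diauxic_scenario(
    n_replicates = 1,
    crp_pulse = pulse_params(baseline = 0, amplitude = 0),
    arac_rise = rise_params(baseline = 0, rate = 0),
    horizon_min = 400)
  truth <- list(ParaBAD = integration_coefficients(alpha = 2.535,
                                                   gamma = 4.347,
                                                   basal_T_B = 3))
  dia <- simulate_diauxic_experiment(scn, truth = truth,
                                     noise = noise_model(0, 0, seed = 1))
  mu <- loss_rate(loss_model(30))
  b <- dia$replicates[[1]]$truth_profile$ParaBAD
  expect_equal(b, rep(3 / mu, length(b)), tolerance = 1e-9)
})

test_that("noise-off diauxic promoter channels are self-consistent with the ODE", {
  cal <- unit_cal()
  dia <- simulate_diauxic_experiment(diauxic_scenario(n_replicates = 2),
                                     cal_A = cal, cal_C = cal,
                                     noise = noise_model(0, 0, seed = 9))
  loss <- ara_loss_models(30)
  for (r in dia$replicates) {
    prof <- r$truth_profile
    for (pid in names(ara_coefficients())) {
      co <- ara_coefficients()[[pid]]
      mu <- loss_rate(loss[[pid]])
      redo <- integrate_expression(prof[, c("time_min", "A_star", "C_star",
                                            "sigma")],
                                   co, loss[[pid]], b0 = co$basal_T_B / mu)
      expect_equal(redo$expression, prof[[pid]], tolerance = 1e-12)
    }
  }
})
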