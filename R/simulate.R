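#' Reference input-integration coefficients for the arabinose regulon
#'
#' The fitted coefficient sets reported for the four arabinose catabolic
#' promoters (AraC-alone term `alpha` and joint term `gamma`; the
#' CRP-alone term `beta` was insignificant at every promoter and is
#' structurally absent). These serve as the default ground truth for the
#' synthetic-data generator and for parameter-recovery studies.
#'
#' @param basal_T_B basal transcription given to every set (default 0).
#' @return Named list of [integration_coefficients()] for `ParaBAD`,
#'   `ParaC`, `ParaE`, `ParaFGH`.
#' @export
#' @examples
#' ara_coefficients()$ParaBAD
ara_coefficients <- function(basal_T_B = 0) {
  list(
    ParaBAD = integration_coefficients(alpha = 2.535, gamma = 4.347,
                                       basal_T_B = basal_T_B),
    ParaC   = integration_coefficients(alpha = 1.656, gamma = 1.078,
                                       basal_T_B = basal_T_B),
    ParaE   = integration_coefficients(alpha = 1.684, gamma = 7.726,
                                       basal_T_B = basal_T_B),
    ParaFGH = integration_coefficients(alpha = 0.6546, gamma = 3.344,
                                       basal_T_B = basal_T_B))
}

#' Default loss models per promoter
#'
#' Dilution-only loss for the catabolic gene products (long-lived
#' relative to the cell cycle); dilution plus degradation for AraC, whose
#' reported degradation constant is 0.0833 per minute.
#'
#' @param tau_min cell-cycle time, minutes (default 30).
#' @return Named list of [loss_model()]s for the four promoters.
#' @export
ara_loss_models <- function(tau_min = 30) {
  list(
    ParaBAD = loss_model(tau_min),
    ParaC   = loss_model(tau_min, k_deg = 0.0833,
                         mode = "dilution_plus_degradation"),
    ParaE   = loss_model(tau_min),
    ParaFGH = loss_model(tau_min))
}

#' Parameters of the transient CRP-cAMP activity pulse
#'
#' At glucose exhaustion CRP-cAMP activity shows a strong transient peak
#' and rapidly returns to baseline. The pulse here is a phenomenological
#' stand-in with independent rise and decay scales:
#' `baseline + amplitude * (1 - exp(-(t-onset)/rise)) *
#' exp(-max(0, t-onset-rise)/decay)`.
#'
#' @param baseline resting activity, `>= 0` (default 0.1).
#' @param amplitude peak excess over baseline, `>= 0` (default 3).
#' @param onset_min pulse onset, minutes. In a diauxic scenario this is
#'   an offset relative to the replicate's glucose-exhaustion time
#'   (default 0 = at exhaustion).
#' @param rise_min rise time scale, minutes, `> 0` (default 6).
#' @param decay_min decay time scale, minutes, `> 0` (default 10).
#' @return An object of class `pulse_params`.
#' @export
pulse_params <- function(baseline = 0.1, amplitude = 3, onset_min = 0,
                         rise_min = 6, decay_min = 10) {
  stopifnot(baseline >= 0, amplitude >= 0, rise_min > 0, decay_min > 0,
            is.finite(onset_min))
  structure(list(baseline = baseline, amplitude = amplitude,
                 onset_min = onset_min, rise_min = rise_min,
                 decay_min = decay_min), class = "pulse_params")
}

#' Parameters of the post-shift AraC-arabinose activity rise
#'
#' After the drop in CRP-cAMP activity, AraC-arabinose activity rises
#' exponentially toward a ceiling:
#' `baseline + (ceiling - baseline) * (1 - exp(-rate*(t-onset)))`.
#' `rate = 0` leaves the baseline unchanged for all times.
#'
#' @param baseline pre-induction activity, `>= 0` (default 0.05).
#' @param rate rise rate, per minute, `>= 0` (default 0.05).
#' @param onset_min onset, minutes; in a diauxic scenario relative to the
#'   replicate's exhaustion time (default 10, after the cAMP peak).
#' @param ceiling asymptotic activity cap (default 2.5).
#' @return An object of class `rise_params`.
#' @export
rise_params <- function(baseline = 0.05, rate = 0.05, onset_min = 10,
                        ceiling = 2.5) {
  stopifnot(baseline >= 0, rate >= 0, ceiling >= baseline,
            is.finite(onset_min))
  structure(list(baseline = baseline, rate = rate, onset_min = onset_min,
                 ceiling = ceiling), class = "rise_params")
}

#' CRP-cAMP pulse activity at given times
#'
#' @param t times, minutes, `>= 0`; vectorized.
#' @param p a [pulse_params()].
#' @return Activity values; equal to `p$baseline` for `t <= onset`, with
#'   a single maximum after onset and decay back toward baseline.
#' @export
crp_activity_pulse <- function(t, p) {
  stopifnot(inherits(p, "pulse_params"), is.numeric(t))
  if (any(!is.finite(t))) stop("non-finite time rejected")
  if (any(t < 0)) stop("negative time rejected")
  dt <- t - p$onset_min
  up <- 1 - exp(-pmax(dt, 0) / p$rise_min)
  down <- exp(-pmax(dt - p$rise_min, 0) / p$decay_min)
  p$baseline + p$amplitude * up * down
}

#' AraC-arabinose rise activity at given times
#'
#' @param t times, minutes, `>= 0`; vectorized.
#' @param p a [rise_params()].
#' @return Activity values; non-decreasing in `t`, equal to the baseline
#'   before onset, bounded by the ceiling.
#' @export
arac_activity_rise <- function(t, p) {
  stopifnot(inherits(p, "rise_params"), is.numeric(t))
  if (any(!is.finite(t))) stop("non-finite time rejected")
  if (any(t < 0)) stop("negative time rejected")
  dt <- pmax(t - p$onset_min, 0)
  p$baseline + (p$ceiling - p$baseline) * (1 - exp(-p$rate * dt))
}

#' Measurement-noise model for simulated plates
#'
#' Multiplicative lognormal noise on luminescence (counts per second) and
#' additive Gaussian noise on OD600 (floored at a small positive value).
#' Both sigmas zero reproduces the noise-free forward model exactly; the
#' same seed reproduces the identical dataset.
#'
#' @param lum_lognormal_sigma sdlog of the lognormal factor on CPS,
#'   `>= 0` (default 0.05).
#' @param od_gaussian_sd additive SD on OD600, `>= 0` (default 0.002).
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(lum_lognormal_sigma = 0.05, od_gaussian_sd = 0.002,
                        seed = 1L) {
  stopifnot(lum_lognormal_sigma >= 0, od_gaussian_sd >= 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(lum_lognormal_sigma = lum_lognormal_sigma,
                 od_gaussian_sd = od_gaussian_sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' Arabinose x cAMP gradient design
#'
#' A combinatorial steady-state gradient: arabinose 0-0.2 percent (w/v)
#' crossed with cAMP 0-1 mM, at most 96 wells, read at 4-minute
#' intervals.
#'
#' @param arabinose_levels percent w/v, non-negative, within `[0, 0.2]`
#'   (default 12 levels).
#' @param camp_levels mM, non-negative, within `[0, 1]` (default
#'   8 levels).
#' @param read_interval_min minutes between reads (default 4).
#' @param horizon_min total read duration (default 90).
#' @param steady_time_min the read treated as steady state (default 44).
#' @return An object of class `gradient_design`.
#' @export
gradient_design <- function(arabinose_levels = seq(0, 0.2, length.out = 12),
                            camp_levels = seq(0, 1, length.out = 8),
                            read_interval_min = 4, horizon_min = 90,
                            steady_time_min = 44) {
  stopifnot(is.numeric(arabinose_levels), is.numeric(camp_levels),
            read_interval_min > 0, horizon_min >= read_interval_min)
  if (any(arabinose_levels < 0) || any(camp_levels < 0))
    stop("negative concentrations rejected")
  if (any(arabinose_levels > 0.2) || any(camp_levels > 1))
    stop("levels outside the assay ranges (arabinose 0-0.2%, cAMP 0-1 mM)")
  arabinose_levels <- sort(arabinose_levels)
  camp_levels <- sort(camp_levels)
  if (length(arabinose_levels) * length(camp_levels) > 96L)
    stop("more than 96 arabinose x cAMP combinations do not fit one plate")
  structure(list(arabinose_levels = arabinose_levels,
                 camp_levels = camp_levels,
                 read_interval_min = read_interval_min,
                 horizon_min = horizon_min,
                 steady_time_min = steady_time_min),
            class = "gradient_design")
}

#' Dose-response map from inducer concentrations to activities
#'
#' The generator's ground-truth mapping from (arabinose, cAMP) to
#' activities. AraC-arabinose responds in a step-like manner, modelled as
#' a Hill function `A* = a_max * (ara / (K_a + ara))^h` with a steep
#' default `h = 4`; CRP-cAMP responds gradedly,
#' `C* = c_max * cAMP / (K_c + cAMP)`; polymerase activity `sigma` is
#' constant. Defaults span activities roughly 0-3.
#'
#' @param a_max,K_a,h AraC branch: maximum activity, half-saturation
#'   (percent w/v) and Hill steepness (defaults 3, 0.02, 4).
#' @param c_max,K_c CRP branch: maximum activity and half-saturation
#'   (mM) (defaults 3, 0.25).
#' @param sigma_level constant polymerase expression, CPS/OD (default 1).
#' @return A function `(arabinose_percent, camp_mM) -> list(A_star,
#'   C_star, sigma)`, with the parameters attached as an attribute.
#' @export
dose_response_map <- function(a_max = 3, K_a = 0.02, h = 4,
                              c_max = 3, K_c = 0.25, sigma_level = 1) {
  stopifnot(a_max >= 0, K_a > 0, h > 0, c_max >= 0, K_c > 0,
            sigma_level > 0)
  f <- function(arabinose_percent, camp_mM) {
    list(A_star = a_max * (arabinose_percent / (K_a + arabinose_percent))^h,
         C_star = c_max * camp_mM / (K_c + camp_mM),
         sigma = rep_len(sigma_level,
                         max(length(arabinose_percent), length(camp_mM))))
  }
  attr(f, "params") <- list(a_max = a_max, K_a = K_a, h = h, c_max = c_max,
                            K_c = K_c, sigma_level = sigma_level)
  f
}

# Run `expr` under the noise model's seed without disturbing the
# caller's RNG state.
with_noise_seed <- function(noise, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(noise$seed)
  force(expr)
}

# Shared logistic OD curve used by the gradient generator (no
# growth-expression feedback; expression rides on top of it).
logistic_od <- function(t, od0 = 0.1, od_max = 0.6, tau_min = 30) {
  r <- log(2) / tau_min
  od_max * od0 / (od0 + (od_max - od0) * exp(-r * t))
}

plate_well_names <- function(n_rows, n_cols) {
  outer(LETTERS[seq_len(n_rows)], seq_len(n_cols), paste0)
}

#' Simulate a steady-state gradient plate
#'
#' Generates one well per (arabinose, cAMP) combination. True activities
#' come from the dose-response map; the promoter channel is the additive
#' (or occupancy) forward model of those activities, the synARA / synCRP
#' channels are the repression model of `A*` / `C*`, and the
#' synRNAP-s70 channel reads the constant polymerase expression.
#' Expression is held at its steady value over the whole read window, so
#' any single read (the 44-minute read by convention) is the steady
#' state. Luminescence is emitted as CPS = expression x OD with optional
#' lognormal noise; OD600 follows a shared logistic curve with optional
#' Gaussian noise. Ground-truth activities are returned for recovery
#' tests.
#'
#' @param design a [gradient_design()].
#' @param truth an [integration_coefficients()] ground truth for the
#'   promoter channel.
#' @param cal_A,cal_C [reporter_calibration()]s for the synARA and
#'   synCRP channels.
#' @param dose_response a [dose_response_map()] (or compatible function).
#' @param noise a [noise_model()].
#' @param promoter_id name for the promoter channel (default
#'   `"ParaBAD"`).
#' @return List: `plate` (long data frame `well`, `time_min`,
#'   `channel` in OD600/CPS, `reporter_id`, `value`), `layout`
#'   (`well`, `arabinose_percent`, `camp_mM`), `truth`
#'   (per-well `A_star`, `C_star`, `sigma`), and `design`.
#' @export
simulate_gradient_plate <- function(design, truth, cal_A, cal_C,
                                    dose_response = dose_response_map(),
                                    noise = noise_model(),
                                    promoter_id = "ParaBAD") {
  stopifnot(inherits(design, "gradient_design"),
            inherits(truth, "integration_coefficients"),
            inherits(cal_A, "reporter_calibration"),
            inherits(cal_C, "reporter_calibration"),
            is.function(dose_response), inherits(noise, "noise_model"))
  na <- length(design$arabinose_levels)
  nc <- length(design$camp_levels)
  wells <- as.vector(plate_well_names(nc, na))   # rows = cAMP, cols = ara
  layout <- data.frame(
    well = wells,
    arabinose_percent = rep(design$arabinose_levels, each = nc),
    camp_mM = rep(design$camp_levels, times = na))
  act <- dose_response(layout$arabinose_percent, layout$camp_mM)
  truth_df <- data.frame(well = layout$well,
                         arabinose_percent = layout$arabinose_percent,
                         camp_mM = layout$camp_mM,
                         A_star = act$A_star, C_star = act$C_star,
                         sigma = act$sigma)
  times <- seq(0, design$horizon_min, by = design$read_interval_min)
  expr <- list(
    promoter = forward_expression(act$A_star, act$C_star, act$sigma, truth),
    synARA = repression_forward(act$A_star, cal_A),
    synCRP = repression_forward(act$C_star, cal_C),
    synRNAP_s70 = act$sigma)
  names(expr)[1] <- promoter_id
  od_clean <- logistic_od(times)
  nw <- nrow(layout); nt <- length(times)
  plate <- with_noise_seed(noise, {
    do.call(rbind, lapply(names(expr), function(rid) {
      cps_clean <- outer(od_clean, expr[[rid]])          # time x well
      cps <- if (noise$lum_lognormal_sigma > 0)
        cps_clean * matrix(rlnorm(nt * nw, 0, noise$lum_lognormal_sigma),
                           nt, nw) else cps_clean
      od <- matrix(od_clean, nt, nw)
      if (noise$od_gaussian_sd > 0)
        od <- pmax(od + matrix(rnorm(nt * nw, 0, noise$od_gaussian_sd),
                               nt, nw), 1e-4)
      data.frame(
        well = rep(layout$well, each = nt, times = 2),
        time_min = rep(times, times = 2 * nw),
        channel = rep(c("OD600", "CPS"), each = nt * nw),
        reporter_id = rid,
        value = c(as.vector(od), as.vector(cps)))
    }))
  })
  list(plate = plate, layout = layout, truth = truth_df, design = design)
}

#' Diauxic-shift scenario
#'
#' Describes a set of replicate diauxic-shift experiments: glucose runs
#' out at `exhaustion_time_min` (jittered independently per replicate
#' within `jitter_min`), CRP-cAMP activity pulses at exhaustion, and
#' AraC-arabinose activity rises afterwards.
#'
#' @param n_replicates number of replicate experiments (default 7).
#' @param exhaustion_time_min nominal glucose-exhaustion time, minutes
#'   (default 60).
#' @param jitter_min half-width of the uniform exhaustion-time jitter
#'   (default 12).
#' @param crp_pulse a [pulse_params()]; its onset is relative to each
#'   replicate's exhaustion time.
#' @param arac_rise a [rise_params()]; onset likewise relative.
#' @param sigma_level constant polymerase expression (default 1).
#' @param tau_min cell-cycle time for the generated OD curve (default
#'   30).
#' @param read_interval_min read spacing (default 4).
#' @param horizon_min duration (default 180, a three-hour assay).
#' @return An object of class `diauxic_scenario`.
#' @export
diauxic_scenario <- function(n_replicates = 7, exhaustion_time_min = 60,
                             jitter_min = 12, crp_pulse = pulse_params(),
                             arac_rise = rise_params(), sigma_level = 1,
                             tau_min = 30, read_interval_min = 4,
                             horizon_min = 180) {
  stopifnot(n_replicates >= 1, exhaustion_time_min > 0, jitter_min >= 0,
            inherits(crp_pulse, "pulse_params"),
            inherits(arac_rise, "rise_params"),
            sigma_level > 0, tau_min > 0, read_interval_min > 0,
            horizon_min > read_interval_min)
  if (exhaustion_time_min - jitter_min <= 0)
    stop("jitter window allows non-positive exhaustion times")
  structure(list(n_replicates = as.integer(n_replicates),
                 exhaustion_time_min = exhaustion_time_min,
                 jitter_min = jitter_min, crp_pulse = crp_pulse,
                 arac_rise = arac_rise, sigma_level = sigma_level,
                 tau_min = tau_min, read_interval_min = read_interval_min,
                 horizon_min = horizon_min), class = "diauxic_scenario")
}

# OD with a diauxic lag: exponential to the exhaustion point, a flat lag,
# then renewed exponential growth, capped.
diauxic_od <- function(t, exhaustion_min, tau_min, od0 = 0.05,
                       lag_min = 20, od_cap = 1.2) {
  r <- log(2) / tau_min
  od_ex <- od0 * exp(r * exhaustion_min)
  od <- ifelse(t <= exhaustion_min, od0 * exp(r * t),
        ifelse(t <= exhaustion_min + lag_min, od_ex,
               od_ex * exp(r * (t - exhaustion_min - lag_min))))
  pmin(od, od_cap)
}

#' Simulate replicate diauxic-shift experiments
#'
#' For each replicate, a jittered exhaustion time positions the CRP-cAMP
#' pulse and the subsequent AraC-arabinose rise; reporter channels follow
#' the repression model of those true activities, and each promoter
#' channel is obtained by integrating the production/dilution ODE with
#' its ground-truth coefficients and loss model. Ground-truth activity
#' and expression trajectories are retained per replicate.
#'
#' @param scenario a [diauxic_scenario()].
#' @param truth named list of [integration_coefficients()], one per
#'   promoter (default [ara_coefficients()]).
#' @param loss named list of [loss_model()]s matching `truth` (default
#'   [ara_loss_models()] with the scenario's `tau_min`).
#' @param cal_A,cal_C [reporter_calibration()]s for synARA / synCRP.
#' @param noise a [noise_model()].
#' @return List with `replicates` — per replicate a list of
#'   `truth_profile` (data frame `time_min`, `A_star`, `C_star`,
#'   `sigma`, plus `<promoter>` true-expression columns),
#'   `plate` (long data frame as in [simulate_gradient_plate()]) and
#'   `exhaustion_min` — plus the `scenario`.
#' @export
simulate_diauxic_experiment <- function(scenario,
                                        truth = ara_coefficients(),
                                        loss = NULL,
                                        cal_A = reporter_calibration(1, 0.02),
                                        cal_C = reporter_calibration(1, 0.02),
                                        noise = noise_model()) {
  stopifnot(inherits(scenario, "diauxic_scenario"), is.list(truth),
            length(truth) >= 1, !is.null(names(truth)))
  if (is.null(loss)) {
    loss <- ara_loss_models(scenario$tau_min)[names(truth)]
    if (any(vapply(loss, is.null, logical(1))))
      loss <- setNames(rep(list(loss_model(scenario$tau_min)),
                           length(truth)), names(truth))
  }
  stopifnot(identical(sort(names(truth)), sort(names(loss))))
  times <- seq(0, scenario$horizon_min, by = scenario$read_interval_min)
  nt <- length(times)
  with_noise_seed(noise, {
    ex <- scenario$exhaustion_time_min +
      runif(scenario$n_replicates, -scenario$jitter_min, scenario$jitter_min)
    replicates <- lapply(seq_len(scenario$n_replicates), function(r) {
      pulse_r <- scenario$crp_pulse
      pulse_r$onset_min <- pulse_r$onset_min + ex[r]
      rise_r <- scenario$arac_rise
      rise_r$onset_min <- rise_r$onset_min + ex[r]
      A <- arac_activity_rise(times, rise_r)
      C <- crp_activity_pulse(times, pulse_r)
      S <- rep(scenario$sigma_level, nt)
      prof <- data.frame(time_min = times, A_star = A, C_star = C,
                         sigma = S)
      expr <- list(synARA = repression_forward(A, cal_A),
                   synCRP = repression_forward(C, cal_C),
                   synRNAP_s70 = S)
      for (pid in names(truth)) {
        mu <- loss_rate(loss[[pid]])
        traj <- integrate_expression(prof, truth[[pid]], loss[[pid]],
                                     b0 = truth[[pid]]$basal_T_B / max(mu, 1e-12))
        prof[[pid]] <- traj$expression
        expr[[pid]] <- traj$expression
      }
      od_clean <- diauxic_od(times, ex[r], scenario$tau_min)
      plate <- do.call(rbind, lapply(names(expr), function(rid) {
        cps <- expr[[rid]] * od_clean
        if (noise$lum_lognormal_sigma > 0)
          cps <- cps * rlnorm(nt, 0, noise$lum_lognormal_sigma)
        od <- od_clean
        if (noise$od_gaussian_sd > 0)
          od <- pmax(od + rnorm(nt, 0, noise$od_gaussian_sd), 1e-4)
        data.frame(
          well = sprintf("R%02d", r),
          time_min = rep(times, 2),
          channel = rep(c("OD600", "CPS"), each = nt),
          reporter_id = rid,
          value = c(od, cps))
      }))
      list(truth_profile = prof, plate = plate, exhaustion_min = ex[r])
    })
    list(replicates = replicates, scenario = scenario)
  })
}
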