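#' Protein loss model: dilution and optional degradation
#'
#' During exponential growth a stable protein is lost mainly by dilution,
#' at rate `ln(2) / tau` for cell-cycle time `tau`. For short-lived
#' proteins (AraC has a measured degradation constant of 0.0833 per
#' minute) first-order degradation is added on top.
#'
#' @param tau_min cell-cycle (doubling) time in minutes, `> 0`
#'   (may be `Inf` for a non-growing culture).
#' @param k_deg first-order degradation constant, per minute, `>= 0`;
#'   ignored under `"dilution_only"`.
#' @param mode `"dilution_only"` (default) or
#'   `"dilution_plus_degradation"`.
#' @return An object of class `loss_model`.
#' @seealso [loss_rate()], [estimate_tau()]
#' @export
loss_model <- function(tau_min, k_deg = 0,
                       mode = c("dilution_only", "dilution_plus_degradation")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(tau_min), length(tau_min) == 1L,
            is.numeric(k_deg), length(k_deg) == 1L, is.finite(k_deg))
  if (is.na(tau_min) || tau_min <= 0) stop("'tau_min' must be > 0")
  if (k_deg < 0) stop("'k_deg' must be >= 0")
  structure(list(tau_min = tau_min, k_deg = k_deg, mode = mode),
            class = "loss_model")
}

#' First-order loss rate of a loss model
#'
#' `mu = ln(2) / tau` (dilution only) or `ln(2) / tau + k_deg`
#' (dilution plus degradation), per minute.
#'
#' @param loss a [loss_model()].
#' @return Loss rate `mu`, per minute.
#' @export
#' @examples
#' loss_rate(loss_model(tau_min = 30))  # log(2)/30 ~ 0.0231
loss_rate <- function(loss) {
  stopifnot(inherits(loss, "loss_model"))
  mu <- log(2) / loss$tau_min
  if (loss$mode == "dilution_plus_degradation") mu <- mu + loss$k_deg
  mu
}

#' Estimate cell-cycle time from an OD time course
#'
#' Log-linear regression of `log(OD)` on time over an exponential-phase
#' window; the doubling time is `ln(2)` over the fitted slope.
#'
#' @param time_min time grid, minutes.
#' @param od OD600 readings, same length.
#' @param window optional `c(t_start, t_end)` restricting the regression
#'   to an exponential window (default: the whole series).
#' @return Cell-cycle time in minutes.
#' @export
estimate_tau <- function(time_min, od, window = range(time_min)) {
  stopifnot(is.numeric(time_min), is.numeric(od),
            length(time_min) == length(od), length(window) == 2L)
  keep <- is.finite(od) & od > 0 & time_min >= window[1] & time_min <= window[2]
  if (sum(keep) < 3L) stop("need at least 3 positive OD readings in the window")
  slope <- coef(lm(log(od[keep]) ~ time_min[keep]))[[2]]
  if (slope <= 0) stop("non-positive growth rate in the chosen window")
  log(2) / slope
}

# Piecewise-linear interpolant of a driving signal; errors on NaN,
# naming the offending time.
driver_fun <- function(time_min, value, name) {
  bad <- !is.finite(value)
  if (any(bad))
    stop(sprintf("non-finite %s at time(s) %s min", name,
                 paste(time_min[bad], collapse = ", ")))
  function(t) approx(time_min, value, xout = t, rule = 2)$y
}

#' Integrate promoter expression driven by measured activities
#'
#' Solves `dB/dt = sigma(t) * (alpha*A(t) + beta*C(t) + gamma*A(t)*C(t))
#' + T_B - mu*B` over the profile's time grid, where the driving signals
#' `A*`, `C*`, `sigma` are the measured activity profile interpolated
#' linearly between readings. Fixed-step classical Runge-Kutta (RK4),
#' sub-stepped `substeps` times per grid interval; the drivers are
#' piecewise-linear measurements and the loss rates involved are small, so
#' a fixed-step non-stiff solver is appropriate.
#'
#' @param profile data frame with columns `time_min` (strictly
#'   increasing), `A_star`, `C_star`, `sigma`.
#' @param coeffs an [integration_coefficients()] object.
#' @param loss a [loss_model()].
#' @param b0 initial expression (default: `T_B / mu` steady state; the
#'   usual alternative is the first observed expression value).
#' @param substeps RK4 sub-steps per grid interval (default 4).
#' @return Data frame `time_min`, `expression` on the profile's grid,
#'   non-negative.
#' @export
integrate_expression <- function(profile, coeffs, loss, b0 = NULL,
                                 substeps = 4L) {
  stopifnot(inherits(coeffs, "integration_coefficients"),
            inherits(loss, "loss_model"),
            all(c("time_min", "A_star", "C_star", "sigma") %in% names(profile)),
            substeps >= 1L)
  tt <- profile$time_min
  if (any(diff(tt) <= 0)) stop("profile time grid must be strictly increasing")
  mu <- loss_rate(loss)
  fA <- driver_fun(tt, profile$A_star, "A_star")
  fC <- driver_fun(tt, profile$C_star, "C_star")
  fS <- driver_fun(tt, profile$sigma, "sigma")
  val <- function(v) if (is.null(v)) 0 else v
  production <- function(t) {
    a <- fA(t); cc <- fC(t)
    num <- val(coeffs$alpha) * a + val(coeffs$beta) * cc +
      val(coeffs$gamma) * a * cc
    if (coeffs$form == "occupancy") num <- num / (1 + a + cc + a * cc)
    fS(t) * num + coeffs$basal_T_B
  }
  deriv <- function(t, B) production(t) - mu * B
  if (is.null(b0)) b0 <- coeffs$basal_T_B / max(mu, .Machine$double.eps)
  stopifnot(is.numeric(b0), length(b0) == 1L, b0 >= 0)

  B <- numeric(length(tt))
  B[1] <- b0
  for (i in seq_len(length(tt) - 1L)) {
    h <- (tt[i + 1L] - tt[i]) / substeps
    b <- B[i]
    t0 <- tt[i]
    for (s in seq_len(substeps)) {
      k1 <- deriv(t0, b)
      k2 <- deriv(t0 + h / 2, b + h * k1 / 2)
      k3 <- deriv(t0 + h / 2, b + h * k2 / 2)
      k4 <- deriv(t0 + h, b + h * k3)
      b <- b + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
      t0 <- t0 + h
    }
    B[i + 1L] <- max(b, 0)
  }
  data.frame(time_min = tt, expression = B)
}

#' Detect the onset of a CRP-cAMP activity rise
#'
#' Glucose exhaustion announces itself as a sharp rise in CRP-cAMP
#' activity. The onset is the first time at which `C*` exceeds the
#' baseline mean plus `k_sd` baseline standard deviations for at least
#' `persistence` consecutive readings, with the baseline taken from the
#' first `baseline_window` points.
#'
#' @param time_min time grid, minutes.
#' @param c_star CRP-cAMP activity series, same length.
#' @param baseline_window number of initial points defining the baseline
#'   (default 5).
#' @param k_sd threshold multiplier on the baseline SD (default 3).
#' @param persistence consecutive supra-threshold readings required
#'   (default 2).
#' @return Onset time in minutes, or `NA` if no rise is found.
#' @export
detect_crp_rise <- function(time_min, c_star, baseline_window = 5L,
                            k_sd = 3, persistence = 2L) {
  stopifnot(is.numeric(time_min), is.numeric(c_star),
            length(time_min) == length(c_star))
  if (all(is.na(c_star))) stop("all-missing activity series")
  n <- length(c_star)
  if (n <= baseline_window + 2L)
    stop("series too short for the chosen baseline window")
  base <- c_star[seq_len(baseline_window)]
  thr <- mean(base, na.rm = TRUE) + k_sd * sd(base, na.rm = TRUE)
  above <- !is.na(c_star) & c_star > thr
  run <- 0L
  for (i in seq.int(baseline_window + 1L, n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= persistence) return(time_min[i - persistence + 1L])
  }
  NA_real_
}

#' Align diauxic-shift replicates on the CRP rise and average
#'
#' Glucose-exhaustion timing varies between experiments, so each
#' replicate is shifted so that time zero sits `offset_min` minutes
#' before its detected CRP-cAMP rise; replicates are then resampled onto
#' a common grid by linear interpolation and averaged pointwise.
#' Replicates without a detectable rise are dropped with a warning.
#'
#' @param replicates list of data frames, each with `time_min`, `A_star`,
#'   `C_star`, `sigma`, plus any extra numeric columns (e.g. promoter
#'   expression channels); all numeric columns are aligned and averaged.
#' @param offset_min minutes of pre-rise context kept before time zero
#'   (default 20).
#' @param step_min common grid spacing (default: the first replicate's
#'   median spacing).
#' @param ... passed to [detect_crp_rise()].
#' @return List with `mean` (data frame on the common grid: `time_min`,
#'   averaged columns, and `n` replicates contributing per point) and
#'   `shifts` (per-replicate time shifts applied, minutes).
#' @export
align_and_average <- function(replicates, offset_min = 20, step_min = NULL,
                              ...) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  rises <- vapply(replicates, function(r)
    detect_crp_rise(r$time_min, r$C_star, ...), numeric(1))
  keep <- !is.na(rises)
  if (!any(keep)) stop("no replicate with a detectable CRP rise")
  if (any(!keep))
    warning(sprintf("dropping %d replicate(s) without a detectable CRP rise",
                    sum(!keep)))
  reps <- replicates[keep]
  shifts <- rises[keep] - offset_min
  shifted <- Map(function(r, s) {
    r$time_min <- r$time_min - s
    r
  }, reps, shifts)
  if (is.null(step_min))
    step_min <- stats::median(diff(shifted[[1]]$time_min))
  lo <- max(vapply(shifted, function(r) min(r$time_min), numeric(1)))
  hi <- min(vapply(shifted, function(r) max(r$time_min), numeric(1)))
  if (hi <= lo) stop("aligned replicates have no overlapping time range")
  grid <- seq(lo, hi, by = step_min)
  cols <- setdiff(names(shifted[[1]]),
                  "time_min")
  cols <- cols[vapply(shifted[[1]][cols], is.numeric, logical(1))]
  acc <- lapply(shifted, function(r) {
    vapply(cols, function(cl)
      approx(r$time_min, r[[cl]], xout = grid)$y, numeric(length(grid)))
  })
  arr <- simplify2array(acc)                      # grid x cols x reps
  if (length(grid) == 1L) arr <- array(arr, dim = c(1, length(cols),
                                                    length(acc)))
  mean_mat <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  n_rep <- apply(!is.na(arr[, 1, , drop = FALSE]), 1, sum)
  out <- data.frame(time_min = grid, mean_mat)
  names(out) <- c("time_min", cols)
  out$n <- as.integer(n_rep)
  list(mean = out, shifts = shifts)
}

#' Score a dynamic prediction against observation
#'
#' Root-mean-square error over the common grid, the absolute difference
#' between the times of the observed and predicted maxima, and the
#' observed-to-predicted peak-magnitude ratio (the statistic behind
#' statements like "observed expression was about two-fold higher than
#' predicted").
#'
#' @param predicted,observed numeric series on a common time grid.
#' @param time_min the common grid, minutes.
#' @return List `rmse`, `peak_time_error_min`, `magnitude_ratio`.
#' @export
evaluate_prediction <- function(predicted, observed, time_min) {
  stopifnot(is.numeric(predicted), is.numeric(observed),
            length(predicted) == length(observed),
            length(time_min) == length(predicted))
  ok <- is.finite(predicted) & is.finite(observed)
  if (!any(ok)) stop("no overlapping finite points")
  p <- predicted[ok]; o <- observed[ok]; tt <- time_min[ok]
  if (max(p) <= 0) stop("non-positive predicted peak; magnitude ratio undefined")
  list(rmse = sqrt(mean((p - o)^2)),
       peak_time_error_min = abs(tt[which.max(o)] - tt[which.max(p)]),
       magnitude_ratio = max(o) / max(p))
}
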