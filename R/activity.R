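#' Reporter calibration: dynamic range of a repression reporter
#'
#' Holds the two constants of the repression readout
#' `S = alpha_rep / (1 + A) + basal_T`: the activation rate `alpha_rep`
#' (the span between fully unrepressed and fully repressed expression, in
#' CPS/OD) and the basal (fully repressed) level `basal_T`. `activity_cap`
#' bounds the inferred activity, because the inversion diverges as
#' expression approaches `basal_T`.
#'
#' @param alpha_rep activation rate, CPS/OD; must be positive.
#' @param basal_T basal (fully repressed) expression, CPS/OD; non-negative.
#' @param activity_cap upper clamp for inferred activity (dimensionless,
#'   default 50). A finite cap keeps downstream fits well-posed when the
#'   reporter is driven to its basal level.
#' @return An object of class `reporter_calibration`.
#' @seealso [calibrate_reporter()] to estimate one from data,
#'   [infer_activity()] for the inversion it parameterizes.
#' @export
#' @examples
#' cal <- reporter_calibration(alpha_rep = 100, basal_T = 10)
#' repression_forward(1, cal)  # 100/2 + 10 = 60
reporter_calibration <- function(alpha_rep, basal_T, activity_cap = 50) {
  stopifnot(is.numeric(alpha_rep), length(alpha_rep) == 1L, is.finite(alpha_rep),
            is.numeric(basal_T), length(basal_T) == 1L, is.finite(basal_T),
            is.numeric(activity_cap), length(activity_cap) == 1L)
  if (alpha_rep <= 0) stop("'alpha_rep' must be > 0 (no dynamic range)")
  if (basal_T < 0) stop("'basal_T' must be >= 0")
  if (activity_cap <= 0) stop("'activity_cap' must be > 0")
  structure(list(alpha_rep = alpha_rep, basal_T = basal_T,
                 activity_cap = activity_cap),
            class = "reporter_calibration")
}

#' @export
print.reporter_calibration <- function(x, ...) {
  cat("Repression-reporter calibration\n")
  cat(sprintf("  activation rate (span): %.4g CPS/OD\n", x$alpha_rep))
  cat(sprintf("  basal expression:       %.4g CPS/OD\n", x$basal_T))
  cat(sprintf("  activity cap:           %.4g\n", x$activity_cap))
  invisible(x)
}

#' Normalize luminescence to optical density
#'
#' Per-cell expression is luminescence (counts per second) divided by
#' culture density (OD600). Readings at or below `od_floor` are unreliable
#' (early time points, near-empty wells) and are returned as `NA` rather
#' than being divided through silently.
#'
#' @param lum luminescence, counts per second; non-negative.
#' @param od optical density (OD600), same length as `lum`.
#' @param od_floor minimum trustworthy OD (default 0.01).
#' @return Expression in CPS/OD, with `NA` where `od <= od_floor`.
#' @export
normalize_to_od <- function(lum, od, od_floor = 0.01) {
  stopifnot(is.numeric(lum), is.numeric(od), length(lum) == length(od))
  if (any(lum < 0, na.rm = TRUE)) stop("negative luminescence values")
  bad <- !is.finite(od) | od <= od_floor
  out <- ifelse(bad, NA_real_, lum / od)
  out
}

#' Forward repression model: expression given activity
#'
#' Expression of a repression reporter falls hyperbolically with the
#' activity of its cognate transcription factor:
#' `S = alpha_rep / (1 + A) + basal_T`. Strictly decreasing in `A`, from
#' `alpha_rep + basal_T` (unrepressed) down to `basal_T` (full repression).
#'
#' @param activity dimensionless activity, `>= 0`; vectorized.
#' @param cal a [reporter_calibration()].
#' @return Expression in CPS/OD.
#' @export
repression_forward <- function(activity, cal) {
  stopifnot(inherits(cal, "reporter_calibration"), is.numeric(activity))
  if (any(!is.finite(activity))) stop("non-finite activity")
  if (any(activity < 0)) stop("negative activity rejected")
  cal$alpha_rep / (1 + activity) + cal$basal_T
}

#' Infer transcription-factor activity from reporter expression
#'
#' Inverts the repression model:
#' `A = alpha_rep / (S - basal_T) - 1`, clamped to `[0, activity_cap]`.
#' Expression above the unrepressed level (`alpha_rep + basal_T`) would
#' give a negative activity and is normalized to 0; expression at or below
#' the basal level corresponds to (at least) complete repression and is
#' returned as the cap, with a warning rather than an error. `NA`
#' expression propagates to `NA` activity.
#'
#' @param expression reporter expression, CPS/OD; vectorized.
#' @param cal a [reporter_calibration()].
#' @return Dimensionless activity in `[0, activity_cap]` (or `NA`).
#' @export
#' @examples
#' cal <- reporter_calibration(100, 10)
#' infer_activity(60, cal)   # 1
#' infer_activity(110, cal)  # 0 (unrepressed)
infer_activity <- function(expression, cal) {
  stopifnot(inherits(cal, "reporter_calibration"), is.numeric(expression))
  if (any(is.infinite(expression))) stop("non-finite expression")
  out <- rep(NA_real_, length(expression))
  ok <- !is.na(expression)
  at_basal <- ok & expression <= cal$basal_T
  if (any(at_basal)) {
    warning(sprintf(
      "%d expression value(s) at or below the basal level; activity capped at %g",
      sum(at_basal), cal$activity_cap))
    out[at_basal] <- cal$activity_cap
  }
  inv <- ok & !at_basal
  a <- cal$alpha_rep / (expression[inv] - cal$basal_T) - 1
  out[inv] <- pmin(pmax(a, 0), cal$activity_cap)
  out
}

#' Calibrate a repression reporter from its expression range
#'
#' The activation rate is by definition the difference between fully
#' unrepressed and fully repressed expression, so a calibration needs
#' expression values spanning both ends of the reporter's range: the basal
#' level is taken as a robust minimum (fully repressed plateau) and the
#' activation rate as robust maximum minus that minimum.
#'
#' @param expression numeric vector of expression values (CPS/OD) covering
#'   uninduced (unrepressed) and fully induced (repressed) conditions.
#' @param probs length-2 probabilities for the robust minimum/maximum
#'   (default `c(0, 1)`, i.e. plain min/max; use e.g. `c(0.02, 0.98)` on
#'   noisy data).
#' @param activity_cap passed through to [reporter_calibration()].
#' @return A [reporter_calibration()].
#' @export
calibrate_reporter <- function(expression, probs = c(0, 1), activity_cap = 50) {
  stopifnot(is.numeric(expression), length(probs) == 2L, probs[1] < probs[2])
  x <- expression[is.finite(expression)]
  if (length(x) < 2L) stop("need at least two finite expression values")
  q <- quantile(x, probs = probs, names = FALSE, type = 7)
  if (q[2] <= q[1]) stop("calibration failure: no dynamic range (max <= min)")
  reporter_calibration(alpha_rep = q[2] - q[1], basal_T = q[1],
                       activity_cap = activity_cap)
}
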