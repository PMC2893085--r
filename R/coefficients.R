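#' Input-integration coefficients of a promoter
#'
#' The promoter model assigns a transcription rate to each bound state:
#' `alpha` for AraC-arabinose alone (`A*`), `beta` for CRP-cAMP alone
#' (`C*`), and `gamma` for the doubly bound state (`A* x C*`), plus a basal
#' rate `basal_T_B`. A term can be structurally absent (dropped from the
#' model, not merely zero): pass `NULL` for it. Fitted values are relative
#' strengths — they absorb the ratio of transcription-factor binding at the
#' synthetic reporter versus the natural promoter, so only their relative
#' magnitudes are interpretable.
#'
#' @param alpha,beta,gamma dimensionless transcription-activation
#'   coefficients; `NULL` marks a structurally absent term.
#' @param basal_T_B basal transcription, expression units (default 0).
#' @param form `"additive"` (default; production linear in the terms) or
#'   `"occupancy"` (production divided by the partition
#'   `1 + A + C + A*C` over bound states).
#' @return An object of class `integration_coefficients`.
#' @export
#' @examples
#' co <- integration_coefficients(alpha = 2.535, beta = NULL, gamma = 4.347)
#' forward_expression(1, 1, 1, co)  # 2.535 + 4.347 = 6.882
integration_coefficients <- function(alpha = NULL, beta = NULL, gamma = NULL,
                                     basal_T_B = 0,
                                     form = c("additive", "occupancy")) {
  form <- match.arg(form)
  chk <- function(x, nm) {
    if (is.null(x)) return(NULL)
    stopifnot(is.numeric(x), length(x) == 1L)
    if (!is.finite(x)) stop(sprintf("'%s' must be finite", nm))
    as.numeric(x)
  }
  co <- list(alpha = chk(alpha, "alpha"), beta = chk(beta, "beta"),
             gamma = chk(gamma, "gamma"),
             basal_T_B = chk(basal_T_B, "basal_T_B"), form = form)
  if (is.null(co$basal_T_B)) stop("'basal_T_B' may not be NULL")
  if (is.null(co$alpha) && is.null(co$beta) && is.null(co$gamma))
    warning("all activity terms absent: model is basal-only")
  structure(co, class = "integration_coefficients")
}

#' Active (structurally present) terms of a coefficient set
#' @param coeffs an [integration_coefficients()] object.
#' @return Character vector among `"alpha"`, `"beta"`, `"gamma"`.
#' @export
active_terms <- function(coeffs) {
  stopifnot(inherits(coeffs, "integration_coefficients"))
  nm <- c("alpha", "beta", "gamma")
  nm[!vapply(coeffs[nm], is.null, logical(1))]
}

#' @export
print.integration_coefficients <- function(x, ...) {
  cat(sprintf("Input-integration coefficients (%s form)\n", x$form))
  fmt <- function(v) if (is.null(v)) "  --  (absent)" else sprintf("%8.4g", v)
  cat("  alpha (AraC alone): ", fmt(x$alpha), "\n", sep = "")
  cat("  beta  (CRP alone):  ", fmt(x$beta), "\n", sep = "")
  cat("  gamma (joint):      ", fmt(x$gamma), "\n", sep = "")
  cat("  basal T_B:          ", fmt(x$basal_T_B), "\n", sep = "")
  invisible(x)
}

#' Promoter expression from measured activities
#'
#' Evaluates the input-integration model at given activities. The default
#' additive form is
#' `B = sigma * (alpha*A + beta*C + gamma*A*C) + T_B`,
#' with absent terms contributing nothing; `sigma` is the measured
#' polymerase (constitutive-promoter) expression, so `B` carries sigma's
#' units and the coefficients are dimensionless. The occupancy form
#' divides the weighted sum by the bound-state partition
#' `1 + A + C + A*C`.
#'
#' @param a_star,c_star dimensionless activities, `>= 0`; vectorized
#'   (recycled to a common length).
#' @param sigma measured polymerase activity (expression units, `> 0`).
#' @param coeffs an [integration_coefficients()] object.
#' @return Expression, same units as `sigma`.
#' @export
forward_expression <- function(a_star, c_star, sigma, coeffs) {
  stopifnot(inherits(coeffs, "integration_coefficients"),
            is.numeric(a_star), is.numeric(c_star), is.numeric(sigma))
  if (any(!is.finite(a_star)) || any(!is.finite(c_star)))
    stop("non-finite activity")
  if (any(a_star < 0) || any(c_star < 0)) stop("negative activities rejected")
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  n <- max(length(a_star), length(c_star), length(sigma))
  a <- rep_len(a_star, n); cc <- rep_len(c_star, n); s <- rep_len(sigma, n)
  val <- function(v) if (is.null(v)) 0 else v
  num <- val(coeffs$alpha) * a + val(coeffs$beta) * cc +
    val(coeffs$gamma) * a * cc
  if (coeffs$form == "occupancy") num <- num / (1 + a + cc + a * cc)
  s * num + coeffs$basal_T_B
}
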