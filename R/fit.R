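#' Gaussian AIC from a residual sum of squares
#'
#' `AIC = n * ln(rss/n) + 2 * (k + 1)`, the Gaussian-likelihood form with
#' the error variance counted as a parameter (hence `k + 1`). Conventions
#' differ by an additive constant; comparisons between models fitted to the
#' same data are unaffected.
#'
#' @param rss residual sum of squares (`> 0`; `rss = 0` returns `-Inf`
#'   with a warning — a perfect fit has no finite Gaussian AIC).
#' @param n_obs number of observations.
#' @param n_params number of mean parameters `k`.
#' @return AIC (dimensionless scalar).
#' @export
#' @examples
#' compute_aic(rss = 10, n_obs = 10, n_params = 2)  # 10*log(1) + 6 = 6
compute_aic <- function(rss, n_obs, n_params) {
  stopifnot(is.numeric(rss), is.numeric(n_obs), is.numeric(n_params),
            n_obs > n_params, n_params >= 0)
  if (rss < 0) stop("'rss' must be non-negative")
  if (rss == 0) {
    warning("rss = 0: AIC is -Inf (degenerate perfect fit)")
    return(-Inf)
  }
  n_obs * log(rss / n_obs) + 2 * (n_params + 1)
}

term_regressor <- function(term, a, cc) {
  switch(term, alpha = a, beta = cc, gamma = a * cc,
         stop("unknown term: ", term))
}

# OLS start values (and the exact solution for the additive form).
ols_start <- function(df, terms, fit_basal, pin_basal) {
  X <- do.call(cbind, lapply(terms, function(tm)
    df$sigma * term_regressor(tm, df$A_star, df$C_star)))
  colnames(X) <- terms
  y <- df$expression
  if (fit_basal) {
    X <- cbind(X, T_B = 1)
  } else {
    y <- y - pin_basal
  }
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop("singular fit: design is rank-deficient (constant or collinear activities)")
  coef(fit)
}

#' Fit the input-integration model by nonlinear least squares
#'
#' Fits promoter expression against measured activities by
#' Levenberg-Marquardt nonlinear least squares (`minpack.lm::nlsLM`),
#' started at the ordinary-least-squares solution on the additive
#' regressors — for the additive form the model is linear in its
#' parameters, so that start is the optimum itself and noise-free data
#' is recovered exactly. Standard errors, t statistics and p-values are
#' asymptotic, from the Jacobian at the optimum with
#' `n_obs - n_params` residual degrees of freedom.
#'
#' @param data data frame with columns `A_star`, `C_star`, `sigma`,
#'   `expression` (one row per steady-state condition). Rows with missing
#'   values are dropped.
#' @param terms which activity terms to include: subset of
#'   `c("alpha", "beta", "gamma")`.
#' @param form `"additive"` (default) or `"occupancy"`; see
#'   [forward_expression()].
#' @param fit_basal fit the basal level `T_B` as a free intercept
#'   (default `TRUE`)?
#' @param pin_basal value at which `T_B` is pinned when
#'   `fit_basal = FALSE` (default 0, or a measured uninduced mean).
#' @return An object of class `fit_result`: `coefficients`
#'   (an [integration_coefficients()]), `table` (estimate / std.error /
#'   t / p per parameter), `rss`, `rse`, `aic`, `n_obs`, `n_params`,
#'   `converged`, and the fitting spec for later refits.
#' @seealso [coefficient_significance()], [reduce_and_compare()]
#' @export
fit_integration_model <- function(data,
                                  terms = c("alpha", "beta", "gamma"),
                                  form = c("additive", "occupancy"),
                                  fit_basal = TRUE, pin_basal = 0) {
  form <- match.arg(form)
  terms <- match.arg(terms, c("alpha", "beta", "gamma"), several.ok = TRUE)
  need <- c("A_star", "C_star", "sigma", "expression")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  df <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
  if (any(df$A_star < 0) || any(df$C_star < 0))
    stop("negative activities rejected")
  n_params <- length(terms) + as.integer(fit_basal)
  if (nrow(df) <= n_params)
    stop("need more observations than parameters (n_obs > n_params)")

  start <- as.list(ols_start(df, terms, fit_basal, pin_basal))

  prod_txt <- paste(vapply(terms, function(tm) switch(
    tm,
    alpha = "alpha * A_star",
    beta  = "beta * C_star",
    gamma = "gamma * A_star * C_star"), character(1)), collapse = " + ")
  if (form == "occupancy")
    prod_txt <- sprintf("(%s) / (1 + A_star + C_star + A_star * C_star)",
                        prod_txt)
  rhs <- sprintf("sigma * (%s) + %s", prod_txt,
                 if (fit_basal) "T_B" else format(pin_basal, digits = 17))
  fml <- stats::as.formula(paste("expression ~", rhs))

  # Levenberg-Marquardt from the OLS start: stable on zero-residual
  # (exact-recovery) data and when the start is already the optimum,
  # where Gauss-Newton step halving stalls. A final undamped
  # Gauss-Newton step with the analytic Jacobian then polishes the
  # solution past the damped iteration's finite-difference precision.
  grad_fun <- deriv(stats::as.formula(paste("~", rhs))[[2]], names(start),
                    function.arg = c(names(start),
                                     c("A_star", "C_star", "sigma")))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) {
      if (grepl("singular", conditionMessage(e), ignore.case = TRUE))
        stop("singular fit: ", conditionMessage(e), call. = FALSE)
      stop("nls did not converge: ", conditionMessage(e), call. = FALSE)
    })

  data_args <- df[c("A_star", "C_star", "sigma")]
  eval_model <- function(est) {
    gv <- do.call(grad_fun, c(as.list(est), data_args))
    list(pred = as.vector(gv), J = attr(gv, "gradient"))
  }
  est <- coef(fit)
  m0 <- eval_model(est)
  r0 <- df$expression - m0$pred
  delta <- tryCatch(qr.coef(qr(m0$J), r0), error = function(e) NULL)
  if (!is.null(delta) && all(is.finite(delta))) {
    cand <- est + delta
    rc <- df$expression - eval_model(cand)$pred
    if (sum(rc^2) <= sum(r0^2)) {
      est <- cand
      r0 <- rc
    }
  }
  m <- eval_model(est)
  rss <- sum(r0^2)
  df_resid <- nrow(df) - n_params
  # asymptotic covariance from the Jacobian at the optimum
  R <- qr.R(qr(m$J))
  se <- sqrt(pmax(diag(chol2inv(R)), 0) * rss / df_resid)
  tval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  tab <- cbind(estimate = est, std.error = se, t.value = tval,
               p.value = 2 * pt(abs(tval), df_resid, lower.tail = FALSE))
  rownames(tab) <- names(est)
  co <- integration_coefficients(
    alpha = if ("alpha" %in% terms) est[["alpha"]],
    beta  = if ("beta" %in% terms) est[["beta"]],
    gamma = if ("gamma" %in% terms) est[["gamma"]],
    basal_T_B = if (fit_basal) est[["T_B"]] else pin_basal,
    form = form)
  neg_sig <- rownames(tab) %in% terms & tab[, "estimate"] < 0 &
    tab[, "p.value"] <= 0.05
  if (any(neg_sig))
    warning("significant negative coefficient(s): ",
            paste(rownames(tab)[neg_sig], collapse = ", "))
  structure(list(
    coefficients = co,
    table = tab,
    rss = rss,
    rse = sqrt(rss / (nrow(df) - n_params)),
    aic = suppressWarnings(compute_aic(rss, nrow(df), n_params)),
    n_obs = nrow(df),
    n_params = n_params,
    converged = isTRUE(fit$convInfo$isConv),
    spec = list(terms = terms, form = form, fit_basal = fit_basal,
                pin_basal = pin_basal),
    nls = fit), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Input-integration model fit (%s form), n = %d, %d parameter(s)\n",
              x$spec$form, x$n_obs, x$n_params))
  stars <- cut(x$table[, "p.value"], c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  tab <- data.frame(round(x$table, 4), sig = as.character(stars))
  print(tab)
  cat(sprintf("RSS %.6g  RSE %.6g  AIC %.6g  converged: %s\n",
              x$rss, x$rse, x$aic, x$converged))
  invisible(x)
}

#' Per-coefficient significance against zero
#'
#' Two-sided t-test of each fitted coefficient against zero at the given
#' level, with `n_obs - n_params` residual degrees of freedom (the
#' p-values computed at fit time).
#'
#' @param fit a [fit_integration_model()] result; must have converged.
#' @param level significance level (default 0.05). A coefficient is
#'   significant when `p <= level`.
#' @return Named logical vector over the fitted parameters.
#' @export
coefficient_significance <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("fit did not converge")
  if (fit$n_obs - fit$n_params <= 0) stop("zero residual degrees of freedom")
  stopifnot(is.numeric(level), length(level) == 1L, level > 0)
  setNames(fit$table[, "p.value"] <= level, rownames(fit$table))
}

#' Drop insignificant terms, refit, and compare by RSE and AIC
#'
#' Activity terms whose coefficients are insignificant at `level` are
#' removed (the basal intercept is never removed), the model is refit on
#' the same data, and the two fits are compared by the change in residual
#' standard error and AIC. The reduced model is selected iff its AIC is
#' lower. If every term is significant the comparison reports
#' `"no reduction"` with the reduced fit identical to the full fit.
#'
#' @param data the data frame the full model was fitted to.
#' @param full_fit a converged [fit_integration_model()] result.
#' @param level significance level for term removal (default 0.05).
#' @return An object of class `model_comparison`: `full`, `reduced`
#'   (both `fit_result`), `dropped` (character), `delta_aic`, `delta_rse`
#'   (reduced minus full), `selected` (`"reduced"`, `"full"`, or
#'   `"no reduction"`).
#' @export
reduce_and_compare <- function(data, full_fit, level = 0.05) {
  stopifnot(inherits(full_fit, "fit_result"))
  if (!full_fit$converged) stop("full fit did not converge")
  sig <- coefficient_significance(full_fit, level)
  terms <- full_fit$spec$terms
  drop <- terms[!sig[terms]]
  if (length(drop) == 0L) {
    return(structure(list(full = full_fit, reduced = full_fit,
                          dropped = character(0), delta_aic = 0,
                          delta_rse = 0, selected = "no reduction"),
                     class = "model_comparison"))
  }
  keep <- setdiff(terms, drop)
  if (length(keep) == 0L) {
    warning("all activity terms removed: reduced model is basal-only (degenerate)")
    # intercept-only least squares, reported through the same machinery
    df <- data[stats::complete.cases(
      data[, c("A_star", "C_star", "sigma", "expression")]), ]
    est <- mean(df$expression)
    rss <- sum((df$expression - est)^2)
    n <- nrow(df)
    se <- sqrt(rss / (n - 1)) / sqrt(n)
    tval <- est / se
    tab <- matrix(c(est, se, tval, 2 * pt(abs(tval), n - 1, lower.tail = FALSE)),
                  nrow = 1,
                  dimnames = list("T_B", c("estimate", "std.error",
                                           "t.value", "p.value")))
    reduced <- structure(list(
      coefficients = suppressWarnings(
        integration_coefficients(basal_T_B = est, form = full_fit$spec$form)),
      table = tab, rss = rss, rse = sqrt(rss / (n - 1)),
      aic = suppressWarnings(compute_aic(rss, n, 1)), n_obs = n, n_params = 1,
      converged = TRUE,
      spec = list(terms = character(0), form = full_fit$spec$form,
                  fit_basal = TRUE, pin_basal = 0), nls = NULL),
      class = "fit_result")
  } else {
    reduced <- fit_integration_model(
      data, terms = keep, form = full_fit$spec$form,
      fit_basal = full_fit$spec$fit_basal,
      pin_basal = full_fit$spec$pin_basal)
  }
  delta_aic <- reduced$aic - full_fit$aic
  structure(list(full = full_fit, reduced = reduced, dropped = drop,
                 delta_aic = delta_aic,
                 delta_rse = reduced$rse - full_fit$rse,
                 selected = if (is.finite(delta_aic) && delta_aic < 0 ||
                                (is.infinite(reduced$aic) && reduced$aic < 0))
                   "reduced" else "full"),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison after significance-based reduction\n")
  if (x$selected == "no reduction") {
    cat("  all terms significant; no reduction performed\n")
  } else {
    cat("  dropped term(s): ", paste(x$dropped, collapse = ", "), "\n",
        sep = "")
    cat(sprintf("  delta AIC (reduced - full): %.4g\n", x$delta_aic))
    cat(sprintf("  delta RSE (reduced - full): %.4g\n", x$delta_rse))
    cat("  selected: ", x$selected, "\n", sep = "")
  }
  invisible(x)
}

#' Fit-result and comparison records as JSON-ready lists
#'
#' Flattens a [fit_integration_model()] result (or a
#' [reduce_and_compare()] comparison) into a plain list mirroring a
#' coefficient table: one record per term with estimate, standard error,
#' p-value and significance stars, plus the fit statistics.
#'
#' @param x a `fit_result` or `model_comparison`.
#' @return A list safe for `jsonlite::write_json(..., auto_unbox = TRUE)`.
#' @export
as_fit_record <- function(x) {
  if (inherits(x, "model_comparison")) {
    return(list(full = as_fit_record(x$full),
                reduced = as_fit_record(x$reduced),
                dropped = as.list(x$dropped),
                delta_aic = x$delta_aic, delta_rse = x$delta_rse,
                selected = x$selected))
  }
  stopifnot(inherits(x, "fit_result"))
  stars <- function(p) if (p <= 0.001) "***" else if (p <= 0.01) "**"
    else if (p <= 0.05) "*" else "NS"
  terms <- lapply(rownames(x$table), function(nm) list(
    term = nm,
    estimate = unname(x$table[nm, "estimate"]),
    std_error = unname(x$table[nm, "std.error"]),
    p_value = unname(x$table[nm, "p.value"]),
    significance = stars(x$table[nm, "p.value"])))
  list(form = x$spec$form, terms = terms, rss = x$rss, rse = x$rse,
       aic = x$aic, n_obs = x$n_obs, n_params = x$n_params,
       converged = x$converged)
}
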