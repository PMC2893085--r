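#' Write / read a plate time series as long-format CSV
#'
#' One canonical long schema for every time series in the package:
#' columns `well`, `time_min`, `channel` (`OD600` or `CPS`),
#' `reporter_id`, `value`. Rows are written in a canonical order
#' (reporter, channel, well, time), and reads canonicalize likewise, so
#' write/read/write round-trips are byte-identical and row order on disk
#' is irrelevant.
#'
#' @param plate long data frame with the five schema columns.
#' @param path CSV path.
#' @return `write_plate_csv`: `path`, invisibly. `read_plate_csv`: the
#'   validated, canonically ordered data frame.
#' @export
write_plate_csv <- function(plate, path) {
  plate <- validate_plate(plate)
  write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_plate(df)
}

validate_plate <- function(df) {
  need <- c("well", "time_min", "channel", "reporter_id", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("plate table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$channel %in% c("OD600", "CPS")))
    stop("channel must be 'OD600' or 'CPS'")
  key <- paste(df$well, df$time_min, df$channel, df$reporter_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (well, time, channel, reporter) row(s), e.g.: ",
         sub("\r.*", "", key[duplicated(key)][1]))
  df <- df[order(df$reporter_id, df$channel, df$well, df$time_min),
           need, drop = FALSE]
  rownames(df) <- NULL
  by_well <- split(df$time_min, paste(df$well, df$channel, df$reporter_id))
  if (any(vapply(by_well, function(tt) any(diff(tt) <= 0), logical(1))))
    stop("times are not strictly increasing within a (well, channel, reporter)")
  df
}

#' Write / read a gradient layout CSV
#'
#' Columns `well`, `arabinose_percent`, `camp_mM`.
#' @param layout layout data frame.
#' @param path CSV path.
#' @return The path (write) or validated data frame (read).
#' @export
write_layout_csv <- function(layout, path) {
  stopifnot(all(c("well", "arabinose_percent", "camp_mM") %in% names(layout)))
  write.csv(layout, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "arabinose_percent", "camp_mM")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("layout is missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$arabinose_percent < 0) || any(df$camp_mM < 0))
    stop("negative concentrations in layout")
  df
}

#' Per-cell expression table from a long plate table
#'
#' Pairs each CPS reading with its OD600 reading and normalizes
#' ([normalize_to_od()]): one row per (well, time, reporter) with the
#' expression in CPS/OD (`NA` where OD is at or below the floor).
#'
#' @param plate long plate data frame (see [write_plate_csv()]).
#' @param od_floor minimum trustworthy OD600 (default 0.01).
#' @return Data frame `well`, `time_min`, `reporter_id`, `expression`.
#' @export
plate_expression <- function(plate, od_floor = 0.01) {
  plate <- validate_plate(plate)
  cps <- plate[plate$channel == "CPS", ]
  od <- plate[plate$channel == "OD600", ]
  m <- merge(cps[, c("well", "time_min", "reporter_id", "value")],
             od[, c("well", "time_min", "reporter_id", "value")],
             by = c("well", "time_min", "reporter_id"),
             suffixes = c("_cps", "_od"))
  m$expression <- normalize_to_od(m$value_cps, m$value_od,
                                  od_floor = od_floor)
  m <- m[order(m$reporter_id, m$well, m$time_min),
         c("well", "time_min", "reporter_id", "expression")]
  rownames(m) <- NULL
  m
}

#' Steady-state fit table from a simulated or measured gradient plate
#'
#' Extracts, at the steady-state read time, the promoter expression and
#' the activities inferred from the synARA / synCRP channels (with
#' `sigma` from the synRNAP-s70 channel), merged with the layout: the
#' input [fit_integration_model()] expects.
#'
#' @param plate long plate data frame containing the promoter channel
#'   plus `synARA`, `synCRP`, `synRNAP_s70`.
#' @param layout gradient layout (see [read_layout_csv()]).
#' @param cal_A,cal_C [reporter_calibration()]s for synARA / synCRP.
#' @param promoter_id name of the promoter channel.
#' @param steady_time_min the read used as steady state (default 44).
#' @param od_floor passed to [plate_expression()].
#' @return Data frame `well`, `arabinose_percent`, `camp_mM`, `A_star`,
#'   `C_star`, `sigma`, `expression`.
#' @export
steady_state_table <- function(plate, layout, cal_A, cal_C, promoter_id,
                               steady_time_min = 44, od_floor = 0.01) {
  ex <- plate_expression(plate, od_floor = od_floor)
  tt <- sort(unique(ex$time_min))
  t_star <- tt[which.min(abs(tt - steady_time_min))]
  ex <- ex[ex$time_min == t_star, ]
  wide <- function(rid, col) {
    sub <- ex[ex$reporter_id == rid, c("well", "expression")]
    names(sub)[2] <- col
    sub
  }
  out <- Reduce(function(a, b) merge(a, b, by = "well"), list(
    layout,
    wide(promoter_id, "expression"),
    wide("synARA", "ara_expr"),
    wide("synCRP", "crp_expr"),
    wide("synRNAP_s70", "sigma")))
  out$A_star <- infer_activity(out$ara_expr, cal_A)
  out$C_star <- infer_activity(out$crp_expr, cal_C)
  out[order(out$well),
      c("well", "arabinose_percent", "camp_mM", "A_star", "C_star",
        "sigma", "expression")]
}

#' Activity profile of one diauxic replicate
#'
#' Converts a replicate's reporter channels into a time-indexed activity
#' profile: `A*` from synARA, `C*` from synCRP (both via
#' [infer_activity()]), `sigma` from the synRNAP-s70 channel, plus an
#' expression column per promoter channel present.
#'
#' @param plate one replicate's long plate table.
#' @param cal_A,cal_C [reporter_calibration()]s.
#' @param od_floor passed to [plate_expression()].
#' @return Data frame `time_min`, `A_star`, `C_star`, `sigma`, and one
#'   column per promoter channel.
#' @export
diauxic_activity_profile <- function(plate, cal_A, cal_C, od_floor = 0.01) {
  ex <- plate_expression(plate, od_floor = od_floor)
  ids <- unique(ex$reporter_id)
  need <- c("synARA", "synCRP", "synRNAP_s70")
  if (!all(need %in% ids))
    stop("plate lacks reporter channel(s): ",
         paste(setdiff(need, ids), collapse = ", "))
  grab <- function(rid) {
    sub <- ex[ex$reporter_id == rid, ]
    sub[order(sub$time_min), c("time_min", "expression")]
  }
  base <- grab("synARA")
  out <- data.frame(time_min = base$time_min,
                    A_star = infer_activity(base$expression, cal_A),
                    C_star = infer_activity(grab("synCRP")$expression, cal_C),
                    sigma = grab("synRNAP_s70")$expression)
  for (pid in setdiff(ids, need)) out[[pid]] <- grab(pid)$expression
  out
}

#' Write an activity profile CSV
#'
#' @param profile data frame with `time_min` (or condition columns) plus
#'   `A_star`, `C_star`, `sigma`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(profile, path) {
  stopifnot(all(c("A_star", "C_star", "sigma") %in% names(profile)))
  write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_schema <- function() {
  list(
    seed = NULL, outdir = NULL, promoters = NULL,
    gradient = c("arabinose_levels", "camp_levels", "read_interval_min",
                 "horizon_min", "steady_time_min"),
    dose_response = c("a_max", "K_a", "h", "c_max", "K_c", "sigma_level"),
    noise = c("lum_lognormal_sigma", "od_gaussian_sd"),
    calibration = c("alpha_rep", "basal_T", "activity_cap", "od_floor"),
    fit = c("form", "level", "fit_basal"),
    scenario = c("n_replicates", "exhaustion_time_min", "jitter_min",
                 "sigma_level", "tau_min", "read_interval_min",
                 "horizon_min", "offset_min"))
}

#' Read and validate a pipeline configuration (JSON)
#'
#' One canonical schema: top-level keys `seed` (required), `outdir`,
#' `promoters`, and the blocks `gradient`, `dose_response`, `noise`,
#' `calibration`, `fit`, `scenario`. Unknown keys anywhere are rejected;
#' every random choice in the pipeline flows from `seed`.
#'
#' @param path JSON file path.
#' @return Validated configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg configuration list (as from `jsonlite::fromJSON`).
#' @export
validate_run_config <- function(cfg) {
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (blk in names(schema)) {
    if (!is.null(schema[[blk]]) && !is.null(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), schema[[blk]])
      if (length(bad))
        stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
    }
  }
  if (is.null(cfg$seed))
    stop("configuration must set an explicit 'seed'")
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  defaults <- list(
    outdir = ".",
    promoters = names(ara_coefficients()),
    gradient = list(), dose_response = list(),
    noise = list(lum_lognormal_sigma = 0.05, od_gaussian_sd = 0.002),
    calibration = list(alpha_rep = 1, basal_T = 0.02, activity_cap = 50,
                       od_floor = 0.01),
    fit = list(form = "additive", level = 0.05, fit_basal = TRUE),
    scenario = list(offset_min = 20))
  cfg <- modifyList(defaults, cfg)
  bad_prom <- setdiff(cfg$promoters, names(ara_coefficients()))
  if (length(bad_prom))
    stop("unknown promoter(s): ", paste(bad_prom, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Sequences the whole method: simulate a steady-state gradient per
#' promoter and a shared diauxic-shift experiment; normalize to OD;
#' infer activities from the reporter channels; fit the integration
#' model per promoter and reduce it by coefficient significance; align
#' diauxic replicates on the CRP rise, average, and predict each
#' promoter's diauxic expression from its reduced fit; score predictions.
#' Everything is deterministic given the configuration's seed. When
#' `write = TRUE`, fit records (JSON), activity and prediction CSVs,
#' metrics (JSON) and a parameter log are written under `outdir`.
#'
#' @param config configuration list (see [read_run_config()]); a path to
#'   a JSON file is also accepted.
#' @param write write the report bundle to `config$outdir` (default
#'   `TRUE`)?
#' @return Invisible list: `fits` and `comparisons` (per promoter),
#'   `steady_tables`, `aligned` (averaged diauxic profile),
#'   `predictions`, `metrics`, `config`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- validate_run_config(config)
  cfg <- config
  log_lines <- c(sprintf("araLogic pipeline, seed %d", cfg$seed))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  design <- do.call(gradient_design, cfg$gradient)
  dr <- do.call(dose_response_map, cfg$dose_response)
  cal <- reporter_calibration(cfg$calibration$alpha_rep,
                              cfg$calibration$basal_T,
                              cfg$calibration$activity_cap)
  od_floor <- cfg$calibration$od_floor
  truth <- ara_coefficients()[cfg$promoters]
  scn_args <- cfg$scenario[setdiff(names(cfg$scenario), "offset_min")]
  scenario <- do.call(diauxic_scenario, scn_args)
  say("gradient: %d x %d wells, steady read %g min",
      length(design$arabinose_levels), length(design$camp_levels),
      design$steady_time_min)
  say("dose-response: %s",
      paste(names(attr(dr, "params")), unlist(attr(dr, "params")),
            sep = "=", collapse = ", "))
  say("calibration: alpha_rep=%g basal_T=%g cap=%g od_floor=%g",
      cal$alpha_rep, cal$basal_T, cal$activity_cap, od_floor)
  say("noise: lum sdlog=%g, od sd=%g", cfg$noise$lum_lognormal_sigma,
      cfg$noise$od_gaussian_sd)
  say("fit: form=%s, significance level=%g, fit_basal=%s",
      cfg$fit$form, cfg$fit$level, cfg$fit$fit_basal)
  say("scenario: n=%d, exhaustion %g +/- %g min, tau=%g min, align offset %g min",
      scenario$n_replicates, scenario$exhaustion_time_min,
      scenario$jitter_min, scenario$tau_min, cfg$scenario$offset_min)

  # --- steady-state gradients, one per promoter --------------------------
  fits <- list(); comparisons <- list(); steady_tables <- list()
  for (i in seq_along(cfg$promoters)) {
    pid <- cfg$promoters[i]
    nz <- do.call(noise_model, c(cfg$noise, list(seed = cfg$seed + i)))
    sim <- simulate_gradient_plate(design, truth[[pid]], cal, cal,
                                   dose_response = dr, noise = nz,
                                   promoter_id = pid)
    tab <- steady_state_table(sim$plate, sim$layout, cal, cal, pid,
                              steady_time_min = design$steady_time_min,
                              od_floor = od_floor)
    full <- fit_integration_model(tab, terms = c("alpha", "beta", "gamma"),
                                  form = cfg$fit$form,
                                  fit_basal = cfg$fit$fit_basal)
    cmp <- reduce_and_compare(tab, full, level = cfg$fit$level)
    fits[[pid]] <- full; comparisons[[pid]] <- cmp
    steady_tables[[pid]] <- tab
    say("%s: dropped [%s], delta AIC %.3f, selected %s", pid,
        paste(cmp$dropped, collapse = ","), cmp$delta_aic, cmp$selected)
  }

  # --- diauxic shift ------------------------------------------------------
  nz_d <- do.call(noise_model, c(cfg$noise, list(seed = cfg$seed + 100L)))
  dia <- simulate_diauxic_experiment(scenario, truth = truth,
                                     cal_A = cal, cal_C = cal, noise = nz_d)
  profiles <- lapply(dia$replicates, function(r)
    diauxic_activity_profile(r$plate, cal, cal, od_floor = od_floor))
  aligned <- align_and_average(profiles, offset_min = cfg$scenario$offset_min)
  avg <- aligned$mean

  predictions <- list(); metrics <- list()
  loss <- ara_loss_models(scenario$tau_min)
  for (pid in cfg$promoters) {
    co <- comparisons[[pid]]$reduced$coefficients
    obs <- avg[[pid]]
    traj <- integrate_expression(
      avg[, c("time_min", "A_star", "C_star", "sigma")], co, loss[[pid]],
      b0 = obs[1])
    predictions[[pid]] <- data.frame(time_min = avg$time_min,
                                     predicted = traj$expression,
                                     observed = obs,
                                     n_replicates = avg$n)
    metrics[[pid]] <- evaluate_prediction(traj$expression, obs, avg$time_min)
    say("%s prediction: rmse %.4g, peak timing error %g min, magnitude ratio %.3f",
        pid, metrics[[pid]]$rmse, metrics[[pid]]$peak_time_error_min,
        metrics[[pid]]$magnitude_ratio)
  }

  if (write) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(lapply(comparisons, as_fit_record),
                         file.path(cfg$outdir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    write_activity_csv(avg, file.path(cfg$outdir, "diauxic_activity_mean.csv"))
    for (pid in cfg$promoters)
      write.csv(predictions[[pid]],
                file.path(cfg$outdir, sprintf("prediction_%s.csv", pid)),
                row.names = FALSE)
    jsonlite::write_json(metrics, file.path(cfg$outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))
  }
  invisible(list(fits = fits, comparisons = comparisons,
                 steady_tables = steady_tables, aligned = aligned,
                 predictions = predictions, metrics = metrics,
                 config = cfg, log = log_lines))
}
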