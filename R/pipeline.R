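# Pipeline orchestration: simulate (or read) -> fit both phases (pooled and
# habitat-indexed) -> nested comparisons -> endpoint contrast -> report
# bundle on disk, plus a small command-line front end.

#' Run the full analysis pipeline
#'
#' Executes the complete sequence on one dataset: pooled and
#' habitat-indexed fits for both phases, the two nested model comparisons,
#' the endpoint linear-model contrast with term tests and residual
#' diagnostics, and writes a report bundle: a parameter table CSV (model
#' type x habitat x phase with estimates, CI bounds and adjusted R-squared),
#' comparison and endpoint JSON files, a fitted-curve prediction table
#' (0-42 days at 0.25-day steps for every fitted model, for plotting), and
#' a plain-text run log recording the schedule, seed, package version,
#' convergence and multi-start outcomes.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   `data` (CSV path) plus optional `mapping` (named list for
#'   [column_mapping()]), or `simulate` (a [simulation_config()] or a list
#'   of its arguments); optional `schedule` (list of `C_I0`, `C_Eu`,
#'   `C_Ed`, `t_C`; `C_I0` defaults to the mean day-0 concentration);
#'   optional `endpoint_days` (default `c(0, 42)`).
#' @param out_dir output directory, created if needed.
#' @param seed integer used for any simulation randomness.
#' @return Invisibly, the report bundle as a list (`observations`, `fits`,
#'   `comparisons`, `endpoint`, `schedule`, `files`).
#' @examples
#' \donttest{
#' out <- run_pipeline(list(simulate = list()), out_dir = tempfile(),
#'                     seed = 1)
#' out$comparisons$contamination
#' }
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_add("cdtk pipeline run, ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  log_add("package version: ",
          as.character(utils::packageVersion("cdtk")),
          "; R ", R.version$major, ".", R.version$minor)

  # --- input stage -----------------------------------------------------
  obs <- stage("input", {
    if (!is.null(config$data)) {
      mapping <- if (is.null(config$mapping)) column_mapping()
                 else do.call(column_mapping, as.list(config$mapping))
      log_add("input: ", config$data)
      read_observations(config$data, mapping)
    } else if (!is.null(config$simulate)) {
      sim_cfg <- config$simulate
      if (!inherits(sim_cfg, "simulation_config")) {
        args <- as.list(sim_cfg)
        if (!is.null(args$schedule) &&
            !inherits(args$schedule, "exposure_schedule"))
          args$schedule <- do.call(exposure_schedule, as.list(args$schedule))
        sim_cfg <- do.call(simulation_config, args)
      }
      if (!is.null(seed)) sim_cfg$seed <- as.integer(seed)
      ds <- generate_dataset(sim_cfg)
      log_add("input: simulated, seed ", ds$seed, ", ",
              nrow(ds$observations), " colonies")
      write_simulated(ds, file.path(out_dir, "observations.csv"))
      ds$observations
    } else stop("config must provide either 'data' or 'simulate'")
  })

  # --- schedule: C_I0 defaults to the mean of the day-0 colonies -------
  schedule <- stage("schedule", {
    sc <- as.list(config$schedule)
    if (is.null(sc$C_I0)) {
      day0 <- obs$concentration[obs$time_days == 0]
      if (length(day0) == 0)
        stop("no day-0 observations to estimate C_I0; supply schedule$C_I0")
      sc$C_I0 <- mean(day0)
    }
    do.call(exposure_schedule, sc)
  })
  log_add(sprintf("schedule: C_I0 = %.4f, C_Eu = %g, C_Ed = %g, t_C = %g",
                  schedule$C_I0, schedule$C_Eu, schedule$C_Ed,
                  schedule$t_C))

  # --- fits ------------------------------------------------------------
  fits <- list()
  for (phase in c("contamination", "decontamination"))
    for (grouping in c("pooled", "by_habitat")) {
      key <- paste(phase, grouping, sep = ".")
      fits[[key]] <- stage(paste("fit", key),
                           fit_phase(obs, phase, schedule, grouping))
      f <- fits[[key]]
      log_add(sprintf(
        "fit %s: %sconverged in %d iter; RSS = %.4f; starts tried = %d (%d converged)",
        key, if (f$converged) "" else "NOT ", f$n_iterations, f$rss,
        nrow(f$multistart), sum(f$multistart$converged)))
    }

  comparisons <- stage("comparisons", list(
    contamination = compare_nested(fits[["contamination.pooled"]],
                                   fits[["contamination.by_habitat"]]),
    decontamination = compare_nested(fits[["decontamination.pooled"]],
                                     fits[["decontamination.by_habitat"]])))

  endpoint_days <- if (is.null(config$endpoint_days)) c(0, 42)
                   else as.numeric(config$endpoint_days)
  endpoint <- stage("endpoint", {
    ef <- fit_endpoint_model(obs, endpoint_days)
    list(fit = ef,
         tests = lapply(setNames(nm = c("time_point", "habitat",
                                        "interaction")),
                        function(tm) test_term(obs, tm, endpoint_days)),
         diagnostics = residual_diagnostics(ef))
  })

  # --- report files ----------------------------------------------------
  files <- stage("report", {
    param_csv <- file.path(out_dir, "parameters.csv")
    utils::write.csv(parameter_table(fits), param_csv, row.names = FALSE)

    cmp_json <- file.path(out_dir, "comparisons.json")
    jsonlite::write_json(lapply(comparisons, unclass), cmp_json,
                         auto_unbox = TRUE, digits = NA)

    ep_json <- file.path(out_dir, "endpoint.json")
    jsonlite::write_json(list(
      reference_levels = as.list(endpoint$fit$reference),
      coefficients = as.list(stats::coef(endpoint$fit$model)),
      group_means = endpoint$fit$group_means,
      tests = lapply(endpoint$tests, unclass),
      diagnostics = endpoint$diagnostics[
        c("shapiro_stat", "shapiro_p", "variance_ratio")]),
      ep_json, auto_unbox = TRUE, digits = NA)

    pred_csv <- file.path(out_dir, "predictions.csv")
    utils::write.csv(prediction_table(fits, schedule), pred_csv,
                     row.names = FALSE)

    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(log_lines, log_path)
    c(parameters = param_csv, comparisons = cmp_json,
      endpoint = ep_json, predictions = pred_csv, log = log_path)
  })

  invisible(list(observations = obs, fits = fits,
                 comparisons = comparisons, endpoint = endpoint,
                 schedule = schedule, files = files))
}

#' Flat parameter table across fitted models
#'
#' One row per parameter of every fit, in the layout of a published
#' kinetic-parameter table: model type (pooled/by_habitat), habitat, phase,
#' parameter, estimate, CI bounds, adjusted R-squared.
#'
#' @param fits named list of `tk_fit` objects.
#' @return A data frame.
#' @export
parameter_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    est <- unlist(f$estimates)
    hab <- ifelse(f$grouping == "pooled", "all",
                  sub("^k[AE]_", "", names(est)))
    par <- sub("_.*$", "", names(est))
    data.frame(model = f$grouping, habitat = hab, phase = f$phase,
               parameter = par, estimate = unname(est),
               ci_low = unname(f$ci95[, 1]), ci_high = unname(f$ci95[, 2]),
               adjusted_r2 = f$adjusted_r2, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dense fitted-curve prediction table for plotting
#'
#' @param fits named list of `tk_fit` objects (as produced by
#'   [run_pipeline()]).
#' @param schedule the [exposure_schedule()] used for the fits.
#' @param step grid step in days (default 0.25, over 0 to 42).
#' @param t_max last day of the grid.
#' @return Long data frame: `model`, `habitat`, `time_days`, `predicted`.
#' @export
prediction_table <- function(fits, schedule, step = 0.25, t_max = 42) {
  grid <- seq(0, t_max, by = step)
  t_C <- schedule$t_C
  piece <- function(fit, hab) {
    tt <- if (fit$phase == "contamination") grid[grid <= t_C]
          else grid[grid > t_C]
    sub <- data.frame(habitat = hab, time_days = tt)
    data.frame(model = fit$grouping, habitat = hab, time_days = tt,
               predicted = .refit_predict(fit, sub))
  }
  rows <- list()
  for (f in fits) {
    habs <- if (f$grouping == "pooled") "all" else f$habitats
    for (h in habs) {
      hh <- if (f$grouping == "pooled") f$habitats[1] else h
      blk <- piece(f, hh)
      blk$habitat <- h
      rows[[length(rows) + 1]] <- blk
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Command-line entry point
#'
#' Verbs: `simulate` (write a synthetic dataset), `fit`, `compare`,
#' `endpoints` (each runs the relevant slice of the pipeline), and `run`
#' (everything).  All verbs accept `--config <json>`, `--out <dir>` and
#' `--seed <int>`.  Invoke via the wrapper script in
#' `system.file("cli", "cdtk", package = "cdtk")` or directly as
#' `Rscript -e 'cdtk::cdtk_cli()' <verb> --config cfg.json --out out/`.
#'
#' @param args character vector of command-line arguments; defaults to the
#'   process arguments.
#' @return Invisibly, the verb's result object.
#' @export
cdtk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cdtk <simulate|fit|compare|endpoints|run>",
    "[--config <json>] [--out <dir>] [--seed <int>]")
  if (length(args) < 1) stop(usage, call. = FALSE)
  verb <- args[1]
  opt <- list(config = NULL, out = "cdtk_out", seed = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args))
      stop(usage, call. = FALSE)
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (!is.null(opt$seed)) opt$seed <- as.integer(opt$seed)
  cfg <- if (!is.null(opt$config))
    jsonlite::read_json(opt$config, simplifyVector = TRUE) else list()

  if (verb == "simulate") {
    args_sim <- as.list(cfg$simulate)
    if (!is.null(args_sim$schedule))
      args_sim$schedule <- do.call(exposure_schedule,
                                   as.list(args_sim$schedule))
    sim_cfg <- do.call(simulation_config, args_sim)
    if (!is.null(opt$seed)) sim_cfg$seed <- opt$seed
    ds <- generate_dataset(sim_cfg)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    paths <- write_simulated(ds, file.path(opt$out, "observations.csv"))
    message("wrote ", paste(paths, collapse = " and "))
    return(invisible(ds))
  }
  if (!verb %in% c("fit", "compare", "endpoints", "run"))
    stop(usage, call. = FALSE)
  res <- run_pipeline(cfg, out_dir = opt$out, seed = opt$seed)
  if (verb == "fit") {
    for (f in res$fits) print(f)
  } else if (verb == "compare") {
    for (cmp in res$comparisons) print(cmp)
  } else if (verb == "endpoints") {
    print(res$endpoint$fit)
    for (tt in res$endpoint$tests) print(tt)
  } else {
    message("report written to ", opt$out)
  }
  invisible(res)
}
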