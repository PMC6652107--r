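#' Load and validate a run configuration
#'
#' Configurations are YAML documents with a strict schema: unknown
#' keys are rejected so a misspelled option cannot silently fall back
#' to a default. Recognized blocks and keys:
#'
#' * `output_dir` — directory for run artifacts;
#' * `params_file` — JSON file of rate coefficients (optional; the
#'   shipped calibrated set is used when absent);
#' * `dataset_file` — measurement CSV (needed by `calibrate`);
#' * `simulation`: `duration`, `step`, `remnant_fraction`;
#' * `design`: `phx_n`, `sham_n`, `untreated_n`, `days`,
#'   `observables`;
#' * `noise`: `cv`;
#' * `optimizer`: `seed`, `n_starts`, `max_eval`, `fit_mapping`,
#'   `lower`, `upper`;
#' * `recovery`: `n_replicates`, `cv`;
#' * `report`: `make_plots`.
#'
#' @param path YAML file path, or `NULL` for an all-defaults config.
#' @return A list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  }
  schema <- list(
    output_dir = NULL, params_file = NULL, dataset_file = NULL,
    simulation = c("duration", "step", "remnant_fraction"),
    design = c("phx_n", "sham_n", "untreated_n", "days", "observables"),
    noise = "cv",
    optimizer = c("seed", "n_starts", "max_eval", "fit_mapping",
                  "lower", "upper"),
    recovery = c("n_replicates", "cv"),
    report = "make_plots"
  )
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (block in names(schema)) {
    if (!is.null(schema[[block]]) && !is.null(raw[[block]])) {
      bad <- setdiff(names(raw[[block]]), schema[[block]])
      if (length(bad)) {
        stop("unknown key(s) in config block '", block, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  defaults <- list(
    output_dir = "liverregen_run", params_file = NULL, dataset_file = NULL,
    simulation = list(duration = 100, step = 1 / 24, remnant_fraction = 0.3),
    design = list(phx_n = c(5, 4, 4, 4), sham_n = c(3, 3, 3, 6),
                  untreated_n = 10, days = c(4, 8, 14, 21),
                  observables = .OBSERVABLES),
    noise = list(cv = 0.15),
    optimizer = list(seed = 1L, n_starts = 10L, max_eval = 5000L,
                     fit_mapping = FALSE, lower = rep(0, 6),
                     upper = rep(2, 6)),
    recovery = list(n_replicates = 5L, cv = 0),
    report = list(make_plots = TRUE)
  )
  cfg <- utils::modifyList(defaults, raw)
  structure(cfg, class = "run_config")
}

config_params <- function(config) {
  if (is.null(config$params_file)) calibrated_parameters()
  else read_parameters_json(config$params_file)
}

config_bounds <- function(config) {
  list(lower = stats::setNames(as.numeric(config$optimizer$lower),
                               .PARAM_NAMES),
       upper = stats::setNames(as.numeric(config$optimizer$upper),
                               .PARAM_NAMES))
}

prepare_output_dir <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  # embed the effective configuration so the run is reproducible from
  # its artifacts alone
  yaml::write_yaml(unclass(config), file.path(config$output_dir,
                                              "config_used.yaml"))
  config$output_dir
}

write_manifest <- function(config, command, inputs, outputs) {
  manifest <- list(
    command = command,
    package = "liverregen",
    package_version = as.character(utils::packageVersion("liverregen")),
    seed = config$optimizer$seed,
    inputs = inputs,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(config$output_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Plot the four compartment curves of a trajectory
#'
#' @param trajectory A `trajectory`.
#' @return A ggplot object.
#' @export
plot_compartments <- function(trajectory) {
  df <- data.frame(time_days = trajectory$times,
                   as.data.frame(trajectory$states))
  long <- stats::reshape(df, direction = "long",
                         varying = .COMPARTMENTS, v.names = "fraction",
                         timevar = "compartment", times = .COMPARTMENTS)
  long$compartment <- factor(long$compartment, levels = .COMPARTMENTS,
                             labels = c("hepatocytes", "Kupffer cells",
                                        "macrophages", "endothelial cells"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_days,
                                     y = .data$fraction,
                                     colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time after hepatectomy (days)",
                  y = "fraction of healthy liver", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the four simulated measurement curves
#'
#' @param curves An `observable_curves` data frame.
#' @return A ggplot object, faceted by observable (free y scales:
#'   the observables live on different scales).
#' @export
plot_observables <- function(curves) {
  df <- as.data.frame(curves)
  long <- stats::reshape(df, direction = "long",
                         varying = .OBSERVABLES, v.names = "value",
                         timevar = "observable", times = .OBSERVABLES)
  long$observable <- factor(long$observable, levels = .OBSERVABLES)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_days,
                                     y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.7) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time after hepatectomy (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Run the simulation stage of the pipeline
#'
#' Integrates the post-hepatectomy model with the configured
#' parameters, writes the trajectory/observable CSV, a run manifest,
#' an embedded copy of the configuration, and (optionally) compartment
#' and observable figures. If the initial state is the homeostatic
#' fixed point the log notes it.
#'
#' @param config A `run_config` (see [load_config()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the trajectory, curves, and output
#'   paths.
#' @export
run_simulate <- function(config = load_config(), quiet = FALSE) {
  params <- config_params(config)  # fails before any output is written
  sim_cfg <- config$simulation
  initial <- apply_partial_hepatectomy(homeostatic_state(),
                                       sim_cfg$remnant_fraction)
  out_dir <- prepare_output_dir(config)
  settings <- simulation_settings(duration = sim_cfg$duration,
                                  step = sim_cfg$step,
                                  initial_state = initial, params = params)
  if (max(abs(unclass(initial) - unclass(homeostatic_state()))) < 1e-12 &&
      !quiet) {
    message("initial state is the homeostatic fixed point; curves will be flat")
  }
  traj <- integrate_model(settings)
  curves <- extract_observables(traj, params)
  csv_path <- file.path(out_dir, "curves.csv")
  write_trajectory_csv(traj, csv_path)
  outputs <- list(curves = csv_path)
  if (isTRUE(config$report$make_plots)) {
    p1 <- plot_compartments(traj)
    p2 <- plot_observables(curves)
    f1 <- file.path(out_dir, "compartments.pdf")
    f2 <- file.path(out_dir, "observables.pdf")
    ggplot2::ggsave(f1, p1, width = 7, height = 4)
    ggplot2::ggsave(f2, p2, width = 7, height = 5)
    outputs$figures <- c(f1, f2)
  }
  manifest <- write_manifest(config, "simulate",
                             inputs = list(params = as.list(unclass(params)),
                                           simulation = sim_cfg),
                             outputs = outputs)
  if (!quiet) message("simulation written to ", out_dir)
  invisible(list(trajectory = traj, curves = curves, outputs = outputs,
                 manifest = manifest))
}

#' Run the calibration stage of the pipeline
#'
#' Reads the configured measurement dataset, fits the model, and
#' writes the fit result (JSON) and the constraint report (CSV).
#'
#' @param config A `run_config` with `dataset_file` set.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the `fit_result`.
#' @export
run_calibrate <- function(config, quiet = FALSE) {
  if (is.null(config$dataset_file)) {
    stop("config must set dataset_file for calibration", call. = FALSE)
  }
  dataset <- read_dataset_csv(config$dataset_file)
  out_dir <- prepare_output_dir(config)
  opt <- config$optimizer
  fit <- fit_model(dataset, bounds = config_bounds(config),
                   seed = opt$seed, fit_mapping = isTRUE(opt$fit_mapping),
                   n_starts = opt$n_starts, max_eval = opt$max_eval)
  fit_path <- file.path(out_dir, "fit_result.json")
  write_fit_result_json(fit, fit_path)
  report_path <- file.path(out_dir, "constraint_report.csv")
  utils::write.csv(fit$constraint_report, report_path, row.names = FALSE)
  write_manifest(config, "calibrate",
                 inputs = list(dataset_file = config$dataset_file,
                               optimizer = opt),
                 outputs = list(fit = fit_path, constraints = report_path))
  if (!quiet) {
    message("fit ", if (fit$converged) "converged" else "did not converge",
            "; objective = ", signif(fit$objective, 6))
  }
  invisible(fit)
}

#' Run the synthetic-cohort stage of the pipeline
#'
#' Generates a synthetic measurement dataset from the configured
#' parameters, design, and noise model and writes it as CSV.
#'
#' @param config A `run_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the generated dataset.
#' @export
run_synth <- function(config = load_config(), quiet = FALSE) {
  params <- config_params(config)
  d <- config$design
  design <- study_design(phx_n = d$phx_n, sham_n = d$sham_n,
                         untreated_n = d$untreated_n, days = d$days,
                         observables = d$observables)
  out_dir <- prepare_output_dir(config)
  dataset <- generate_cohort(params, design = design,
                             noise = noise_model(config$noise$cv),
                             seed = config$optimizer$seed)
  path <- file.path(out_dir, "synthetic_dataset.csv")
  write_dataset_csv(dataset, path)
  write_manifest(config, "synth",
                 inputs = list(params = as.list(unclass(params)),
                               design = d, noise = config$noise),
                 outputs = list(dataset = path))
  if (!quiet) message(nrow(dataset), " records written to ", path)
  invisible(dataset)
}

#' Run the parameter-recovery stage of the pipeline
#'
#' Generates synthetic cohorts from the configured (ground-truth)
#' parameters, refits, and writes a table of true versus recovered
#' coefficients with relative errors across replicates.
#'
#' @param config A `run_config`; `recovery$n_replicates` must be >= 1.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the recovery result list.
#' @export
run_recover <- function(config = load_config(), quiet = FALSE) {
  n_rep <- config$recovery$n_replicates
  if (is.null(n_rep) || n_rep < 1) {
    stop("recovery requires n_replicates >= 1", call. = FALSE)
  }
  params <- config_params(config)
  out_dir <- prepare_output_dir(config)
  rec <- recover_parameters(params, cv = config$recovery$cv,
                            n_replicates = n_rep,
                            seed = config$optimizer$seed,
                            bounds = config_bounds(config))
  path <- file.path(out_dir, "recovery.csv")
  utils::write.csv(rec$per_replicate, path, row.names = FALSE)
  write_manifest(config, "recover",
                 inputs = list(params = as.list(unclass(params)),
                               recovery = config$recovery),
                 outputs = list(table = path,
                                median_rel_error = rec$median_rel_error))
  if (!quiet) {
    message("median relative recovery error: ",
            signif(rec$median_rel_error, 4))
  }
  invisible(rec)
}

#' Run the constraint-check stage of the pipeline
#'
#' Checks the configured parameters against the default time-course
#' constraints and writes the report.
#'
#' @param config A `run_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the constraint report data frame.
#' @export
run_check <- function(config = load_config(), quiet = FALSE) {
  params <- config_params(config)
  out_dir <- prepare_output_dir(config)
  report <- check_constraints(params)
  path <- file.path(out_dir, "constraint_report.csv")
  utils::write.csv(report, path, row.names = FALSE)
  write_manifest(config, "check",
                 inputs = list(params = as.list(unclass(params))),
                 outputs = list(report = path))
  if (!quiet) {
    message(sum(report$pass), " of ", nrow(report), " constraints satisfied")
  }
  invisible(report)
}
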