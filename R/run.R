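#' Reproducible run commands
#'
#' Thin, file-oriented wrappers binding the modelling, inference and
#' evaluation functions into reproducible runs driven by a config list (see
#' [read_run_config()]). Every run is reproducible from `(config, seed)`;
#' all randomness flows from the single master seed, which is recorded in
#' the output manifest. These functions back the command-line script
#' shipped in `inst/cli/srpdyn.R`.
#'
#' * `run_simulate`: build the configured stimulation protocols, sample
#'   amplitude tables from the configured SRP model, and write per-protocol
#'   CSVs, spike-time files and a manifest.
#' * `run_fit`: fit the configured model (SRP maximum likelihood or TM grid
#'   search) to an amplitude directory and write a JSON fit result.
#' * `run_predict`: predict per-pulse mean (and SD) for a protocol from a
#'   saved fit.
#' * `run_evaluate`: protocol hold-out with trial bootstrap; writes the
#'   (n_boot x protocols) MSE table per model.
#' * `run_recover`: parameter-recovery curve on surrogate data.
#'
#' @param config A config list (see package vignette for the schema).
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param data_dir Directory of per-protocol amplitude/spike files.
#' @param fit_path Path to a JSON fit result written by `run_fit`.
#' @param train A [spike_train()] to predict for.
#' @return Paths of the written artifacts (invisibly), or for
#'   `run_predict` the prediction data.frame.
#' @name run_commands
NULL

fitting_bases <- function(config) {
  fb <- config$fitting$basis
  taus <- if (!is.null(fb$taus)) vapply(fb$taus, parse_time, numeric(1))
          else c(0.015, 0.1, 0.65)
  lapply(taus, exp_basis)
}

write_manifest <- function(out_dir, seed, config, extra = list()) {
  manifest <- c(list(seed = seed, created = as.character(Sys.time()),
                     package_version = as.character(utils::packageVersion("srpdyn")),
                     config = config), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  path
}

#' @rdname run_commands
#' @export
run_simulate <- function(config, out_dir, seed = 1L) {
  if (is.null(config$model)) stop("config error: 'model' section is missing")
  params <- srp_from_config(config$model)
  trains <- trains_from_config(config$data, seed = seed)
  n_trials <- if (!is.null(config$data$n_trials)) as.integer(config$data$n_trials) else 1L
  protocols <- list()
  for (i in seq_along(trains)) {
    nm <- names(trains)[i]
    protocols[[nm]] <- list(
      train = trains[[nm]],
      amplitudes = sample_efficacies(params, trains[[nm]], n_trials,
                                     seed = as.integer(seed) + 1000L * i))
  }
  data <- amplitude_data(protocols)
  write_amplitude_dir(data, out_dir)
  write_manifest(out_dir, seed, config,
                 list(command = "simulate", n_trials = n_trials,
                      protocols = names(trains)))
  invisible(out_dir)
}

#' @rdname run_commands
#' @export
run_fit <- function(config, data_dir, out_dir, seed = 1L) {
  data <- read_amplitude_dir(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  type <- if (!is.null(config$model$type)) config$model$type else "srp"
  if (type == "srp") {
    bases <- fitting_bases(config)
    n_starts <- if (!is.null(config$fitting$n_starts))
      as.integer(config$fitting$n_starts) else 256L
    fixed <- config$fitting$sigma_scale
    fit <- fit_srp(data, bases, n_starts = n_starts, seed = seed,
                   sigma_scale = if (is.null(fixed)) NULL else as.numeric(fixed))
    out <- list(model = "srp",
                parameters = srp_to_config(fit$parameters),
                objective = fit$objective, converged = fit$converged,
                n_starts = fit$n_starts, seed = seed,
                per_start_objective = fit$per_start$objective,
                start_values = apply(fit$start_values, 1, as.numeric,
                                     simplify = FALSE))
  } else if (type == "tm") {
    g <- config$fitting$tm_grid
    grid <- if (is.null(g)) tm_grid() else
      tm_grid(n_U = g$n %||% 10, n_f = g$n %||% 10,
              n_tau_u = g$n %||% 10, n_tau_R = g$n %||% 10)
    variant <- config$model$variant %||% "classic"
    fit <- fit_tm(data, grid, variant = variant)
    p <- fit$parameters
    out <- list(model = "tm",
                parameters = list(U = p$U, f = p$f, tau_u = p$tau_u,
                                  tau_R = p$tau_R, variant = p$variant),
                objective = fit$objective, converged = TRUE,
                n_grid = fit$n_starts, seed = seed)
  } else stop("config error: model.type must be 'srp' or 'tm'")
  path <- file.path(out_dir, "fit.json")
  jsonlite::write_json(c(out, list(config = config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname run_commands
#' @export
run_predict <- function(fit_path, train, out_path = NULL) {
  fx <- jsonlite::read_json(fit_path, simplifyVector = FALSE)
  if (fx$model == "srp") {
    params <- srp_from_config(fx$parameters)
    fit <- structure(list(model = "srp", parameters = params), class = "fit_result")
  } else {
    p <- fx$parameters
    fit <- structure(list(model = "tm",
                          parameters = tm_parameters(p$U, p$f, p$tau_u, p$tau_R,
                                                     variant = p$variant),
                          normalize = TRUE),
                     class = "fit_result")
  }
  pred <- predict_heldout(fit, train)
  if (!is.null(out_path)) {
    utils::write.csv(pred, out_path, row.names = FALSE)
    return(invisible(out_path))
  }
  pred
}

#' @rdname run_commands
#' @export
run_evaluate <- function(config, data_dir, out_dir, seed = 1L) {
  data <- read_amplitude_dir(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ev <- config$evaluate
  n_boot <- as.integer(ev$n_boot %||% 20)
  drop_fraction <- as.numeric(ev$drop_fraction %||% 0.2)
  bases <- fitting_bases(config)
  n_starts <- as.integer(config$fitting$n_starts %||% 256)
  g <- config$fitting$tm_grid
  grid <- if (is.null(g)) tm_grid() else
    tm_grid(n_U = g$n %||% 10, n_f = g$n %||% 10,
            n_tau_u = g$n %||% 10, n_tau_R = g$n %||% 10)
  mse_srp <- holdout_bootstrap(data, "srp", n_boot = n_boot,
                               drop_fraction = drop_fraction, seed = seed,
                               mu_bases = bases, n_starts = n_starts)
  mse_tm <- holdout_bootstrap(data, "tm", n_boot = n_boot,
                              drop_fraction = drop_fraction,
                              seed = seed + 1L, grid = grid)
  utils::write.csv(as.data.frame(mse_srp),
                   file.path(out_dir, "holdout_mse_srp.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(mse_tm),
                   file.path(out_dir, "holdout_mse_tm.csv"), row.names = FALSE)
  summary <- list(srp_mean_mse = mean(mse_srp), tm_mean_mse = mean(mse_tm),
                  n_boot = n_boot, drop_fraction = drop_fraction, seed = seed)
  jsonlite::write_json(summary, file.path(out_dir, "holdout_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, seed, config, list(command = "evaluate"))
  invisible(out_dir)
}

#' @rdname run_commands
#' @export
run_recover <- function(config, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- if (!is.null(config$model)) srp_from_config(config$model)
            else surrogate_srp_parameters()
  rc <- config$recover
  sizes <- if (!is.null(rc$sizes)) as.numeric(unlist(rc$sizes)) else c(100, 500, 2000)
  rec <- recovery_experiment(params, sizes = sizes,
                             rate = as.numeric(rc$rate %||% 10),
                             n_seeds = as.integer(rc$n_seeds %||% 5),
                             seed = seed,
                             n_starts = as.integer(config$fitting$n_starts %||% 16))
  utils::write.csv(rec$details, file.path(out_dir, "recovery_details.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$curve, file.path(out_dir, "recovery_curve.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, seed, config, list(command = "recover"))
  invisible(out_dir)
}
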