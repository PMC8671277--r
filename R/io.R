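# Configuration, serialisation and the pipeline entry points behind the
# command-line wrapper (inst/cli/lvadopt.R).

.RUN_CONFIG_FIELDS <- c("profile", "scenarios", "seed", "out_dir",
                        "verbosity", "n_m", "noise_sd", "params_file",
                        "ocp", "transcription")

#' Run configuration
#'
#' Bundles everything a pipeline run needs: the patient preset (or a
#' parameter file), the scenario list, the single seed from which all
#' randomness flows, the output directory and the nested solver
#' configurations. Unknown fields are rejected on load so that typos in
#' config files fail loudly.
#'
#' @param profile patient preset name (see [make_reference_patient()]).
#' @param scenarios character subset of
#'   `c("CONSTANT", "CONTINUOUS", "PWC")`.
#' @param seed integer seed recorded with every artifact.
#' @param out_dir artifact directory.
#' @param verbosity 0 (quiet), 1 (progress).
#' @param n_m measurement count for synthetic data.
#' @param noise_sd measurement noise SD (mmHg).
#' @param params_file optional JSON parameter file overriding the preset.
#' @param ocp named list of [ocp_config()] overrides.
#' @param transcription named list of [transcription_config()] overrides.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(profile = "paper_subject",
                       scenarios = c("CONSTANT", "CONTINUOUS", "PWC"),
                       seed = 1, out_dir = "lvadopt-run", verbosity = 1,
                       n_m = 27, noise_sd = 1, params_file = NULL,
                       ocp = list(), transcription = list()) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  stopifnot(length(seed) == 1, is.finite(seed), seed == round(seed),
            n_m >= 2, noise_sd >= 0, verbosity %in% 0:1)
  ocp_cfg <- do.call(ocp_config, ocp)
  tr_cfg <- do.call(transcription_config, transcription)
  structure(list(profile = profile, scenarios = scenarios,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbosity = verbosity, n_m = as.integer(n_m),
                 noise_sd = noise_sd, params_file = params_file,
                 ocp = ocp_cfg, transcription = tr_cfg,
                 ocp_overrides = ocp, transcription_overrides = transcription),
            class = "run_config")
}

#' Load / save a run configuration (JSON)
#'
#' @param path JSON file path.
#' @return `load_config()`: a validated [run_config()] with defaults
#'   filled in; schema violations raise an error naming the field.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(obj), .RUN_CONFIG_FIELDS)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(obj$ocp)) {
    bad <- setdiff(names(obj$ocp), names(formals(ocp_config)))
    if (length(bad))
      stop("unknown ocp field(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(obj$transcription)) {
    bad <- setdiff(names(obj$transcription),
                   names(formals(transcription_config)))
    if (length(bad))
      stop("unknown transcription field(s): ", paste(bad, collapse = ", "))
  }
  args <- obj[intersect(names(obj), .RUN_CONFIG_FIELDS)]
  if (!is.null(args$ocp)) args$ocp <- as.list(args$ocp)
  if (!is.null(args$transcription))
    args$transcription <- as.list(args$transcription)
  tryCatch(do.call(run_config, args), error = function(e)
    stop("invalid configuration: ", conditionMessage(e), call. = FALSE))
}

#' @rdname load_config
#' @param cfg a [run_config()].
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(profile = cfg$profile, scenarios = cfg$scenarios,
              seed = cfg$seed, out_dir = cfg$out_dir,
              verbosity = cfg$verbosity, n_m = cfg$n_m,
              noise_sd = cfg$noise_sd)
  if (!is.null(cfg$params_file)) out$params_file <- cfg$params_file
  if (length(cfg$ocp_overrides)) out$ocp <- cfg$ocp_overrides
  if (length(cfg$transcription_overrides))
    out$transcription <- cfg$transcription_overrides
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.pipeline_params <- function(cfg) {
  if (!is.null(cfg$params_file)) read_params_json(cfg$params_file)
  else make_reference_patient(cfg$profile)$params
}

.log <- function(cfg, ...) if (cfg$verbosity > 0) message(...)

#' Run a pipeline stage
#'
#' `simulate` writes the periodic pump-free cycle of the configured
#' patient as a trajectory CSV plus a JSON summary; `fit` generates a
#' synthetic measurement series from the configured seed and personalises
#' the model from a perturbed start; `optimize` solves the configured
#' scenarios and writes per-scenario results and the comparison table;
#' `report` re-reads the artifacts and prints a digest. Every artifact
#' directory receives an echo of the configuration and the seed so each
#' numerical artifact is regenerable.
#'
#' @param cmd one of `"simulate"`, `"fit"`, `"optimize"`, `"report"`.
#' @param cfg a [run_config()].
#' @return invisibly, a list of artifact paths; stages raise errors on
#'   failure (partial artifacts are retained).
#' @export
run_pipeline <- function(cmd = c("simulate", "fit", "optimize", "report"),
                         cfg = run_config()) {
  cmd <- match.arg(cmd)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  save_config(cfg, file.path(cfg$out_dir, "config-echo.json"))
  artifacts <- c(config = file.path(cfg$out_dir, "config-echo.json"))
  par <- .pipeline_params(cfg)
  patient <- make_reference_patient(cfg$profile)

  if (cmd == "simulate") {
    .log(cfg, "simulating periodic pump-free cycle")
    ss <- steady_state_x0(par, pump_constant(0), tf = patient$h_cycle,
                          lvad_present = FALSE)
    traj <- simulate_cycle(par, pump_constant(0), ss$x0,
                           tf = patient$h_cycle, lvad_present = FALSE)
    p_csv <- file.path(cfg$out_dir, "trajectory.csv")
    write_trajectory_csv(traj, p_csv)
    met <- derived_metrics(traj)
    p_json <- file.path(cfg$out_dir, "simulate-summary.json")
    jsonlite::write_json(list(seed = cfg$seed, tau = traj$tau,
                              metrics = met[c("avpd_amplitude_mm",
                                              "atrial_contraction_s",
                                              "cardiac_output_L_min")]),
                         p_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts <- c(artifacts, trajectory = p_csv, summary = p_json)
  } else if (cmd == "fit") {
    .log(cfg, "generating synthetic measurements and fitting")
    gen <- generate_measurements(patient, n_m = cfg$n_m,
                                 noise_sd = cfg$noise_sd, seed = cfg$seed)
    p_meas <- file.path(cfg$out_dir, "measurements.csv")
    write_measurements_csv(gen$data, p_meas)
    set.seed(cfg$seed + 1L)
    p0 <- patient$p * runif(9, 0.95, 1.05)
    bounds <- default_param_bounds()
    p0 <- pmin(pmax(p0, bounds$lb), bounds$ub)
    fit <- solve_pe(gen$data, p0, bounds, gen$schedule, par,
                    tf = patient$h_cycle)
    p_json <- file.path(cfg$out_dir, "pe-result.json")
    write_pe_json(fit, p_json)
    artifacts <- c(artifacts, measurements = p_meas, pe = p_json)
  } else if (cmd == "optimize") {
    .log(cfg, "solving OCP scenarios: ",
         paste(cfg$scenarios, collapse = ", "))
    cmpr <- compare_scenarios(par, cfg$ocp)
    for (sc in cfg$scenarios) {
      r <- cmpr$results[[sc]]
      if (!inherits(r, "ocp_result")) next
      base <- file.path(cfg$out_dir, paste0("ocp-", tolower(sc)))
      write_trajectory_csv(r$trajectory, paste0(base, "-trajectory.csv"))
      jsonlite::write_json(list(
        seed = cfg$seed, scenario = sc, J = r$J,
        J_unloading = r$J_unloading, J_aov = r$J_aov, tf = r$tf,
        tau = r$schedule, feasible = r$feasible,
        pulsatility = r$pulsatility$class),
        paste0(base, ".json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      artifacts <- c(artifacts, setNames(paste0(base, ".json"), sc))
    }
    p_tab <- file.path(cfg$out_dir, "comparison.csv")
    write.csv(cmpr$table, p_tab, row.names = FALSE)
    artifacts <- c(artifacts, comparison = p_tab)
    if (length(cmpr$failures))
      warning("scenario failures: ", paste(cmpr$failures, collapse = ", "))
  } else {
    files <- list.files(cfg$out_dir, pattern = "\\.(json|csv)$",
                        full.names = TRUE)
    .log(cfg, "artifacts in ", cfg$out_dir, ":")
    for (f in files) .log(cfg, "  ", basename(f))
    artifacts <- c(artifacts, setNames(files, basename(files)))
  }
  invisible(artifacts)
}
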