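# Config-driven experiment drivers that reproduce the headline protocols as
# data tables: the staircase sweet-spot run, the panel grid of ratio sweeps
# (noise corruption x fluctuation magnitude), its linear-network variant,
# and a theory-vs-simulation cross-check on random quadratics.

experiment_defaults <- function(experiment, scale = "full") {
  full <- scale == "full"
  base <- list(
    experiment = experiment,
    network = list(layer_sizes = c(12L, 20L, 10L), activation = "sigmoid"),
    n_inputs = if (full) 1000L else 200L,
    n_steps = if (full) 8000L else 2000L,
    repeats = if (full) 8L else 4L,
    window = 500L,
    master_seed = 1L,
    output_dir = NULL,
    scale = scale,
    write_plots = FALSE
  )
  extra <- switch(
    experiment,
    staircase_run = list(
      eps_magnitude = 2,
      gamma_noise_ratio = 0,
      stage_magnitudes = NULL, # geometric 0.25e..2e, 8 stages
      stage_length = if (full) 2000L else 1000L,
      settle_discard = if (full) 1500L else 600L
    ),
    sweep_grid = list(
      eps_magnitudes = c(0.5, 1, 2, 4),
      gamma_noise_ratios = c(0, 0.5, 1, 2),
      ratios = c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 2)
    ),
    linear_sweep_grid = list(
      network = list(layer_sizes = c(12L, 10L), activation = "linear"),
      eps_magnitudes = c(0.5, 1, 2),
      gamma_noise_ratios = c(0, 1),
      ratios = c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 2)
    ),
    theory_check = list(
      n_instances = if (full) 10L else 5L,
      n_par = 50L,
      eigen_range = c(0.1, 10),
      eps_magnitude = 0.5,
      ratios = seq(0.25, 1.5, by = 0.25),
      n_steps = if (full) 4000L else 2000L,
      repeats = if (full) 4L else 2L
    ),
    stop(sprintf("unknown experiment '%s'", experiment))
  )
  utils::modifyList(base, extra)
}

validate_config <- function(config) {
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(is.character(config$experiment) && length(config$experiment) == 1,
       "experiment: must be a single string")
  need(config$experiment %in% c("staircase_run", "sweep_grid",
                                "linear_sweep_grid", "theory_check"),
       "experiment: unknown experiment name")
  need(is.numeric(config$master_seed) && config$master_seed >= 0,
       "master_seed: must be a non-negative integer")
  need(is.numeric(config$n_steps) && config$n_steps >= 1,
       "n_steps: must be a positive integer")
  need(is.numeric(config$repeats) && config$repeats >= 1,
       "repeats: must be a positive integer")
  need(is.numeric(config$window) && config$window >= 1 &&
         config$window <= config$n_steps,
       "window: must be in [1, n_steps]")
  if (config$experiment %in% c("sweep_grid", "linear_sweep_grid")) {
    need(length(config$ratios) >= 1 && all(config$ratios > 0),
         "ratios: grid must be non-empty and positive")
    need(length(config$eps_magnitudes) >= 1 && all(config$eps_magnitudes > 0),
         "eps_magnitudes: grid must be non-empty and positive")
    need(length(config$gamma_noise_ratios) >= 1 &&
           all(config$gamma_noise_ratios >= 0),
         "gamma_noise_ratios: grid must be non-empty and non-negative")
  }
  if (config$experiment == "staircase_run") {
    need(is.numeric(config$eps_magnitude) && config$eps_magnitude > 0,
         "eps_magnitude: must be positive")
    need(config$stage_length > config$settle_discard,
         "stage_length: must exceed settle_discard")
  }
  if (length(problems)) {
    stop("invalid experiment config:\n  ",
         paste(problems, collapse = "\n  "))
  }
  invisible(config)
}

# FNV-1a hash of the serialized config, for provenance columns in CSVs.
# Output location and plotting flags do not affect the science, so they are
# excluded: identical protocols hash identically wherever they are written.
config_hash <- function(config) {
  config <- config[setdiff(names(config), c("output_dir", "write_plots"))]
  config <- config[order(names(config))]
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run a configured experiment
#'
#' Executes one of the shipped experiment protocols and (optionally) writes
#' its outputs: per-cell CSV tables, a JSON summary with the argmin ratios,
#' the fully resolved config, and PNG plots of the steady-error-vs-ratio
#' curves.  Every CSV row carries the master seed and a hash of the resolved
#' config, so runs are reconstructible.
#'
#' @param config a named list of overrides, or a path to a YAML/JSON config
#'   file.  Must contain `experiment`, one of `"staircase_run"`,
#'   `"sweep_grid"`, `"linear_sweep_grid"`, `"theory_check"`.  Defaults
#'   for all other fields come from the experiment's preset at the given
#'   `scale` (`"full"` = the headline protocol: 8000 steps, 8 repeats,
#'   1000-input suites; `"desk"` = a reduced version for interactive use).
#' @param output_dir directory for output files; overrides the config; if
#'   neither is set, nothing is written and results are only returned.
#' @param scale `"full"` or `"desk"`; overrides the config.
#' @return (invisibly) a list with the resolved `config`, the result
#'   objects, a `summary` list, and `files` written.
#' @export
run_experiment <- function(config = list(), output_dir = NULL, scale = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config_file(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$experiment)) stop("config must name an `experiment`")
  if (!is.null(scale)) config$scale <- scale
  resolved <- utils::modifyList(
    experiment_defaults(config$experiment,
                        scale = if (is.null(config$scale)) "full"
                                else config$scale),
    config)
  if (!is.null(output_dir)) resolved$output_dir <- output_dir
  validate_config(resolved)
  hash <- config_hash(resolved)
  message(sprintf("[driftcomp] experiment %s (scale %s, seed %s, config %s)",
                  resolved$experiment, resolved$scale,
                  resolved$master_seed, hash))

  out <- switch(resolved$experiment,
                staircase_run = exp_staircase(resolved),
                sweep_grid = exp_sweep_grid(resolved, linear = FALSE),
                linear_sweep_grid = exp_sweep_grid(resolved, linear = TRUE),
                theory_check = exp_theory_check(resolved))
  out$config <- resolved
  out$config_hash <- hash
  out$files <- write_experiment_outputs(out, resolved, hash)
  invisible(out)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

exp_staircase <- function(cfg) {
  e <- cfg$eps_magnitude
  stages <- cfg$stage_magnitudes
  if (is.null(stages)) {
    stages <- e * 0.25 * (2 / 0.25)^(seq(0, 1, length.out = 8))
  }
  factory <- nonlinear_task_factory(cfg$network$layer_sizes, cfg$n_inputs,
                                    cfg$network$activation)
  comp <- compensation_config("exact_gradient")
  res <- staircase(factory, comp, eps_magnitude = e,
                   stage_magnitudes = stages,
                   stage_length = cfg$stage_length,
                   settle_discard = cfg$settle_discard,
                   seed = cfg$master_seed)
  list(result = res,
       table = as.data.frame(res),
       summary = list(sweet_spot_magnitude = res$sweet_spot_magnitude,
                      sweet_spot_ratio = res$sweet_spot_magnitude / e,
                      fluctuation_magnitude = e))
}

exp_sweep_grid <- function(cfg, linear = FALSE) {
  factory <- nonlinear_task_factory(cfg$network$layer_sizes, cfg$n_inputs,
                                    cfg$network$activation)
  rows <- list()
  sweeps <- list()
  argmins <- list()
  cell <- 0L
  n_cells <- length(cfg$gamma_noise_ratios) * length(cfg$eps_magnitudes)
  for (rho in cfg$gamma_noise_ratios) {
    for (e in cfg$eps_magnitudes) {
      cell <- cell + 1L
      message(sprintf("[driftcomp]  panel %d/%d: gamma2:gamma1 = %.3g, ||deps|| = %.3g",
                      cell, n_cells, rho, e))
      comp <- if (rho == 0) {
        compensation_config("exact_gradient")
      } else {
        compensation_config("corrupted_gradient", gamma1 = 1, gamma2 = rho)
      }
      sw <- tryCatch(
        ratio_sweep(factory, comp, eps_magnitude = e, ratios = cfg$ratios,
                    n_steps = cfg$n_steps, repeats = cfg$repeats,
                    seed = mix_seed(cfg$master_seed, "panel", cell),
                    window = cfg$window),
        error = function(err) {
          warning(sprintf("panel (rho = %.3g, e = %.3g) failed: %s",
                          rho, e, conditionMessage(err)))
          NULL
        })
      if (is.null(sw)) next
      key <- sprintf("rho=%g|eps=%g", rho, e)
      sweeps[[key]] <- sw
      argmins[[key]] <- sw$argmin_ratio
      df <- as.data.frame(sw)
      df$gamma_noise_ratio <- rho
      df$eps_magnitude <- e
      rows[[key]] <- df
    }
  }
  list(result = sweeps,
       table = do.call(rbind, rows),
       summary = list(argmin_ratios = argmins,
                      linear = linear))
}

exp_theory_check <- function(cfg) {
  rows <- list()
  for (k in seq_len(cfg$n_instances)) {
    seed_k <- mix_seed(cfg$master_seed, "instance", k)
    lam <- with_seed(mix_seed(seed_k, "spectrum"), {
      exp(runif(cfg$n_par, log(cfg$eigen_range[1]), log(cfg$eigen_range[2])))
    })
    quad <- make_quadratic(lam, numeric(cfg$n_par), seed = seed_k)
    comp <- compensation_config("exact_gradient")
    sw <- ratio_sweep(quad, comp, eps_magnitude = cfg$eps_magnitude,
                      ratios = cfg$ratios, n_steps = cfg$n_steps,
                      repeats = cfg$repeats, seed = seed_k,
                      window = cfg$window)
    # Theory evaluated over the steady-state ensemble of the argmin run
    traj <- run_maintenance(quad, comp, cfg$eps_magnitude,
                            c_magnitude = sw$argmin_ratio * cfg$eps_magnitude,
                            n_steps = cfg$n_steps,
                            seed = mix_seed(seed_k, "oppoint"),
                            record_weights_every = 20L)
    pred <- predicted_ratio_steady(quad, traj)
    rows[[k]] <- data.frame(instance = k, seed = seed_k,
                            predicted_ratio = pred,
                            simulated_argmin = sw$argmin_ratio,
                            grid_step = max(diff(sort(cfg$ratios))))
  }
  tab <- do.call(rbind, rows)
  list(result = tab, table = tab,
       summary = list(
         max_abs_gap = max(abs(tab$predicted_ratio - tab$simulated_argmin)),
         within_one_grid_step = all(
           abs(tab$predicted_ratio - tab$simulated_argmin) <=
             tab$grid_step + 1e-12)))
}

#' Predicted optimal ratio for gradient compensation on a quadratic
#'
#' Evaluates \eqn{\sqrt{Q[\Delta\epsilon] / Q[\Delta c]}} at a given
#' operating point: \eqn{Q[\Delta\epsilon] = \mathrm{Tr}(H)/N} and
#' \eqn{Q[\Delta c]} from the closed-form gradient-direction curvature
#' [q_gradient_quadratic()].
#'
#' @param quad a `quadratic_landscape`.
#' @param w the operating point (commonly time-averaged steady-state
#'   weights).
#' @return predicted compensation:fluctuation ratio.
#' @export
predicted_ratio_quadratic <- function(quad, w) {
  proj <- drop(crossprod(quad$basis, w - quad$w_star))
  q_c <- q_gradient_quadratic(quad$eigenvalues, proj)
  q_eps <- expected_q_random(sum(quad$eigenvalues), quad$n_par)
  steady_state_ratio(q_eps, q_c)
}

#' Steady-state ratio prediction from a simulated trajectory
#'
#' Evaluates the optimal-ratio prediction over the steady-state ensemble of
#' a quadratic-landscape trajectory: the squared eigen-projections
#' \eqn{c_i^2} of \eqn{w - w^*} are time-averaged over the trajectory's
#' stored weight snapshots (after discarding the settling phase) before
#' applying [q_gradient_quadratic()].  Averaging squared projections rather
#' than the weights themselves keeps the fluctuation-driven components,
#' which a plain mean would cancel.
#'
#' @param quad the `quadratic_landscape` the trajectory ran on.
#' @param traj a `maintenance_trajectory` run with
#'   `record_weights_every > 0`.
#' @param discard_frac fraction of the run treated as settling and excluded
#'   (default the first half).
#' @return predicted compensation:fluctuation ratio.
#' @export
predicted_ratio_steady <- function(quad, traj, discard_frac = 0.5) {
  stopifnot(inherits(quad, "quadratic_landscape"),
            inherits(traj, "maintenance_trajectory"))
  if (is.null(traj$snapshots)) {
    stop("trajectory has no weight snapshots; rerun with record_weights_every > 0")
  }
  times <- as.integer(names(traj$snapshots))
  keep <- traj$snapshots[times > discard_frac * traj$n_steps]
  z2 <- rowMeans(vapply(keep, function(w) {
    drop(crossprod(quad$basis, w - quad$w_star))^2
  }, numeric(quad$n_par)))
  q_c <- q_gradient_quadratic(quad$eigenvalues, sqrt(z2))
  q_eps <- expected_q_random(sum(quad$eigenvalues), quad$n_par)
  steady_state_ratio(q_eps, q_c)
}

write_experiment_outputs <- function(out, cfg, hash) {
  if (is.null(cfg$output_dir)) return(character(0))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  tab <- out$table
  tab$config_hash <- hash
  csv <- file.path(cfg$output_dir, paste0(cfg$experiment, ".csv"))
  write.csv(tab, csv, row.names = FALSE)
  files <- c(files, csv)
  summ <- file.path(cfg$output_dir, paste0(cfg$experiment, "_summary.json"))
  jsonlite::write_json(list(experiment = cfg$experiment,
                            config_hash = hash,
                            master_seed = cfg$master_seed,
                            summary = out$summary),
                       summ, auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- c(files, summ)
  cfgf <- file.path(cfg$output_dir, paste0(cfg$experiment, "_config.json"))
  jsonlite::write_json(cfg, cfgf, auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- c(files, cfgf)
  if (isTRUE(cfg$write_plots) && !is.null(out$result) &&
      inherits(out$result[[1]], "sweep_result")) {
    for (key in names(out$result)) {
      png_path <- file.path(cfg$output_dir,
                            paste0(cfg$experiment, "_",
                                   gsub("[^0-9a-zA-Z._-]", "_", key), ".png"))
      plot_sweep(out$result[[key]], png_path)
      files <- c(files, png_path)
    }
  }
  files
}

#' Plot a ratio sweep as mean steady error with +/- 1 sd shading
#'
#' One curve of mean steady-state error against the
#' compensation:fluctuation ratio, a shaded band of one standard deviation
#' across repeats, and the argmin marked.
#'
#' @param result a `sweep_result`.
#' @param path optional PNG path; when `NULL`, draws on the current device.
#' @param ... passed to [graphics::plot()].
#' @return the path (if written), invisibly.
#' @export
plot_sweep <- function(result, path = NULL, ...) {
  stopifnot(inherits(result, "sweep_result"))
  draw <- function() {
    r <- result$ratios
    m <- result$steady_errors
    s <- ifelse(is.na(result$steady_sds), 0, result$steady_sds)
    graphics::plot(r, m, type = "n",
                   ylim = range(c(m - s, m + s)),
                   xlab = "||dc|| : ||deps|| ratio",
                   ylab = "steady-state task error", ...)
    graphics::polygon(c(r, rev(r)), c(m - s, rev(m + s)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(r, m, type = "b", pch = 16, col = "steelblue4")
    graphics::points(result$argmin_ratio, min(m), pch = 8, cex = 1.6,
                     col = "firebrick")
  }
  if (is.null(path)) {
    draw()
    return(invisible(NULL))
  }
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}
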