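# Time-stepping engine: iterate w <- w + delta_c + delta_eps, recording the
# task error, plus the two headline protocols (staircase over compensation
# magnitudes; steady-state error vs compensation:fluctuation ratio sweeps).

#' Run a maintenance simulation
#'
#' Iterates the weight dynamics \eqn{w_{t+1} = w_t + \Delta c_t +
#' \Delta\epsilon_t} for `n_steps` timesteps, recording the task error at
#' every step.  The student starts at the teacher weights (network tasks)
#' or at the minimiser (quadratic landscapes) unless `start` is given, so
#' the initial error is zero and the trajectory shows pure maintenance:
#' degradation by fluctuations balanced by compensation.
#'
#' @param problem a `teacher_student_task` or `quadratic_landscape`.
#' @param comp a [compensation_config()].
#' @param eps_magnitude fluctuation norm per step (>= 0).
#' @param c_magnitude overall compensation magnitude per step (>= 0); for
#'   gradient-family rules, `(gamma1, gamma2)` are rescaled to this norm
#'   preserving their ratio.
#' @param n_steps number of timesteps (>= 1).
#' @param seed master seed; the run is fully deterministic given it.
#' @param start optional starting weight vector.
#' @param subspace optional orthonormal-column matrix restricting the
#'   fluctuations (see [fluctuation_step()]).
#' @param record_weights_every store a weight snapshot every k steps
#'   (0 = none).
#' @param mean_weight_window if > 0, also return the time-averaged weights
#'   over the final `mean_weight_window` steps (used to evaluate curvature
#'   predictions at the steady-state operating point).
#' @return object of class `maintenance_trajectory`: list with `errors`
#'   (length `n_steps + 1`, including t = 0), `w_final`, optional
#'   `snapshots` and `w_mean`, `aborted` flag, and a `config` echo.
#' @export
run_maintenance <- function(problem, comp, eps_magnitude, c_magnitude,
                            n_steps, seed = 0L, start = NULL,
                            subspace = NULL, record_weights_every = 0L,
                            mean_weight_window = 0L) {
  stopifnot(inherits(comp, "compensation_config"),
            eps_magnitude >= 0, c_magnitude >= 0, n_steps >= 1)
  loss <- as_loss(problem)
  n <- loss$n_par
  w <- if (!is.null(start)) {
    as.numeric(start)
  } else if (loss$kind == "task") {
    loss$problem$student_weights
  } else {
    loss$problem$w_star
  }
  if (length(w) != n) stop("start vector has wrong length")

  grad_rule <- comp$rule %in% c("exact_gradient", "corrupted_gradient")
  gnorm <- sqrt(comp$gamma1^2 + comp$gamma2^2)
  g1 <- comp$gamma1 / gnorm * c_magnitude
  g2 <- comp$gamma2 / gnorm * c_magnitude
  if (comp$clamp_overshoot && loss$kind != "quadratic") {
    stop("clamp_overshoot is supported on quadratic landscapes only")
  }
  if (comp$rule == "newton" && loss$kind != "quadratic") {
    stop("the newton rule is defined on quadratic landscapes only")
  }

  errors <- numeric(n_steps + 1L)
  snapshots <- if (record_weights_every > 0L) list(`0` = w) else NULL
  w_sum <- if (mean_weight_window > 0L) numeric(n) else NULL
  aborted <- FALSE

  with_seed(mix_seed(seed, "traj"), {
    for (i in seq_len(n_steps)) {
      if (grad_rule && c_magnitude > 0) {
        vg <- loss$value_grad(w)
        errors[i] <- vg$value
        g <- vg$grad
      } else {
        errors[i] <- loss$value(w)
        g <- NULL
      }
      if (!is.finite(errors[i])) {
        aborted <- TRUE
        errors <- errors[seq_len(i - 1L)]
        break
      }

      delta_c <- numeric(n)
      if (c_magnitude > 0) {
        if (grad_rule) {
          ng <- sqrt(sum(g^2))
          if (ng > 0) {
            m1 <- g1
            if (comp$clamp_overshoot && m1 > 0) {
              qg <- q_value(loss, w, g)
              if (qg > 0) m1 <- min(m1, optimal_magnitude(g, -g, qg))
            }
            delta_c <- -m1 * g / ng
          }
          if (g2 > 0) {
            nu <- rnorm(n)
            delta_c <- delta_c + g2 * nu / sqrt(sum(nu^2))
          }
          if (comp$renormalize) {
            ns <- sqrt(sum(delta_c^2))
            if (ns > 0) delta_c <- delta_c * c_magnitude / ns
          }
        } else if (comp$rule == "zero_order") {
          delta_c <- zero_order_step(loss, w, c_magnitude,
                                     probe_scale = comp$probe_scale)
        } else { # newton
          if (any(w != loss$problem$w_star)) {
            delta_c <- newton_step(loss$problem, w, c_magnitude)
          }
        }
      }
      delta_eps <- fluctuation_step(n, eps_magnitude, subspace = subspace)
      w <- w + delta_c + delta_eps

      if (!is.null(snapshots) && i %% record_weights_every == 0L) {
        snapshots[[as.character(i)]] <- w
      }
      if (!is.null(w_sum) && i > n_steps - mean_weight_window) {
        w_sum <- w_sum + w
      }
    }
    if (!aborted) errors[n_steps + 1L] <- loss$value(w)
  })

  structure(list(
    errors = errors,
    w_final = w,
    w_mean = if (!is.null(w_sum)) w_sum / mean_weight_window else NULL,
    snapshots = snapshots,
    aborted = aborted,
    n_steps = n_steps,
    config = list(rule = comp$rule, gamma1 = g1, gamma2 = g2,
                  renormalize = comp$renormalize,
                  eps_magnitude = eps_magnitude, c_magnitude = c_magnitude,
                  n_steps = n_steps, seed = seed,
                  kind = loss$kind, n_par = n)
  ), class = "maintenance_trajectory")
}

#' @export
print.maintenance_trajectory <- function(x, ...) {
  cat(sprintf("Maintenance trajectory (%s, %d weights, %d steps%s)\n",
              x$config$kind, x$config$n_par, x$n_steps,
              if (x$aborted) ", ABORTED" else ""))
  cat(sprintf("  rule %s | ||dc|| = %.3g, ||deps|| = %.3g\n",
              x$config$rule, x$config$c_magnitude, x$config$eps_magnitude))
  cat(sprintf("  error: start %.4g, final %.4g\n",
              x$errors[1], x$errors[length(x$errors)]))
  invisible(x)
}

#' @export
plot.maintenance_trajectory <- function(x, ...) {
  graphics::plot(seq_along(x$errors) - 1L, x$errors, type = "l",
                 xlab = "timestep", ylab = "task error", ...)
  invisible(x)
}

#' Steady-state error of a trajectory
#'
#' The time-averaged task error over the final `window` timepoints.
#'
#' @param traj a `maintenance_trajectory`.
#' @param window number of final timepoints to average (default 500).
#' @return mean of the last `window` error values.
#' @export
steady_state_error <- function(traj, window = 500L) {
  stopifnot(inherits(traj, "maintenance_trajectory"), window >= 1)
  if (window > length(traj$errors)) {
    stop("window exceeds trajectory length")
  }
  mean(traj$errors[(length(traj$errors) - window + 1L):length(traj$errors)])
}

resolve_problem <- function(problem, seed) {
  if (is.function(problem)) problem(seed) else problem
}

#' Sweep the compensation-to-fluctuation ratio
#'
#' For each ratio \eqn{r} in `ratios`, runs `repeats` independent
#' maintenance trajectories with compensation magnitude
#' \eqn{r \cdot \|\Delta\epsilon\|} and summarises the steady-state error.
#' When `problem` is a factory function (taking a seed, returning a task or
#' landscape), each repeat gets a fresh problem instance shared across all
#' ratios of that repeat; noise streams are split per (ratio, repeat) cell.
#'
#' @param problem a task/landscape, or a `function(seed)` producing one
#'   (e.g. [nonlinear_task_factory()]).
#' @param comp a [compensation_config()].
#' @param eps_magnitude fluctuation norm (> 0).
#' @param ratios positive ratio grid (ascending recommended; ties in the
#'   argmin resolve to the earliest, i.e. smallest, ratio).
#' @param n_steps,seed,start,window,subspace as in [run_maintenance()] /
#'   [steady_state_error()].
#' @param repeats independent repeats per ratio.
#' @return object of class `sweep_result`: `ratios`, `steady_errors`
#'   (per-ratio means), `steady_sds`, `cells` (ratio x repeat matrix),
#'   `argmin_ratio`, `repeats`, `config`.
#' @export
ratio_sweep <- function(problem, comp, eps_magnitude, ratios, n_steps,
                        repeats = 8L, seed = 0L, window = 500L,
                        start = NULL, subspace = NULL) {
  stopifnot(length(ratios) >= 1, all(ratios > 0), eps_magnitude > 0,
            repeats >= 1)
  cells <- matrix(NA_real_, length(ratios), repeats)
  for (j in seq_len(repeats)) {
    prob_j <- resolve_problem(problem, mix_seed(seed, "problem", j))
    for (i in seq_along(ratios)) {
      traj <- run_maintenance(prob_j, comp, eps_magnitude,
                              c_magnitude = ratios[i] * eps_magnitude,
                              n_steps = n_steps,
                              seed = mix_seed(seed, "cell", i, j),
                              start = start, subspace = subspace)
      if (traj$aborted) {
        warning(sprintf("trajectory aborted (ratio %.3g, repeat %d); cell excluded",
                        ratios[i], j))
      } else {
        cells[i, j] <- steady_state_error(traj, window)
      }
    }
  }
  means <- rowMeans(cells, na.rm = TRUE)
  sds <- apply(cells, 1L, stats::sd, na.rm = TRUE)
  structure(list(
    ratios = ratios,
    steady_errors = means,
    steady_sds = sds,
    cells = cells,
    argmin_ratio = ratios[which.min(means)],
    repeats = repeats,
    config = list(rule = comp$rule,
                  gamma_noise_ratio = if (comp$gamma1 > 0)
                    comp$gamma2 / comp$gamma1 else Inf,
                  eps_magnitude = eps_magnitude, n_steps = n_steps,
                  window = window, seed = seed)
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Ratio sweep: %d ratios x %d repeats (%s rule, ||deps|| = %.3g)\n",
              length(x$ratios), x$repeats, x$config$rule,
              x$config$eps_magnitude))
  cat(sprintf("  argmin ratio: %.3g (steady error %.4g)\n",
              x$argmin_ratio, min(x$steady_errors)))
  invisible(x)
}

#' @export
summary.sweep_result <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- data.frame(ratio = object$ratios,
                    mean_steady_error = object$steady_errors,
                    sd_steady_error = object$steady_sds)
  cat(sprintf("Steady-state error vs compensation:fluctuation ratio (argmin %.3g)\n",
              object$argmin_ratio))
  print(agg, row.names = FALSE)
  invisible(df)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  data.frame(
    ratio = rep(x$ratios, times = x$repeats),
    repeat_ = rep(seq_len(x$repeats), each = length(x$ratios)),
    steady_error = as.vector(x$cells),
    seed = x$config$seed
  )
}

#' @export
plot.sweep_result <- function(x, ...) {
  plot_sweep(x, path = NULL, ...)
  invisible(x)
}

#' Staircase protocol: step up the compensation magnitude
#'
#' Runs one continuous trajectory in which the compensation magnitude is
#' held at each value of `stage_magnitudes` for `stage_length` steps before
#' moving to the next.  Each stage's steady error is the mean over its last
#' `stage_length - settle_discard` steps.  The stage with the lowest steady
#' error is the "sweet spot"; with gradient compensation it sits below the
#' fluctuation magnitude.
#'
#' @inheritParams run_maintenance
#' @param stage_magnitudes strictly increasing compensation magnitudes.
#' @param stage_length steps per stage.
#' @param settle_discard steps discarded at the start of each stage before
#'   averaging (must be < `stage_length`).
#' @return object of class `staircase_result`: `stage_magnitudes`,
#'   `stage_steady_errors`, `sweet_spot_magnitude`, `fluctuation_magnitude`,
#'   `errors` (full concatenated series), `drift` (||w - w(0)|| at each
#'   stage end), `config`.
#' @export
staircase <- function(problem, comp, eps_magnitude, stage_magnitudes,
                      stage_length = 2000L, settle_discard = 1500L,
                      seed = 0L, start = NULL) {
  stopifnot(all(diff(stage_magnitudes) > 0), stage_length > settle_discard,
            settle_discard >= 0)
  loss <- as_loss(if (is.function(problem)) {
    problem(mix_seed(seed, "problem"))
  } else {
    problem
  })
  w <- if (!is.null(start)) {
    as.numeric(start)
  } else if (loss$kind == "task") {
    loss$problem$student_weights
  } else {
    loss$problem$w_star
  }
  w0 <- w
  n_stages <- length(stage_magnitudes)
  stage_err <- numeric(n_stages)
  drift <- numeric(n_stages)
  all_errors <- NULL
  keep <- stage_length - settle_discard
  for (s in seq_len(n_stages)) {
    traj <- run_maintenance(loss, comp, eps_magnitude,
                            c_magnitude = stage_magnitudes[s],
                            n_steps = stage_length,
                            seed = mix_seed(seed, "stage", s),
                            start = w)
    if (traj$aborted) stop(sprintf("trajectory aborted in stage %d", s))
    w <- traj$w_final
    drift[s] <- sqrt(sum((w - w0)^2))
    err <- traj$errors[-1L] # drop the carried-over starting value
    stage_err[s] <- mean(err[(stage_length - keep + 1L):stage_length])
    all_errors <- c(all_errors, err)
  }
  structure(list(
    stage_magnitudes = stage_magnitudes,
    stage_steady_errors = stage_err,
    sweet_spot_magnitude = stage_magnitudes[which.min(stage_err)],
    fluctuation_magnitude = eps_magnitude,
    errors = c(0, all_errors),
    drift = drift,
    stage_length = stage_length,
    settle_discard = settle_discard,
    config = list(rule = comp$rule, eps_magnitude = eps_magnitude,
                  stage_length = stage_length,
                  settle_discard = settle_discard, seed = seed)
  ), class = "staircase_result")
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf("Staircase: %d stages, ||deps|| = %.3g\n",
              length(x$stage_magnitudes), x$fluctuation_magnitude))
  cat(sprintf("  sweet-spot magnitude: %.3g (ratio %.3g to fluctuations)\n",
              x$sweet_spot_magnitude,
              x$sweet_spot_magnitude / x$fluctuation_magnitude))
  invisible(x)
}

#' @export
as.data.frame.staircase_result <- function(x, ...) {
  data.frame(stage = seq_along(x$stage_magnitudes),
             c_magnitude = x$stage_magnitudes,
             steady_error = x$stage_steady_errors,
             drift = x$drift,
             seed = x$config$seed)
}

#' @export
plot.staircase_result <- function(x, ...) {
  graphics::plot(seq_along(x$errors) - 1L, x$errors, type = "l",
                 xlab = "timestep", ylab = "task error", ...)
  bounds <- cumsum(rep(x$stage_length, length(x$stage_magnitudes)))
  graphics::abline(v = bounds, lty = 3, col = "grey60")
  invisible(x)
}

#' Factory for fresh nonlinear student-teacher tasks
#'
#' Returns a `function(seed)` building a sigmoid network task: Xavier
#' teacher of the given architecture plus a fresh unit-Gaussian input suite.
#' Handy as the `problem` argument of [ratio_sweep()], which draws a fresh
#' teacher per repeat.
#'
#' @param layer_sizes architecture (input dimension first); default the
#'   12-20-10 network.
#' @param n_inputs suite size; default 1000.
#' @param activation `"sigmoid"` or `"linear"`.
#' @return a factory `function(seed)` returning a `teacher_student_task`.
#' @export
nonlinear_task_factory <- function(layer_sizes = c(12L, 20L, 10L),
                                   n_inputs = 1000L,
                                   activation = "sigmoid") {
  force(layer_sizes); force(n_inputs); force(activation)
  function(seed) {
    teacher <- make_layered_network(layer_sizes, activation,
                                    seed = mix_seed(seed, "teacher"))
    suite <- make_input_suite(n_inputs, layer_sizes[1L],
                              seed = mix_seed(seed, "suite"))
    teacher_student_task(teacher, suite)
  }
}

#' Factory for fresh linear student-teacher tasks
#'
#' Single-layer linear network (default 12 inputs, 10 outputs).
#'
#' @inheritParams nonlinear_task_factory
#' @export
linear_task_factory <- function(layer_sizes = c(12L, 10L),
                                n_inputs = 1000L) {
  nonlinear_task_factory(layer_sizes, n_inputs, activation = "linear")
}

#' Factory for fresh quadratic landscapes with a fixed spectrum
#'
#' @param eigenvalues Hessian eigenvalues.
#' @param w_star minimiser (default the origin).
#' @return a factory `function(seed)` returning a `quadratic_landscape`
#'   with a fresh random orthonormal basis.
#' @export
quadratic_factory <- function(eigenvalues, w_star = NULL) {
  force(eigenvalues)
  if (is.null(w_star)) w_star <- numeric(length(eigenvalues))
  force(w_star)
  function(seed) make_quadratic(eigenvalues, w_star, seed = seed)
}
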