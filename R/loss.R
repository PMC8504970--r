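# Uniform "loss handle" over the two problem families.  A handle bundles
# closures for the loss value, analytic gradient, a combined value+gradient
# pass, and Hessian-vector products, so the curvature operators and the
# simulation engine are agnostic to what generates the landscape.

#' Build a loss handle for a task or landscape
#'
#' @param problem a `teacher_student_task` or `quadratic_landscape`.
#' @return object of class `loss_handle`: list with `n_par` and closures
#'   `value(w)`, `grad(w)`, `value_grad(w)`, `hvp(w, v)`.  For quadratic
#'   landscapes the Hessian-vector product is exact; for network tasks it is
#'   a central difference of analytic gradients with step
#'   \eqn{h = 10^{-5}(1 + \|w\|_\infty)}.
#' @export
as_loss <- function(problem) UseMethod("as_loss")

#' @export
as_loss.loss_handle <- function(problem) problem

#' @export
as_loss.teacher_student_task <- function(problem) {
  task <- problem
  check_len <- function(w) {
    if (length(w) != task$n_par) stop("weight vector has wrong length")
  }
  grad_fn <- function(w) {
    check_len(w)
    task_value_grad(task, w)$grad
  }
  structure(list(
    n_par = task$n_par,
    kind = "task",
    problem = task,
    value = function(w) task_error(task, w),
    grad = grad_fn,
    value_grad = function(w) {
      check_len(w)
      task_value_grad(task, w)
    },
    hvp = function(w, v) fd_hvp(grad_fn, w, v)
  ), class = "loss_handle")
}

#' @export
as_loss.quadratic_landscape <- function(problem) {
  quad <- problem
  structure(list(
    n_par = quad$n_par,
    kind = "quadratic",
    problem = quad,
    value = function(w) quadratic_value(quad, w),
    grad = function(w) quadratic_gradient(quad, w),
    value_grad = function(w) {
      list(value = quadratic_value(quad, w), grad = quadratic_gradient(quad, w))
    },
    hvp = function(w, v) quadratic_hvp(quad, v)
  ), class = "loss_handle")
}

# Central-difference Hessian-vector product from an analytic gradient.
# Step scales with the weight magnitude to keep truncation error stable.
fd_hvp <- function(grad_fn, w, v, h_scale = 1e-5) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(numeric(length(v)))
  vhat <- v / nv
  h <- h_scale * (1 + max(abs(w)))
  (grad_fn(w + h * vhat) - grad_fn(w - h * vhat)) * nv / (2 * h)
}

#' Evaluate a loss gradient
#'
#' @param loss a `loss_handle` (or a task/landscape, coerced via [as_loss()]).
#' @param w weight vector of length `n_par`.
#' @return the gradient \eqn{\nabla F[w]} (exact backpropagation for network
#'   tasks, \eqn{H(w - w^*)} for quadratics).
#' @export
gradient <- function(loss, w) {
  loss <- as_loss(loss)
  loss$grad(w)
}

#' Hessian-vector product \eqn{\nabla^2 F[w] \, v}
#'
#' @inheritParams gradient
#' @param v direction vector; `v = 0` returns the zero vector.
#' @export
hessian_vector <- function(loss, w, v) {
  loss <- as_loss(loss)
  stopifnot(length(w) == loss$n_par, length(v) == loss$n_par)
  loss$hvp(w, v)
}

#' Directional curvature \eqn{Q_w[v] = \hat v^T \nabla^2 F[w] \hat v}
#'
#' The normalised Hessian quadratic form: the upward curvature of the loss
#' landscape in direction `v` at state `w`.  Depends only on the direction
#' of `v`, not its magnitude.
#'
#' @inheritParams gradient
#' @param v nonzero direction vector.
#' @return scalar curvature.
#' @export
q_value <- function(loss, w, v) {
  loss <- as_loss(loss)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("q_value is undefined for the zero direction")
  vhat <- v / nv
  sum(vhat * loss$hvp(w, vhat))
}

#' Hutchinson estimate of the Hessian trace
#'
#' Unbiased Monte-Carlo estimator
#' \eqn{\mathrm{Tr}(\nabla^2 F[w]) \approx \frac{1}{K}\sum_k v_k^T \nabla^2 F[w] v_k}
#' with i.i.d. Rademacher probe vectors \eqn{v_k}.
#'
#' @inheritParams gradient
#' @param n_probes number of probe vectors (>= 1).
#' @param seed optional seed for the probe draws (`NULL` = current stream).
#' @param return_samples if `TRUE`, also return the per-probe estimates.
#' @return the trace estimate, or a list with `estimate` and `samples`.
#' @export
hutchinson_trace <- function(loss, w, n_probes = 100L, seed = NULL,
                             return_samples = FALSE) {
  loss <- as_loss(loss)
  stopifnot(n_probes >= 1)
  samples <- with_seed(seed, {
    vapply(seq_len(n_probes), function(k) {
      v <- sample(c(-1, 1), loss$n_par, replace = TRUE)
      sum(v * loss$hvp(w, v))
    }, numeric(1))
  })
  if (return_samples) {
    list(estimate = mean(samples), samples = samples)
  } else {
    mean(samples)
  }
}

# Dense Hessian by Hessian-vector products against the unit basis,
# symmetrised.  Only sensible for small N.
dense_hessian <- function(loss, w, max_n = 2000L) {
  loss <- as_loss(loss)
  n <- loss$n_par
  if (n > max_n) {
    stop(sprintf("dense Hessian requested for N = %d > %d; supply trace/",
                 n, max_n),
         "min-eigenvalue estimates to classify_trained_state() instead")
  }
  H <- vapply(seq_len(n), function(i) {
    e <- numeric(n)
    e[i] <- 1
    loss$hvp(w, e)
  }, numeric(n))
  (H + t(H)) / 2
}

#' Classify a network state by its landscape curvature
#'
#' A state is *partially trained* when \eqn{\mathrm{Tr}(\nabla^2 F[w]) > 0}
#' (unbiased fluctuations increase error in expectation) and *highly
#' trained* when additionally \eqn{\nabla^2 F[w] \succeq 0} (every direction
#' curves upward, as near a local minimum).
#'
#' @inheritParams gradient
#' @param trace,min_eigenvalue optional externally supplied estimates; when
#'   both are given the Hessian is not formed.
#' @param max_n guard on forming the dense Hessian (default 2000).
#' @return object of class `trained_state`: list with `label` (one of
#'   `"highly_trained"`, `"partially_trained"`, `"neither"`), `trace`,
#'   `min_eigenvalue`.
#' @export
classify_trained_state <- function(loss, w, trace = NULL,
                                   min_eigenvalue = NULL, max_n = 2000L) {
  loss <- as_loss(loss)
  if (is.null(trace) || is.null(min_eigenvalue)) {
    if (loss$kind == "quadratic") {
      ev <- loss$problem$eigenvalues
      trace <- sum(ev)
      min_eigenvalue <- min(ev)
      spectral <- max(abs(ev))
    } else {
      H <- dense_hessian(loss, w, max_n = max_n)
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      trace <- sum(ev)
      min_eigenvalue <- min(ev)
      spectral <- max(abs(ev))
    }
  } else {
    spectral <- abs(min_eigenvalue) + abs(trace)
  }
  tol <- 1e-8 * max(spectral, .Machine$double.eps)
  label <- if (trace > 0 && min_eigenvalue >= -tol) {
    "highly_trained"
  } else if (trace > 0) {
    "partially_trained"
  } else {
    "neither"
  }
  structure(list(label = label, trace = trace,
                 min_eigenvalue = min_eigenvalue),
            class = "trained_state")
}

#' @export
print.trained_state <- function(x, ...) {
  cat(sprintf("Landscape state: %s (trace %.4g, min eigenvalue %.4g)\n",
              x$label, x$trace, x$min_eigenvalue))
  invisible(x)
}
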