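# Student-teacher maintenance task: the loss is the mean squared error of
# the current (student) weights in recreating the outputs of a frozen copy
# of the initial network (the teacher), over a fixed suite of inputs.

#' Construct a student-teacher maintenance task
#'
#' Freezes `teacher`, caches its outputs on every input of `suite`, and
#' defines the task error over student weight vectors
#' \deqn{F[w] = \frac{1}{|U|} \sum_{u \in U} \| y(w, u) - y(w_0, u) \|_2^2,}
#' where \eqn{y(w, u)} is the network output under weights \eqn{w}.  Perfect
#' maintenance (student = teacher) has error exactly zero.
#'
#' @param teacher a `layered_network`; copied and never modified.
#' @param suite an `input_suite` whose dimension matches the teacher input.
#' @param student_weights optional starting student weight vector; defaults
#'   to the teacher's own (flattened) weights.
#' @return object of class `teacher_student_task`.
#' @examples
#' net <- make_layered_network(c(4, 3), "sigmoid", seed = 1)
#' task <- teacher_student_task(net, make_input_suite(50, 4, seed = 2))
#' task_error(task, task$student_weights) # 0
#' @export
teacher_student_task <- function(teacher, suite, student_weights = NULL) {
  stopifnot(inherits(teacher, "layered_network"), inherits(suite, "input_suite"))
  if (suite$dim != teacher$layer_sizes[1L]) {
    stop("input suite dimension does not match teacher input dimension")
  }
  if (is.null(student_weights)) student_weights <- flatten_weights(teacher)
  if (length(student_weights) != teacher$n_par) {
    stop("student weight vector length does not match teacher parameter count")
  }
  structure(
    list(teacher = teacher,
         suite = suite,
         student_weights = as.numeric(student_weights),
         teacher_outputs = forward(teacher, suite$inputs),
         n_par = teacher$n_par),
    class = "teacher_student_task")
}

#' @export
print.teacher_student_task <- function(x, ...) {
  cat("Student-teacher maintenance task\n")
  cat("  architecture:", paste(x$teacher$layer_sizes, collapse = " -> "),
      sprintf("(%s)\n", x$teacher$activation))
  cat("  inputs:      ", x$suite$n_inputs, "\n")
  cat(sprintf("  current student error: %.6g\n",
              task_error(x, x$student_weights)))
  invisible(x)
}

#' Task error of a student weight vector
#'
#' @param task a `teacher_student_task`.
#' @param student_weights numeric vector of length `task$n_par`.
#' @return non-negative scalar: per-input sum of squared output errors,
#'   averaged over the input suite.
#' @export
task_error <- function(task, student_weights) {
  if (length(student_weights) != task$n_par) {
    stop("weight vector has wrong length")
  }
  student <- set_weights(task$teacher, student_weights)
  y <- forward(student, task$suite$inputs)
  sum((y - task$teacher_outputs)^2) / task$suite$n_inputs
}

# Loss value and analytic gradient in one pass (reverse-mode/backprop on
# the <=3-layer network; sigmoid derivative r(1-r) reuses the activations).
task_value_grad <- function(task, w) {
  student <- set_weights(task$teacher, w)
  acts <- forward_activations(student, task$suite$inputs)
  n_layers <- length(student$weights)
  y <- acts[[n_layers + 1L]]
  diff <- y - task$teacher_outputs
  n <- task$suite$n_inputs
  value <- sum(diff^2) / n
  grads <- vector("list", n_layers)
  delta <- 2 * diff / n
  if (student$activation == "sigmoid") delta <- delta * y * (1 - y)
  for (k in n_layers:1L) {
    grads[[k]] <- tcrossprod(delta, acts[[k]])
    if (k > 1L) {
      delta <- crossprod(student$weights[[k]], delta)
      if (student$activation == "sigmoid") {
        r <- acts[[k]]
        delta <- delta * r * (1 - r)
      }
    }
  }
  list(value = value, grad = flatten_weights(grads))
}
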