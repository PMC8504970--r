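# Shared fixtures, all built in code.

toy_task <- function(seed = 1L, layer_sizes = c(3L, 4L, 2L),
                     n_inputs = 25L, activation = "sigmoid") {
  teacher <- make_layered_network(layer_sizes, activation, seed = seed)
  suite <- make_input_suite(n_inputs, layer_sizes[1L], seed = seed + 100L)
  teacher_student_task(teacher, suite)
}

# Random perturbed student weights for a task.
perturbed_weights <- function(task, sd = 0.3, seed = 7L) {
  set.seed(seed)
  task$student_weights + rnorm(task$n_par, 0, sd)
}

# A modest anisotropic PD quadratic.
aniso_quad <- function(n = 30L, lo = 0.1, hi = 10, seed = 3L) {
  lam <- exp(seq(log(lo), log(hi), length.out = n))
  make_quadratic(lam, numeric(n), seed = seed)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", object, expected, tol))
}
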