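# Per-timestep plasticity generators.  Every weight update is decomposed as
# delta_w = delta_c + delta_eps: a compensatory term that moves downhill on
# the task-error landscape in expectation, and a task-independent
# fluctuation term of controlled norm whose direction is uncorrelated with
# the gradient.

#' Configuration of a compensatory plasticity rule
#'
#' The gradient-family update is
#' \eqn{\Delta c = -\gamma_1 \widehat{\nabla F}[w] + \gamma_2 \hat\nu},
#' with \eqn{\nu \sim N(0, I)} redrawn every step: \eqn{\gamma_2 : \gamma_1}
#' sets the noise corruption of the compensation direction and
#' \eqn{\sqrt{\gamma_1^2 + \gamma_2^2}} its overall magnitude.
#' `exact_gradient` is the \eqn{\gamma_2 = 0} special case.  `zero_order` is
#' a single-probe sign rule (probe the loss in a random direction, step with
#' or against it).  `newton` steps along \eqn{-(\nabla^2 F)^{-1} \nabla F}
#' and is defined on positive-definite quadratic landscapes only.
#'
#' @param rule one of `"exact_gradient"`, `"corrupted_gradient"`,
#'   `"zero_order"`, `"newton"`.
#' @param gamma1,gamma2 non-negative weights of the gradient and noise
#'   components (gradient-family rules; at least one must be positive).
#'   The simulation engine rescales the pair to the requested overall step
#'   magnitude, preserving `gamma2/gamma1`.
#' @param renormalize if `TRUE`, the summed corrupted-gradient step is
#'   rescaled to norm \eqn{\sqrt{\gamma_1^2+\gamma_2^2}} exactly; the
#'   default `FALSE` follows the update formula literally (the realized norm
#'   then differs by an \eqn{O(1/\sqrt{N})} cross-term).
#' @param probe_scale probe length for the zero-order rule; default
#'   \eqn{10^{-3}(1 + \|w\|_\infty)} at the evaluation point.
#' @param clamp_overshoot if `TRUE` (exact-gradient on quadratics only), cap
#'   each step at the 1-D line-search optimal magnitude so the noise-free
#'   dynamics converge to the minimum instead of bouncing around it.
#' @return object of class `compensation_config`.
#' @export
compensation_config <- function(rule = c("exact_gradient",
                                         "corrupted_gradient",
                                         "zero_order", "newton"),
                                gamma1 = 1, gamma2 = 0,
                                renormalize = FALSE,
                                probe_scale = NULL,
                                clamp_overshoot = FALSE) {
  rule <- match.arg(rule)
  stopifnot(gamma1 >= 0, gamma2 >= 0)
  if (gamma1^2 + gamma2^2 <= 0) {
    stop("an active rule needs gamma1^2 + gamma2^2 > 0")
  }
  if (rule == "exact_gradient" && gamma2 != 0) {
    stop("exact_gradient requires gamma2 = 0; use corrupted_gradient")
  }
  structure(list(rule = rule, gamma1 = gamma1, gamma2 = gamma2,
                 renormalize = renormalize, probe_scale = probe_scale,
                 clamp_overshoot = clamp_overshoot),
            class = "compensation_config")
}

#' @export
print.compensation_config <- function(x, ...) {
  cat(sprintf("Compensation rule: %s", x$rule))
  if (x$rule %in% c("exact_gradient", "corrupted_gradient")) {
    cat(sprintf(" (gamma2:gamma1 = %.3g, renormalize = %s)",
                if (x$gamma1 > 0) x$gamma2 / x$gamma1 else Inf,
                x$renormalize))
  }
  cat("\n")
  invisible(x)
}

#' Draw one synaptic-fluctuation step
#'
#' White-noise fluctuation \eqn{\Delta\epsilon \propto N(0, I)} rescaled so
#' \eqn{\|\Delta\epsilon\|_2} equals `magnitude` exactly.  If `subspace` is
#' given (an N x k matrix with orthonormal columns), the draw is projected
#' onto its span before rescaling: fluctuations restricted to, say, the
#' low-curvature eigenvectors of the Hessian model volatility confined to
#' "unimportant" synapses.
#'
#' @param n_par weight-space dimension N.
#' @param magnitude requested Euclidean norm (0 returns the zero vector).
#' @param seed optional seed (`NULL` = current stream).
#' @param subspace optional N x k orthonormal-column matrix.
#' @return numeric vector of length `n_par` with exact norm `magnitude`.
#' @export
fluctuation_step <- function(n_par, magnitude, seed = NULL, subspace = NULL) {
  stopifnot(n_par >= 1, magnitude >= 0)
  if (!is.null(subspace)) {
    subspace <- as.matrix(subspace)
    if (nrow(subspace) != n_par) stop("subspace rows must equal n_par")
    gram <- crossprod(subspace)
    if (max(abs(gram - diag(ncol(subspace)))) > 1e-8) {
      stop("subspace columns must be orthonormal")
    }
  }
  if (magnitude == 0) return(numeric(n_par))
  with_seed(seed, {
    z <- rnorm(n_par)
    if (!is.null(subspace)) z <- drop(subspace %*% crossprod(subspace, z))
    nz <- sqrt(sum(z^2))
    if (nz == 0) return(numeric(n_par)) # astronomically unlikely
    z * (magnitude / nz)
  })
}

#' One corrupted-gradient compensation step
#'
#' Returns \eqn{-\gamma_1 \widehat{\nabla F} + \gamma_2 \hat\nu} with a
#' fresh normalised Gaussian \eqn{\hat\nu}.
#'
#' @param grad the loss gradient at the current weights; must be nonzero
#'   when `gamma1 > 0`.
#' @param gamma1,gamma2 non-negative component weights.
#' @param seed optional seed (`NULL` = current stream).
#' @param renormalize if `TRUE`, rescale the sum to norm
#'   \eqn{\sqrt{\gamma_1^2 + \gamma_2^2}} exactly.
#' @return numeric step vector.
#' @export
corrupted_gradient_step <- function(grad, gamma1, gamma2, seed = NULL,
                                    renormalize = FALSE) {
  stopifnot(gamma1 >= 0, gamma2 >= 0)
  ng <- sqrt(sum(grad^2))
  if (gamma1 > 0 && ng == 0) {
    stop("degenerate gradient: cannot normalise a zero gradient with gamma1 > 0")
  }
  with_seed(seed, {
    step <- numeric(length(grad))
    if (gamma1 > 0) step <- step - gamma1 * grad / ng
    if (gamma2 > 0) {
      nu <- rnorm(length(grad))
      step <- step + gamma2 * nu / sqrt(sum(nu^2))
    }
    if (renormalize) {
      ns <- sqrt(sum(step^2))
      if (ns > 0) step <- step * sqrt(gamma1^2 + gamma2^2) / ns
    }
    step
  })
}

#' One zero-order (probe-and-keep) compensation step
#'
#' The minimal member of the REINFORCE family: draw a random unit direction
#' \eqn{\hat\delta}, probe the loss a short distance along it, and step with
#' magnitude `magnitude` along \eqn{-\mathrm{sign}(F(w + s\hat\delta) -
#' F(w)) \, \hat\delta}.  In expectation this decreases the loss for small
#' magnitudes on smooth landscapes, while the step direction itself has
#' average curvature.
#'
#' @inheritParams gradient
#' @param magnitude step norm.
#' @param probe_scale probe distance `s`; default
#'   \eqn{10^{-3}(1 + \|w\|_\infty)}.
#' @param seed optional seed (`NULL` = current stream).
#' @return numeric step vector.
#' @export
zero_order_step <- function(loss, w, magnitude, probe_scale = NULL,
                            seed = NULL) {
  loss <- as_loss(loss)
  if (is.null(probe_scale)) probe_scale <- 1e-3 * (1 + max(abs(w)))
  stopifnot(probe_scale > 0, magnitude >= 0)
  with_seed(seed, {
    d <- rnorm(loss$n_par)
    d <- d / sqrt(sum(d^2))
    s <- sign(loss$value(w + probe_scale * d) - loss$value(w))
    -s * magnitude * d
  })
}

#' One Newton compensation step on a positive-definite quadratic
#'
#' Steps along the Newton direction \eqn{-H^{-1} \nabla F(w)}, which on a
#' quadratic landscape points straight at the minimiser ("beeline"), scaled
#' to `magnitude`.
#'
#' @param quad a `quadratic_landscape` with strictly positive eigenvalues.
#' @param w current weights; must differ from the minimiser.
#' @param magnitude step norm.
#' @return numeric step vector.
#' @export
newton_step <- function(quad, w, magnitude) {
  stopifnot(inherits(quad, "quadratic_landscape"))
  if (any(quad$eigenvalues <= 0)) {
    stop("newton_step is defined only on positive-definite quadratic landscapes")
  }
  d <- quad$w_star - w # -H^{-1} H (w - w*)
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("newton_step is undefined at the minimiser")
  magnitude * d / nd
}
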