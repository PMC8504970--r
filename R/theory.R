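# Closed-form predictions of the curvature theory: expected error change of
# a combined plasticity step, the optimal compensation magnitude for a given
# direction, the steady-state compensation-to-fluctuation ratio, and the
# curvature statistics of random and gradient directions.

#' Expected second-order change in task error for one plasticity step
#'
#' Under the assumptions that fluctuations are uncorrelated with the
#' gradient and with the Hessian image of the compensation step, the
#' expected error change of \eqn{\Delta w = \Delta c + \Delta\epsilon} is
#' \deqn{E[\Delta F] = \Delta c^T \nabla F
#'   + \tfrac12 \|\Delta c\|^2 Q_w[\Delta c]
#'   + \tfrac12 \|\Delta\epsilon\|^2 E[Q_w[\Delta\epsilon]].}
#' (The fluctuation's linear and cross terms vanish in expectation.)
#'
#' @param grad loss gradient at the current weights.
#' @param delta_c compensatory step vector.
#' @param eps_magnitude fluctuation norm \eqn{\|\Delta\epsilon\|_2}.
#' @param q_c curvature \eqn{Q_w[\Delta c]} of the compensation direction.
#' @param q_eps_expected expected curvature of the fluctuation direction
#'   (\eqn{\mathrm{Tr}(\nabla^2 F)/N} for isotropic white noise).
#' @return predicted \eqn{E[\Delta F]}.
#' @export
predicted_delta_F <- function(grad, delta_c, eps_magnitude, q_c,
                              q_eps_expected) {
  stopifnot(is.finite(q_c), is.finite(q_eps_expected), eps_magnitude >= 0)
  sum(delta_c * grad) + 0.5 * sum(delta_c^2) * q_c +
    0.5 * eps_magnitude^2 * q_eps_expected
}

#' Optimal compensation magnitude for a given direction
#'
#' The magnitude of a step along direction \eqn{\hat d} that minimises the
#' second-order error change:
#' \deqn{\|\Delta c\|_2^* = \frac{-\hat d^T \widehat{\nabla F}}{Q_w[d]}
#'   \, \|\nabla F\|_2,}
#' clamped below at zero (an uphill direction gets magnitude 0).  Valid only
#' for upwardly curved directions (`q_dir > 0`); equals the 1-D line-search
#' argmin on quadratic landscapes.
#'
#' @param grad loss gradient (nonzero).
#' @param direction step direction (nonzero; only its direction is used).
#' @param q_dir curvature \eqn{Q_w[d] > 0} of the direction.
#' @return non-negative optimal magnitude.
#' @export
optimal_magnitude <- function(grad, direction, q_dir) {
  if (q_dir <= 0) {
    stop("optimal_magnitude is out of regime for non-positive curvature; ",
         "handle negative-curvature directions explicitly")
  }
  nd <- sqrt(sum(direction^2))
  ng <- sqrt(sum(grad^2))
  if (nd == 0) stop("direction must be nonzero")
  if (ng == 0) return(0)
  m <- -sum((direction / nd) * (grad / ng)) / q_dir * ng
  max(m, 0)
}

#' Optimal steady-state compensation-to-fluctuation ratio
#'
#' At steady state (\eqn{E[\Delta F] = 0}) the error-minimising
#' compensation magnitude satisfies
#' \deqn{\frac{\|\Delta c\|_2^{*2}}{\|\Delta\epsilon\|_2^2}
#'   = \frac{Q_w[\Delta\epsilon]}{Q_w[\Delta c]},}
#' so the ratio of magnitudes is \eqn{\sqrt{Q_w[\Delta\epsilon] /
#' Q_w[\Delta c]}}.  Valid only when both curvatures are strictly positive.
#' Whenever the compensation direction is at least as upwardly curved as the
#' fluctuations (\eqn{Q[\Delta c] \ge Q[\Delta\epsilon]}), the optimal ratio
#' is at most 1: optimal compensation does not outcompete the fluctuations.
#'
#' @param q_eps curvature of the fluctuation direction (> 0).
#' @param q_c curvature of the compensation direction (> 0).
#' @return \eqn{\sqrt{q_{\epsilon} / q_c}}.
#' @export
steady_state_ratio <- function(q_eps, q_c) {
  if (q_eps <= 0 || q_c <= 0) {
    stop("steady_state_ratio is out of regime unless both curvatures are positive")
  }
  sqrt(q_eps / q_c)
}

#' Expected curvature of a random direction
#'
#' A direction drawn uniformly at random has expected curvature
#' \eqn{E[Q_w[\Delta\epsilon]] = \mathrm{Tr}(\nabla^2 F[w]) / N}: the mean
#' eigenvalue of the Hessian.
#'
#' @param trace Hessian trace.
#' @param n_par dimension N (>= 1).
#' @return `trace / n_par`.
#' @export
expected_q_random <- function(trace, n_par) {
  stopifnot(n_par >= 1)
  trace / n_par
}

#' Curvature of the gradient direction on a quadratic landscape
#'
#' With Hessian eigenvalues \eqn{\lambda_i} and projections \eqn{c_i} of
#' \eqn{w - w^*} onto the eigenvectors, the gradient
#' \eqn{\nabla F = H (w - w^*)} has curvature
#' \deqn{Q_w[\nabla F[w]] = \frac{\sum_i c_i^2 \lambda_i^3}
#'   {\sum_i c_i^2 \lambda_i^2}.}
#' Because high-curvature components are amplified by \eqn{H}, this is an
#' eigenvalue average biased toward large \eqn{\lambda}: the gradient
#' direction is generically more curved than a random one.
#'
#' @param eigenvalues Hessian eigenvalues \eqn{\lambda_i}.
#' @param projections components \eqn{c_i} of \eqn{w - w^*} in the
#'   eigenbasis.
#' @return the curvature of the gradient direction.
#' @export
q_gradient_quadratic <- function(eigenvalues, projections) {
  stopifnot(length(eigenvalues) == length(projections))
  denom <- sum(projections^2 * eigenvalues^2)
  if (denom <= 0) {
    stop("degenerate state: the gradient vanishes (zero denominator)")
  }
  sum(projections^2 * eigenvalues^3) / denom
}

#' Steady state of noisy gradient descent on the isotropic quadratic
#'
#' For \eqn{F = \tfrac12 \|w - w^*\|^2} with per-step exact-gradient
#' compensation of fixed norm \eqn{m} and fluctuations of norm \eqn{e}, the
#' expected squared distance to the minimiser obeys the one-step recurrence
#' \eqn{E[d'^2] = (d - m)^2 + e^2} (the fluctuation is orthogonal to any
#' fixed vector in expectation, the gradient step is exactly radial).  Its
#' fixed point is
#' \deqn{d = \frac{m^2 + e^2}{2m}, \qquad F = d^2 / 2.}
#' The formula describes the regime \eqn{d \ge m} (equivalently
#' \eqn{e \ge m}); for \eqn{m > e}, fixed-magnitude steps overshoot the
#' minimiser and the realized steady distance departs from it (with
#' overshoot clamping, the noise-free dynamics instead converge to
#' \eqn{d = 0}).  Over all \eqn{m}, \eqn{d(m) = m/2 + e^2/(2m)} is
#' minimised at \eqn{m = e}: the optimal ratio is 1, matching
#' [steady_state_ratio()] since every direction of the isotropic landscape
#' has equal curvature.
#'
#' @param c_magnitude gradient-step norm `m` (> 0).
#' @param eps_magnitude fluctuation norm `e` (>= 0).
#' @return list with `distance` (steady \eqn{d}) and `error`
#'   (\eqn{F = d^2/2}).
#' @export
isotropic_steady_state <- function(c_magnitude, eps_magnitude) {
  stopifnot(c_magnitude > 0, eps_magnitude >= 0)
  d <- (c_magnitude^2 + eps_magnitude^2) / (2 * c_magnitude)
  list(distance = d, error = d^2 / 2)
}
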