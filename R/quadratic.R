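# Analytic quadratic landscapes F(w) = 0.5 (w - w*)' H (w - w*) with known
# eigenstructure: the exact test bed for the curvature theory (the gradient
# obeys grad F = H (w - w*), so every prediction can be checked in closed
# form).

#' Construct a quadratic loss landscape with chosen eigen-spectrum
#'
#' Builds \eqn{F(w) = \tfrac12 (w - w^*)^T H (w - w^*)} with
#' \eqn{H = B \,\mathrm{diag}(\lambda)\, B^T} for a uniformly random
#' orthonormal basis \eqn{B} (deterministic given `seed`).
#'
#' @param eigenvalues numeric vector of Hessian eigenvalues \eqn{\lambda_i}.
#' @param w_star the minimiser \eqn{w^*}; same length as `eigenvalues`.
#' @param seed non-negative integer controlling the random basis.
#' @return object of class `quadratic_landscape` with fields `eigenvalues`,
#'   `basis` (columns are eigenvectors), `w_star`, `n_par`.
#' @examples
#' quad <- make_quadratic(c(1, 4), c(0, 0), seed = 1)
#' quadratic_value(quad, quad$w_star) # 0
#' @export
make_quadratic <- function(eigenvalues, w_star, seed = 0L) {
  n <- length(eigenvalues)
  stopifnot(n >= 1, length(w_star) == n)
  basis <- with_seed(seed, random_orthonormal(n))
  structure(
    list(eigenvalues = as.numeric(eigenvalues),
         basis = basis,
         w_star = as.numeric(w_star),
         n_par = n),
    class = "quadratic_landscape")
}

# Haar-ish random orthonormal matrix: QR of a Gaussian matrix with the sign
# convention diag(R) > 0 (makes the draw unique and seed-deterministic).
random_orthonormal <- function(n) {
  if (n == 1L) return(matrix(1, 1, 1))
  qr_ <- qr(matrix(rnorm(n * n), n, n))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), n)
}

#' @export
print.quadratic_landscape <- function(x, ...) {
  cat("Quadratic loss landscape\n")
  cat("  dimension:  ", x$n_par, "\n")
  cat(sprintf("  eigenvalues: [%.4g, %.4g], trace %.4g\n",
              min(x$eigenvalues), max(x$eigenvalues), sum(x$eigenvalues)))
  invisible(x)
}

#' Evaluate a quadratic landscape
#' @param quad a `quadratic_landscape`.
#' @param w weight vector.
#' @return \eqn{F(w)}.
#' @export
quadratic_value <- function(quad, w) {
  z <- crossprod(quad$basis, w - quad$w_star)
  0.5 * sum(quad$eigenvalues * z^2)
}

#' Gradient of a quadratic landscape, \eqn{H (w - w^*)}
#' @inheritParams quadratic_value
#' @return gradient vector.
#' @export
quadratic_gradient <- function(quad, w) {
  z <- crossprod(quad$basis, w - quad$w_star)
  drop(quad$basis %*% (quad$eigenvalues * z))
}

# Exact Hessian-vector product H v (state-independent).
quadratic_hvp <- function(quad, v) {
  drop(quad$basis %*% (quad$eigenvalues * crossprod(quad$basis, v)))
}
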