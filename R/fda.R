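#' B-spline basis on a normalized-time domain
#'
#' Open uniform knot vector: `order` copies of each boundary plus
#' `K - order` equally spaced interior knots, giving exactly `K` basis
#' functions. Order 4 (cubic) with K = 20 over \[0, 100\] is the default used
#' to represent lifting waveforms.
#'
#' @param K number of basis functions (>= order).
#' @param order spline order (degree + 1), default 4.
#' @param domain length-2 interval, default c(0, 100).
#' @return object of class `bspline_basis`.
#' @export
make_basis <- function(K, order = 4, domain = c(0, 100)) {
  if (order < 2) stop("invalid basis: order must be >= 2")
  if (K < order) stop("invalid basis: K must be >= order")
  n_int <- K - order
  interior <- if (n_int > 0) seq(domain[1], domain[2], length.out = n_int + 2)[-c(1, n_int + 2)] else numeric(0)
  knots <- c(rep(domain[1], order), interior, rep(domain[2], order))
  structure(list(K = K, order = order, domain = domain, knots = knots),
            class = "bspline_basis")
}

#' Evaluate basis functions (or a derivative) at points
#'
#' @param basis a `bspline_basis`.
#' @param t evaluation points within the domain.
#' @param deriv derivative order (0 = function values).
#' @return length(t) x K design matrix.
#' @export
eval_basis <- function(basis, t, deriv = 0) {
  if (any(t < basis$domain[1] - 1e-9) || any(t > basis$domain[2] + 1e-9))
    stop("evaluation points outside basis domain")
  t <- pmin(pmax(t, basis$domain[1]), basis$domain[2])
  # splineDesign is exclusive at the right boundary; nudge inside
  eps <- (basis$domain[2] - basis$domain[1]) * 1e-12
  t[t >= basis$domain[2]] <- basis$domain[2] - eps
  splines::splineDesign(basis$knots, t, ord = basis$order,
                        derivs = rep(deriv, length(t)))
}

#' Curvature penalty matrix of a basis
#'
#' \eqn{P_{jk} = \int D^2\phi_j(t)\, D^2\phi_k(t)\, dt}, computed exactly by
#' Gauss--Legendre quadrature on each knot span (the integrand is piecewise
#' polynomial of degree 2(order - 3)).
#'
#' @param basis a `bspline_basis`.
#' @return K x K symmetric positive semi-definite matrix.
#' @export
penalty_matrix <- function(basis) {
  brk <- unique(basis$knots)
  ng <- max(2, basis$order - 2)
  gl <- pracma::gaussLegendre(ng, -1, 1)
  P <- matrix(0, basis$K, basis$K)
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    x <- (b - a) / 2 * gl$x + (a + b) / 2
    w <- (b - a) / 2 * gl$w
    B2 <- eval_basis(basis, x, deriv = 2)
    P <- P + crossprod(B2, B2 * w)
  }
  (P + t(P)) / 2
}

#' Penalized B-spline smoothing of a set of curves
#'
#' Minimizes, per curve, \eqn{\sum_i (X(t_i) - x(t_i))^2 +
#' \lambda \int (D^2 x)^2 dt} over coefficients of the basis expansion
#' \eqn{x(t) = \sum_k c_k \phi_k(t)} via the penalized normal equations.
#'
#' @param Y observations: numeric vector (one curve) or n_curves x n_points
#'   matrix, all on the common grid `argvals`.
#' @param argvals common sampling grid (within the basis domain).
#' @param basis a `bspline_basis`.
#' @param lambda roughness penalty >= 0. With `lambda = 0` the basis must not
#'   exceed the number of sample points.
#' @param labels optional data.frame of per-curve labels (subject, group...).
#' @return object of class `fd_sample`: basis, coefficient matrix
#'   (curves x K), lambda, argvals, labels.
#' @export
smooth_curves <- function(Y, argvals, basis, lambda = 0, labels = NULL) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  if (lambda < 0) stop("lambda must be >= 0")
  n <- ncol(Y)
  if (length(argvals) != n) stop("argvals length must match curve length")
  B <- eval_basis(basis, argvals)
  M <- crossprod(B)
  if (lambda > 0) M <- M + lambda * penalty_matrix(basis)
  R <- tryCatch(chol(M), error = function(e)
    stop("rank deficiency: smoothing system singular (K > N with lambda = 0?)", call. = FALSE))
  coefs <- t(backsolve(R, forwardsolve(t(R), crossprod(B, t(Y)))))
  structure(list(basis = basis, coef = coefs, lambda = lambda,
                 argvals = argvals, labels = labels),
            class = "fd_sample")
}

#' Evaluate smoothed curves (or a derivative) on a grid
#'
#' @param sample an `fd_sample`.
#' @param t evaluation points (default the sample's argvals).
#' @param deriv derivative order.
#' @return n_curves x length(t) matrix.
#' @export
eval_fd <- function(sample, t = sample$argvals, deriv = 0) {
  sample$coef %*% t(eval_basis(sample$basis, t, deriv = deriv))
}

#' @export
print.fd_sample <- function(x, ...) {
  cat(sprintf("<fd_sample> %d curve(s), K = %d (order %d), lambda = %g\n",
              nrow(x$coef), x$basis$K, x$basis$order, x$lambda))
  invisible(x)
}

#' Select the roughness penalty by generalized cross-validation
#'
#' GCV(lambda) = RSS / (n (1 - tr(S)/n)^2) summed over curves, with S the
#' smoother matrix; the grid value with smallest score is returned.
#'
#' @param Y curve matrix (curves x points) or vector.
#' @param argvals common grid.
#' @param basis a `bspline_basis`.
#' @param grid candidate lambdas (default `10^seq(-2, 4)`).
#' @return selected lambda (attribute `gcv` holds the score per candidate).
#' @export
select_lambda <- function(Y, argvals, basis, grid = 10^seq(-2, 4, by = 1)) {
  if (!length(grid)) stop("lambda grid must be non-empty")
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  n <- ncol(Y)
  B <- eval_basis(basis, argvals)
  P <- penalty_matrix(basis)
  BtB <- crossprod(B)
  scores <- sapply(grid, function(lam) {
    M <- BtB + lam * P
    Minv_Bt <- solve(M, t(B))
    trS <- sum(B * t(Minv_Bt))
    fit <- Y %*% t(B %*% Minv_Bt)
    rss <- sum((Y - fit)^2)
    rss / (n * (1 - trS / n)^2) / nrow(Y)
  })
  out <- grid[which.min(scores)]
  attr(out, "gcv") <- scores
  out
}
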