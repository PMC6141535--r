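#' Geometric anisotropy matrix
#'
#' Builds the unit-determinant symmetric positive-definite 2x2 matrix `H`
#' that defines the anisotropic distance metric
#' `d = sqrt(t(delta) %*% H %*% delta)`. The parameterization is
#' `H = [[exp(h1), h2], [h2, (1 + h2^2) * exp(-h1)]]`, so `det(H) = 1`
#' for any `(h1, h2)` and `h1 = h2 = 0` recovers the identity (isotropy).
#'
#' @param h1,h2 Anisotropy parameters (dimensionless).
#' @return A 2x2 matrix with determinant 1.
#' @export
anisotropy_matrix <- function(h1 = 0, h2 = 0) {
  stopifnot(is.finite(h1), is.finite(h2))
  matrix(c(exp(h1), h2, h2, (1 + h2^2) * exp(-h1)), 2, 2)
}

#' Anisotropic distance between two points
#'
#' Distance in the metric defined by [anisotropy_matrix()]: correlations can
#' decay faster in one direction than another (e.g. across- vs along-shelf)
#' while the area of any correlation ellipse is preserved (`det(H) = 1`).
#'
#' @param p1,p2 Numeric length-2 vectors, planar coordinates in km.
#' @param h1,h2 Anisotropy parameters; both 0 gives Euclidean distance.
#' @return Distance in km (symmetric in its arguments, 0 iff `p1 == p2`).
#' @export
anisotropic_distance <- function(p1, p2, h1 = 0, h2 = 0) {
  stopifnot(length(p1) == 2, length(p2) == 2,
            all(is.finite(p1)), all(is.finite(p2)))
  d <- as.numeric(p1) - as.numeric(p2)
  H <- anisotropy_matrix(h1, h2)
  sqrt(max(0, sum(d * (H %*% d))))
}

#' Matern correlation function
#'
#' Standard Matern correlation
#' `2^(1 - nu) / Gamma(nu) * (kappa * d)^nu * K_nu(kappa * d)`,
#' with `K_nu` the modified Bessel function of the second kind. Value 1 at
#' `d = 0`, continuous and monotone decreasing in `d`. `nu = 0.5` gives the
#' exponential correlation `exp(-kappa * d)` exactly. The package default
#' smoothness is `nu = 1`, the usual SPDE-approach choice.
#'
#' @param d Distances in km (vectorized), all `>= 0`.
#' @param kappa Inverse range parameter (1/km), `> 0`.
#' @param nu Smoothness, `> 0`. Default 1.
#' @return Correlations in (0, 1].
#' @export
matern_correlation <- function(d, kappa, nu = 1) {
  stopifnot(kappa > 0, nu > 0)
  if (any(d < 0)) stop("negative distance in matern_correlation()")
  u <- kappa * d
  out <- ifelse(u == 0, 1,
                2^(1 - nu) / gamma(nu) * u^nu * besselK(u, nu))
  # besselK underflows for large u; the correlation is 0 there
  out[!is.finite(out)] <- 0
  pmin(out, 1)
}

#' Knot-to-knot correlation matrix
#'
#' Dense anisotropic Matern correlation matrix over a knot grid, with a small
#' diagonal jitter so downstream Cholesky factorizations are stable even when
#' knots nearly coincide.
#'
#' @param grid A knot grid from [make_knot_grid()] (or any data frame with
#'   columns `x_km`, `y_km`).
#' @param kappa Inverse range (1/km).
#' @param nu Matern smoothness. Default 1.
#' @param h1,h2 Anisotropy parameters. Default isotropic.
#' @param jitter Added to the diagonal. Default `1e-8`.
#' @return Symmetric positive-definite matrix with (near-)unit diagonal.
#' @export
build_correlation_matrix <- function(grid, kappa, nu = 1, h1 = 0, h2 = 0,
                                     jitter = 1e-8) {
  xy <- as.matrix(grid[, c("x_km", "y_km")])
  n <- nrow(xy)
  if (n < 1) stop("need at least one knot")
  H <- anisotropy_matrix(h1, h2)
  dx <- outer(xy[, 1], xy[, 1], "-")
  dy <- outer(xy[, 2], xy[, 2], "-")
  d2 <- H[1, 1] * dx^2 + 2 * H[1, 2] * dx * dy + H[2, 2] * dy^2
  D <- sqrt(pmax(d2, 0))
  R <- matrix(matern_correlation(as.vector(D), kappa, nu), n, n)
  if (n > 1 && any(R[upper.tri(R)] >= 1 - 1e-12))
    warning("coincident knots: correlation matrix is rank-deficient")
  R <- (R + t(R)) / 2
  diag(R) <- 1 + jitter
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop(sprintf("correlation matrix not positive definite after jitter (smallest eigenvalue %.3e)", ev_min))
  R
}

#' Decorrelation range
#'
#' Smallest distance at which the Matern correlation has dropped to a given
#' threshold (default 10%, the convention used when quoting a field's
#' "range"), found by bracketing and bisection to 0.01 km.
#'
#' @param kappa Inverse range (1/km).
#' @param nu Smoothness. Default 1.
#' @param threshold Correlation level in (0, 1). Default 0.1.
#' @return Distance in km.
#' @export
decorrelation_range <- function(kappa, nu = 1, threshold = 0.1) {
  stopifnot(threshold > 0, threshold <= 1)
  if (threshold == 1) return(0)
  f <- function(d) matern_correlation(d, kappa, nu) - threshold
  hi <- 1 / kappa
  while (f(hi) > 0) hi <- hi * 2
  uniroot(f, c(0, hi), tol = 1e-5 / kappa)$root
}

#' Matrix-normal log-density
#'
#' Log-density of a knot-by-species (or knot-by-factor) matrix `E` whose
#' vectorization is multivariate normal with covariance `kronecker(V, R)`
#' (i.e. `R` among rows, `V` among columns), evaluated via the matrix-normal
#' identity without ever forming the Kronecker product:
#' `-np/2 log(2*pi) - p/2 log|R| - n/2 log|V| - tr(solve(V) t(E) solve(R) E)/2`.
#'
#' @param E Numeric matrix (rows = knots, columns = species/factors).
#' @param R Row covariance (knots x knots), positive definite.
#' @param V Column covariance (species x species), positive definite. Supply
#'   `L %*% t(L) + jitter * I` for factor-implied covariances.
#' @return Scalar log-density.
#' @export
matrix_normal_logpdf <- function(E, R, V) {
  E <- as.matrix(E)
  n <- nrow(E); p <- ncol(E)
  if (nrow(R) != n || ncol(R) != n) stop("R must be ", n, "x", n)
  if (nrow(V) != p || ncol(V) != p) stop("V must be ", p, "x", p)
  cR <- chol(R)
  cV <- chol(V)
  # tr(V^-1 E' R^-1 E) = || cR^-T E cV^-1 ||_F^2
  A <- backsolve(cR, E, transpose = TRUE)
  B <- t(backsolve(cV, t(A), transpose = TRUE))
  -0.5 * n * p * log(2 * pi) - p * sum(log(diag(cR))) -
    n * sum(log(diag(cV))) - 0.5 * sum(B^2)
}

# Symmetric PSD square root, tolerating (near-)semidefinite matrices.
psd_sqrt <- function(M, tol = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -tol * max(abs(lam), 1)))
    stop("matrix is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(lam, 0)) * t(e$vectors))
}

#' Sample a matrix-normal deviate
#'
#' Draws `E` (knots x species) with `vec(E) ~ MVN(0, kronecker(V, R))`.
#' `V` may be rank-deficient (factor-implied); `R` must be positive definite.
#'
#' @param R Row covariance.
#' @param V Column covariance (PSD allowed).
#' @param seed Optional integer seed for reproducibility.
#' @return Matrix of dimension `nrow(R)` x `nrow(V)`.
#' @export
sample_matrix_normal <- function(R, V, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(R); p <- nrow(V)
  A <- t(chol(R))
  B <- psd_sqrt(V)
  Z <- matrix(rnorm(n * p), n, p)
  A %*% Z %*% B
}
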