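#' PCA rotation of a loading matrix
#'
#' Rotates loadings (and, optionally, the matching factor fields) to the
#' principal-component basis of the implied species covariance `L %*% t(L)`:
#' rotated factors are orthogonal, ordered by decreasing explained variance,
#' and leave every model prediction unchanged. Computed from the SVD
#' `L = U D t(W)`: rotated loadings are `U %*% D` and factor values are
#' counter-rotated by `W`. Each rotated column's sign is normalized so its
#' largest-magnitude loading is positive.
#'
#' @param L Species x factors loading matrix.
#' @param coeffs Optional factor values to counter-rotate: a knots x factors
#'   matrix (spatial factors) or knots x factors x years array
#'   (spatiotemporal factors).
#' @return List of class `sdfa_rotated`: `L_rot`, `coeff_rot` (or `NULL`),
#'   `var_explained` (fractions, non-increasing, summing to 1), `rotation`
#'   (the orthogonal matrix `W`).
#' @export
pca_rotate <- function(L, coeffs = NULL) {
  L <- as.matrix(L)
  stopifnot(all(is.finite(L)))
  n_f <- ncol(L)
  sv <- svd(L, nu = nrow(L), nv = n_f)
  d <- sv$d[seq_len(n_f)]
  L_rot <- sv$u[, seq_len(n_f), drop = FALSE] %*% diag(d, n_f)
  W <- sv$v
  # sign convention: largest |loading| positive per factor
  for (f in seq_len(n_f)) {
    col <- L_rot[, f]
    if (length(col) && col[which.max(abs(col))] < 0) {
      L_rot[, f] <- -col
      W[, f] <- -W[, f]
    }
  }
  coeff_rot <- NULL
  if (!is.null(coeffs)) {
    if (length(dim(coeffs)) == 3) {
      coeff_rot <- coeffs
      for (t in seq_len(dim(coeffs)[3]))
        coeff_rot[, , t] <- coeffs[, , t] %*% W
    } else {
      coeff_rot <- as.matrix(coeffs) %*% W
    }
  }
  tot <- sum(d^2)
  structure(list(L_rot = L_rot, coeff_rot = coeff_rot,
                 var_explained = if (tot > 0) d^2 / tot else rep(0, n_f),
                 rotation = W),
            class = "sdfa_rotated")
}

#' Cumulative variance explained by the leading factors
#'
#' Fraction of among-species variance (trace of `L %*% t(L)`) captured by
#' the first `k` PCA-rotated factors. Monotone non-decreasing in `k` and
#' exactly 1 at the full factor count.
#'
#' @param rf An [pca_rotate()] result.
#' @param k Number of leading factors.
#' @return Fraction in `[0, 1]`.
#' @export
variance_explained <- function(rf, k) {
  stopifnot(inherits(rf, "sdfa_rotated"))
  n_f <- length(rf$var_explained)
  if (k < 1 || k > n_f) stop("k must be in [1, ", n_f, "]")
  sum(rf$var_explained[seq_len(k)])
}

#' Factor-implied species correlation matrix
#'
#' Correlations among species implied by a loading matrix:
#' `Sigma = L %*% t(L)`, `corr[i, j] = Sigma[i, j] / sqrt(Sigma[i, i] *
#' Sigma[j, j])`. Species with zero loading variance get `NA` rows/columns
#' and are flagged, never silently zeroed.
#'
#' @param L Species x factors loading matrix.
#' @return List of class `sdfa_corr` with `corr` (species x species),
#'   `undefined` (logical per species), and `NULL` CI slots (see
#'   [correlation_cis()] for uncertainty).
#' @export
species_correlations <- function(L) {
  L <- as.matrix(L)
  if (ncol(L) < 1) stop("L needs at least one factor")
  S <- L %*% t(L)
  v <- diag(S)
  undefined <- v == 0
  sdv <- sqrt(ifelse(undefined, NA_real_, v))
  corr <- S / outer(sdv, sdv)
  diag(corr)[!undefined] <- 1
  rn <- rownames(L)
  if (!is.null(rn)) dimnames(corr) <- list(rn, rn)
  structure(list(corr = corr, undefined = undefined, se = NULL,
                 ci_lo = NULL, ci_hi = NULL, significant = NULL),
            class = "sdfa_corr")
}

#' Species correlations with Monte-Carlo confidence intervals
#'
#' Propagates fixed-effect uncertainty to the factor-implied species
#' correlations: loading entries are drawn from their asymptotic normal
#' (mean = estimates, covariance = the relevant block of the inverse outer
#' Hessian), the correlation matrix is recomputed per draw, the SE is the
#' across-draw standard deviation and the CI is `estimate +/- 1.96 * SE`.
#' Correlations whose CI spans zero are marked non-significant.
#'
#' @param fit A converged [fit_sdfa()] with SEs available.
#' @param component Which loading matrix: `"omega_p"` (spatial encounter,
#'   default), `"omega_r"`, `"eps_p"` or `"eps_r"`.
#' @param n_draws Monte-Carlo draws. Default 500.
#' @param seed Integer seed.
#' @return `sdfa_corr` list: `corr`, `se`, `ci_lo`, `ci_hi`, `significant`
#'   (logical matrix; diagonal `TRUE`).
#' @export
correlation_cis <- function(fit, component = c("omega_p", "omega_r",
                                               "eps_p", "eps_r"),
                            n_draws = 500, seed = 1) {
  stopifnot(inherits(fit, "sdfa_fit"))
  component <- match.arg(component)
  if (is.null(fit$vcov_fixed))
    stop("fit has no fixed-effect covariance (outer Hessian not PD)")
  lname <- c(omega_p = "l_om_p", eps_p = "l_eps_p",
             omega_r = "l_om_r", eps_r = "l_eps_r")[[component]]
  Lname <- c(omega_p = "L_om_p", eps_p = "L_eps_p",
             omega_r = "L_om_r", eps_r = "L_eps_r")[[component]]
  idx <- which(names(fit$par_fixed) == lname)
  if (!length(idx)) stop("no estimated loadings for component ", component)
  est <- fit$par_fixed[idx]
  V <- fit$vcov_fixed[idx, idx, drop = FALSE]
  nc <- fit$config$n_species
  n_f <- ncol(fit$params[[Lname]])

  point <- species_correlations(fit$params[[Lname]])$corr
  set.seed(seed)
  A <- psd_sqrt(V)
  draws <- array(NA_real_, c(nc, nc, n_draws))
  for (b in seq_len(n_draws)) {
    lb <- est + as.vector(A %*% rnorm(length(est)))
    draws[, , b] <- species_correlations(lt_unpack(lb, nc, n_f))$corr
  }
  se <- apply(draws, c(1, 2), sd)
  ci_lo <- point - 1.96 * se
  ci_hi <- point + 1.96 * se
  significant <- !(ci_lo <= 0 & ci_hi >= 0)
  diag(significant) <- TRUE
  sp <- fit$config$species
  dimnames(point) <- dimnames(se) <- dimnames(ci_lo) <- dimnames(ci_hi) <-
    dimnames(significant) <- list(sp, sp)
  structure(list(corr = point, undefined = rep(FALSE, nc), se = se,
                 ci_lo = ci_lo, ci_hi = ci_hi, significant = significant,
                 component = component),
            class = "sdfa_corr")
}

#' Cluster species into assemblages
#'
#' Agglomerative hierarchical clustering of species on the distance
#' `1 - corr`, cut at `n_groups` groups. Undefined correlations are imputed
#' as 0 with a warning. Group labels are deterministic: numbered by first
#' appearance in species order.
#'
#' @param cs An `sdfa_corr` (or a bare correlation matrix).
#' @param n_groups Number of assemblages. Default 3 (the typical
#'   roundfish / flatfish / deeper-water split in demersal communities).
#' @param linkage Agglomeration method for [hclust()]. Default `"average"`.
#' @return Named integer vector: species -> group label.
#' @export
cluster_assemblages <- function(cs, n_groups = 3, linkage = "average") {
  corr <- if (inherits(cs, "sdfa_corr")) cs$corr else as.matrix(cs)
  n <- nrow(corr)
  if (n_groups > n) stop("n_groups (", n_groups, ") exceeds species count (", n, ")")
  if (anyNA(corr)) {
    warning("undefined correlations imputed as 0 for clustering")
    corr[is.na(corr)] <- 0
    diag(corr) <- 1
  }
  hc <- hclust(as.dist(1 - corr), method = linkage)
  grp <- cutree(hc, k = n_groups)
  # renumber by first appearance in species order
  grp <- match(grp, unique(grp))
  names(grp) <- rownames(corr)
  grp
}

fisher_z_ci <- function(r, n, level = 0.95) {
  if (n <= 3 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  hw <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

#' Regress spatiotemporal on average spatial species correlations
#'
#' How stable are pairwise species associations from year to year? For each
#' species pair, the realized correlation of the spatiotemporal
#' (year-varying) fields in each year is regressed on the realized
#' correlation of the average spatial fields; a high correlation means the
#' time-invariant association predicts the year-specific one.
#'
#' @param fit An [fit_sdfa()] result (or [simulate_truth()] object).
#' @param component `"p"` (encounter, default) or `"r"` (positive density).
#' @return List: `slope`, `intercept`, `r` (Pearson), `ci` (95% Fisher-z),
#'   `r_squared`, `n` (pair-year points).
#' @export
spatial_vs_spatiotemporal_regression <- function(fit, component = c("p", "r")) {
  component <- match.arg(component)
  st <- model_state(fit)
  L_om <- st$params[[paste0("L_om_", component)]]
  L_eps <- st$params[[paste0("L_eps_", component)]]
  omega <- st$fields[[paste0("omega_", component)]]
  eps <- st$fields[[paste0("eps_", component)]]
  nc <- nrow(L_om)
  if (nc * (nc - 1) / 2 < 3) stop("need at least 3 species pairs")
  off <- upper.tri(matrix(0, nc, nc))
  sp_corr <- cor(omega %*% t(L_om))[off]
  n_t <- dim(eps)[3]
  x <- rep(sp_corr, n_t)
  y <- unlist(lapply(seq_len(n_t), function(t)
    cor(eps[, , t] %*% t(L_eps))[off]))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  fit_lm <- lm(y ~ x)
  r <- cor(x, y)
  list(slope = unname(coef(fit_lm)[2]), intercept = unname(coef(fit_lm)[1]),
       r = r, ci = fisher_z_ci(r, length(x)), r_squared = r^2,
       n = length(x))
}

#' Correlate a rotated factor's knot coefficients with a covariate
#'
#' Pearson correlation (with a 95% Fisher-z CI) between factor values at the
#' knots and an environmental covariate such as `log(depth)` at the same
#' knots. Used to interpret latent factors post hoc without putting the
#' covariate in the model.
#'
#' @param coeffs Factor values at the knots (numeric vector).
#' @param covariate Covariate values at the same knots.
#' @return List: `r`, `ci_lo`, `ci_hi`, `n`. Constant covariates give `NA`
#'   with a warning.
#' @export
covariate_correlation <- function(coeffs, covariate) {
  stopifnot(length(coeffs) == length(covariate), all(is.finite(covariate)))
  if (sd(covariate) == 0) {
    warning("constant covariate: correlation undefined")
    return(list(r = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                n = length(coeffs)))
  }
  r <- cor(coeffs, covariate)
  ci <- fisher_z_ci(r, length(coeffs))
  list(r = r, ci_lo = ci[1], ci_hi = ci[2], n = length(coeffs))
}

#' @export
print.sdfa_corr <- function(x, ...) {
  cat("Species correlation matrix (factor-implied)\n")
  print(round(x$corr, 2))
  if (!is.null(x$significant)) {
    ns <- sum(!x$significant[upper.tri(x$significant)])
    cat(ns, "of", sum(upper.tri(x$corr)), "pairs non-significant (CI spans 0)\n")
  }
  invisible(x)
}
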