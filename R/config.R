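#' Model / simulation configuration
#'
#' Dimensions, factor counts, link and offset policy, Matern parameters and
#' the sampling distributions used by the synthetic-data generator. Defaults
#' are a Celtic-Sea-like mixed demersal fishery: 18 species-size classes
#' observed 1990-2015 (26 years) by 7 surveys over a ~715 x 445 km domain,
#' with 9 factors each for spatial and spatiotemporal variation in encounter
#' probability and positive density, and decorrelation ranges of 97 km
#' (encounter) and 140 km (density). Desk-scale analyses pass smaller values.
#'
#' @param n_species Number of species (species-size classes).
#' @param n_years Number of years (contiguous).
#' @param n_surveys Number of surveys/gears; the first is the catchability
#'   reference (its effects fixed at 0).
#' @param n_factors Factors per component; either a single integer used for
#'   all four components or a named list with elements `omega_p`, `eps_p`,
#'   `omega_r`, `eps_r`. Each must be in `[1, n_species]`.
#' @param extent Domain bounding box `c(xmin, xmax, ymin, ymax)` in km.
#' @param range_p,range_r Decorrelation range (km at correlation 0.1) of the
#'   encounter and density fields; converted internally to the Matern
#'   inverse-range `kappa` at smoothness `nu`.
#' @param nu Matern smoothness (fixed, not estimated). Default 1.
#' @param h1,h2 Geometric anisotropy parameters. Default isotropic.
#' @param offset_density Logical; if `TRUE` (default) `log(swept_area)` is
#'   added to the log positive-density predictor, so catches scale with area
#'   swept while encounter probability is area-free.
#' @param beta_p_mean,beta_p_sd Normal prior used by the generator for
#'   encounter intercepts (logit scale).
#' @param beta_r_mean,beta_r_sd Generator prior for density intercepts (log
#'   kg per km2).
#' @param delta_sd Generator SD of survey-by-species catchability effects.
#' @param loading_sd Generator SD of unstructured loadings (used when no
#'   assemblage structure is requested).
#' @param gamma_shape Per-species gamma shape `k` of positive catches
#'   (recycled to `n_species`); catch CV on encounter is `1/sqrt(k)`.
#' @param species,surveys Optional character labels.
#' @return An object of class `sdfa_config`.
#' @export
sdfa_config <- function(n_species = 18, n_years = 26, n_surveys = 7,
                        n_factors = 9,
                        extent = c(0, 715, 0, 445),
                        range_p = 97, range_r = 140, nu = 1,
                        h1 = 0, h2 = 0,
                        offset_density = TRUE,
                        beta_p_mean = 0, beta_p_sd = 1,
                        beta_r_mean = log(100), beta_r_sd = 1,
                        delta_sd = 0.5, loading_sd = 0.5,
                        gamma_shape = 1,
                        species = NULL, surveys = NULL) {
  if (is.numeric(n_factors) && length(n_factors) == 1)
    n_factors <- list(omega_p = n_factors, eps_p = n_factors,
                      omega_r = n_factors, eps_r = n_factors)
  comp <- c("omega_p", "eps_p", "omega_r", "eps_r")
  if (!all(comp %in% names(n_factors)))
    stop("n_factors must name components ", paste(comp, collapse = ", "))
  n_factors <- lapply(n_factors[comp], as.integer)
  if (any(unlist(n_factors) < 1) || any(unlist(n_factors) > n_species))
    stop("each factor count must be between 1 and n_species (", n_species, ")")
  stopifnot(n_species >= 1, n_years >= 1, n_surveys >= 1,
            range_p > 0, range_r > 0, nu > 0,
            length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  if (is.null(species)) species <- sprintf("sp%02d", seq_len(n_species))
  if (is.null(surveys)) surveys <- sprintf("survey%d", seq_len(n_surveys))
  stopifnot(length(species) == n_species, length(surveys) == n_surveys)
  gamma_shape <- rep_len(gamma_shape, n_species)
  stopifnot(all(gamma_shape > 0))
  structure(list(
    n_species = as.integer(n_species), n_years = as.integer(n_years),
    n_surveys = as.integer(n_surveys), n_factors = n_factors,
    extent = extent,
    range = c(p = range_p, r = range_r),
    kappa = c(p = kappa_for_range(range_p, nu), r = kappa_for_range(range_r, nu)),
    nu = nu, h1 = h1, h2 = h2,
    offset_density = isTRUE(offset_density),
    beta_p_mean = beta_p_mean, beta_p_sd = beta_p_sd,
    beta_r_mean = beta_r_mean, beta_r_sd = beta_r_sd,
    delta_sd = delta_sd, loading_sd = loading_sd,
    gamma_shape = gamma_shape,
    species = species, surveys = surveys
  ), class = "sdfa_config")
}

#' Matern inverse range for a stated decorrelation range
#'
#' Inverts [decorrelation_range()]: returns the `kappa` whose correlation
#' falls to `threshold` exactly at `range_km`.
#'
#' @param range_km Target range in km.
#' @param nu Matern smoothness.
#' @param threshold Correlation level defining the range. Default 0.1.
#' @return `kappa` in 1/km.
#' @export
kappa_for_range <- function(range_km, nu = 1, threshold = 0.1) {
  stopifnot(range_km > 0)
  # matern_correlation(d, kappa, nu) depends on d, kappa through kappa * d
  # only, so range scales as 1/kappa: one root-find at kappa = 1 suffices.
  u_star <- decorrelation_range(1, nu, threshold)
  u_star / range_km
}

#' @export
print.sdfa_config <- function(x, ...) {
  cat(sprintf(
    "sdfa model configuration\n  %d species, %d years, %d surveys\n  factors (omega_p/eps_p/omega_r/eps_r): %s\n  ranges: encounter %.0f km, density %.0f km (nu = %g)\n  swept-area offset on density: %s\n",
    x$n_species, x$n_years, x$n_surveys,
    paste(unlist(x$n_factors), collapse = "/"),
    x$range["p"], x$range["r"], x$nu,
    x$offset_density))
  invisible(x)
}
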