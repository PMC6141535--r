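# Uniform access to (params, fields, grid, config) for fits and simulation
# truths, so prediction products work on both.
model_state <- function(x) {
  if (inherits(x, "sdfa_fit") || inherits(x, "sdfa_truth"))
    return(list(params = x$params, fields = x$fields, grid = x$grid,
                config = x$config))
  stop("expected an sdfa_fit or sdfa_truth object")
}

species_index <- function(config, species) {
  i <- if (is.character(species)) match(species, config$species)
  else as.integer(species)
  if (anyNA(i) || any(i < 1) || any(i > config$n_species))
    stop("unknown species: ", paste(species, collapse = ", "))
  i
}

survey_index <- function(config, survey) {
  i <- if (is.character(survey)) match(survey, config$surveys)
  else as.integer(survey)
  if (anyNA(i) || any(i < 1) || any(i > config$n_surveys))
    stop("unknown survey/gear: ", paste(survey, collapse = ", "))
  i
}

#' Predicted density surface for one species and year
#'
#' At every knot: encounter probability `p` (inverse-logit predictor),
#' positive-catch density `r` (exp predictor, per km2, no swept-area
#' offset), and expected density `p * r` — the delta-gamma mean — at
#' reference catchability (all survey effects zero), so surfaces are
#' gear-free.
#'
#' @param fit An [fit_sdfa()] result or [simulate_truth()] object.
#' @param species Species label or index.
#' @param year Year index.
#' @return Data frame of class `sdfa_surface`: `knot_id`, `x_km`, `y_km`,
#'   `p`, `r`, `density` (kg per km2), plus `species`/`year` attributes.
#' @export
predict_density <- function(fit, species, year) {
  st <- model_state(fit)
  ci <- species_index(st$config, species)
  if (length(year) != 1 || year < 1 || year > st$config$n_years)
    stop("year must be a single index in [1, ", st$config$n_years, "]")
  ns <- nrow(st$grid)
  eta <- linear_predictors(st$params, st$fields, knot = seq_len(ns),
                           species = rep(ci, ns), year = rep(year, ns),
                           survey = rep(1L, ns), offset_density = FALSE)
  out <- data.frame(knot_id = st$grid$knot_id, x_km = st$grid$x_km,
                    y_km = st$grid$y_km, p = plogis(eta$eta_p),
                    r = exp(eta$eta_r),
                    density = plogis(eta$eta_p) * exp(eta$eta_r))
  attr(out, "species") <- st$config$species[ci]
  attr(out, "year") <- year
  class(out) <- c("sdfa_surface", "data.frame")
  out
}

#' Standardize a density surface
#'
#' Z-scores the density across knots (mean 0, SD 1), putting species with
#' very different absolute abundance on a common scale so their
#' distributions can be compared. `method = "minmax"` rescales to [0, 1]
#' instead. A constant surface is flagged and returned as all zeros.
#'
#' @param ds An [predict_density()] surface (or any data frame with a
#'   `density` column).
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return The input with a `density_std` column added.
#' @export
standardize_surface <- function(ds, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  if (nrow(ds) < 2) stop("need at least 2 knots to standardize")
  d <- ds$density
  if (sd(d) == 0) {
    warning("constant density surface: standardized values set to 0")
    ds$density_std <- rep(0, length(d))
    return(ds)
  }
  ds$density_std <- switch(method,
    zscore = (d - mean(d)) / sd(d),
    minmax = (d - min(d)) / (max(d) - min(d)))
  ds
}

#' Standardized density difference map between two species
#'
#' Per-knot difference of the two species' standardized density surfaces in
#' one year: positive values mark knots where species A is relatively more
#' concentrated than species B — the axes along which a mixed fishery can
#' separate catches of the pair. Antisymmetric under swapping the species.
#'
#' @param fit An [fit_sdfa()] result or [simulate_truth()] object.
#' @param species_a,species_b Species labels or indices.
#' @param year Year index.
#' @param method Standardization method, see [standardize_surface()].
#' @return Data frame: `knot_id`, `x_km`, `y_km`, `diff`.
#' @export
difference_map <- function(fit, species_a, species_b, year,
                           method = "zscore") {
  a <- standardize_surface(predict_density(fit, species_a, year), method)
  b <- standardize_surface(predict_density(fit, species_b, year), method)
  data.frame(knot_id = a$knot_id, x_km = a$x_km, y_km = a$y_km,
             diff = a$density_std - b$density_std)
}

#' Expected catch composition for a gear at a location
#'
#' Per-species expected catch rate `p * r` for a given survey gear at one
#' knot and year, including the gear's survey-by-species catchability
#' effects on both predictors, normalized to proportions. This is the
#' decision product for mixed fisheries: what a tow with this gear, here,
#' would be made of.
#'
#' @param fit An [fit_sdfa()] result or [simulate_truth()] object.
#' @param gear Survey/gear label or index.
#' @param knot Knot id (0-based, as in the knot grid) or 1-based row index;
#'   matched against `knot_id` first.
#' @param year Year index.
#' @return Data frame of class `sdfa_composition`: `species`,
#'   `expected_catch` (kg per km2 swept), `proportion` (sums to 1; an
#'   all-zero composition is flagged via the `defined` attribute).
#' @export
catch_composition <- function(fit, gear, knot, year) {
  st <- model_state(fit)
  v <- survey_index(st$config, gear)
  s <- match(knot, st$grid$knot_id)
  if (is.na(s)) {
    if (knot >= 1 && knot <= nrow(st$grid)) s <- as.integer(knot)
    else stop("unknown knot: ", knot)
  }
  nc <- st$config$n_species
  eta <- linear_predictors(st$params, st$fields, knot = rep(s, nc),
                           species = seq_len(nc), year = rep(year, nc),
                           survey = rep(v, nc), offset_density = FALSE)
  expected <- plogis(eta$eta_p) * exp(eta$eta_r)
  tot <- sum(expected)
  out <- data.frame(species = st$config$species,
                    expected_catch = expected,
                    proportion = if (tot > 0) expected / tot else NA_real_)
  attr(out, "defined") <- tot > 0
  attr(out, "gear") <- st$config$surveys[v]
  attr(out, "knot") <- st$grid$knot_id[s]
  attr(out, "year") <- year
  class(out) <- c("sdfa_composition", "data.frame")
  out
}

#' Yearly abundance index
#'
#' Area-weighted total expected density per year:
#' `index(t) = sum_knots area_km2 * p * r` at reference catchability — a
#' gear-free relative biomass trajectory comparable to stock-assessment
#' trends. Optional SEs propagate fixed-effect uncertainty by Monte Carlo
#' (fields held at their modes).
#'
#' @param fit An [fit_sdfa()] result or [simulate_truth()] object.
#' @param species Species labels or indices; default all.
#' @param n_draws Monte-Carlo draws for SEs (0 = point estimates only;
#'   requires a fit with SEs when positive).
#' @param seed Integer seed for the draws.
#' @return Data frame: `species`, `year`, `index` (kg), and `se` when
#'   requested.
#' @export
abundance_index <- function(fit, species = NULL, n_draws = 0, seed = 1) {
  st <- model_state(fit)
  if (is.null(species)) species <- st$config$species
  ci <- species_index(st$config, species)
  years <- seq_len(st$config$n_years)

  index_from_state <- function(params, fields) {
    ns <- nrow(st$grid)
    out <- matrix(0, length(ci), length(years))
    for (j in seq_along(years)) {
      eta <- linear_predictors(params, fields,
                               knot = rep(seq_len(ns), length(ci)),
                               species = rep(ci, each = ns),
                               year = rep(years[j], ns * length(ci)),
                               survey = rep(1L, ns * length(ci)),
                               offset_density = FALSE)
      dens <- matrix(plogis(eta$eta_p) * exp(eta$eta_r), ns, length(ci))
      out[, j] <- colSums(dens * st$grid$area_km2)
    }
    out
  }
  est <- index_from_state(st$params, st$fields)
  out <- data.frame(species = rep(st$config$species[ci], length(years)),
                    year = rep(years, each = length(ci)),
                    index = as.vector(est))
  if (n_draws > 0) {
    if (!inherits(fit, "sdfa_fit") || is.null(fit$vcov_fixed))
      stop("SEs require a fitted model with fixed-effect covariance")
    set.seed(seed)
    A <- psd_sqrt(fit$vcov_fixed)
    lp0 <- fit$obj$env$last.par.best
    rnd <- fit$obj$env$random
    sims <- array(0, c(length(ci), length(years), n_draws))
    for (b in seq_len(n_draws)) {
      lp <- lp0
      lp[-rnd] <- fit$par_fixed + as.vector(A %*% rnorm(nrow(A)))
      pl <- fit$obj$env$parList(par = lp)
      nf <- st$config$n_factors
      nc <- st$config$n_species
      pb <- list(beta_p = pl$beta_p, beta_r = pl$beta_r,
                 L_om_p = lt_unpack(pl$l_om_p, nc, nf$omega_p),
                 L_eps_p = lt_unpack(pl$l_eps_p, nc, nf$eps_p),
                 L_om_r = lt_unpack(pl$l_om_r, nc, nf$omega_r),
                 L_eps_r = lt_unpack(pl$l_eps_r, nc, nf$eps_r),
                 delta_p = pl$delta_p, delta_r = pl$delta_r,
                 k = exp(pl$log_k))
      sims[, , b] <- index_from_state(pb, st$fields)
    }
    out$se <- as.vector(apply(sims, c(1, 2), sd))
  }
  out
}
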