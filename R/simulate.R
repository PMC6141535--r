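#' Simulate ground-truth parameters and latent fields
#'
#' Draws a complete parameter set and latent field set with exactly the
#' structure assumed by the model: year-by-species intercepts and
#' survey-by-species catchability effects from the normal priors recorded in
#' the configuration; factor loadings either unstructured or with planted
#' assemblage (block) structure; and unit-variance anisotropic-Matern GMRF
#' factor fields at the knots — spatial fields `omega` drawn once per factor,
#' spatiotemporal fields `eps` per factor and year. Identical
#' `(config, grid, seed)` give identical output.
#'
#' @param config An [sdfa_config()].
#' @param grid A knot grid from [make_knot_grid()].
#' @param seed Integer seed.
#' @param assemblages Optional integer/character vector of length
#'   `n_species` mapping each species to an assemblage. When supplied,
#'   loadings are block-structured: each factor is assigned a dominant
#'   assemblage (cycling through them) whose species load with magnitude 1,
#'   other species with magnitude 0.2; each factor's overall sign is random,
#'   and off-block signs are random per entry.
#' @return An object of class `sdfa_truth`: list with `params` (see Details),
#'   `fields` (`omega_p`, `omega_r`: knots x factors; `eps_p`, `eps_r`:
#'   knots x factors x years), `grid`, `config`, `seed`, `assemblage_map`.
#'
#' @details `params` holds `beta_p`, `beta_r` (species x years), the four
#' loading matrices `L_om_p`, `L_eps_p`, `L_om_r`, `L_eps_r` (species x
#' factors), `delta_p`, `delta_r` (species x surveys, first column 0 as the
#' catchability reference), per-species gamma shape `k`, and the Matern
#' parameters `kappa`, `nu`, `h1`, `h2`.
#' @export
simulate_truth <- function(config, grid, seed = 1, assemblages = NULL) {
  stopifnot(inherits(config, "sdfa_config"))
  nc <- config$n_species; nt <- config$n_years; nv <- config$n_surveys
  nf <- config$n_factors
  ns <- nrow(grid)
  if (!is.null(assemblages) && length(assemblages) != nc)
    stop("assemblages must have one entry per species")
  set.seed(seed)

  block_loadings <- function(n_factor) {
    if (is.null(assemblages)) {
      L <- matrix(rnorm(nc * n_factor, 0, config$loading_sd), nc, n_factor)
    } else {
      groups <- unique(assemblages)
      L <- matrix(0, nc, n_factor)
      for (f in seq_len(n_factor)) {
        dominant <- groups[(f - 1) %% length(groups) + 1]
        s_col <- sample(c(-1, 1), 1)
        inblk <- assemblages == dominant
        L[inblk, f] <- s_col * 1.0
        L[!inblk, f] <- sample(c(-0.2, 0.2), sum(!inblk), replace = TRUE)
      }
    }
    L
  }

  params <- list(
    beta_p = matrix(rnorm(nc * nt, config$beta_p_mean, config$beta_p_sd), nc, nt),
    beta_r = matrix(rnorm(nc * nt, config$beta_r_mean, config$beta_r_sd), nc, nt),
    L_om_p = block_loadings(nf$omega_p),
    L_eps_p = block_loadings(nf$eps_p),
    L_om_r = block_loadings(nf$omega_r),
    L_eps_r = block_loadings(nf$eps_r),
    delta_p = cbind(0, matrix(rnorm(nc * (nv - 1), 0, config$delta_sd), nc)),
    delta_r = cbind(0, matrix(rnorm(nc * (nv - 1), 0, config$delta_sd), nc)),
    k = config$gamma_shape,
    kappa = config$kappa, nu = config$nu, h1 = config$h1, h2 = config$h2
  )
  if (nv == 1) {
    params$delta_p <- matrix(0, nc, 1)
    params$delta_r <- matrix(0, nc, 1)
  }
  dimnames(params$beta_p) <- dimnames(params$beta_r) <-
    list(config$species, NULL)

  R_p <- build_correlation_matrix(grid, config$kappa["p"], config$nu,
                                  config$h1, config$h2)
  R_r <- build_correlation_matrix(grid, config$kappa["r"], config$nu,
                                  config$h1, config$h2)
  cp <- t(chol(R_p)); cr <- t(chol(R_r))
  draw_fields <- function(cf, n_factor, n_rep = 1) {
    a <- array(0, c(ns, n_factor, n_rep))
    for (t in seq_len(n_rep))
      a[, , t] <- cf %*% matrix(rnorm(ns * n_factor), ns, n_factor)
    if (n_rep == 1) a[, , 1, drop = TRUE] else a
  }
  fields <- list(
    omega_p = matrix(draw_fields(cp, nf$omega_p), ns, nf$omega_p),
    eps_p = array(draw_fields(cp, nf$eps_p, nt), c(ns, nf$eps_p, nt)),
    omega_r = matrix(draw_fields(cr, nf$omega_r), ns, nf$omega_r),
    eps_r = array(draw_fields(cr, nf$eps_r, nt), c(ns, nf$eps_r, nt))
  )

  structure(list(params = params, fields = fields, grid = grid,
                 config = config, seed = seed,
                 assemblage_map = assemblages),
            class = "sdfa_truth")
}

#' Survey station plan
#'
#' How many hauls each survey makes per year, and the swept-area
#' distribution. Stations are placed uniformly at random over the knot
#' grid's extent and mapped to the nearest knot.
#'
#' @param hauls_per_year Integer vector, one entry per survey (recycled).
#' @param years Years to sample (indices into the configured year range).
#' @param swept_area_meanlog,swept_area_sdlog Lognormal swept-area (km2)
#'   parameters; the default median of 0.05 km2 is a typical research-trawl
#'   tow.
#' @return List of class `sdfa_design`.
#' @export
survey_design <- function(hauls_per_year, years,
                          swept_area_meanlog = log(0.05),
                          swept_area_sdlog = 0.25) {
  stopifnot(length(years) >= 1, all(hauls_per_year >= 0))
  structure(list(hauls_per_year = hauls_per_year, years = years,
                 swept_area_meanlog = swept_area_meanlog,
                 swept_area_sdlog = swept_area_sdlog),
            class = "sdfa_design")
}

#' Simulate haul-level survey catches from a ground truth
#'
#' For each haul and species, encounter is Bernoulli with probability `p`
#' from the logit-link predictor at the haul's nearest knot; on encounter the
#' catch is gamma with per-species shape `k` and mean `r` from the log-link
#' predictor (times swept area when the offset policy is on). Zeros are
#' explicit: every haul x species pair appears.
#'
#' @param truth An [simulate_truth()] object.
#' @param design A [survey_design()].
#' @param seed Integer seed.
#' @return Long-format data frame of class `sdfa_catch` with columns
#'   `haul_id`, `x_km`, `y_km`, `year`, `survey`, `swept_area_km2`,
#'   `species`, `catch_kg`.
#' @export
simulate_survey <- function(truth, design, seed = 1) {
  stopifnot(inherits(truth, "sdfa_truth"), inherits(design, "sdfa_design"))
  config <- truth$config
  nv <- config$n_surveys
  hy <- rep_len(design$hauls_per_year, nv)
  years <- design$years
  stopifnot(all(years >= 1), all(years <= config$n_years))
  set.seed(seed)

  ext <- config$extent
  hauls <- do.call(rbind, lapply(years, function(t) {
    do.call(rbind, lapply(seq_len(nv), function(v) {
      n <- hy[v]
      if (n == 0) return(NULL)
      data.frame(x_km = runif(n, ext[1], ext[2]),
                 y_km = runif(n, ext[3], ext[4]),
                 year = t, survey_idx = v)
    }))
  }))
  n_haul <- nrow(hauls)
  hauls$haul_id <- seq_len(n_haul)
  hauls$swept_area_km2 <- exp(rnorm(n_haul, design$swept_area_meanlog,
                                    design$swept_area_sdlog))
  hauls$knot <- nearest_knot(hauls$x_km, hauls$y_km,
                             truth$grid$x_km, truth$grid$y_km)

  nc <- config$n_species
  long <- hauls[rep(seq_len(n_haul), each = nc), ]
  long$species_idx <- rep(seq_len(nc), n_haul)
  eta <- linear_predictors(truth$params, truth$fields,
                           knot = long$knot, species = long$species_idx,
                           year = long$year, survey = long$survey_idx,
                           logarea = log(long$swept_area_km2),
                           offset_density = config$offset_density)
  p <- plogis(eta$eta_p)
  r <- exp(eta$eta_r)
  n_obs <- nrow(long)
  enc <- rbinom(n_obs, 1, p)
  k <- truth$params$k[long$species_idx]
  catch <- numeric(n_obs)
  pos <- enc == 1
  catch[pos] <- rgamma(sum(pos), shape = k[pos], rate = k[pos] / r[pos])

  out <- data.frame(haul_id = long$haul_id, x_km = long$x_km,
                    y_km = long$y_km, year = long$year,
                    survey = config$surveys[long$survey_idx],
                    swept_area_km2 = long$swept_area_km2,
                    species = config$species[long$species_idx],
                    catch_kg = catch)
  rownames(out) <- NULL
  class(out) <- c("sdfa_catch", "data.frame")
  out
}

#' Simulate fish length samples with allometric weights
#'
#' Used to exercise the length-weight and size-class preprocessing steps.
#' Lengths are drawn from a lognormal (or held constant) and converted to
#' weight by the allometric power law `W = a * L^b`.
#'
#' @param n Number of fish.
#' @param a,b Allometric coefficients (`W` in grams for `L` in cm under the
#'   usual convention).
#' @param meanlog,sdlog Lognormal length distribution (cm); set `sdlog = 0`
#'   for constant lengths `exp(meanlog)`.
#' @param species Species label.
#' @param seed Integer seed.
#' @return Data frame with columns `species`, `length_cm`, `weight_g`.
#' @export
simulate_length_samples <- function(n, a, b, meanlog = log(25), sdlog = 0.3,
                                    species = "sp01", seed = 1) {
  stopifnot(a > 0, b > 0, n >= 0)
  set.seed(seed)
  len <- exp(rnorm(n, meanlog, sdlog))
  data.frame(species = rep(species, n), length_cm = len,
             weight_g = length_to_weight(len, a, b))
}
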