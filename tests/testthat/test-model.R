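test_that("linear predictors match a term-by-term hand sum", {
  inst <- small_instance()
  pm <- inst$truth$params; fl <- inst$truth$fields
  expect_equal(plogis(0), 0.5)
  # only an intercept: inverse-logit of ln 4 is 0.8
  pm0 <- pm
  for (nm in c("L_om_p", "L_eps_p", "L_om_r", "L_eps_r")) pm0[[nm]][] <- 0
  pm0$delta_p[] <- 0
  pm0$beta_p[] <- log(4)
  expect_equal(plogis(predictor_encounter(pm0, fl, 1, 1, 1, 1)), 0.8)
  # offset policy: beta_r = ln 2 and swept area 2 give positive mean 4
  pm0$beta_r[] <- log(2)
  expect_equal(exp(predictor_density(pm0, fl, 1, 1, 1, 1, swept_area = 2)), 4)
  # random instance against explicit summation
  s <- 5; c <- 2; t <- 3; v <- 2
  hand <- pm$beta_p[c, t] + pm$delta_p[c, v] +
    sum(pm$L_om_p[c, ] * fl$omega_p[s, ]) +
    sum(pm$L_eps_p[c, ] * fl$eps_p[s, , t])
  expect_equal(predictor_encounter(pm, fl, s, c, t, v), unname(hand),
               tolerance = 1e-12)
  expect_error(predictor_encounter(pm, fl, 1, 1, 1, survey = 9), "survey")
})

test_that("delta-gamma likelihood has its closed forms and integrates to p", {
  expect_equal(delta_gamma_loglik(0, 0.25, 1, 1), log(0.75))
  # shape 1 is exponential with rate 1/r
  C <- 3.2; p <- 0.6; r <- 2.5
  expect_equal(delta_gamma_loglik(C, p, r, 1),
               log(p) + log(1 / r) - C / r, tolerance = 1e-12)
  # positive branch integrates to p (quadrature)
  for (p in c(0.1, 0.9)) for (r in c(0.5, 4)) for (k in c(0.7, 2)) {
    I <- integrate(function(x) exp(delta_gamma_loglik(x, p, r, k)),
                   0, Inf, rel.tol = 1e-9)$value
    expect_equal(I, p, tolerance = 1e-6)
  }
  expect_error(delta_gamma_loglik(-1, 0.5, 1, 1))
})

test_that("pure-R joint NLL equals the compiled objective", {
  inst <- small_instance()
  nll_r <- joint_nll(inst$truth$params, inst$truth$fields, inst$dat,
                     inst$grid, inst$cfg)
  obj <- sdfa:::tmb_joint_obj(inst$truth$params, inst$truth$fields,
                              inst$dat, inst$grid, inst$cfg)
  expect_equal(nll_r, as.numeric(obj$fn(obj$par)), tolerance = 1e-8)
})

test_that("joint NLL is additive in observations and reduces to the prior", {
  inst <- small_instance()
  empty <- inst$dat[0, ]
  prior_only <- joint_nll(inst$truth$params, inst$truth$fields, empty,
                          inst$grid, inst$cfg)
  # prior at zero fields is the matrix-normal normalizing constant
  zero <- sdfa:::empty_params(inst$cfg, inst$grid)
  R_p <- build_correlation_matrix(inst$grid, inst$cfg$kappa[["p"]])
  R_r <- build_correlation_matrix(inst$grid, inst$cfg$kappa[["r"]])
  nf <- inst$cfg$n_factors
  expected0 <- -(matrix_normal_logpdf(zero$fields$omega_p, R_p, diag(nf$omega_p)) +
                 matrix_normal_logpdf(zero$fields$omega_r, R_r, diag(nf$omega_r)) +
                 sum(vapply(1:4, function(t)
                   matrix_normal_logpdf(zero$fields$eps_p[, , t], R_p,
                                        diag(nf$eps_p)) +
                   matrix_normal_logpdf(zero$fields$eps_r[, , t], R_r,
                                        diag(nf$eps_r)), numeric(1))))
  pm <- inst$truth$params
  expect_equal(joint_nll(pm, zero$fields, empty, inst$grid, inst$cfg),
               expected0, tolerance = 1e-10)
  # adding one observation changes the NLL by exactly minus its loglik
  one <- inst$dat[17, ]
  with_one <- joint_nll(pm, inst$truth$fields, one, inst$grid, inst$cfg)
  sp <- match(one$species, inst$cfg$species)
  sv <- match(one$survey, inst$cfg$surveys)
  knot <- sdfa:::nearest_knot(one$x_km, one$y_km, inst$grid$x_km, inst$grid$y_km)
  eta <- sdfa:::linear_predictors(pm, inst$truth$fields, knot, sp, one$year,
                                  sv, log(one$swept_area_km2), TRUE)
  ll <- delta_gamma_loglik(one$catch_kg, plogis(eta$eta_p), exp(eta$eta_r),
                           pm$k[sp])
  expect_equal(with_one - prior_only, -ll, tolerance = 1e-10)
})

test_that("automatic gradients agree with finite differences of the R likelihood", {
  inst <- small_instance()
  obj <- sdfa:::tmb_joint_obj(inst$truth$params, inst$truth$fields,
                              inst$dat, inst$grid, inst$cfg)
  set.seed(21)
  p0 <- obj$par + rnorm(length(obj$par), 0, 0.05)
  g <- as.vector(obj$gr(p0))
  i_sub <- sort(sample(length(p0), 25))
  h <- 1e-6
  fd <- vapply(i_sub, function(i) {
    e <- p0; e[i] <- e[i] + h; f1 <- obj$fn(e)
    e[i] <- e[i] - 2 * h; (f1 - obj$fn(e)) / (2 * h)
  }, numeric(1))
  rel <- abs(fd - g[i_sub]) / pmax(abs(fd), 1)
  expect_lt(max(rel), 1e-5)
})

test_that("the likelihood is invariant to orthogonal rotation of loadings", {
  inst <- small_instance()
  cfg <- sdfa_config(n_species = 3, n_years = 4, n_surveys = 2,
                     n_factors = 2, extent = c(0, 200, 0, 150),
                     gamma_shape = 1.5)
  tr <- simulate_truth(cfg, inst$grid, seed = 30)
  base <- joint_nll(tr$params, tr$fields, inst$dat, inst$grid, cfg)
  set.seed(31)
  Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  pm <- tr$params; fl <- tr$fields
  pm$L_om_p <- pm$L_om_p %*% Q
  fl$omega_p <- fl$omega_p %*% Q
  pm$L_eps_r <- pm$L_eps_r %*% Q
  for (t in 1:4) fl$eps_r[, , t] <- fl$eps_r[, , t] %*% Q
  expect_equal(joint_nll(pm, fl, inst$dat, inst$grid, cfg), base,
               tolerance = 1e-8)
})

test_that("Laplace marginal likelihood behaves at its exact limits", {
  inst <- small_instance()
  pm <- inst$truth$params
  # with all loadings zero the fields integrate out completely: the marginal
  # NLL is the pure observation NLL
  pm0 <- pm
  for (nm in c("L_om_p", "L_eps_p", "L_om_r", "L_eps_r")) pm0[[nm]][] <- 0
  zero <- sdfa:::empty_params(inst$cfg, inst$grid)
  obs_nll <- joint_nll(pm0, zero$fields, inst$dat, inst$grid, inst$cfg) -
    joint_nll(pm0, zero$fields, inst$dat[0, ], inst$grid, inst$cfg)
  lp <- laplace_marginal_nll(pm0, inst$dat, inst$grid, inst$cfg)
  expect_equal(lp$nll, obs_nll, tolerance = 1e-6)
  # duplicating every observation strictly increases the marginal NLL
  lp1 <- laplace_marginal_nll(pm, inst$dat, inst$grid, inst$cfg)
  lp2 <- laplace_marginal_nll(pm, rbind(inst$dat, inst$dat), inst$grid,
                              inst$cfg)
  expect_gt(lp2$nll, lp1$nll)
})

test_that("fits report coherent information criteria and converge stably", {
  fit <- small_fit()
  expect_equal(fit$aic, 2 * fit$n_fixed + 2 * fit$nll)
  expect_equal(fit$bic, log(fit$n_obs) * fit$n_fixed + 2 * fit$nll)
  expect_identical(unname(information_criteria(fit)), c(fit$aic, fit$bic))
  expect_equal(fit$convergence$code, 0)
  # multi-start stability: independent restarts land on the same NLL
  inst <- small_instance()
  nlls <- vapply(2:3, function(s)
    suppressWarnings(fit_sdfa(inst$dat, inst$grid, inst$cfg,
                              estimate_kappa = FALSE, start_seed = s))$nll,
    numeric(1))
  expect_lt(max(abs(c(nlls, fit$nll) - fit$nll)), 0.5)
})

test_that("a nested richer model never fits worse in-sample", {
  inst <- small_instance()
  fit1 <- small_fit()
  cfg2 <- sdfa_config(n_species = 3, n_years = 4, n_surveys = 2,
                      n_factors = 2, extent = c(0, 200, 0, 150),
                      gamma_shape = 1.5)
  fit2 <- suppressWarnings(fit_sdfa(inst$dat, inst$grid, cfg2,
                                    estimate_kappa = FALSE))
  expect_lte(fit2$nll, fit1$nll + 0.1)
})
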