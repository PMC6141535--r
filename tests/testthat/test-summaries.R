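test_that("PCA rotation preserves the implied covariance and predictions", {
  set.seed(10)
  L <- matrix(rnorm(12), 4, 3)
  coeffs <- matrix(rnorm(30), 10, 3)
  rf <- pca_rotate(L, coeffs)
  expect_equal(rf$L_rot %*% t(rf$L_rot), L %*% t(L), tolerance = 1e-10)
  # predictions (fields x loadings) unchanged
  expect_equal(rf$coeff_rot %*% t(rf$L_rot), coeffs %*% t(L),
               tolerance = 1e-9)
  # explained variance matches the eigenvalue oracle, ordered, sums to 1
  ev <- eigen(L %*% t(L), symmetric = TRUE, only.values = TRUE)$values[1:3]
  expect_equal(rf$var_explained, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(rf$var_explained) <= 1e-12))
  expect_equal(sum(rf$var_explained), 1)
  # sign convention: largest-|entry| positive
  for (f in 1:3)
    expect_gt(rf$L_rot[which.max(abs(rf$L_rot[, f])), f], 0)
  # already-diagonal loadings rotate by identity up to sign
  D <- diag(c(3, 2, 1))
  rfD <- pca_rotate(D)
  expect_equal(abs(rfD$rotation), diag(3), tolerance = 1e-10)
  # spatiotemporal (3-d) coefficients are counter-rotated per year
  arr <- array(rnorm(10 * 3 * 2), c(10, 3, 2))
  rfa <- pca_rotate(L, arr)
  expect_equal(rfa$coeff_rot[, , 2] %*% t(rfa$L_rot), arr[, , 2] %*% t(L),
               tolerance = 1e-9)
})

test_that("cumulative variance explained is monotone with exact endpoints", {
  set.seed(11)
  rf <- pca_rotate(matrix(rnorm(15), 5, 3))
  vals <- vapply(1:3, function(k) variance_explained(rf, k), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[3], 1)
  rf1 <- pca_rotate(cbind(c(1, 2, 3)))  # rank 1
  expect_equal(variance_explained(rf1, 1), 1)
  expect_error(variance_explained(rf, 4), "k must be")
})

test_that("factor-implied correlations match a Monte-Carlo oracle", {
  cs <- species_correlations(diag(3))
  expect_equal(cs$corr, diag(3))
  cs1 <- species_correlations(matrix(1, 4, 1))
  expect_true(all(cs1$corr == 1))
  set.seed(12)
  L <- matrix(rnorm(8), 4, 2)
  psi <- matrix(rnorm(2 * 1e5), 1e5, 2)
  mc <- cor(psi %*% t(L))
  expect_equal(species_correlations(L)$corr, mc, tolerance = 0.01)
  # invariance to orthogonal rotation
  Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  expect_equal(species_correlations(L %*% Q)$corr,
               species_correlations(L)$corr, tolerance = 1e-12)
  # zero-variance species flagged, not silently zero
  L0 <- rbind(c(1, 0), c(0, 0), c(0, 1))
  cs0 <- species_correlations(L0)
  expect_true(cs0$undefined[2])
  expect_true(all(is.na(cs0$corr[2, ])))
})

test_that("correlation CIs are seeded and degenerate covariance means certainty", {
  fit <- small_fit()
  cs1 <- correlation_cis(fit, "omega_p", n_draws = 50, seed = 4)
  cs2 <- correlation_cis(fit, "omega_p", n_draws = 50, seed = 4)
  expect_identical(cs1, cs2)
  # zero outer covariance: SEs 0, every non-zero correlation significant
  fit0 <- fit
  fit0$vcov_fixed <- fit$vcov_fixed * 0
  cs0 <- correlation_cis(fit0, "omega_p", n_draws = 50, seed = 1)
  expect_equal(max(cs0$se), 0)
  expect_true(all(cs0$significant[abs(cs0$corr) > 1e-12]))
  fitna <- fit
  fitna$vcov_fixed <- NULL
  expect_error(correlation_cis(fitna), "covariance")
})

test_that("true-zero correlations in a signal-bearing model are mostly masked", {
  # two 2-species blocks on orthogonal factors: the 4 between-block pairs
  # have true correlation 0 while real signal keeps the fit off boundaries
  masked <- unlist(lapply(1:5, function(rep_seed) {
    cfg <- sdfa_config(n_species = 4, n_years = 4, n_surveys = 1,
                       n_factors = 2, extent = c(0, 700, 0, 450),
                       gamma_shape = 1.5, beta_p_mean = 0.5,
                       beta_r_mean = log(100))
    grid <- make_knot_grid(20, cfg$extent)
    truth <- simulate_truth(cfg, grid, seed = rep_seed)
    Lz <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)) * 0.8
    for (nm in c("L_om_p", "L_eps_p", "L_om_r", "L_eps_r"))
      truth$params[[nm]] <- Lz
    dat <- simulate_survey(truth, survey_design(250, 1:4),
                           seed = rep_seed + 1000)
    fit <- tryCatch(
      suppressWarnings(fit_sdfa(dat, grid, cfg, estimate_kappa = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || is.null(fit$vcov_fixed)) return(NULL)
    unlist(lapply(c("omega_p", "omega_r"), function(comp) {
      cs <- correlation_cis(fit, comp, n_draws = 400, seed = 1)
      !cs$significant[rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4))]
    }))
  }))
  expect_gte(mean(masked), 0.8)
})

test_that("hierarchical clustering recovers block structure", {
  blocks <- c(1, 1, 2, 2, 2, 3, 3)
  corr <- outer(blocks, blocks, function(a, b) ifelse(a == b, 1, 0)) * 1
  diag(corr) <- 1
  rownames(corr) <- colnames(corr) <- paste0("s", 1:7)
  grp <- cluster_assemblages(corr, 3)
  expect_equal(rand_index(grp, blocks), 1)
  expect_equal(unname(cluster_assemblages(corr, 7)), 1:7)  # singletons
  expect_error(cluster_assemblages(corr, 8), "exceeds")
  # noisy blocks: within 0.7, between 0, noise sd 0.05
  set.seed(14)
  ri <- vapply(1:10, function(i) {
    C <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.7, 0))
    noise <- matrix(rnorm(49, 0, 0.05), 7)
    C <- C + (noise + t(noise)) / 2
    diag(C) <- 1
    rand_index(cluster_assemblages(C, 3), blocks)
  }, numeric(1))
  expect_gte(mean(ri), 0.9)
  # undefined entries imputed with a warning
  corr_na <- corr; corr_na[1, 2] <- corr_na[2, 1] <- NA
  expect_warning(cluster_assemblages(corr_na, 3), "imputed")
})

test_that("spatial vs spatiotemporal correlation regression detects shared structure", {
  inst <- small_instance()
  cfg <- sdfa_config(n_species = 4, n_years = 6, n_surveys = 1,
                     n_factors = 2, extent = c(0, 200, 0, 150))
  grid <- make_knot_grid(25, cfg$extent)
  tr <- simulate_truth(cfg, grid, seed = 40)
  # identical loadings and identical fields every year: r and R^2 exactly 1
  tr1 <- tr
  tr1$params$L_eps_p <- tr1$params$L_om_p
  for (t in 1:6) tr1$fields$eps_p[, , t] <- tr1$fields$omega_p
  res <- spatial_vs_spatiotemporal_regression(tr1, "p")
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_equal(res$r_squared, res$r^2)
  expect_equal(res$slope, 1, tolerance = 1e-10)
  # independent loadings and fields: r centred on zero across replicates
  rs <- vapply(1:30, function(s) {
    tri <- simulate_truth(cfg, grid, seed = 100 + s)
    spatial_vs_spatiotemporal_regression(tri, "r")$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.1)
  expect_error(spatial_vs_spatiotemporal_regression(small_instance()$truth, "p"),
               NA)
})

test_that("covariate correlation reports Pearson r with Fisher-z intervals", {
  set.seed(15)
  x <- rnorm(200)
  expect_equal(covariate_correlation(x, x)$r, 1)
  expect_equal(covariate_correlation(x, -x)$r, -1)
  expect_warning(res <- covariate_correlation(x, rep(2, 200)), "constant")
  expect_true(is.na(res$r))
  # attenuation: coeff = 0.8 z + noise(sd 0.6) has r = 0.8/sqrt(0.64+0.36)
  z <- rnorm(4000)
  co <- 0.8 * z + rnorm(4000, 0, 0.6)
  res2 <- covariate_correlation(co, z)
  expect_equal(res2$r, 0.8, tolerance = 0.03)
  expect_true(res2$ci_lo < 0.8 && res2$ci_hi > res2$r)
})
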