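test_that("anisotropic distance reduces to Euclidean and matches the matrix form", {
  expect_equal(anisotropic_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(anisotropic_distance(c(2, -1), c(2, -1), 0.5, 0.1), 0)
  # explicit 2x2 arithmetic oracle
  p1 <- c(1.3, -0.7); p2 <- c(-2.1, 4.2); h1 <- 0.5; h2 <- 0.1
  H <- matrix(c(exp(h1), h2, h2, (1 + h2^2) * exp(-h1)), 2, 2)
  d <- p1 - p2
  expect_equal(anisotropic_distance(p1, p2, h1, h2),
               sqrt(as.numeric(t(d) %*% H %*% d)), tolerance = 1e-12)
  # symmetry and unit determinant
  expect_equal(anisotropic_distance(p2, p1, h1, h2),
               anisotropic_distance(p1, p2, h1, h2))
  expect_equal(det(anisotropy_matrix(1.2, -0.8)), 1, tolerance = 1e-12)
})

test_that("Matern correlation has its closed forms and monotonicity", {
  expect_equal(matern_correlation(0, kappa = 2, nu = 1), 1)
  d <- c(0.3, 1, 2.5, 7)
  expect_equal(matern_correlation(d, 1.3, nu = 0.5), exp(-1.3 * d),
               tolerance = 1e-12)
  # half-integer closed form at nu = 3/2: (1 + kd) exp(-kd)
  expect_equal(matern_correlation(2, 1, nu = 1.5), (1 + 2) * exp(-2),
               tolerance = 1e-10)
  for (nu in c(0.5, 1, 1.5, 2.5)) {
    v <- matern_correlation(seq(0, 50, by = 0.25), 0.8, nu)
    expect_true(all(diff(v) <= 1e-12))
    expect_true(all(v > 0 | seq(0, 50, by = 0.25) > 20))
  }
  expect_error(matern_correlation(-1, 1), "negative")
})

test_that("knot correlation matrices are PD and flag degeneracy", {
  g1 <- data.frame(knot_id = 0L, x_km = 5, y_km = 5, area_km2 = 1)
  expect_equal(build_correlation_matrix(g1, 0.1)[1, 1], 1, tolerance = 1e-7)
  g2 <- data.frame(knot_id = 0:1, x_km = c(1, 1), y_km = c(2, 2),
                   area_km2 = 1)
  expect_warning(R2 <- build_correlation_matrix(g2, 0.1), "rank-deficient")
  expect_equal(R2[1, 2], 1)
  g5 <- make_knot_grid(6, c(0, 100, 0, 100), layout = "random", seed = 4)
  R <- build_correlation_matrix(g5, 0.03, h1 = 0.3, h2 = -0.2)
  expect_true(all(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_equal(R, t(R))
})

test_that("decorrelation range inverts the correlation analytically", {
  expect_equal(decorrelation_range(1, nu = 0.5), log(10), tolerance = 0.01)
  expect_equal(decorrelation_range(1, nu = 0.5, threshold = 1), 0)
  r1 <- decorrelation_range(0.05, nu = 0.5)
  r2 <- decorrelation_range(0.10, nu = 0.5)
  expect_equal(r1 / r2, 2, tolerance = 1e-4)
  # kappa_for_range round-trips
  k <- kappa_for_range(97, nu = 1)
  expect_equal(decorrelation_range(k, nu = 1), 97, tolerance = 0.01)
})

test_that("matrix-normal log-density matches the dense Kronecker oracle", {
  expect_equal(matrix_normal_logpdf(matrix(0, 2, 2), diag(2), diag(2)),
               -2 * log(2 * pi))
  for (s in 1:4) {
    n <- sample(2:6, 1); p <- sample(2:4, 1)
    R <- random_spd(n, 100 + s); V <- random_spd(p, 200 + s)
    set.seed(300 + s)
    E <- matrix(rnorm(n * p), n, p)
    dense <- dense_mvn_logpdf(as.vector(E), rep(0, n * p), kronecker(V, R))
    expect_equal(matrix_normal_logpdf(E, R, V), dense, tolerance = 1e-8)
    # Kronecker symmetry
    expect_equal(matrix_normal_logpdf(E, R, V),
                 matrix_normal_logpdf(t(E), V, R), tolerance = 1e-9)
  }
  # determinant scaling at E = 0
  R <- random_spd(3, 1); V <- random_spd(2, 2)
  expect_equal(matrix_normal_logpdf(matrix(0, 3, 2), R, 4 * V),
               matrix_normal_logpdf(matrix(0, 3, 2), R, V) - 3 * log(4),
               tolerance = 1e-10)
})

test_that("matrix-normal sampler has the right covariance and is seeded", {
  R <- random_spd(2, 5); V <- random_spd(2, 6)
  expect_equal(sample_matrix_normal(R, matrix(0, 2, 2), seed = 1),
               matrix(0, 2, 2))
  expect_identical(sample_matrix_normal(R, V, seed = 9),
                   sample_matrix_normal(R, V, seed = 9))
  draws <- vapply(1:10000, function(i)
    as.vector(sample_matrix_normal(R, V)), numeric(4))
  emp <- cov(t(draws))
  expect_equal(emp, kronecker(V, R), tolerance = 0.05 * max(abs(kronecker(V, R))))
  expect_error(sample_matrix_normal(R, matrix(c(1, 2, 2, 1), 2), seed = 1),
               "semi-definite")
})

test_that("unit-determinant anisotropy approximately preserves ring-average correlation", {
  kappa <- 0.03
  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  for (d in c(30, 60)) {
    pts <- cbind(d * cos(theta), d * sin(theta))
    iso <- matern_correlation(d, kappa, 1)
    aniso <- mean(vapply(seq_len(nrow(pts)), function(i)
      matern_correlation(anisotropic_distance(c(0, 0), pts[i, ], 0.3, 0.1),
                         kappa, 1), numeric(1)))
    expect_equal(aniso, iso, tolerance = 0.05 * iso)
  }
})
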