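# Shared fixtures, built once per test run and cached (the recovery fit is
# the expensive one). All sizes are desk-scale: small enough to run the
# whole suite in minutes, large enough that recovery checks are meaningful.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Tiny instance: 3 species, 12 knots, 4 years, 2 surveys, 1 factor each.
small_instance <- function() {
  cached("small", function() {
    cfg <- sdfa_config(n_species = 3, n_years = 4, n_surveys = 2,
                       n_factors = 1, extent = c(0, 200, 0, 150),
                       gamma_shape = 1.5)
    grid <- make_knot_grid(12, cfg$extent)
    truth <- simulate_truth(cfg, grid, seed = 7)
    dat <- simulate_survey(truth, survey_design(c(30, 30), 1:4), seed = 8)
    list(cfg = cfg, grid = grid, truth = truth, dat = dat)
  })
}

small_fit <- function() {
  cached("small_fit", function() {
    inst <- small_instance()
    suppressWarnings(fit_sdfa(inst$dat, inst$grid, inst$cfg,
                              estimate_kappa = FALSE))
  })
}

# Recovery experiment: 4 species in 2 assemblages, 2 factors per component,
# 30 knots, 10 years, 2 surveys x 150 hauls/year = 3000 hauls.
recovery_instance <- function() {
  cached("recovery", function() {
    cfg <- sdfa_config(n_species = 4, n_years = 10, n_surveys = 2,
                       n_factors = 2, extent = c(0, 400, 0, 300),
                       gamma_shape = 1.5, beta_p_mean = 0.5, beta_p_sd = 0.5,
                       beta_r_mean = log(100), beta_r_sd = 0.5)
    grid <- make_knot_grid(30, cfg$extent)
    truth <- simulate_truth(cfg, grid, seed = 11, assemblages = c(1, 1, 2, 2))
    dat <- simulate_survey(truth, survey_design(c(150, 150), 1:10), seed = 12)
    list(cfg = cfg, grid = grid, truth = truth, dat = dat)
  })
}

recovery_fit <- function() {
  cached("recovery_fit", function() {
    inst <- recovery_instance()
    fit_sdfa(inst$dat, inst$grid, inst$cfg)
  })
}

# Independent dense MVN negative log-density (chol-based), used as the
# oracle for Kronecker/matrix-normal checks.
dense_mvn_logpdf <- function(x, mu, Sigma) {
  cc <- chol(Sigma)
  z <- backsolve(cc, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(cc))) - 0.5 * sum(z^2)
}

random_spd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(n)
}

# Adjusted-for-chance-free Rand index between two partitions.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Simulate data whose true loadings are all zero (intercept-only truth).
simulate_null_data <- function(rep_seed, cfg, grid, hauls = 250) {
  truth <- simulate_truth(cfg, grid, seed = rep_seed)
  for (nm in c("L_om_p", "L_eps_p", "L_om_r", "L_eps_r"))
    truth$params[[nm]][] <- 0
  dat <- simulate_survey(truth, survey_design(hauls, seq_len(cfg$n_years)),
                         seed = rep_seed + 1000)
  list(truth = truth, dat = dat)
}
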