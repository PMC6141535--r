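#define TMB_LIB_INIT R_init_sdfa
#include <TMB.hpp>

// Lower-triangular loading matrix (n_c x n_f) from its free entries,
// stacked column-major: column f holds rows f..n_c-1.
template <class Type>
matrix<Type> loadings_matrix(const vector<Type> &l, int n_c, int n_f) {
  matrix<Type> L(n_c, n_f);
  L.setZero();
  int idx = 0;
  for (int f = 0; f < n_f; f++)
    for (int c = f; c < n_c; c++) L(c, f) = l(idx++);
  return L;
}

// Anisotropic Matern (nu = 1) correlation among knots.
// H = [[exp(h1), h2], [h2, (1 + h2^2) * exp(-h1)]], det(H) = 1.
template <class Type>
matrix<Type> matern_corr_matrix(const matrix<Type> &coords, Type kappa,
                                Type h1, Type h2, Type jitter) {
  int n = coords.rows();
  Type H11 = exp(h1);
  Type H22 = (Type(1) + h2 * h2) * exp(-h1);
  matrix<Type> R(n, n);
  for (int i = 0; i < n; i++) {
    R(i, i) = Type(1) + jitter;
    for (int j = 0; j < i; j++) {
      Type dx = coords(i, 0) - coords(j, 0);
      Type dy = coords(i, 1) - coords(j, 1);
      Type d = sqrt(H11 * dx * dx + Type(2) * h2 * dx * dy + H22 * dy * dy);
      Type u = kappa * d;
      R(i, j) = R(j, i) = u * besselK(u, Type(1));
    }
  }
  return R;
}

template <class Type>
Type objective_function<Type>::operator()() {
  using namespace density;

  DATA_INTEGER(family);          // 0 = delta-gamma; 1 = gaussian identity-link (test hook)
  DATA_INTEGER(offset_density);  // 1 = add log swept area to log positive density
  DATA_MATRIX(coords);           // n_s x 2, planar km
  DATA_IVECTOR(obs_knot);        // 0-based indices
  DATA_IVECTOR(obs_species);
  DATA_IVECTOR(obs_year);
  DATA_IVECTOR(obs_survey);
  DATA_VECTOR(obs_catch);
  DATA_VECTOR(obs_logarea);

  PARAMETER_MATRIX(beta_p);  // n_c x n_t year-species intercepts, encounter
  PARAMETER_MATRIX(beta_r);  // n_c x n_t, positive density
  PARAMETER_VECTOR(l_om_p);  // free loading entries (lower-triangular)
  PARAMETER_VECTOR(l_eps_p);
  PARAMETER_VECTOR(l_om_r);
  PARAMETER_VECTOR(l_eps_r);
  PARAMETER_MATRIX(delta_p);  // n_c x n_v survey-species catchability
  PARAMETER_MATRIX(delta_r);
  PARAMETER_VECTOR(log_k);  // per-species gamma shape
  PARAMETER(log_kappa_p);
  PARAMETER(log_kappa_r);
  PARAMETER(h1);
  PARAMETER(h2);
  PARAMETER(log_sigma);  // gaussian family only

  PARAMETER_MATRIX(omega_p);  // n_s x nf_om_p
  PARAMETER_ARRAY(eps_p);     // n_s x nf_eps_p x n_t
  PARAMETER_MATRIX(omega_r);
  PARAMETER_ARRAY(eps_r);

  int n_c = beta_p.rows();
  int n_t = beta_p.cols();
  int n_s = coords.rows();
  int n_i = obs_catch.size();
  int nf_om_p = omega_p.cols();
  int nf_eps_p = eps_p.dim(1);
  int nf_om_r = omega_r.cols();
  int nf_eps_r = eps_r.dim(1);

  matrix<Type> Lom_p = loadings_matrix(l_om_p, n_c, nf_om_p);
  matrix<Type> Leps_p = loadings_matrix(l_eps_p, n_c, nf_eps_p);
  matrix<Type> Lom_r = loadings_matrix(l_om_r, n_c, nf_om_r);
  matrix<Type> Leps_r = loadings_matrix(l_eps_r, n_c, nf_eps_r);

  Type jitter = Type(1e-8);
  matrix<Type> R_p =
      matern_corr_matrix(coords, exp(log_kappa_p), h1, h2, jitter);
  matrix<Type> R_r =
      matern_corr_matrix(coords, exp(log_kappa_r), h1, h2, jitter);
  MVNORM_t<Type> gmrf_p(R_p), gmrf_r(R_r);

  Type nll = 0;

  // GMRF priors: one unit-variance field per factor (and year, for eps).
  for (int f = 0; f < nf_om_p; f++) nll += gmrf_p(vector<Type>(omega_p.col(f)));
  for (int f = 0; f < nf_om_r; f++) nll += gmrf_r(vector<Type>(omega_r.col(f)));
  vector<Type> tmp(n_s);
  for (int t = 0; t < n_t; t++) {
    for (int f = 0; f < nf_eps_p; f++) {
      for (int s = 0; s < n_s; s++) tmp(s) = eps_p(s, f, t);
      nll += gmrf_p(tmp);
    }
    for (int f = 0; f < nf_eps_r; f++) {
      for (int s = 0; s < n_s; s++) tmp(s) = eps_r(s, f, t);
      nll += gmrf_r(tmp);
    }
  }

  // Observation likelihood.
  for (int i = 0; i < n_i; i++) {
    int c = obs_species(i), s = obs_knot(i), t = obs_year(i), v = obs_survey(i);
    Type eta_p = beta_p(c, t) + delta_p(c, v);
    for (int f = 0; f < nf_om_p; f++) eta_p += Lom_p(c, f) * omega_p(s, f);
    for (int f = 0; f < nf_eps_p; f++) eta_p += Leps_p(c, f) * eps_p(s, f, t);
    Type eta_r = beta_r(c, t) + delta_r(c, v);
    for (int f = 0; f < nf_om_r; f++) eta_r += Lom_r(c, f) * omega_r(s, f);
    for (int f = 0; f < nf_eps_r; f++) eta_r += Leps_r(c, f) * eps_r(s, f, t);

    if (family == 1) {
      nll -= dnorm(obs_catch(i), eta_r, exp(log_sigma), true);
    } else {
      if (offset_density == 1) eta_r += obs_logarea(i);
      Type log1pexp = logspace_add(Type(0), eta_p);
      if (obs_catch(i) == Type(0)) {
        nll -= -log1pexp;  // log(1 - p)
      } else {
        Type k = exp(log_k(c));
        Type r = exp(eta_r);  // mean of positive catch; scale = r / k
        nll -= (eta_p - log1pexp) + dgamma(obs_catch(i), k, r / k, true);
      }
    }
  }

  REPORT(Lom_p);
  REPORT(Leps_p);
  REPORT(Lom_r);
  REPORT(Leps_r);
  return nll;
}
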