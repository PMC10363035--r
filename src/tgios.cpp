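// Biexponential tumor-size nonlinear mixed-effects model.
//
// Structural model (t in weeks, size in mm):
//   t <  0 : TS(t) = TS0 * exp(KG * t)
//   t >= 0 : TS(t) = TS0 * (exp(-KS * t) + exp(KG * t) - 1)
// Individual log-parameters are typical log-values plus normal random
// effects (log-normal IIV): KG, KS arm-specific, TS0 common. Additive
// normal residual error. The Laplace approximation to the marginal
// likelihood is taken over the per-subject random effects `eta`.
#include <TMB.hpp>

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_VECTOR(t);        // observation times, weeks
  DATA_VECTOR(y);        // observed SLD, mm
  DATA_IVECTOR(subj);    // 0-based subject index per observation
  DATA_IVECTOR(pre);     // 1 if t < 0 (pre-treatment branch)
  DATA_IVECTOR(arm);     // per subject: 0 = treatment, 1 = control

  // order: kg_treatment, ks_treatment, kg_control, ks_control, ts0
  PARAMETER_VECTOR(log_theta);
  PARAMETER_VECTOR(log_omega2);  // same order as log_theta
  PARAMETER(log_sigma2);         // additive residual variance, mm^2
  PARAMETER_MATRIX(eta);         // 3 x nsubj rows: kg, ks, ts0

  int nobs = t.size();
  int nsub = arm.size();
  Type sigma = exp(Type(0.5) * log_sigma2);
  vector<Type> omega = exp(Type(0.5) * log_omega2);

  Type nll = 0;
  for (int i = 0; i < nsub; i++) {
    int kgi = (arm(i) == 0) ? 0 : 2;
    nll -= dnorm(eta(0, i), Type(0), omega(kgi), true);
    nll -= dnorm(eta(1, i), Type(0), omega(kgi + 1), true);
    nll -= dnorm(eta(2, i), Type(0), omega(4), true);
  }
  // overflow guard for optimizer excursions: beyond exponent `cap` the
  // growth term continues linearly (monotone, finite, nonzero gradient);
  // the cap is far outside any region supported by tumor-size data
  Type cap = Type(30);
  for (int j = 0; j < nobs; j++) {
    int i = subj(j);
    int kgi = (arm(i) == 0) ? 0 : 2;
    Type kg = exp(log_theta(kgi) + eta(0, i));
    Type ks = exp(log_theta(kgi + 1) + eta(1, i));
    Type ts0 = exp(log_theta(4) + eta(2, i));
    Type eg = kg * t(j);
    Type grow = CppAD::CondExpGt(eg, cap,
                                 exp(cap) * (Type(1) + eg - cap), exp(eg));
    Type pred;
    if (pre(j) == 1) {
      pred = ts0 * grow;
    } else {
      pred = ts0 * (exp(-ks * t(j)) + grow - Type(1));
    }
    nll -= dnorm(y(j), pred, sigma, true);
  }

  vector<Type> theta = exp(log_theta);
  vector<Type> omega2 = exp(log_omega2);
  Type sigma2 = exp(log_sigma2);
  ADREPORT(theta);
  ADREPORT(omega2);
  ADREPORT(sigma2);
  return nll;
}
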