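// Laplace-approximate marginal likelihood of the joint concentration-QTc
// model. Mirrors the R-side structural model (R/model.R): circadian
// three-oscillator baseline, exponential secular trend, competitive /
// empirical / independent drug-effect models with individual EC50s, five
// log-normal random-effect dimensions and eta-on-epsilon residual scaling.
// Normal prior penalties ((theta - mu)/sd)^2 enter the -2LL objective on the
// natural parameter scale.
#include <TMB.hpp>

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_IVECTOR(subj);    // 0-based subject index per record
  DATA_VECTOR(qtcf);     // observed (triplicate-averaged) QTcF, ms
  DATA_VECTOR(tclock);   // clock time, h
  DATA_VECTOR(tweeks);   // max(treatment time, 0) in weeks
  DATA_VECTOR(secon);    // 1 if on treatment (t > 0), else 0
  DATA_VECTOR(cm2);      // BDQM2 concentration, mg/L
  DATA_VECTOR(cpa);      // pretomanid concentration, mg/L
  DATA_VECTOR(ccfz);     // clofazimine concentration, mg/L
  DATA_MATRIX(Xcov);     // centred covariate columns acting on baseline
  DATA_VECTOR(sqrtnrep); // sqrt(#replicates averaged) per record
  DATA_INTEGER(mode);      // 0 competitive, 1 empirical, 2 independent
  DATA_INTEGER(ec50_frac); // 1: EC50 parameterised as fraction of Emax
  DATA_IVECTOR(re_active); // which of the 5 eta dimensions are active
  DATA_VECTOR(prior_mu);   // natural-scale prior means (sd<=0 disables)
  DATA_VECTOR(prior_sd);

  PARAMETER(log_base);
  PARAMETER_VECTOR(log_amp);   // 3
  PARAMETER_VECTOR(acro);      // 3
  PARAMETER(qtc_ss);           // natural scale, sign-free
  PARAMETER(log_thalf);
  PARAMETER_VECTOR(cov_slope); // ncov
  PARAMETER(log_emax);
  PARAMETER_VECTOR(log_ec50);  // m2, cfz, pa (log mg/L or log fraction)
  PARAMETER(beta);
  PARAMETER(log_sigma);
  PARAMETER_VECTOR(log_omega); // 5: base, ss, ec50_cfz, ec50_m2, eps
  PARAMETER_MATRIX(eta);       // n_subj x 5

  Type base = exp(log_base);
  vector<Type> amp = exp(log_amp);
  Type thalf = exp(log_thalf);
  Type emax = exp(log_emax);
  vector<Type> ec50(3);
  for (int j = 0; j < 3; j++)
    ec50(j) = ec50_frac ? emax * exp(log_ec50(j)) : exp(log_ec50(j));
  Type sigma = exp(log_sigma);
  vector<Type> omega = exp(log_omega);

  int nrec = qtcf.size();
  int ncov = cov_slope.size();
  Type pi2 = Type(2) * Type(M_PI);
  Type ln2 = log(Type(2));
  Type period[3] = {Type(24), Type(12), Type(6)};

  Type nll = 0;
  for (int i = 0; i < nrec; i++) {
    int s = subj(i);
    Type circ = Type(1);
    for (int k = 0; k < 3; k++)
      circ += amp(k) * cos(pi2 * (tclock(i) - acro(k)) / period[k]);
    Type sec = secon(i) * qtc_ss * (Type(1) - exp(-ln2 * tweeks(i) / thalf));
    Type e50m2 = ec50(0) * exp(eta(s, 3));
    Type e50cfz = ec50(1) * exp(eta(s, 2));
    Type e50pa = ec50(2);
    Type de;
    if (mode == 0) {
      de = emax * cm2(i) /
             (e50m2 * (Type(1) + cpa(i) / e50pa) *
                (Type(1) + ccfz(i) / e50cfz) + cm2(i)) +
           emax * cpa(i) /
             (e50pa * (Type(1) + cm2(i) / e50m2) *
                (Type(1) + ccfz(i) / e50cfz) + cpa(i)) +
           emax * ccfz(i) /
             (e50cfz * (Type(1) + cm2(i) / e50m2) *
                (Type(1) + cpa(i) / e50pa) + ccfz(i));
    } else {
      Type da = emax * cm2(i) / (e50m2 + cm2(i));
      Type db = emax * cpa(i) / (e50pa + cpa(i));
      Type dc = emax * ccfz(i) / (e50cfz + ccfz(i));
      de = da + db + dc;
      if (mode == 1) de += beta * da * db * dc;
    }
    Type basei = base * exp(eta(s, 0));
    for (int c = 0; c < ncov; c++) basei += cov_slope(c) * Xcov(i, c);
    Type pred = basei * circ + sec * exp(eta(s, 1)) + de;
    Type sd = sigma * exp(eta(s, 4)) / sqrtnrep(i);
    nll -= dnorm(qtcf(i), pred, sd, true);
  }

  int nsub = eta.rows();
  for (int k = 0; k < 5; k++) {
    if (!re_active(k)) continue;
    for (int s = 0; s < nsub; s++)
      nll -= dnorm(eta(s, k), Type(0), omega(k), true);
  }

  // natural-scale vector, fixed order shared with the R side
  vector<Type> nat(20 + ncov);
  nat(0) = base;
  for (int k = 0; k < 3; k++) nat(1 + k) = amp(k);
  for (int k = 0; k < 3; k++) nat(4 + k) = acro(k);
  nat(7) = qtc_ss;
  nat(8) = thalf;
  nat(9) = emax;
  for (int j = 0; j < 3; j++) nat(10 + j) = ec50(j);
  nat(13) = beta;
  nat(14) = sigma;
  for (int k = 0; k < 5; k++) nat(15 + k) = omega(k);
  for (int c = 0; c < ncov; c++) nat(20 + c) = cov_slope(c);

  for (int j = 0; j < nat.size(); j++)
    if (asDouble(prior_sd(j)) > 0)
      nll += Type(0.5) * pow((nat(j) - prior_mu(j)) / prior_sd(j), 2);

  ADREPORT(nat);
  return nll;
}
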