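# Shared fixtures: small parameter sets, reduced designs and an
# independently coded evaluator of the competitive-interaction model used as
# the analytic oracle.

# reference (published) parameter set
ref_params <- function(...) qtc_params(...)

# quiet parameters: no circadian, no covariate slope -- convenient for exact
# arithmetic checks
flat_params <- function(...) {
  qtc_params(amp = c(0, 0, 0), age_slope = 0, ...)
}

# small control-only design for fast estimation tests
control_design <- function(n = 20, days = c(1, 2, 3, 8, 14, 28)) {
  eba_design(n_subjects = n, arms = list(CTL = character()),
             ecg_days = days)
}

# Independent direct evaluation of the competitive interaction equations,
# written from the algebra (companions inflate the EC50), sharing no code
# with the package implementation.
oracle_competitive <- function(ca, cb, cc, emax, ea, eb, ec) {
  # drug A with companions B and C
  num <- emax * ca
  den <- ea * (1 + cb / eb) * (1 + cc / ec) + ca
  num / den
}

# brute-force total of the three cyclic terms
oracle_competitive_total <- function(cm2, cpa, ccfz, emax, em2, epa, ecfz) {
  oracle_competitive(cm2, cpa, ccfz, emax, em2, epa, ecfz) +
    oracle_competitive(cpa, cm2, ccfz, emax, epa, em2, ecfz) +
    oracle_competitive(ccfz, cm2, cpa, emax, ecfz, em2, epa)
}

fast_control <- function(...) qtcfit_control(se = FALSE, restarts = 1, ...)
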