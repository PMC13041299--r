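# qtcompete

Population concentration-QTc (PK/PD) modelling of the three QT-prolonging
antituberculosis drugs bedaquiline (through its N-desmethyl metabolite,
BDQM2), pretomanid (Pa) and clofazimine (CFZ) — for pharmacometricians and
clinical pharmacologists who need to ask: *when these drugs are given
together, how much QT prolongation should a patient expect, and under which
dosing regimens does the risk cross the regulatory thresholds?*

## The model

Heart-rate-corrected QT (QTcF, Fridericia `QT/RR^(1/3)`) is described, per
subject *i* and observation *j*, as

    QTcF_ij = [ base * exp(eta_base,i) + slope_age (age_i - 37.5) ]
                * ( 1 + sum_k A_k cos(2*pi*(t_clock - phi_k)/P_k) )   , P_k = 24, 12, 6 h
              + QTc_ss * exp(eta_ss,i) * (1 - 2^(-t_weeks / T_half))
              + DE(C_M2, C_Pa, C_CFZ)  +  eps_ij

with a **competitive-interaction drug effect**: the three drugs share one
maximal effect Emax, and each companion drug inflates the apparent potency
of the others,

    DE_A = Emax * C_A / ( EC50_A * (1 + C_B/EC50_B) * (1 + C_C/EC50_C) + C_A )

(cyclically for B and C; total effect = DE_A + DE_B + DE_C). With the
companions absent this is exactly the single-drug Emax model; the combined
drug-driven effect can never exceed the shared Emax. Additive
("independent") and empirical (`beta * DE_A*DE_B*DE_C`) combination rules
are available for model comparison. Random effects (log-normal) act on
baseline, the secular asymptote, the BDQM2/CFZ EC50s and the residual-error
magnitude; estimation is Laplace-approximate maximum marginal likelihood
(via a TMB template) with optional normal prior penalties — e.g. the
pretomanid EC50 prior derived from its linear concentration-QTc slope.

Because no patient-level data ship with the analysis, the package includes
a first-class virtual-trial generator reproducing the 14-day
early-bactericidal-activity study design (105 subjects, seven arms,
triplicate ECGs at pre-dose/5/10 h on the pre-treatment day and days
1, 2, 3, 8, 14, 28, PK-matched sampling), plus a Monte-Carlo regimen
simulator summarised against the ICH E14 thresholds (QTcF > 450/480/500 ms,
dQTcF > 30/60 ms).

## A worked example

```r
library(qtcompete)

trial <- sim_trial(eba_design(), qtc_params(), pk_profile(), seed = 1)
fit   <- qtcfit(trial, ec50_as_fraction = TRUE,
                control = qtcfit_control(se = FALSE))
round(fit$natural[c("emax", "ec50_m2", "ec50_cfz", "ec50_pa",
                    "qtc_ss", "t_half", "qtcf_base", "sigma_add")], 3)
```

    #>      emax   ec50_m2  ec50_cfz   ec50_pa    qtc_ss    t_half qtcf_base sigma_add
    #>    46.826     0.549     1.023    29.961     5.889     1.048   392.521     8.725

One virtual trial generated at the reference estimates (Emax 44.5 ms,
EC50s 0.57 / 0.903 / 26.9 mg/L, baseline 393 ms, secular asymptote 6.33 ms,
residual SD 8.59 ms) and refitted: every recovered value above lies inside
the corresponding published 95% confidence interval. The secular asymptote
is the wobbliest quantity across seeds (81.5% CV between-subject
variability on it, and only the two drug-free arms separate it cleanly
from drug accumulation).

Downstream, the fitted model drives regimen risk simulation:

```r
s <- simulate_regimen(build_regimen("unite4tb_bdq"), n_reps = 5000,
                      params = coef(fit), seed = 2)
format_ich_table(ich_summary(s, weeks = c(1, 2, 8, 28)))
```

which prints, per week and threshold, the percentage of replicates
exceeding each ICH flag for absolute QTcF, drug-driven dQTcF and total
dQTcF (with Monte-Carlo standard errors in the tidy `ich_summary()`
data.frame).

See the vignette (`vignettes/qtc-methods.Rmd`) for the full model
description, estimation details, generator calibration and limitations.

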