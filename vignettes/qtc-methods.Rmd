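---
title: "Joint concentration-QTc modelling of bedaquiline-M2, pretomanid and clofazimine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint concentration-QTc modelling of bedaquiline-M2, pretomanid and clofazimine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(qtcompete)
```

# The problem

Bedaquiline (BDQ), pretomanid (Pa) and clofazimine (CFZ) are cornerstones
of modern regimens against drug-resistant tuberculosis, and all three
prolong the QT interval — most plausibly through a common mechanism,
blockade of the hERG potassium channel. When the drugs are co-administered
the clinically relevant question is not what each does alone but what the
combination does: are the effects additive, or do the drugs compete for the
same target so that the combined effect saturates below the sum?

`qtcompete` implements a population concentration-QTc (PK/PD) model built
around that question. Its parts are:

* a **structural QTc model**: heart-rate-corrected QT (QTcF) described by a
  subject-specific baseline, a three-oscillator circadian rhythm, an
  exponential "secular" drift over treatment time, an additive age effect,
  and a concentration-driven drug effect;
* a **competitive-interaction drug-effect model** in which the three drugs
  share one maximal effect and each companion drug inflates the apparent
  EC50 of the others;
* a **mixed-effects estimator** (Laplace-approximate maximum marginal
  likelihood with optional normal prior penalties) with likelihood-ratio
  testing and stepwise covariate selection;
* a **virtual-trial generator** reproducing the sampling structure of a
  14-day early-bactericidal-activity (EBA) study, used for all simulation
  studies and tests; and
* a **Monte-Carlo regimen simulator** that converts the fitted model into
  ICH E14 threshold-exceedance risk for long-term dosing regimens.

# The structural model

For subject $i$, record $j$:

$$
QTcF_{ij} = \left[\theta_{base} e^{\eta_{base,i}} +
  \theta_{age}(age_i - 37.5)\right]\cdot
  \underbrace{\left(1 + \sum_{k\in\{24,12,6\}} A_k
  \cos\tfrac{2\pi (t^{clock}_{ij} - \phi_k)}{k}\right)}_{\text{circadian}} +
  \underbrace{QTc_{ss}\,e^{\eta_{ss,i}}
  \left(1 - 2^{-t^{weeks}_{ij}/T_{1/2}}\right)}_{\text{secular trend}} +
  DE_{ij} + \varepsilon_{ij}
$$

Design choices worth making explicit:

* **Units decide composition.** The circadian amplitudes are fractions of
  baseline (reported as %), so the circadian factor multiplies the
  age-adjusted baseline only; the secular and drug terms are in ms and are
  added, not scaled by the circadian factor.
* **Secular trend** uses the half-life parameterisation
  $2^{-t/T_{1/2}}$ with $T_{1/2}$ in weeks, applies only after the first
  dose ($t \le 0 \Rightarrow 0$), and its between-subject variability acts
  on the asymptote $QTc_{ss}$ (not the half-life). The asymptote is
  estimated sign-free: treatment-time drifts reported in the literature go
  in both directions.
* **Heart-rate correction.** Raw QT is corrected as $QT/RR^{1/3}$
  (Fridericia) by default; Bazett ($1/2$) and a free exponent are
  available, and `estimate_correction_exponent()` estimates the exponent
  from data by log-log regression (cohorts like this one typically land
  near 0.4, between Fridericia and Bazett).
* **Bedaquiline's QT effect is carried by its N-desmethyl metabolite**
  (BDQM2); the parent concentration is ignored by the model.

## The competitive-interaction drug effect

The three drugs share one $E_{max}$ and each has its own potency; the
companions act as competitive antagonists that shift that potency to the
right:

$$
DE_A = \frac{E_{max}\,C_A}
 {EC_{50,A}\left(1+\frac{C_B}{EC_{50,B}}\right)
  \left(1+\frac{C_C}{EC_{50,C}}\right) + C_A},
$$

cyclically for $B$ and $C$, with $DE = DE_A + DE_B + DE_C$. Two properties
make this model attractive and are enforced by tests: with companions
absent each curve collapses exactly to the single-drug Emax model, and
every per-drug effect stays strictly below
$E_{max}$ — with all three drugs at $c\cdot EC_{50}$ the combined effect
peaks at $0.6\,E_{max}$ at $c = 1$, so no per-drug or drug-driven combined
effect ever exceeds $E_{max}$.

Two alternative combination rules are retained for model comparison: plain
additivity of independent Emax curves (`mode = "independent"`) and the
empirical interaction $DE_A + DE_B + DE_C + \beta\,DE_A DE_B DE_C$
(`mode = "empirical"`).

Individual random effects (log-normal) act on baseline, the secular
asymptote, the BDQM2 and CFZ EC50s, and on the magnitude of the residual
error ("eta-on-epsilon"); residual error is additive normal per ECG
replicate. Random-effect SDs are reported as approximate %CV
(`100 * omega`).

# Estimation

`qtcfit()` maximises the marginal likelihood with the individual random
effects integrated out by the **Laplace approximation**, implemented as a
TMB template so that gradients are exact (automatic differentiation) and
the inner per-subject optimisation is fast. This is a deliberate deviation
from the FOCE-I scheme of classic NONMEM workflows: Laplace is simpler to
state, and its accuracy is verified directly in the test-suite against an
independently coded adaptive Gauss-Hermite quadrature oracle
(`qtc_objective_gh()`, pure R, 64 nodes per dimension, mode-centred and
curvature-scaled) on small instances. On the baseline and secular
dimensions agreement is ~0.1 objective units or better; on the
eta-on-epsilon (residual-magnitude) dimension Laplace carries a known
one-directional error of about +0.085 per subject (six observations
each) — the familiar Laplace weakness on variance parameters — so
instances with many eps-subjects drift beyond the half-unit mark. The
test-suite quantifies both facts rather than hiding the second.

Numerical choices:

* positive parameters on the log scale; acrophases box-constrained to
  their periods; the secular asymptote unbounded; EC50s optionally
  parameterised as fractions of $E_{max}$ (`ec50_as_fraction = TRUE`) —
  the two are strongly positively correlated in this design and the
  fraction parameterisation roughly halves optimisation time;
* priors are normal penalties $((\theta-\mu)/\sigma)^2$ on the natural
  scale, added to the $-2\log L$ objective. "Weakly informative, about
  30% uncertainty" is read as prior SD $= 0.30\,\mu$ (a CV); this is a
  convention, and explicit `c(mean, sd)` pairs override it;
* the default prior set stabilises the six circadian parameters at their
  literature values and centres the pretomanid EC50 at 25.3 mg/L — the
  value obtained by `pa_prior_from_linear()`, which solves for the EC50
  whose shared-Emax curve best matches a linear slope of 1.57 ms/(mg/L)
  over the observed low-mg/L pretomanid range. Because the published
  concentration grid behind that construction is not available, the grid
  is an argument, not a constant;
* optimisation is `nlminb` with exact gradients, up to 3 jittered
  restarts, and a warm-restart "polish" step; large fits additionally use
  a two-strategy multi-start (a direct pass, and one warm-started from a
  circadian-fixed first stage), keeping the lower objective — the
  marginal likelihood is mildly multimodal along the secular-trend /
  drug-accumulation directions and a single start finds the better mode
  only most of the time. The polish exists because
  the model has a genuinely flat direction whenever a subject's simulated
  individual EC50 (168% CV for BDQM2!) drifts into effect saturation: the
  inner Hessian then has a near-zero eigenvalue, the Laplace gradient
  becomes ill-conditioned at the optimum, and `nlminb` reports "false
  convergence" at what is in fact the maximum. A restart that cannot
  improve the objective by more than 0.01 units is accepted as converged;
* structurally unidentifiable parameters are fixed automatically (a
  drug's EC50 when that drug never appears in the data, the secular trend
  without on-treatment records), which is also how the sequential
  model-building strategy — clofazimine monotherapy first, then
  combination arms — is expressed with `fix = ...` masks.

Model comparison uses `lrt()` / `anova()`: $dOFV$ against a
$\chi^2_{df}$ reference. The 2-df secular-trend test deserves a caveat
that the test-suite quantifies by simulation (200 null fits on a reduced
40-subject control-only design): under the null ($QTc_{ss}=0$) the
half-life is unidentified, the statistic behaves like a supremum over a
strongly correlated one-parameter family — effectively closer to 1 df —
and the conventional 2-df reference is therefore *conservative* (realised
type-I error around 0.01 rather than 0.05). Detection of a real secular
trend of the magnitude estimated here is unaffected (the packaged example
rejects far below 0.01), but borderline secular effects are judged
against a stricter-than-nominal bar. Covariate screening
(`step_covariates()`) uses forward inclusion at 0.05 and backward
retention at 0.01 — the conventional pairing when only the retention
threshold is reported.

Asymptotic standard errors come from the delta method on the natural
scale (`TMB::sdreport`); sampling-importance-resampling intervals are out
of scope.

# The virtual-trial generator

No individual-level data are distributed with the analysis this package
implements, so the generator is a first-class module: every estimation
property is demonstrated on virtual trials with the study's structure.

* **Design** (`eba_design()`): 105 subjects, seven arms of 15 covering
  each QT-active drug alone or in combination plus two control arms
  without QT-prolonging drugs; triplicate ECGs at pre-dose/5 h/10 h on
  the pre-treatment day and days 1, 2, 3, 8, 14, 28; 14 days of dosing
  (BDQ 400/300/200 mg loading, CFZ 300 mg × 3 then 100 mg, Pa 200 mg);
  dosing at 08:00 — the source study does not state a clock time, so this
  is a flagged convention that places the 5 h/10 h samples at 13:00/18:00
  for the circadian term.
* **Covariates** match the cohort: age median ~30 y, 62% male, weight
  median ~53.8 kg, electrolytes around reference values.
* **PK stand-ins** (`pk_profile()`): one-compartment first-order
  absorption with analytic dose superposition; BDQM2 as a first-order
  metabolite compartment. Parameters are calibrated — once — so typical
  concentrations land where the QTc model's EC50s are informative: BDQM2
  and CFZ ~0.1–1 mg/L with slow accumulation, pretomanid ~1–3 mg/L and at
  steady state within days, inside the region where its
  concentration-effect relationship is locally linear (within 10% of the
  low-concentration slope $E_{max}/EC_{50}$). These stand-ins are
  configurable inputs, *not* published population-PK parameter sets, and
  none of their values is asserted as literature truth.
* **Noise** follows the estimation model exactly, with residual error
  applied per ECG replicate *before* triplicate averaging (so averaged
  records carry residual SD $\sigma/\sqrt{3}$ — a decomposition the
  test-suite checks against the simulated baseline SD).

What the generator deliberately does not emulate: dropout and missing
ECGs (the real study's 2,062 records vs the ideal 2,205), assay error in
concentrations, hysteresis between concentration and effect, tolerance
development, and mechanistic multi-compartment PK. Passing
parameter-recovery tests therefore demonstrates internal consistency of
the estimator under the stated model, not robustness to these real-data
features.

# Parameter recovery and what the tests show

The headline simulation study refits virtual trials generated at the
reference estimates (105 subjects, EBA design) and asks whether the
recovered $E_{max}$, EC50s, baseline, secular parameters, residual SD and
baseline BSV land inside the published 95% confidence intervals. Across
seeds, coverage is essentially complete for all parameters except the
secular asymptote $QTc_{ss}$, whose per-trial maximum-likelihood estimate
is intrinsically variable at this design (81.5% CV between-subject
variability on the asymptote, only two fully drug-free arms to separate
it from drug accumulation, a 14-day treatment window); its estimates
scatter somewhat wider than the published interval, which was itself the
widest relative interval in the reference analysis. The acceptance
machinery reports the realised values rather than forcing them.

Problem sizes used by the packaged simulation studies (chosen as a
balance between Monte-Carlo error and a test-suite that runs in minutes):
20 recovery seeds at the full 105-subject design, 200 null fits at a
40-subject control-only design for the LRT calibration, and
300–10,000 replicates for regimen summaries (the reference analysis used
100,000; exceedance percentages carry the binomial Monte-Carlo standard
error, which the summaries report).

# Regimen simulation

`simulate_regimen()` propagates the fitted pharmacodynamics (PD
between-subject variability only — no residual error, since risk concerns
the underlying QTcF) and the configurable PK stand-ins (BSV on clearance,
weekly inter-occasion variability on absorption) through long-term
regimens: the UNITE4TB bedaquiline schedule (400 mg × 2 weeks → 100 mg),
BPaL (BDQ 200 mg × 8 weeks → 100 mg + Pa 200 mg), and clofazimine 100 mg
with or without loading. Weekly QTcF is evaluated at the expected peak
(5 h post-dose); three trajectories are kept per replicate — absolute
QTcF, *drug-driven* ΔQTcF (the drug-effect term alone), and *total*
ΔQTcF from the subject's own pre-treatment baseline at the same clock
time (drug + secular). Both Δ definitions are reported because published
threshold summaries mix the two conventions.

`ich_summary()` reduces trajectories to the ICH E14 exceedance table:
absolute QTcF > 450/480/500 ms and ΔQTcF > 30/60 ms. A structural
consequence of the competitive model worth stating: the drug-driven
ΔQTcF can never exceed the shared $E_{max}$ (44.5 ms at the reference
estimates), so drug-driven exceedance of the 60 ms flag is *exactly*
zero — a bounded-effect property, not a simulation outcome.

Quantitative exceedance percentages published for specific regimens
depend on external population-PK models whose parameters are not
reproduced here; with the package's PK stand-ins the simulator is
intended for *qualitative* patterns (loading phases raise early
exceedance; covariate settings that raise BDQM2 exposure — e.g. reduced
metabolite clearance in older, non-black patients, available as
configurable multipliers in `pk_profile()` — raise exceedance
monotonically). The default horizon is 28 weeks, matching the published
summary tables, although the accompanying text describes 26 weeks of
dosing; both are supported.

# A worked example

```{r example, eval = FALSE}
library(qtcompete)

# 1. a virtual EBA trial at the reference parameters
trial <- sim_trial(eba_design(), qtc_params(), pk_profile(), seed = 1)

# 2. refit in competitive mode with the pretomanid EC50 prior
fit <- qtcfit(trial, ec50_as_fraction = TRUE)
summary(fit)

# 3. was the secular trend needed?
no_sec <- qtcfit(trial, start = qtc_params(qtc_ss = 0), fix = "secular",
                 ec50_as_fraction = TRUE)
anova(no_sec, fit)

# 4. predictive check
plot(qtc_vpc(fit, n_sim = 200, seed = 2))

# 5. long-term risk of the UNITE4TB bedaquiline schedule
s <- simulate_regimen(build_regimen("unite4tb_bdq"), n_reps = 5000,
                      params = coef(fit), seed = 3)
format_ich_table(ich_summary(s, weeks = c(1, 2, 8, 28)))
```

# Known limitations

* The Laplace approximation is used at estimation scale; its error is
  bounded by oracle tests only on small instances. Skewed random-effect
  posteriors (the eta-on-epsilon dimension, saturated individual EC50s)
  are exactly where Laplace is weakest.
* Asymptotic (Wald) intervals on a boundary-prone, ridge-shaped
  likelihood are approximate; the reference analysis used
  sampling-importance-resampling instead, which is not implemented.
* The PK stand-ins are calibrated plumbing. Any quantitative regimen
  claim requires substituting real population-PK parameter sets through
  `pk_profile()`.
* Tolerance development, effect-compartment hysteresis, moxifloxacin
  co-administration and alternative heart-rate corrections beyond the
  power-law family are out of scope.
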