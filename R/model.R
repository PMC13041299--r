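# Structural concentration-QTc model: heart-rate correction, circadian
# baseline, secular trend, and the drug-effect/interaction models. All
# functions are pure and vectorised; the estimator's C++ objective mirrors
# them and the test-suite quadrature oracle is built on top of these R
# versions.

#' Heart-rate correction of the QT interval
#'
#' Corrects a raw QT interval for heart rate as `QTc = QT / RR^e`, with
#' `e = 1/3` (Fridericia, the default used throughout), `e = 1/2` (Bazett) or
#' a user exponent (`method = "power"`), as in individual- or
#' population-corrected QTc.
#'
#' @param qt_ms raw QT interval (ms); vectorised.
#' @param rr_s RR interval (seconds); vectorised.
#' @param method `"fridericia"`, `"bazett"` or `"power"`.
#' @param exponent correction exponent in (0, 1); only used for
#'   `method = "power"`.
#' @return corrected QTc (ms).
#' @examples
#' correct_qt(400, 1.0)                        # RR = 1 s is the identity
#' correct_qt(380, 0.8)                        # Fridericia
#' correct_qt(380, 0.8, "bazett")
#' correct_qt(380, 0.8, "power", exponent = 0.41)
#' @export
correct_qt <- function(qt_ms, rr_s,
                       method = c("fridericia", "bazett", "power"),
                       exponent = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(qt_ms)) || any(qt_ms <= 0))
    stop("qt_ms must be positive and finite")
  if (any(!is.finite(rr_s)) || any(rr_s <= 0))
    stop("rr_s must be positive and finite")
  e <- switch(method,
              fridericia = 1 / 3,
              bazett = 1 / 2,
              power = {
                if (is.null(exponent)) stop("method 'power' needs 'exponent'")
                if (exponent <= 0 || exponent >= 1)
                  stop("exponent must lie in (0, 1)")
                exponent
              })
  qt_ms / rr_s^e
}

#' Estimate the QT heart-rate correction exponent from data
#'
#' Finds the exponent `e` for which `QT / RR^e` is uncorrelated with RR, via
#' the slope of the log-log regression `log(QT) ~ log(RR)`. The population
#' variant pools all records with per-subject intercepts (so differing
#' individual QT levels do not bias the shared slope); the individual variant
#' returns one exponent per subject.
#'
#' @param qt_ms raw QT (ms).
#' @param rr_s RR interval (s).
#' @param id optional subject identifier, required for per-subject intercepts
#'   and for `by = "individual"`.
#' @param by `"population"` (one pooled exponent) or `"individual"`.
#' @return a single exponent, or a named vector of per-subject exponents.
#' @examples
#' rr <- runif(200, 0.6, 1.2)
#' qt <- 400 * rr^0.41
#' estimate_correction_exponent(qt, rr)   # ~0.41
#' @export
estimate_correction_exponent <- function(qt_ms, rr_s, id = NULL,
                                         by = c("population", "individual")) {
  by <- match.arg(by)
  if (any(qt_ms <= 0) || any(rr_s <= 0))
    stop("qt_ms and rr_s must be positive")
  if (length(unique(rr_s)) < 2L)
    stop("degenerate design: need at least 2 distinct RR values")
  lqt <- log(qt_ms); lrr <- log(rr_s)
  one <- function(lq, lr) {
    if (length(unique(lr)) < 2L)
      stop("degenerate design: constant RR within subject")
    unname(coef(lm(lq ~ lr))[2])
  }
  if (by == "individual") {
    if (is.null(id)) stop("'id' is required for the individual variant")
    vapply(split(seq_along(lqt), id),
           function(ix) one(lqt[ix], lrr[ix]), numeric(1))
  } else {
    if (!is.null(id) && length(unique(id)) > 1L) {
      f <- factor(id)
      unname(coef(lm(lqt ~ lrr + f))["lrr"])
    } else {
      one(lqt, lrr)
    }
  }
}

#' Circadian multiplier of baseline QTcF
#'
#' Sum-of-cosines diurnal model with fixed 24, 12 and 6 h periods:
#' `1 + sum_k A_k cos(2*pi*(t - phi_k)/P_k)`, where `A_k` are the amplitudes
#' (fractions of baseline) and `phi_k` the acrophases (clock hour of each
#' oscillator's peak). Averages to exactly 1 over a full day.
#'
#' @param t_clock clock time (hours in `[0, 24)`); vectorised.
#' @param params a [qtc_params()] object, or anything with `amp`/`acro`.
#' @return dimensionless multiplier applied to the (age-adjusted) baseline.
#' @examples
#' circadian_factor(3, qtc_params())
#' mean(circadian_factor(seq(0, 24, length.out = 4801), qtc_params()))
#' @export
circadian_factor <- function(t_clock, params = qtc_params()) {
  if (any(t_clock < 0 | t_clock >= 24))
    stop("t_clock must lie in [0, 24)")
  periods <- c(24, 12, 6)
  f <- rep(1, length(t_clock))
  for (k in 1:3)
    f <- f + params$amp[k] * cos(2 * pi * (t_clock - params$acro[k]) / periods[k])
  f
}

#' Secular (treatment-time) QTcF trend
#'
#' Exponential rise to an asymptote, parameterised by the asymptotic shift
#' `qtc_ss` (ms) and its half-life in weeks:
#' `qtc_ss * (1 - 2^(-t_weeks / t_half))` for positive treatment time and 0
#' before treatment start. At one half-life the offset is exactly
#' `qtc_ss / 2`.
#'
#' @param t_treatment_h time since first dose (hours; non-positive values
#'   return 0); vectorised.
#' @param params a [qtc_params()] object (fields `qtc_ss`, `t_half`).
#' @return QTcF offset (ms).
#' @examples
#' p <- qtc_params()
#' secular_offset(p$t_half * 168, p)   # exactly qtc_ss / 2
#' @export
secular_offset <- function(t_treatment_h, params = qtc_params()) {
  tw <- pmax(t_treatment_h, 0) / 168
  ifelse(t_treatment_h > 0,
         params$qtc_ss * (1 - 2^(-tw / params$t_half)),
         0)
}

#' Competitive-interaction drug effect on QTcF
#'
#' Shared-Emax model of three drugs binding a common target (hERG): each
#' drug follows an Emax curve in its own concentration, while the two
#' companion drugs act as competitive antagonists that inflate its apparent
#' EC50:
#' \deqn{DE_A = \frac{E_{max} \, C_A}{EC_{50,A}\,(1 + C_B/EC_{50,B})\,(1 +
#'   C_C/EC_{50,C}) + C_A}}
#' and cyclically for B and C. With both companions absent this reduces
#' exactly to the single-drug Emax model; every per-drug effect stays in
#' `[0, emax)`.
#'
#' @param conc_m2,conc_pa,conc_cfz plasma concentrations (mg/L) of
#'   bedaquiline-M2, pretomanid and clofazimine; vectorised (recycled to a
#'   common length).
#' @param params a [qtc_params()] object; `emax` and the EC50s are used. Pass
#'   individual (eta-scaled) EC50s here for subject-level effects.
#' @return a data.frame with columns `de_m2`, `de_pa`, `de_cfz`, `total`
#'   (all ms).
#' @examples
#' p <- qtc_params()
#' drug_effect_competitive(p$ec50_m2, 0, 0, p)$de_m2   # half-maximal: 22.25
#' @export
drug_effect_competitive <- function(conc_m2, conc_pa, conc_cfz,
                                    params = qtc_params()) {
  n <- max(length(conc_m2), length(conc_pa), length(conc_cfz))
  cm2 <- rep_len(conc_m2, n); cpa <- rep_len(conc_pa, n)
  ccfz <- rep_len(conc_cfz, n)
  if (any(cm2 < 0) || any(cpa < 0) || any(ccfz < 0))
    stop("concentrations must be non-negative")
  e <- params$emax
  one <- function(ca, ea, cb, eb, cc, ec)
    e * ca / (ea * (1 + cb / eb) * (1 + cc / ec) + ca)
  de_m2 <- one(cm2, params$ec50_m2, cpa, params$ec50_pa, ccfz, params$ec50_cfz)
  de_pa <- one(cpa, params$ec50_pa, cm2, params$ec50_m2, ccfz, params$ec50_cfz)
  de_cfz <- one(ccfz, params$ec50_cfz, cm2, params$ec50_m2, cpa, params$ec50_pa)
  data.frame(de_m2 = de_m2, de_pa = de_pa, de_cfz = de_cfz,
             total = de_m2 + de_pa + de_cfz)
}

#' Empirical interaction combination of single-drug effects
#'
#' Additive combination of three independently computed drug effects plus an
#' estimated three-way interaction term:
#' `DE = DE_A + DE_B + DE_C + beta * DE_A * DE_B * DE_C`. `beta = 0` is strict
#' additivity; a zero single-drug effect removes the interaction term.
#'
#' @param de_a,de_b,de_c single-drug effects (ms), computed under
#'   `mode = "independent"`.
#' @param beta interaction coefficient (dimensionless).
#' @return combined effect (ms).
#' @examples
#' drug_effect_empirical(5, 3, 2, 0)       # 10
#' drug_effect_empirical(5, 3, 2, -0.01)   # 9.7
#' @export
drug_effect_empirical <- function(de_a, de_b, de_c, beta = 0) {
  de_a + de_b + de_c + beta * de_a * de_b * de_c
}

# Single-drug (independent) Emax effects; used for modes "independent" and
# "empirical".
drug_effect_independent <- function(conc_m2, conc_pa, conc_cfz, params) {
  if (any(conc_m2 < 0) || any(conc_pa < 0) || any(conc_cfz < 0))
    stop("concentrations must be non-negative")
  e <- params$emax
  data.frame(de_m2 = e * conc_m2 / (params$ec50_m2 + conc_m2),
             de_pa = e * conc_pa / (params$ec50_pa + conc_pa),
             de_cfz = e * conc_cfz / (params$ec50_cfz + conc_cfz))
}

# Dispatch on params$mode; returns data.frame(de_m2, de_pa, de_cfz, total).
drug_effect <- function(conc_m2, conc_pa, conc_cfz, params) {
  if (params$mode == "competitive")
    return(drug_effect_competitive(conc_m2, conc_pa, conc_cfz, params))
  de <- drug_effect_independent(conc_m2, conc_pa, conc_cfz, params)
  de$total <- if (params$mode == "empirical")
    drug_effect_empirical(de$de_m2, de$de_pa, de$de_cfz, params$beta)
  else de$de_m2 + de$de_pa + de$de_cfz
  de
}

#' Predict QTcF for observation records
#'
#' Deterministic model prediction (no residual error) for a set of records:
#' \deqn{QTcF = [base\,e^{\eta_{base}} + slope_{age}(age - 37.5)] \cdot
#'   circ(t_{clock}) + sec(t_{treat})\,e^{\eta_{ss}} + DE(C; EC_{50}
#'   e^{\eta})}
#' The circadian factor multiplies the age-adjusted baseline only; secular
#' and drug terms are additive in ms. Individual EC50s of clofazimine and
#' BDQM2 are the typical values scaled by `exp(eta)`.
#'
#' @param data data.frame with columns `CLOCK_H`, `TIME_H` (hours since first
#'   dose, negative pre-treatment), `CM2_MGL`, `CPA_MGL`, `CCFZ_MGL`, `AGE_Y`
#'   and (for individual predictions) `ID`.
#' @param params a [qtc_params()] object.
#' @param etas `NULL` for the typical individual, or a numeric matrix with
#'   one row per subject (rownames = subject IDs) and columns
#'   [QTC_ETA_NAMES].
#' @return numeric vector of predicted QTcF (ms), one per row of `data`.
#' @examples
#' d <- data.frame(ID = 1, TIME_H = 0, CLOCK_H = 8, CM2_MGL = 0.57,
#'                 CPA_MGL = 0, CCFZ_MGL = 0, AGE_Y = 37.5)
#' predict_qtcf(d, qtc_params(amp = c(0, 0, 0)))   # 393 + 22.25
#' @export
predict_qtcf <- function(data, params = qtc_params(), etas = NULL) {
  need <- c("CLOCK_H", "TIME_H", "CM2_MGL", "CPA_MGL", "CCFZ_MGL", "AGE_Y")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (any(is.na(data$AGE_Y))) stop("missing covariate AGE_Y")
  n <- nrow(data)
  if (is.null(etas)) {
    eta <- matrix(0, n, 5, dimnames = list(NULL, QTC_ETA_NAMES))
  } else {
    if (is.null(rownames(etas)))
      stop("etas must have subject IDs as rownames")
    ix <- match(as.character(data$ID), rownames(etas))
    if (any(is.na(ix))) stop("etas missing for some subjects in data")
    eta <- etas[ix, QTC_ETA_NAMES, drop = FALSE]
  }
  base_i <- params$qtcf_base * exp(eta[, "base"]) +
    params$age_slope * (data$AGE_Y - params$age_center)
  pind <- params
  out <- numeric(n)
  # individual EC50s vary by subject: evaluate per unique eta pattern
  key <- paste(eta[, "ec50_cfz"], eta[, "ec50_m2"])
  for (k in unique(key)) {
    ix <- which(key == k)
    pind$ec50_cfz <- params$ec50_cfz * exp(eta[ix[1], "ec50_cfz"])
    pind$ec50_m2 <- params$ec50_m2 * exp(eta[ix[1], "ec50_m2"])
    out[ix] <- drug_effect(data$CM2_MGL[ix], data$CPA_MGL[ix],
                           data$CCFZ_MGL[ix], pind)$total
  }
  unname(base_i * circadian_factor(data$CLOCK_H, params) +
           secular_offset(data$TIME_H, params) * exp(eta[, "ss"]) + out)
}
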