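# Population parameter container for the joint concentration-QTc model.
#
# All fixed effects, random-effect SDs (log-normal, reported downstream as
# approximate %CV = 100*omega) and the residual-error model live in one
# validated list so that simulation, prediction and estimation share a single
# source of truth.

#' Names of the individual random-effect dimensions, in canonical order
#'
#' `base` scales baseline QTcF, `ss` the secular-trend asymptote, `ec50_cfz`
#' and `ec50_m2` the respective drug potencies, and `eps` the magnitude of the
#' individual residual error (eta-on-epsilon). All act multiplicatively as
#' `exp(eta)`.
#'
#' @export
QTC_ETA_NAMES <- c("base", "ss", "ec50_cfz", "ec50_m2", "eps")

#' Population parameters of the concentration-QTc model
#'
#' Constructs the full parameter set of the structural model: typical baseline
#' QTcF, three-oscillator circadian variation, exponential secular trend,
#' age effect on baseline, the shared-Emax drug-effect model with one EC50 per
#' drug, between-subject variability (BSV) and the additive residual error.
#' Defaults are the final population estimates of the joint
#' bedaquiline-M2/pretomanid/clofazimine analysis this package implements, so
#' `qtc_params()` with no arguments is the reference parameter set used
#' throughout the documentation and the simulation studies.
#'
#' @param qtcf_base typical baseline QTcF (ms).
#' @param amp circadian amplitudes as fractions of baseline for the 24, 12 and
#'   6 h oscillators (e.g. `0.0113` = 1.13%).
#' @param acro circadian acrophases (clock hours of each oscillator's peak)
#'   for the 24, 12 and 6 h oscillators.
#' @param qtc_ss asymptotic secular-trend QTcF shift on treatment (ms). May be
#'   negative (a declining trend).
#' @param t_half secular-trend half-life (weeks).
#' @param age_slope additive age effect on baseline (ms per year).
#' @param age_center centering age (years) for the age effect.
#' @param emax shared maximal drug effect (ms).
#' @param ec50_m2,ec50_cfz,ec50_pa potency (mg/L) of bedaquiline-M2,
#'   clofazimine and pretomanid.
#' @param beta empirical interaction coefficient (dimensionless); only used
#'   when `mode = "empirical"`.
#' @param mode drug-interaction model: `"competitive"` (companions inflate
#'   each other's EC50), `"empirical"` (additive plus `beta` times the triple
#'   product) or `"independent"` (plain additive Emax curves).
#' @param omega_base,omega_ss,omega_ec50_cfz,omega_ec50_m2,omega_eps
#'   between-subject SDs of the log-normal random effects (so 0.034
#'   is approximately 3.4 %CV), in the order of [QTC_ETA_NAMES].
#' @param sigma_add additive residual error SD (ms) of a single ECG replicate.
#'
#' @return An object of class `qtc_params` (a validated named list).
#' @examples
#' p <- qtc_params()
#' p$emax
#' qtc_params(emax = 30, ec50_m2 = 0.45)$ec50_m2
#' @export
qtc_params <- function(qtcf_base = 393,
                       amp = c(0.0113, 0.00586, 0.00289),
                       acro = c(3.32, 3.54, 5.14),
                       qtc_ss = 6.33,
                       t_half = 1.04,
                       age_slope = 0.472,
                       age_center = 37.5,
                       emax = 44.5,
                       ec50_m2 = 0.57,
                       ec50_cfz = 0.903,
                       ec50_pa = 26.9,
                       beta = 0,
                       mode = c("competitive", "empirical", "independent"),
                       omega_base = 0.034,
                       omega_ss = 0.815,
                       omega_ec50_cfz = 0.92,
                       omega_ec50_m2 = 1.68,
                       omega_eps = 0.311,
                       sigma_add = 8.59) {
  mode <- match.arg(mode)
  p <- list(qtcf_base = qtcf_base, amp = as.numeric(amp),
            acro = as.numeric(acro), qtc_ss = qtc_ss, t_half = t_half,
            age_slope = age_slope, age_center = age_center, emax = emax,
            ec50_m2 = ec50_m2, ec50_cfz = ec50_cfz, ec50_pa = ec50_pa,
            beta = beta, mode = mode,
            omega_base = omega_base, omega_ss = omega_ss,
            omega_ec50_cfz = omega_ec50_cfz, omega_ec50_m2 = omega_ec50_m2,
            omega_eps = omega_eps, sigma_add = sigma_add)
  validate_qtc_params(p)
  structure(p, class = "qtc_params")
}

validate_qtc_params <- function(p) {
  stopifnot(
    "qtcf_base must lie in (250, 550) ms" =
      is.numeric(p$qtcf_base) && p$qtcf_base > 250 && p$qtcf_base < 550,
    "amp must be 3 non-negative amplitudes" =
      length(p$amp) == 3L && all(p$amp >= 0),
    "sum of circadian amplitudes must be < 1" = sum(p$amp) < 1,
    "acro must be 3 acrophases within the oscillator periods" =
      length(p$acro) == 3L && all(p$acro >= 0) &&
        all(p$acro < c(24, 12, 6)),
    "t_half must be > 0" = p$t_half > 0,
    "age_center must be > 0" = p$age_center > 0,
    "emax must be > 0" = p$emax > 0,
    "EC50s must be > 0" =
      p$ec50_m2 > 0 && p$ec50_cfz > 0 && p$ec50_pa > 0,
    "random-effect SDs must be >= 0" =
      all(c(p$omega_base, p$omega_ss, p$omega_ec50_cfz,
            p$omega_ec50_m2, p$omega_eps) >= 0),
    "sigma_add must be > 0" = p$sigma_add > 0
  )
  invisible(p)
}

#' @export
print.qtc_params <- function(x, digits = 4, ...) {
  cat("Population concentration-QTc parameters (mode:", x$mode, ")\n")
  cat(sprintf("  Baseline QTcF        %8.4g ms  (BSV %.3g %%CV)\n",
              x$qtcf_base, 100 * x$omega_base))
  cat(sprintf("  Circadian amp (%%)    %s\n",
              paste(signif(100 * x$amp, 3), collapse = " / ")))
  cat(sprintf("  Circadian acro (h)   %s   [periods 24/12/6 h]\n",
              paste(signif(x$acro, 3), collapse = " / ")))
  cat(sprintf("  Secular QTc_ss       %8.4g ms  (T1/2 %.3g wk, BSV %.3g %%CV)\n",
              x$qtc_ss, x$t_half, 100 * x$omega_ss))
  cat(sprintf("  Age effect           %8.4g ms/yr (centred %.3g yr)\n",
              x$age_slope, x$age_center))
  cat(sprintf("  Emax (shared)        %8.4g ms\n", x$emax))
  cat(sprintf("  EC50 BDQM2/CFZ/Pa    %.4g / %.4g / %.4g mg/L (BSV %.3g / %.3g / - %%CV)\n",
              x$ec50_m2, x$ec50_cfz, x$ec50_pa,
              100 * x$omega_ec50_m2, 100 * x$omega_ec50_cfz))
  if (x$mode == "empirical")
    cat(sprintf("  Interaction beta     %8.4g\n", x$beta))
  cat(sprintf("  Additive error       %8.4g ms  (BSV on magnitude %.3g %%CV)\n",
              x$sigma_add, 100 * x$omega_eps))
  invisible(x)
}

# Canonical flat natural-scale parameter vector used by the estimator and the
# prior machinery. Covariate slopes (beyond age) are appended by the fitter.
QTC_NATURAL_NAMES <- c(
  "qtcf_base", "amp24", "amp12", "amp6", "acro24", "acro12", "acro6",
  "qtc_ss", "t_half", "age_slope", "emax", "ec50_m2", "ec50_cfz", "ec50_pa",
  "beta", "sigma_add", "omega_base", "omega_ss", "omega_ec50_cfz",
  "omega_ec50_m2", "omega_eps")

qtc_params_to_natural <- function(p) {
  setNames(c(p$qtcf_base, p$amp, p$acro, p$qtc_ss, p$t_half, p$age_slope,
             p$emax, p$ec50_m2, p$ec50_cfz, p$ec50_pa, p$beta, p$sigma_add,
             p$omega_base, p$omega_ss, p$omega_ec50_cfz, p$omega_ec50_m2,
             p$omega_eps),
           QTC_NATURAL_NAMES)
}

natural_to_qtc_params <- function(v, mode = "competitive",
                                  age_center = 37.5) {
  qtc_params(qtcf_base = v[["qtcf_base"]],
             amp = v[c("amp24", "amp12", "amp6")],
             acro = v[c("acro24", "acro12", "acro6")],
             qtc_ss = v[["qtc_ss"]], t_half = v[["t_half"]],
             age_slope = v[["age_slope"]], age_center = age_center,
             emax = v[["emax"]], ec50_m2 = v[["ec50_m2"]],
             ec50_cfz = v[["ec50_cfz"]], ec50_pa = v[["ec50_pa"]],
             beta = v[["beta"]], mode = mode,
             omega_base = v[["omega_base"]], omega_ss = v[["omega_ss"]],
             omega_ec50_cfz = v[["omega_ec50_cfz"]],
             omega_ec50_m2 = v[["omega_ec50_m2"]],
             omega_eps = v[["omega_eps"]], sigma_add = v[["sigma_add"]])
}

#' Normal prior specification for penalised estimation
#'
#' Priors are normal penalties on natural-scale parameters, each contributing
#' `((theta - mean)/sd)^2` to the -2 log-likelihood objective. The default
#' follows the weakly-informative convention of prior SD = `cv` times the
#' prior mean ("around 30% variance" read as a 30% CV).
#'
#' `qtc_priors()` with defaults returns the prior set used in the reference
#' analysis: a prior on the pretomanid EC50 (mean 25.3 mg/L, the value that a
#' linear slope of 1.57 ms/(mg/L) implies under the shared Emax; see
#' [pa_prior_from_linear()]) plus stabilising priors on the six circadian
#' parameters centred at their literature values.
#'
#' @param ... named prior entries. Each is either a numeric `c(mean, sd)` or a
#'   single mean (SD then taken as `cv * mean`). Names must be among the
#'   natural parameter names (e.g. `ec50_pa`, `amp24`, `acro12`) or a
#'   covariate-slope name used by the fitter.
#' @param cv default coefficient of variation applied when only a mean is
#'   given.
#' @return object of class `qtc_priors`: named list of `c(mean, sd)`.
#' @examples
#' qtc_priors()                          # reference prior set
#' qtc_priors(ec50_pa = c(25.3, 7.59))   # explicit SD
#' qtc_priors(ec50_pa = 20, cv = 0.25)
#' @export
qtc_priors <- function(..., cv = 0.30) {
  entries <- list(...)
  if (length(entries) == 0L) {
    d <- qtc_params()
    entries <- list(ec50_pa = 25.3,
                    amp24 = d$amp[1], amp12 = d$amp[2], amp6 = d$amp[3],
                    acro24 = d$acro[1], acro12 = d$acro[2], acro6 = d$acro[3])
  }
  if (is.null(names(entries)) || any(names(entries) == ""))
    stop("all prior entries must be named")
  out <- lapply(entries, function(e) {
    e <- as.numeric(e)
    if (length(e) == 1L) e <- c(e, abs(cv * e))
    if (length(e) != 2L) stop("each prior must be c(mean) or c(mean, sd)")
    if (e[2] <= 0) stop("prior SD must be > 0")
    setNames(e, c("mean", "sd"))
  })
  structure(out, class = "qtc_priors")
}

#' @export
print.qtc_priors <- function(x, ...) {
  cat("Normal prior penalties (natural scale):\n")
  for (nm in names(x))
    cat(sprintf("  %-10s mean %9.4g  sd %9.4g\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}
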