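# S3 methods for fitted qtcfit objects.

#' @export
print.qtcfit <- function(x, ...) {
  cat("Population concentration-QTc model fit (", x$mode, " interaction)\n",
      sep = "")
  cat(sprintf("  %d subjects, %d observations; OFV (-2LL + prior) = %.3f\n",
              x$n_subjects, x$n_obs, x$objective))
  cat(sprintf("  %d free parameters; convergence code %d (%s)\n",
              x$df, x$convergence,
              if (!is.null(x$message)) x$message else ""))
  est <- x$natural[x$free]
  cat("  Estimates:\n")
  print(signif(est, 4))
  invisible(x)
}

#' Parameter table of a fitted concentration-QTc model
#'
#' Builds the parameter table in the conventional population-PK/PD report
#' layout: typical values with asymptotic 95% Wald confidence intervals,
#' between-subject variability as approximate %CV, and the residual-error
#' block.
#'
#' @param object a [qtcfit()] object.
#' @param level confidence level.
#' @param ... unused.
#' @return object of class `summary.qtcfit`; its `$table` is a data.frame
#'   with columns `parameter`, `estimate`, `se`, `lo`, `hi`, `fixed`.
#' @export
summary.qtcfit <- function(object, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  nat <- object$natural
  se <- if (is.null(object$se)) rep(NA_real_, length(nat)) else
    object$se[names(nat)]
  pct <- grepl("^omega_", names(nat)) | grepl("^amp", names(nat))
  est <- ifelse(pct, 100 * nat, nat)
  sep <- ifelse(pct, 100 * se, se)
  tab <- data.frame(parameter = names(nat),
                    estimate = est, se = sep,
                    lo = est - z * sep, hi = est + z * sep,
                    fixed = !(names(nat) %in% object$free),
                    row.names = NULL)
  structure(list(table = tab, mode = object$mode, level = level,
                 objective = object$objective, n_obs = object$n_obs,
                 n_subjects = object$n_subjects, df = object$df),
            class = "summary.qtcfit")
}

#' @export
print.summary.qtcfit <- function(x, ...) {
  cat("Concentration-QTc model (", x$mode, " interaction): ",
      x$n_subjects, " subjects, ", x$n_obs, " observations\n", sep = "")
  cat(sprintf("OFV = %.3f, %d free parameters\n\n", x$objective, x$df))
  t <- x$table
  lab <- c(qtcf_base = "QTcF base (ms)",
           amp24 = "24-h cycle amplitude (%)",
           amp12 = "12-h cycle amplitude (%)",
           amp6 = "6-h cycle amplitude (%)",
           acro24 = "24-h cycle acrophase (h)",
           acro12 = "12-h cycle acrophase (h)",
           acro6 = "6-h cycle acrophase (h)",
           qtc_ss = "QTc_ss (ms)", t_half = "T1/2 (weeks)",
           age_slope = "Age effect (ms per year)",
           emax = "Emax (ms)", ec50_m2 = "EC50 BDQM2 (mg/L)",
           ec50_cfz = "EC50 CFZ (mg/L)", ec50_pa = "EC50 Pa (mg/L)",
           beta = "Interaction beta",
           sigma_add = "Additive error (ms)",
           omega_base = "BSV QTcF base (%CV)",
           omega_ss = "BSV QTc_ss (%CV)",
           omega_ec50_cfz = "BSV CFZ EC50 (%CV)",
           omega_ec50_m2 = "BSV BDQM2 EC50 (%CV)",
           omega_eps = "Residual variability (%CV)")
  nm <- ifelse(t$parameter %in% names(lab), lab[t$parameter], t$parameter)
  for (i in seq_len(nrow(t))) {
    if (t$fixed[i]) {
      cat(sprintf("  %-28s %10.4g  (fixed)\n", nm[i], t$estimate[i]))
    } else {
      cat(sprintf("  %-28s %10.4g  (%.4g - %.4g)\n", nm[i],
                  t$estimate[i], t$lo[i], t$hi[i]))
    }
  }
  cat(sprintf("\n%g%% CIs are asymptotic (Wald); BSV reported as approximate %%CV.\n",
              100 * x$level))
  invisible(x)
}

#' @export
coef.qtcfit <- function(object, ...) object$coefficients

#' @export
logLik.qtcfit <- function(object, ...) {
  structure(-object$objective / 2, df = object$df,
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.qtcfit <- function(object, ...) object$vcov

#' Model predictions for a fitted concentration-QTc model
#'
#' @param object a [qtcfit()] object.
#' @param newdata optional data.frame of records (defaults to the fitting
#'   data).
#' @param type `"population"` (typical-individual prediction, all etas 0) or
#'   `"individual"` (empirical-Bayes etas; subjects must appear in the
#'   fitting data).
#' @param ... unused.
#' @return numeric vector of predicted QTcF (ms).
#' @export
predict.qtcfit <- function(object, newdata = NULL,
                           type = c("individual", "population"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  predict_qtcf(newdata, coef(object),
               etas = if (type == "individual") object$etas else NULL)
}

#' @export
residuals.qtcfit <- function(object,
                             type = c("individual", "population"), ...) {
  object$data$QTCF_MS - predict(object, type = match.arg(type))
}

#' Simulate replicate datasets from a fitted model
#'
#' Re-simulates the QTcF observations of the fitting dataset under the
#' estimated parameters: new random effects and replicate-level residual
#' errors are drawn while the design — sampling times, observed drug
#' concentrations and covariates — is kept fixed. This is the simulation
#' basis of the visual predictive check ([qtc_vpc()]).
#'
#' @param object a [qtcfit()] object.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a matrix with one column per replicate of simulated `QTCF_MS`
#'   aligned with `object$data` rows.
#' @export
simulate.qtcfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_qtcf_replicates(object$data, coef(object), nsim)
}

# shared by simulate.qtcfit and qtc_vpc: redraw etas + residuals at a fixed
# design
simulate_qtcf_replicates <- function(data, params, nsim) {
  data <- prepare_qtc_data(data)
  ids <- unique(data$ID)
  ix <- match(data$ID, ids)
  out <- matrix(NA_real_, nrow(data), nsim)
  for (r in seq_len(nsim)) {
    eta <- draw_etas(length(ids), params)
    rownames(eta) <- ids
    pred <- predict_qtcf(data, params, eta)
    sd_i <- params$sigma_add * exp(eta[ix, "eps"]) / sqrt(data$NREP)
    out[, r] <- pred + rnorm(nrow(data), 0, sd_i)
  }
  out
}

#' Likelihood-ratio test between nested model fits
#'
#' Compares the objective (-2 log marginal likelihood, plus identical prior
#' penalties) of two nested fits against a chi-square reference:
#' `dOFV = OFV_reduced - OFV_full`, `p = P(chi2_df > dOFV)` (and `p = 1` when
#' the full model fits no better). Nestedness is checked on the sets of
#' freely estimated parameters.
#'
#' @param fit_full,fit_reduced [qtcfit()] objects; the reduced model's free
#'   parameters must be a subset of the full model's.
#' @param df test degrees of freedom; default is the difference in the
#'   number of free parameters.
#' @return list with `dofv`, `df`, `p_value`.
#' @examples
#' # lrt(fit_full, fit_reduced)   # e.g. 2-df test of the secular trend
#' @export
lrt <- function(fit_full, fit_reduced, df = NULL) {
  stopifnot(inherits(fit_full, "qtcfit"), inherits(fit_reduced, "qtcfit"))
  if (!all(fit_reduced$free %in% fit_full$free))
    stop("invalid comparison: models are not nested ",
         "(reduced model frees parameters the full model does not)")
  if (is.null(df)) df <- fit_full$df - fit_reduced$df
  if (df < 1) stop("df must be >= 1")
  dofv <- fit_reduced$objective - fit_full$objective
  p <- if (dofv <= 0) 1 else pchisq(dofv, df, lower.tail = FALSE)
  list(dofv = dofv, df = df, p_value = p)
}

#' @describeIn lrt `anova` interface: `anova(fit_reduced, fit_full)`.
#' @param object,... for `anova`: two `qtcfit` objects, reduced then full.
#' @export
anova.qtcfit <- function(object, ...) {
  fits <- c(list(object), list(...))
  fits <- fits[vapply(fits, inherits, logical(1), "qtcfit")]
  if (length(fits) != 2L) stop("anova needs exactly two qtcfit objects")
  r <- lrt(fits[[2]], fits[[1]])
  out <- data.frame(model = c("reduced", "full"),
                    df = c(fits[[1]]$df, fits[[2]]$df),
                    OFV = c(fits[[1]]$objective, fits[[2]]$objective),
                    dOFV = c(NA, -r$dofv),
                    p = c(NA, r$p_value))
  class(out) <- c("anova", "data.frame")
  out
}

#' Diagnostic plot of a fitted model
#'
#' Observed QTcF and individual predictions against time on treatment.
#'
#' @param x a [qtcfit()] object.
#' @param ... passed to [plot()].
#' @export
plot.qtcfit <- function(x, ...) {
  d <- x$data
  plot(d$TIME_H / 24, d$QTCF_MS, col = "grey50", pch = 16, cex = 0.4,
       xlab = "Time since first dose (days)", ylab = "QTcF (ms)", ...)
  points(d$TIME_H / 24, predict(x, type = "individual"), col = "red3",
         pch = 1, cex = 0.4)
  legend("topleft", legend = c("observed", "individual prediction"),
         col = c("grey50", "red3"), pch = c(16, 1), bty = "n", cex = 0.8)
  invisible(x)
}
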