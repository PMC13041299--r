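# Forward-inclusion / backward-elimination covariate selection on baseline
# QTcF, the classic stepwise procedure of population-model covariate
# screening (forward at a liberal alpha, retention at a stricter one).

#' Stepwise covariate selection on baseline QTcF
#'
#' Classic forward/backward stepwise search over candidate baseline
#' covariates. Each candidate enters as an additive centred slope on
#' baseline (ms per unit). In each forward round every excluded candidate is
#' added in turn and the one with the largest drop in objective is included
#' if its 1-df likelihood-ratio p-value meets `alpha_forward`; backward
#' elimination then removes, one at a time, any included covariate whose
#' exclusion is not significant at `alpha_backward`.
#'
#' Near-collinear candidate pairs (subject-level correlation > 0.99) are
#' flagged with a warning entry in the trace but do not abort the search.
#'
#' @param data trial dataset (see [qtcfit()]).
#' @param candidates character vector of covariate column names.
#' @param alpha_forward,alpha_backward inclusion / retention significance
#'   levels (forward 0.05, backward 0.01 by convention).
#' @param centers optional named centring values; defaults to subject-level
#'   medians.
#' @param ... further arguments passed to every [qtcfit()] call (e.g. `fix`,
#'   `random`, `control`).
#' @return list with `selected` (character), `trace` (data.frame of steps:
#'   phase, covariate, dOFV, p, decision), `warnings` (character), and
#'   `fit` (the final model).
#' @export
step_covariates <- function(data, candidates,
                            alpha_forward = 0.05, alpha_backward = 0.01,
                            centers = NULL, ...) {
  if (length(candidates) == 0L) stop("no candidate covariates supplied")
  data <- prepare_qtc_data(data)
  miss <- setdiff(candidates, names(data))
  if (length(miss)) stop("candidate column(s) not in data: ",
                         paste(miss, collapse = ", "))
  sub1 <- data[!duplicated(data$ID), , drop = FALSE]
  num <- function(x) if (is.character(x) || is.factor(x))
    as.numeric(factor(x)) - 1 else x
  warns <- character()
  if (length(candidates) > 1L) {
    cx <- sapply(candidates, function(cc) num(sub1[[cc]]))
    cm <- suppressWarnings(cor(cx))
    for (i in seq_len(ncol(cm) - 1)) for (j in (i + 1):ncol(cm))
      if (is.na(cm[i, j]) || abs(cm[i, j]) > 0.99)
        warns <- c(warns, paste0("collinear candidates: ", candidates[i],
                                 " ~ ", candidates[j]))
  }
  if (is.null(centers))
    centers <- vapply(candidates, function(cc) median(num(sub1[[cc]])),
                      numeric(1))

  fit_with <- function(set) {
    covs <- setNames(centers[set], set)
    if (length(set) == 0L) covs <- numeric(0)
    qtcfit(data, covariates = covs, ...)
  }

  trace <- data.frame(phase = character(), covariate = character(),
                      dofv = numeric(), p = numeric(),
                      decision = character(), stringsAsFactors = FALSE)
  included <- character()
  base_fit <- fit_with(included)

  repeat {   # forward
    pool <- setdiff(candidates, included)
    if (!length(pool)) break
    res <- lapply(pool, function(cc) {
      f <- fit_with(c(included, cc))
      dofv <- base_fit$objective - f$objective
      list(cov = cc, fit = f, dofv = dofv,
           p = if (dofv <= 0) 1 else pchisq(dofv, 1, lower.tail = FALSE))
    })
    best <- res[[which.max(vapply(res, `[[`, numeric(1), "dofv"))]]
    for (r in res)
      trace <- rbind(trace, data.frame(
        phase = "forward", covariate = r$cov, dofv = r$dofv, p = r$p,
        decision = if (identical(r$cov, best$cov) && best$p < alpha_forward)
          "included" else "not included"))
    if (best$p < alpha_forward) {
      included <- c(included, best$cov)
      base_fit <- best$fit
    } else break
  }

  repeat {   # backward
    if (!length(included)) break
    res <- lapply(included, function(cc) {
      f <- fit_with(setdiff(included, cc))
      dofv <- f$objective - base_fit$objective
      list(cov = cc, fit = f, dofv = dofv,
           p = if (dofv <= 0) 1 else pchisq(dofv, 1, lower.tail = FALSE))
    })
    worst <- res[[which.min(vapply(res, `[[`, numeric(1), "dofv"))]]
    if (worst$p >= alpha_backward) {
      trace <- rbind(trace, data.frame(
        phase = "backward", covariate = worst$cov, dofv = worst$dofv,
        p = worst$p, decision = "removed"))
      included <- setdiff(included, worst$cov)
      base_fit <- worst$fit
    } else {
      for (r in res)
        trace <- rbind(trace, data.frame(
          phase = "backward", covariate = r$cov, dofv = r$dofv, p = r$p,
          decision = "retained"))
      break
    }
  }
  for (w in warns) warning(w, call. = FALSE)
  list(selected = included, trace = trace, warnings = warns, fit = base_fit)
}

#' Emax-prior mean matching a linear concentration-QTc slope
#'
#' Given a linear concentration-QTc slope observed over a concentration
#' range, solves for the EC50 whose shared-Emax curve
#' `emax * c / (ec50 + c)` best matches the linear prediction `slope * c`
#' (least squares over `conc_grid`). Used to turn a linear pretomanid
#' exposure-QTc slope into an informative prior mean for its EC50 when the
#' observed concentrations only probe the linear region of the curve.
#'
#' @param slope linear effect slope (ms per mg/L), > 0.
#' @param emax shared maximal effect (ms).
#' @param conc_grid concentrations (mg/L) over which to match.
#' @return EC50 (mg/L).
#' @examples
#' pa_prior_from_linear(1.57, 44.2, seq(0.5, 6, by = 0.25))
#' @export
pa_prior_from_linear <- function(slope, emax, conc_grid) {
  if (slope <= 0) stop("slope must be > 0")
  if (length(conc_grid) == 0L || any(conc_grid <= 0))
    stop("conc_grid must be positive concentrations")
  if (slope * max(conc_grid) >= emax)
    stop("no workable EC50 in bracket: linear prediction reaches Emax ",
         "within conc_grid")
  f <- function(le) {
    ec50 <- exp(le)
    sum((emax * conc_grid / (ec50 + conc_grid) - slope * conc_grid)^2)
  }
  opt <- optimize(f, interval = log(c(1e-6, 1e8)))
  if (opt$minimum <= log(1e-6) + 1e-6 || opt$minimum >= log(1e8) - 1e-6)
    stop("no interior EC50 solution found in bracket")
  exp(opt$minimum)
}
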