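# Maximum marginal-likelihood estimation of the population concentration-QTc
# model. The Laplace approximation over the individual random effects is
# provided by the package's TMB template (src/qtcompete.cpp); this file owns
# parameter transforms, masking, prior plumbing, optimisation with jittered
# restarts, and the S3 modelling interface around the fitted object.

# natural-scale parameter order shared with the C++ template (covariate
# slopes are appended)
NAT_C_ORDER <- c("qtcf_base", "amp24", "amp12", "amp6",
                 "acro24", "acro12", "acro6", "qtc_ss", "t_half",
                 "emax", "ec50_m2", "ec50_cfz", "ec50_pa", "beta",
                 "sigma_add", "omega_base", "omega_ss", "omega_ec50_cfz",
                 "omega_ec50_m2", "omega_eps")

FIX_GROUPS <- list(
  circadian = c("amp24", "amp12", "amp6", "acro24", "acro12", "acro6"),
  secular = c("qtc_ss", "t_half"),
  drug = c("emax", "ec50_m2", "ec50_cfz", "ec50_pa", "beta"),
  omegas = c("omega_base", "omega_ss", "omega_ec50_cfz", "omega_ec50_m2",
             "omega_eps"))

# covariate column -> natural slope name
cov_slope_name <- function(col)
  ifelse(col == "AGE_Y", "age_slope", paste0("slope_", tolower(col)))

#' Control options for [qtcfit()]
#'
#' @param se compute asymptotic standard errors (delta method on the natural
#'   scale) after optimisation. Disable in large simulation loops.
#' @param staged for large problems with the circadian parameters free, use
#'   a two-strategy multi-start: the full optimisation is run both directly
#'   and warm-started from a first pass with the circadian parameters fixed
#'   at their starting (prior mean) values, and the lower objective wins.
#'   Guards against the mild multimodality of the marginal likelihood along
#'   the secular-trend/drug-accumulation directions; disable for a single
#'   direct pass.
#' @param restarts jittered re-initialisations attempted on convergence
#'   failure.
#' @param jitter_sd SD of the normal jitter applied to the transformed
#'   starting values on restart.
#' @param jitter_seed seed for the jitter draws (derives restart
#'   reproducibility from the run seed).
#' @param iter.max,eval.max,rel.tol passed to [stats::nlminb()].
#' @param trace optimiser trace level.
#' @return list of class `qtcfit_control`.
#' @export
qtcfit_control <- function(se = TRUE, staged = TRUE, restarts = 3,
                           jitter_sd = 0.2, jitter_seed = 20260923,
                           iter.max = 1000, eval.max = 2000,
                           rel.tol = 1e-8, trace = 0) {
  structure(list(se = se, staged = staged, restarts = restarts,
                 jitter_sd = jitter_sd, jitter_seed = jitter_seed,
                 iter.max = iter.max, eval.max = eval.max,
                 rel.tol = rel.tol, trace = trace),
            class = "qtcfit_control")
}

# Ensure QTCF_MS exists (Fridericia-correct raw QT if needed) and NREP set.
prepare_qtc_data <- function(data) {
  data <- as.data.frame(data)
  if (is.null(data$QTCF_MS)) {
    if (is.null(data$QT_MS) || is.null(data$RR_S))
      stop("data needs either QTCF_MS or both QT_MS and RR_S")
    data$QTCF_MS <- correct_qt(data$QT_MS, data$RR_S)
  }
  if (is.null(data$NREP)) data$NREP <- 1L
  need <- c("ID", "TIME_H", "CLOCK_H", "CM2_MGL", "CPA_MGL", "CCFZ_MGL")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  data[order(data$ID, data$TIME_H), ]
}

# Assemble the TMB data/parameter/map lists.
build_tmb_inputs <- function(data, start, mode, priors, fix, random,
                             covariates, ec50_as_fraction) {
  ids <- unique(data$ID)
  subj <- match(data$ID, ids) - 1L
  ncov <- length(covariates)
  covnat <- if (ncov) cov_slope_name(names(covariates)) else character()
  Xcov <- matrix(0, nrow(data), ncov)
  for (j in seq_len(ncov)) {
    col <- names(covariates)[j]
    if (is.null(data[[col]])) stop("covariate column not in data: ", col)
    x <- data[[col]]
    if (is.character(x) || is.factor(x))
      x <- as.numeric(factor(x)) - 1   # e.g. SEX F/M -> 0/1
    Xcov[, j] <- x - covariates[j]
  }

  # expand fix groups and validate
  fix <- unique(unlist(lapply(fix, function(f)
    if (f %in% names(FIX_GROUPS)) FIX_GROUPS[[f]] else f)))
  valid <- c(NAT_C_ORDER, covnat)
  bad <- setdiff(fix, valid)
  if (length(bad))
    stop("unknown parameter(s) in fix: ", paste(bad, collapse = ", "))

  # auto-fix structurally unidentifiable parameters
  auto <- character()
  if (max(data$CM2_MGL) == 0) auto <- c(auto, "ec50_m2", "omega_ec50_m2")
  if (max(data$CCFZ_MGL) == 0) auto <- c(auto, "ec50_cfz", "omega_ec50_cfz")
  if (max(data$CPA_MGL) == 0) auto <- c(auto, "ec50_pa")
  if (max(data$CM2_MGL) == 0 && max(data$CCFZ_MGL) == 0 &&
      max(data$CPA_MGL) == 0) auto <- c(auto, "emax")
  if (!any(data$TIME_H > 0)) auto <- c(auto, "qtc_ss", "t_half", "omega_ss")
  if (mode != "empirical") auto <- c(auto, "beta")
  fix <- unique(c(fix, auto))

  if (length(random))
    random <- match.arg(random, QTC_ETA_NAMES, several.ok = TRUE)
  if (max(data$CM2_MGL) == 0) random <- setdiff(random, "ec50_m2")
  if (max(data$CCFZ_MGL) == 0) random <- setdiff(random, "ec50_cfz")
  if (!any(data$TIME_H > 0)) random <- setdiff(random, "ss")
  re_active <- as.integer(QTC_ETA_NAMES %in% random)
  # an omega whose eta dimension is off has no likelihood contribution
  fix <- unique(c(fix, paste0("omega_", c("base", "ss", "ec50_cfz",
                                          "ec50_m2", "eps"))[re_active == 0]))

  # priors -> natural-order vectors
  natnames <- c(NAT_C_ORDER, covnat)
  prior_mu <- numeric(length(natnames))
  prior_sd <- rep(-1, length(natnames))
  if (!is.null(priors)) {
    badp <- setdiff(names(priors), natnames)
    if (length(badp))
      stop("prior(s) on unknown parameter(s): ", paste(badp, collapse = ", "))
    for (nm in names(priors)) {
      j <- match(nm, natnames)
      prior_mu[j] <- priors[[nm]]["mean"]
      prior_sd[j] <- priors[[nm]]["sd"]
    }
  }

  tmbdat <- list(
    subj = subj,
    qtcf = data$QTCF_MS,
    tclock = data$CLOCK_H,
    tweeks = pmax(data$TIME_H, 0) / 168,
    secon = as.numeric(data$TIME_H > 0),
    cm2 = data$CM2_MGL, cpa = data$CPA_MGL, ccfz = data$CCFZ_MGL,
    Xcov = Xcov,
    sqrtnrep = sqrt(data$NREP),
    mode = match(mode, c("competitive", "empirical", "independent")) - 1L,
    ec50_frac = as.integer(ec50_as_fraction),
    re_active = re_active,
    prior_mu = prior_mu, prior_sd = prior_sd)

  slopes0 <- setNames(numeric(ncov), covnat)
  if ("age_slope" %in% covnat) slopes0["age_slope"] <- start$age_slope
  ec50s <- c(start$ec50_m2, start$ec50_cfz, start$ec50_pa)
  omg <- pmax(c(start$omega_base, start$omega_ss, start$omega_ec50_cfz,
                start$omega_ec50_m2, start$omega_eps), 1e-3)
  pars <- list(
    log_base = log(start$qtcf_base),
    log_amp = log(pmax(start$amp, 1e-9)),
    acro = start$acro,
    qtc_ss = start$qtc_ss,
    log_thalf = log(start$t_half),
    cov_slope = unname(slopes0),
    log_emax = log(start$emax),
    log_ec50 = if (ec50_as_fraction) log(ec50s / start$emax) else log(ec50s),
    beta = start$beta,
    log_sigma = log(start$sigma_add),
    log_omega = log(omg),
    eta = matrix(0, length(ids), 5))

  # map: NA entries are fixed at their starting values
  mk <- function(names_here) {
    f <- seq_along(names_here)
    f[names_here %in% fix] <- NA
    factor(f)
  }
  map <- list(
    log_base = mk("qtcf_base"),
    log_amp = mk(c("amp24", "amp12", "amp6")),
    acro = mk(c("acro24", "acro12", "acro6")),
    qtc_ss = mk("qtc_ss"),
    log_thalf = mk("t_half"),
    log_emax = mk("emax"),
    log_ec50 = mk(c("ec50_m2", "ec50_cfz", "ec50_pa")),
    beta = mk("beta"),
    log_sigma = mk("sigma_add"),
    log_omega = mk(c("omega_base", "omega_ss", "omega_ec50_cfz",
                     "omega_ec50_m2", "omega_eps")))
  if (ncov) map$cov_slope <- mk(covnat)
  etam <- matrix(seq_len(length(ids) * 5), length(ids), 5)
  etam[, re_active == 0] <- NA
  map$eta <- factor(etam)
  map <- map[vapply(map, anyNA, logical(1))]

  list(data = tmbdat, parameters = pars, map = map, ids = ids,
       fix = fix, random = random, covnat = covnat, natnames = natnames)
}

# box constraints on the transformed outer parameters, by TMB name
outer_bounds <- function(parnames) {
  lo <- rep(-Inf, length(parnames)); hi <- rep(Inf, length(parnames))
  set <- function(nm, l, h) {
    ix <- which(parnames == nm)
    lo[ix] <<- l; hi[ix] <<- h
  }
  set("log_base", log(250), log(550))
  set("log_amp", log(1e-9), log(0.25))
  ix <- which(parnames == "acro")
  if (length(ix) == 3L) { lo[ix] <- 0; hi[ix] <- c(24, 12, 6) - 1e-6 }
  set("qtc_ss", -100, 100)
  set("log_thalf", log(0.05), log(20))
  set("cov_slope", -50, 50)
  set("log_emax", log(1), log(500))
  set("log_ec50", log(1e-4), log(1e4))
  set("beta", -10, 10)
  set("log_sigma", log(0.1), log(100))
  set("log_omega", log(1e-4), log(5))
  list(lower = lo, upper = hi)
}

#' Default starting values derived from a dataset
#'
#' Heuristic, data-driven initial values: baseline from the median
#' pre-treatment QTcF, circadian parameters at their prior means when priors
#' are supplied, pretomanid EC50 at its prior mean, and generic mid-range
#' values elsewhere.
#'
#' @param data a trial dataset (see [qtcfit()]).
#' @param priors optional [qtc_priors()] used to centre prior-stabilised
#'   parameters.
#' @return a [qtc_params()] object of starting values.
#' @export
qtc_start <- function(data, priors = NULL) {
  data <- prepare_qtc_data(data)
  pre <- data$TIME_H <= 0
  base0 <- if (any(pre)) median(data$QTCF_MS[pre]) else median(data$QTCF_MS)
  # moment start for the secular asymptote: late drug-free on-treatment
  # records vs pre-treatment level. Starting the asymptote near its crude
  # data estimate matters: the Laplace gradient is unreliable in parts of
  # the parameter space (see qtcfit details), and a far-off secular start
  # can strand the optimiser.
  nodrug <- data$CM2_MGL == 0 & data$CPA_MGL == 0 & data$CCFZ_MGL == 0
  late <- nodrug & data$TIME_H > 7 * 24
  ss0 <- if (any(pre) && any(late))
    mean(data$QTCF_MS[late]) - mean(data$QTCF_MS[pre]) else 3
  # age-slope start from the pre-treatment cross-section
  age0 <- 0
  if (any(pre) && !is.null(data$AGE_Y) &&
      length(unique(data$AGE_Y[pre])) > 2)
    age0 <- unname(coef(lm(data$QTCF_MS[pre] ~ data$AGE_Y[pre]))[2])
  gp <- function(nm, def) if (!is.null(priors[[nm]])) priors[[nm]][["mean"]] else def
  qtc_params(
    qtcf_base = min(max(base0, 300), 500),
    amp = c(gp("amp24", 0.01), gp("amp12", 0.005), gp("amp6", 0.003)),
    acro = c(gp("acro24", 3), gp("acro12", 3), gp("acro6", 3)),
    qtc_ss = min(max(ss0, -30), 30), t_half = 1, age_slope = age0,
    emax = 30, ec50_m2 = 0.4, ec50_cfz = 0.6,
    ec50_pa = gp("ec50_pa", 20),
    omega_base = 0.05, omega_ss = 0.5, omega_ec50_cfz = 0.5,
    omega_ec50_m2 = 0.5, omega_eps = 0.3,
    sigma_add = max(mad(data$QTCF_MS) / 2, 2))
}

#' Fit the population concentration-QTc model
#'
#' Maximum marginal-likelihood estimation by the Laplace approximation over
#' the individual random effects, with optional normal prior penalties
#' (`((theta - mu)/sd)^2` added to the -2 log-likelihood) on natural-scale
#' parameters. Positive parameters are estimated on the log scale, the
#' secular asymptote sign-free, acrophases box-constrained to their periods.
#' On convergence failure the optimisation is restarted from jittered
#' starting values.
#'
#' Structurally unidentifiable parameters are fixed automatically (e.g. the
#' EC50 of a drug absent from the dataset, or the secular trend when no
#' on-treatment records exist), which supports the sequential estimation
#' strategy of fitting monotherapy arms first.
#'
#' @param data long-format trial dataset: a [sim_trial()] result, a
#'   data.frame, or the value of [read_qtc_dataset()]. Needs `QTCF_MS` or
#'   raw `QT_MS` + `RR_S` (Fridericia-corrected on the fly).
#' @param start starting values as a [qtc_params()]; default [qtc_start()].
#' @param mode drug-interaction model (see [qtc_params()]).
#' @param priors a [qtc_priors()] object or `NULL`.
#' @param fix character vector of parameters to fix at their starting
#'   values; natural names (e.g. `"emax"`) and the groups `"circadian"`,
#'   `"secular"`, `"drug"`, `"omegas"` are accepted.
#' @param random random-effect dimensions to include, a subset of
#'   [QTC_ETA_NAMES].
#' @param covariates named numeric vector mapping baseline covariate columns
#'   to their centring values, e.g. `c(AGE_Y = 37.5)`. Slopes act additively
#'   on baseline (ms per unit) before the circadian multiplier.
#' @param ec50_as_fraction estimate EC50s as fractions of Emax (a
#'   stabilising reparameterisation; reported values are always mg/L).
#' @param control a [qtcfit_control()] list.
#' @return an object of class `qtcfit`; see [summary.qtcfit()],
#'   [predict.qtcfit()], [anova.qtcfit()].
#' @examples
#' \donttest{
#' d <- sim_trial(eba_design(n_subjects = 21), seed = 1)
#' f <- qtcfit(d, fix = c("circadian"), control = qtcfit_control(se = FALSE))
#' coef(f)$emax
#' }
#' @export
qtcfit <- function(data,
                   start = NULL,
                   mode = c("competitive", "empirical", "independent"),
                   priors = qtc_priors(),
                   fix = character(),
                   random = QTC_ETA_NAMES,
                   covariates = c(AGE_Y = 37.5),
                   ec50_as_fraction = FALSE,
                   control = qtcfit_control()) {
  cl <- match.call()
  mode <- match.arg(mode)
  data <- prepare_qtc_data(data)
  if (is.null(start)) start <- qtc_start(data, priors)
  validate_qtc_params(start)

  # Multi-start: the marginal likelihood can be multimodal along the
  # (secular trend, drug accumulation) directions, so large fits are
  # optimised from two starting strategies — the data-driven start
  # directly, and warm-started from a first pass with the circadian
  # parameters fixed — and the lower objective wins.
  fix_expanded <- unique(unlist(lapply(fix, function(f)
    if (f %in% names(FIX_GROUPS)) FIX_GROUPS[[f]] else f)))
  circ_free <- !all(FIX_GROUPS$circadian %in% fix_expanded)
  starts <- list(start)
  if (isTRUE(control$staged) && circ_free && nrow(data) > 500) {
    ctl1 <- control
    ctl1$staged <- FALSE
    ctl1$se <- FALSE
    stage1 <- qtcfit(data, start = start, mode = mode, priors = priors,
                     fix = c(fix, "circadian"), random = random,
                     covariates = covariates,
                     ec50_as_fraction = ec50_as_fraction, control = ctl1)
    starts <- c(starts, list(coef(stage1)))
  }

  fit_from <- function(st) {
    inp <- build_tmb_inputs(data, st, mode, priors, fix, random,
                            covariates, ec50_as_fraction)
    obj <- TMB::MakeADFun(data = inp$data, parameters = inp$parameters,
                          map = inp$map,
                          random = if (any(inp$data$re_active == 1)) "eta",
                          DLL = "qtcompete", silent = TRUE)
    bounds <- outer_bounds(names(obj$par))
    run_opt <- function(p0) {
      # muffle nlminb's line-search NA/NaN chatter; real failures error
      withCallingHandlers(
        nlminb(p0, obj$fn, obj$gr, lower = bounds$lower,
               upper = bounds$upper,
               control = list(iter.max = control$iter.max,
                              eval.max = control$eval.max,
                              rel.tol = control$rel.tol,
                              trace = control$trace)),
        warning = function(w) {
          if (grepl("NA/NaN function evaluation", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    }
    safe_opt <- function(p0) tryCatch(run_opt(p0), error = function(e) list(
      objective = Inf, convergence = 99, message = conditionMessage(e),
      par = p0, iterations = 0))
    # Flat individual-EC50 directions (subjects simulated into effect
    # saturation) make the final Laplace gradient ill-conditioned, so
    # nlminb can flag "false convergence" at a perfectly good optimum. A
    # warm restart that fails to improve the objective is accepted as
    # converged.
    polish <- function(o) {
      if (!is.finite(o$objective)) return(o)
      o2 <- safe_opt(o$par)
      if (o2$objective <= o$objective) {
        if (o$objective - o2$objective < 1e-2 && o2$convergence != 0) {
          o2$convergence <- 0
          o2$message <- "restart-stable optimum (ill-conditioned gradient)"
        }
        o2$iterations <- o$iterations + o2$iterations
        return(o2)
      }
      o
    }
    ok <- function(o) is.finite(o$objective) && o$convergence == 0
    opt <- safe_opt(obj$par)
    if (!ok(opt)) opt <- polish(opt)
    best <- opt
    tries <- 0
    rng <- local({ set.seed(control$jitter_seed)
                   function(n, s) rnorm(n, 0, s) })
    while (!ok(best) && tries < control$restarts) {
      tries <- tries + 1
      p0 <- obj$par + rng(length(obj$par), control$jitter_sd)
      p0 <- pmin(pmax(p0, bounds$lower), bounds$upper)
      o <- safe_opt(p0)
      if (!ok(o)) o <- polish(o)
      if (o$objective < best$objective || (ok(o) && !ok(best))) best <- o
    }
    list(opt = polish(best), obj = obj, inp = inp, tries = tries)
  }

  runs <- lapply(starts, fit_from)
  ofvs <- vapply(runs, function(r) r$opt$objective, numeric(1))
  if (!any(is.finite(ofvs)))
    stop("estimation failure after ", control$restarts,
         " restarts: ", runs[[1]]$opt$message)
  win <- runs[[which.min(ofvs)]]
  opt <- win$opt
  obj <- win$obj
  inp <- win$inp
  tries <- win$tries
  invisible(obj$fn(opt$par))   # restore the winner's inner state

  pl <- obj$env$parList(opt$par)
  natural <- natural_from_parlist(pl, inp, ec50_as_fraction)
  se <- vc <- NULL
  if (control$se) {
    # NaN SEs (boundary omegas, flat directions) are reported as NA
    sdr <- tryCatch(suppressWarnings(
      TMB::sdreport(obj, getReportCovariance = TRUE)),
      error = function(e) NULL)
    if (!is.null(sdr)) {
      rep <- summary(sdr, select = "report")
      se <- setNames(rep[, "Std. Error"], inp$natnames)
      vc <- sdr$cov
      if (!is.null(vc)) dimnames(vc) <- list(inp$natnames, inp$natnames)
    }
  }
  eta <- pl$eta
  dimnames(eta) <- list(inp$ids, QTC_ETA_NAMES)

  v <- natural
  coefp <- qtc_params(
    qtcf_base = v[["qtcf_base"]],
    amp = v[c("amp24", "amp12", "amp6")],
    acro = v[c("acro24", "acro12", "acro6")],
    qtc_ss = v[["qtc_ss"]], t_half = v[["t_half"]],
    age_slope = if ("age_slope" %in% inp$covnat) v[["age_slope"]] else 0,
    age_center = if ("AGE_Y" %in% names(covariates))
      covariates[["AGE_Y"]] else 37.5,
    emax = v[["emax"]], ec50_m2 = v[["ec50_m2"]],
    ec50_cfz = v[["ec50_cfz"]], ec50_pa = v[["ec50_pa"]],
    beta = v[["beta"]], mode = mode,
    omega_base = v[["omega_base"]], omega_ss = v[["omega_ss"]],
    omega_ec50_cfz = v[["omega_ec50_cfz"]],
    omega_ec50_m2 = v[["omega_ec50_m2"]],
    omega_eps = v[["omega_eps"]], sigma_add = v[["sigma_add"]])

  structure(list(
    coefficients = coefp,
    natural = natural,
    se = se, vcov = vc,
    objective = 2 * opt$objective,
    df = length(opt$par),
    n_obs = nrow(data), n_subjects = length(inp$ids),
    etas = eta,
    free = setdiff(inp$natnames, inp$fix),
    fix = inp$fix, random = inp$random,
    covariates = covariates, covnat = inp$covnat,
    mode = mode, priors = priors, start = start,
    ec50_as_fraction = ec50_as_fraction,
    convergence = opt$convergence, message = opt$message,
    restarts_used = tries,
    iterations = opt$iterations,
    data = data, call = cl), class = "qtcfit")
}

# transformed parameter list -> named natural vector (shared C++ order)
natural_from_parlist <- function(pl, inp, ec50_frac) {
  emax <- exp(pl$log_emax)
  ec50 <- if (ec50_frac) emax * exp(pl$log_ec50) else exp(pl$log_ec50)
  v <- c(exp(pl$log_base), exp(pl$log_amp), pl$acro, pl$qtc_ss,
         exp(pl$log_thalf), emax, ec50, pl$beta, exp(pl$log_sigma),
         exp(pl$log_omega))
  if (length(inp$covnat)) v <- c(v, pl$cov_slope)
  setNames(v, inp$natnames)
}

#' Marginal -2 log-likelihood objective at fixed parameters
#'
#' Evaluates the estimation objective (marginal -2 log-likelihood plus any
#' prior penalty) at a given parameter set without optimising the population
#' parameters; only the Laplace inner problem over the random effects is
#' solved. With all random effects excluded (`random = character()`) this is
#' the closed-form normal -2 log-likelihood of the residuals. An independent
#' Gauss-Hermite quadrature implementation of the same integral is available
#' in [qtc_objective_gh()] for cross-checking the Laplace approximation.
#'
#' @inheritParams qtcfit
#' @param params the [qtc_params()] at which to evaluate.
#' @return scalar objective value (-2 log marginal likelihood + prior
#'   penalty, including normalising constants).
#' @export
qtc_objective <- function(data, params, priors = NULL,
                          random = QTC_ETA_NAMES,
                          mode = params$mode,
                          covariates = c(AGE_Y = params$age_center)) {
  data <- prepare_qtc_data(data)
  validate_qtc_params(params)
  # leave sigma_add formally unmapped (TMB needs >= 1 free parameter); the
  # objective is evaluated at the starting values, never optimised
  inp <- build_tmb_inputs(data, params, mode, priors,
                          fix = c(setdiff(NAT_C_ORDER, "sigma_add"),
                                  cov_slope_name(names(covariates))),
                          random = random, covariates = covariates,
                          ec50_as_fraction = FALSE)
  has_re <- any(inp$data$re_active == 1)
  obj <- TMB::MakeADFun(data = inp$data, parameters = inp$parameters,
                        map = inp$map,
                        random = if (has_re) "eta" else NULL,
                        DLL = "qtcompete", silent = TRUE)
  2 * as.numeric(obj$fn(obj$par))
}
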