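# Monte-Carlo dosing-regimen simulator: long-term QTcF trajectories for a
# specified patient under named or custom regimens, summarised against ICH
# E14 thresholds.

#' Dosing regimen specification
#'
#' A regimen is a per-drug list of contiguous dosing phases
#' `(dose mg, interval h, duration weeks)`; `Inf` duration extends to the
#' simulation horizon.
#'
#' @param ... per-drug phase tables: named arguments `bdq`, `pa`, `cfz`,
#'   each a data.frame/list with `dose`, `interval_h`, `weeks`.
#' @param label regimen label.
#' @return object of class `qtc_regimen`.
#' @examples
#' regimen_spec(cfz = data.frame(dose = 100, interval_h = 24, weeks = Inf),
#'              label = "CFZ 100 mg daily")
#' @export
regimen_spec <- function(..., label = "custom") {
  drugs <- list(...)
  bad <- setdiff(names(drugs), c("bdq", "pa", "cfz"))
  if (length(bad)) stop("unknown drug(s): ", paste(bad, collapse = ", "))
  if (!length(drugs)) stop("empty regimen")
  for (d in names(drugs)) {
    ph <- as.data.frame(drugs[[d]])
    if (!all(c("dose", "interval_h", "weeks") %in% names(ph)))
      stop(d, ": phases need dose, interval_h, weeks")
    if (any(ph$dose < 0)) stop(d, ": doses must be >= 0")
    if (any(ph$interval_h <= 0)) stop(d, ": intervals must be > 0")
    if (any(ph$weeks <= 0)) stop(d, ": invalid regimen, non-positive phase duration")
    drugs[[d]] <- ph
  }
  structure(list(drugs = drugs, label = label), class = "qtc_regimen")
}

#' Named reference regimens
#'
#' Pre-specified dosing schedules:
#' \describe{
#'   \item{`unite4tb_bdq`}{bedaquiline 400 mg daily for 2 weeks, then
#'     100 mg daily.}
#'   \item{`bpal`}{bedaquiline 200 mg daily for 8 weeks then 100 mg daily,
#'     with pretomanid 200 mg daily throughout.}
#'   \item{`cfz_100`}{clofazimine 100 mg daily.}
#'   \item{`cfz_loading`}{clofazimine 300 mg daily for 3 days, then 100 mg
#'     daily.}
#' }
#'
#' @param name one of the regimen names above.
#' @return a [regimen_spec()] object.
#' @examples
#' build_regimen("unite4tb_bdq")
#' @export
build_regimen <- function(name) {
  known <- c("unite4tb_bdq", "bpal", "cfz_100", "cfz_loading")
  if (length(name) != 1L || !name %in% known)
    stop("unknown regimen '", name, "'; choices: ",
         paste(known, collapse = ", "))
  switch(name,
    unite4tb_bdq = regimen_spec(
      bdq = data.frame(dose = c(400, 100), interval_h = 24,
                       weeks = c(2, Inf)),
      label = "UNITE4TB BDQ 400 mg x2wk -> 100 mg"),
    bpal = regimen_spec(
      bdq = data.frame(dose = c(200, 100), interval_h = 24,
                       weeks = c(8, Inf)),
      pa = data.frame(dose = 200, interval_h = 24, weeks = Inf),
      label = "BPaL (BDQ 200 mg x8wk -> 100 mg + Pa 200 mg)"),
    cfz_100 = regimen_spec(
      cfz = data.frame(dose = 100, interval_h = 24, weeks = Inf),
      label = "CFZ 100 mg daily"),
    cfz_loading = regimen_spec(
      cfz = data.frame(dose = c(300, 100), interval_h = 24,
                       weeks = c(3 / 7, Inf)),
      label = "CFZ 300 mg x3d -> 100 mg"))
}

#' @export
print.qtc_regimen <- function(x, ...) {
  cat("Regimen:", x$label, "\n")
  for (d in names(x$drugs)) {
    ph <- x$drugs[[d]]
    for (i in seq_len(nrow(ph)))
      cat(sprintf("  %-4s %4g mg q%gh for %s weeks\n", toupper(d),
                  ph$dose[i], ph$interval_h[i],
                  ifelse(is.finite(ph$weeks[i]), format(ph$weeks[i]),
                         "remaining")))
  }
  invisible(x)
}

# expand phases into dose times (h) and amounts up to the horizon
regimen_doses <- function(reg, drug, horizon_weeks) {
  ph <- reg$drugs[[drug]]
  if (is.null(ph)) return(list(times = numeric(), amt = numeric()))
  t0 <- 0
  times <- amt <- numeric()
  horizon_h <- horizon_weeks * 168
  for (i in seq_len(nrow(ph))) {
    t1 <- min(t0 + ph$weeks[i] * 168, horizon_h)
    if (t1 > t0) {
      # doses at t0, t0+tau, ... strictly before t1 (robust to FP fuzz)
      nd <- ceiling((t1 - t0) / ph$interval_h[i] - 1e-9)
      tt <- t0 + (seq_len(nd) - 1) * ph$interval_h[i]
      times <- c(times, tt)
      amt <- c(amt, rep(ph$dose[i], length(tt)))
    }
    t0 <- t1
    if (t0 >= horizon_h) break
  }
  list(times = times, amt = amt)
}

#' Reference simulated patient
#'
#' The typical simulation patient of the reference analysis: 56 kg total
#' body weight, 43 kg fat-free mass, baseline albumin 3.65 g/dL; age and
#' ancestry configurable to explore higher-exposure settings (older,
#' non-black patients accumulate more BDQM2 when the PK covariate factors
#' are enabled, see [pk_profile()]).
#'
#' @param age years.
#' @param ancestry `"black"` or `"non_black"`.
#' @param weight,ffm,albumin kg, kg, g/dL.
#' @return list of patient covariates.
#' @export
typical_patient <- function(age = 32, ancestry = c("black", "non_black"),
                            weight = 56, ffm = 43, albumin = 3.65) {
  ancestry <- match.arg(ancestry)
  list(age = age, ancestry = ancestry, weight = weight, ffm = ffm,
       albumin = albumin)
}

#' Monte-Carlo simulation of QTcF under a dosing regimen
#'
#' Simulates `n_reps` virtual patients under a dosing regimen over up to 28
#' weeks: per replicate, pharmacodynamic between-subject variability is
#' drawn (baseline, secular asymptote, the two EC50s — no residual error,
#' as appropriate for underlying-QTcF risk), PK variability is drawn (BSV
#' on clearances, inter-occasion variability on absorption, one occasion
#' per week), concentrations are evaluated weekly at a fixed post-dose
#' clock time (default 5 h after a 08:00 dose), and QTcF is predicted.
#'
#' Three trajectories are stored per replicate: absolute QTcF, the
#' drug-driven \eqn{\Delta}QTcF (the model's total drug-effect term), and
#' the total \eqn{\Delta}QTcF from the subject's own pre-treatment baseline
#' at the same clock time (drug effect + secular trend).
#'
#' @param regimen a [regimen_spec()] / [build_regimen()] object.
#' @param n_reps number of replicates.
#' @param params [qtc_params()].
#' @param pk [pk_profile()].
#' @param patient [typical_patient()].
#' @param horizon_weeks simulation horizon (capped at the regimen duration
#'   where finite; default 28).
#' @param seed integer seed.
#' @param clock_dose dosing clock time (h).
#' @param eval_offset_h evaluation time after the weekly reference dose (h).
#' @return object of class `qtc_regsim` with matrices `qtcf`, `delta_drug`,
#'   `delta_total` (`n_reps` x weeks), element `weeks`, and metadata.
#' @export
simulate_regimen <- function(regimen, n_reps = 1000,
                             params = qtc_params(), pk = pk_profile(),
                             patient = typical_patient(),
                             horizon_weeks = 28, seed = NULL,
                             clock_dose = 8, eval_offset_h = 5) {
  stopifnot(inherits(regimen, "qtc_regimen"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (horizon_weeks > 28)
    warning("horizon capped at 28 weeks")
  horizon_weeks <- min(horizon_weeks, 28)
  if (!is.null(seed)) set.seed(seed)
  weeks <- seq_len(horizon_weeks)
  # evaluation at eval_offset_h after the first dose of each week's last day
  teval <- (weeks * 7 - 1) * 24 + eval_offset_h
  tclock <- (clock_dose + eval_offset_h) %% 24
  circ <- circadian_factor(tclock, params)
  agedev <- patient$age - params$age_center
  secular <- secular_offset(teval, params)

  doses <- lapply(c(bdq = "bdq", pa = "pa", cfz = "cfz"), regimen_doses,
                  reg = regimen, horizon_weeks = horizon_weeks)
  occ <- lapply(doses, function(d) floor(d$times / 168) + 1L)  # weekly IOV
  # BDQM2 covariate factors on metabolite clearance
  clm_fac <- (if (patient$ancestry == "non_black")
    pk$bdq$cl_met_nonblack else 1) *
    exp(pk$bdq$cl_met_age_slope * (patient$age - 32))

  qtcf <- dd <- dt <- matrix(NA_real_, n_reps, length(weeks))
  for (r in seq_len(n_reps)) {
    eta <- draw_etas(1, params)
    cm2 <- cpa <- ccfz <- numeric(length(teval))
    if (length(doses$bdq$times)) {
      cl_m <- exp(rnorm(1, 0, pk$bdq$bsv_cl))
      ka_m <- exp(rnorm(max(occ$bdq), 0, pk$bdq$iov_ka))[occ$bdq]
      pkb <- pk$bdq
      pkb$cl_met <- pkb$cl_met * clm_fac
      cm2 <- conc_profile(doses$bdq$times, doses$bdq$amt, teval, pkb,
                          "metabolite", cl_m, ka_m)
    }
    if (length(doses$pa$times)) {
      cl_m <- exp(rnorm(1, 0, pk$pa$bsv_cl))
      ka_m <- exp(rnorm(max(occ$pa), 0, pk$pa$iov_ka))[occ$pa]
      cpa <- conc_profile(doses$pa$times, doses$pa$amt, teval, pk$pa,
                          "parent", cl_m, ka_m)
    }
    if (length(doses$cfz$times)) {
      cl_m <- exp(rnorm(1, 0, pk$cfz$bsv_cl))
      ka_m <- exp(rnorm(max(occ$cfz), 0, pk$cfz$iov_ka))[occ$cfz]
      ccfz <- conc_profile(doses$cfz$times, doses$cfz$amt, teval, pk$cfz,
                           "parent", cl_m, ka_m)
    }
    pind <- params
    pind$ec50_cfz <- params$ec50_cfz * exp(eta[1, "ec50_cfz"])
    pind$ec50_m2 <- params$ec50_m2 * exp(eta[1, "ec50_m2"])
    de <- drug_effect(cm2, cpa, ccfz, pind)$total
    base_i <- (params$qtcf_base * exp(eta[1, "base"]) +
                 params$age_slope * agedev) * circ
    qtcf[r, ] <- base_i + secular * exp(eta[1, "ss"]) + de
    dd[r, ] <- de
    dt[r, ] <- qtcf[r, ] - base_i
  }
  structure(list(qtcf = qtcf, delta_drug = dd, delta_total = dt,
                 weeks = weeks, regimen = regimen$label, n_reps = n_reps,
                 patient = patient, seed = seed),
            class = "qtc_regsim")
}

#' ICH E14 threshold specification
#'
#' @param absolute absolute QTcF thresholds (ms); defaults 450/480/500.
#' @param delta change-from-baseline thresholds (ms); defaults 30/60.
#' @return list with sorted `absolute` and `delta` components.
#' @export
ich_thresholds <- function(absolute = c(450, 480, 500), delta = c(30, 60)) {
  list(absolute = sort(absolute), delta = sort(delta))
}

#' Exceedance summary against ICH E14 thresholds
#'
#' Percentage of simulation replicates exceeding each threshold at each
#' requested week, separately for absolute QTcF and for both
#' change-from-baseline definitions (drug-driven and total), with the
#' binomial Monte-Carlo standard error `100*sqrt(p(1-p)/n)`.
#'
#' @param sim a [simulate_regimen()] result, or a plain replicate x week
#'   matrix of trajectories (then summarised under `definition`).
#' @param thresholds an [ich_thresholds()] list (unsorted inputs are
#'   sorted).
#' @param weeks weeks to summarise (default all simulated); requesting a
#'   week beyond the horizon is an error.
#' @param definition definition label used when `sim` is a plain matrix.
#' @return data.frame `regimen`, `week`, `definition`, `threshold`,
#'   `percent`, `mc_se`, `n_reps`.
#' @examples
#' tr <- matrix(c(rep(40, 4), rep(10, 6)), ncol = 1)
#' ich_summary(tr, weeks = 1)   # 40% above 30 ms
#' @export
ich_summary <- function(sim, thresholds = ich_thresholds(), weeks = NULL,
                        definition = "delta_total") {
  thresholds <- ich_thresholds(thresholds$absolute, thresholds$delta)
  if (is.matrix(sim)) {
    sim <- structure(list(qtcf = NULL, delta_drug = NULL, delta_total = NULL,
                          weeks = seq_len(ncol(sim)), regimen = "custom",
                          n_reps = nrow(sim)),
                     class = "qtc_regsim") |>
      (\(s) { s[[definition]] <- sim; s })()
  }
  if (is.null(weeks)) weeks <- sim$weeks
  if (any(!weeks %in% sim$weeks))
    stop("requested week(s) beyond the simulated horizon: ",
         paste(setdiff(weeks, sim$weeks), collapse = ", "))
  defs <- list(qtcf_abs = list(mat = sim$qtcf, thr = thresholds$absolute),
               delta_drug = list(mat = sim$delta_drug,
                                 thr = thresholds$delta),
               delta_total = list(mat = sim$delta_total,
                                  thr = thresholds$delta))
  out <- list()
  for (dn in names(defs)) {
    m <- defs[[dn]]$mat
    if (is.null(m)) next
    for (th in defs[[dn]]$thr) for (w in weeks) {
      p <- mean(m[, match(w, sim$weeks)] > th)
      out[[length(out) + 1L]] <- data.frame(
        regimen = sim$regimen, week = w, definition = dn, threshold = th,
        percent = 100 * p,
        mc_se = 100 * sqrt(p * (1 - p) / sim$n_reps),
        n_reps = sim$n_reps)
    }
  }
  do.call(rbind, out)
}

#' Text summary of exceedance percentages
#'
#' Formats an [ich_summary()] data.frame as a compact per-definition table
#' (weeks as rows, thresholds as columns).
#'
#' @param x an [ich_summary()] data.frame.
#' @param ... unused.
#' @export
format_ich_table <- function(x, ...) {
  for (dn in unique(x$definition)) {
    d <- x[x$definition == dn, ]
    cat(sprintf("\n%s (%s, n=%d):\n", d$regimen[1], dn, d$n_reps[1]))
    thr <- sort(unique(d$threshold))
    cat(sprintf("%6s", "week"),
        sprintf(">%d ms", thr), "\n")
    for (w in sort(unique(d$week))) {
      row <- vapply(thr, function(th)
        d$percent[d$week == w & d$threshold == th][1], numeric(1))
      cat(sprintf("%6d", w), sprintf("%6.2f", row), "\n")
    }
  }
  invisible(x)
}
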