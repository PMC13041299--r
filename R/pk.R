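# Configurable pharmacokinetic stand-ins driving the synthetic trials and
# the regimen simulator: one-compartment first-order-absorption kinetics with
# dose superposition, plus a metabolite compartment for bedaquiline (whose QT
# effect is carried by the N-desmethyl metabolite BDQM2). These are
# deliberately simple, fully configurable profiles calibrated so typical
# concentrations land in the ranges where the QTc model's EC50s are
# informative; they are not published population-PK parameter sets.

#' Pharmacokinetic profile specification for the three drugs
#'
#' One-compartment oral-absorption parameters per drug. For bedaquiline the
#' QT-active species is the metabolite BDQM2, produced with fraction `fm` of
#' parent clearance and eliminated with clearance `cl_met` from volume
#' `v_met`; its long half-life drives slow accumulation. Clofazimine defaults
#' give pronounced accumulation (10-day half-life stand-in); pretomanid
#' defaults reach steady state within a few days and keep typical
#' concentrations in the low-mg/L range where its concentration-QTc
#' relationship is locally linear.
#'
#' Between-subject variability is log-normal on clearance (`bsv_cl`, SD of
#' log) and inter-occasion variability log-normal on the absorption rate
#' (`iov_ka`), one occasion per dosing day. `cl_met_nonblack` and
#' `cl_met_age_slope` (bedaquiline only) are optional covariate multipliers
#' on metabolite clearance — `cl_met * cl_met_nonblack^I(non-black) *
#' exp(cl_met_age_slope * (age - 32))` — default off (1 and 0), mirroring
#' reports of higher BDQM2 exposure in older, non-black patients.
#'
#' @param bdq,pa,cfz named lists overriding individual defaults, e.g.
#'   `bdq = list(fm = 0.3)`.
#' @return object of class `qtc_pk`: per-drug parameter lists with fields
#'   `ka` (1/h), `cl` (L/h), `v` (L), `bsv_cl`, `iov_ka` and, for `bdq`,
#'   `fm`, `cl_met`, `v_met`, `cl_met_nonblack`, `cl_met_age_slope`.
#' @examples
#' pk <- pk_profile(cfz = list(cl = 5))
#' pk$cfz$cl
#' @export
pk_profile <- function(bdq = list(), pa = list(), cfz = list()) {
  def <- list(
    bdq = list(ka = 0.6, cl = 3.0, v = 200, fm = 0.25,
               cl_met = 2.0, v_met = 1500, bsv_cl = 0.3, iov_ka = 0.3,
               cl_met_nonblack = 1.0, cl_met_age_slope = 0.0),
    pa = list(ka = 0.8, cl = 3.8, v = 105, bsv_cl = 0.3, iov_ka = 0.3),
    cfz = list(ka = 0.3, cl = 6.0, v = 2080, bsv_cl = 0.3, iov_ka = 0.3))
  chk <- function(d, o, drug) {
    bad <- setdiff(names(o), names(d))
    if (length(bad))
      stop("unknown ", drug, " PK field(s): ", paste(bad, collapse = ", "))
    d <- modifyList(d, o)
    pos <- setdiff(names(d), c("bsv_cl", "iov_ka", "cl_met_age_slope"))
    if (any(unlist(d[pos]) <= 0))
      stop(drug, ": PK rates, volumes and fractions must be > 0")
    d
  }
  structure(list(bdq = chk(def$bdq, bdq, "bdq"),
                 pa = chk(def$pa, pa, "pa"),
                 cfz = chk(def$cfz, cfz, "cfz")),
            class = "qtc_pk")
}

# exp(-k * dt) for dt >= 0, 0 otherwise; dt may be a matrix
.edecay <- function(k, dt) ifelse(dt >= 0, exp(-k * pmax(dt, 0)), 0)

#' Concentration-time profile under a dosing history
#'
#' Analytic superposition of one-compartment first-order-absorption doses.
#' For `what = "parent"`:
#' `C(t) = sum_d (D_d/V) ka/(ka-ke) (e^{-ke dt} - e^{-ka dt})`, `dt = t - t_d`.
#' For `what = "metabolite"` the first-order metabolite compartment
#' (formation fraction `fm`, elimination `km = cl_met/v_met`) is solved in
#' closed form (a three-exponential Bateman term per dose). Closed-form
#' evaluation makes the series exactly invariant to how the time grid is
#' split.
#'
#' @param dose_times dosing times (hours).
#' @param dose_amt dose amounts (mg), recycled to `length(dose_times)`.
#' @param times evaluation times (hours).
#' @param pk a single-drug parameter list from [pk_profile()].
#' @param what `"parent"` or `"metabolite"` (bedaquiline only).
#' @param cl_mult,ka_mult multiplicative individual factors: scalar on
#'   clearance(s), and per-dose vector on `ka` (inter-occasion variability).
#' @return concentrations (mg/L) at `times`.
#' @examples
#' pk <- pk_profile()$pa
#' conc_profile(seq(0, 24 * 13, by = 24), 200, c(0, 5, 100, 300), pk)
#' @export
conc_profile <- function(dose_times, dose_amt, times, pk,
                         what = c("parent", "metabolite"),
                         cl_mult = 1, ka_mult = 1) {
  what <- match.arg(what)
  if (length(dose_times) == 0L) return(numeric(length(times)))
  if (any(diff(dose_times) < 0)) stop("invalid regimen: dose times must be non-decreasing")
  if (any(times < 0)) stop("evaluation times must be >= 0")
  amt <- rep_len(dose_amt, length(dose_times))
  if (any(amt < 0)) stop("doses must be >= 0")
  kam <- rep_len(ka_mult, length(dose_times))
  ke <- pk$cl * cl_mult / pk$v
  out <- numeric(length(times))
  if (what == "parent") {
    for (d in seq_along(dose_times)) {
      if (amt[d] == 0) next
      ka <- pk$ka * kam[d]
      if (abs(ka - ke) < 1e-10) ka <- ke * (1 + 1e-8)  # degenerate-rate guard
      dt <- times - dose_times[d]
      out <- out + (amt[d] / pk$v) * ka / (ka - ke) *
        (.edecay(ke, dt) - .edecay(ka, dt))
    }
  } else {
    if (is.null(pk$fm)) stop("this drug has no metabolite compartment")
    km <- pk$cl_met * cl_mult / pk$v_met
    for (d in seq_along(dose_times)) {
      if (amt[d] == 0) next
      ka <- pk$ka * kam[d]
      if (abs(ka - ke) < 1e-10) ka <- ke * (1 + 1e-8)
      if (abs(km - ke) < 1e-12) km <- ke * (1 + 1e-8)
      if (abs(km - ka) < 1e-12) km <- km * (1 + 1e-8)
      dt <- times - dose_times[d]
      pre <- pk$fm * ke * amt[d] * ka / ((ka - ke) * pk$v_met)
      out <- out + pre *
        ((.edecay(ke, dt) - .edecay(km, dt)) / (km - ke) -
         (.edecay(ka, dt) - .edecay(km, dt)) / (km - ka))
    }
  }
  pmax(out, 0)
}

# Dosing history (times, amounts) for one drug of the 14-day EBA study:
# BDQ 400/300/200... mg, CFZ 300 x3 then 100 mg, Pa 200 mg, daily at
# `clock_dose` for `n_days` days.
eba_doses <- function(drug, n_days = 14) {
  day <- (seq_len(n_days) - 1) * 24
  switch(drug,
         bdq = list(times = day, amt = c(400, 300, rep(200, n_days - 2))),
         cfz = list(times = day, amt = c(rep(300, 3), rep(100, n_days - 3))),
         pa = list(times = day, amt = rep(200, n_days)),
         stop("unknown drug: ", drug))
}
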