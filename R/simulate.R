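# Virtual-trial generator: covariate sampling calibrated to the study
# demographics, the EBA ECG/PK sampling schedule, and QTcF observations with
# between-subject variability and replicate-level residual noise.

#' Sample virtual subject covariates
#'
#' Draws baseline covariates from distributions calibrated to the study
#' cohort: age log-normal (median ~30 y, IQR ~23-40), 62% male, weight
#' log-normal (median ~53.8 kg, IQR ~47-60), fat-free mass derived from
#' weight and sex, electrolytes (K, Ca, Na) normal around reference values,
#' albumin around 3.65 g/dL, and ancestry black/non-black.
#'
#' @param n number of subjects (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @param p_male,p_black sampling fractions.
#' @return data.frame with one row per subject: `ID`, `AGE_Y`, `SEX`
#'   ("M"/"F"), `WT_KG`, `FFM_KG`, `K_MMOL`, `CA_MMOL`, `NA_MMOL`,
#'   `ALB_GDL`, `ANCESTRY` ("black"/"non_black").
#' @examples
#' head(sim_subjects(5, seed = 1))
#' @export
sim_subjects <- function(n, seed = NULL, p_male = 0.62, p_black = 0.8) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  age <- pmin(pmax(rlnorm(n, log(30), 0.41), 18), 80)
  sex <- ifelse(runif(n) < p_male, "M", "F")
  wt <- pmin(pmax(rlnorm(n, log(53.8), 0.19), 35), 95)
  ffm_frac <- ifelse(sex == "M", 0.80, 0.67) * exp(rnorm(n, 0, 0.06))
  ffm <- pmin(wt * pmin(ffm_frac, 0.95), wt - 1)
  data.frame(
    ID = seq_len(n),
    AGE_Y = age, SEX = sex, WT_KG = wt, FFM_KG = ffm,
    K_MMOL = rnorm(n, 4.2, 0.35),
    CA_MMOL = rnorm(n, 2.35, 0.10),
    NA_MMOL = rnorm(n, 139, 2.5),
    ALB_GDL = rnorm(n, 3.65, 0.35),
    ANCESTRY = ifelse(runif(n) < p_black, "black", "non_black"),
    stringsAsFactors = FALSE)
}

#' EBA trial design
#'
#' The ECG/PK sampling layout of the 14-day early-bactericidal-activity
#' study: triplicate 12-lead ECGs at pre-dose, 5 h and 10 h post-dose on the
#' day before treatment and on days 1, 2, 3, 8, 14 and 28, PK samples matched
#' to the first ECG of each triplicate, morning dosing (08:00 by convention;
#' the source study does not state a clock time). Default arms place 105
#' subjects in seven groups of 15 covering each QT-active drug alone or in
#' combination plus two control arms without QT-prolonging drugs.
#'
#' @param n_subjects total subjects, allocated to `arms` proportionally.
#' @param arms named list: arm label -> character vector of drugs among
#'   `"bdq"`, `"pa"`, `"cfz"` (empty = control).
#' @param ecg_days ECG days (day 1 = first dosing day); a pre-treatment day
#'   is always added.
#' @param ecg_times ECG times (hours post-dose).
#' @param triplicate logical; average triplicate ECGs per timepoint.
#' @param clock_dose dosing clock time (hours).
#' @param treat_days dosing duration (days).
#' @return object of class `qtc_design`.
#' @examples
#' eba_design(n_subjects = 21)
#' @export
eba_design <- function(n_subjects = 105,
                       arms = list(PZA = character(), HRZE = character(),
                                   CFZ = "cfz", BDQ_CFZ = c("bdq", "cfz"),
                                   PA_CFZ = c("pa", "cfz"),
                                   BDQ_PA = c("bdq", "pa"),
                                   BDQ_PA_CFZ = c("bdq", "pa", "cfz")),
                       ecg_days = c(1, 2, 3, 8, 14, 28),
                       ecg_times = c(0, 5, 10),
                       triplicate = TRUE,
                       clock_dose = 8,
                       treat_days = 14) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (length(arms) == 0L) stop("at least one arm required")
  if (any(ecg_times < 0 | ecg_times >= 24))
    stop("ecg_times must lie within the dosing interval [0, 24)")
  n_arm <- diff(round(seq(0, n_subjects, length.out = length(arms) + 1)))
  structure(list(n_subjects = as.integer(n_subjects), arms = arms,
                 n_per_arm = setNames(n_arm, names(arms)),
                 ecg_days = ecg_days, ecg_times = ecg_times,
                 triplicate = isTRUE(triplicate), clock_dose = clock_dose,
                 treat_days = treat_days),
            class = "qtc_design")
}

#' @export
print.qtc_design <- function(x, ...) {
  cat("EBA-style trial design:", x$n_subjects, "subjects,",
      length(x$arms), "arms\n")
  for (a in names(x$arms))
    cat(sprintf("  %-12s n=%-3d %s\n", a, x$n_per_arm[[a]],
                if (length(x$arms[[a]])) paste(toupper(x$arms[[a]]),
                                               collapse = "+") else "(control)"))
  cat("  ECG days:", paste(x$ecg_days, collapse = ", "),
      "(+ pre-treatment day) at", paste(x$ecg_times, collapse = "/"),
      "h post-dose;", if (x$triplicate) "triplicate ECGs averaged" else
        "single ECGs", "\n")
  invisible(x)
}

# Draw the individual random-effect matrix (n x 5) from the omegas.
draw_etas <- function(n, params) {
  om <- c(params$omega_base, params$omega_ss, params$omega_ec50_cfz,
          params$omega_ec50_m2, params$omega_eps)
  eta <- matrix(rnorm(n * 5), n, 5) * rep(om, each = n)
  dimnames(eta) <- list(seq_len(n), QTC_ETA_NAMES)
  eta
}

#' Simulate a virtual concentration-QTc trial
#'
#' Generates a complete analysis-ready dataset under the study design: per
#' subject, covariates are sampled, random effects drawn (log-normal, per the
#' omega block of `params`), drug concentrations simulated from the PK
#' stand-ins (BSV on clearance, inter-occasion variability on absorption),
#' QTcF computed from the structural model, and additive residual error
#' applied to each ECG replicate before triplicate averaging. Pre-treatment
#' records carry zero concentrations and zero secular offset.
#'
#' When `qt_exponent` is non-`NULL`, raw QT and RR columns are also emitted
#' with `QT = QTcF * RR^qt_exponent` (RR log-normal around the cohort's
#' ~89 bpm heart rate), so that heart-rate-correction workflows can be
#' exercised end to end.
#'
#' @param design a [eba_design()] object.
#' @param params true population parameters ([qtc_params()]).
#' @param pk PK stand-ins ([pk_profile()]).
#' @param seed integer seed; the dataset is reproducible given
#'   (design, params, pk, seed).
#' @param qt_exponent optional true heart-rate-correction exponent used to
#'   de-correct QTcF into raw QT/RR columns.
#' @return a data.frame of class `qtc_trial` in the long dataset dialect
#'   (see [read_qtc_dataset()]), one row per averaged ECG timepoint, with
#'   attributes `design`, `params`, `pk`, `seed`, `etas` (true random
#'   effects).
#' @examples
#' d <- sim_trial(eba_design(n_subjects = 14), seed = 1)
#' nrow(d)   # 14 subjects x 7 days x 3 timepoints
#' @export
sim_trial <- function(design = eba_design(), params = qtc_params(),
                      pk = pk_profile(), seed = NULL, qt_exponent = NULL) {
  if (!inherits(design, "qtc_design")) stop("design must be a qtc_design")
  validate_qtc_params(params)
  if (!is.null(seed)) set.seed(seed)
  subs <- sim_subjects(design$n_subjects)
  subs$ARM <- rep(names(design$arms), design$n_per_arm)
  eta <- draw_etas(nrow(subs), params)
  rownames(eta) <- subs$ID

  # nominal schedule: pre-treatment day (day 0) + ECG days, relative to the
  # first dose at clock_dose on day 1
  days <- c(0, design$ecg_days)
  sched <- expand.grid(tp = design$ecg_times, day = days)
  t_treat <- (sched$day - 1) * 24 + sched$tp      # hours since first dose
  t_clock <- (design$clock_dose + sched$tp) %% 24
  nrep <- if (design$triplicate) 3L else 1L

  rows <- vector("list", nrow(subs))
  for (i in seq_len(nrow(subs))) {
    drugs <- design$arms[[subs$ARM[i]]]
    conc <- matrix(0, nrow(sched), 3,
                   dimnames = list(NULL, c("CM2_MGL", "CPA_MGL", "CCFZ_MGL")))
    pos <- t_treat > 0
    if (any(pos)) {
      if ("bdq" %in% drugs) {
        dd <- eba_doses("bdq", design$treat_days)
        cl_m <- exp(rnorm(1, 0, pk$bdq$bsv_cl))
        ka_m <- exp(rnorm(length(dd$times), 0, pk$bdq$iov_ka))
        conc[pos, "CM2_MGL"] <- conc_profile(dd$times, dd$amt, t_treat[pos],
                                             pk$bdq, "metabolite", cl_m, ka_m)
      }
      if ("pa" %in% drugs) {
        dd <- eba_doses("pa", design$treat_days)
        cl_m <- exp(rnorm(1, 0, pk$pa$bsv_cl))
        ka_m <- exp(rnorm(length(dd$times), 0, pk$pa$iov_ka))
        conc[pos, "CPA_MGL"] <- conc_profile(dd$times, dd$amt, t_treat[pos],
                                             pk$pa, "parent", cl_m, ka_m)
      }
      if ("cfz" %in% drugs) {
        dd <- eba_doses("cfz", design$treat_days)
        cl_m <- exp(rnorm(1, 0, pk$cfz$bsv_cl))
        ka_m <- exp(rnorm(length(dd$times), 0, pk$cfz$iov_ka))
        conc[pos, "CCFZ_MGL"] <- conc_profile(dd$times, dd$amt, t_treat[pos],
                                              pk$cfz, "parent", cl_m, ka_m)
      }
    }
    rec <- data.frame(ID = subs$ID[i], TIME_H = t_treat, CLOCK_H = t_clock,
                      conc, AGE_Y = subs$AGE_Y[i], stringsAsFactors = FALSE)
    pred <- predict_qtcf(rec, params, eta)
    # residual per ECG replicate, then average the triplicate
    sd_i <- params$sigma_add * exp(eta[i, "eps"])
    eps <- rowMeans(matrix(rnorm(nrow(rec) * nrep, 0, sd_i), ncol = nrep))
    rec$QTCF_MS <- pred + eps
    rec$NREP <- nrep
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  out <- merge(out, subs[, c("ID", "SEX", "WT_KG", "FFM_KG", "K_MMOL",
                             "CA_MMOL", "NA_MMOL", "ALB_GDL", "ANCESTRY",
                             "ARM")],
               by = "ID", sort = FALSE)
  out <- out[order(out$ID, out$TIME_H), ]
  if (!is.null(qt_exponent)) {
    rr <- rlnorm(nrow(out), log(60 / 89), 0.12)
    out$RR_S <- rr
    out$QT_MS <- out$QTCF_MS * rr^qt_exponent
  }
  rownames(out) <- NULL
  structure(out, design = design, params = params, pk = pk, seed = seed,
            etas = eta, class = c("qtc_trial", "data.frame"))
}
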