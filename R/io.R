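# Dataset and report I/O. The long CSV dialect has one row per (averaged)
# ECG timepoint: ID, TIME_H, CLOCK_H, QTCF_MS (or QT_MS + RR_S), CM2_MGL,
# CPA_MGL, CCFZ_MGL, NREP, covariate columns and ARM. Missing numeric values
# are empty cells. A leading '#'-comment records provenance (seed, record
# count).

QTC_DATASET_COLS <- c("ID", "TIME_H", "CLOCK_H", "QT_MS", "RR_S", "QTCF_MS",
                      "CM2_MGL", "CPA_MGL", "CCFZ_MGL", "NREP", "AGE_Y",
                      "SEX", "WT_KG", "FFM_KG", "K_MMOL", "CA_MMOL",
                      "NA_MMOL", "ALB_GDL", "ANCESTRY", "ARM")

#' Write a trial dataset to CSV
#'
#' @param data a trial dataset (e.g. from [sim_trial()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qtc_dataset <- function(data, path) {
  seed <- attr(data, "seed")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# qtcompete dataset: %d records, %d subjects%s",
                     nrow(data), length(unique(data$ID)),
                     if (!is.null(seed)) sprintf(", seed=%d", seed) else ""),
             con)
  cols <- intersect(QTC_DATASET_COLS, names(data))
  write.csv(as.data.frame(data)[, cols], con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial dataset from CSV
#'
#' Reads and validates the long dataset dialect. Either pre-corrected
#' `QTCF_MS` or raw `QT_MS` + `RR_S` must be present (the raw branch is
#' Fridericia-corrected at fit time). Validation errors name the offending
#' rows.
#'
#' @param path CSV file (leading `#` comment lines are ignored).
#' @return a `qtc_trial` data.frame.
#' @export
read_qtc_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("ID", "TIME_H", "CLOCK_H", "CM2_MGL", "CPA_MGL", "CCFZ_MGL")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$QTCF_MS) && (is.null(d$QT_MS) || is.null(d$RR_S)))
    stop("dataset needs QTCF_MS or both QT_MS and RR_S")
  for (cc in c("CM2_MGL", "CPA_MGL", "CCFZ_MGL")) {
    bad <- which(!is.na(d[[cc]]) & d[[cc]] < 0)
    if (length(bad))
      stop("negative concentration in column ", cc, " at row(s) ",
           paste(head(bad, 5), collapse = ", "))
  }
  dup <- duplicated(d[, c("ID", "TIME_H")])
  if (any(dup))
    stop("duplicate (ID, TIME_H) at row(s) ",
         paste(head(which(dup), 5), collapse = ", "))
  if (any(d$CLOCK_H < 0 | d$CLOCK_H >= 24))
    stop("CLOCK_H must lie in [0, 24)")
  d <- d[order(d$ID, d$TIME_H), ]
  rownames(d) <- NULL
  class(d) <- c("qtc_trial", "data.frame")
  d
}

#' Write a fit report as JSON
#'
#' Structured report of a fitted model: estimates (natural scale), standard
#' errors, 95% CIs, objective, convergence and dimensions — the parameter
#' table in machine-readable form.
#'
#' @param fit a [qtcfit()] object.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  s <- summary(fit)$table
  jsonlite::write_json(list(
    model = list(mode = fit$mode, n_subjects = fit$n_subjects,
                 n_obs = fit$n_obs, objective = fit$objective,
                 convergence = fit$convergence,
                 free_parameters = fit$free),
    parameters = s), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a run configuration file
#'
#' One human-editable YAML file per run, combining any of the sections
#' `seed`, `design` (arguments of [eba_design()]), `params`
#' ([qtc_params()]), `pk` ([pk_profile()]), `priors` ([qtc_priors()]),
#' `regimen` (a [build_regimen()] name or [regimen_spec()] drug phases),
#' `fit` (extra [qtcfit()] arguments) and `simulate`
#' ([simulate_regimen()] arguments). Unknown keys are an error naming the
#' key.
#'
#' @param path YAML file.
#' @return named list of parsed sections with constructed objects.
#' @export
read_qtc_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "design", "params", "pk", "priors", "regimen", "fit",
             "simulate")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  out <- list(seed = cfg$seed)
  out$design <- if (!is.null(cfg$design)) do.call(eba_design, cfg$design)
    else eba_design()
  out$params <- if (!is.null(cfg$params)) do.call(qtc_params, cfg$params)
    else qtc_params()
  out$pk <- if (!is.null(cfg$pk)) do.call(pk_profile, cfg$pk)
    else pk_profile()
  out$priors <- if (!is.null(cfg$priors)) do.call(qtc_priors, cfg$priors)
    else qtc_priors()
  if (!is.null(cfg$regimen)) {
    out$regimen <- if (is.character(cfg$regimen)) build_regimen(cfg$regimen)
      else do.call(regimen_spec, cfg$regimen)
  }
  out$fit <- cfg$fit
  out$simulate <- cfg$simulate
  out
}
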