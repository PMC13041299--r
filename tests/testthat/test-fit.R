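# Estimation: self-consistency, sequential (masked) fits, likelihood-ratio
# tests, the pretomanid prior constructor, and covariate stepwise selection.

test_that("fixed-effect fit recovers truth from near-noise-free data", {
  # no random effects, tiny residual: the optimum must sit at the truth
  p <- qtc_params(amp = c(0, 0, 0), age_slope = 0, qtc_ss = 6.33,
                  omega_base = 0, omega_ss = 0, omega_ec50_cfz = 0,
                  omega_ec50_m2 = 0, omega_eps = 0, sigma_add = 0.5)
  d <- sim_trial(eba_design(n_subjects = 21), params = p, seed = 41)
  f <- qtcfit(d, start = p, priors = NULL,
              fix = c("circadian", "omegas", "ec50_pa"),
              random = character(), covariates = numeric(),
              control = fast_control())
  expect_equal(f$convergence, 0)
  expect_equal(unname(f$natural["qtcf_base"]), 393, tolerance = 1e-3)
  expect_equal(unname(f$natural["emax"]), p$emax, tolerance = 0.02)
  expect_equal(unname(f$natural["ec50_m2"]), p$ec50_m2, tolerance = 0.05)
  expect_equal(unname(f$natural["qtc_ss"]), p$qtc_ss, tolerance = 0.02)
  expect_equal(unname(f$natural["sigma_add"]), p$sigma_add,
               tolerance = 0.05)
})

test_that("sequential strategy: clofazimine EC50 from its monotherapy arm", {
  p <- qtc_params(amp = c(0, 0, 0), age_slope = 0)
  des <- eba_design(n_subjects = 30, arms = list(CFZ = "cfz"))
  d <- sim_trial(des, params = p, seed = 42)
  f <- qtcfit(d, start = p, priors = NULL,
              fix = c("qtcf_base", "emax", "sigma_add", "omega_base",
                      "omega_eps", "omega_ec50_cfz", "secular",
                      "circadian"),
              random = c("base", "ec50_cfz", "eps"),
              covariates = numeric(), control = fast_control())
  # only ec50_cfz (and the auto-kept omegas already fixed) was free
  expect_true("ec50_cfz" %in% f$free)
  expect_false("emax" %in% f$free)
  expect_equal(unname(f$natural["ec50_cfz"]), p$ec50_cfz, tolerance = 0.35)
})

test_that("structurally absent parameters are fixed automatically", {
  p <- flat_params()
  d <- sim_trial(control_design(n = 8, days = c(1, 3)), params = p,
                 seed = 43)
  f <- qtcfit(d, start = p, priors = NULL, fix = "circadian",
              random = c("base", "eps"), covariates = numeric(),
              control = fast_control())
  # no drug on board anywhere: all drug-effect parameters fixed
  expect_true(all(c("emax", "ec50_m2", "ec50_cfz", "ec50_pa") %in% f$fix))
  expect_false("emax" %in% f$free)
  expect_true(all(c("qtcf_base", "sigma_add") %in% f$free))
})

test_that("likelihood-ratio test compares nested fits correctly", {
  p <- flat_params()   # truth includes the secular trend
  d <- sim_trial(control_design(n = 30), params = p, seed = 44)
  full <- qtcfit(d, start = p, priors = NULL, fix = "circadian",
                 random = c("base", "eps"), covariates = numeric(),
                 control = fast_control())
  p0 <- qtc_params(amp = c(0, 0, 0), age_slope = 0, qtc_ss = 0)
  red <- qtcfit(d, start = p0, priors = NULL,
                fix = c("circadian", "secular"),
                random = c("base", "eps"), covariates = numeric(),
                control = fast_control())
  r <- lrt(full, red)
  expect_equal(r$df, 2)
  expect_equal(r$dofv, red$objective - full$objective)
  # a 6.33 ms secular trend in 30 subjects is clearly detectable
  expect_lt(r$p_value, 0.01)
  # chi-square reference: the canonical 3.84 / 1 df boundary
  fake <- function(ofv, free) structure(
    list(objective = ofv, df = length(free), free = free), class = "qtcfit")
  r2 <- lrt(fake(100, c("a", "b")), fake(103.84, "a"))
  expect_equal(r2$p_value, 0.05, tolerance = 1e-3)
  # worse full fit: p = 1
  expect_equal(lrt(fake(104, c("a", "b")), fake(100, "a"))$p_value, 1)
  # non-nested comparison is refused
  expect_error(lrt(fake(100, c("a", "b")), fake(101, "c")), "not nested")
  # anova interface mirrors lrt
  tab <- anova(red, full)
  expect_equal(tab$p[2], r$p_value)
})

test_that("pretomanid EC50 prior construction matches its linear origin", {
  # linear limit: for concentrations far below EC50 the matched EC50 is
  # emax/slope
  grid <- seq(0.1, 1, by = 0.1)
  expect_equal(pa_prior_from_linear(44.5 / 80, 44.5, grid), 80,
               tolerance = 0.02)
  # reference construction: slope 1.57 ms/(mg/L), shared Emax 44.2 ms over
  # the observed low-mg/L pretomanid range gives an EC50 in the low tens
  ec50 <- pa_prior_from_linear(1.57, 44.2, seq(0.5, 6, by = 0.25))
  expect_gt(ec50, 10); expect_lt(ec50, 60)
  # monotone in emax at fixed slope
  es <- vapply(c(30, 40, 50, 60), pa_prior_from_linear, numeric(1),
               slope = 1.57, conc_grid = seq(0.5, 6, by = 0.5))
  expect_true(all(diff(es) > 0))
  expect_error(pa_prior_from_linear(10, 44.2, seq(1, 10, 1)),
               "reaches Emax")
  expect_error(pa_prior_from_linear(-1, 44.2, 1:5), "slope")
})

test_that("stepwise selection recovers a true age effect on baseline", {
  p <- qtc_params(amp = c(0, 0, 0))   # age slope 0.472 ms/yr in truth
  d <- sim_trial(control_design(n = 110, days = c(1, 3)), params = p,
                 seed = 46)
  out <- step_covariates(d, c("AGE_Y", "SEX", "WT_KG"),
                         start = qtc_params(amp = c(0, 0, 0), age_slope = 0),
                         priors = NULL, fix = c("circadian", "secular"),
                         random = c("base", "eps"),
                         control = fast_control())
  expect_true("AGE_Y" %in% out$selected)
  expect_false("SEX" %in% out$selected)
  expect_true(all(c("phase", "covariate", "dofv", "p", "decision") %in%
                    names(out$trace)))
  # trace records a forward inclusion for age
  tr <- out$trace
  expect_true(any(tr$phase == "forward" & tr$covariate == "AGE_Y" &
                    tr$decision == "included"))
})

test_that("stepwise selection stays empty under the null and flags collinearity", {
  p <- qtc_params(amp = c(0, 0, 0), age_slope = 0)   # no covariate effects
  d <- sim_trial(control_design(n = 40, days = 1), params = p, seed = 47)
  out <- suppressWarnings(step_covariates(
    d, c("WT_KG", "FFM_KG"),
    start = p, priors = NULL, fix = c("circadian", "secular"),
    random = "base", control = fast_control()))
  expect_length(out$selected, 0)
  # an exact duplicate candidate triggers the collinearity warning
  d$WT2_KG <- d$WT_KG
  expect_warning(
    step_covariates(d, c("WT_KG", "WT2_KG"), start = p, priors = NULL,
                    fix = c("circadian", "secular"), random = "base",
                    control = fast_control()),
    "collinear")
})

test_that("fit report and summary expose the parameter table", {
  p <- flat_params()
  d <- sim_trial(control_design(n = 10, days = 1), params = p, seed = 48)
  f <- qtcfit(d, start = p, priors = NULL, fix = "circadian",
              random = "base", covariates = numeric(),
              control = qtcfit_control(se = TRUE, restarts = 1))
  s <- summary(f)
  expect_s3_class(s, "summary.qtcfit")
  expect_true(all(c("parameter", "estimate", "se", "lo", "hi") %in%
                    names(s$table)))
  # BSV rows are reported as %CV
  est <- s$table$estimate[s$table$parameter == "omega_base"]
  expect_equal(est, 100 * f$natural[["omega_base"]])
  tmp <- tempfile(fileext = ".json")
  write_fit_report(f, tmp)
  rep <- jsonlite::read_json(tmp)
  expect_equal(rep$model$n_subjects, 10)
  expect_true(length(rep$parameters) >= 10)
  unlink(tmp)
})
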