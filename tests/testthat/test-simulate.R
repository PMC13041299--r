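# Virtual-trial generator: covariate distributions, schedule arithmetic,
# noise structure and reproducibility.

test_that("subject covariates match the cohort's distributions", {
  s <- sim_subjects(10000, seed = 101)
  expect_equal(nrow(s), 10000)
  expect_true(median(s$AGE_Y) >= 28 && median(s$AGE_Y) <= 32)
  m <- mean(s$SEX == "M")
  expect_true(m >= 0.58 && m <= 0.66)
  expect_equal(median(s$WT_KG), 53.8, tolerance = 0.05)
  expect_error(sim_subjects(0), ">= 1")
})

test_that("covariate draws respect their bounds for every seed", {
  for (s in 1:5) {
    d <- sim_subjects(400, seed = s)
    expect_true(all(d$AGE_Y >= 18 & d$AGE_Y <= 90))
    expect_true(all(d$WT_KG > 0))
    expect_true(all(d$FFM_KG < d$WT_KG))
    expect_true(all(d$FFM_KG > 0))
  }
})

test_that("trial schedule arithmetic matches the EBA design", {
  d <- sim_trial(eba_design(n_subjects = 14), seed = 3)
  # 6 on-treatment ECG days + the pre-treatment day, 3 timepoints each
  expect_equal(nrow(d), 14 * 7 * 3)
  expect_equal(sort(unique(d$CLOCK_H)), c(8, 13, 18))
  # pre-treatment rows: negative treatment time, zero concentrations
  pre <- d[d$TIME_H <= 0, ]
  expect_true(all(pre$CM2_MGL == 0 & pre$CPA_MGL == 0 & pre$CCFZ_MGL == 0))
  # full default design gives the ~2,000-record magnitude of the study
  d2 <- sim_trial(seed = 5)
  expect_equal(nrow(d2), 105 * 7 * 3)
  expect_equal(length(unique(d2$ID)), 105)
  # arm assignment controls which drugs are on board
  on <- d2[d2$TIME_H > 0, ]
  expect_true(all(on$CM2_MGL[!grepl("BDQ", on$ARM)] == 0))
  expect_true(all(tapply(on$CCFZ_MGL, on$ID, max)[
    tapply(grepl("CFZ", on$ARM), on$ID, any)] > 0))
})

test_that("the noise-free limit reproduces the structural model exactly", {
  p <- qtc_params(omega_base = 0, omega_ss = 0, omega_ec50_cfz = 0,
                  omega_ec50_m2 = 0, omega_eps = 0, sigma_add = 1e-9)
  d <- sim_trial(eba_design(n_subjects = 7), params = p, seed = 9)
  expect_equal(d$QTCF_MS, predict_qtcf(d, p), tolerance = 1e-6)
})

test_that("identical seeds give identical datasets", {
  a <- sim_trial(eba_design(n_subjects = 10), seed = 77)
  b <- sim_trial(eba_design(n_subjects = 10), seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- sim_trial(eba_design(n_subjects = 10), seed = 78)
  expect_false(identical(a$QTCF_MS, c$QTCF_MS))
})

test_that("baseline variability decomposes into BSV and averaged noise", {
  # with the circadian/age terms silenced and no eta-on-epsilon, the
  # pre-treatment SD is sqrt((base*omega)^2 + sigma^2/3): triplicate
  # averaging divides residual variance by 3
  p <- qtc_params(amp = c(0, 0, 0), age_slope = 0, omega_eps = 0)
  d <- sim_trial(control_design(n = 2000, days = 1), params = p, seed = 13)
  pre <- d[d$TIME_H <= 0, ]
  want <- sqrt((p$qtcf_base * p$omega_base)^2 + p$sigma_add^2 / 3)
  expect_equal(sd(pre$QTCF_MS), want, tolerance = 0.04)
  # and without averaging the full replicate-level residual SD remains
  d1 <- sim_trial(eba_design(n_subjects = 400,
                             arms = list(CTL = character()),
                             ecg_days = 1, triplicate = FALSE),
                  params = p, seed = 14)
  pre1 <- d1[d1$TIME_H <= 0, ]
  expect_equal(sd(pre1$QTCF_MS),
               sqrt((p$qtcf_base * p$omega_base)^2 + p$sigma_add^2),
               tolerance = 0.05)
})

test_that("raw QT/RR emission is consistent with the correction model", {
  d <- sim_trial(eba_design(n_subjects = 60), seed = 21, qt_exponent = 0.41)
  expect_true(all(c("QT_MS", "RR_S") %in% names(d)))
  expect_equal(d$QT_MS, d$QTCF_MS * d$RR_S^0.41)
  # estimate from the baseline ECGs, where QTcF itself is stable within
  # subject and the exponent is cleanly identified
  pre <- d[d$TIME_H <= 0, ]
  est <- estimate_correction_exponent(pre$QT_MS, pre$RR_S, id = pre$ID)
  expect_equal(est, 0.41, tolerance = 0.05)
})
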