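# Structural model: QT correction, circadian baseline, secular trend, drug
# effects and assembled prediction.

test_that("heart-rate correction matches the power-law arithmetic", {
  # RR = 1 s is the identity for any exponent
  expect_equal(correct_qt(400, 1.0), 400)
  expect_equal(correct_qt(400, 1.0, "bazett"), 400)
  expect_equal(correct_qt(380, 0.8), 380 / 0.8^(1 / 3))
  expect_equal(correct_qt(380, 0.8, "bazett"), 380 / 0.8^(1 / 2))
  expect_equal(correct_qt(380, 0.8, "power", exponent = 0.41),
               380 / 0.8^0.41)
  # named methods are exactly their power-law counterparts
  rr <- c(0.6, 0.8, 1.1, 1.3)
  expect_identical(correct_qt(400, rr),
                   correct_qt(400, rr, "power", exponent = 1 / 3))
  expect_identical(correct_qt(400, rr, "bazett"),
                   correct_qt(400, rr, "power", exponent = 1 / 2))
})

test_that("heart-rate correction rejects invalid input", {
  expect_error(correct_qt(400, 0), "positive")
  expect_error(correct_qt(400, -0.8), "positive")
  expect_error(correct_qt(-1, 0.8), "positive")
  expect_error(correct_qt(400, 0.8, "power"), "exponent")
  expect_error(correct_qt(400, 0.8, "power", exponent = 1.2), "\\(0, 1\\)")
})

test_that("correction exponent is recovered from power-law data", {
  # noiseless power law: exact recovery
  set.seed(11)
  rr <- runif(50, 0.6, 1.2)
  expect_equal(estimate_correction_exponent(420 * rr^(1 / 3), rr), 1 / 3)
  # noisy data around exponent 0.41 (the in-between estimate typical of
  # TB cohorts): pooled log-log recovery
  rr <- runif(2000, 0.55, 1.25)
  qt <- 400 * rr^0.41 * exp(rnorm(2000, 0, 0.01))
  expect_equal(estimate_correction_exponent(qt, rr), 0.41, tolerance = 0.02)
  # per-subject variant: different individual levels, shared exponent
  rr1 <- runif(60, 0.6, 1.2); rr2 <- runif(60, 0.6, 1.2)
  qt12 <- c(380 * rr1^0.5, 430 * rr2^0.5)
  out <- estimate_correction_exponent(qt12, c(rr1, rr2),
                                      id = rep(1:2, each = 60),
                                      by = "individual")
  expect_equal(unname(out), c(0.5, 0.5))
  # pooled variant must not be biased by between-subject level differences
  expect_equal(estimate_correction_exponent(qt12, c(rr1, rr2),
                                            id = rep(1:2, each = 60)),
               0.5, tolerance = 1e-10)
  expect_error(estimate_correction_exponent(c(400, 401), c(1, 1)),
               "degenerate")
})

test_that("circadian factor is a unit-mean sum of cosines", {
  p0 <- flat_params()
  expect_equal(circadian_factor(c(0, 6, 13.7, 23.9), p0), rep(1, 4))
  # single oscillator evaluated at its acrophase
  p1 <- qtc_params(amp = c(0.01, 0, 0), acro = c(3, 0, 0))
  expect_equal(circadian_factor(3, p1), 1.01)
  # published parameter set integrates to 1 over the day
  tt <- seq(0, 24, length.out = 48001)[-48001]
  expect_equal(mean(circadian_factor(tt, ref_params())), 1,
               tolerance = 1e-8)
  # property: unit mean for arbitrary amplitude/acrophase sets
  set.seed(42)
  for (i in 1:20) {
    p <- qtc_params(amp = runif(3, 0, 0.2), acro = runif(3) * c(24, 12, 6))
    expect_equal(mean(circadian_factor(tt, p)), 1, tolerance = 1e-8)
  }
  expect_error(circadian_factor(24, p0), "\\[0, 24\\)")
})

test_that("secular trend follows the half-life parameterisation", {
  p <- ref_params()   # qtc_ss 6.33 ms, half-life 1.04 wk
  expect_equal(secular_offset(0, p), 0)
  expect_equal(secular_offset(-24, p), 0)
  # exactly half the asymptote at one half-life
  expect_identical(secular_offset(p$t_half * 168, p), p$qtc_ss / 2)
  # asymptote reached at 20 half-lives
  expect_equal(secular_offset(20 * p$t_half * 168, p), 6.33,
               tolerance = 1e-4)
  expect_true(all(diff(secular_offset(seq(0, 2000, 10), p)) >= 0))
})

test_that("competitive drug effect matches its defining algebra", {
  p <- ref_params()   # shared Emax 44.5 ms, EC50s 0.57 / 0.903 / 26.9 mg/L
  # half-maximal at own EC50 when alone
  de <- drug_effect_competitive(p$ec50_m2, 0, 0, p)
  expect_equal(de$de_m2, p$emax / 2)
  expect_equal(de$de_pa, 0)
  expect_equal(de$de_cfz, 0)
  # normalised worked case: EC50s (1, 2, 4), companions at 3
  pn <- qtc_params(emax = 1, ec50_m2 = 1, ec50_pa = 2, ec50_cfz = 4)
  expect_equal(drug_effect_competitive(1, 3, 3, pn)$de_m2,
               1 / (1 * (1 + 3 / 2) * (1 + 3 / 4) + 1))
  # equal scaled concentrations c * EC50 give total 0.6 Emax at c = 1,
  # and c = 1 is the maximum over c (analytic: d/dc c/((1+c)^2+c) = 0)
  tot_at <- function(cc) with(p, drug_effect_competitive(
    cc * ec50_m2, cc * ec50_pa, cc * ec50_cfz, p)$total)
  expect_equal(tot_at(1), 0.6 * p$emax)
  cgrid <- seq(0.05, 20, by = 0.05)
  expect_equal(cgrid[which.max(vapply(cgrid, tot_at, numeric(1)))], 1)
  expect_error(drug_effect_competitive(-1, 0, 0, p), "non-negative")
})

test_that("competitive effect satisfies its structural invariants", {
  p <- ref_params()
  set.seed(7)
  cm2 <- runif(300, 0, 3); cpa <- runif(300, 0, 40); ccfz <- runif(300, 0, 5)
  de <- drug_effect_competitive(cm2, cpa, ccfz, p)
  # bounded in [0, emax)
  expect_true(all(de$de_m2 >= 0 & de$de_m2 < p$emax))
  expect_true(all(de$de_pa >= 0 & de$de_pa < p$emax))
  expect_true(all(de$de_cfz >= 0 & de$de_cfz < p$emax))
  # single-drug limit equals the plain Emax model to machine precision
  expect_equal(drug_effect_competitive(cm2, 0, 0, p)$de_m2,
               p$emax * cm2 / (p$ec50_m2 + cm2), tolerance = 1e-15)
  # strictly decreasing in each companion concentration
  for (b in seq(0.5, 40, length.out = 10)) {
    lo <- drug_effect_competitive(1, b, 1, p)$de_m2
    hi <- drug_effect_competitive(1, b + 0.5, 1, p)$de_m2
    expect_lt(hi, lo)
  }
})

test_that("empirical interaction combines additively with a product term", {
  expect_equal(drug_effect_empirical(5, 3, 2, 0), 10)
  expect_equal(drug_effect_empirical(5, 3, 2, -0.01), 9.7)
  expect_equal(drug_effect_empirical(0, 3, 2, -5), 5)
  expect_equal(drug_effect_empirical(0, 3, 2, 17), 5)
})

test_that("assembled QTcF prediction composes the terms correctly", {
  p <- flat_params()
  rec <- function(age = 37.5, t = 0, cm2 = 0, clock = 8)
    data.frame(ID = 1, TIME_H = t, CLOCK_H = clock, CM2_MGL = cm2,
               CPA_MGL = 0, CCFZ_MGL = 0, AGE_Y = age)
  # typical subject pre-dose: the baseline itself
  expect_equal(predict_qtcf(rec(), p), 393)
  # age effect: +0.472 ms per year above 37.5
  p2 <- qtc_params(amp = c(0, 0, 0))
  expect_equal(predict_qtcf(rec(age = 47.5), p2), 393 + 4.72)
  # half-maximal BDQM2 effect on top of baseline
  expect_equal(predict_qtcf(rec(cm2 = p$ec50_m2), p), 393 + 44.5 / 2)
  # secular trend appears only after treatment start
  expect_equal(predict_qtcf(rec(t = 168 * p$t_half), p),
               393 + p$qtc_ss / 2)
  # individual random effects: baseline scales log-normally
  eta <- matrix(0, 1, 5, dimnames = list("1", QTC_ETA_NAMES))
  eta[1, "base"] <- 0.1
  expect_equal(predict_qtcf(rec(), p, eta), 393 * exp(0.1))
  # individual EC50 scaling shifts the drug effect
  eta[1, "base"] <- 0; eta[1, "ec50_m2"] <- log(2)
  expect_equal(predict_qtcf(rec(cm2 = p$ec50_m2), p, eta),
               393 + p$emax * p$ec50_m2 / (2 * p$ec50_m2 + p$ec50_m2))
  expect_error(predict_qtcf(rec(age = NA), p), "AGE_Y")
  expect_error(predict_qtcf(rec()[, -7], p), "missing required")
})
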