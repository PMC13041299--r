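# Regimen builder, Monte-Carlo simulator and ICH exceedance summaries.

test_that("named regimens expand to their published schedules", {
  r <- build_regimen("unite4tb_bdq")
  dd <- qtcompete:::regimen_doses(r, "bdq", 4)
  expect_equal(dd$times, seq(0, 27 * 24, by = 24))
  expect_equal(dd$amt, c(rep(400, 14), rep(100, 14)))

  r <- build_regimen("bpal")
  db <- qtcompete:::regimen_doses(r, "bdq", 10)
  expect_equal(db$amt, c(rep(200, 56), rep(100, 14)))
  dp <- qtcompete:::regimen_doses(r, "pa", 10)
  expect_equal(unique(dp$amt), 200)
  expect_equal(length(dp$times), 70)

  r <- build_regimen("cfz_loading")
  dc <- qtcompete:::regimen_doses(r, "cfz", 2)
  expect_equal(dc$amt, c(300, 300, 300, rep(100, 11)))

  expect_equal(qtcompete:::regimen_doses(build_regimen("cfz_100"), "bdq", 2),
               list(times = numeric(), amt = numeric()))
  expect_error(build_regimen("nonsense"), "choices")
  expect_error(regimen_spec(cfz = data.frame(dose = 100, interval_h = 24,
                                             weeks = -1)),
               "invalid regimen")
})

test_that("regimen simulation is reproducible and respects degeneracy", {
  p0 <- qtc_params(amp = c(0, 0, 0), age_slope = 0, omega_base = 0,
                   omega_ss = 0, omega_ec50_cfz = 0, omega_ec50_m2 = 0,
                   omega_eps = 0)
  pk0 <- pk_profile(bdq = list(bsv_cl = 0, iov_ka = 0),
                    pa = list(bsv_cl = 0, iov_ka = 0),
                    cfz = list(bsv_cl = 0, iov_ka = 0))
  s <- simulate_regimen(build_regimen("cfz_100"), n_reps = 8, params = p0,
                        pk = pk0, horizon_weeks = 4, seed = 1)
  # all variability off: every replicate identical
  expect_equal(apply(s$qtcf, 2, sd), rep(0, 4))
  # zero-dose regimen: drug-driven delta identically zero
  z <- regimen_spec(cfz = data.frame(dose = 0, interval_h = 24,
                                     weeks = Inf))
  sz <- simulate_regimen(z, n_reps = 5, horizon_weeks = 3, seed = 2)
  expect_true(all(sz$delta_drug == 0))
  # seed reproducibility
  a <- simulate_regimen(build_regimen("unite4tb_bdq"), n_reps = 20,
                        horizon_weeks = 3, seed = 9)
  b <- simulate_regimen(build_regimen("unite4tb_bdq"), n_reps = 20,
                        horizon_weeks = 3, seed = 9)
  expect_identical(a$qtcf, b$qtcf)
  expect_identical(ich_summary(a), ich_summary(b))
})

test_that("exceedance summaries count correctly", {
  # hand-built trajectories: 4 of 10 above 30 ms at the single week
  tr <- matrix(c(rep(40, 4), rep(10, 6)), ncol = 1)
  s <- ich_summary(tr, weeks = 1, definition = "delta_total")
  expect_equal(s$percent[s$threshold == 30], 40)
  expect_equal(s$percent[s$threshold == 60], 0)
  expect_equal(s$mc_se[s$threshold == 30],
               100 * sqrt(0.4 * 0.6 / 10))
  # unsorted thresholds are canonicalised; summary invariant
  s2 <- ich_summary(tr, thresholds = list(absolute = c(500, 450, 480),
                                          delta = c(60, 30)), weeks = 1)
  expect_equal(s2[order(s2$threshold), "percent"],
               s[order(s$threshold), "percent"])
  expect_error(ich_summary(tr, weeks = 5), "beyond")
})

test_that("exceedance is monotone in threshold and bounded by Emax", {
  s <- simulate_regimen(build_regimen("bpal"), n_reps = 300,
                        horizon_weeks = 8, seed = 5)
  tab <- ich_summary(s)
  # non-increasing across ascending thresholds at fixed week/definition
  for (d in unique(tab$definition)) for (w in unique(tab$week)) {
    x <- tab[tab$definition == d & tab$week == w, ]
    x <- x[order(x$threshold), ]
    expect_true(all(diff(x$percent) <= 0))
  }
  # the competitive model caps the drug-driven effect below the shared
  # Emax of 44.5 ms, so >60 ms drug-driven exceedance is exactly zero
  expect_true(all(s$delta_drug < qtc_params()$emax))
  expect_true(all(tab$percent[tab$definition == "delta_drug" &
                                tab$threshold == 60] == 0))
})

test_that("week numbering and patient settings flow through", {
  s <- simulate_regimen(build_regimen("cfz_100"), n_reps = 10,
                        horizon_weeks = 5, seed = 3,
                        patient = typical_patient(age = 70,
                                                  ancestry = "non_black"))
  expect_equal(s$weeks, 1:5)
  expect_equal(s$patient$age, 70)
  expect_warning(simulate_regimen(build_regimen("cfz_100"), n_reps = 2,
                                  horizon_weeks = 30, seed = 3),
                 "capped")
})
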