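# IWRES standardization, NPDE calibration mechanics, prediction bands and
# observed-vs-predicted coverage.

test_that("IWRES is the residual weighted by the residual SD", {
  # with IIV off, individual predictions equal population predictions exactly
  pop <- population_model(c(ka = 1.5, v = 100, kel = 0.03),
                          omega = c(ka = 0, v = 0, kel = 0),
                          error = error_model("additive", a = 0.1))
  reg <- study_regimen()
  tt <- c(1, 6, 18)
  f <- concentration_profile(pk_params(1.5, 100, 0.03), reg, tt)
  d <- doxypk:::.new_dataset(ID = rep(1:2, each = 8),
                             TIME = rep(c(reg$time, tt), 2),
                             EVID = rep(c(rep(1L, 5), rep(0L, 3)), 2),
                             AMT = rep(c(reg$amount, rep(NA, 3)), 2),
                             DV = rep(c(rep(NA, 5), f), 2),
                             MATRIX = "serum", VALID = 1L)
  d$DV[d$EVID == 0 & d$ID == 2] <- f + 0.2
  iw <- iwres(pop, d)
  expect_equal(iw$iwres[iw$ID == 1], rep(0, 3))
  expect_equal(iw$iwres[iw$ID == 2], rep(2, 3))
})

test_that("IWRES is approximately standard normal under the true model", {
  tms <- c(0.25, 0.5, 1, 2, 4, 6, 12, 18, 24, 24.5, 28, 30, 36, 36.5, 42, 48,
           48.5, 54, 60, 72)
  truth <- unit_truth()
  d <- generate_study(study_design(n_subjects = 40, serum_times = tms,
                                   dropout = NULL), truth, seed = 81)
  iw <- iwres(truth, d, n = 300, seed = 82)
  expect_equal(nrow(iw), 800)
  expect_equal(mean(iw$iwres), 0, tolerance = 0.1)
  expect_equal(sd(iw$iwres), 1, tolerance = 0.1)
})

test_that("NPDE has one value per retained observation and a finite extreme under the rank correction", {
  pop <- unit_truth()
  reg <- study_regimen()
  # single observation per subject; one observation far above all replicates
  n_sub <- 6
  d <- do.call(rbind, lapply(1:n_sub, function(i) {
    doxypk:::.new_dataset(ID = rep(i, 6), TIME = c(reg$time, 2),
                          EVID = c(rep(1L, 5), 0L), AMT = c(reg$amount, NA),
                          DV = c(rep(NA, 5), 0.1), MATRIX = "serum", VALID = 1L)
  }))
  d$DV[d$EVID == 0 & d$ID == 1] <- 50 # far outside the prediction distribution
  np <- npde(pop, d, n_sim = 500, seed = 83)
  expect_equal(nrow(np), n_sub)
  expect_equal(np$npde[np$ID == 1], qnorm((500 + 0.5) / 501))
  expect_true(all(is.finite(np$npde)))
  # retained = valid records only
  d$VALID[d$EVID == 0 & d$ID == 2] <- 0L
  expect_equal(nrow(npde(pop, d, n_sim = 100, seed = 84)), n_sub - 1)
})

test_that("NPDE is calibrated under the true model and flags a misspecified elimination rate", {
  tms <- c(0.25, 0.5, 1, 2, 4, 6, 12, 18, 24, 24.5, 28, 30, 36, 36.5, 42, 48,
           48.5, 54, 60, 72)
  truth <- recovery_truth()
  d <- generate_study(study_design(n_subjects = 40, serum_times = tms,
                                   dropout = NULL), truth, seed = 85)
  np <- npde(truth, d, n_sim = 500, seed = 86)
  expect_equal(nrow(np), 800)
  expect_gt(suppressWarnings(ks.test(np$npde, "pnorm"))$p.value, 0.01)
  wrong <- population_model(c(ka = 10.3, v = 108, kel = 0.0253 / 2),
                            omega = c(ka = 0.2, v = 0.2, kel = 0),
                            error = error_model("proportional", b = 0.1))
  np2 <- npde(wrong, d, n_sim = 500, seed = 86)
  expect_lt(suppressWarnings(ks.test(np2$npde, "pnorm"))$p.value, 0.01)
})

test_that("prediction bands collapse without variability, are nested, and widen with omega", {
  reg <- study_regimen()
  grid <- c(0.5, 2, 12, 24, 48, 72)
  det <- population_model(c(ka = 10.3, v = 108, kel = 0.0253),
                          omega = c(ka = 0, v = 0, kel = 0),
                          error = error_model("additive", a = 1e-12))
  b0 <- prediction_bands(det, reg, grid, n_sim = 200, seed = 87)
  f <- concentration_profile(table1_params(), reg, grid)
  expect_equal(b0$pct_5, f, tolerance = 1e-6)
  expect_equal(b0$pct_50, f, tolerance = 1e-6)
  expect_equal(b0$pct_95, f, tolerance = 1e-6)
  narrow <- population_model(c(ka = 10.3, v = 108, kel = 0.0253),
                             omega = c(ka = 0, v = 0.2, kel = 0),
                             error = error_model("proportional", b = 0.05))
  wide <- population_model(c(ka = 10.3, v = 108, kel = 0.0253),
                           omega = c(ka = 0, v = 0.8, kel = 0),
                           error = error_model("proportional", b = 0.05))
  bn <- prediction_bands(narrow, reg, grid, n_sim = 1000, seed = 88)
  bw <- prediction_bands(wide, reg, grid, n_sim = 1000, seed = 88)
  expect_true(all(bn$pct_5 <= bn$pct_50 & bn$pct_50 <= bn$pct_95))
  expect_true(all(bw$pct_95 - bw$pct_5 > bn$pct_95 - bn$pct_5))
  # the median band tracks the typical-value profile for modest variability
  bm <- prediction_bands(narrow, reg, grid, n_sim = 8000, seed = 89)
  expect_equal(bm$pct_50, f, tolerance = 0.05)
  expect_error(prediction_bands(narrow, reg, grid, percentiles = c(0, 50)),
               "strictly between")
})

test_that("the observed-vs-predicted table reproduces a noise-free fit on the identity line with nominal coverage", {
  pop <- population_model(c(ka = 1.5, v = 100, kel = 0.03),
                          omega = c(ka = 0, v = 0, kel = 0),
                          error = error_model("additive", a = 1e-9))
  d <- generate_study(study_design(n_subjects = 3, dropout = NULL), pop, seed = 90)
  ovp <- observed_vs_predicted(pop, d)
  expect_equal(nrow(ovp), 3 * 19) # pre-first-dose records are not retained
  expect_equal(ovp$observed, ovp$pred, tolerance = 1e-6)
  expect_equal(ovp$observed, ovp$ipred, tolerance = 1e-6)

  # ~90% of fresh true-model observations fall in the 90% prediction interval
  truth <- unit_truth()
  reg <- study_regimen()
  grid <- c(1, 6, 18, 30, 54)
  bands <- prediction_bands(truth, reg, grid, n_sim = 2000, seed = 91)
  set.seed(92)
  sims <- doxypk:::.simulate_replicates(truth, "one_cmt", reg, grid, 2000)
  inside <- sweep(sims, 2, bands$pct_5, ">=") & sweep(sims, 2, bands$pct_95, "<=")
  expect_equal(mean(inside), 0.90, tolerance = 0.034)
})
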