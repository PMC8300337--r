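# Conditional sampling, post-hoc individual estimates, five-number summaries,
# shrinkage behavior.

test_that("the conditional posterior collapses to the prior (or to zero) in the degenerate limits", {
  reg <- study_regimen()
  # dose-only subject: posterior = prior
  d <- doxypk:::.new_dataset(ID = rep(1, 5), TIME = reg$time, EVID = 1L,
                             AMT = reg$amount, DV = NA_real_, MATRIX = "serum",
                             VALID = 1L)
  pop <- unit_truth()
  draws <- conditional_samples(pop, d, 1, n = 4000, seed = 101)
  expect_equal(colnames(draws), c("ka", "v"))
  expect_equal(unname(colMeans(draws)), c(0, 0), tolerance = 0.02)
  expect_equal(unname(apply(draws, 2, sd)), c(0.2, 0.2), tolerance = 0.02)
  # no active effects: all draws exactly zero-length
  pop0 <- population_model(c(ka = 1.5, v = 108, kel = 0.0253),
                           omega = c(ka = 0, v = 0, kel = 0),
                           error = error_model("additive", a = 0.01))
  expect_equal(ncol(conditional_samples(pop0, d, 1, n = 10)), 0)
  expect_error(conditional_samples(pop, d, 99), "not found")
})

test_that("the conditional mean matches a dense-quadrature oracle for one observation and one effect", {
  pop <- population_model(c(ka = 1.5, v = 100, kel = 0.03),
                          omega = c(ka = 0, v = 0.4, kel = 0),
                          error = error_model("proportional", b = 0.15))
  d <- doxypk:::.new_dataset(ID = c(1, 1), TIME = c(0, 6), EVID = c(1L, 0L),
                             AMT = c(10, NA), DV = c(NA, 0.07),
                             MATRIX = "serum", VALID = 1L)
  draws <- conditional_samples(pop, d, 1, n = 8000, seed = 102, burn_in = 500)
  reg <- dosing_regimen(0, 10)
  grid <- seq(-2.4, 2.4, length.out = 1e4)
  post <- vapply(grid, function(e) {
    f <- concentration_profile(pk_params(1.5, 100 * exp(e), 0.03), reg, 6)
    dnorm(0.07, f, 0.15 * f) * dnorm(e, 0, 0.4)
  }, numeric(1))
  post_mean <- sum(grid * post) / sum(post)
  expect_equal(mean(draws[, "v"]), post_mean, tolerance = abs(post_mean) * 0.01 + 2e-3)
})

test_that("parameters without IIV return the population value exactly for every subject", {
  d <- generate_study(study_design(n_subjects = 8), reference_population(), seed = 103)
  est <- individual_estimates(reference_population(), d, n = 150, seed = 104)
  expect_equal(nrow(est), 8)
  expect_true(all(est$kel == 0.0253))
  expect_true(all(est$sd_kel == 0))
  fns <- five_number_summary(est)
  kel_row <- fns[fns$parameter == "kel", ]
  expect_equal(as.numeric(kel_row[, c("min", "q1", "median", "q3", "max")]),
               rep(0.0253, 5))
})

test_that("noise-free single-subject data recover the generating parameters as conditional means", {
  truth <- population_model(c(ka = 1.5, v = 108, kel = 0.0253),
                            omega = c(ka = 0.3, v = 0.3, kel = 0),
                            error = error_model("proportional", b = 0.01))
  d <- generate_study(study_design(n_subjects = 2, dropout = NULL), truth, seed = 105)
  psi <- attr(d, "psi")
  est <- individual_estimates(truth, d, n = 400, seed = 106)
  expect_equal(est$ka, psi$ka, tolerance = 0.05)
  expect_equal(est$v, psi$v, tolerance = 0.05)
})

test_that("five-number summaries use type-7 quartiles and ignore subject order", {
  x <- data.frame(ID = 1:5, ka = 1:5)
  fns <- five_number_summary(x)
  expect_equal(as.numeric(fns[1, c("min", "q1", "median", "q3", "max")]),
               c(1, 2, 3, 4, 5))
  x2 <- x[sample(5), ]
  expect_equal(five_number_summary(x2), fns)
  expect_error(five_number_summary(x[0, ]), "empty")
})

test_that("conditional means shrink toward the population value and sharpen with more data", {
  pop <- population_model(c(ka = 1.5, v = 100, kel = 0.03),
                          omega = c(ka = 0, v = 0.4, kel = 0),
                          error = error_model("proportional", b = 0.15))
  reg <- study_regimen()
  true_eta <- 0.5
  p_i <- pk_params(1.5, 100 * exp(true_eta), 0.03)
  sparse_t <- c(6, 18)
  rich_t <- c(1, 2, 6, 12, 18, 24, 30, 42, 54, 66)
  mk <- function(tt) {
    doxypk:::.new_dataset(ID = rep(1, 5 + length(tt)), TIME = c(reg$time, tt),
                          EVID = c(rep(1L, 5), rep(0L, length(tt))),
                          AMT = c(reg$amount, rep(NA, length(tt))),
                          DV = c(rep(NA, 5),
                                 concentration_profile(p_i, reg, tt)),
                          MATRIX = "serum", VALID = 1L)
  }
  dr_s <- conditional_samples(pop, mk(sparse_t), 1, n = 3000, seed = 107)
  dr_r <- conditional_samples(pop, mk(rich_t), 1, n = 3000, seed = 108)
  # naive fit would give eta = 0.5 exactly (noise-free observations)
  expect_gt(mean(dr_s[, "v"]), 0)
  expect_lt(mean(dr_s[, "v"]), true_eta)
  # shrinkage weakens and the posterior sharpens as observations accumulate
  expect_gt(mean(dr_r[, "v"]), mean(dr_s[, "v"]))
  expect_lt(sd(dr_r[, "v"]), sd(dr_s[, "v"]))
})
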