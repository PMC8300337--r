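# Lognormal hierarchy, residual error model, conditional likelihood and
# subject simulation.

test_that("the lognormal link maps eta to individual parameters", {
  pop <- population_model(c(ka = 10.3, v = 108, kel = 0.0253),
                          omega = c(ka = 0.5, v = 0.5, kel = 0.5))
  p0 <- individual_params(pop, c(0, 0, 0))
  expect_equal(c(p0$ka, p0$v, p0$kel), c(10.3, 108, 0.0253))
  p1 <- individual_params(pop, c(log(2), 0, 0))
  expect_equal(p1$ka, 2 * 10.3)
  expect_equal(c(p1$v, p1$kel), c(108, 0.0253))
  # eta must be zero where IIV is off
  pop2 <- population_model(c(ka = 1, v = 1, kel = 1), omega = c(ka = 0.3, v = 0, kel = 0))
  expect_error(individual_params(pop2, c(0.1, 0.2, 0)), "without IIV")
  expect_equal(individual_params(pop2, 0.25)$ka, exp(0.25))
})

test_that("simulated parameter quartiles follow the lognormal quartile identity", {
  # Q3/Q1 = exp(2 * z_.75 * omega); with omega_V = 0.877 the ratio is ~3.26,
  # the ratio implied by the reported individual V quartiles (204 / 62.5)
  set.seed(42)
  eta <- rnorm(1e5, 0, 0.877)
  v <- 108 * exp(eta)
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(q[3] / q[1], exp(2 * qnorm(0.75) * 0.877), tolerance = 0.03)
  expect_equal(q[3] / q[1], 204 / 62.5, tolerance = 0.03)
  # median invariance: the median of a lognormal individual parameter is theta
  expect_equal(q[2], 108, tolerance = 0.01)
})

test_that("residual SD covers additive, proportional and combined forms", {
  expect_equal(residual_sd(0, error_model("combined", a = 0.01, b = 0.18)), 0.01)
  expect_equal(residual_sd(1, error_model("proportional", b = 0.18)), 0.18)
  expect_equal(residual_sd(1, error_model("combined", a = 0.03, b = 0.04)), 0.05)
  expect_error(residual_sd(-1, error_model("additive", a = 0.1)), ">= 0")
  expect_error(error_model("additive", a = 0, b = 0), "strictly positive")
})

test_that("the conditional log-likelihood is a sum of Gaussian log-densities", {
  p <- table1_params()
  reg <- study_regimen()
  tt <- c(1, 6, 18, 30)
  f <- concentration_profile(p, reg, tt)
  err <- error_model("additive", a = 1)
  # one observation exactly at the prediction, additive SD 1
  expect_equal(loglik_conditional(list(time = 1, conc = f[1]), p, reg, err),
               -0.5 * log(2 * pi))
  # brute-force density-product oracle
  err2 <- error_model("combined", a = 0.02, b = 0.15)
  obs <- list(time = tt, conc = f * c(1.1, 0.8, 1.05, 0.9))
  want <- log(prod(dnorm(obs$conc, f, sqrt(0.02^2 + (0.15 * f)^2))))
  expect_equal(loglik_conditional(obs, p, reg, err2), want, tolerance = 1e-10)
  # doubling the additive SD around a perfect fit costs log(2) per point
  perfect <- list(time = tt, conc = f)
  l1 <- loglik_conditional(perfect, p, reg, error_model("additive", a = 0.05))
  l2 <- loglik_conditional(perfect, p, reg, error_model("additive", a = 0.10))
  expect_equal(l1 - l2, length(tt) * log(2), tolerance = 1e-12)
})

test_that("subject simulation is seed-reproducible, noise-free in the degenerate limit, and correctly scaled", {
  reg <- study_regimen()
  tt <- c(0.5, 2, 18, 30)
  pop0 <- population_model(c(ka = 10.3, v = 108, kel = 0.0253),
                           omega = c(ka = 0, v = 0, kel = 0),
                           error = error_model("additive", a = 1e-12))
  sim0 <- simulate_subject(pop0, reg, tt, seed = 1)
  expect_equal(sim0$conc, concentration_profile(table1_params(), reg, tt),
               tolerance = 1e-9)
  pop <- recovery_truth()
  s1 <- simulate_subject(pop, reg, tt, seed = 7)
  s2 <- simulate_subject(pop, reg, tt, seed = 7)
  expect_identical(s1$conc, s2$conc)
  # empirical residual SD ~ b * prediction when omega = 0
  popb <- population_model(c(ka = 10.3, v = 108, kel = 0.0253),
                           omega = c(ka = 0, v = 0, kel = 0),
                           error = error_model("proportional", b = 0.1))
  set.seed(99)
  reps <- replicate(1e4, simulate_subject(popb, reg, 18)$conc)
  f18 <- concentration_profile(table1_params(), reg, 18)
  expect_equal(sd(reps), 0.1 * f18, tolerance = 0.03)
})

test_that("correlated random effects require a positive-definite correlation", {
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(population_model(c(ka = 1, v = 1, kel = 1),
                                omega = c(ka = 0.3, v = 0.3, kel = 0),
                                corr = bad), "positive definite")
  good <- matrix(c(1, 0.8, 0.8, 1), 2)
  pop <- population_model(c(ka = 1, v = 1, kel = 1),
                          omega = c(ka = 0.3, v = 0.3, kel = 0), corr = good)
  set.seed(5)
  etas <- t(replicate(4000, attr(simulate_subject(pop, study_regimen(), 2), "eta")))
  expect_equal(cor(etas)[1, 2], 0.8, tolerance = 0.05)
})
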