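# SAEM estimator: degenerate and stochastic recovery, trace behavior,
# invariances, marginal likelihood, BIC, standard errors, correlations.

test_that("with IIV off and noise-free data the fit reduces to nonlinear regression on the truth", {
  truth <- population_model(c(ka = 1.5, v = 108, kel = 0.0253),
                            omega = c(ka = 0, v = 0, kel = 0),
                            error = error_model("additive", a = 1e-9))
  d <- generate_study(study_design(n_subjects = 4, dropout = NULL), truth, seed = 21)
  pop0 <- population_model(c(ka = 0.8, v = 60, kel = 0.05),
                           omega = c(ka = 0, v = 0, kel = 0),
                           error = error_model("additive", a = 0.01))
  fit <- fit_saem(d, pop0 = pop0, settings = saem_settings(150, 50, seed = 22),
                  compute_loglik = FALSE)
  expect_equal(as.numeric(fit$pop_hat$theta),
               c(1.5, 108, 0.0253), tolerance = 1e-3)
  # direct-optimizer oracle on the pooled nonlinear regression
  reg <- study_regimen()
  obs <- d[d$EVID == 0 & d$TIME > 0, ]
  sse <- function(lp) {
    p <- pk_params(exp(lp[1]), exp(lp[2]), exp(lp[3]))
    sum((obs$DV - concentration_profile(p, reg, obs$TIME))^2)
  }
  ml <- optim(log(c(0.8, 60, 0.05)), sse, method = "BFGS")
  expect_equal(as.numeric(fit$pop_hat$theta), as.numeric(exp(ml$par)), tolerance = 0.01)
})

test_that("a moderate recovery simulation returns estimates near the truth with stable smoothing traces", {
  sf <- shared_fit()
  fit <- sf$fit
  th <- fit$pop_hat$theta
  expect_equal(as.numeric(th["ka"]), 1.5, tolerance = 0.15)
  expect_equal(as.numeric(th["v"]), 108, tolerance = 0.12)
  expect_equal(as.numeric(th["kel"]), 0.0253, tolerance = 0.08)
  expect_equal(as.numeric(fit$pop_hat$omega[c("ka", "v")]), c(0.2, 0.2),
               tolerance = 0.5)
  # smoothing traces settle: max change over the last 50 iterations < 1% of the estimate
  tr <- fit$traces
  last50 <- tr[(nrow(tr) - 49):nrow(tr), c("ka", "v", "kel")]
  rel_drift <- vapply(names(last50),
                      function(cn) diff(range(last50[[cn]])) / tr[[cn]][nrow(tr)],
                      numeric(1))
  expect_true(all(rel_drift < 0.01))
  expect_equal(nrow(tr), 400 + 150)
})

test_that("estimates are invariant to relabeling subject IDs", {
  truth <- recovery_truth()
  d <- generate_study(study_design(n_subjects = 10, dropout = NULL), truth, seed = 31)
  d2 <- d
  d2$ID <- d$ID * 100 + 7
  s <- saem_settings(150, 50, seed = 32)
  f1 <- fit_saem(d, settings = s, compute_loglik = FALSE)
  f2 <- fit_saem(d2, settings = s, compute_loglik = FALSE)
  expect_identical(f1$pop_hat$theta, f2$pop_hat$theta)
  expect_identical(f1$pop_hat$omega, f2$pop_hat$omega)
})

test_that("degenerate or infeasible fits are rejected up front", {
  truth <- recovery_truth()
  d1 <- generate_study(study_design(n_subjects = 1, dropout = NULL), truth, seed = 41)
  expect_error(fit_saem(d1, settings = saem_settings(50, 10, seed = 1)),
               "at least 2 subjects")
  d2 <- generate_study(study_design(n_subjects = 2, dropout = NULL), truth, seed = 42)
  pop_wide <- population_model(c(ka = 1, v = 50, kel = 0.05),
                               omega = c(ka = 0.5, v = 0.5, kel = 0.5))
  expect_error(fit_saem(d2, pop0 = pop_wide, settings = saem_settings(50, 10, seed = 1)),
               "fewer subjects than random effects")
})

test_that("BIC follows -2*loglik + k*log(N) and penalizes extra parameters", {
  design <- study_design()
  d <- generate_tissue_records(generate_study(design, seed = 51),
                               design = design, seed = 52)
  d <- apply_missingness(d, design, seed = 52)
  # 149 valid serum observations remain
  expect_equal(bic(-100, 5, d), 200 + 5 * log(149))
  expect_lt(bic(-100, 5, d), bic(-100, 7, d))
})

test_that("importance sampling reduces to the conditional likelihood without random effects and matches quadrature with one effect", {
  # no active effects: exact equality
  truth0 <- population_model(c(ka = 1.5, v = 108, kel = 0.0253),
                             omega = c(ka = 0, v = 0, kel = 0),
                             error = error_model("proportional", b = 0.1))
  d0 <- generate_study(study_design(n_subjects = 3, dropout = NULL), truth0, seed = 61)
  f0 <- fit_saem(d0, pop0 = truth0, settings = saem_settings(60, 30, seed = 62),
                 compute_loglik = FALSE)
  ll_is <- loglik_importance_sampling(f0, d0, n_is = 50, seed = 63)
  reg <- study_regimen()
  ll_direct <- sum(vapply(unique(d0$ID), function(id) {
    obs <- d0[d0$ID == id & d0$EVID == 0 & d0$TIME > 0, ]
    loglik_conditional(list(time = obs$TIME, conc = obs$DV),
                       pk_params(f0$pop_hat$theta["ka"], f0$pop_hat$theta["v"],
                                 f0$pop_hat$theta["kel"]),
                       reg, f0$pop_hat$error)
  }, numeric(1)))
  expect_equal(ll_is, ll_direct, tolerance = 1e-12)

  # one subject, one observation, one random effect: dense trapezoid oracle
  pop1 <- population_model(c(ka = 1.5, v = 100, kel = 0.03),
                           omega = c(ka = 0, v = 0.4, kel = 0),
                           error = error_model("proportional", b = 0.15))
  d1 <- doxypk:::.new_dataset(ID = c(1, 1), TIME = c(0, 6), EVID = c(1L, 0L),
                              AMT = c(10, NA), DV = c(NA, 0.07),
                              MATRIX = "serum", VALID = 1L)
  fake <- structure(list(pop_hat = pop1, structural = "one_cmt",
                         model_names = c("ka", "v", "kel"), active = "v",
                         ids = 1, eta_samples = array(rnorm(200, 0, 0.4),
                                                      dim = c(200, 1, 1))),
                    class = "saem_fit")
  ll_is1 <- loglik_importance_sampling(fake, d1, n_is = 8000, seed = 64)
  grid <- seq(-6 * 0.4, 6 * 0.4, length.out = 1e4)
  reg1 <- dosing_regimen(0, 10)
  dens <- vapply(grid, function(e) {
    f <- concentration_profile(pk_params(1.5, 100 * exp(e), 0.03), reg1, 6)
    dnorm(0.07, f, 0.15 * f) * dnorm(e, 0, 0.4)
  }, numeric(1))
  ll_quad <- log(sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  expect_equal(ll_is1, ll_quad, tolerance = 0.01)
  # doubling the draw count leaves the estimate stable
  ll_is2 <- loglik_importance_sampling(fake, d1, n_is = 16000, seed = 65)
  expect_equal(ll_is1, ll_is2, tolerance = 0.01)
})

test_that("standard errors are finite, positive, and ordered as expected for the study design", {
  sf <- shared_fit()
  rse <- sf$fit$rse
  expect_true(all(is.finite(rse)) && all(rse > 0))
  # the elimination rate is the best-determined parameter
  expect_lt(rse["kel"], rse["v"])
  expect_lt(rse["kel"], rse["ka"])
})

test_that("posterior eta correlations are near zero for independently generated effects", {
  sf <- shared_fit()
  ec <- eta_correlations(sf$fit)
  expect_equal(diag(ec$correlation), c(ka = 1, v = 1))
  expect_lt(abs(ec$correlation["ka", "v"]), 0.4)
  expect_true(is.na(ec$p_values["ka", "ka"]))
})

test_that("correlated random effects are detected in the posterior means", {
  pop <- population_model(c(ka = 1.5, v = 108, kel = 0.0253),
                          omega = c(ka = 0.3, v = 0.3, kel = 0),
                          corr = matrix(c(1, 0.8, 0.8, 1), 2),
                          error = error_model("proportional", b = 0.1))
  d <- generate_study(study_design(n_subjects = 40, dropout = NULL), pop, seed = 71)
  fit <- fit_saem(d, settings = saem_settings(300, 100, seed = 72),
                  compute_loglik = FALSE)
  ec <- eta_correlations(fit)
  expect_gt(ec$correlation["ka", "v"], 0.4)
  expect_lt(ec$p_values["ka", "v"], 0.01)
})
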