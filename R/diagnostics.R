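# Goodness-of-fit machinery: IWRES, NPDE, observed-vs-predicted pairs, and
# Monte-Carlo prediction bands. Each function accepts a fitted `saem_fit` or
# a bare population model (useful for evaluating a known model against data).

# estimation subset of a dataset, in fit row order
.retained_obs <- function(dataset) {
  prep <- .saem_prep(dataset)
  data.frame(ID = prep$ids[prep$obs_id], time = prep$t, observed = prep$y)
}

# simulate n_sim replicate observation vectors for one subject design
# (IIV + residual noise, negatives truncated at 0), as an n_sim x n_t matrix
.simulate_replicates <- function(pop, structural, regimen, times, n_sim) {
  model <- .model_def(structural)
  act <- which(pop$iiv)
  n_t <- length(times)
  L <- .omega_chol(pop)
  eta <- if (length(act)) {
    matrix(stats::rnorm(n_sim * length(act)), n_sim) %*% t(L)
  } else matrix(0, n_sim, 0)
  phi <- matrix(log(pop$theta), n_sim, length(pop$theta), byrow = TRUE)
  if (length(act)) phi[, act] <- phi[, act] + eta
  psi <- exp(phi)
  tau <- outer(rep(times, times = n_sim), regimen$time, "-")
  prep <- list(obs_id = rep(seq_len(n_sim), each = n_t), tau = tau,
               DA = matrix(regimen$amount, n_sim * n_t, nrow(regimen), byrow = TRUE))
  prep$tau_active <- prep$tau > 0
  prep$tau[!prep$tau_active] <- 0
  prep$DA <- prep$DA * prep$tau_active
  f <- model$pred(psi, prep)
  sd <- sqrt(pop$error$a^2 + (pop$error$b * f)^2)
  y <- pmax(f + stats::rnorm(length(f), 0, sd), 0)
  matrix(y, n_sim, n_t, byrow = TRUE)
}

#' Individual weighted residuals (IWRES)
#'
#' `(observed - individual prediction) / residual_sd(individual prediction)`,
#' one value per retained (valid, post-first-dose) serum observation. The
#' individual predictions come from the post-hoc conditional-mean parameters.
#' Under a correct model the IWRES are approximately standard normal.
#'
#' @param fit An `saem_fit` or [population_model()].
#' @param dataset The dataset.
#' @param n Posterior draws per subject for the individual estimates.
#' @param seed Integer seed.
#' @return Data frame with columns `ID, time, observed, ipred, iwres`.
#' @export
iwres <- function(fit, dataset, n = 500L, seed = 1L) {
  fl <- .fitlike(fit)
  model <- .model_def(fl$structural)
  est <- individual_estimates(fit, dataset, n = n, seed = seed)
  obs <- .retained_obs(dataset)
  pnames <- names(fl$pop$theta)
  ipred <- numeric(nrow(obs))
  for (id in unique(obs$ID)) {
    sdat <- .subject_data(dataset, id)
    psi <- as.numeric(est[est$ID == id, pnames])
    sel <- obs$ID == id
    ipred[sel] <- .profile_vec(psi, sdat$regimen, obs$time[sel], model)
  }
  sd <- sqrt(fl$pop$error$a^2 + (fl$pop$error$b * ipred)^2)
  if (any(sd <= 0)) {
    stop("iwres: residual SD is zero at an individual prediction; weighting is ill-posed",
         call. = FALSE)
  }
  data.frame(obs, ipred = ipred, iwres = (obs$observed - ipred) / sd)
}

#' Normalized prediction distribution errors (NPDE)
#'
#' For each subject, simulates `n_sim` replicate observation vectors under
#' the (fitted) population model, decorrelates both the observed and the
#' simulated vectors with the inverse lower Cholesky factor of the empirical
#' simulation covariance, and converts the rank of each decorrelated
#' observation among its decorrelated replicates into a normal score. The
#' rank probability uses the correction `(rank + 0.5) / (n_sim + 1)`
#' throughout (ties counted as half), which keeps the extreme values finite.
#' Under a correct model the NPDE are standard normal.
#'
#' @param fit An `saem_fit` or [population_model()].
#' @param dataset The dataset (retained serum observations are used).
#' @param n_sim Number of Monte-Carlo replicates (default 500, minimum 50).
#' @param seed Integer seed.
#' @return Data frame with columns `ID, time, observed, npde`, one row per
#'   retained serum observation.
#' @export
npde <- function(fit, dataset, n_sim = 500L, seed = 1L) {
  if (n_sim < 50L) stop("npde: n_sim must be at least 50", call. = FALSE)
  fl <- .fitlike(fit)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  obs <- .retained_obs(dataset)
  out <- numeric(nrow(obs))
  for (id in unique(obs$ID)) {
    sel <- which(obs$ID == id)
    sdat <- .subject_data(dataset, id)
    times <- obs$time[sel]
    sims <- .simulate_replicates(fl$pop, fl$structural, sdat$regimen, times, n_sim)
    mu <- colMeans(sims)
    V <- stats::cov(sims)
    L <- tryCatch(t(chol(V)), error = function(e) {
      stop("npde: simulation covariance is singular (duplicate times or too few ",
           "replicates); increase n_sim", call. = FALSE)
    })
    y_dec <- forwardsolve(L, obs$observed[sel] - mu)
    sim_dec <- forwardsolve(L, t(sims) - mu)   # n_t x n_sim
    cnt <- rowSums(sim_dec < y_dec) + 0.5 * rowSums(sim_dec == y_dec)
    pde <- (cnt + 0.5) / (n_sim + 1)
    out[sel] <- stats::qnorm(pde)
  }
  data.frame(obs, npde = out)
}

#' Monte-Carlo prediction bands
#'
#' Pointwise percentiles of `n_sim` population profiles simulated with both
#' inter-individual variability and residual noise, on a time grid. These are
#' the prediction distributions used to judge whether the model reproduces
#' the observed variability.
#'
#' @param fit An `saem_fit` or [population_model()].
#' @param regimen A [dosing_regimen()].
#' @param grid Time grid (h), non-empty.
#' @param n_sim Number of simulated profiles (default 500).
#' @param percentiles Percentiles in (0, 100); default 5, 50, 95.
#' @param seed Integer seed.
#' @return Data frame with column `time` and one `pct_<p>` column per
#'   requested percentile (nested by construction).
#' @export
prediction_bands <- function(fit, regimen, grid, n_sim = 500L,
                             percentiles = c(5, 50, 95), seed = 1L) {
  fl <- .fitlike(fit)
  if (length(grid) == 0L) stop("prediction_bands: grid must be non-empty", call. = FALSE)
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("prediction_bands: percentiles must lie strictly between 0 and 100",
         call. = FALSE)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sims <- .simulate_replicates(fl$pop, fl$structural, regimen, grid, n_sim)
  qs <- apply(sims, 2L, stats::quantile, probs = sort(percentiles) / 100,
              type = 7, names = FALSE)
  qs <- matrix(qs, nrow = length(percentiles))
  out <- data.frame(time = grid, t(qs))
  names(out)[-1] <- paste0("pct_", sort(percentiles))
  out
}

#' Observed versus predicted table
#'
#' One row per retained serum observation with the population prediction
#' (random effects at zero), the individual (post-hoc) prediction, and the
#' observation -- the table behind identity-line goodness-of-fit plots.
#' Log-scale columns are included for positive values (zeros are left NA on
#' the log scale).
#'
#' @param fit An `saem_fit` or [population_model()].
#' @param dataset The dataset.
#' @param n Posterior draws per subject for individual predictions.
#' @param seed Integer seed.
#' @return Data frame with columns
#'   `ID, time, observed, pred, ipred, log_observed, log_pred, log_ipred`.
#' @export
observed_vs_predicted <- function(fit, dataset, n = 500L, seed = 1L) {
  fl <- .fitlike(fit)
  model <- .model_def(fl$structural)
  iw <- iwres(fit, dataset, n = n, seed = seed)
  pred <- numeric(nrow(iw))
  for (id in unique(iw$ID)) {
    sdat <- .subject_data(dataset, id)
    sel <- iw$ID == id
    pred[sel] <- .profile_vec(as.numeric(fl$pop$theta), sdat$regimen,
                              iw$time[sel], model)
  }
  out <- data.frame(ID = iw$ID, time = iw$time, observed = iw$observed,
                    pred = pred, ipred = iw$ipred)
  out$log_observed <- ifelse(out$observed > 0, log10(out$observed), NA_real_)
  out$log_pred <- ifelse(out$pred > 0, log10(out$pred), NA_real_)
  out$log_ipred <- ifelse(out$ipred > 0, log10(out$ipred), NA_real_)
  out
}
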