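# Post-hoc (conditional) individual parameter estimation and the
# five-number summaries of the individual estimates.

# Accept either a fitted object or a population model wherever only the
# population parameters are needed.
.fitlike <- function(x) {
  if (inherits(x, "saem_fit")) {
    list(pop = x$pop_hat, structural = x$structural)
  } else if (inherits(x, "population_model") || inherits(x, "population_list")) {
    list(pop = x, structural = if (length(x$theta) == 3L) "one_cmt" else "two_cmt")
  } else {
    stop("expected an 'saem_fit' or a 'population_model'", call. = FALSE)
  }
}

# per-subject observation/dosing extraction (estimation subset: valid serum,
# post first dose)
.subject_data <- function(dataset, subject) {
  rows <- dataset[dataset$ID == subject, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("subject '%s' not found in dataset", subject), call. = FALSE)
  }
  doses <- rows[rows$EVID == 1L, , drop = FALSE]
  if (nrow(doses) == 0L) {
    stop(sprintf("subject '%s' has no dose records", subject), call. = FALSE)
  }
  doses <- doses[order(doses$TIME), , drop = FALSE]
  obs <- rows[rows$EVID == 0L & rows$MATRIX == "serum" & rows$VALID == 1L &
                rows$TIME > min(doses$TIME), , drop = FALSE]
  list(regimen = dosing_regimen(doses$TIME, doses$AMT),
       time = obs$TIME, conc = obs$DV)
}

#' Conditional (posterior) samples of one subject's random effects
#'
#' Draws from `p(eta | subject data, theta-hat)` by random-walk
#' Metropolis-Hastings, with scale adaptation toward 30% acceptance during
#' burn-in. For a subject with dose records but no retained serum
#' observations the posterior equals the prior and draws are taken from
#' `N(0, omega^2)` directly.
#'
#' @param fit An `saem_fit` or a [population_model()].
#' @param dataset The dataset containing the subject.
#' @param subject Subject ID.
#' @param n Number of retained draws (default 500).
#' @param seed Integer seed.
#' @param burn_in Burn-in iterations (default 200).
#' @return An `n` x (active effects) matrix of eta draws, with the MH
#'   acceptance rate attached as attribute `"acceptance"`.
#' @export
conditional_samples <- function(fit, dataset, subject, n = 500L, seed = 1L,
                                burn_in = 200L) {
  fl <- .fitlike(fit)
  pop <- fl$pop
  act <- which(pop$iiv)
  n_act <- length(act)
  sdat <- .subject_data(dataset, subject)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (n_act == 0L) {
    out <- matrix(0, n, 0)
    attr(out, "acceptance") <- NA_real_
    return(out)
  }
  omega <- pop$omega[act]
  if (length(sdat$time) == 0L) {
    out <- matrix(stats::rnorm(n * n_act, 0, rep(omega, each = n)), n, n_act)
    colnames(out) <- names(pop$theta)[act]
    attr(out, "acceptance") <- NA_real_
    return(out)
  }
  ll_of <- .subject_loglik_fun(pop, fl$structural, sdat, act)
  eta <- rep(0, n_act)
  ll <- ll_of(eta)
  scale <- pmax(omega, 0.05)
  out <- matrix(NA_real_, n, n_act)
  acc_count <- 0L; tot <- 0L
  for (k in seq_len(burn_in + n)) {
    # independence kernel: propose from the prior (densities cancel)
    eta_p <- stats::rnorm(n_act, 0, omega)
    ll_p <- ll_of(eta_p)
    if (log(stats::runif(1)) < (ll_p - ll)) { eta <- eta_p; ll <- ll_p }
    for (j in seq_len(n_act)) {
      eta_p <- eta
      eta_p[j] <- eta[j] + stats::rnorm(1, 0, scale[j])
      ll_p <- ll_of(eta_p)
      la <- (ll_p - ll) + (eta[j]^2 - eta_p[j]^2) / (2 * omega[j]^2)
      acc <- log(stats::runif(1)) < la
      if (acc) { eta <- eta_p; ll <- ll_p }
      if (k <= burn_in) {
        scale[j] <- min(5, max(1e-3, scale[j] * exp((acc - 0.3) / sqrt(k))))
      } else {
        acc_count <- acc_count + acc; tot <- tot + 1L
      }
    }
    if (k > burn_in) out[k - burn_in, ] <- eta
  }
  colnames(out) <- names(pop$theta)[act]
  attr(out, "acceptance") <- acc_count / tot
  out
}

.spread_eta <- function(eta, act, npar) {
  full <- numeric(npar)
  full[act] <- eta
  full
}

# data log-likelihood of one subject as a function of the active eta vector
.subject_loglik_fun <- function(pop, structural, sdat, act) {
  theta <- pop$theta
  model <- .model_def(structural)
  a2 <- pop$error$a^2; b2 <- pop$error$b^2
  function(eta) {
    psi <- theta * exp(.spread_eta(eta, act, length(theta)))
    f <- .profile_vec(psi, sdat$regimen, sdat$time, model)
    sd <- sqrt(a2 + b2 * f^2)
    sum(stats::dnorm(sdat$conc, f, sd, log = TRUE))
  }
}

# profile for an arbitrary parameter vector under the registered structural
# models (concentration_profile covers the one-compartment case only)
.profile_vec <- function(psi, regimen, times, model) {
  prep1 <- list(obs_id = rep(1L, length(times)),
                tau = outer(times, regimen$time, "-"),
                DA = matrix(regimen$amount, length(times), nrow(regimen), byrow = TRUE))
  prep1$tau_active <- prep1$tau > 0
  prep1$tau[!prep1$tau_active] <- 0
  prep1$DA <- prep1$DA * prep1$tau_active
  model$pred(matrix(psi, 1L), prep1)
}

#' Post-hoc individual parameter estimates
#'
#' Conditional mean of each individual parameter per subject, computed by
#' transforming posterior eta draws through the lognormal link and averaging
#' (`mode = "mean"`), or by transforming the posterior modal eta
#' (`mode = "mode"`). Parameters without IIV return the population estimate
#' exactly. Posterior standard deviations are included.
#'
#' @param fit An `saem_fit` or [population_model()].
#' @param dataset The dataset.
#' @param n Draws per subject (default 500).
#' @param seed Integer seed (per-subject seeds are derived from it).
#' @param mode `"mean"` (default) or `"mode"`.
#' @return A data frame of class `individual_estimates`: one row per subject,
#'   columns `ID`, the parameters, and `sd_<parameter>` posterior SDs.
#' @export
individual_estimates <- function(fit, dataset, n = 500L, seed = 1L,
                                 mode = c("mean", "mode")) {
  mode <- match.arg(mode)
  fl <- .fitlike(fit)
  pop <- fl$pop
  theta <- pop$theta
  act <- which(pop$iiv)
  ids <- unique(dataset$ID)
  pnames <- names(theta)
  est <- matrix(rep(theta, each = length(ids)), length(ids), length(theta),
                dimnames = list(NULL, pnames))
  psd <- matrix(0, length(ids), length(theta),
                dimnames = list(NULL, paste0("sd_", pnames)))
  if (length(act)) {
    for (i in seq_along(ids)) {
      draws <- conditional_samples(fit, dataset, ids[i], n = n,
                                   seed = seed + i)
      psi_draws <- sweep(exp(draws), 2L, theta[act], "*")
      if (mode == "mean") {
        est[i, act] <- colMeans(psi_draws)
      } else {
        # MAP: maximize the conditional posterior, started from the mean draw
        sdat <- .subject_data(dataset, ids[i])
        ll_of <- .subject_loglik_fun(pop, fl$structural, sdat, act)
        omega <- pop$omega[act]
        neg_post <- function(eta) -(ll_of(eta) - sum(eta^2 / (2 * omega^2)))
        opt <- stats::optim(colMeans(draws), neg_post, method = "BFGS")
        est[i, act] <- theta[act] * exp(opt$par)
      }
      psd[i, act] <- apply(psi_draws, 2L, stats::sd)
    }
  }
  out <- data.frame(ID = ids, est, psd)
  class(out) <- c("individual_estimates", "data.frame")
  out
}

#' Five-number summary of individual estimates
#'
#' Minimum, lower quartile, median, upper quartile and maximum per parameter,
#' with linear-interpolation (type-7) quartiles, mirroring the layout used to
#' report individual serum parameter estimates.
#'
#' @param estimates An [individual_estimates()] data frame, or any data frame
#'   whose non-ID numeric columns are to be summarized.
#' @return A data frame with one row per parameter and columns
#'   `parameter, min, q1, median, q3, max`.
#' @export
five_number_summary <- function(estimates) {
  if (NROW(estimates) < 1L) stop("five_number_summary: empty input", call. = FALSE)
  cols <- setdiff(names(estimates), "ID")
  cols <- cols[!startsWith(cols, "sd_")]
  cols <- cols[vapply(estimates[cols], is.numeric, logical(1))]
  rows <- lapply(cols, function(cn) {
    q <- stats::quantile(estimates[[cn]], c(0, 0.25, 0.5, 0.75, 1),
                         type = 7, names = FALSE)
    data.frame(parameter = cn, min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
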