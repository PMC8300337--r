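# SAEM estimation of the population model.
#
# E-step: componentwise Gaussian random-walk Metropolis-Hastings on the
# subject random effects, with Robbins-Monro scale adaptation toward a target
# acceptance rate during the exploratory phase. SA-step: stochastic
# approximation of the sufficient statistics of the lognormal hierarchy with
# step size 1 (exploration) then 1/(k - K1) (smoothing). M-step: typical
# values and omega^2 from the smoothed statistics; parameters without IIV and
# the residual-error parameters by bounded one-dimensional inner
# optimization, relaxed with the same step size. A simulated-annealing lower
# bound keeps variance components from collapsing early.
#
# All subjects are updated in one vectorized batch per MH proposal, which is
# what makes default-length runs (1200 iterations) cheap.

#' SAEM settings
#'
#' @param n_exploratory Exploration-phase iterations (step size 1); default
#'   1000.
#' @param n_smoothing Smoothing-phase iterations (decreasing step size);
#'   default 200.
#' @param n_chains Number of independent MCMC chains per subject (>= 1,
#'   default 3). The stochastic-approximation statistics average over
#'   chains, which damps the path dependence of the estimates on flat
#'   likelihood ridges and enlarges the stored posterior sample.
#' @param mh_steps_per_iteration Metropolis-Hastings sweeps per iteration
#'   (default 5). Thorough per-iteration mixing matters on nearly flat
#'   likelihood ridges (weakly identified absorption), where an under-mixed
#'   E-step biases the ridge parameter upward.
#' @param target_acceptance Target MH acceptance rate in (0, 1); default 0.3.
#' @param annealing Apply the simulated-annealing lower bound on variance
#'   components during exploration; default TRUE.
#' @param seed Integer seed for the whole fit.
#' @return An object of class `saem_settings`.
#' @export
saem_settings <- function(n_exploratory = 1000L, n_smoothing = 200L,
                          n_chains = 3L, mh_steps_per_iteration = 5L,
                          target_acceptance = 0.3, annealing = TRUE,
                          seed = 12345L) {
  s <- list(n_exploratory = as.integer(n_exploratory),
            n_smoothing = as.integer(n_smoothing),
            n_chains = as.integer(n_chains),
            mh_steps_per_iteration = as.integer(mh_steps_per_iteration),
            target_acceptance = as.numeric(target_acceptance),
            annealing = isTRUE(annealing),
            seed = as.integer(seed))
  counts <- c(s$n_exploratory, s$n_smoothing, s$n_chains, s$mh_steps_per_iteration)
  if (any(counts < 1L)) stop("saem_settings: all counts must be positive integers", call. = FALSE)
  if (s$target_acceptance <= 0 || s$target_acceptance >= 1) {
    stop("saem_settings: target_acceptance must lie in (0, 1)", call. = FALSE)
  }
  structure(s, class = "saem_settings")
}

# ---- structural-model registry ---------------------------------------------
# The one-compartment model is the user-facing fit model; the two-compartment
# alternative exists so BIC-based structural selection can be exercised.

.model_def <- function(structural) {
  switch(structural,
    one_cmt = list(
      names = c("ka", "v", "kel"),
      pred = .pred_rows_onecmt,
      default_iiv = c(ka = TRUE, v = TRUE, kel = FALSE)
    ),
    two_cmt = list(
      names = c("ka", "v", "kel", "k12", "k21"),
      pred = .pred_rows_twocmt,
      default_iiv = c(ka = TRUE, v = TRUE, kel = FALSE, k12 = FALSE, k21 = FALSE)
    ),
    stop("unknown structural model: ", structural, call. = FALSE)
  )
}

# psi: n_subj x npar matrix on the natural scale; prep: see .saem_prep
.pred_rows_onecmt <- function(psi, prep) {
  ka <- psi[prep$obs_id, 1L]
  v <- psi[prep$obs_id, 2L]
  kel <- psi[prep$obs_id, 3L]
  tau <- prep$tau
  act <- prep$tau_active
  f <- (prep$DA / v) * (ka / (ka - kel)) * (exp(-kel * tau) - exp(-ka * tau))
  deg <- abs(ka - kel) < .DEGENERACY_TOL * pmax(ka, kel)
  if (any(deg)) {
    lim <- (prep$DA / v) * kel * tau * exp(-kel * tau)
    f[deg, ] <- lim[deg, ]
  }
  f[!act] <- 0
  pmax(rowSums(f), 0)
}

# triexponential oral two-compartment solution (central concentration)
.pred_rows_twocmt <- function(psi, prep) {
  ka <- psi[prep$obs_id, 1L]
  v <- psi[prep$obs_id, 2L]
  k10 <- psi[prep$obs_id, 3L]
  k12 <- psi[prep$obs_id, 4L]
  k21 <- psi[prep$obs_id, 5L]
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s^2 - 4 * k21 * k10, 0))
  al <- (s + disc) / 2
  be <- (s - disc) / 2
  eps <- 1e-10
  A <- ka * (k21 - al) / (.sg(ka - al, eps) * .sg(be - al, eps))
  B <- ka * (k21 - be) / (.sg(ka - be, eps) * .sg(al - be, eps))
  C <- ka * (k21 - ka) / (.sg(al - ka, eps) * .sg(be - ka, eps))
  tau <- prep$tau
  f <- (prep$DA / v) * (A * exp(-al * tau) + B * exp(-be * tau) + C * exp(-ka * tau))
  f[!prep$tau_active] <- 0
  pmax(rowSums(f), 0)
}

# keep denominators away from 0 while preserving sign
.sg <- function(x, eps) sign(x + (x == 0)) * pmax(abs(x), eps)

# ---- dataset preparation ----------------------------------------------------

# Flattens the serum observations into row vectors plus per-row dose matrices
# so a whole-population prediction is one vectorized call. Pre-first-dose
# records are excluded from estimation: their prediction is identically zero,
# which a proportional error term cannot weight.
.saem_prep <- function(dataset) {
  stopifnot(is.data.frame(dataset))
  need <- c("ID", "TIME", "EVID", "AMT", "DV", "MATRIX", "VALID")
  if (!all(need %in% names(dataset))) {
    stop("dataset must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  doses <- dataset[dataset$EVID == 1L, , drop = FALSE]
  if (nrow(doses) == 0L) stop("dataset contains no dose records", call. = FALSE)
  obs <- dataset[dataset$EVID == 0L & dataset$MATRIX == "serum" &
                   dataset$VALID == 1L, , drop = FALSE]
  ids <- unique(dataset$ID)
  first_dose <- vapply(ids, function(i) min(doses$TIME[doses$ID == i]), numeric(1))
  obs <- obs[obs$TIME > first_dose[match(obs$ID, ids)], , drop = FALSE]
  keep_ids <- ids[ids %in% unique(obs$ID)]
  if (length(keep_ids) < length(ids)) {
    obs <- obs[obs$ID %in% keep_ids, , drop = FALSE]
  }
  ids <- keep_ids
  n <- length(ids)
  if (n == 0L) stop("no post-dose serum observations to fit", call. = FALSE)
  nd <- vapply(ids, function(i) sum(doses$ID == i), integer(1))
  maxd <- max(nd)
  DTs <- matrix(Inf, n, maxd)
  DAs <- matrix(0, n, maxd)
  for (i in seq_len(n)) {
    di <- doses[doses$ID == ids[i], , drop = FALSE]
    di <- di[order(di$TIME), , drop = FALSE]
    DTs[i, seq_len(nrow(di))] <- di$TIME
    DAs[i, seq_len(nrow(di))] <- di$AMT
  }
  obs_id <- match(obs$ID, ids)
  tau <- obs$TIME - DTs[obs_id, , drop = FALSE]
  act <- is.finite(tau) & tau > 0
  tau[!act] <- 0
  list(ids = ids, n = n, obs_id = obs_id, t = obs$TIME, y = obs$DV,
       n_obs = nrow(obs), DT = DTs[obs_id, , drop = FALSE],
       DA = DAs[obs_id, , drop = FALSE] * act, tau = tau, tau_active = act,
       n_obs_by_subject = tabulate(obs_id, n))
}

# replicate the prepared data across independent MCMC chains: chain c of
# subject i becomes pseudo-subject i + (c-1)*n
.stack_chains <- function(prep, C) {
  if (C == 1L) return(prep)
  idx <- rep(seq_len(prep$n_obs), C)
  list(ids = prep$ids, n = prep$n * C,
       obs_id = rep(prep$obs_id, C) + rep((seq_len(C) - 1L) * prep$n,
                                          each = prep$n_obs),
       y = rep(prep$y, C),
       DA = prep$DA[idx, , drop = FALSE],
       tau = prep$tau[idx, , drop = FALSE],
       tau_active = prep$tau_active[idx, , drop = FALSE],
       n_obs = prep$n_obs * C)
}

.sd_rows <- function(f, a2, b2) sqrt(a2 + b2 * f * f)

# per-subject data log-likelihood at psi (natural scale)
.ll_by_subject <- function(psi, prep, a2, b2, model) {
  f <- model$pred(psi, prep)
  sd <- .sd_rows(f, a2, b2)
  ll <- stats::dnorm(prep$y, f, sd, log = TRUE)
  as.numeric(rowsum(ll, prep$obs_id, reorder = TRUE))
}

# ---- initialization ---------------------------------------------------------

# Naive starting values from curve features: Kel from the terminal log-linear
# slope of the pooled mean profile, V from dose / peak mean, Ka = 1,
# omega0 = 0.5, proportional residual b0 = 0.2.
.init_population <- function(dataset, structural = "one_cmt",
                             error = error_model("proportional", b = 0.2)) {
  prep <- .saem_prep(dataset)
  means <- tapply(prep$y, prep$t, mean)
  tms <- as.numeric(names(means))
  last_dose <- max(dataset$TIME[dataset$EVID == 1L])
  term <- tms > last_dose & means > 0
  kel0 <- 0.1
  if (sum(term) >= 3) {
    sl <- stats::coef(stats::lm(log(means[term]) ~ tms[term]))[2]
    if (is.finite(sl) && sl < 0) kel0 <- -sl
  }
  amt <- max(dataset$AMT, na.rm = TRUE)
  v0 <- amt / max(means)
  theta <- c(ka = 1, v = as.numeric(v0), kel = as.numeric(kel0))
  if (structural == "two_cmt") theta <- c(theta, k12 = 0.5, k21 = 0.5)
  list(theta = theta, omega = 0.5, error = error)
}

# Accepts a population_model (one-compartment) or a bare list
# (theta, omega-by-name, error, iiv) for the extended models.
.pop0_to_state <- function(pop0, model, structural) {
  npar <- length(model$names)
  if (inherits(pop0, "population_model")) {
    if (structural != "one_cmt") {
      stop("population_model objects describe the one-compartment model; ",
           "pass a list(theta=, omega=, error=, iiv=) for other structures",
           call. = FALSE)
    }
    theta <- pop0$theta
    omega <- pop0$omega
    iiv <- pop0$iiv
    error <- pop0$error
  } else {
    theta <- pop0$theta[model$names]
    if (anyNA(theta)) stop("pop0$theta must name: ", paste(model$names, collapse = ", "),
                           call. = FALSE)
    iiv <- if (!is.null(pop0$iiv)) pop0$iiv[model$names] else model$default_iiv
    iiv[is.na(iiv)] <- FALSE
    om <- rep(0, npar); names(om) <- model$names
    if (!is.null(pop0$omega)) {
      if (is.null(names(pop0$omega)) && length(pop0$omega) == 1L) {
        om[iiv] <- pop0$omega
      } else {
        om[names(pop0$omega)] <- pop0$omega
      }
    } else om[iiv] <- 0.5
    omega <- om
    error <- if (!is.null(pop0$error)) pop0$error else error_model("combined", 0.01, 0.2)
  }
  if (any(theta <= 0) || any(!is.finite(theta))) {
    stop("initial theta must be strictly positive and finite", call. = FALSE)
  }
  list(mu = log(theta), act = which(iiv), iiv = iiv,
       omega2 = pmax(omega[iiv]^2, 1e-4), error = error)
}

# ---- the fit ----------------------------------------------------------------

#' Fit the population model by SAEM
#'
#' Stochastic approximation EM with a Metropolis-Hastings E-step on the
#' subject random effects. Only valid post-first-dose serum observations
#' enter the fit. Returns population estimates, full iteration traces, stored
#' posterior eta samples from the smoothing phase, the importance-sampling
#' marginal log-likelihood, BIC, and Louis-identity relative standard errors.
#'
#' @param dataset A long-format dataset (see [read_dataset()] /
#'   [generate_study()]).
#' @param pop0 Initial [population_model()] (its `iiv` flags select which
#'   parameters carry random effects). `NULL` uses data-derived naive
#'   starting values with IIV on `ka` and `v`.
#' @param settings A [saem_settings()].
#' @param structural `"one_cmt"` (the fit model) or `"two_cmt"` (structural
#'   alternative retained for BIC comparison).
#' @param compute_loglik Estimate the marginal log-likelihood / BIC / RSEs at
#'   the end (default TRUE).
#' @param n_is Importance-sampling draws for the log-likelihood.
#' @return An object of class `saem_fit` with elements `pop_hat`, `traces`,
#'   `eta_samples`, `loglik`, `bic`, `rse`, `converged`, `settings`,
#'   `structural`, and bookkeeping needed by the diagnostic functions.
#' @examples
#' \donttest{
#' d <- generate_study(study_design(n_subjects = 12),
#'                     population_model(c(ka = 10.3, v = 108, kel = 0.0253),
#'                                      omega = c(ka = 0.2, v = 0.2, kel = 0),
#'                                      error = error_model("proportional", b = 0.1)),
#'                     seed = 7)
#' fit <- fit_saem(d, settings = saem_settings(200, 100, seed = 7))
#' fit$pop_hat$theta
#' }
#' @export
fit_saem <- function(dataset, pop0 = NULL, settings = saem_settings(),
                     structural = c("one_cmt", "two_cmt"),
                     compute_loglik = TRUE, n_is = 1000L) {
  structural <- match.arg(structural)
  stopifnot(inherits(settings, "saem_settings"))
  model <- .model_def(structural)
  prep <- .saem_prep(dataset)
  if (prep$n < 2L || any(prep$n_obs_by_subject < 2L)) {
    stop("fit_saem: need at least 2 subjects with at least 2 post-dose serum observations each",
         call. = FALSE)
  }
  if (is.null(pop0)) pop0 <- .init_population(dataset, structural)
  st <- .pop0_to_state(pop0, model, structural)
  n_act <- length(st$act)
  if (prep$n <= n_act) {
    stop("fit_saem: fewer subjects than random effects; estimation is not identifiable",
         call. = FALSE)
  }

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(settings$seed)

  npar <- length(model$names)
  K1 <- settings$n_exploratory
  K2 <- settings$n_smoothing
  C <- settings$n_chains
  cprep <- .stack_chains(prep, C)
  n <- cprep$n # pseudo-subjects: real subjects x chains
  kind <- st$error$kind
  a2 <- max(st$error$a^2, if (kind != "proportional") 1e-8 else 0)
  b2 <- max(st$error$b^2, if (kind != "additive") 1e-8 else 0)
  mu <- st$mu
  omega2 <- st$omega2
  act <- st$act
  inact <- setdiff(seq_len(npar), act)

  psi_of <- function(mu, eta) {
    phi <- matrix(mu, n, npar, byrow = TRUE)
    if (n_act) phi[, act] <- phi[, act] + eta
    exp(phi)
  }

  eta <- matrix(0, n, n_act)
  ll_cur <- .ll_by_subject(psi_of(mu, eta), cprep, a2, b2, model)
  if (any(!is.finite(ll_cur))) {
    stop("fit_saem: non-finite likelihood at the initial values", call. = FALSE)
  }
  prop_scale <- rep(0.4, n_act)

  m1 <- mu[act] # smoothed sufficient statistics (means / raw second moments)
  m2 <- mu[act]^2 + omega2
  trace_names <- c(model$names, if (n_act) paste0("omega_", model$names[act]),
                   "a", "b")
  traces <- matrix(NA_real_, K1 + K2, length(trace_names),
                   dimnames = list(NULL, trace_names))
  save_from <- K1 + 1L
  eta_store <- vector("list", K2)
  mh_sweeps <- settings$mh_steps_per_iteration

  for (k in seq_len(K1 + K2)) {
    gamma <- if (k <= K1) 1 else 1 / (k - K1)

    # E-step. Kernel 1: independence proposal from the prior (prior and
    # proposal densities cancel, so the ratio is the likelihood ratio). This
    # keeps the sampler anchored where the data are uninformative and a pure
    # random walk would drift along flat likelihood ridges.
    if (n_act) {
      eta_prop <- matrix(stats::rnorm(n * n_act), n, n_act) %*%
        diag(sqrt(omega2), n_act)
      ll_prop <- .ll_by_subject(psi_of(mu, eta_prop), cprep, a2, b2, model)
      accept <- log(stats::runif(n)) < (ll_prop - ll_cur)
      if (any(accept)) {
        eta[accept, ] <- eta_prop[accept, , drop = FALSE]
        ll_cur[accept] <- ll_prop[accept]
      }
      # Kernel 2: componentwise random walk, all subjects in one batch
      for (sweep in seq_len(mh_sweeps)) {
        for (j in seq_len(n_act)) {
          eta_prop <- eta
          eta_prop[, j] <- eta[, j] + stats::rnorm(n, 0, prop_scale[j])
          ll_prop <- .ll_by_subject(psi_of(mu, eta_prop), cprep, a2, b2, model)
          dprior <- (eta[, j]^2 - eta_prop[, j]^2) / (2 * omega2[j])
          accept <- log(stats::runif(n)) < (ll_prop - ll_cur + dprior)
          if (any(accept)) {
            eta[accept, j] <- eta_prop[accept, j]
            ll_cur[accept] <- ll_prop[accept]
          }
          if (k <= K1) {
            rate <- mean(accept)
            prop_scale[j] <- min(5, max(1e-3, prop_scale[j] *
              exp((rate - settings$target_acceptance) / sqrt(k))))
          }
        }
      }
    }

    # SA-step + M-step for the lognormal hierarchy
    if (n_act) {
      phi <- matrix(mu[act], n, n_act, byrow = TRUE) + eta
      m1 <- m1 + gamma * (colMeans(phi) - m1)
      m2 <- m2 + gamma * (colMeans(phi^2) - m2)
      mu[act] <- m1
      om_new <- pmax(m2 - m1^2, 1e-10)
      if (settings$annealing && k <= K1) om_new <- pmax(om_new, 0.95 * omega2)
      omega2 <- om_new
    }

    # M-step for fixed effects without IIV: relaxed 1-D conditional maximization
    for (j in inact) {
      f_j <- function(m) {
        mu2 <- mu; mu2[j] <- m
        sum(.ll_by_subject(psi_of(mu2, eta), cprep, a2, b2, model))
      }
      opt <- stats::optimize(f_j, interval = c(mu[j] - 1.5, mu[j] + 1.5),
                             maximum = TRUE, tol = 1e-4)
      mu[j] <- mu[j] + gamma * (opt$maximum - mu[j])
    }

    # M-step for the residual error parameters
    f_rows <- model$pred(psi_of(mu, eta), cprep)
    r2 <- (cprep$y - f_rows)^2
    if (kind == "additive") {
      a2_star <- mean(r2); b2_star <- 0
    } else if (kind == "proportional") {
      b2_star <- mean(r2 / pmax(f_rows^2, 1e-12)); a2_star <- 0
    } else {
      nll <- function(a2c, b2c) {
        s2 <- a2c + b2c * f_rows^2
        0.5 * sum(log(s2) + r2 / s2)
      }
      a2_star <- stats::optimize(function(x) nll(x, b2), c(1e-12, max(r2) + 1e-8))$minimum
      b2_star <- stats::optimize(function(x) nll(a2_star, x), c(1e-12, 4))$minimum
    }
    if (kind != "proportional") {
      a2_new <- a2 + gamma * (a2_star - a2)
      if (settings$annealing && k <= K1) a2_new <- max(a2_new, 0.95 * a2)
      a2 <- max(a2_new, 1e-12)
    }
    if (kind != "additive") {
      b2_new <- b2 + gamma * (b2_star - b2)
      if (settings$annealing && k <= K1) b2_new <- max(b2_new, 0.95 * b2)
      b2 <- max(b2_new, 1e-12)
    }
    ll_cur <- .ll_by_subject(psi_of(mu, eta), cprep, a2, b2, model)

    traces[k, ] <- c(exp(mu), if (n_act) sqrt(omega2), sqrt(a2), sqrt(b2))
    if (k >= save_from) eta_store[[k - K1]] <- eta
  }

  eta_samples <- if (n_act) {
    arr <- array(unlist(eta_store, use.names = FALSE), dim = c(n, n_act, K2))
    arr <- aperm(arr, c(3, 1, 2)) # iterations x pseudo-subjects x effects
    # interleave chains along the draw dimension: draws = iterations x chains
    out <- array(NA_real_, dim = c(K2 * C, prep$n, n_act),
                 dimnames = list(NULL, NULL, model$names[act]))
    for (cc in seq_len(C)) {
      out[((cc - 1L) * K2 + 1L):(cc * K2), , ] <-
        arr[, ((cc - 1L) * prep$n + 1L):(cc * prep$n), , drop = FALSE]
    }
    out
  } else {
    array(0, dim = c(K2 * C, prep$n, 0))
  }

  est_cols <- .estimated_trace_cols(kind, model, act)
  converged <- .check_convergence(traces, est_cols, 100L)

  theta_hat <- stats::setNames(exp(mu), model$names)
  omega_hat <- stats::setNames(rep(0, npar), model$names)
  if (n_act) omega_hat[act] <- sqrt(omega2)
  err_hat <- .rebuild_error(kind, sqrt(a2), sqrt(b2))

  pop_hat <- if (structural == "one_cmt") {
    population_model(theta = theta_hat, omega = omega_hat, error = err_hat,
                     iiv = st$iiv)
  } else {
    structure(list(theta = theta_hat, omega = omega_hat, corr = NULL,
                   error = err_hat, iiv = st$iiv), class = "population_list")
  }

  fit <- structure(list(
    pop_hat = pop_hat, structural = structural, model_names = model$names,
    active = model$names[act], traces = as.data.frame(traces),
    eta_samples = eta_samples, settings = settings, converged = converged,
    ids = prep$ids, n_obs = prep$n_obs, prop_scale = prop_scale,
    loglik = NA_real_, bic = NA_real_, rse = NULL,
    n_estimated = npar + n_act + if (kind == "combined") 2L else 1L
  ), class = "saem_fit")

  if (compute_loglik) {
    fit$loglik <- loglik_importance_sampling(fit, dataset, n_is = n_is,
                                             seed = settings$seed + 1L)
    fit$bic <- bic(fit$loglik, fit$n_estimated, dataset)
    fit$rse <- tryCatch(standard_errors(fit, dataset),
                        error = function(e) {
                          warning("standard errors unavailable: ",
                                  conditionMessage(e), call. = FALSE)
                          NULL
                        })
  }
  fit
}

.estimated_trace_cols <- function(kind, model, act) {
  c(model$names, if (length(act)) paste0("omega_", model$names[act]),
    if (kind != "proportional") "a", if (kind != "additive") "b")
}

.rebuild_error <- function(kind, a, b) {
  switch(kind,
         additive = error_model("additive", a = a, b = 0),
         proportional = error_model("proportional", a = 0, b = b),
         error_model("combined", a = a, b = b))
}

# relative change of every estimated quantity over the final window
.check_convergence <- function(traces, cols, window = 100L) {
  k <- nrow(traces)
  window <- min(window, k)
  tail_block <- traces[(k - window + 1L):k, cols, drop = FALSE]
  rel <- apply(tail_block, 2L, function(x) {
    fin <- abs(x[length(x)])
    if (fin < 1e-12) return(max(x) - min(x))
    (max(x) - min(x)) / fin
  })
  all(rel < 1e-3)
}

#' @export
print.saem_fit <- function(x, ...) {
  cat(sprintf("SAEM fit (%s), %d subjects, %d serum observations\n",
              x$structural, length(x$ids), x$n_obs))
  th <- x$pop_hat$theta
  om <- x$pop_hat$omega
  for (nm in names(th)) {
    rse <- if (!is.null(x$rse) && nm %in% names(x$rse)) sprintf(" (RSE %.3g%%)", x$rse[nm]) else ""
    cat(sprintf("  %-4s = %#.3g%s%s\n", nm, th[nm], rse,
                if (om[nm] > 0) sprintf("  [omega = %.3g]", om[nm]) else ""))
  }
  cat(sprintf("  error: %s (a = %.4g, b = %.4g)\n", x$pop_hat$error$kind,
              x$pop_hat$error$a, x$pop_hat$error$b))
  if (is.finite(x$loglik)) {
    cat(sprintf("  loglik = %.2f, BIC = %.2f\n", x$loglik, x$bic))
  }
  cat(sprintf("  converged: %s\n", x$converged))
  invisible(x)
}
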