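# Post-fit inference: importance-sampling marginal log-likelihood, BIC,
# Louis-identity standard errors, and posterior parameter correlations.

# shared unpacking of a fit for likelihood work
.fit_internals <- function(fit, dataset) {
  model <- .model_def(fit$structural)
  prep <- .saem_prep(dataset)
  if (!identical(as.vector(prep$ids), as.vector(fit$ids))) {
    stop("dataset does not match the one the model was fitted to", call. = FALSE)
  }
  pop <- fit$pop_hat
  act <- match(fit$active, model$names)
  list(model = model, prep = prep, mu = log(pop$theta),
       act = act, omega2 = pop$omega[act]^2,
       a2 = pop$error$a^2, b2 = pop$error$b^2)
}

.psi_from_eta <- function(mu, eta, act, n, npar) {
  phi <- matrix(mu, n, npar, byrow = TRUE)
  if (length(act)) phi[, act] <- phi[, act] + eta
  exp(phi)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Marginal log-likelihood by importance sampling
#'
#' Estimates the marginal log-likelihood of the fitted model by importance
#' sampling, with a per-subject independent Gaussian proposal matched to the
#' moments of the stored posterior eta samples. Subjects' contributions are
#' summed. With no active random effects the integral is degenerate and the
#' conditional log-likelihood at the estimates is returned exactly.
#'
#' @param fit An `saem_fit`.
#' @param dataset The dataset the model was fitted to.
#' @param n_is Number of importance-sampling draws (default 1000).
#' @param seed Integer seed.
#' @return The estimated marginal log-likelihood (scalar).
#' @export
loglik_importance_sampling <- function(fit, dataset, n_is = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "saem_fit"))
  fi <- .fit_internals(fit, dataset)
  n <- fi$prep$n
  npar <- length(fi$model$names)
  n_act <- length(fi$act)
  if (n_act == 0L) {
    psi <- .psi_from_eta(fi$mu, NULL, integer(0), n, npar)
    return(sum(.ll_by_subject(psi, fi$prep, fi$a2, fi$b2, fi$model)))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  # proposal moments from the stored posterior draws
  m <- apply(fit$eta_samples, c(2, 3), mean)
  s <- apply(fit$eta_samples, c(2, 3), stats::sd)
  m <- matrix(m, n, n_act); s <- matrix(s, n, n_act)
  prior_sd <- matrix(sqrt(fi$omega2), n, n_act, byrow = TRUE)
  degen <- !is.finite(s) | s < 1e-8
  if (any(degen)) {
    # degenerate proposal: fall back to prior-based sampling for those entries
    m[degen] <- 0
    s[degen] <- prior_sd[degen]
  }
  logw <- matrix(NA_real_, n_is, n)
  for (d in seq_len(n_is)) {
    z <- matrix(stats::rnorm(n * n_act), n, n_act)
    eta_d <- m + s * z
    psi <- .psi_from_eta(fi$mu, eta_d, fi$act, n, npar)
    ll <- .ll_by_subject(psi, fi$prep, fi$a2, fi$b2, fi$model)
    lprior <- rowSums(stats::dnorm(eta_d, 0, prior_sd, log = TRUE))
    lq <- rowSums(stats::dnorm(eta_d, m, s, log = TRUE))
    logw[d, ] <- ll + lprior - lq
  }
  sum(apply(logw, 2L, .logsumexp) - log(n_is))
}

#' Bayesian information criterion
#'
#' `-2 * loglik + k * log(N)` where `N` is the number of valid serum
#' observation records in the dataset (the convention used throughout this
#' package; other pharmacometric platforms split N between fixed and random
#' parts, but no reference values exist to match). Lower is better.
#'
#' @param loglik Marginal log-likelihood.
#' @param n_fixed_plus_random_params Total number of estimated parameters
#'   (fixed effects + variance components + residual parameters).
#' @param dataset The fitted dataset (supplies N).
#' @return The BIC (scalar).
#' @examples
#' # with 149 observations: -2*(-100) + 5*log(149)
#' @export
bic <- function(loglik, n_fixed_plus_random_params, dataset) {
  k <- as.integer(n_fixed_plus_random_params)
  if (k <= 0) stop("bic: parameter count must be positive", call. = FALSE)
  N <- sum(dataset$EVID == 0L & dataset$MATRIX == "serum" & dataset$VALID == 1L)
  if (N <= 0) stop("bic: dataset has no valid serum observations", call. = FALSE)
  -2 * loglik + k * log(N)
}

#' Relative standard errors of the fixed effects
#'
#' Assembles the observed Fisher information of the fixed effects (on the
#' log scale) by Louis' identity from the stored posterior eta samples:
#' `I = sum_i ( -E[H_i | y_i] - E[s_i s_i' | y_i] + E[s_i|y_i] E[s_i|y_i]' )`.
#' For parameters with IIV the complete-data score is analytic
#' (`eta / omega^2`); for parameters without IIV it is obtained by central
#' finite differences of the data log-likelihood. RSE% = 100 * SE(log theta),
#' which equals 100 * SE(theta) / theta by the delta method.
#'
#' @param fit An `saem_fit` with stored eta samples.
#' @param dataset The fitted dataset.
#' @param n_draws Maximum number of posterior draws used (default 100,
#'   thinned evenly from the stored smoothing-phase draws).
#' @return Named vector of RSE percentages, one per fixed effect.
#' @export
standard_errors <- function(fit, dataset, n_draws = 100L) {
  stopifnot(inherits(fit, "saem_fit"))
  fi <- .fit_internals(fit, dataset)
  model <- fi$model; prep <- fi$prep
  n <- prep$n; npar <- length(model$names)
  act <- fi$act
  inact <- setdiff(seq_len(npar), act)
  R_avail <- dim(fit$eta_samples)[1]
  take <- unique(round(seq(1L, R_avail, length.out = min(n_draws, R_avail))))
  R <- length(take)
  h <- 1e-3

  Es <- matrix(0, n, npar)           # E[s_i]
  Ess <- array(0, c(n, npar, npar))  # E[s_i s_i']
  EH <- array(0, c(n, npar, npar))   # E[H_i]
  for (r in take) {
    eta_r <- if (length(act)) matrix(fit$eta_samples[r, , ], n, length(act)) else NULL
    s_r <- matrix(0, n, npar)
    H_r <- array(0, c(n, npar, npar))
    if (length(act)) {
      s_r[, act] <- sweep(eta_r, 2L, fi$omega2, "/")
      for (j in seq_along(act)) H_r[, act[j], act[j]] <- -1 / fi$omega2[j]
    }
    if (length(inact)) {
      ll0 <- .ll_by_subject(.psi_from_eta(fi$mu, eta_r, act, n, npar),
                            prep, fi$a2, fi$b2, model)
      llp <- llm <- list()
      for (j in inact) {
        mup <- fi$mu; mup[j] <- mup[j] + h
        mum <- fi$mu; mum[j] <- mum[j] - h
        llp[[as.character(j)]] <- .ll_by_subject(.psi_from_eta(mup, eta_r, act, n, npar),
                                                 prep, fi$a2, fi$b2, model)
        llm[[as.character(j)]] <- .ll_by_subject(.psi_from_eta(mum, eta_r, act, n, npar),
                                                 prep, fi$a2, fi$b2, model)
        s_r[, j] <- (llp[[as.character(j)]] - llm[[as.character(j)]]) / (2 * h)
        H_r[, j, j] <- (llp[[as.character(j)]] - 2 * ll0 + llm[[as.character(j)]]) / h^2
      }
      if (length(inact) > 1L) {
        for (a_ in seq_along(inact)[-length(inact)]) {
          for (b_ in (a_ + 1L):length(inact)) {
            j <- inact[a_]; l <- inact[b_]
            mupp <- fi$mu; mupp[c(j, l)] <- mupp[c(j, l)] + h
            mupm <- fi$mu; mupm[j] <- mupm[j] + h; mupm[l] <- mupm[l] - h
            mump <- fi$mu; mump[j] <- mump[j] - h; mump[l] <- mump[l] + h
            mumm <- fi$mu; mumm[c(j, l)] <- mumm[c(j, l)] - h
            cross <- (.ll_by_subject(.psi_from_eta(mupp, eta_r, act, n, npar), prep, fi$a2, fi$b2, model) -
                      .ll_by_subject(.psi_from_eta(mupm, eta_r, act, n, npar), prep, fi$a2, fi$b2, model) -
                      .ll_by_subject(.psi_from_eta(mump, eta_r, act, n, npar), prep, fi$a2, fi$b2, model) +
                      .ll_by_subject(.psi_from_eta(mumm, eta_r, act, n, npar), prep, fi$a2, fi$b2, model)) / (4 * h^2)
            H_r[, j, l] <- H_r[, l, j] <- cross
          }
        }
      }
    }
    Es <- Es + s_r / R
    for (i in seq_len(n)) {
      Ess[i, , ] <- Ess[i, , ] + tcrossprod(s_r[i, ]) / R
      EH[i, , ] <- EH[i, , ] + H_r[i, , ] / R
    }
  }
  I <- matrix(0, npar, npar)
  for (i in seq_len(n)) {
    I <- I + (-EH[i, , ] - Ess[i, , ] + tcrossprod(Es[i, ]))
  }
  V <- tryCatch(solve(I), error = function(e) NULL)
  if (is.null(V) || any(diag(V) <= 0)) {
    worst <- model$names[which.min(diag(I))]
    stop(sprintf("standard_errors: information matrix is singular; parameter '%s' appears non-identifiable",
                 worst), call. = FALSE)
  }
  rse <- 100 * sqrt(diag(V))
  stats::setNames(rse, model$names)
}

#' Random-effect correlations across subjects
#'
#' Pearson correlation, across subjects, of the posterior-mean random effects
#' per parameter, together with pairwise Pearson test p-values. Used to
#' decide whether correlations between model parameters should enter the
#' model.
#'
#' @param fit An `saem_fit` with at least two active random effects.
#' @return A list with `correlation` (symmetric matrix, unit diagonal),
#'   `p_values` (matrix, NA on the diagonal), and `eta_mean` (the
#'   subject-by-effect matrix of posterior means).
#' @export
eta_correlations <- function(fit) {
  stopifnot(inherits(fit, "saem_fit"))
  n_act <- dim(fit$eta_samples)[3]
  if (n_act < 2L) {
    stop("eta_correlations: at least two active random effects are required", call. = FALSE)
  }
  n <- dim(fit$eta_samples)[2]
  if (n < 2L) stop("eta_correlations: correlation is undefined for a single subject",
                   call. = FALSE)
  eta_mean <- apply(fit$eta_samples, c(2, 3), mean)
  colnames(eta_mean) <- fit$active
  cm <- stats::cor(eta_mean)
  diag(cm) <- 1
  pm <- matrix(NA_real_, n_act, n_act, dimnames = dimnames(cm))
  for (a_ in seq_len(n_act - 1L)) {
    for (b_ in (a_ + 1L):n_act) {
      pv <- stats::cor.test(eta_mean[, a_], eta_mean[, b_])$p.value
      pm[a_, b_] <- pm[b_, a_] <- pv
    }
  }
  list(correlation = cm, p_values = pm, eta_mean = eta_mean)
}
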