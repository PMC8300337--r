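# Hierarchical layer: population typical values, lognormal inter-individual
# variability (IIV), residual error model, and subject-level simulation.

.PARAM_NAMES <- c("ka", "v", "kel")

#' Residual error model
#'
#' Residual standard deviation as a function of the model prediction `f`:
#' additive (`a`), proportional (`b * f`), or combined
#' (`sqrt(a^2 + (b*f)^2)`).
#'
#' @param kind One of `"additive"`, `"proportional"`, `"combined"`.
#' @param a Additive SD in ug/mL (>= 0).
#' @param b Proportional SD, dimensionless (>= 0).
#' @return An object of class `error_model`.
#' @examples
#' error_model("combined", a = 0.01, b = 0.18)
#' @export
error_model <- function(kind = c("combined", "additive", "proportional"),
                        a = 0.01, b = 0.18) {
  kind <- match.arg(kind)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!is.finite(a) || a < 0 || !is.finite(b) || b < 0) {
    stop("error_model: a and b must be finite and >= 0", call. = FALSE)
  }
  if (kind == "additive") b <- 0
  if (kind == "proportional") a <- 0
  if (a <= 0 && b <= 0) {
    stop("error_model: at least one of a, b must be strictly positive", call. = FALSE)
  }
  structure(list(kind = kind, a = a, b = b), class = "error_model")
}

#' Residual standard deviation at a prediction
#'
#' @param pred Model prediction(s), ug/mL, >= 0.
#' @param error An [error_model()].
#' @return Residual SD(s), ug/mL.
#' @export
residual_sd <- function(pred, error) {
  stopifnot(inherits(error, "error_model"))
  pred <- as.numeric(pred)
  if (any(!is.finite(pred)) || any(pred < 0)) {
    stop("residual_sd: predictions must be finite and >= 0", call. = FALSE)
  }
  sqrt(error$a^2 + (error$b * pred)^2)
}

#' Population pharmacokinetic model
#'
#' Typical values `theta`, lognormal IIV standard deviations `omega` (log
#' scale), an optional correlation matrix among the active random effects, a
#' residual [error_model()], and per-parameter IIV flags. Individual
#' parameters follow \eqn{\psi_i = \theta\,e^{\eta_i}},
#' \eqn{\eta_i \sim N(0, \Omega)}; parameters with IIV switched off have
#' \eqn{\eta \equiv 0}.
#'
#' @param theta Named numeric vector `c(ka=, v=, kel=)` of typical values,
#'   strictly positive.
#' @param omega Named numeric vector of IIV SDs (log scale, >= 0); missing
#'   names default to 0.
#' @param corr Optional correlation matrix among the *active* random effects
#'   (unit diagonal, symmetric positive definite), in the order of the active
#'   parameters.
#' @param error An [error_model()].
#' @param iiv Named logical vector: which parameters carry IIV. Defaults to
#'   `omega > 0`.
#' @return An object of class `population_model`.
#' @examples
#' population_model(theta = c(ka = 10.3, v = 108, kel = 0.0253),
#'                  omega = c(ka = 0.2, v = 0.2, kel = 0))
#' @export
population_model <- function(theta, omega = c(ka = 0, v = 0, kel = 0),
                             corr = NULL, error = error_model(), iiv = NULL) {
  theta <- .named_param_vec(theta, "theta")
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop("population_model: theta must be strictly positive and finite", call. = FALSE)
  }
  omega <- .named_param_vec(omega, "omega", default = 0)
  if (any(!is.finite(omega)) || any(omega < 0)) {
    stop("population_model: omega must be finite and >= 0", call. = FALSE)
  }
  if (is.null(iiv)) iiv <- omega > 0
  iiv <- .named_param_vec(iiv, "iiv", default = FALSE, logical = TRUE)
  omega[!iiv] <- 0
  stopifnot(inherits(error, "error_model"))
  n_act <- sum(iiv)
  if (!is.null(corr)) {
    corr <- as.matrix(corr)
    if (nrow(corr) != n_act || ncol(corr) != n_act ||
        max(abs(corr - t(corr))) > 1e-12 || any(abs(diag(corr) - 1) > 1e-12)) {
      stop("population_model: corr must be a symmetric matrix with unit diagonal, ",
           "sized to the active random effects", call. = FALSE)
    }
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop("population_model: corr must be positive definite", call. = FALSE)
    }
  }
  structure(list(theta = theta, omega = omega, corr = corr, error = error,
                 iiv = iiv),
            class = "population_model")
}

.named_param_vec <- function(x, what, default = NULL, logical = FALSE) {
  if (is.null(names(x))) {
    if (length(x) == 3L) names(x) <- .PARAM_NAMES
    else stop(sprintf("%s must be named with ka, v, kel", what), call. = FALSE)
  }
  names(x) <- tolower(names(x))
  if (!all(names(x) %in% .PARAM_NAMES)) {
    stop(sprintf("%s names must be among: %s", what,
                 paste(.PARAM_NAMES, collapse = ", ")), call. = FALSE)
  }
  full <- stats::setNames(rep(if (is.null(default)) NA else default, 3L), .PARAM_NAMES)
  full[names(x)] <- x
  if (anyNA(full)) stop(sprintf("%s must specify ka, v and kel", what), call. = FALSE)
  full <- if (logical) as.logical(full) else as.numeric(full)
  stats::setNames(full, .PARAM_NAMES)
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (one-compartment, first-order absorption)\n")
  cat(sprintf("  theta: Ka = %g /h, V = %g L/kg, Kel = %g /h\n",
              x$theta["ka"], x$theta["v"], x$theta["kel"]))
  cat(sprintf("  omega: %s\n",
              paste(sprintf("%s = %g%s", .PARAM_NAMES, x$omega,
                            ifelse(x$iiv, "", " (no IIV)")), collapse = ", ")))
  cat(sprintf("  error: %s (a = %g ug/mL, b = %g)\n",
              x$error$kind, x$error$a, x$error$b))
  if (!is.null(x$corr)) {
    cat("  correlation among random effects:\n")
    print(round(x$corr, 3))
  }
  invisible(x)
}

#' Individual parameters from random effects
#'
#' Applies the lognormal link: each individual parameter equals the typical
#' value times `exp(eta)`; parameters without IIV get `eta = 0`.
#'
#' @param pop A [population_model()].
#' @param eta Numeric vector of random effects on the log scale, of length
#'   equal to the number of active random effects (in the order ka, v, kel
#'   restricted to active ones), or a full named vector over ka, v, kel.
#' @return A [pk_params()] object.
#' @export
individual_params <- function(pop, eta) {
  stopifnot(inherits(pop, "population_model"))
  eta_full <- .expand_eta(pop, eta)
  psi <- pop$theta * exp(eta_full)
  pk_params(psi["ka"], psi["v"], psi["kel"])
}

.expand_eta <- function(pop, eta) {
  eta <- as.numeric(eta)
  if (any(!is.finite(eta))) stop("eta must be finite", call. = FALSE)
  act <- which(pop$iiv)
  eta_full <- stats::setNames(numeric(3L), .PARAM_NAMES)
  if (length(eta) == length(act)) {
    eta_full[act] <- eta
  } else if (length(eta) == 3L) {
    if (any(eta[!pop$iiv] != 0)) {
      stop("eta supplied for parameters without IIV must be 0", call. = FALSE)
    }
    eta_full[] <- eta
  } else {
    stop(sprintf("eta must have length %d (active effects) or 3", length(act)),
         call. = FALSE)
  }
  eta_full
}

#' Conditional log-likelihood of one subject's observations
#'
#' Sum of Gaussian log-densities of the observed concentrations, with mean
#' equal to the multiple-dose model prediction and SD from the residual error
#' model.
#'
#' @param observations Data frame (or list) with components `time` (h) and
#'   `conc` (ug/mL, >= 0).
#' @param params A [pk_params()] object (individual parameters).
#' @param regimen A [dosing_regimen()].
#' @param error An [error_model()].
#' @return The conditional log-likelihood (scalar).
#' @export
loglik_conditional <- function(observations, params, regimen, error) {
  time <- observations$time
  conc <- observations$conc
  if (is.null(time) || is.null(conc) || length(time) == 0L) {
    stop("loglik_conditional: observations must be non-empty with time and conc",
         call. = FALSE)
  }
  if (any(conc < 0)) stop("loglik_conditional: concentrations must be >= 0", call. = FALSE)
  f <- concentration_profile(params, regimen, time)
  sd <- residual_sd(f, error)
  if (any(sd <= 0)) {
    stop("loglik_conditional: residual SD is zero at a prediction; ",
         "use an error model with an additive component", call. = FALSE)
  }
  sum(stats::dnorm(conc, mean = f, sd = sd, log = TRUE))
}

# Cholesky factor of the covariance of the active random effects
.omega_chol <- function(pop) {
  act <- which(pop$iiv)
  if (length(act) == 0L) return(matrix(0, 0, 0))
  sd <- pop$omega[act]
  if (is.null(pop$corr)) {
    diag(sd, nrow = length(act))
  } else {
    Sigma <- diag(sd, nrow = length(act)) %*% pop$corr %*% diag(sd, nrow = length(act))
    L <- tryCatch(t(chol(Sigma)), error = function(e) {
      stop("simulate_subject: random-effect covariance is not positive definite",
           call. = FALSE)
    })
    L
  }
}

#' Simulate one subject's observation vector
#'
#' Draws a random-effect vector from the multivariate normal implied by
#' `omega`/`corr`, computes the multiple-dose profile at `times`, adds
#' residual noise from the error model, and truncates negative values to 0
#' (a simulation artifact only possible at near-zero predictions).
#'
#' @param pop A [population_model()].
#' @param regimen A [dosing_regimen()].
#' @param times Observation times (h).
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `time` and `conc`; the drawn random
#'   effects are attached as attribute `"eta"` and the individual parameters
#'   as attribute `"params"`.
#' @export
simulate_subject <- function(pop, regimen, times, seed = NULL) {
  stopifnot(inherits(pop, "population_model"))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  act <- which(pop$iiv)
  L <- .omega_chol(pop)
  eta <- if (length(act)) as.numeric(L %*% stats::rnorm(length(act))) else numeric(0)
  params <- individual_params(pop, eta)
  f <- concentration_profile(params, regimen, times)
  sd <- residual_sd(f, pop$error)
  conc <- pmax(f + stats::rnorm(length(f), 0, sd), 0)
  out <- data.frame(time = times, conc = conc)
  attr(out, "eta") <- eta
  attr(out, "params") <- params
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
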