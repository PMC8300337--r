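# One-compartment, first-order absorption, linear elimination: closed-form
# predictions under repeated extravascular (intragastric) dosing.
#
# Unit conventions are fixed package-wide: time in hours, dose in mg/kg,
# volume in L/kg, concentration in mg/L (= ug/mL); body weight cancels.

#' Individual pharmacokinetic parameters
#'
#' Bundle of the three structural parameters of the one-compartment
#' extravascular model: first-order absorption rate constant `ka` (1/h),
#' apparent volume of distribution `v` (L/kg, i.e. V_z/F -- bioavailability F
#' is not identifiable from extravascular data and is absorbed into the
#' volume), and first-order elimination rate constant `kel` (1/h).
#'
#' @param ka Absorption rate constant (1/h), strictly positive and finite.
#' @param v Apparent volume of distribution (L/kg), strictly positive.
#' @param kel Elimination rate constant (1/h), strictly positive.
#' @return An object of class `pk_params`.
#' @examples
#' pk_params(ka = 10.3, v = 108, kel = 0.0253)
#' @export
pk_params <- function(ka, v, kel) {
  x <- c(ka = as.numeric(ka), v = as.numeric(v), kel = as.numeric(kel))
  if (length(x) != 3L || any(!is.finite(x)) || any(x <= 0)) {
    stop("pk_params: ka, v and kel must each be a single finite, strictly positive number",
         call. = FALSE)
  }
  structure(as.list(x), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("PK parameters: Ka = %g /h, V = %g L/kg, Kel = %g /h (CL/F = %g L/kg/h)\n",
              x$ka, x$v, x$kel, x$kel * x$v))
  invisible(x)
}

.check_params <- function(params) {
  if (!inherits(params, "pk_params")) {
    if (is.list(params) && all(c("ka", "v", "kel") %in% names(params))) {
      params <- pk_params(params$ka, params$v, params$kel)
    } else {
      stop("expected a 'pk_params' object (see pk_params())", call. = FALSE)
    }
  }
  params
}

#' Extravascular dosing regimen
#'
#' Ordered dose events for one subject: administration times (h) and amounts
#' (mg/kg). Doses are treated as instantaneous gut boluses at the nominal
#' administration times.
#'
#' @param times Dose times in hours, strictly increasing, all >= 0.
#' @param amounts Dose amounts in mg/kg; recycled to the length of `times`.
#' @return An object of class `dosing_regimen`: a data frame with columns
#'   `time` and `amount`.
#' @examples
#' dosing_regimen(times = c(0, 12, 24, 36, 48), amounts = 10)
#' @export
dosing_regimen <- function(times, amounts) {
  times <- as.numeric(times)
  amounts <- rep_len(as.numeric(amounts), length(times))
  if (length(times) < 1L) stop("dosing_regimen: at least one dose event required", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("dosing_regimen: dose times must be finite and >= 0", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("dosing_regimen: dose times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(amounts)) || any(amounts <= 0)) {
    stop("dosing_regimen: dose amounts must be finite and positive", call. = FALSE)
  }
  structure(data.frame(time = times, amount = amounts),
            class = c("dosing_regimen", "data.frame"))
}

# relative difference below which the two-exponential form is replaced by its
# Ka -> Kel limit, avoiding catastrophic cancellation
.DEGENERACY_TOL <- 1e-8

#' Concentration after a single extravascular dose
#'
#' Closed-form (Bateman) solution of the one-compartment model with
#' first-order absorption and linear elimination:
#' \deqn{C(\tau) = \frac{D}{V}\,\frac{K_a}{K_a - K_{el}}
#'   \left(e^{-K_{el}\tau} - e^{-K_a\tau}\right)}
#' with the continuous limit \eqn{(D/V)\,K_{el}\,\tau\,e^{-K_{el}\tau}} used
#' when \eqn{|K_a - K_{el}|} falls below a relative degeneracy threshold.
#'
#' @param params A [pk_params()] object.
#' @param amount Dose in mg/kg (>= 0).
#' @param tau Time since that dose, hours (vectorised, all >= 0).
#' @return Concentration(s) in ug/mL (mg/L); zero at `tau = 0`.
#' @examples
#' p <- pk_params(10.3, 108, 0.0253)
#' concentration_single_dose(p, amount = 10, tau = 2)
#' @export
concentration_single_dose <- function(params, amount, tau) {
  params <- .check_params(params)
  tau <- as.numeric(tau)
  if (any(!is.finite(tau)) || any(tau < 0)) {
    stop("concentration_single_dose: tau must be finite and >= 0", call. = FALSE)
  }
  if (length(amount) != 1L || !is.finite(amount) || amount < 0) {
    stop("concentration_single_dose: amount must be a single finite number >= 0", call. = FALSE)
  }
  .bateman(params$ka, params$v, params$kel, amount, tau)
}

# vectorised Bateman kernel; ka/v/kel may be vectors conformable with tau
.bateman <- function(ka, v, kel, amount, tau) {
  degen <- abs(ka - kel) < .DEGENERACY_TOL * pmax(ka, kel)
  out <- (amount / v) * (ka / (ka - kel)) * (exp(-kel * tau) - exp(-ka * tau))
  if (any(degen)) {
    lim <- (amount / v) * kel * tau * exp(-kel * tau)
    out[degen] <- lim[degen]
  }
  pmax(out, 0)
}

#' Concentration profile under repeated dosing
#'
#' Superposition of single-dose curves: under linear kinetics the predicted
#' concentration at time `t` is the sum, over all dose events administered at
#' or before `t`, of the single-dose solution evaluated at the elapsed time.
#'
#' @param params A [pk_params()] object.
#' @param regimen A [dosing_regimen()].
#' @param times Observation times (h, >= 0); need not be sorted, output
#'   follows the input order.
#' @return Numeric vector of concentrations (ug/mL), zero before the first
#'   dose.
#' @examples
#' p <- pk_params(10.3, 108, 0.0253)
#' reg <- dosing_regimen(c(0, 12, 24, 36, 48), 10)
#' concentration_profile(p, reg, times = c(0.5, 18, 50))
#' @export
concentration_profile <- function(params, regimen, times) {
  params <- .check_params(params)
  stopifnot(inherits(regimen, "dosing_regimen"))
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("concentration_profile: times must be finite and >= 0", call. = FALSE)
  }
  tau <- outer(times, regimen$time, "-")   # n_times x n_doses
  active <- tau > 0
  tau[!active] <- 0
  contrib <- .bateman(params$ka, params$v, params$kel, 1, tau)
  contrib <- sweep(contrib, 2L, regimen$amount, "*")
  contrib[!active] <- 0
  rowSums(contrib)
}

#' Time of maximum concentration after a single dose
#'
#' Analytic Tmax of the one-compartment extravascular model,
#' \eqn{\ln(K_a/K_{el})/(K_a - K_{el})}, with limit \eqn{1/K_{el}} when
#' \eqn{K_a \to K_{el}}. The expression is symmetric in (Ka, Kel).
#'
#' @param params A [pk_params()] object.
#' @return Time of the single-dose concentration maximum, hours.
#' @export
time_of_max_single_dose <- function(params) {
  params <- .check_params(params)
  ka <- params$ka; kel <- params$kel
  if (abs(ka - kel) < .DEGENERACY_TOL * max(ka, kel)) return(1 / kel)
  log(ka / kel) / (ka - kel)
}

#' Apparent clearance
#'
#' CL/F from the apparent parameterization: `kel * v` (L/kg/h). With
#' bioavailability absorbed into the volume, this is the apparent clearance
#' after extravascular administration.
#'
#' @param params A [pk_params()] object.
#' @return Apparent clearance CL/F in L/kg/h.
#' @examples
#' apparent_clearance(pk_params(10.3, 108, 0.0253))  # 2.7324
#' @export
apparent_clearance <- function(params) {
  params <- .check_params(params)
  params$kel * params$v
}
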