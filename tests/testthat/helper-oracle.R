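# Brute-force ODE oracle: integrates the compartment system with impulse
# (event) dosing using a high-accuracy adaptive integrator. Independent of
# the package's closed-form predictions.

ode_oracle_profile <- function(params, regimen, times, two_compartment = FALSE) {
  psi <- unlist(params, use.names = FALSE)
  if (two_compartment) {
    rhs <- function(t, y, p) {
      list(c(-p[1] * y[1],
             p[1] * y[1] - (p[3] + p[4]) * y[2] + p[5] * y[3],
             p[4] * y[2] - p[5] * y[3]))
    }
    y0 <- c(Agut = 0, Ac = 0, Ap = 0)
  } else {
    rhs <- function(t, y, p) list(c(-p[1] * y[1], p[1] * y[1] - p[3] * y[2]))
    y0 <- c(Agut = 0, Ac = 0)
  }
  ev <- data.frame(var = "Agut", time = regimen$time, value = regimen$amount,
                   method = "add")
  tt <- sort(unique(c(0, times, regimen$time)))
  out <- deSolve::ode(y0, tt, rhs, psi, events = list(data = ev),
                      rtol = 1e-11, atol = 1e-13)
  out[match(times, out[, "time"]), "Ac"] / psi[2]
}
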