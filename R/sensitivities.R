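#' Simulate states together with forward parameter sensitivities
#'
#' Integrates the augmented system consisting of the gas balances and the
#' forward sensitivity equations
#' `d/dt (dx/dtheta) = (df/dx) (dx/dtheta) + df/dtheta`, starting from
#' `dx/dtheta = 0` at `t = 0`.  The Jacobians of the rate laws and mass
#' balances are analytic; finite-difference cross-checks live in the test
#' suite.  Sensitivities are taken with respect to the six parameters of
#' interest in the canonical (inverse-Kmn) order of [param_names()].
#'
#' @inheritParams simulate_jar
#' @return An object of class `sensitivity_trajectory` with fields
#'   `times`, `states` (`N x 2`, kPa) and `sens` (`N x 2 x 6` array,
#'   kPa per parameter unit; dimension names follow [param_names()]).
#' @export
simulate_sensitivities <- function(jar, profile, params, grid,
                                   rtol = 1e-3, atol = 1e-6) {
  stopifnot(inherits(jar, "jar_setup"), inherits(params, "kinetic_params"),
            inherits(grid, "experiment_grid"))
  if (abs(grid$te - profile$te) > 1e-9)
    stop("grid and profile must share the same end time")
  res <- .cpp_simulate(as_param_vector(params), unclass(jar), profile$u,
                       profile$te, grid$times, TRUE, rtol, atol)
  N <- length(grid$times)
  sens <- array(res$sens, dim = c(N, 2, 6),
                dimnames = list(NULL, c("pO2", "pCO2"), param_names()))
  states <- res$states
  colnames(states) <- c("pO2_kPa", "pCO2_kPa")
  structure(list(times = grid$times, states = states, sens = sens,
                 params = params),
            class = "sensitivity_trajectory")
}

#' Finite-difference sensitivities (independent oracle)
#'
#' Central differences of [simulate_jar()] with a relative step per
#' parameter.  This is deliberately independent of the integrated
#' sensitivity path and is used to validate it.
#'
#' @inheritParams simulate_jar
#' @param rel_step relative perturbation per parameter.
#' @return `N x 2 x 6` array matching the layout of
#'   [simulate_sensitivities()].
#' @export
fd_sensitivities <- function(jar, profile, params, grid, rel_step = 1e-6,
                             rtol = 1e-8, atol = 1e-10) {
  theta <- as_param_vector(params)
  N <- length(grid$times)
  out <- array(0, dim = c(N, 2, 6),
               dimnames = list(NULL, c("pO2", "pCO2"), param_names()))
  for (m in seq_len(6)) {
    h <- rel_step * max(abs(theta[m]), 1e-8)
    up <- theta; up[m] <- theta[m] + h
    if (m == 4) up[m] <- min(up[m], 1)   # rq is bounded by 1
    dn <- theta; dn[m] <- max(theta[m] - h, 0)
    hh <- up[m] - dn[m]
    sp <- simulate_jar(jar, profile, params_from_vector(up), grid,
                       rtol = rtol, atol = atol)
    sm <- simulate_jar(jar, profile, params_from_vector(dn), grid,
                       rtol = rtol, atol = atol)
    out[, , m] <- (sp$states - sm$states) / hh
  }
  out
}

#' Map sensitivities from the inverse-Kmn to the direct parameterization
#'
#' The chain rule gives `dx/dKmn = dx/d(1/Kmn) * (-1/Kmn^2)`; all other
#' columns are unchanged.
#'
#' @param straj a `sensitivity_trajectory`.
#' @return The same object with the third sensitivity column expressed
#'   with respect to `Kmn_CO2` instead of its inverse.
#' @export
sens_to_direct <- function(straj) {
  ik <- straj$params$inv_Kmn_CO2
  if (ik == 0)
    stop("no finite Kmn_CO2: inverse parameter is 0")
  straj$sens[, , 3] <- straj$sens[, , 3] * (-ik^2)
  dimnames(straj$sens)[[3]][3] <- "Kmn_CO2"
  straj
}
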