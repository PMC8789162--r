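#' Time derivative of the jar gas balances
#'
#' Pure-R evaluation of the mass-balance right-hand side, mainly useful for
#' inspection and as an independent check of the compiled integrator.  In
#' flow-through mode
#' `d pO2/dt = (Qin * pO2_in - Qout * pO2)/Vj - c * rO2` and
#' `d pCO2/dt = (Qin * pCO2_in - Qout * pCO2)/Vj + c * rCO2`,
#' where `c` converts areal rates (umol kg^-1 s^-1) to kPa/h inside the
#' jar; in closed mode the flow terms vanish.
#'
#' @param t time, h.
#' @param state numeric (pO2, pCO2), kPa.
#' @param profile a [control_profile()] (ignored in closed mode).
#' @param params a [kinetic_params()] object.
#' @param jar a [jar_setup()] object.
#' @return Numeric length-2 derivative, kPa/h.
#' @export
jar_rhs <- function(t, state, profile, params, jar) {
  p <- pmax(state, 0)
  r <- respiration_rates(p[1], p[2], params)
  kr <- jar$mp * 3.6e-3 * jar$Rgas * jar$T / (1000 * jar$Vj)
  if (jar$mode == "closed")
    return(c(-kr * r$rO2, kr * r$rCO2))
  u <- control_at(profile, t)
  Qout <- outflow_rate(u[1], r$rO2, r$rCO2, jar)
  c((u[1] * u[2] - Qout * state[1]) / jar$Vj - kr * r$rO2,
    (u[1] * u[3] - Qout * state[2]) / jar$Vj + kr * r$rCO2)
}

#' Simulate the jar experiment
#'
#' Integrates the gas balances with an adaptive Dormand-Prince 5(4) method,
#' restarting cleanly at every control switch so discontinuities never
#' straddle a step, and reports the states on the measurement grid.
#'
#' @param jar a [jar_setup()] object.
#' @param profile a [control_profile()] object.
#' @param params a [kinetic_params()] object.
#' @param grid an [experiment_grid()] object; its `te` must match the
#'   profile's.
#' @param rtol,atol relative / absolute integration tolerances.
#' @return An object of class `trajectory` with fields `times` (h) and
#'   `states` (`N x 2` matrix of pO2, pCO2 in kPa).
#' @export
simulate_jar <- function(jar, profile, params, grid,
                         rtol = 1e-3, atol = 1e-6) {
  stopifnot(inherits(jar, "jar_setup"), inherits(params, "kinetic_params"),
            inherits(grid, "experiment_grid"))
  if (abs(grid$te - profile$te) > 1e-9)
    stop("grid and profile must share the same end time")
  res <- .cpp_simulate(as_param_vector(params), unclass(jar), profile$u,
                       profile$te, grid$times, FALSE, rtol, atol)
  states <- res$states
  colnames(states) <- c("pO2_kPa", "pCO2_kPa")
  structure(list(times = grid$times, states = states),
            class = "trajectory")
}

#' Measurement noise covariance at a true output value
#'
#' Diagonal, heteroscedastic: `diag(sigma2_O2 * pO2 + floor,
#' sigma2_CO2 * pCO2 + floor)` in kPa^2.
#'
#' @param y_true numeric (pO2, pCO2), kPa.
#' @param noise a [noise_params()] object.
#' @return 2 x 2 diagonal covariance matrix.
#' @export
measurement_cov <- function(y_true, noise) {
  stopifnot(all(y_true >= 0))
  diag(c(noise$sigma2_O2 * y_true[1] + noise$floor,
         noise$sigma2_CO2 * y_true[2] + noise$floor))
}

#' Draw a noisy measurement set from a trajectory
#'
#' Independent Gaussian noise per channel and time point with the
#' heteroscedastic variances of [measurement_cov()].
#'
#' @param traj a `trajectory` from [simulate_jar()].
#' @param noise a [noise_params()] object.
#' @param seed optional integer seed for reproducible draws.
#' @return An object of class `measurement_set` with fields `times`,
#'   `yO2`, `yCO2`.
#' @export
sample_measurements <- function(traj, noise, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- pmax(traj$states, 0)
  vO2 <- noise$sigma2_O2 * mu[, 1] + noise$floor
  vCO2 <- noise$sigma2_CO2 * mu[, 2] + noise$floor
  n <- length(traj$times)
  structure(list(times = traj$times,
                 yO2 = traj$states[, 1] + stats::rnorm(n, 0, sqrt(vO2)),
                 yCO2 = traj$states[, 2] + stats::rnorm(n, 0, sqrt(vCO2))),
            class = "measurement_set")
}

#' Write / read measurement datasets as CSV
#'
#' Columns: `time_h,pO2_kPa,pCO2_kPa`.
#'
#' @param ms a `measurement_set` (or any list with `times`, `yO2`, `yCO2`).
#' @param path file path.
#' @return `read_measurements()` returns a `measurement_set`.
#' @export
write_measurements <- function(ms, path) {
  d <- data.frame(time_h = ms$times, pO2_kPa = ms$yO2, pCO2_kPa = ms$yCO2)
  utils::write.csv(format(d, digits = 12, scientific = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_h", "pO2_kPa", "pCO2_kPa")
  if (!all(need %in% names(d)))
    stop("measurement file lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  structure(list(times = d$time_h, yO2 = d$pO2_kPa, yCO2 = d$pCO2_kPa),
            class = "measurement_set")
}
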