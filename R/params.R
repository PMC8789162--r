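#' Canonical order of the six parameters of interest
#'
#' The kinetic parameters are handled everywhere in the inverse-Kmn
#' parameterization: the CO2 inhibition constant `Kmn_CO2` enters as its
#' inverse `inv_Kmn_CO2` (units 1/kPa), because posterior draws of
#' `inv_Kmn_CO2` pile up near zero (weak or absent inhibition) and the
#' inverse scale is the one on which priors and sigma points are formed.
#'
#' @return Character vector of the six canonical parameter names.
#' @export
param_names <- function() {
  c("Vm_O2", "Km_O2", "inv_Kmn_CO2", "rq", "Vmf_CO2", "Kmf_O2")
}

nuisance_names <- function() {
  c("Ea_O2", "Ea_CO2", "sigma2_O2", "sigma2_CO2")
}

#' Kinetic parameters of the respiration/fermentation rate laws
#'
#' @param Vm_O2 maximal respiration rate, umol kg^-1 s^-1.
#' @param Km_O2 O2 half-saturation constant of respiration, kPa.
#' @param Kmn_CO2 CO2 inhibition constant of respiration, kPa. Exactly one
#'   of `Kmn_CO2` and `inv_Kmn_CO2` must be given. `inv_Kmn_CO2 = 0`
#'   (equivalently `Kmn_CO2 = Inf`) means no CO2 inhibition.
#' @param rq respiration quotient (fraction of consumed O2 returned as
#'   CO2), dimensionless, at most 1.
#' @param Vmf_CO2 maximal fermentative CO2 production rate,
#'   umol kg^-1 s^-1.
#' @param Kmf_O2 O2 inhibition constant of fermentation, kPa.
#' @param inv_Kmn_CO2 inverse CO2 inhibition constant, 1/kPa.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(Vm_O2 = 0.283, Km_O2 = 4.43, Kmn_CO2 = 182.5,
#'                rq = 0.637, Vmf_CO2 = 0.136, Kmf_O2 = 0.187)
#' @export
kinetic_params <- function(Vm_O2, Km_O2, Kmn_CO2 = NULL, rq, Vmf_CO2,
                           Kmf_O2, inv_Kmn_CO2 = NULL) {
  if (is.null(Kmn_CO2) == is.null(inv_Kmn_CO2))
    stop("give exactly one of Kmn_CO2 and inv_Kmn_CO2")
  if (is.null(inv_Kmn_CO2)) {
    stopifnot(Kmn_CO2 > 0)
    inv_Kmn_CO2 <- if (is.infinite(Kmn_CO2)) 0 else 1 / Kmn_CO2
  } else {
    stopifnot(inv_Kmn_CO2 >= 0)
    Kmn_CO2 <- if (inv_Kmn_CO2 == 0) Inf else 1 / inv_Kmn_CO2
  }
  vals <- c(Vm_O2, Km_O2, inv_Kmn_CO2, rq, Vmf_CO2, Kmf_O2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("kinetic parameters must be finite and nonnegative")
  if (rq > 1) stop("rq must be at most 1")
  structure(list(Vm_O2 = Vm_O2, Km_O2 = Km_O2, inv_Kmn_CO2 = inv_Kmn_CO2,
                 Kmn_CO2 = Kmn_CO2, rq = rq, Vmf_CO2 = Vmf_CO2,
                 Kmf_O2 = Kmf_O2),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (inverse-Kmn parameterization):\n")
  print(unlist(x[param_names()]))
  invisible(x)
}

#' Convert kinetic parameters to / from the canonical numeric vector
#'
#' The canonical vector is ordered as [param_names()]:
#' (Vm_O2, Km_O2, inv_Kmn_CO2, rq, Vmf_CO2, Kmf_O2).
#'
#' @param params a `kinetic_params` object.
#' @return `as_param_vector()` returns a named length-6 numeric vector;
#'   `params_from_vector()` returns a `kinetic_params` object.
#' @export
as_param_vector <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  unlist(params[param_names()])
}

#' @rdname as_param_vector
#' @param theta named or ordered length-6 numeric vector.
#' @export
params_from_vector <- function(theta) {
  if (!is.null(names(theta))) theta <- theta[param_names()]
  kinetic_params(Vm_O2 = theta[[1]], Km_O2 = theta[[2]],
                 inv_Kmn_CO2 = theta[[3]], rq = theta[[4]],
                 Vmf_CO2 = theta[[5]], Kmf_O2 = theta[[6]])
}

#' Measurement noise model parameters
#'
#' The two gas sensors are independent and heteroscedastic: the variance of
#' a reading at true partial pressure p is `sigma2 * p + floor` (kPa^2).
#' The additive floor keeps the noise covariance positive definite even at
#' zero concentration.
#'
#' @param sigma2_O2,sigma2_CO2 noise scale of the O2 / CO2 sensor (kPa).
#' @param floor additive variance floor, kPa^2; must be > 0.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sigma2_O2 = 0.063, sigma2_CO2 = 0.093,
                         floor = 0.01) {
  stopifnot(sigma2_O2 >= 0, sigma2_CO2 >= 0, floor > 0)
  structure(list(sigma2_O2 = sigma2_O2, sigma2_CO2 = sigma2_CO2,
                 floor = floor),
            class = "noise_params")
}

#' Arrhenius temperature-scaling parameters
#'
#' @param Ea_O2,Ea_CO2 activation energies of respiration / fermentation,
#'   kJ mol^-1.
#' @param Tr reference temperature, K.
#' @return An object of class `arrhenius_params`.
#' @export
arrhenius_params <- function(Ea_O2 = 70, Ea_CO2 = 60, Tr = 293.15) {
  stopifnot(Ea_O2 >= 0, Ea_CO2 >= 0, Tr > 0)
  structure(list(Ea_O2 = Ea_O2, Ea_CO2 = Ea_CO2, Tr = Tr),
            class = "arrhenius_params")
}

#' Jar and experiment configuration
#'
#' Describes the physical measurement setup: a well-mixed jar of volume
#' `Vj` containing `mp` kg of fruit at fixed temperature `T`.  In
#' `flow_through` mode a gas mixture is pumped through the jar and the
#' outflow adjusts so pressure stays atmospheric; in `closed` mode there is
#' no gas exchange with the environment.
#'
#' @param Vj jar volume, m^3.
#' @param mp fruit mass, kg.
#' @param T temperature, K.
#' @param Patm atmospheric pressure, kPa.
#' @param Rgas universal gas constant, J mol^-1 K^-1.
#' @param x0 initial partial pressures (pO2, pCO2) in kPa; the default is
#'   regular air with the ambient CO2 trace treated as zero.
#' @param mode `"flow_through"` or `"closed"`.
#' @return An object of class `jar_setup`.
#' @export
jar_setup <- function(Vj = 5e-3, mp = 4, T = 293.15, Patm = 101.325,
                      Rgas = 8.314462618, x0 = c(21, 0),
                      mode = c("flow_through", "closed")) {
  mode <- match.arg(mode)
  stopifnot(Vj > 0, mp >= 0, T > 0, length(x0) == 2,
            all(x0 >= 0), all(x0 <= Patm))
  structure(list(Vj = Vj, mp = mp, T = T, Patm = Patm, Rgas = Rgas,
                 x0 = as.numeric(x0), mode = mode),
            class = "jar_setup")
}

#' Equispaced measurement grid
#'
#' Measurements are taken at times `k * te / N` for `k = 1..N`: the grid
#' includes the end of the experiment but not its start.
#'
#' @param te experiment end time, h.
#' @param N number of measurement times.
#' @return An object of class `experiment_grid` with a `times` field.
#' @export
experiment_grid <- function(te = 24, N = 1440) {
  stopifnot(te > 0, N >= 1)
  structure(list(te = te, N = as.integer(N),
                 times = seq_len(N) * te / N),
            class = "experiment_grid")
}

#' Respiration and fermentation rates
#'
#' Michaelis-Menten respiration with noncompetitive CO2 inhibition and
#' O2-inhibited fermentation:
#' `rO2 = Vm_O2 * pO2 / ((Km_O2 + pO2) * (1 + pCO2 / Kmn_CO2))` and
#' `rCO2 = rq * rO2 + Vmf_CO2 / (1 + pO2 / Kmf_O2)`.
#'
#' @param pO2,pCO2 partial pressures, kPa (vectorized).
#' @param params a [kinetic_params()] object.
#' @return List with components `rO2` and `rCO2` in umol kg^-1 s^-1.
#' @export
respiration_rates <- function(pO2, pCO2, params) {
  if (any(pO2 < 0) || any(pCO2 < 0))
    stop("partial pressures must be nonnegative")
  rO2 <- params$Vm_O2 * pO2 /
    ((params$Km_O2 + pO2) * (1 + pCO2 * params$inv_Kmn_CO2))
  rCO2 <- params$rq * rO2 + params$Vmf_CO2 / (1 + pO2 / params$Kmf_O2)
  list(rO2 = rO2, rCO2 = rCO2)
}

#' Scale maximal rates to a new temperature via the Arrhenius law
#'
#' `Vm_O2` and `Vmf_CO2` are multiplied by
#' `exp(Ea / Rgas * (1/Tr - 1/T))`; the Michaelis and inhibition constants,
#' and the respiration quotient, are temperature-independent in this model.
#'
#' @param params a [kinetic_params()] object at the reference temperature.
#' @param arr an [arrhenius_params()] object.
#' @param T target temperature, K.
#' @param Rgas universal gas constant, J mol^-1 K^-1.
#' @return A `kinetic_params` object valid at temperature `T`.
#' @export
arrhenius_adjust <- function(params, arr, T, Rgas = 8.314462618) {
  stopifnot(T > 0)
  # Ea in kJ/mol, Rgas in J/mol/K
  fac_O2 <- exp(1000 * arr$Ea_O2 / Rgas * (1 / arr$Tr - 1 / T))
  fac_CO2 <- exp(1000 * arr$Ea_CO2 / Rgas * (1 / arr$Tr - 1 / T))
  out <- params
  out$Vm_O2 <- params$Vm_O2 * fac_O2
  out$Vmf_CO2 <- params$Vmf_CO2 * fac_CO2
  out
}

#' Outflow rate keeping jar pressure atmospheric
#'
#' From the ideal gas law, net gas production by the fruit pushes extra
#' volume out of the jar: `Qout = Qin + (rCO2 - rO2) * mp * Rgas * T / Patm`
#' with the rates converted from umol kg^-1 s^-1 to mol h^-1.
#'
#' @param Qin inflow, m^3 h^-1.
#' @param rO2,rCO2 respiration rates, umol kg^-1 s^-1.
#' @param jar a [jar_setup()] object.
#' @return Outflow, m^3 h^-1; exceeds `Qin` when fermentation dominates.
#' @export
outflow_rate <- function(Qin, rO2, rCO2, jar) {
  stopifnot(all(Qin >= 0))
  mol_per_h <- (rCO2 - rO2) * jar$mp * 3.6e-3
  Qin + mol_per_h * jar$Rgas * jar$T / (1000 * jar$Patm)
}
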