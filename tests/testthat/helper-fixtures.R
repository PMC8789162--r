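# Shared fixtures: the reference kinetic parameters, a desk-scale grid,
# and small deterministic profiles.  All fixtures are built in code.

ref_params <- function() {
  kinetic_params(Vm_O2 = 0.283, Km_O2 = 4.43, Kmn_CO2 = 182.5,
                 rq = 0.637, Vmf_CO2 = 0.136, Kmf_O2 = 0.187)
}

ref_noise <- function() noise_params(0.063, 0.093, 0.01)

small_grid <- function(N = 48, te = 24) experiment_grid(te = te, N = N)

# a fixed 12-interval profile spanning the admissible box: quiet first
# half (gas accumulation), venting with air later -- the qualitative shape
# of informative designs for this system
bench_profile <- function(te = 24) {
  u <- rbind(c(1e-4, 21, 0), c(1e-4, 15, 5), c(1e-4, 10, 10),
             c(1e-4, 5, 15), c(1e-4, 2, 18), c(1e-4, 0, 21),
             c(4e-3, 0, 0), c(2e-3, 1, 0), c(1e-4, 1, 0),
             c(1e-4, 0, 9), c(4e-3, 0, 0), c(1e-4, 0, 11))
  control_profile(u, te = te)
}

# random admissible profile under a fixed RNG state
random_profile <- function(M = 6, te = 24,
                           umin = c(1e-4, 0, 0), umax = c(4e-3, 21, 21)) {
  u <- sapply(1:3, function(j) stats::runif(M, umin[j], umax[j]))
  control_profile(u, te = te, umin = umin, umax = umax)
}

# random kinetic parameters: lognormal jitter around the reference values
random_params <- function(spread = 0.25) {
  th <- as_param_vector(ref_params()) *
    exp(stats::rnorm(6, 0, spread))
  th["rq"] <- min(th["rq"], 1)
  params_from_vector(th)
}

# Independent fixed-step classic RK4 integrator over the same model,
# written against the R-level rhs -- the oracle for the compiled adaptive
# integrator.  Returns states at the measurement grid times.
rk4_oracle <- function(jar, profile, params, grid, dt = 1 / 3600) {
  M <- profile$M
  te <- profile$te
  x <- jar$x0
  out <- matrix(NA_real_, grid$N, 2)
  kr <- jar$mp * 3.6e-3 * jar$Rgas * jar$T / (1000 * jar$Vj)
  k_next <- 1L
  t <- 0
  for (j in seq_len(M)) {
    u <- profile$u[j, ]
    f <- if (jar$mode == "closed") {
      function(x) {
        r <- respiration_rates(max(x[1], 0), max(x[2], 0), params)
        c(-kr * r$rO2, kr * r$rCO2)
      }
    } else {
      function(x) {
        r <- respiration_rates(max(x[1], 0), max(x[2], 0), params)
        Qout <- outflow_rate(u[1], r$rO2, r$rCO2, jar)
        c((u[1] * u[2] - Qout * x[1]) / jar$Vj - kr * r$rO2,
          (u[1] * u[3] - Qout * x[2]) / jar$Vj + kr * r$rCO2)
      }
    }
    seg_end <- j * te / M
    while (t < seg_end - 1e-12) {
      h <- min(dt, seg_end - t)
      # also land exactly on measurement times inside the segment
      if (k_next <= grid$N && grid$times[k_next] > t &&
          grid$times[k_next] <= t + h + 1e-12)
        h <- grid$times[k_next] - t
      k1 <- f(x); k2 <- f(x + h / 2 * k1); k3 <- f(x + h / 2 * k2)
      k4 <- f(x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
      if (k_next <= grid$N && abs(t - grid$times[k_next]) < 1e-9) {
        out[k_next, ] <- x
        k_next <- k_next + 1L
      }
    }
  }
  out
}

# closed-form expected Gaussian log-likelihood at params `th`, data-
# generating truth `th0`; used by the Fisher-identity oracle
expected_loglik <- function(th, th0, jar, profile, grid, noise,
                            rtol = 1e-10, atol = 1e-12) {
  mu0 <- simulate_jar(jar, profile, params_from_vector(th0), grid,
                      rtol = rtol, atol = atol)$states
  mu <- simulate_jar(jar, profile, params_from_vector(th), grid,
                     rtol = rtol, atol = atol)$states
  s2 <- c(noise$sigma2_O2, noise$sigma2_CO2)
  ll <- 0
  for (i in 1:2) {
    v0 <- s2[i] * pmax(mu0[, i], 0) + noise$floor
    v <- s2[i] * pmax(mu[, i], 0) + noise$floor
    ll <- ll + sum(-0.5 * (log(2 * pi * v) +
                             (v0 + (mu0[, i] - mu[, i])^2) / v))
  }
  ll
}

# centered L2 discrepancy (closed form); lower = more uniform point set
cl2_discrepancy <- function(X) {
  n <- nrow(X); d <- ncol(X)
  t1 <- prod(rep(13 / 12, d))
  xc <- abs(X - 0.5)
  t2 <- sum(apply(1 + 0.5 * xc - 0.5 * xc^2, 1, prod))
  t3 <- 0
  for (i in seq_len(n)) {
    a <- 1 + 0.5 * (xc[i, ] + t(xc)) -
      0.5 * abs(X[i, ] - t(X))
    t3 <- t3 + sum(apply(a, 2, prod))
  }
  t1 - 2 / n * t2 + t3 / n^2
}
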