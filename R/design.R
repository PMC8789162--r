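#' Define a design-optimization problem
#'
#' Bundles the experiment configuration, the objective (local, robust, or
#' sigma-point D-criterion), the control bounds and discretization, and
#' the optimizer settings.
#'
#' @param jar a [jar_setup()] object.
#' @param grid an [experiment_grid()] object.
#' @param noise a [noise_params()] object (variance floor and fallback
#'   noise scales).
#' @param objective `"local"`, `"robust"`, or `"sigma"`.
#' @param params [kinetic_params()] for the local objective.
#' @param chain [parameter_chain()] for the robust objective.
#' @param sigma [sigma_points()] set for the sigma objective.
#' @param M number of constant control intervals.
#' @param umin,umax per-channel bounds `(Qin m^3/h, pO2_in kPa,
#'   pCO2_in kPa)`; the flow lower bound must be strictly positive.
#' @param noise_source per-draw or fixed noise scales for the robust
#'   objective (see [robust_criterion()]).
#' @param n_starts number of multistart initial designs.
#' @param maxit iteration cap per local solve.
#' @param rel_tol relative objective-change tolerance of each local solve.
#' @param seed seed for the start generator.
#' @param rtol,atol integration tolerances inside the objective; tighter
#'   than simulation defaults so finite-difference gradients of the
#'   criterion are smooth.
#' @return An object of class `design_problem`.
#' @export
design_problem <- function(jar, grid, noise = noise_params(),
                           objective = c("local", "robust", "sigma"),
                           params = NULL, chain = NULL, sigma = NULL,
                           M = 12, umin = c(1e-4, 0, 0),
                           umax = c(4e-3, 21, 21),
                           noise_source = c("per_draw", "fixed"),
                           n_starts = 50, maxit = 200, rel_tol = 1e-3,
                           seed = 1L, rtol = 1e-8, atol = 1e-10) {
  objective <- match.arg(objective)
  noise_source <- match.arg(noise_source)
  stopifnot(M >= 1, all(is.finite(umin)), all(is.finite(umax)),
            all(umin < umax))
  if (umin[1] <= 0)
    stop("the flow lower bound must be strictly positive: at zero flow ",
         "the criterion is flat in the gas inputs")
  if (objective == "local" && is.null(params))
    stop("local objective needs `params`")
  if (objective == "robust" && is.null(chain))
    stop("robust objective needs `chain`")
  if (objective == "sigma" && is.null(sigma))
    stop("sigma objective needs `sigma` points")
  structure(list(jar = jar, grid = grid, noise = noise,
                 objective = objective, params = params, chain = chain,
                 sigma = sigma, M = as.integer(M), umin = umin,
                 umax = umax, noise_source = noise_source,
                 n_starts = n_starts, maxit = maxit, rel_tol = rel_tol,
                 seed = seed, rtol = rtol, atol = atol),
            class = "design_problem")
}

# scaled [0,1]^{3M} <-> control matrix
scaled_to_profile <- function(x, problem) {
  M <- problem$M
  u <- matrix(x, M, 3)
  for (j in 1:3)
    u[, j] <- problem$umin[j] + u[, j] * (problem$umax[j] - problem$umin[j])
  control_profile(u, te = problem$grid$te,
                  umin = problem$umin, umax = problem$umax)
}

profile_to_scaled <- function(profile, problem) {
  u <- profile$u
  for (j in 1:3)
    u[, j] <- (u[, j] - problem$umin[j]) /
      (problem$umax[j] - problem$umin[j])
  as.numeric(pmin(pmax(u, 0), 1))
}

# raw-scale criterion value of a design under the problem's objective
criterion_value <- function(problem, profile) {
  with(problem, switch(objective,
    local = {
      dets <- det_fim_over_draws(
        profile, as.data.frame(t(as_param_vector(params))), jar, grid,
        noise, "fixed", rtol, atol)
      dets[1]
    },
    robust = mean(det_fim_over_draws(profile, chain_draws(chain), jar,
                                     grid, noise, noise_source, rtol,
                                     atol)),
    sigma = {
      draws <- as.data.frame(sigma$points)
      dets <- det_fim_over_draws(profile, draws, jar, grid, noise,
                                 "fixed", rtol, atol)
      sum(sigma$weights_mean * dets)
    }))
}

#' Low-discrepancy multistart design candidates
#'
#' Generates `n` starting profiles spread over the `3M`-dimensional
#' control box using a Latin hypercube (a space-filling low-discrepancy
#' scheme); deterministic under the seed.
#'
#' @param problem a [design_problem()].
#' @param n number of starts.
#' @param seed integer seed.
#' @return List of `n` [control_profile()] objects.
#' @export
design_starts <- function(problem, n = problem$n_starts,
                          seed = problem$seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  X <- lhs::randomLHS(n, 3 * problem$M)
  lapply(seq_len(n), function(i) scaled_to_profile(X[i, ], problem))
}

#' Optimize a design by multistart box-constrained ascent
#'
#' Maximizes the (log) D-criterion over the piecewise-constant control
#' values with projected quasi-Newton ascent (`L-BFGS-B`) from each start;
#' gradients are central finite differences of the criterion with step
#' `1e-4` of the box width per channel.  Starts whose objective is
#' non-finite are discarded with a warning.  The best local optimum over
#' all starts is returned.
#'
#' @param problem a [design_problem()].
#' @param extra_starts optional list of [control_profile()] objects to
#'   include among the starts (for example a previously optimized design).
#' @return An object of class `design_result`: `profile`, `criterion`
#'   (raw determinant scale), `log_criterion`, `starts` (per-start data
#'   frame with start id, final value and evaluation count), `seed`.
#' @export
optimize_design <- function(problem, extra_starts = NULL) {
  starts <- design_starts(problem)
  if (!is.null(extra_starts)) {
    if (inherits(extra_starts, "control_profile"))
      extra_starts <- list(extra_starts)
    starts <- c(extra_starts, starts)
  }
  n_evals <- 0L
  fn <- function(x) {
    n_evals <<- n_evals + 1L
    v <- criterion_value(problem, scaled_to_profile(x, problem))
    if (!is.finite(v)) return(NA_real_)
    -log(max(v, 1e-300))
  }
  h <- 1e-4
  gr <- function(x) {
    g <- numeric(length(x))
    for (i in seq_along(x)) {
      up <- x; dn <- x
      up[i] <- min(x[i] + h, 1)
      dn[i] <- max(x[i] - h, 0)
      g[i] <- (fn(up) - fn(dn)) / (up[i] - dn[i])
    }
    g
  }
  # map the relative objective tolerance onto L-BFGS-B's factr; the
  # objective is a log determinant, so an absolute log change equals a
  # relative determinant change
  factr <- problem$rel_tol / .Machine$double.eps /
    max(1, abs(log(1e16)))
  rows <- list()
  best <- NULL
  for (s in seq_along(starts)) {
    x0 <- profile_to_scaled(starts[[s]], problem)
    e0 <- n_evals
    f0 <- fn(x0)
    if (!is.finite(f0)) {
      warning("start ", s, ": non-finite objective, discarded")
      rows[[s]] <- data.frame(start = s, value = NA_real_, evals = 1L,
                              converged = FALSE)
      next
    }
    fit <- tryCatch(
      stats::optim(x0, fn, gr, method = "L-BFGS-B", lower = 0, upper = 1,
                   control = list(maxit = problem$maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(fit)) fit <- list(par = x0, value = f0, convergence = 1L)
    val <- exp(-fit$value)
    if (fit$value >= -log(1e-300) * 0.999) val <- 0  # flat/degenerate case
    rows[[s]] <- data.frame(start = s, value = val,
                            evals = n_evals - e0,
                            converged = fit$convergence == 0)
    if (is.null(best) || (is.finite(val) && val > best$value))
      best <- list(par = fit$par, value = val)
  }
  if (is.null(best)) stop("no start produced a finite objective")
  profile <- scaled_to_profile(best$par, problem)
  structure(list(profile = profile,
                 criterion = criterion_value(problem, profile),
                 log_criterion = log(max(best$value, 1e-300)),
                 starts = do.call(rbind, rows),
                 objective = problem$objective, M = problem$M,
                 seed = problem$seed),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("Optimized %s design: M = %d, criterion = %.6g (%d starts)\n",
              x$objective, x$M, x$criterion, nrow(x$starts)))
  invisible(x)
}

#' Refine a profile onto a finer discretization
#'
#' Every `M`-interval profile is exactly representable with `k * M`
#' intervals; this replicates each interval `k` times.
#'
#' @param profile a [control_profile()].
#' @param M_new new interval count, a multiple of the current one.
#' @return A [control_profile()] with `M_new` intervals.
#' @export
refine_profile <- function(profile, M_new) {
  k <- M_new / profile$M
  if (k != round(k) || k < 1)
    stop("M_new must be a positive multiple of the current M")
  control_profile(profile$u[rep(seq_len(profile$M), each = k), ,
                            drop = FALSE],
                  te = profile$te, umin = profile$umin,
                  umax = profile$umax)
}

#' Discretization refinement study
#'
#' Optimizes the design along an increasing sequence of interval counts,
#' warm-starting each level with the refined best design of the previous
#' one (so the optimized criterion is non-decreasing along the chain, up
#' to optimizer tolerance).
#'
#' @param problem a [design_problem()]; its `M` is ignored.
#' @param Ms increasing interval counts, each a multiple of its
#'   predecessor, e.g. `c(3, 6, 12, 24)`.
#' @return List of [optimize_design()] results, one per `M`.
#' @export
optimize_refinement <- function(problem, Ms = c(3, 6, 12, 24)) {
  out <- vector("list", length(Ms))
  prev <- NULL
  for (i in seq_along(Ms)) {
    problem$M <- as.integer(Ms[i])
    extra <- if (!is.null(prev)) list(refine_profile(prev, Ms[i]))
    out[[i]] <- optimize_design(problem, extra_starts = extra)
    prev <- out[[i]]$profile
  }
  names(out) <- paste0("M", Ms)
  out
}

#' Per-draw FIM determinants of a design over a chain
#'
#' Evaluates `det F(theta_r, u)` for every draw of the chain; the mean of
#' the returned vector equals [robust_criterion()] exactly.
#'
#' @inheritParams robust_criterion
#' @return Numeric vector, one determinant per draw.
#' @export
evaluate_design_over_chain <- function(profile, chain, jar, grid,
                                       noise = noise_params(),
                                       noise_source = c("per_draw", "fixed"),
                                       rtol = 1e-3, atol = 1e-6) {
  det_fim_over_draws(profile, chain_draws(chain), jar, grid, noise,
                     match.arg(noise_source), rtol, atol)
}

#' Compare two designs draw-by-draw over a chain
#'
#' Computes the per-draw difference in FIM determinants (design B minus
#' design A) and summary statistics; a positive mean with a heavy right
#' tail indicates B is the more robust design.
#'
#' @param designA,designB [control_profile()] objects.
#' @inheritParams robust_criterion
#' @return List with `difference` (per-draw vector), `detA`, `detB`,
#'   `mean`, `skewness`, and `tail_counts` (draws where |difference|
#'   exceeds 2 standard deviations, split by sign).
#' @export
compare_designs <- function(designA, designB, chain, jar, grid,
                            noise = noise_params(),
                            noise_source = c("per_draw", "fixed"),
                            rtol = 1e-3, atol = 1e-6) {
  noise_source <- match.arg(noise_source)
  dA <- evaluate_design_over_chain(designA, chain, jar, grid, noise,
                                   noise_source, rtol, atol)
  dB <- evaluate_design_over_chain(designB, chain, jar, grid, noise,
                                   noise_source, rtol, atol)
  diff <- dB - dA
  s <- stats::sd(diff)
  m3 <- mean((diff - mean(diff))^3)
  list(difference = diff, detA = dA, detB = dB,
       mean = mean(diff),
       skewness = if (s > 0) m3 / s^3 else 0,
       tail_counts = c(negative = sum(diff < -2 * s),
                       positive = sum(diff > 2 * s)))
}
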