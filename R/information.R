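#' Fisher information matrix of a jar experiment
#'
#' For independent heteroscedastic Gaussian noise whose variance depends on
#' the noise-free outputs, the information about the kinetic parameters has
#' a mean-sensitivity and a variance-sensitivity contribution.  With
#' identity measurement function and diagonal noise covariance
#' `R = diag(v_1, v_2)`, `v_i = sigma2_i * y_i + floor`, the `(m,n)` entry
#' reduces to
#' `F_mn = sum_k sum_i s_kim s_kin (1/v_ki + sigma2_i^2 / (2 v_ki^2))`
#' with `s_kim = d y_i(t_k) / d theta_m`.
#'
#' @param straj a [simulate_sensitivities()] result.
#' @param noise a [noise_params()] object; `floor` must be > 0.
#' @return An object of class `fim_result`: fields `matrix` (6 x 6,
#'   symmetric PSD), `param_order`, `det`, `log_det`, `cond`.
#' @export
fisher_information <- function(straj, noise) {
  stopifnot(inherits(straj, "sensitivity_trajectory"))
  if (noise$floor <= 0)
    stop("variance floor must be > 0 for an invertible noise covariance")
  s2 <- c(noise$sigma2_O2, noise$sigma2_CO2)
  F <- matrix(0, 6, 6)
  for (i in 1:2) {
    v <- s2[i] * pmax(straj$states[, i], 0) + noise$floor
    w <- 1 / v + 0.5 * s2[i]^2 / v^2
    S <- straj$sens[, i, , drop = TRUE]
    if (is.null(dim(S))) S <- matrix(S, nrow = 1)   # N = 1 edge case
    F <- F + crossprod(S * sqrt(w))
  }
  F <- (F + t(F)) / 2
  dimnames(F) <- list(param_names(), param_names())
  new_fim(F)
}

new_fim <- function(F) {
  ev <- eigen(F, symmetric = TRUE, only.values = TRUE)$values
  ldet <- determinant(F, logarithm = TRUE)
  structure(list(matrix = F, param_order = colnames(F),
                 det = det(F),
                 log_det = as.numeric(ldet$modulus) *
                   ifelse(ldet$sign > 0, 1, NA),
                 cond = if (min(ev) > 0) max(ev) / min(ev) else Inf),
            class = "fim_result")
}

#' @export
print.fim_result <- function(x, ...) {
  cat(sprintf("Fisher information matrix (%d x %d): det = %.6g, cond = %.3g\n",
              nrow(x$matrix), ncol(x$matrix), x$det, x$cond))
  invisible(x)
}

#' D-optimality criterion
#'
#' The determinant of the Fisher information matrix, in natural (printed)
#' parameter units; maximizing it minimizes the volume of the asymptotic
#' parameter confidence ellipsoid.
#'
#' @param fim a [fisher_information()] result (or a plain matrix).
#' @param log return the log determinant instead (used internally by the
#'   optimizer for conditioning).
#' @return Scalar determinant (or log determinant).
#' @export
d_criterion <- function(fim, log = FALSE) {
  F <- if (inherits(fim, "fim_result")) fim$matrix else fim
  if (log) {
    ld <- determinant(F, logarithm = TRUE)
    return(if (ld$sign > 0) as.numeric(ld$modulus) else -Inf)
  }
  det(F)
}

# Shared fast path: per-draw FIM determinants for a chain (or plain draw
# matrix) on one design.  noise_source = "per_draw" uses the chain's own
# sigma2 columns, falling back to `noise` where absent.
det_fim_over_draws <- function(profile, draws, jar, grid, noise,
                               noise_source = c("per_draw", "fixed"),
                               rtol = 1e-3, atol = 1e-6) {
  noise_source <- match.arg(noise_source)
  Theta <- as.matrix(draws[, param_names(), drop = FALSE])
  R <- nrow(Theta)
  if (R < 1) stop("empty parameter chain")
  has_s2 <- all(c("sigma2_O2", "sigma2_CO2") %in% colnames(draws))
  sig2 <- if (noise_source == "per_draw" && has_s2)
    as.matrix(draws[, c("sigma2_O2", "sigma2_CO2"), drop = FALSE])
  else
    matrix(c(noise$sigma2_O2, noise$sigma2_CO2), R, 2, byrow = TRUE)
  .cpp_det_fim(Theta, sig2, unclass(jar), profile$u, profile$te,
               grid$times, noise$floor, rtol, atol)
}

#' Robust (pseudo-Bayesian) D-criterion
#'
#' The arithmetic mean of `det F(theta_r, u)` over all draws of a
#' parameter chain: the Monte-Carlo approximation of the expected
#' D-criterion under the prior represented by the chain.
#'
#' @param profile a [control_profile()] design.
#' @param chain a [parameter_chain()] of prior draws.
#' @param jar,grid experiment configuration.
#' @param noise a [noise_params()] object supplying the variance floor and
#'   the fallback noise scales.
#' @param noise_source `"per_draw"` uses each draw's own `sigma2` columns
#'   when present (the default); `"fixed"` uses `noise` for every draw.
#' @param rtol,atol integration tolerances.
#' @return Scalar mean determinant.
#' @export
robust_criterion <- function(profile, chain, jar, grid,
                             noise = noise_params(),
                             noise_source = c("per_draw", "fixed"),
                             rtol = 1e-3, atol = 1e-6) {
  mean(det_fim_over_draws(profile, chain_draws(chain), jar, grid, noise,
                          noise_source, rtol, atol))
}

#' Precision summary from a Fisher information matrix
#'
#' Inverts the FIM to obtain the Cramer-Rao covariance lower bound and
#' summarizes it: per-parameter coefficients of variation
#' `CoV_m = sqrt(cov_mm) / theta_m`, the correlation matrix, and 95%
#' confidence-ellipsoid axes for the two 3-parameter blocks
#' (Vm_O2, Km_O2, inv_Kmn_CO2) and (rq, Vmf_CO2, Kmf_O2), scaled by the
#' chi-squared(3) quantile.
#'
#' @param fim a [fisher_information()] result.
#' @param params the [kinetic_params()] at which the FIM was evaluated.
#' @return List with `cov`, `cov_pct` (CoV as a fraction), `correlation`,
#'   and `ellipsoids` (per block: eigenvectors and semi-axis lengths).
#' @export
precision_summary <- function(fim, params) {
  F <- fim$matrix
  theta <- as_param_vector(params)
  ev <- eigen(F, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-12
  if (!all(pos)) {
    # singular information: infinite uncertainty along null directions
    inv_vals <- ifelse(pos, 1 / ev$values, Inf)
  } else inv_vals <- 1 / ev$values
  cov <- ev$vectors %*% (ifelse(is.finite(inv_vals), inv_vals, 0) *
                           t(ev$vectors))
  dimnames(cov) <- dimnames(F)
  se <- sqrt(pmax(diag(cov), 0))
  if (!all(pos)) se[] <- Inf
  cov_frac <- se / abs(theta)
  corr <- cov / outer(se, se)
  diag(corr) <- 1
  q <- stats::qchisq(0.95, df = 3)
  ellips <- lapply(list(block1 = 1:3, block2 = 4:6), function(idx) {
    e <- eigen(cov[idx, idx], symmetric = TRUE)
    list(params = param_names()[idx], axes = e$vectors,
         semi_lengths = sqrt(pmax(e$values, 0) * q))
  })
  list(cov = cov, cov_pct = cov_frac, correlation = corr,
       ellipsoids = ellips)
}

#' Export a FIM (or any labeled matrix) as CSV / JSON-ready list
#'
#' @param fim a [fisher_information()] result.
#' @param path CSV output path.
#' @return Invisibly, the path.
#' @export
write_fim <- function(fim, path) {
  utils::write.csv(as.data.frame(fim$matrix), path, row.names = TRUE)
  invisible(path)
}
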