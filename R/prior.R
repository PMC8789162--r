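#' Parameter chain: ordered posterior draws
#'
#' A thin wrapper around a data frame with bookkeeping columns `chain_id`
#' and `step` plus one column per parameter.  The six canonical kinetic
#' columns ([param_names()], with the CO2 inhibition constant stored as
#' `inv_Kmn_CO2`) are required; nuisance columns (`Ea_O2`, `Ea_CO2`,
#' `sigma2_O2`, `sigma2_CO2`) and any extra columns are preserved.
#'
#' @param draws data frame of draws.
#' @param chain_id,step optional bookkeeping vectors; defaults are a single
#'   chain with consecutive steps.
#' @return An object of class `parameter_chain` (also a data.frame).
#' @export
parameter_chain <- function(draws, chain_id = NULL, step = NULL) {
  draws <- as.data.frame(draws)
  missing_cols <- setdiff(param_names(), names(draws))
  if (length(missing_cols))
    stop("chain lacks canonical columns: ",
         paste(missing_cols, collapse = ", "))
  if (is.null(chain_id))
    chain_id <- if ("chain_id" %in% names(draws)) draws$chain_id else 1L
  if (is.null(step))
    step <- if ("step" %in% names(draws)) draws$step
    else stats::ave(seq_len(nrow(draws)), chain_id, FUN = seq_along)
  draws$chain_id <- as.integer(chain_id)
  draws$step <- as.integer(step)
  front <- c("chain_id", "step")
  draws <- draws[, c(front, setdiff(names(draws), front))]
  if (any(draws$rq > 1) || any(draws[, param_names()] < 0))
    stop("chain draws violate kinetic parameter constraints")
  class(draws) <- c("parameter_chain", "data.frame")
  draws
}

#' @export
print.parameter_chain <- function(x, ...) {
  cat(sprintf("Parameter chain: %d draws, %d chain(s)\n",
              nrow(x), length(unique(x$chain_id))))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

# draw matrix without bookkeeping columns
chain_draws <- function(chain) {
  if (inherits(chain, "parameter_chain"))
    as.data.frame(chain)[, setdiff(names(chain), c("chain_id", "step")),
                         drop = FALSE]
  else as.data.frame(chain)
}

#' Read / write parameter chains as CSV
#'
#' Values round-trip at full printed precision (15 significant digits).
#'
#' @param path CSV file with a header; must contain the canonical kinetic
#'   columns, unrecognized columns are kept.
#' @return `load_chain()` returns a [parameter_chain()].
#' @export
load_chain <- function(path) {
  parameter_chain(utils::read.csv(path))
}

#' @rdname load_chain
#' @param chain a [parameter_chain()].
#' @export
save_chain <- function(chain, path) {
  d <- as.data.frame(chain)
  num <- vapply(d, is.numeric, logical(1)) & !(names(d) %in% c("chain_id", "step"))
  d[num] <- lapply(d[num], function(x) sprintf("%.17g", x))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Burn-in and thinning
#'
#' Per chain, drop the first `burn` steps and keep every `thin`-th of the
#' remainder (the first kept step is `burn + 1`).
#'
#' @param chain a [parameter_chain()].
#' @param burn number of initial steps to discard per chain.
#' @param thin thinning factor (keep one draw in `thin`).
#' @return A [parameter_chain()] with renumbered steps retained from the
#'   original `step` labels.
#' @export
burn_and_thin <- function(chain, burn, thin = 1L) {
  stopifnot(burn >= 0, thin >= 1)
  d <- as.data.frame(chain)
  keep <- unlist(lapply(split(seq_len(nrow(d)), d$chain_id), function(idx) {
    idx <- idx[order(d$step[idx])]
    if (burn >= length(idx))
      stop("burn-in (", burn, ") exceeds chain length (", length(idx), ")")
    rest <- idx[(burn + 1):length(idx)]
    rest[seq(1, length(rest), by = thin)]
  }), use.names = FALSE)
  out <- d[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("parameter_chain", "data.frame")
  out
}

#' Chain mean and covariance
#'
#' Sample mean and unbiased sample covariance of the six parameters of
#' interest, computed in the inverse-Kmn parameterization.
#'
#' @param chain a [parameter_chain()].
#' @param columns which columns to summarize (default the six canonical
#'   kinetic parameters).
#' @return List with `mean` (named vector) and `cov` (matrix; requires at
#'   least two draws).
#' @export
chain_summary <- function(chain, columns = param_names()) {
  d <- as.data.frame(chain)[, columns, drop = FALSE]
  m <- colMeans(d)
  if (nrow(d) < 2)
    stop("covariance requires at least two draws")
  list(mean = m, cov = stats::cov(as.matrix(d)))
}

#' Convert a chain between inverse and direct Kmn parameterizations
#'
#' @param chain a [parameter_chain()].
#' @param to `"direct"` replaces `inv_Kmn_CO2` by `Kmn_CO2 = 1/inv`;
#'   `"inverse"` does the reverse.
#' @return A data frame (direct form) or [parameter_chain()] (inverse
#'   form); converting there and back is the identity where values are
#'   finite.
#' @export
convert_chain <- function(chain, to = c("direct", "inverse")) {
  to <- match.arg(to)
  d <- as.data.frame(chain)
  if (to == "direct") {
    if (!"inv_Kmn_CO2" %in% names(d)) stop("chain is already direct")
    d$Kmn_CO2 <- 1 / d$inv_Kmn_CO2
    d$inv_Kmn_CO2 <- NULL
    d
  } else {
    if (!"Kmn_CO2" %in% names(d)) stop("chain is already inverse")
    d$inv_Kmn_CO2 <- 1 / d$Kmn_CO2
    d$Kmn_CO2 <- NULL
    parameter_chain(d)
  }
}

#' Sigma points of the unscented transform
#'
#' Generates the `2n + 1` deterministic points and weights that match a
#' given mean and covariance: the center plus the mean shifted along the
#' columns of a scaled matrix square root of the covariance.  The scaled
#' unscented transform with parameters `(alpha, beta, kappa)` is used;
#' the default `alpha = 1, beta = 0, kappa = 3 - n` is the classic
#' recommendation for near-Gaussian priors.
#'
#' @param mean length-n mean vector.
#' @param cov n x n symmetric positive semi-definite covariance.
#' @param alpha,beta,kappa scaling parameters of the transform.
#' @param clip_negative clip coordinates below zero (kinetic parameters
#'   are nonnegative) to `eps_frac` times the mean, with a warning.
#' @param eps_frac clipping floor as a fraction of the mean coordinate.
#' @return An object of class `sigma_point_set`: `points`
#'   (`(2n+1) x n`), `weights_mean`, `weights_cov`.
#' @export
sigma_points <- function(mean, cov, alpha = 1, beta = 0,
                         kappa = 3 - length(mean),
                         clip_negative = TRUE, eps_frac = 1e-8) {
  n <- length(mean)
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == n, ncol(cov) == n)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance must be symmetric")
  lambda <- alpha^2 * (n + kappa) - n
  scl <- n + lambda
  if (scl <= 0) stop("alpha/kappa give a nonpositive scaling n + lambda")
  L <- tryCatch(t(chol(scl * cov)), error = function(e) {
    e <- eigen(scl * cov, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values), 1))
      stop("covariance is not positive semi-definite")
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
  })
  pts <- rbind(mean,
               t(mean + L),
               t(mean - L))
  rownames(pts) <- NULL
  colnames(pts) <- names(mean)
  wm <- c(lambda / scl, rep(1 / (2 * scl), 2 * n))
  wc <- wm
  wc[1] <- wc[1] + (1 - alpha^2 + beta)
  if (clip_negative && any(pts < 0)) {
    floor_pt <- pmax(eps_frac * abs(mean), .Machine$double.xmin)
    for (j in seq_len(n)) {
      bad <- pts[, j] < 0
      if (any(bad)) {
        warning("clipping ", sum(bad), " negative sigma-point coordinate(s) ",
                "in '", colnames(pts)[j] %||% j, "'")
        pts[bad, j] <- floor_pt[j]
      }
    }
  }
  structure(list(points = pts, weights_mean = wm, weights_cov = wc,
                 alpha = alpha, beta = beta, kappa = kappa),
            class = "sigma_point_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sigma_point_set <- function(x, ...) {
  cat(sprintf("Sigma-point set: %d points in %d dimensions\n",
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' Write sigma points as CSV
#'
#' @param sp a [sigma_points()] result.
#' @param path output path.
#' @export
write_sigma_points <- function(sp, path) {
  d <- data.frame(weight_mean = sp$weights_mean,
                  weight_cov = sp$weights_cov, sp$points)
  utils::write.csv(format(d, digits = 15), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
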