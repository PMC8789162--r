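#' Piecewise-constant control profile
#'
#' The three controllable inputs -- inflow rate and inlet O2 / CO2 partial
#' pressures -- are held constant on `M` equal subintervals of `[0, te]`.
#' The profile is right-continuous with left limits; its value at `t = te`
#' is defined as the last interval's value (the endpoint value carries no
#' information and does not affect the Fisher information matrix).
#'
#' @param u numeric `M x 3` matrix, one row per interval, columns
#'   `(Qin_m3_h, pO2_in_kPa, pCO2_in_kPa)`; a length-3 vector is treated as
#'   a single-interval profile.
#' @param te experiment end time, h.
#' @param umin,umax per-channel bounds; defaults follow the reference
#'   setup: flow between 0.1 and 4 l/h, inlet gases between 0 and 21 kPa.
#'   The flow lower bound is strictly positive because the design criteria
#'   are flat in the gas inputs at zero flow.
#' @return An object of class `control_profile`.
#' @export
control_profile <- function(u, te = 24,
                            umin = c(1e-4, 0, 0),
                            umax = c(4e-3, 21, 21)) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  u <- as.matrix(u)
  stopifnot(ncol(u) == 3, nrow(u) >= 1, te > 0,
            length(umin) == 3, length(umax) == 3)
  colnames(u) <- c("Qin_m3_h", "pO2_in_kPa", "pCO2_in_kPa")
  eps <- 1e-9
  for (j in 1:3)
    if (any(u[, j] < umin[j] - eps) || any(u[, j] > umax[j] + eps))
      stop("control values violate the bounds in channel ", j)
  structure(list(u = u, M = nrow(u), te = te,
                 umin = as.numeric(umin), umax = as.numeric(umax)),
            class = "control_profile")
}

#' Evaluate a control profile at given times
#'
#' @param profile a [control_profile()] object.
#' @param t vector of times in `[0, te]`, h.
#' @return Numeric `length(t) x 3` matrix of control values.
#' @export
control_at <- function(profile, t) {
  stopifnot(all(t >= 0), all(t <= profile$te))
  j <- pmin(floor(t * profile$M / profile$te) + 1L, profile$M)
  profile$u[j, , drop = FALSE]
}

#' @export
print.control_profile <- function(x, ...) {
  cat(sprintf("Piecewise-constant control profile: M = %d intervals over %g h\n",
              x$M, x$te))
  print(utils::head(x$u, 12))
  if (x$M > 12) cat("...\n")
  invisible(x)
}

#' Write / read a design as CSV
#'
#' Columns: `interval,start_h,end_h,Qin_l_per_h,pO2in_kPa,pCO2in_kPa`.
#' Flow is written in l/h for readability and converted back on read.
#'
#' @param profile a [control_profile()] object.
#' @param path file path.
#' @return `read_design()` returns a `control_profile`.
#' @export
write_design <- function(profile, path) {
  M <- profile$M
  d <- data.frame(interval = seq_len(M),
                  start_h = (seq_len(M) - 1) * profile$te / M,
                  end_h = seq_len(M) * profile$te / M,
                  Qin_l_per_h = profile$u[, 1] * 1000,
                  pO2in_kPa = profile$u[, 2],
                  pCO2in_kPa = profile$u[, 3])
  utils::write.csv(format(d, digits = 12, scientific = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @param te,umin,umax passed to [control_profile()].
#' @export
read_design <- function(path, te = NULL, umin = c(1e-4, 0, 0),
                        umax = c(4e-3, 21, 21)) {
  d <- utils::read.csv(path)
  need <- c("Qin_l_per_h", "pO2in_kPa", "pCO2in_kPa")
  if (!all(need %in% names(d)))
    stop("design file lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  if (is.null(te)) te <- max(d$end_h)
  control_profile(cbind(d$Qin_l_per_h / 1000, d$pO2in_kPa, d$pCO2in_kPa),
                  te = te, umin = umin, umax = umax)
}
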