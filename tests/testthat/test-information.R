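test_that("zero sensitivities give a zero information matrix", {
  grid <- small_grid(24)
  st <- simulate_sensitivities(jar_setup(mp = 0), bench_profile(),
                               ref_params(), grid)
  fim <- fisher_information(st, ref_noise())
  expect_equal(max(abs(fim$matrix)), 0)
  expect_equal(fim$det, 0)
})

test_that("scalar reduction: one time point, one effective parameter", {
  # craft a sensitivity trajectory with a single nonzero sensitivity s on
  # the O2 channel; the information about that parameter reduces to
  # s^2 / v + (sigma2 * s / v)^2 / 2
  st <- structure(list(
    times = 1,
    states = matrix(c(10, 0), 1, 2,
                    dimnames = list(NULL, c("pO2_kPa", "pCO2_kPa"))),
    sens = array(0, c(1, 2, 6),
                 dimnames = list(NULL, c("pO2", "pCO2"), param_names())),
    params = ref_params()), class = "sensitivity_trajectory")
  s <- 3.7
  st$sens[1, "pO2", "Vm_O2"] <- s
  n <- ref_noise()
  v <- n$sigma2_O2 * 10 + n$floor
  fim <- fisher_information(st, n)
  expect_equal(fim$matrix["Vm_O2", "Vm_O2"],
               s^2 / v + 0.5 * (n$sigma2_O2 * s / v)^2, tolerance = 1e-12)
  expect_equal(sum(abs(fim$matrix)) , abs(fim$matrix["Vm_O2", "Vm_O2"]))
})

test_that("variance-dependence term is included (constant-mean check)", {
  # if only the variance carried information the mean term would vanish;
  # verify the weight exceeds the pure mean-term weight 1/v
  st <- structure(list(
    times = 1,
    states = matrix(c(10, 0), 1, 2),
    sens = array(0, c(1, 2, 6),
                 dimnames = list(NULL, c("pO2", "pCO2"), param_names())),
    params = ref_params()), class = "sensitivity_trajectory")
  st$sens[1, 1, 1] <- 1
  n <- ref_noise()
  v <- n$sigma2_O2 * 10 + n$floor
  fim <- fisher_information(st, n)
  expect_gt(fim$matrix[1, 1], 1 / v)
})

test_that("D-criterion basics: identity, homogeneity, hand determinant", {
  expect_equal(d_criterion(diag(6)), 1)
  F <- diag(c(1, 2, 3, 4, 5, 6))
  expect_equal(d_criterion(3 * F), 3^6 * d_criterion(F))
  expect_equal(d_criterion(matrix(c(4, 1, 1, 1), 2)), 3)
  expect_equal(d_criterion(diag(6), log = TRUE), 0)
})

test_that("FIM is symmetric PSD and invariant under parameter permutation", {
  grid <- small_grid(48)
  st <- simulate_sensitivities(jar_setup(), bench_profile(), ref_params(),
                               grid)
  fim <- fisher_information(st, ref_noise())
  F <- fim$matrix
  expect_lt(max(abs(F - t(F))) / max(abs(F)), 1e-8)
  ev <- eigen(F, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(F)))

  perm <- c(3, 1, 6, 2, 5, 4)
  st2 <- st
  st2$sens <- st$sens[, , perm]
  F2 <- fisher_information(st2, ref_noise())$matrix
  expect_equal(unname(F2), unname(F[perm, perm]), tolerance = 1e-12)
  expect_equal(det(F2), det(F), tolerance = 1e-8)
})

test_that("information is additive over the grid and det is monotone", {
  set.seed(202)
  jar <- jar_setup()
  n <- ref_noise()
  for (case in 1:10) {
    p <- random_params()
    prof <- random_profile(M = 6)
    g_full <- small_grid(48)
    g_half <- small_grid(24)   # every other point of the full grid
    st_full <- simulate_sensitivities(jar, prof, p, g_full,
                                      rtol = 1e-8, atol = 1e-10)
    F_full <- fisher_information(st_full, n)$matrix
    # sub-grid FIM assembled from the same sensitivities
    st_half <- st_full
    idx <- seq(2, 48, by = 2)
    st_half$times <- st_full$times[idx]
    st_half$states <- st_full$states[idx, , drop = FALSE]
    st_half$sens <- st_full$sens[idx, , , drop = FALSE]
    F_half <- fisher_information(st_half, n)$matrix
    st_rest <- st_full
    idx2 <- seq(1, 47, by = 2)
    st_rest$times <- st_full$times[idx2]
    st_rest$states <- st_full$states[idx2, , drop = FALSE]
    st_rest$sens <- st_full$sens[idx2, , , drop = FALSE]
    F_rest <- fisher_information(st_rest, n)$matrix
    expect_equal(F_full, F_half + F_rest, tolerance = 1e-10)
    expect_gte(det(F_full), det(F_half) * (1 - 1e-8))
    # sanity: the independently integrated sub-grid agrees
    st_dir <- simulate_sensitivities(jar, prof, p, g_half,
                                     rtol = 1e-8, atol = 1e-10)
    F_dir <- fisher_information(st_dir, n)$matrix
    expect_equal(F_dir, F_half, tolerance = 1e-4 * max(abs(F_half)))
  }
})

test_that("FIM matches the Hessian of the expected log-likelihood", {
  # Fisher identity, brute force: F = -E[grad^2 log L], the expectation
  # taken under the model at the same parameters, on a coarse grid
  jar <- jar_setup()
  grid <- small_grid(48)
  prof <- bench_profile()
  noise <- ref_noise()
  th0 <- as_param_vector(ref_params())

  st <- simulate_sensitivities(jar, prof, ref_params(), grid,
                               rtol = 1e-10, atol = 1e-12)
  F <- fisher_information(st, noise)$matrix

  f <- function(th) expected_loglik(th, th0, jar, prof, grid, noise)
  h <- 1e-2 * abs(th0)
  H <- matrix(0, 6, 6)
  for (m in 1:6) {
    em <- replace(numeric(6), m, h[m])
    H[m, m] <- (f(th0 + em) - 2 * f(th0) + f(th0 - em)) / h[m]^2
    for (nn in seq_len(m - 1)) {
      en <- replace(numeric(6), nn, h[nn])
      H[m, nn] <- H[nn, m] <-
        (f(th0 + em + en) - f(th0 + em - en) -
           f(th0 - em + en) + f(th0 - em - en)) / (4 * h[m] * h[nn])
    }
  }
  rel <- abs(F + H) / max(abs(F))
  expect_lt(max(rel), 1e-2)
})

test_that("robust criterion is exactly the mean of per-draw determinants", {
  jar <- jar_setup()
  grid <- small_grid(24)
  prof <- bench_profile()
  chain <- make_synthetic_chain(R = 6, seed = 3, tail_frac = 0)
  dets <- evaluate_design_over_chain(prof, chain, jar, grid, ref_noise())
  expect_identical(robust_criterion(prof, chain, jar, grid, ref_noise()),
                   mean(dets))

  # single draw and R identical draws both reduce to the local criterion
  one <- chain[1, , drop = FALSE]
  class(one) <- class(chain)
  d1 <- robust_criterion(prof, one, jar, grid, ref_noise())
  rep5 <- chain[rep(1, 5), , drop = FALSE]
  class(rep5) <- class(chain)
  expect_equal(robust_criterion(prof, rep5, jar, grid, ref_noise()), d1)

  # two draws with known determinants average exactly
  two <- chain[1:2, , drop = FALSE]
  class(two) <- class(chain)
  expect_equal(robust_criterion(prof, two, jar, grid, ref_noise()),
               (dets[1] + dets[2]) / 2, tolerance = 1e-12)

  empty <- chain[0, , drop = FALSE]
  class(empty) <- class(chain)
  expect_error(robust_criterion(prof, empty, jar, grid, ref_noise()),
               "empty")
})

test_that("per-draw noise scales are used when present, else the fixed ones", {
  jar <- jar_setup()
  grid <- small_grid(24)
  prof <- bench_profile()
  chain <- make_synthetic_chain(R = 3, seed = 9, tail_frac = 0)
  d_per <- evaluate_design_over_chain(prof, chain, jar, grid, ref_noise(),
                                      noise_source = "per_draw")
  d_fix <- evaluate_design_over_chain(prof, chain, jar, grid, ref_noise(),
                                      noise_source = "fixed")
  expect_false(isTRUE(all.equal(d_per, d_fix)))
})

test_that("precision summary inverts the FIM and flags the hard parameters", {
  p <- ref_params()
  theta <- as_param_vector(p)
  d <- c(4e6, 2e3, 9e7, 8e5, 5e6, 1e4)
  fim <- structure(list(matrix = diag(d), param_order = param_names(),
                        det = prod(d), log_det = sum(log(d)),
                        cond = max(d) / min(d)), class = "fim_result")
  dimnames(fim$matrix) <- list(param_names(), param_names())
  ps <- precision_summary(fim, p)
  expect_equal(unname(ps$cov_pct), unname(1 / (theta * sqrt(d))),
               tolerance = 1e-10)
  expect_equal(unname(ps$correlation), diag(6), tolerance = 1e-12)
  # block-diagonal FIM: no cross-block correlation, ellipsoid axes from
  # the inverse eigenvalues scaled by the chi-squared(3) quantile
  expect_equal(ps$ellipsoids$block1$semi_lengths,
               sort(sqrt(stats::qchisq(0.95, 3) / d[1:3]),
                    decreasing = TRUE),
               tolerance = 1e-10)
})
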