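test_that("across-Delta regressions match the normal-equations oracle", {
  set.seed(4)
  De <- c(10, 20, 30, 40, 50)
  vic <- 0.65 - 0.001 * De + rnorm(5, 0, 0.01)
  fit <- extrapolate_icv(data.frame(Delta = De, v_ic = vic))
  oracle <- ols_normal_equations(De, vic)
  expect_equal(fit$icv0, oracle[1], tolerance = 1e-12)
  expect_equal(fit$slope, oracle[2], tolerance = 1e-12)

  dpar <- 0.9 - 0.002 * De + rnorm(5, 0, 0.01)
  fit2 <- fit_parallel_diffusivity(data.frame(Delta = De, d_par = dpar))
  oracle2 <- ols_normal_equations(De, dpar)
  expect_equal(fit2$d0, oracle2[1], tolerance = 1e-12)
  expect_equal(fit2$c1, oracle2[2], tolerance = 1e-12)
})

test_that("regression edge cases: exact lines, constants, clamping, errors", {
  De <- c(10, 20, 30, 40, 50)
  exact <- extrapolate_icv(data.frame(Delta = De, v_ic = 0.65 - 0.001 * De))
  expect_equal(exact$icv0, 0.65, tolerance = 1e-12)
  expect_equal(exact$slope, -0.001, tolerance = 1e-12)
  expect_false(exact$clamped)

  const <- extrapolate_icv(data.frame(Delta = De, v_ic = rep(0.6, 5)))
  expect_equal(const$icv0, 0.6, tolerance = 1e-12)
  expect_equal(const$slope, 0, tolerance = 1e-12)

  over <- extrapolate_icv(data.frame(Delta = c(10, 50), v_ic = c(1.0, 0.8)))
  expect_true(over$clamped)
  expect_equal(over$icv0, 1)

  expect_error(extrapolate_icv(data.frame(Delta = 10, v_ic = 0.5)),
               "at least 2")
  expect_error(extrapolate_icv(data.frame(Delta = c(10, 10),
                                          v_ic = c(0.5, 0.6))),
               "distinct")

  expect_equal(fit_parallel_diffusivity(
    data.frame(Delta = De, d_par = 0.9 - 0.002 * De))$d0, 0.9,
    tolerance = 1e-12)
  expect_error(fit_parallel_diffusivity(
    data.frame(Delta = De, d_par = -0.5 + 0.001 * De)), "non-positive")
})

test_that("radius fitting inverts the forward perpendicular model", {
  De <- c(10, 20, 30, 40, 50)
  mk <- function(r, d0 = 0.9) data.frame(
    Delta = De,
    dperp = vapply(De, function(D) dperp_app(r, d0, D, 2.5), numeric(1)))
  fit <- fit_radii(list(mk(6.7), mk(6.7)), d0 = 0.9, delta = 2.5)
  expect_lt(abs(fit$r1 - 6.7), 0.01)
  expect_equal(fit$r1, fit$r2)  # identical inputs -> equal radii

  fit2 <- fit_radii(list(mk(8.7), mk(5.1)), d0 = 0.9, delta = 2.5)
  expect_lt(abs(fit2$r1 - 8.7), 0.01)
  expect_lt(abs(fit2$r2 - 5.1), 0.01)
  expect_true(fit2$r1 >= fit2$r2)

  # unrestricted-looking data (dperp == d0) carries no size information
  free <- data.frame(Delta = De, dperp = rep(0.9, 5))
  expect_warning(fb <- fit_radii(list(free), d0 = 0.9, delta = 2.5),
                 "bound")
  expect_gt(fb$r1, 29)
})

test_that("radius fitting agrees with an exhaustive fine-grid minimiser", {
  set.seed(21)
  De <- c(10, 20, 30, 40, 50)
  roots <- bessel_j1prime_roots(100)
  for (i in 1:10) {
    r_true <- runif(1, 2, 12)
    d0 <- runif(1, 0.6, 1.2)
    df <- data.frame(Delta = De, dperp = vapply(De, function(D)
      dperp_app(r_true, d0, D, 2.5, roots = roots), numeric(1)) +
        rnorm(5, 0, 0.005))
    fit <- fit_radii(list(df), d0 = d0, delta = 2.5)
    grid <- seq(0.5, 30, by = 0.01)
    cost <- vapply(grid, function(r) {
      pred <- vapply(De, function(D) dperp_app(r, d0, D, 2.5,
                                               roots = roots), numeric(1))
      sum((df$dperp - pred)^2)
    }, numeric(1))
    expect_lt(abs(fit$r1 - grid[which.min(cost)]), 0.02)
  }
})

test_that("noiseless step-1 fits recover the generating parameters", {
  sch <- scheme_1delta()
  s <- tensor_tensor_signal(as.list(tt_truth), sch)
  fit <- fit_tensor_tensor(measurement_vector(s, sch),
                           fixed = list(d_ec_par = 2.1), restarts = 10,
                           seed = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params[1:7] - tt_truth[1:7])), 1e-3)
  expect_lt(fit$rmse, 1e-6)
  # canonical orderings on the reported parameters
  expect_true(fit$params[["d_ic_par"]] >= fit$params[["d_ic_perp1"]])
  expect_true(fit$params[["d_ic_perp1"]] >= fit$params[["d_ic_perp2"]])
})

test_that("a single-compartment signal collapses the mixture", {
  sch <- scheme_1delta()
  ec_only <- tensor_signal(list(d_par = 2.1, d_perp1 = 1.6, d_perp2 = 1.0,
                                theta = 0, phi = 0, alpha = 0), sch)
  fit <- fit_tensor_tensor(measurement_vector(ec_only, sch),
                           fixed = list(d_ec_par = 2.1), restarts = 10,
                           seed = 3)
  expect_lt(fit$params[["v_ic"]], 0.02)
  expect_lt(abs(fit$params[["d_ec_perp1"]] - 1.6), 0.02)
  expect_lt(abs(fit$params[["d_ec_perp2"]] - 1.0), 0.02)
})

test_that("degenerate inputs raise contract errors", {
  b0only <- build_protocol_scheme(n_dirs = 1, bvals = 0.5, Deltas = 10)[1, ]
  class(b0only) <- c("dwi_scheme", "data.frame")
  expect_error(fit_tensor_tensor(measurement_vector(1, b0only)),
               "under-determined")
  sch <- scheme_full()
  s <- tensor_tensor_signal(as.list(tt_truth), sch)
  expect_error(fit_tensor_tensor(measurement_vector(s, sch)),
               "single diffusion time")
})

test_that("the profiled Gaussian objective ranks fits like the RMSE", {
  sch <- scheme_1delta()
  s <- add_rician_noise(tensor_tensor_signal(as.list(tt_truth), sch),
                        0.02, seed = 5)
  mv <- measurement_vector(s, sch)
  cands <- lapply(c(2, 9, 17, 33), function(k)
    fit_tensor_tensor(mv, fixed = list(d_ec_par = 2.1), restarts = 1,
                      seed = k, init = list(v_ic = runif(1))))
  rmse <- vapply(cands, `[[`, numeric(1), "rmse")
  nll <- vapply(cands, `[[`, numeric(1), "objective")
  expect_equal(order(rmse), order(nll))
})

test_that("estimator recovers random ground truths at high SNR", {
  sch <- scheme_1delta()
  set.seed(31)
  errs <- matrix(NA_real_, 50, 7)
  for (i in 1:50) {
    perp_ic <- sort(runif(2, 0.2, 0.7), decreasing = TRUE)
    perp_ec <- sort(runif(2, 0.8, 1.8), decreasing = TRUE)
    p <- c(v_ic = runif(1, 0.35, 0.75),
           d_ic_par = runif(1, max(perp_ic[1], 0.7), 1.3),
           d_ic_perp1 = perp_ic[1], d_ic_perp2 = perp_ic[2],
           d_ec_par = runif(1, 1.9, 2.4),
           d_ec_perp1 = perp_ec[1], d_ec_perp2 = perp_ec[2],
           theta = runif(1, 0, pi / 2), phi = runif(1, -pi, pi),
           alpha = runif(1, -pi, pi))
    s <- add_rician_noise(tensor_tensor_signal(as.list(p), sch),
                          snr_db_to_sigma(80), seed = 100 + i)
    fit <- fit_tensor_tensor(measurement_vector(s, sch),
                             fixed = list(d_ec_par = unname(p["d_ec_par"])),
                             restarts = 3, seed = i)
    errs[i, ] <- (fit$params[1:7] - p[1:7]) / c(1, 3, 3, 3, 3, 3, 3)
  }
  med <- apply(abs(errs), 2, median)
  expect_true(all(med < 0.02))
})

test_that("hierarchical fit recovers diameters and ICV from 5-Delta data", {
  truth <- list(v_ic = 0.6, d = 0.9, r1 = 8.7, r2 = 5.1,
                d_ec_par = 2.1, d_ec_perp1 = 1.6, d_ec_perp2 = 1.0,
                theta = 0, phi = 0, alpha = 0)
  mv <- generate_synthetic_dataset(truth, scheme_full(),
                                   noise = noise_spec(60, seed = 8))
  fit <- hierarchical_fit(mv, restarts = 4, seed = 2)
  expect_lt(abs(fit$diameter_major - 17.4) / 17.4, 0.10)
  expect_lt(abs(fit$diameter_minor - 10.2) / 10.2, 0.10)
  expect_lt(abs(fit$icv0 - 0.6), 0.05)
  expect_true(fit$r1 >= fit$r2)
})

test_that("hierarchical fit flags degenerate and insufficient inputs", {
  sch <- scheme_full()
  # single-compartment extracellular-like data: ICV extrapolates to ~0
  ec_only <- tensor_signal(list(d_par = 2.1, d_perp1 = 1.6, d_perp2 = 1.0,
                                theta = 0, phi = 0, alpha = 0), sch)
  fit <- suppressWarnings(
    hierarchical_fit(measurement_vector(ec_only, sch), restarts = 4,
                     seed = 1))
  expect_lt(fit$icv0, 0.05)

  # an unrestricted (Gaussian) intracellular pool shows no diffusion-time
  # dependence, so the radius search runs into its bound and is flagged
  free_ic <- tensor_tensor_signal(list(
    v_ic = 0.6, d_ic_par = 0.9, d_ic_perp1 = 0.9, d_ic_perp2 = 0.9,
    d_ec_par = 2.1, d_ec_perp1 = 1.6, d_ec_perp2 = 1.0,
    theta = 0, phi = 0, alpha = 0), sch)
  fit2 <- suppressWarnings(
    hierarchical_fit(measurement_vector(free_ic, sch), restarts = 4,
                     seed = 1))
  expect_true(any(fit2$radius_at_bound))

  one_delta <- generate_synthetic_dataset(as.list(tt_truth), scheme_1delta())
  expect_error(hierarchical_fit(one_delta), ">= 2 diffusion")
})
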