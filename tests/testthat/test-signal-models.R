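test_that("orientation angles produce orthonormal right-handed frames", {
  expect_equal(angles_to_frame(0, 0, 0)[, 1], c(0, 0, 1), tolerance = 1e-14)
  expect_equal(angles_to_frame(pi / 2, 0, 0)[, 1], c(1, 0, 0),
               tolerance = 1e-14)
  set.seed(11)
  for (i in 1:25) {
    ang <- c(runif(1, 0, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    U <- angles_to_frame(ang[1], ang[2], ang[3])
    expect_equal(unname(crossprod(U)), diag(3), tolerance = 1e-12)
    expect_equal(det(U), 1, tolerance = 1e-12)
    # chart inversion reproduces the frame
    back <- frame_to_angles(U)
    U2 <- angles_to_frame(back[1], back[2], back[3])
    expect_equal(U2, U, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("roots of J1' match an independent series oracle", {
  r <- bessel_j1prime_roots(25)
  # frozen values computed by bisection on the series oracle
  expect_equal(r[1], 1.8411837813, tolerance = 1e-9)
  expect_equal(r[2], 5.3314427735, tolerance = 1e-9)
  # the ascending series loses precision to cancellation beyond x ~ 15,
  # so the oracle checks the first few roots only
  expect_true(all(abs(j1prime_series(r[1:4])) < 1e-10))
  expect_true(all(diff(r) > 0))
  # asymptotic spacing approaches pi (within 1% by the 20th root)
  expect_lt(abs(diff(r)[20] - pi) / pi, 0.01)
})

test_that("parallel attenuation is the free Stejskal-Tanner coefficient", {
  expect_equal(L_parallel(0, 50, 2.5), 0)
  expect_equal(L_parallel(1.8, 50, 2.5), 2 * L_parallel(0.9, 50, 2.5))
  ge2 <- (2.6752218744e8 * 1e-12)^2
  expect_equal(L_parallel(0.9, 50, 2.5) / (ge2 * 2.5^2 * (50 - 2.5 / 3)),
               0.9, tolerance = 1e-12)
  expect_error(L_parallel(0.9, 0.5, 2.5), "delta/3")
})

test_that("perpendicular attenuation has the restricted and free limits", {
  # fully restricted: tiny cylinder barely attenuates
  expect_lt(dperp_app(0.05, 0.9, 10, 2.5), 0.01 * 0.9)
  # free diffusion: huge cylinder approaches the intrinsic diffusivity
  d_free <- suppressWarnings(dperp_app(500, 0.9, 10, 2.5))
  expect_lt(abs(d_free - 0.9) / 0.9, 0.01)
})

test_that("apparent perpendicular diffusivity is monotone in r and Delta", {
  roots <- bessel_j1prime_roots(100)
  rs <- c(1, 2, 5, 10, 20, 50)
  Ds <- c(5, 10, 30, 50, 100)
  grid <- sapply(Ds, function(D)
    sapply(rs, function(r) dperp_app(r, 0.9, D, 2.5, roots = roots)))
  expect_true(all(apply(grid, 2, diff) > 0))   # increasing in r
  expect_true(all(apply(grid, 1, diff) <= 0))  # non-increasing in Delta
})

test_that("series truncation error is negligible beyond 60 roots", {
  r60 <- bessel_j1prime_roots(60)
  r120 <- bessel_j1prime_roots(120)
  for (r in c(1, 5, 20, 50)) for (D in c(5, 30, 100)) {
    a <- suppressWarnings(dperp_app(r, 0.9, D, 2.5, roots = r60, tol = 0))
    b <- suppressWarnings(dperp_app(r, 0.9, D, 2.5, roots = r120, tol = 0))
    expect_lt(abs(a - b) / b, 1e-6)
  }
})

test_that("tensor signal follows the quadratic-form attenuation", {
  sch <- scheme_1delta()
  p <- list(d_par = 0.9, d_perp1 = 0.5, d_perp2 = 0.3,
            theta = 0.4, phi = 1.0, alpha = -0.3)
  s <- tensor_signal(p, sch)
  expect_true(all(s > 0 & s <= 1))
  expect_equal(s[sch$is_b0], 1)
  # isotropic tensor: exp(-b d) in every direction
  iso <- tensor_signal(list(d_par = 0.7, d_perp1 = 0.7, d_perp2 = 0.7,
                            theta = 0.2, phi = 0.1, alpha = 0), sch)
  expect_equal(iso, exp(-sch$b * 0.7), tolerance = 1e-12)
  # along the principal axis the perpendicular eigenvalues are invisible
  one <- dwi_scheme(0, 0, 1, 1, 20, 2.5)
  s1 <- tensor_signal(list(d_par = 2.1, d_perp1 = 0.5, d_perp2 = 0.1,
                           theta = 0, phi = 0, alpha = 0), one)
  expect_equal(s1, exp(-2.1), tolerance = 1e-12)
  expect_error(tensor_signal(list(d_par = -1, d_perp1 = 0.5, d_perp2 = 0.3,
                                  theta = 0, phi = 0, alpha = 0), sch),
               "non-negative")
})

test_that("cylinder signal respects symmetry, axis, and radius ordering", {
  sch <- scheme_1delta()
  # circular cross-section: invariant under rotation about the axis
  s_a <- cylinder_ecs_signal(list(d = 0.9, r1 = 6, r2 = 6, theta = 0.5,
                                  phi = 0.2, alpha = 0), sch)
  s_b <- cylinder_ecs_signal(list(d = 0.9, r1 = 6, r2 = 6, theta = 0.5,
                                  phi = 0.2, alpha = 1.2), sch)
  expect_equal(s_a, s_b, tolerance = 1e-12)
  # along the axis only the free axial diffusivity matters
  one <- dwi_scheme(0, 0, 1, 2, 30, 2.5)
  for (rr in list(c(3, 2), c(12, 8))) {
    s1 <- cylinder_ecs_signal(list(d = 0.9, r1 = rr[1], r2 = rr[2],
                                   theta = 0, phi = 0, alpha = 0), one)
    expect_equal(s1, exp(-2 * 0.9), tolerance = 1e-12)
  }
  # larger radius -> larger apparent diffusivity -> stronger attenuation
  # along u2 (major axis direction of the cross-section) than along u3
  g2 <- dwi_scheme(1, 0, 0, 2, 30, 2.5)  # u2 = x at theta=phi=alpha=0...
  g3 <- dwi_scheme(0, 1, 0, 2, 30, 2.5)
  U <- angles_to_frame(0, 0, 0)
  p <- list(d = 0.9, r1 = 8.7, r2 = 5.1, theta = 0, phi = 0, alpha = 0)
  s_u2 <- cylinder_ecs_signal(p, dwi_scheme(U[1, 2], U[2, 2], U[3, 2],
                                            2, 30, 2.5))
  s_u3 <- cylinder_ecs_signal(p, dwi_scheme(U[1, 3], U[2, 3], U[3, 3],
                                            2, 30, 2.5))
  expect_lt(s_u2, s_u3)
  expect_error(cylinder_ecs_signal(list(d = 0.9, r1 = 2, r2 = 5,
                                        theta = 0, phi = 0, alpha = 0),
                                   sch), "r1")
})

test_that("cylinder and tensor models coincide at a single diffusion time", {
  sch <- scheme_1delta()  # one Delta, one delta
  p <- list(d = 0.9, r1 = 8.7, r2 = 5.1, theta = 0.7, phi = -0.4,
            alpha = 0.9)
  d1 <- dperp_app(p$r1, p$d, 10, 2.5)
  d2 <- dperp_app(p$r2, p$d, 10, 2.5)
  s_cyl <- cylinder_ecs_signal(p, sch)
  s_ten <- tensor_signal(list(d_par = p$d, d_perp1 = d1, d_perp2 = d2,
                              theta = p$theta, phi = p$phi,
                              alpha = p$alpha), sch)
  expect_equal(s_cyl, s_ten, tolerance = 1e-12)
})

test_that("two-compartment mixing is a convex combination", {
  s_ic <- c(1, 0.5, 0.2)
  s_ec <- c(1, 0.3, 0.05)
  expect_equal(two_compartment_signal(1, s_ic, s_ec), s_ic)
  expect_equal(two_compartment_signal(0, s_ic, s_ec), s_ec)
  expect_equal(two_compartment_signal(0.5, s_ic, s_ic), s_ic)
  expect_error(two_compartment_signal(1.2, s_ic, s_ec), "0, 1")
  expect_error(two_compartment_signal(0.5, s_ic, s_ec[1:2]), "length")
})

test_that("random-walk simulation reproduces the series prediction", {
  # one moderate case in the unit suite; the full grid runs in the
  # acceptance suite
  an <- dperp_app(5, 0.9, 10, 2.5)
  mc <- mc_dperp_app(5, 0.9, 10, 2.5, n_walkers = 3e4, seed = 7)
  expect_lt(abs(mc - an) / an, 0.03)
  # determinism under a seed
  expect_equal(mc_dperp_app(3, 0.9, 15, 2.5, n_walkers = 5e3, seed = 1),
               mc_dperp_app(3, 0.9, 15, 2.5, n_walkers = 5e3, seed = 1))
})
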