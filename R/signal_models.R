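# Forward signal models: Gaussian tensor compartment, restricted cylinder
# with elliptical cross-section (van Gelderen series), and their mixture.

.pkg_env <- new.env(parent = emptyenv())

# J1'(x) via the recurrence J1'(x) = (J0(x) - J2(x)) / 2.
.j1prime <- function(x) 0.5 * (besselJ(x, 0) - besselJ(x, 2))

#' Roots of the derivative of the Bessel function J1
#'
#' Ascending positive solutions of J1'(x) = 0. These are the dimensionless
#' eigenvalues of the radial diffusion operator in an impermeable cylinder:
#' for a cylinder of radius r the spatial frequencies are beta_m = root_m / r.
#'
#' @param n number of roots.
#' @return numeric vector of length `n`, strictly increasing; each root is
#'   refined to near machine precision.
#' @examples
#' bessel_j1prime_roots(3)  # 1.8412, 5.3314, 8.5363
#' @export
bessel_j1prime_roots <- function(n) {
  stopifnot(n >= 1)
  cached <- .pkg_env$j1p_roots
  if (!is.null(cached) && length(cached) >= n) return(cached[seq_len(n)])
  # Scan for sign changes; roots are ~pi apart, so a 0.05 grid is ample.
  upper <- (n + 2) * pi + 2
  xs <- seq(0.5, upper, by = 0.05)
  fx <- .j1prime(xs)
  idx <- which(fx[-1] * fx[-length(fx)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(.j1prime, c(xs[i], xs[i + 1]), tol = 1e-14)$root
  }, numeric(1))
  if (length(roots) < n) stop("failed to bracket ", n, " roots")
  roots <- roots[seq_len(max(n, min(length(roots), 100L)))]
  .pkg_env$j1p_roots <- roots
  roots[seq_len(n)]
}

#' Perpendicular restricted-diffusion attenuation (van Gelderen series)
#'
#' `dperp_app()` evaluates the apparent perpendicular diffusivity of an
#' impermeable cylinder of radius `r` under a pulsed-gradient experiment:
#' the Gaussian-phase series
#' \deqn{L_\perp \propto 2\sum_m \frac{2 d \beta_m^2 \delta - 2
#'   + 2e^{-d\beta_m^2\delta} + 2e^{-d\beta_m^2\Delta}
#'   - e^{-d\beta_m^2(\Delta-\delta)} - e^{-d\beta_m^2(\Delta+\delta)}}
#'   {d^2 \beta_m^6 (r^2\beta_m^2 - 1)}}
#' with beta_m the m-th root of J1' divided by r, normalised by
#' delta^2 (Delta - delta/3) so that a free (unrestricted) compartment
#' returns `d` itself. `L_perp()` returns the corresponding attenuation
#' coefficient per squared gradient magnitude (mT/m)^-2, and `L_parallel()`
#' the unrestricted axial analogue gamma^2 delta^2 (Delta - delta/3) d.
#'
#' @param r cylinder radius in um.
#' @param d intrinsic (axial) diffusivity in um^2/ms.
#' @param Delta,delta gradient pulse separation and duration in ms.
#' @param roots precomputed [bessel_j1prime_roots()] table (default: 100
#'   roots, cached).
#' @param tol series truncation: summation stops once a term's relative
#'   contribution falls below `tol`; exhausting the table first raises a
#'   warning with the tolerance achieved.
#' @return apparent perpendicular diffusivity in um^2/ms (`dperp_app`), or
#'   the attenuation coefficients (`L_perp`, `L_parallel`).
#' @export
dperp_app <- function(r, d, Delta, delta, roots = NULL, tol = 1e-8) {
  if (r <= 0 || d <= 0) stop("r and d must be positive")
  if (Delta <= delta / 3) stop("Delta must exceed delta/3")
  roots <- roots %||% bessel_j1prime_roots(100L)
  beta2 <- (roots / r)^2
  a <- d * beta2
  num <- 2 * a * delta - 2 + 2 * exp(-a * delta) + 2 * exp(-a * Delta) -
    exp(-a * (Delta - delta)) - exp(-a * (Delta + delta))
  den <- d^2 * beta2^3 * (r^2 * beta2 - 1)
  term <- num / den
  csum <- cumsum(term)
  ok <- which(abs(term) <= tol * abs(csum))
  if (length(ok)) {
    s <- csum[ok[1]]
  } else {
    s <- csum[length(csum)]
    warning("van Gelderen series truncated at the root-table length; ",
            "achieved relative tolerance ",
            signif(abs(term[length(term)]) / abs(s), 3))
  }
  2 * s / (delta^2 * (Delta - delta / 3))
}

#' @rdname dperp_app
#' @inheritParams compute_b
#' @export
L_perp <- function(r, d, Delta, delta, gamma = .gamma_default,
                   roots = NULL, tol = 1e-8) {
  ge <- .gamma_eff(gamma)
  ge^2 * delta^2 * (Delta - delta / 3) *
    dperp_app(r, d, Delta, delta, roots = roots, tol = tol)
}

#' @rdname dperp_app
#' @export
L_parallel <- function(d, Delta, delta, gamma = .gamma_default) {
  if (any(d < 0)) stop("d must be non-negative")
  if (any(Delta <= delta / 3)) stop("Delta must exceed delta/3")
  ge <- .gamma_eff(gamma)
  ge^2 * delta^2 * (Delta - delta / 3) * d
}

# Coerce a parameter spec (named list/vector) to a standard list.
.as_tensor_params <- function(params) {
  p <- as.list(params)
  need <- c("d_par", "d_perp1", "d_perp2", "theta", "phi", "alpha")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("tensor params missing: ", paste(miss, collapse = ", "))
  p
}

#' Gaussian tensor compartment signal
#'
#' S = exp(-b g^T D g) for an anisotropic Gaussian compartment with
#' eigenvalues `d_par >= d_perp1 >= d_perp2` along the frame defined by
#' (`theta`, `phi`, `alpha`).
#'
#' @param params named list or vector with `d_par`, `d_perp1`, `d_perp2`
#'   (um^2/ms) and `theta`, `phi`, `alpha` (rad).
#' @param scheme a [dwi_scheme()].
#' @return signal vector in (0, 1], aligned with the scheme rows; exactly 1
#'   on b0 rows.
#' @export
tensor_signal <- function(params, scheme) {
  p <- .as_tensor_params(params)
  if (any(c(p$d_par, p$d_perp1, p$d_perp2) < 0))
    stop("tensor eigenvalues must be non-negative")
  U <- angles_to_frame(p$theta, p$phi, p$alpha)
  G <- cbind(scheme$gx, scheme$gy, scheme$gz)
  proj2 <- (G %*% U)^2
  as.numeric(exp(-scheme$b * (p$d_par * proj2[, 1] +
                                p$d_perp1 * proj2[, 2] +
                                p$d_perp2 * proj2[, 3])))
}

#' Cylinder with elliptical cross-section: forward signal
#'
#' Restricted-diffusion signal of an impermeable cylinder whose
#' cross-section has major radius `r1` (along u2) and minor radius `r2`
#' (along u3), with free axial diffusivity `d` along u1. Perpendicular
#' attenuation follows the van Gelderen series per radius at each
#' measurement's (Delta, delta); axially the compartment is an unrestricted
#' Gaussian. At any single (Delta, delta) the model coincides with a
#' tensor whose perpendicular eigenvalues are the apparent diffusivities
#' [dperp_app()] of the two radii.
#'
#' @param params named list or vector with `d` (um^2/ms), `r1`, `r2` (um,
#'   `r1 >= r2`), `theta`, `phi`, `alpha` (rad).
#' @inheritParams tensor_signal
#' @inheritParams dperp_app
#' @return signal vector in (0, 1], 1 on b0 rows.
#' @export
cylinder_ecs_signal <- function(params, scheme, roots = NULL, tol = 1e-8) {
  p <- as.list(params)
  need <- c("d", "r1", "r2", "theta", "phi", "alpha")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("cylinder params missing: ", paste(miss, collapse = ", "))
  if (p$r1 < p$r2) stop("r1 must be >= r2")
  if (p$r2 <= 0 || p$d <= 0) stop("radii and d must be positive")
  roots <- roots %||% bessel_j1prime_roots(100L)
  U <- angles_to_frame(p$theta, p$phi, p$alpha)
  G <- cbind(scheme$gx, scheme$gy, scheme$gz)
  proj2 <- (G %*% U)^2
  key <- paste(scheme$Delta, scheme$delta)
  s <- numeric(nrow(scheme))
  for (k in unique(key)) {
    i <- key == k
    D <- scheme$Delta[i][1]; del <- scheme$delta[i][1]
    dp1 <- dperp_app(p$r1, p$d, D, del, roots = roots, tol = tol)
    dp2 <- dperp_app(p$r2, p$d, D, del, roots = roots, tol = tol)
    s[i] <- exp(-scheme$b[i] * (p$d * proj2[i, 1] + dp1 * proj2[i, 2] +
                                  dp2 * proj2[i, 3]))
  }
  s
}

#' Two-compartment mixture signal
#'
#' S = v_ic * S_ic + (1 - v_ic) * S_ec: non-exchanging intracellular and
#' extracellular compartments mixed by the intracellular volume fraction.
#'
#' @param v_ic intracellular volume fraction in \[0, 1\].
#' @param s_ic,s_ec per-measurement signal vectors of equal length.
#' @return mixed signal vector.
#' @export
two_compartment_signal <- function(v_ic, s_ic, s_ec) {
  if (v_ic < 0 || v_ic > 1) stop("v_ic must lie in [0, 1]")
  if (length(s_ic) != length(s_ec))
    stop("compartment signal vectors must have equal length")
  v_ic * s_ic + (1 - v_ic) * s_ec
}

#' Bi-exponential (tensor-tensor) model signal
#'
#' The fixed-diffusion-time representation of the two-compartment model:
#' both compartments are Gaussian tensors sharing one eigenvector frame.
#' The parameter vector follows the order
#' `(v_ic, d_ic_par, d_ic_perp1, d_ic_perp2, d_ec_par, d_ec_perp1,
#' d_ec_perp2, theta, phi, alpha)`.
#'
#' @param p named numeric vector or list with the ten parameters above
#'   (diffusivities in um^2/ms, angles in rad).
#' @inheritParams tensor_signal
#' @return signal vector, 1 on b0 rows.
#' @export
tensor_tensor_signal <- function(p, scheme) {
  p <- as.list(p)
  s_ic <- tensor_signal(list(d_par = p$d_ic_par, d_perp1 = p$d_ic_perp1,
                             d_perp2 = p$d_ic_perp2, theta = p$theta,
                             phi = p$phi, alpha = p$alpha), scheme)
  s_ec <- tensor_signal(list(d_par = p$d_ec_par, d_perp1 = p$d_ec_perp1,
                             d_perp2 = p$d_ec_perp2, theta = p$theta,
                             phi = p$phi, alpha = p$alpha), scheme)
  two_compartment_signal(p$v_ic, s_ic, s_ec)
}

#' Parameter vector order for the tensor-tensor model
#'
#' @return character vector of the ten parameter names in canonical order.
#' @export
tt_param_names <- function() {
  c("v_ic", "d_ic_par", "d_ic_perp1", "d_ic_perp2",
    "d_ec_par", "d_ec_perp1", "d_ec_perp2", "theta", "phi", "alpha")
}
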