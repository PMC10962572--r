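# Independent numerical oracles used to freeze expected values. These
# deliberately share no code with the package implementation.

# J1'(x) by term-wise differentiation of the ascending series of J1:
# J1(x) = sum_k (-1)^k / (k! (k+1)!) (x/2)^(2k+1).
j1prime_series <- function(x, kmax = 60) {
  s <- 0
  for (k in 0:kmax) {
    s <- s + (-1)^k * (2 * k + 1) / (factorial(k) * factorial(k + 1)) *
      (x / 2)^(2 * k) / 2
  }
  s
}

# Two-parameter OLS through the normal equations.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Squared magnitude response of a digital order-n Butterworth low-pass at
# normalised frequency f (cutoff fc, Nyquist = 1), designed by bilinear
# transform, hence the tan() frequency prewarping; forward-backward
# filtering applies this gain (|H|^2) with zero phase.
butterworth_gain2 <- function(f, fc, n)
  1 / (1 + (tan(pi * f / 2) / tan(pi * fc / 2))^(2 * n))

# Reference truth used throughout the simulation studies.
tt_truth <- c(v_ic = 0.6, d_ic_par = 0.9, d_ic_perp1 = 0.5,
              d_ic_perp2 = 0.3, d_ec_par = 2.1, d_ec_perp1 = 1.6,
              d_ec_perp2 = 1.0, theta = 0, phi = 0, alpha = 0)
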