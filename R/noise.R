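#' Rician noise for magnitude MR signals
#'
#' `snr_db_to_sigma()` converts an amplitude SNR in decibels to the Gaussian
#' channel noise SD: sigma = s0 * 10^(-snr_db/20), with the reference s0
#' being the (normalised) b0 signal. `add_rician_noise()` corrupts a signal
#' vector as s_noisy = sqrt((S + n1)^2 + n2^2) with n1, n2 independent
#' N(0, sigma^2), the magnitude of a complex signal with Gaussian noise in
#' both channels.
#'
#' @param snr_db amplitude SNR in dB (20 log10(s0 / sigma)).
#' @param s0 reference signal amplitude (1 for b0-normalised data).
#' @return `snr_db_to_sigma`: noise SD on the signal scale.
#' @examples
#' snr_db_to_sigma(40)  # 0.01
#' @export
snr_db_to_sigma <- function(snr_db, s0 = 1) {
  if (any(s0 <= 0)) stop("s0 must be positive")
  s0 * 10^(-snr_db / 20)
}

#' @rdname snr_db_to_sigma
#' @param signals non-negative noise-free signal vector.
#' @param sigma Gaussian channel SD; `sigma = 0` returns `signals` exactly.
#' @param seed optional RNG seed, applied locally so the caller's RNG
#'   stream is unaffected.
#' @return `add_rician_noise`: noisy signal vector of the same length.
#' @export
add_rician_noise <- function(signals, sigma, seed = NULL) {
  if (any(signals < 0)) stop("signals must be non-negative")
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(signals)
  with_preserved_seed(seed, {
    n1 <- stats::rnorm(length(signals), 0, sigma)
    n2 <- stats::rnorm(length(signals), 0, sigma)
    sqrt((signals + n1)^2 + n2^2)
  })
}

#' Noise specification
#'
#' Bundles an SNR level (amplitude dB relative to the b0 signal), the
#' derived channel SD, and a seed for reproducible noise draws.
#'
#' @inheritParams snr_db_to_sigma
#' @param seed integer seed.
#' @return a list of class `noise_spec` with `snr_db`, `sigma`, `seed`.
#' @export
noise_spec <- function(snr_db, seed = 1L, s0 = 1) {
  structure(list(snr_db = snr_db, sigma = snr_db_to_sigma(snr_db, s0),
                 seed = as.integer(seed)),
            class = "noise_spec")
}
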