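#' Monte-Carlo apparent perpendicular diffusivity in a disc
#'
#' Independent random-walk estimate of the quantity computed analytically
#' by [dperp_app()]: walkers diffuse in an impermeable disc of radius `r`
#' with specular boundary reflection, accumulate phase under the pulsed
#' gradient pair, and the apparent diffusivity is recovered from the phase
#' variance under the Gaussian phase approximation,
#' D = Var(phi) / (2 delta^2 (Delta - delta/3)).
#' This route shares no code with the van Gelderen series and serves as its
#' numerical cross-check.
#'
#' @inheritParams dperp_app
#' @param n_walkers number of random walkers (1e5 gives ~1% accuracy).
#' @param dt time step in ms; must resolve `delta` well.
#' @param seed optional RNG seed (applied locally).
#' @return apparent perpendicular diffusivity in um^2/ms.
#' @export
mc_dperp_app <- function(r, d, Delta, delta, n_walkers = 1e5, dt = 0.025,
                         seed = NULL) {
  v <- with_preserved_seed(seed,
    mc_disc_phase_var(r, d, Delta, delta, as.integer(n_walkers), dt))
  v / (2 * delta^2 * (Delta - delta / 3))
}
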