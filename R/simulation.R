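# Simulation framework: estimator sampling distributions under Rician
# noise, profile-objective degeneracy sweeps, and synthetic data.

# Normalisation constants for reporting estimator errors: volume fractions
# on their natural unit scale, diffusivities relative to 3.0 um^2/ms (the
# upper end of the plausible range).
.tt_scalar_norm <- c(v_ic = 1, d_ic_par = 3, d_ic_perp1 = 3, d_ic_perp2 = 3,
                     d_ec_par = 3, d_ec_perp1 = 3, d_ec_perp2 = 3)

#' Sampling-distribution precision analysis of the step-1 estimator
#'
#' Draws `n_draws` Rician-noisy realisations of the tensor-tensor forward
#' signal at each SNR level, refits each realisation, and reports the
#' normalised bias (mean error) and SD of the estimator error per scalar
#' parameter. Errors are normalised to 1 for the volume fraction and to
#' 3.0 um^2/ms for diffusivities. Orientation angles are excluded from the
#' report: no normalisation is defined for them and at the reference truth
#' (theta = 0) the azimuthal angles are individually unidentifiable.
#'
#' Noise draws use per-draw sub-seeds derived from `seed`, so results do
#' not depend on the iteration order or on `n_draws` of other levels.
#'
#' @param p_true named 10-parameter truth vector (see [tt_param_names()]).
#' @param scheme a single-diffusion-time [dwi_scheme()].
#' @param snr_levels amplitude SNRs in dB (relative to the b0 signal).
#' @param n_draws noise realisations per SNR level (>= 2).
#' @param fixed named list of parameters pinned during fitting.
#' @param seed master seed.
#' @param restarts optimiser starts per fit. The default of 1 (the
#'   data-driven initialisation only) characterises the sampling
#'   distribution of the local maximum-likelihood estimator as it is used
#'   in practice; adding jittered restarts lets rare draws hop to distant
#'   noise-fitting optima and fattens the error tails.
#' @param return_errors also attach the raw normalised error draws (one
#'   matrix per SNR level) as attribute `errors`, e.g. for assessing the
#'   Monte-Carlo uncertainty of the reported bias and SD.
#' @return data frame of class `precision_report`: one row per SNR level x
#'   free scalar parameter with `snr_db`, `param`, `bias_norm`, `sd_norm`,
#'   `n_used`, `n_failed`; the truth vector is kept as an attribute.
#' @export
precision_analysis <- function(p_true, scheme, snr_levels, n_draws,
                               fixed = list(), seed = 1L, restarts = 1L,
                               return_errors = FALSE) {
  if (n_draws < 2) stop("n_draws must be >= 2")
  p_true <- unlist(p_true)[tt_param_names()]
  s_clean <- tensor_tensor_signal(as.list(p_true), scheme)
  params <- setdiff(names(.tt_scalar_norm), names(fixed))
  rows <- list()
  all_err <- list()
  for (li in seq_along(snr_levels)) {
    sigma <- snr_db_to_sigma(snr_levels[li])
    err <- matrix(NA_real_, n_draws, length(params),
                  dimnames = list(NULL, params))
    failed <- 0L
    for (k in seq_len(n_draws)) {
      sub <- derive_seed(seed, (li - 1L) * n_draws + k)
      noisy <- add_rician_noise(s_clean, sigma, seed = sub)
      fit <- fit_tensor_tensor(measurement_vector(noisy, scheme),
                               fixed = fixed, restarts = restarts,
                               seed = sub)
      if (is.null(fit$params) || !fit$converged) { failed <- failed + 1L; next }
      err[k, ] <- (fit$params[params] - p_true[params]) /
        .tt_scalar_norm[params]
    }
    all_err[[as.character(snr_levels[li])]] <- err
    for (pm in params) {
      e <- err[, pm]
      e <- e[is.finite(e)]
      rows[[length(rows) + 1L]] <- data.frame(
        snr_db = snr_levels[li], param = pm,
        bias_norm = mean(e), sd_norm = stats::sd(e),
        n_used = length(e), n_failed = failed)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "p_true") <- p_true
  if (return_errors) attr(out, "errors") <- all_err
  class(out) <- c("precision_report", "data.frame")
  out
}

#' Count strict local minima of a profile curve
#'
#' Direct neighbour comparison without smoothing; endpoints count when
#' strictly below their single neighbour. Used to summarise
#' [degeneracy_sweep()] profiles.
#'
#' @param y numeric vector of profile objective values.
#' @return integer count of strict local minima.
#' @export
count_local_minima <- function(y) {
  n <- length(y)
  if (n < 2) return(as.integer(n == 1))
  k <- 0L
  if (y[1] < y[2]) k <- k + 1L
  if (n > 2)
    k <- k + sum(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] < y[3:n])
  if (y[n] < y[n - 1]) k <- k + 1L
  k
}

# Default physiologically plausible sweep grids for the scalar parameters.
.default_sweep_grids <- function() {
  d_grid <- seq(0.1, 3.0, by = 0.1)
  list(v_ic = seq(0, 1, by = 0.05),
       d_ic_par = d_grid, d_ic_perp1 = d_grid, d_ic_perp2 = d_grid,
       d_ec_par = d_grid, d_ec_perp1 = d_grid, d_ec_perp2 = d_grid)
}

#' Profile-objective degeneracy sweep
#'
#' For each swept parameter, fixes it at each grid value, re-optimises all
#' remaining free parameters, and records the minimal RMSE. A unique local
#' minimum in every profile indicates a non-degenerate objective for the
#' given data and acquisition; multiple minima flag parameter degeneracy.
#'
#' The compartment-exchange symmetry of the mixture would by itself place
#' a mirror-image second global minimum in every profile (e.g. at
#' 1 - v_ic); the sweep therefore fits under the slow-compartment-is-
#' intracellular labelling (`slow_ic`), which is the identity the model
#' asserts scientifically. Each inner fit takes the better of a warm start
#' from the neighbouring grid point and a cold data-driven start (plus
#' jittered restarts); non-converged inner fits are retried with 5 extra
#' restarts.
#'
#' @param data a [measurement_vector()] from a single diffusion time.
#' @param param_grids named list of grids to sweep (default: plausible
#'   ranges for the scalar parameters not in `fixed`).
#' @param fixed named list of globally pinned parameters; sweeping a pinned
#'   parameter is an error.
#' @param restarts optimiser starts per inner fit (per warm/cold branch).
#' @param seed RNG seed.
#' @param slow_ic enforce the compartment labelling during inner fits.
#' @return list of `degeneracy_profile` objects, each with `param`, `grid`,
#'   `rmse`, `n_local_minima`, `argmin`.
#' @export
degeneracy_sweep <- function(data, param_grids = NULL, fixed = list(),
                             restarts = 3L, seed = 1L, slow_ic = TRUE) {
  if (is.null(param_grids)) {
    param_grids <- .default_sweep_grids()
    param_grids <- param_grids[setdiff(names(param_grids), names(fixed))]
  }
  bad <- intersect(names(param_grids), names(fixed))
  if (length(bad))
    stop("cannot sweep fixed parameter(s): ", paste(bad, collapse = ", "))
  lapply(names(param_grids), function(pm) {
    grid <- param_grids[[pm]]
    n <- length(grid)
    run <- function(i, ini, rs, off) {
      fx <- c(fixed, stats::setNames(list(grid[i]), pm))
      fit <- fit_tensor_tensor(data, fixed = fx, restarts = rs,
                               seed = derive_seed(seed, off + i),
                               init = ini, slow_ic = slow_ic, polish = TRUE)
      if (!is.null(fit$params) && !fit$converged) {
        fit2 <- fit_tensor_tensor(data, fixed = fx, restarts = rs + 5L,
                                  seed = derive_seed(seed, off + 1000L + i),
                                  init = ini, slow_ic = slow_ic,
                                  polish = TRUE)
        if (!is.null(fit2$params) && fit2$rmse <= fit$rmse) fit <- fit2
      }
      fit
    }
    sols <- vector("list", n)
    rmse <- rep(NA_real_, n)
    keep_best <- function(i, fit) {
      if (!is.null(fit$params) &&
          (is.na(rmse[i]) || fit$rmse < rmse[i])) {
        rmse[i] <<- fit$rmse
        sols[[i]] <<- as.list(fit$params)
      }
    }
    # forward pass: cold start plus warm start from the left neighbour
    for (i in seq_len(n)) {
      keep_best(i, run(i, NULL, restarts, 0L))
      if (i > 1 && !is.null(sols[[i - 1]]))
        keep_best(i, run(i, sols[[i - 1]], restarts, 5000L))
    }
    # backward refinement: warm start from the right neighbour smooths
    # plateau regions where the forward chain changed basins
    for (i in rev(seq_len(n - 1))) {
      if (!is.null(sols[[i + 1]]))
        keep_best(i, run(i, sols[[i + 1]], restarts, 9000L))
    }
    # repair pass: re-optimise the neighbours of any non-global local
    # minimum by continuation from the minimum's own solution (in
    # substeps). Extra optimisation only lowers points toward the true
    # profile, so genuine minima survive while optimiser-noise dimples on
    # flat plateaus are removed.
    for (pass in 1:3) {
      if (count_local_minima(rmse) <= 1L) break
      gmin <- which.min(rmse)
      cand <- setdiff(which(vapply(seq_len(n), function(i) {
        lo <- if (i > 1) rmse[i] < rmse[i - 1] else TRUE
        hi <- if (i < n) rmse[i] < rmse[i + 1] else TRUE
        lo && hi
      }, logical(1))), gmin)
      improved <- FALSE
      for (m in cand) for (j in c(m - 1, m + 1)) {
        if (j < 1 || j > n || is.null(sols[[m]])) next
        ini <- sols[[m]]
        sw <- names(param_grids[pm])
        for (f in c(2 / 3, 1 / 3, 0)) {
          ini[[pm]] <- NULL
          val <- grid[j] + f * (grid[m] - grid[j])
          fxj <- c(fixed, stats::setNames(list(val), pm))
          ft <- fit_tensor_tensor(data, fixed = fxj, restarts = 1L,
                                  seed = derive_seed(seed, 20000L + j),
                                  init = ini, slow_ic = slow_ic,
                                  polish = TRUE)
          if (is.null(ft$params)) break
          ini <- as.list(ft$params)
          if (f == 0 && ft$rmse < rmse[j]) {
            rmse[j] <- ft$rmse
            sols[[j]] <- ini
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    structure(list(param = pm, grid = grid, rmse = rmse,
                   n_local_minima = count_local_minima(rmse),
                   argmin = grid[which.min(rmse)]),
              class = "degeneracy_profile")
  })
}

#' @export
print.degeneracy_profile <- function(x, ...) {
  cat("Profile sweep of", x$param, ":", length(x$grid), "grid points,",
      x$n_local_minima, "local minimum/minima; argmin =", x$argmin, "\n")
  invisible(x)
}

# Forward signal for a ground-truth parameter set: either a tensor-tensor
# vector (has d_ic_par) or a cylinder-ECS + tensor mixture (has r1).
forward_signal <- function(truth, scheme) {
  p <- as.list(truth)
  if (!is.null(p$r1)) {
    s_ic <- cylinder_ecs_signal(list(d = p$d, r1 = p$r1, r2 = p$r2,
                                     theta = p$theta, phi = p$phi,
                                     alpha = p$alpha), scheme)
    s_ec <- tensor_signal(list(d_par = p$d_ec_par, d_perp1 = p$d_ec_perp1,
                               d_perp2 = p$d_ec_perp2, theta = p$theta,
                               phi = p$phi, alpha = p$alpha), scheme)
    return(two_compartment_signal(p$v_ic, s_ic, s_ec))
  }
  if (!is.null(p$d_ic_par)) return(tensor_tensor_signal(p, scheme))
  stop("truth must be a tensor-tensor vector (d_ic_par ...) or a ",
       "cylinder-ECS mixture (v_ic, d, r1, r2, d_ec_* ...)")
}

#' Generate synthetic diffusion-weighted data
#'
#' Forward-simulates the compartment model for a known ground truth on a
#' scheme and applies Rician noise. With a single parameter set the result
#' is a [measurement_vector()]; with a list of per-voxel parameter sets and
#' `dims`, a [dwi_dataset()] phantom is assembled (and optionally written
#' to NIfTI together with the scheme and the ground truth table).
#'
#' @param truth a named parameter set — a tensor-tensor vector or a
#'   cylinder-ECS mixture (`v_ic`, `d`, `r1`, `r2`, `d_ec_par`,
#'   `d_ec_perp1`, `d_ec_perp2`, `theta`, `phi`, `alpha`) — or a list of
#'   such sets, one per voxel (recycled if length 1).
#' @param scheme a [dwi_scheme()].
#' @param noise a [noise_spec()] or `NULL` for noise-free signals.
#' @param dims spatial dimensions (length 3) for a phantom; `NULL` for a
#'   single measurement vector.
#' @param path optional output stem: writes `<path>.nii.gz` (the 4-D
#'   volume), `<path>.scheme.csv`, and `<path>.truth.csv`.
#' @return a [measurement_vector()], or a [dwi_dataset()] when `dims` is
#'   given (ground truth attached as attribute `truth`).
#' @export
generate_synthetic_dataset <- function(truth, scheme, noise = NULL,
                                       dims = NULL, path = NULL) {
  if (is.null(dims)) {
    s <- forward_signal(truth, scheme)
    if (!is.null(noise))
      s <- add_rician_noise(s, noise$sigma, seed = noise$seed)
    return(measurement_vector(s, scheme,
                              sigma = if (is.null(noise)) NULL
                              else noise$sigma))
  }
  stopifnot(length(dims) == 3)
  nvox <- prod(dims)
  sets <- if (!is.null(names(truth))) rep(list(truth), nvox) else truth
  if (length(sets) == 1) sets <- rep(sets, nvox)
  if (length(sets) != nvox)
    stop("need one parameter set per voxel (", nvox, "), got ", length(sets))
  m <- nrow(scheme)
  img <- array(NA_real_, c(dims, m))
  vox <- arrayInd(seq_len(nvox), dims)
  for (v in seq_len(nvox)) {
    s <- forward_signal(sets[[v]], scheme)
    if (!is.null(noise))
      s <- add_rician_noise(s, noise$sigma,
                            seed = derive_seed(noise$seed, v))
    img[vox[v, 1], vox[v, 2], vox[v, 3], ] <- s
  }
  ds <- dwi_dataset(img, scheme, mask = array(TRUE, dims))
  attr(ds, "truth") <- sets
  if (!is.null(path)) {
    RNifti::writeNifti(RNifti::asNifti(img), paste0(path, ".nii.gz"))
    write_scheme(scheme, paste0(path, ".scheme.csv"), dialect = "csv")
    tt <- do.call(rbind, lapply(sets, function(s)
      as.data.frame(as.list(unlist(s)))))
    utils::write.csv(cbind(voxel = seq_len(nvox), tt),
                     paste0(path, ".truth.csv"), row.names = FALSE)
  }
  ds
}
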