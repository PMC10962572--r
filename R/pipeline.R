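# Voxel-wise application to image volumes: container, per-diffusion-time
# b0 normalisation, optional spatial smoothing, masked hierarchical
# fitting, and ROI statistics.

#' Diffusion-weighted image dataset
#'
#' Binds a 4-D volume (three spatial dimensions x measurements) to its
#' acquisition scheme, a binary processing mask, and an optional integer
#' ROI label volume.
#'
#' @param img 4-D numeric array, 4th dimension aligned with the scheme
#'   rows, or a path to a NIfTI file.
#' @param scheme a [dwi_scheme()] (or path + `dialect` passed on to
#'   [read_scheme()]).
#' @param mask logical/0-1 3-D array matching the spatial dims (default:
#'   all voxels), or a NIfTI path.
#' @param roi optional integer 3-D label array (1..K; 0 = unlabelled), or a
#'   NIfTI path.
#' @param dialect scheme file dialect when `scheme` is a path.
#' @return list of class `dwi_dataset` with `img`, `scheme`, `mask`, `roi`.
#' @export
dwi_dataset <- function(img, scheme, mask = NULL, roi = NULL,
                        dialect = "csv") {
  if (is.character(img)) img <- as.array(RNifti::readNifti(img))
  if (is.character(scheme)) scheme <- read_scheme(scheme, dialect = dialect)
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask)) > 0
  if (is.character(roi)) roi <- round(as.array(RNifti::readNifti(roi)))
  validate_scheme(scheme)
  if (length(dim(img)) == 2) dim(img) <- c(dim(img)[1], 1, 1, dim(img)[2])
  if (length(dim(img)) != 4)
    stop("img must be a 4-D array (x, y, z, measurement)")
  if (dim(img)[4] != nrow(scheme))
    stop("4th image dimension (", dim(img)[4], ") != scheme rows (",
         nrow(scheme), ")")
  sdim <- dim(img)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sdim)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), sdim))
    stop("mask dims must match the spatial image dims")
  if (!is.null(roi) && !identical(dim(roi), sdim))
    stop("roi dims must match the spatial image dims")
  structure(list(img = img, scheme = scheme, mask = mask, roi = roi),
            class = "dwi_dataset")
}

#' Normalise signals to the b0 image of their own diffusion time
#'
#' Each diffusion time is acquired at its own echo time, so absolute
#' signal levels differ between diffusion-time groups; dividing by the
#' mean b0 volume of the same group removes both receiver scaling and the
#' group's T2 weighting. Voxels with non-positive b0 in any group are
#' removed from the mask and flagged. The operation is idempotent.
#'
#' @param dataset a [dwi_dataset()]; every diffusion-time group must
#'   contain at least one b0 measurement.
#' @return the dataset with normalised `img` (b0 rows become 1) and a
#'   possibly reduced `mask`; flagged voxel count in attribute
#'   `n_bad_b0`.
#' @export
normalize_to_b0 <- function(dataset) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  sch <- dataset$scheme
  img <- dataset$img
  mask <- dataset$mask
  bad <- array(FALSE, dim(mask))
  for (D in unique(sch$Delta)) {
    gi <- which(sch$Delta == D)
    b0i <- gi[sch$is_b0[gi]]
    if (!length(b0i))
      stop("no b0 measurement in the Delta = ", D, " ms group")
    b0 <- if (length(b0i) == 1) array(img[, , , b0i], dim(img)[1:3])
    else array(apply(img[, , , b0i, drop = FALSE], 1:3, mean),
               dim(img)[1:3])
    bad <- bad | (b0 <= 0)
    b0safe <- as.numeric(ifelse(b0 > 0, b0, 1))
    for (j in gi)
      img[, , , j] <- as.numeric(img[, , , j, drop = FALSE]) / b0safe
  }
  mask <- mask & !bad
  out <- dwi_dataset(img, sch, mask = mask, roi = dataset$roi)
  attr(out, "n_bad_b0") <- sum(bad)
  out
}

#' Spatial low-pass Butterworth filter
#'
#' Zero-phase Butterworth smoothing (order `order`, normalised cutoff
#' `cutoff` of the Nyquist frequency) applied separably along each spatial
#' axis of every measurement volume, via forward-backward filtering so the
#' effective magnitude response is |H(f)|^2 and no phase shift (spatial
#' displacement) is introduced. Constant volumes pass unchanged (unit DC
#' gain). Axes shorter than the filter warm-up length are skipped with a
#' warning.
#'
#' @param dataset a [dwi_dataset()], or a bare 3-D/4-D array.
#' @param order filter order.
#' @param cutoff normalised cutoff frequency in (0, 1).
#' @param min_len shortest axis length that will be filtered.
#' @return the filtered dataset (or array).
#' @export
lowpass_filter <- function(dataset, order = 4L, cutoff = 1 / 3,
                           min_len = 18L) {
  bf <- signal::butter(order, cutoff)
  # zero-phase pass: odd-reflection padding at both ends suppresses edge
  # transients, and filtering the deviation from the first sample keeps
  # the DC response exactly 1 (a constant series is a fixed point)
  one_pass <- function(z) {
    z1 <- z[1]
    z1 + as.numeric(signal::filter(bf, z - z1))
  }
  zero_phase <- function(x) {
    n <- length(x)
    pad <- min(n - 1L, 36L)
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    y <- one_pass(xp)
    y <- rev(one_pass(rev(y)))
    y[(pad + 1):(pad + n)]
  }
  filt_axis <- function(arr4, axis) {
    n <- dim(arr4)[axis]
    if (n == 1L) return(arr4)  # singleton axis: nothing to filter
    if (n < min_len) {
      warning("axis ", axis, " (length ", n,
              ") is shorter than the filter warm-up; skipped")
      return(arr4)
    }
    perm <- c(axis, setdiff(1:4, axis))
    a <- aperm(arr4, perm)
    d <- dim(a)
    mat <- matrix(a, nrow = d[1])
    mat <- apply(mat, 2, zero_phase)
    a <- array(mat, d)
    aperm(a, order(perm))
  }
  apply_all <- function(img) {
    for (ax in 1:3) img <- filt_axis(img, ax)
    img
  }
  if (inherits(dataset, "dwi_dataset")) {
    dataset$img <- apply_all(dataset$img)
    return(dataset)
  }
  img <- dataset
  was3d <- length(dim(img)) == 3
  if (was3d) dim(img) <- c(dim(img), 1)
  img <- apply_all(img)
  if (was3d) dim(img) <- dim(img)[1:3]
  img
}

#' Voxel-wise hierarchical fitting of a volume
#'
#' Runs [hierarchical_fit()] in every masked voxel of a normalised dataset
#' and assembles parameter maps. Voxels are processed independently with
#' per-voxel derived seeds, so results do not depend on processing order;
#' per-voxel failures are recorded in the flag maps and never abort the
#' volume.
#'
#' @param dataset a normalised [dwi_dataset()].
#' @inheritParams hierarchical_fit
#' @return list of class `parameter_maps`: 3-D arrays `icv0`, `icv_slope`,
#'   `d0`, `c1`, `r1`, `r2`, `diameter_major`, `diameter_minor`,
#'   `radius_cost`, flag arrays `flag_converged`, `flag_icv_clamped`,
#'   `flag_radius_bound`, `flag_failed`, and 4-D per-diffusion-time arrays
#'   `v_ic_by_delta`, `d_ic_par_by_delta`, `d_ic_perp1_by_delta`,
#'   `d_ic_perp2_by_delta` (with attribute `Deltas`), plus `mask` and
#'   `roi`.
#' @export
fit_volume <- function(dataset, fixed = list(d_ec_par = 2.1),
                       restarts = 10L, seed = 1L, r_bounds = c(0.5, 30),
                       grid_step = 0.05) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  if (!any(dataset$mask)) stop("mask is empty")
  sdim <- dim(dataset$img)[1:3]
  Deltas <- sort(unique(dataset$scheme$Delta))
  nd <- length(Deltas)
  z3 <- function() array(NA_real_, sdim)
  z4 <- function() array(NA_real_, c(sdim, nd))
  maps <- list(icv0 = z3(), icv_slope = z3(), d0 = z3(), c1 = z3(),
               r1 = z3(), r2 = z3(), diameter_major = z3(),
               diameter_minor = z3(), radius_cost = z3(),
               flag_converged = z3(), flag_icv_clamped = z3(),
               flag_radius_bound = z3(), flag_failed = z3(),
               v_ic_by_delta = z4(), d_ic_par_by_delta = z4(),
               d_ic_perp1_by_delta = z4(), d_ic_perp2_by_delta = z4())
  vox <- which(dataset$mask, arr.ind = TRUE)
  for (v in seq_len(nrow(vox))) {
    i <- vox[v, 1]; j <- vox[v, 2]; k <- vox[v, 3]
    lin <- i + (j - 1) * sdim[1] + (k - 1) * sdim[1] * sdim[2]
    sig <- dataset$img[i, j, k, ]
    fit <- tryCatch(
      hierarchical_fit(measurement_vector(sig, dataset$scheme),
                       fixed = fixed, restarts = restarts,
                       seed = derive_seed(seed, lin),
                       r_bounds = r_bounds, grid_step = grid_step),
      error = function(e) NULL)
    if (is.null(fit)) { maps$flag_failed[i, j, k] <- 1; next }
    maps$flag_failed[i, j, k] <- 0
    maps$icv0[i, j, k] <- fit$icv0
    maps$icv_slope[i, j, k] <- fit$icv_slope
    maps$d0[i, j, k] <- fit$d0
    maps$c1[i, j, k] <- fit$c1
    maps$r1[i, j, k] <- fit$r1
    maps$r2[i, j, k] <- fit$r2
    maps$diameter_major[i, j, k] <- fit$diameter_major
    maps$diameter_minor[i, j, k] <- fit$diameter_minor
    maps$radius_cost[i, j, k] <- fit$radius_cost
    maps$flag_converged[i, j, k] <- as.numeric(fit$all_converged)
    maps$flag_icv_clamped[i, j, k] <- as.numeric(fit$icv_clamped)
    maps$flag_radius_bound[i, j, k] <- as.numeric(any(fit$radius_at_bound))
    for (f in fit$per_delta) {
      di <- match(f$Delta, Deltas)
      if (is.null(f$params)) next
      maps$v_ic_by_delta[i, j, k, di] <- f$params[["v_ic"]]
      maps$d_ic_par_by_delta[i, j, k, di] <- f$params[["d_ic_par"]]
      maps$d_ic_perp1_by_delta[i, j, k, di] <- f$params[["d_ic_perp1"]]
      maps$d_ic_perp2_by_delta[i, j, k, di] <- f$params[["d_ic_perp2"]]
    }
  }
  attr(maps, "Deltas") <- Deltas
  maps$mask <- dataset$mask
  maps$roi <- dataset$roi
  class(maps) <- "parameter_maps"
  maps
}

#' Write parameter maps to NIfTI
#'
#' @param maps a `parameter_maps` object from [fit_volume()].
#' @param stem output filename stem; each 3-D map goes to
#'   `<stem>_<name>.nii.gz`.
#' @return the written paths, invisibly.
#' @export
write_parameter_maps <- function(maps, stem) {
  nm <- names(maps)[vapply(maps, function(m)
    is.array(m) && length(dim(m)) == 3, logical(1))]
  paths <- vapply(nm, function(n) {
    p <- paste0(stem, "_", n, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(maps[[n]] * 1), p)
    p
  }, character(1))
  invisible(paths)
}

# One-voxel 6-connected erosion of a binary volume.
.erode1 <- function(bin) {
  d <- dim(bin)
  shift <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx[[ax]] - by
    pad <- src < 1 | src > d[ax]
    src <- clamp(src, 1, d[ax])
    idx[[ax]] <- src
    out <- do.call(`[`, c(list(a), idx))
    dim(out) <- d
    sel <- lapply(d, seq_len)
    sel[[ax]] <- which(pad)
    if (length(sel[[ax]])) {
      grid <- as.matrix(expand.grid(sel))
      out[grid] <- FALSE
    }
    out
  }
  out <- bin
  for (ax in 1:3) {
    if (d[ax] == 1) next  # singleton axis: nothing to erode along
    for (by in c(-1, 1)) out <- out & shift(bin, ax, by)
  }
  out
}

#' Per-ROI statistics of parameter maps
#'
#' Mean, SD and voxel count of each requested map inside each ROI label,
#' restricted to the mask. With `exclude_boundary = TRUE` each ROI is
#' eroded by one voxel (6-connectivity) first, discarding voxels adjacent
#' to other tissue — the usual guard against partial-volume contamination.
#'
#' @param maps a `parameter_maps` object.
#' @param roi integer label volume (defaults to the one in `maps`).
#' @param params character vector of map names to summarise.
#' @param exclude_boundary erode each ROI by one voxel first.
#' @return data frame with `roi`, `param`, `mean`, `sd`, `n`.
#' @export
roi_statistics <- function(maps, roi = NULL,
                           params = c("icv0", "diameter_major",
                                      "diameter_minor"),
                           exclude_boundary = FALSE) {
  roi <- roi %||% maps$roi
  if (is.null(roi)) stop("no ROI labels supplied")
  bad <- setdiff(params, names(maps))
  if (length(bad)) stop("unknown map(s): ", paste(bad, collapse = ", "))
  labels <- sort(unique(roi[roi > 0]))
  if (!length(labels)) stop("ROI volume contains no positive labels")
  rows <- list()
  for (lab in labels) {
    sel <- roi == lab & maps$mask
    if (exclude_boundary) sel <- .erode1(sel)
    for (pm in params) {
      v <- maps[[pm]][sel]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        roi = lab, param = pm,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else
          if (length(v) == 1) 0 else NA_real_,
        n = length(v))
    }
  }
  do.call(rbind, rows)
}
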