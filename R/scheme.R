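#' Diffusion acquisition schemes
#'
#' A `dwi_scheme` is an ordered table of diffusion measurements, one row per
#' acquired image, holding the gradient direction (unit 3-vector), the
#' diffusion weighting b (ms/um^2), the diffusion time Delta (ms), the
#' gradient duration delta (ms), optionally the gradient magnitude |g|
#' (mT/m), and a b0 flag. Internal units are fixed: time in ms, b in
#' ms/um^2, diffusivity in um^2/ms; file dialects convert at the I/O
#' boundary.
#'
#' @param gx,gy,gz components of the diffusion-encoding direction. Rows with
#'   b = 0 may carry a zero vector.
#' @param b diffusion weighting in ms/um^2 (1 ms/um^2 = 1000 s/mm^2).
#' @param Delta diffusion time (gradient pulse separation) in ms.
#' @param delta gradient pulse duration in ms.
#' @param gmag optional gradient magnitude in mT/m; when supplied it is
#'   checked against b via the Stejskal-Tanner relation.
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1.
#' @param gmag_rtol relative tolerance for the b vs |g| consistency check;
#'   disagreement beyond it raises a warning (measured b-values need not
#'   satisfy the ideal pulsed-gradient relation exactly).
#'
#' @return A data frame of class `dwi_scheme` with columns `gx`, `gy`, `gz`,
#'   `b`, `Delta`, `delta`, `gmag`, `is_b0` and attribute `gamma`.
#' @export
dwi_scheme <- function(gx, gy, gz, b, Delta, delta, gmag = NA_real_,
                       gamma = .gamma_default, gmag_rtol = 0.05) {
  df <- data.frame(gx = as.numeric(gx), gy = as.numeric(gy),
                   gz = as.numeric(gz), b = as.numeric(b),
                   Delta = as.numeric(Delta), delta = as.numeric(delta),
                   gmag = as.numeric(gmag))
  df$is_b0 <- df$b == 0
  attr(df, "gamma") <- gamma
  class(df) <- c("dwi_scheme", "data.frame")
  validate_scheme(df, gmag_rtol = gmag_rtol)
  df
}

#' Validate a diffusion scheme
#'
#' Checks the scheme invariants: unit-norm directions on diffusion-weighted
#' rows, Delta > delta/3 >= 0, non-negative b with b = 0 exactly on b0 rows,
#' and (when |g| is recorded) consistency of b with the Stejskal-Tanner
#' relation within `gmag_rtol`.
#'
#' @param scheme a [dwi_scheme()].
#' @inheritParams dwi_scheme
#' @return `scheme`, invisibly; errors name the first offending row.
#' @export
validate_scheme <- function(scheme, gmag_rtol = 0.05) {
  stopifnot(is.data.frame(scheme))
  req <- c("gx", "gy", "gz", "b", "Delta", "delta", "is_b0")
  miss <- setdiff(req, names(scheme))
  if (length(miss))
    stop("scheme is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(scheme$b < 0)
  if (length(bad))
    stop("negative b-value at row ", bad[1])
  bad <- which(scheme$is_b0 != (scheme$b == 0))
  if (length(bad))
    stop("is_b0 flag inconsistent with b at row ", bad[1])
  bad <- which(scheme$delta < 0)
  if (length(bad))
    stop("negative gradient duration delta at row ", bad[1])
  bad <- which(scheme$Delta <= scheme$delta / 3)
  if (length(bad))
    stop("Delta <= delta/3 at row ", bad[1], " (Delta = ",
         scheme$Delta[bad[1]], " ms, delta = ", scheme$delta[bad[1]], " ms)")
  nrm <- sqrt(scheme$gx^2 + scheme$gy^2 + scheme$gz^2)
  bad <- which(!scheme$is_b0 & abs(nrm - 1) > 1e-9)
  if (length(bad))
    stop("non-unit direction at row ", bad[1], " (|g_hat| = ", nrm[bad[1]], ")")
  if ("gmag" %in% names(scheme)) {
    idx <- which(!scheme$is_b0 & is.finite(scheme$gmag))
    if (length(idx)) {
      gamma <- attr(scheme, "gamma") %||% .gamma_default
      b_pred <- compute_b(scheme$gmag[idx], scheme$Delta[idx],
                          scheme$delta[idx], gamma = gamma)
      rel <- abs(b_pred - scheme$b[idx]) / pmax(scheme$b[idx], 1e-12)
      if (any(rel > gmag_rtol))
        warning("b and |g| disagree beyond ", gmag_rtol * 100,
                "% relative at row ", idx[which.max(rel)],
                " (max relative deviation ",
                signif(max(rel), 3), "); b is treated as authoritative")
    }
  }
  invisible(scheme)
}

#' Compute the diffusion weighting from the gradient strength
#'
#' Ideal pulsed-gradient (Stejskal-Tanner) relation
#' b = gamma^2 delta^2 (Delta - delta/3) |g|^2, expressed in the package's
#' internal units. `compute_gmag()` is the exact inverse.
#'
#' @param gmag gradient magnitude in mT/m.
#' @param Delta,delta pulse separation and duration in ms.
#' @inheritParams dwi_scheme
#' @return b in ms/um^2 (`compute_b`) or |g| in mT/m (`compute_gmag`).
#' @examples
#' compute_b(780.06, Delta = 10, delta = 2.5)  # ~2.5 ms/um^2
#' @export
compute_b <- function(gmag, Delta, delta, gamma = .gamma_default) {
  if (any(Delta <= delta / 3))
    stop("Delta must exceed delta/3")
  if (any(gmag < 0)) stop("gmag must be non-negative")
  ge <- .gamma_eff(gamma)
  ge^2 * delta^2 * (Delta - delta / 3) * gmag^2
}

#' @rdname compute_b
#' @param b diffusion weighting in ms/um^2.
#' @export
compute_gmag <- function(b, Delta, delta, gamma = .gamma_default) {
  if (any(Delta <= delta / 3))
    stop("Delta must exceed delta/3")
  if (any(b < 0)) stop("b must be non-negative")
  ge <- .gamma_eff(gamma)
  sqrt(b / (ge^2 * delta^2 * (Delta - delta / 3)))
}

#' Evenly spread gradient directions by electrostatic repulsion
#'
#' Minimises the antipodally symmetric Coulomb energy
#' sum_{i<j} 1/|x_i - x_j| + 1/|x_i + x_j| over n unit vectors, starting
#' from a seeded random configuration, so the returned set is deterministic
#' for a given seed.
#'
#' @param n number of directions.
#' @param seed RNG seed for the starting configuration.
#' @param maxit optimiser iteration cap.
#' @return an n x 3 matrix of unit row vectors.
#' @export
electrostatic_directions <- function(n, seed = 42L, maxit = 500L) {
  stopifnot(n >= 1)
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  ang0 <- with_preserved_seed(seed, cbind(acos(stats::runif(n, -1, 1)),
                                          stats::runif(n, 0, 2 * pi)))
  energy <- function(par) {
    th <- par[seq_len(n)]; ph <- par[n + seq_len(n)]
    x <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    e <- 0
    for (i in seq_len(n - 1)) {
      dif <- sweep(x[(i + 1):n, , drop = FALSE], 2, x[i, ])
      sum_ <- sweep(x[(i + 1):n, , drop = FALSE], 2, -x[i, ])
      e <- e + sum(1 / sqrt(rowSums(dif^2))) + sum(1 / sqrt(rowSums(sum_^2)))
    }
    e
  }
  opt <- stats::optim(c(ang0[, 1], ang0[, 2]), energy, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  th <- opt$par[seq_len(n)]; ph <- opt$par[n + seq_len(n)]
  dirs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  dirs / sqrt(rowSums(dirs^2))
}

#' Build the multi-diffusion-time acquisition protocol
#'
#' Enumerates a protocol of `n_dirs` directions x `bvals` shells for each
#' diffusion time, plus exactly one b0 per diffusion time (ordered first in
#' its group). Defaults reproduce the ex vivo mouse-heart protocol: 10
#' directions, b = {69, 280, 620, 1100, 1700, 2500} s/mm^2, Delta = 10-50 ms
#' in steps of 10 ms, delta = 2.5 ms — 61 images per diffusion time, 305 in
#' total.
#'
#' @param n_dirs number of diffusion-encoding directions per shell.
#' @param bvals non-zero b-values in ms/um^2.
#' @param Deltas diffusion times in ms.
#' @param delta gradient duration in ms.
#' @param dir_seed seed for the electrostatic direction set.
#' @inheritParams dwi_scheme
#' @return a [dwi_scheme()] grouped by `Delta`.
#' @export
build_protocol_scheme <- function(n_dirs = 10L,
                               bvals = c(0.069, 0.28, 0.62, 1.1, 1.7, 2.5),
                               Deltas = c(10, 20, 30, 40, 50),
                               delta = 2.5,
                               dir_seed = 42L,
                               gamma = .gamma_default) {
  if (n_dirs < 1) stop("n_dirs must be >= 1")
  if (any(bvals <= 0))
    stop("all bvals must be strictly positive; offending entry: ",
         bvals[which(bvals <= 0)[1]])
  if (any(Deltas <= delta / 3))
    stop("every Delta must exceed delta/3; offending entry: Delta = ",
         Deltas[which(Deltas <= delta / 3)[1]], " ms")
  dirs <- electrostatic_directions(n_dirs, seed = dir_seed)
  rows <- lapply(Deltas, function(D) {
    shell <- expand.grid(dir = seq_len(n_dirs), b = bvals,
                         KEEP.OUT.ATTRS = FALSE)
    data.frame(gx = c(0, dirs[shell$dir, 1]),
               gy = c(0, dirs[shell$dir, 2]),
               gz = c(0, dirs[shell$dir, 3]),
               b = c(0, shell$b),
               Delta = D, delta = delta)
  })
  df <- do.call(rbind, rows)
  gmag <- ifelse(df$b > 0, compute_gmag(df$b, df$Delta, df$delta, gamma), 0)
  dwi_scheme(df$gx, df$gy, df$gz, df$b, df$Delta, df$delta,
             gmag = gmag, gamma = gamma)
}

#' Summarise a scheme and flag sampling inadequacies
#'
#' Counts shells, directions and b0 images per diffusion time, and warns
#' when the protocol cannot support the two-step fit: a bi-exponential decay
#' is only observable for b-values above ~1.5 ms/um^2 (1500 s/mm^2), and
#' cell diameters around 20 um require diffusion times of at least 30 ms.
#'
#' @param scheme a [dwi_scheme()].
#' @return a list of class `dwi_scheme_summary` with components
#'   `n_measurements`, `per_delta` (data frame), and `warnings` (character).
#' @export
scheme_summary <- function(scheme) {
  validate_scheme(scheme)
  sp <- split(seq_len(nrow(scheme)), scheme$Delta)
  per <- do.call(rbind, lapply(names(sp), function(D) {
    i <- sp[[D]]
    dw <- i[!scheme$is_b0[i]]
    dirs <- unique(round(cbind(scheme$gx[dw], scheme$gy[dw], scheme$gz[dw]), 9))
    data.frame(Delta = as.numeric(D),
               n_dw = length(dw),
               n_b0 = sum(scheme$is_b0[i]),
               n_shells = length(unique(scheme$b[dw])),
               n_dirs = nrow(dirs))
  }))
  per <- per[order(per$Delta), , drop = FALSE]
  rownames(per) <- NULL
  warn <- character()
  if (max(scheme$b) < 1.5)
    warn <- c(warn, paste0("max b = ", max(scheme$b), " ms/um^2 < 1.5: ",
                           "bi-exponential decay is unreliable to fit"))
  if (max(scheme$Delta) < 30)
    warn <- c(warn, paste0("max Delta = ", max(scheme$Delta), " ms < 30: ",
                           "diameters around 20 um are not resolvable"))
  out <- list(n_measurements = nrow(scheme), per_delta = per, warnings = warn)
  class(out) <- "dwi_scheme_summary"
  out
}

#' @export
print.dwi_scheme_summary <- function(x, ...) {
  cat("Diffusion scheme:", x$n_measurements, "measurements\n")
  print(x$per_delta, row.names = FALSE)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' @export
print.dwi_scheme <- function(x, ...) {
  cat("dwi_scheme:", nrow(x), "measurements,",
      length(unique(x$Delta)), "diffusion time(s)\n")
  print(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Read and write scheme files
#'
#' Three dialects are supported. `"csv"` is the internal format (columns
#' `gx,gy,gz,b,Delta,delta`, b in ms/um^2, times in ms). `"camino"` is the
#' Stejskal-Tanner scheme format (header `VERSION: STEJSKALTANNER`, columns
#' gx gy gz |g| Delta delta TE in SI units); on reading, b is computed from
#' |g| via the ideal relation. `"fslgrad"` reads a bval/bvec pair (b in
#' s/mm^2, converted to ms/um^2) plus a timing table with `Delta`/`delta`
#' columns in ms (one row per measurement, or a single recycled row).
#'
#' @param path file to read or write: the CSV/camino file, or for
#'   `"fslgrad"` the `.bval` file (the `.bvec` path defaults to the same
#'   stem).
#' @param dialect one of `"csv"`, `"camino"`, `"fslgrad"`.
#' @param bvec,timing for `"fslgrad"`: path to the bvec file and the timing
#'   table (a data frame or CSV path with columns `Delta`, `delta` in ms).
#' @inheritParams dwi_scheme
#' @return `read_scheme` returns a [dwi_scheme()]; `write_scheme` returns
#'   `path` invisibly.
#' @export
read_scheme <- function(path, dialect = c("csv", "camino", "fslgrad"),
                        bvec = NULL, timing = NULL,
                        gamma = .gamma_default) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- tryCatch(utils::read.csv(path, comment.char = "#"),
                   error = function(e) stop("malformed scheme CSV '", path,
                                            "': ", conditionMessage(e)))
    need <- c("gx", "gy", "gz", "b", "Delta", "delta")
    if (!all(need %in% names(df)))
      stop("scheme CSV '", path, "' must have columns ",
           paste(need, collapse = ", "))
    gmag <- if ("gmag" %in% names(df)) df$gmag else NA_real_
    return(dwi_scheme(df$gx, df$gy, df$gz, df$b, df$Delta, df$delta,
                      gmag = gmag, gamma = gamma))
  }
  if (dialect == "camino") {
    lines <- readLines(path)
    lines <- trimws(lines)
    body <- lines[!grepl("^($|#|VERSION)", lines)]
    rows <- lapply(seq_along(body), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(body[i], "[ \t,]+")[[1]]))
      if (length(v) != 7 || anyNA(v))
        stop("malformed camino scheme row at data line ", i, " of '", path,
             "' (expected 7 numeric columns: gx gy gz |g| Delta delta TE)")
      v
    })
    m <- do.call(rbind, rows)
    gmag <- m[, 4] * 1e3              # T/m -> mT/m
    Delta <- m[, 5] * 1e3             # s -> ms
    delta <- m[, 6] * 1e3
    b0 <- gmag == 0
    b <- ifelse(b0, 0, compute_b(gmag, Delta, delta, gamma))
    return(dwi_scheme(m[, 1], m[, 2], m[, 3], b, Delta, delta,
                      gmag = gmag, gamma = gamma))
  }
  # fslgrad
  bvals <- scan(path, quiet = TRUE)
  bvec <- bvec %||% sub("\\.bval$", ".bvec", path)
  gm <- as.matrix(utils::read.table(bvec))
  if (nrow(gm) == 3) gm <- t(gm)
  if (nrow(gm) != length(bvals))
    stop("bvec file '", bvec, "' has ", nrow(gm),
         " directions but bval file has ", length(bvals))
  if (is.character(timing)) timing <- utils::read.csv(timing)
  if (is.null(timing) || !all(c("Delta", "delta") %in% names(timing)))
    stop("fslgrad dialect needs a timing table with columns Delta, delta")
  if (nrow(timing) == 1) timing <- timing[rep(1, length(bvals)), ]
  if (nrow(timing) != length(bvals))
    stop("timing table must have 1 row or one row per measurement")
  dwi_scheme(gm[, 1], gm[, 2], gm[, 3], bvals / 1000,
             timing$Delta, timing$delta, gamma = gamma)
}

#' @rdname read_scheme
#' @param scheme a [dwi_scheme()] to write.
#' @export
write_scheme <- function(scheme, path, dialect = c("csv", "camino", "fslgrad"),
                         timing = NULL) {
  dialect <- match.arg(dialect)
  validate_scheme(scheme)
  if (dialect == "csv") {
    df <- as.data.frame(scheme)[c("gx", "gy", "gz", "b", "Delta", "delta",
                                  "gmag")]
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (dialect == "camino") {
    gamma <- attr(scheme, "gamma") %||% .gamma_default
    gmag <- ifelse(scheme$is_b0, 0,
                   compute_gmag(scheme$b, scheme$Delta, scheme$delta, gamma))
    te <- (scheme$Delta + scheme$delta + 5) * 1e-3
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("VERSION: STEJSKALTANNER", con)
    writeLines(sprintf("%.10f %.10f %.10f %.10e %.10e %.10e %.10e",
                       scheme$gx, scheme$gy, scheme$gz, gmag * 1e-3,
                       scheme$Delta * 1e-3, scheme$delta * 1e-3, te), con)
    return(invisible(path))
  }
  # fslgrad: path is the .bval path; .bvec and timing CSV share the stem
  stem <- sub("\\.bval$", "", path)
  cat(paste(format(scheme$b * 1000, digits = 17, trim = TRUE),
            collapse = " "), "\n", file = path)
  gm <- t(as.matrix(as.data.frame(scheme)[c("gx", "gy", "gz")]))
  utils::write.table(format(gm, digits = 17, trim = TRUE),
                     paste0(stem, ".bvec"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(Delta = scheme$Delta, delta = scheme$delta),
                   paste0(stem, ".timing.csv"), row.names = FALSE)
  invisible(path)
}
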