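#' Build the lower-triangular Toeplitz deconvolution system (sSVD)
#'
#' The discrete convolution `v = A r` relating a tissue enhancement curve to
#' the CBF-scaled residue function: `A[i, j] = dt * AIF[i - j]` for `j <= i`,
#' zero above the diagonal. The AIF must be baseline-subtracted enhancement.
#'
#' @param aif An `intensity_curve` or numeric vector of arterial enhancement
#'   (length N >= 2).
#' @param dt Frame interval in seconds; taken from the curve when omitted.
#' @return A `deconv_system`: `A`, `mode = "sSVD"`, `dt`, `n`, and the SVD
#'   factors `u`, `d`, `v`.
#' @export
build_conv_matrix <- function(aif, dt = NULL) {
  a <- aif_values(aif)
  if (is.null(dt)) dt <- aif_dt(aif)
  n <- length(a)
  if (all(a == 0)) stop("singular system: AIF is all zero")
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    A[j:n, j] <- dt * a[seq_len(n - j + 1L)]
  }
  new_deconv_system(A, "sSVD", dt, n)
}

#' Build the block-circulant deconvolution system (bcSVD)
#'
#' Embeds the Toeplitz system in a `2N x 2N` circulant matrix: the AIF is
#' zero-padded to length `2N` and `A[i, j] = column[(i - j) mod 2N]` with
#' `column = dt * c(aif, zeros)`. The top-left `N x N` block equals the
#' sSVD matrix; the circulant wrap-around is what makes the deconvolution
#' insensitive to bolus-arrival delay.
#'
#' @inheritParams build_conv_matrix
#' @return A `deconv_system` with `mode = "bcSVD"` (`2N x 2N`).
#' @export
build_circulant_matrix <- function(aif, dt = NULL) {
  a <- aif_values(aif)
  if (is.null(dt)) dt <- aif_dt(aif)
  n <- length(a)
  if (all(a == 0)) stop("singular system: AIF is all zero")
  L <- 2L * n
  col1 <- c(dt * a, rep(0, n))
  A <- matrix(0, L, L)
  for (j in seq_len(L)) {
    A[, j] <- col1[((seq_len(L) - j) %% L) + 1L]
  }
  new_deconv_system(A, "bcSVD", dt, n)
}

aif_values <- function(aif) {
  v <- if (inherits(aif, "intensity_curve")) aif$values else as.numeric(aif)
  if (length(v) < 2L) stop("AIF must have length >= 2")
  v
}

aif_dt <- function(aif) {
  if (inherits(aif, "intensity_curve")) aif$dt
  else stop("dt must be given when the AIF is a plain vector")
}

new_deconv_system <- function(A, mode, dt, n) {
  s <- svd(A)
  structure(list(A = A, mode = mode, dt = dt, n = n,
                 u = s$u, d = s$d, v = s$v),
            class = "deconv_system")
}

#' @export
print.deconv_system <- function(x, ...) {
  cat(sprintf("<deconv_system> %s, %d x %d, dt %.3g s, cond %.3g\n",
              x$mode, nrow(x$A), ncol(x$A), x$dt,
              max(x$d) / max(min(x$d), .Machine$double.eps)))
  invisible(x)
}

# truncated pseudo-inverse applied to a vector or matrix of curves
svd_solve <- function(system, v, truncation_fraction) {
  keep <- system$d >= truncation_fraction * max(system$d)
  dinv <- ifelse(keep, 1 / system$d, 0)
  system$v %*% (dinv * crossprod(system$u, v))
}

#' Deconvolve a tissue curve against an AIF system
#'
#' Solves `v = A r` for the CBF-scaled residue function by truncated SVD:
#' reciprocal singular values below `truncation_fraction * max(S)` are
#' zeroed. In bcSVD mode the tissue curve is zero-padded to `2N` and the
#' solution has length `2N`; solution indices above `N` correspond to
#' negative (non-physiological) lags.
#'
#' @param tissue An `intensity_curve` or numeric vector of baseline-
#'   subtracted tissue enhancement, length N.
#' @param system A `deconv_system` from [build_conv_matrix()] or
#'   [build_circulant_matrix()] (same `dt`).
#' @param truncation_fraction Relative singular-value cutoff in `[0, 1)`
#'   (default 0.10, the usual circulant-SVD operating point; 0 keeps every
#'   singular value).
#' @return A `residue_solution`: `r` (length N or 2N), `mode`, `dt`,
#'   `argmax_index` (0-based, circular for bcSVD), `argmax_time` (seconds,
#'   negative lags clamped to 0).
#' @export
deconvolve <- function(tissue, system, truncation_fraction = 0.10) {
  stopifnot(inherits(system, "deconv_system"))
  v <- if (inherits(tissue, "intensity_curve")) tissue$values else as.numeric(tissue)
  if (length(v) != system$n) stop("tissue curve length must match the system")
  if (system$mode == "bcSVD") v <- c(v, rep(0, system$n))
  r <- as.vector(svd_solve(system, v, truncation_fraction))
  i_max <- which.max(r) - 1L
  t_max <- if (system$mode == "bcSVD" && i_max >= system$n) 0 else i_max * system$dt
  structure(list(r = r, mode = system$mode, dt = system$dt, n = system$n,
                 argmax_index = i_max, argmax_time = t_max),
            class = "residue_solution")
}

#' Perfusion parameters from a residue solution
#'
#' CBF is the residue maximum (the residue is the product of CBF and a
#' function equal to 1 at its peak); Tmax is the time of that maximum
#' (negative circular lags clamp to 0); CBV is the ratio of the tissue and
#' arterial curve integrals, with a half-sample correction consistent with
#' the rectangle-rule convolution model; MTT = CBV / CBF by the central
#' volume theorem.
#'
#' Integrals are Riemann sums `dt * sum(curve)`; the correction
#' `CBV -> CBV - (dt/2) * CBF` removes the left-endpoint quadrature bias of
#' the discrete forward model (without it MTT is inflated by about half a
#' frame interval).
#'
#' @param r A `residue_solution`.
#' @param tissue Baseline-subtracted tissue curve (vector or
#'   `intensity_curve`).
#' @param aif Baseline-subtracted arterial curve used to build the system.
#' @return A `perfusion_params` list: `cbf`, `cbv`, `mtt` (s), `tmax` (s).
#' @export
estimate_params <- function(r, tissue, aif) {
  stopifnot(inherits(r, "residue_solution"))
  tv <- if (inherits(tissue, "intensity_curve")) tissue$values else as.numeric(tissue)
  av <- if (inherits(aif, "intensity_curve")) aif$values else as.numeric(aif)
  aif_int <- sum(av)
  if (abs(aif_int) < .Machine$double.eps * 1e3 * max(abs(av), 1)) {
    stop("undefined CBV: AIF integral is (near) zero")
  }
  cbf <- max(r$r, 0)
  cbv <- sum(tv) / aif_int - (r$dt / 2) * cbf      # units: CBF * seconds
  mtt <- if (cbf > .Machine$double.eps) cbv / cbf else 0
  structure(list(cbf = cbf, cbv = cbv, mtt = mtt, tmax = r$argmax_time),
            class = "perfusion_params")
}

#' Voxelwise perfusion maps
#'
#' Baseline-subtracts every masked voxel's curve, deconvolves it against the
#' AIF (one pseudo-inverse, applied to all voxels at once) and derives
#' CBF / CBV / MTT / Tmax maps. Unmasked voxels are zero. CBV and MTT are
#' floored at zero.
#'
#' @param series A [ctp_series()].
#' @param aif Baseline-subtracted arterial enhancement curve
#'   (`intensity_curve`).
#' @param mask 3D logical array (default: all voxels).
#' @param mode `"bcSVD"` (default) or `"sSVD"`.
#' @param truncation_fraction Passed to the truncated SVD (default 0.10).
#' @param baseline_frames Frames used for voxelwise baseline subtraction.
#' @return A `perfusion_maps` object: 3D arrays `cbf`, `cbv`, `mtt`,
#'   `tmax`, plus `spacing` and `mask`.
#' @export
make_maps <- function(series, aif, mask = NULL, mode = c("bcSVD", "sSVD"),
                      truncation_fraction = 0.10, baseline_frames = 4L) {
  stopifnot(inherits(series, "ctp_series"))
  mode <- match.arg(mode)
  d <- dim(series$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!all(dim(mask) == d[1:3])) stop("mask dimensions do not match the series")
  system <- if (mode == "bcSVD") build_circulant_matrix(aif)
            else build_conv_matrix(aif)
  if (abs(system$dt - series$dt) > 1e-9) {
    stop("system and series frame intervals differ")
  }
  idx <- which(mask)
  n3 <- prod(d[1:3])
  V <- t(matrix(series$data, n3, d[4])[idx, , drop = FALSE])   # T x nvox
  base <- colMeans(V[seq_len(baseline_frames), , drop = FALSE])
  V <- sweep(V, 2, base)
  if (mode == "bcSVD") V <- rbind(V, matrix(0, d[4], ncol(V)))
  R <- svd_solve(system, V, truncation_fraction)               # L x nvox

  av <- aif$values
  cbf_v <- apply(R, 2, max)
  cbf_v[cbf_v < 0] <- 0
  arg_v <- max.col(t(R), ties.method = "first") - 1L
  tmax_v <- arg_v * series$dt
  if (mode == "bcSVD") tmax_v[arg_v >= d[4]] <- 0
  cbv_v <- colSums(V[seq_len(d[4]), , drop = FALSE]) / sum(av) -
    (series$dt / 2) * cbf_v
  cbv_v[cbv_v < 0] <- 0
  mtt_v <- ifelse(cbf_v > .Machine$double.eps, cbv_v / cbf_v, 0)

  blank <- array(0, d[1:3])
  maps <- list(cbf = blank, cbv = blank, mtt = blank, tmax = blank)
  maps$cbf[idx] <- cbf_v
  maps$cbv[idx] <- cbv_v
  maps$mtt[idx] <- mtt_v
  maps$tmax[idx] <- tmax_v
  structure(c(maps, list(spacing = series$spacing, mask = mask,
                         mode = mode,
                         truncation_fraction = truncation_fraction)),
            class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  d <- dim(x$cbf)
  cat(sprintf("<perfusion_maps> %d x %d x %d (%s), %d masked voxels\n",
              d[1], d[2], d[3], x$mode, sum(x$mask)))
  invisible(x)
}
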