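#' 4D CTP series
#'
#' @param data 4D numeric array (X x Y x Z x T) of HU values, time axis last.
#' @param spacing Voxel spacing in mm, c(dx, dy, dz).
#' @param dt Frame interval in seconds.
#' @return An object of class `ctp_series`.
#' @export
ctp_series <- function(data, spacing = c(1, 1, 4), dt = 1.5) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array (X, Y, Z, T)")
  if (dim(data)[4] < 2L) stop("need at least 2 frames")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(data = data, spacing = as.numeric(spacing), dt = dt),
            class = "ctp_series")
}

#' @export
print.ctp_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ctp_series> %d x %d x %d x %d, spacing %s mm, dt %.3g s\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$spacing, 3), collapse = " x "), x$dt))
  invisible(x)
}

#' @export
dim.ctp_series <- function(x) dim(x$data)

# shift a 3D array by integer voxels, filling exposed voxels with `fill`
shift3 <- function(vol, shift, fill) {
  d <- dim(vol)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) {
      src[[a]] <- 1:(d[a] - s); dst[[a]] <- (1 + s):d[a]
    } else {
      src[[a]] <- (1 - s):d[a]; dst[[a]] <- 1:(d[a] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Integer-translation motion correction
#'
#' Aligns every frame to a reference frame by the integer 3D translation
#' that maximizes Pearson correlation, searched exhaustively within
#' `max_shift` voxels per axis. Exposed voxels are filled with the frame's
#' median edge value. This deliberately replaces full rigid-body
#' registration: it is deterministic, exact for the translations a phantom
#' can plant, and a finer registrar can be substituted upstream.
#'
#' @param series A [ctp_series()].
#' @param reference_frame 1-based index of the reference frame (default 1).
#' @param max_shift Search half-width in voxels per axis (default 3).
#' @return A corrected `ctp_series` with an attribute `shifts` (T x 3 matrix
#'   of applied translations).
#' @export
motion_correct <- function(series, reference_frame = 1L, max_shift = 3L) {
  stopifnot(inherits(series, "ctp_series"))
  d <- dim(series$data)
  if (reference_frame < 1L || reference_frame > d[4]) {
    stop("reference_frame out of range")
  }
  ref <- array(series$data[, , , reference_frame], d[1:3])
  if (stats::sd(ref) == 0) {
    warning("reference frame is constant; motion correction skipped")
    attr(series, "shifts") <- matrix(0L, d[4], 3)
    return(series)
  }
  ref_v <- as.vector(ref)
  offsets <- as.matrix(expand.grid(dx = -max_shift:max_shift,
                                   dy = -max_shift:max_shift,
                                   dz = -max_shift:max_shift))
  # prefer the smallest displacement on ties (zero shift first)
  offsets <- offsets[order(rowSums(abs(offsets)),
                           abs(offsets[, 1]), abs(offsets[, 2]),
                           abs(offsets[, 3])), , drop = FALSE]
  out <- series$data
  shifts <- matrix(0L, d[4], 3)
  for (t in seq_len(d[4])) {
    frame <- array(series$data[, , , t], d[1:3])
    if (stats::sd(frame) == 0) next
    fill <- stats::median(edge_values(frame))
    best <- c(0L, 0L, 0L)
    best_cor <- -Inf
    for (k in seq_len(nrow(offsets))) {
      cand <- shift3(frame, offsets[k, ], fill)
      cc <- suppressWarnings(stats::cor(as.vector(cand), ref_v))
      if (is.finite(cc) && cc > best_cor + 1e-12) {
        best_cor <- cc
        best <- offsets[k, ]
      }
    }
    if (any(best != 0L)) {
      out[, , , t] <- shift3(frame, best, fill)
    }
    shifts[t, ] <- best
  }
  res <- ctp_series(out, series$spacing, series$dt)
  attr(res, "shifts") <- shifts
  res
}

edge_values <- function(vol) {
  d <- dim(vol)
  c(vol[c(1, d[1]), , ], vol[, c(1, d[2]), ], vol[, , c(1, d[3])])
}

# center-crop / zero-pad one axis: returns source and destination index maps
crop_pad_idx <- function(n, m) {
  if (n >= m) {
    start <- (n - m) %/% 2 + 1L
    list(src = start:(start + m - 1L), dst = 1:m)
  } else {
    off <- (m - n) %/% 2
    list(src = 1:n, dst = (off + 1L):(off + n))
  }
}

#' Resize a volume or series to a target grid
#'
#' Centered crop where the input is larger, symmetric zero-padding where it
#' is smaller, independently per spatial axis. A padded-then-cropped volume
#' round-trips exactly.
#'
#' @param x A 3D array, [ctp_series()] or `mip_volume`.
#' @param target_dims Integer triple of target spatial dimensions.
#' @return Same kind of object as `x` at the target grid.
#' @export
resize_to_grid <- function(x, target_dims) {
  target_dims <- as.integer(target_dims)
  if (length(target_dims) != 3L || any(target_dims < 1L)) {
    stop("target_dims must be 3 positive integers")
  }
  if (inherits(x, "ctp_series")) {
    d <- dim(x$data)
    ix <- lapply(1:3, function(a) crop_pad_idx(d[a], target_dims[a]))
    out <- array(0, c(target_dims, d[4]))
    out[ix[[1]]$dst, ix[[2]]$dst, ix[[3]]$dst, ] <-
      x$data[ix[[1]]$src, ix[[2]]$src, ix[[3]]$src, ]
    return(ctp_series(out, x$spacing, x$dt))
  }
  if (inherits(x, "mip_volume")) {
    out <- resize_to_grid(x$data, target_dims)
    x$data <- out
    return(x)
  }
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a 3D array, ctp_series or mip_volume")
  ix <- lapply(1:3, function(a) crop_pad_idx(d[a], target_dims[a]))
  out <- array(0, target_dims)
  out[ix[[1]]$dst, ix[[2]]$dst, ix[[3]]$dst] <-
    x[ix[[1]]$src, ix[[2]]$src, ix[[3]]$src]
  out
}

#' Temporal maximum-minus-minimum projection
#'
#' Collapses the time axis to `max_t - min_t` per voxel, highlighting
#' vessels (large bolus enhancement) against tissue.
#'
#' @param series A [ctp_series()].
#' @return A `mip_volume`: list with `data` (3D, non-negative), `spacing`,
#'   `normalized = FALSE`.
#' @export
compute_mip <- function(series) {
  stopifnot(inherits(series, "ctp_series"))
  d <- dim(series$data)
  frames <- lapply(seq_len(d[4]),
                   function(t) array(series$data[, , , t], d[1:3]))
  mx <- Reduce(pmax, frames)
  mn <- Reduce(pmin, frames)
  structure(list(data = mx - mn, spacing = series$spacing, normalized = FALSE),
            class = "mip_volume")
}

#' @export
print.mip_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mip_volume> %d x %d x %d%s\n", d[1], d[2], d[3],
              if (x$normalized) " (z-normalized)" else ""))
  invisible(x)
}

#' Z-score normalization of a MIP volume
#'
#' Centers and scales to mean 0 / SD 1 using statistics computed within the
#' mask when one is given (brain-only statistics), otherwise over the whole
#' volume. SD uses the population (1/n) convention so the constraint holds
#' exactly at any n.
#'
#' @param vol A `mip_volume` or 3D array.
#' @param mask Optional 3D logical array.
#' @return Same kind as `vol`, normalized; a zero-variance input yields an
#'   all-zero output with a warning.
#' @export
znormalize <- function(vol, mask = NULL) {
  arr <- if (inherits(vol, "mip_volume")) vol$data else vol
  sel <- if (is.null(mask)) rep(TRUE, length(arr)) else as.vector(mask)
  v <- as.vector(arr)[sel]
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) {
    warning("zero-variance input; returning all-zero volume")
    out <- array(0, dim(arr))
  } else {
    out <- (arr - mu) / sdv
  }
  if (inherits(vol, "mip_volume")) {
    vol$data <- out
    vol$normalized <- TRUE
    vol
  } else {
    out
  }
}
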