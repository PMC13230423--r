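#' Vessel landmark
#'
#' A named vessel candidate: one of `AIF_0..AIF_4` or `VOF_0..VOF_2`, with a
#' 1-based 3D voxel index. The kind (arterial/venous) is derived from the
#' name.
#'
#' @param name Landmark name, e.g. `"AIF_0"`.
#' @param index Integer triple (x, y, z), 1-based.
#' @return A `landmark` list with fields `name`, `index`, `kind`.
#' @export
landmark <- function(name, index) {
  if (!grepl("^(AIF_[0-4]|VOF_[0-2])$", name)) {
    stop("landmark name must be AIF_0..AIF_4 or VOF_0..VOF_2")
  }
  index <- as.integer(index)
  if (length(index) != 3L) stop("index must be a 3D voxel index")
  structure(list(name = name, index = index,
                 kind = if (startsWith(name, "AIF")) "AIF" else "VOF"),
            class = "landmark")
}

#' @export
print.landmark <- function(x, ...) {
  cat(sprintf("<landmark> %s (%s) at [%d, %d, %d]\n",
              x$name, x$kind, x$index[1], x$index[2], x$index[3]))
  invisible(x)
}

#' Landmark set from a data.frame
#'
#' @param df data.frame with columns `name`, `x`, `y`, `z`.
#' @return List of [landmark()] objects.
#' @export
landmarks_from_df <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    landmark(df$name[i], c(df$x[i], df$y[i], df$z[i]))
  })
}

#' @export
as.data.frame.landmark <- function(x, ...) {
  data.frame(name = x$name, x = x$index[1], y = x$index[2], z = x$index[3],
             kind = x$kind, stringsAsFactors = FALSE)
}

#' Landmark list to data.frame
#' @param lms List of [landmark()] objects.
#' @return data.frame with columns name, x, y, z, kind.
#' @export
landmarks_to_df <- function(lms) {
  do.call(rbind, lapply(lms, as.data.frame))
}

in_grid <- function(index, dims3) {
  all(index >= 1L) && all(index <= dims3)
}

# offsets within a ball of given radius; metric "euclidean" (default) or
# "chebyshev" (cube). Includes the zero offset.
ball_offsets <- function(radius, metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  r <- as.integer(floor(radius))
  if (r <= 0L) return(matrix(0L, 1, 3))
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  if (metric == "euclidean") {
    g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  }
  g
}

#' Extract an intensity curve at a landmark
#'
#' Mean HU over all in-grid voxels within `radius` voxels (Euclidean) of the
#' landmark, per frame. Radius 0 (the default) reads the single voxel.
#'
#' @param series A [ctp_series()].
#' @param lm A [landmark()] or integer triple.
#' @param radius Neighborhood radius in voxels.
#' @param baseline_frames Baseline frames recorded on the curve.
#' @return An `intensity_curve` of length T.
#' @export
extract_curve <- function(series, lm, radius = 0, baseline_frames = 4L) {
  stopifnot(inherits(series, "ctp_series"))
  index <- if (inherits(lm, "landmark")) lm$index else as.integer(lm)
  d <- dim(series$data)
  if (!in_grid(index, d[1:3])) stop("landmark index outside the grid")
  if (radius <= 0) {
    v <- series$data[index[1], index[2], index[3], ]
  } else {
    off <- ball_offsets(radius)
    pts <- sweep(off, 2, index, `+`)
    keep <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
            pts[, 2] >= 1 & pts[, 2] <= d[2] &
            pts[, 3] >= 1 & pts[, 3] <= d[3]
    pts <- pts[keep, , drop = FALSE]
    v <- vapply(seq_len(d[4]), function(t) {
      mean(series$data[cbind(pts, t)])
    }, numeric(1))
  }
  intensity_curve(v, series$dt, baseline_frames = baseline_frames)
}

#' Baseline-subtracted area under a curve
#'
#' Trapezoidal integral over time of the enhancement above the pre-contrast
#' baseline (mean of the first `baseline_frames` samples). Vessel voxels
#' carry far more bolus than tissue, so this is the objective the ROI
#' grid-search maximizes.
#'
#' @param curve An `intensity_curve`.
#' @return AUC in HU * s.
#' @export
curve_auc <- function(curve) {
  stopifnot(inherits(curve, "intensity_curve"))
  v <- curve$values - curve_baseline(curve)
  n <- length(v)
  curve$dt * sum((v[-1] + v[-n]) / 2)
}

#' Grid-search ROI correction of a landmark
#'
#' Searches all in-grid voxels within a ball of `radius` voxels around the
#' landmark and moves it to the voxel whose extracted curve has the highest
#' baseline-subtracted AUC. Ties are broken by smaller displacement from the
#' original position, then lexicographic voxel order, so the result is
#' deterministic and the original voxel wins when already optimal.
#'
#' @param series A [ctp_series()].
#' @param lm A [landmark()].
#' @param radius Search radius in voxels (default 8).
#' @param metric `"euclidean"` ball (default) or `"chebyshev"` cube.
#' @param extraction_radius Radius passed to [extract_curve()] at each
#'   candidate voxel (default 0).
#' @param baseline_frames Baseline frames for the AUC.
#' @return The corrected [landmark()] (same name and kind).
#' @export
correct_roi <- function(series, lm, radius = 8, metric = "euclidean",
                        extraction_radius = 0, baseline_frames = 4L) {
  stopifnot(inherits(series, "ctp_series"), inherits(lm, "landmark"))
  d <- dim(series$data)
  if (!in_grid(lm$index, d[1:3])) stop("landmark index outside the grid")
  off <- ball_offsets(radius, metric)
  pts <- sweep(off, 2, lm$index, `+`)
  keep <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
          pts[, 2] >= 1 & pts[, 2] <= d[2] &
          pts[, 3] >= 1 & pts[, 3] <= d[3]
  pts <- pts[keep, , drop = FALSE]
  dist2 <- rowSums(sweep(pts, 2, lm$index, `-`)^2)
  # lexicographic key for deterministic tie-breaks
  ord <- order(dist2, pts[, 1], pts[, 2], pts[, 3])
  pts <- pts[ord, , drop = FALSE]
  auc <- vapply(seq_len(nrow(pts)), function(k) {
    curve_auc(extract_curve(series, pts[k, ], radius = extraction_radius,
                            baseline_frames = baseline_frames))
  }, numeric(1))
  best <- which.max(auc)  # first max in (distance, lexicographic) order
  landmark(lm$name, pts[best, ])
}

#' Heuristic vessel localization
#'
#' A fully automatic stand-in for a learned landmark detector: ranks masked
#' voxels by baseline-subtracted AUC, splits them at the masked median
#' time-to-peak (arteries peak early, veins late), and greedily picks the 5
#' top-AUC early voxels as AIF candidates and the 3 top-AUC late voxels as
#' VOF candidates, enforcing a pairwise separation of at least
#' `min_separation` voxels.
#'
#' @param series A [ctp_series()].
#' @param mask 3D logical array of eligible voxels.
#' @param min_separation Minimum pairwise Euclidean distance in voxels.
#' @param baseline_frames Baseline frames for AUC/time-to-peak.
#' @return List of 8 [landmark()]s (AIF_0..AIF_4, VOF_0..VOF_2).
#' @export
heuristic_localize <- function(series, mask, min_separation = 3,
                               baseline_frames = 4L) {
  stopifnot(inherits(series, "ctp_series"))
  d <- dim(series$data)
  idx <- which(mask)
  if (length(idx) < 8L) stop("localization error: fewer than 8 eligible voxels")
  n3 <- prod(d[1:3])
  mat <- matrix(series$data, n3, d[4])[idx, , drop = FALSE]
  base <- rowMeans(mat[, seq_len(baseline_frames), drop = FALSE])
  enh <- mat - base
  # trapezoid weights over the time axis
  w <- rep(series$dt, d[4]); w[c(1, d[4])] <- series$dt / 2
  auc <- as.vector(enh %*% w)
  ttp <- max.col(enh, ties.method = "first")
  med_ttp <- stats::median(ttp)
  coords <- arrayInd(idx, d[1:3])

  pick <- function(cand, k, taken) {
    chosen <- integer(0)
    for (i in cand) {
      ok <- TRUE
      for (j in c(taken, chosen)) {
        if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < min_separation) {
          ok <- FALSE; break
        }
      }
      if (ok) chosen <- c(chosen, i)
      if (length(chosen) == k) break
    }
    chosen
  }

  early <- which(ttp < med_ttp)
  late <- which(ttp >= med_ttp)
  aif_sel <- pick(early[order(-auc[early])], 5L, integer(0))
  vof_sel <- pick(late[order(-auc[late])], 3L, aif_sel)
  if (length(aif_sel) < 5L || length(vof_sel) < 3L) {
    stop("localization error: could not place 5 AIF + 3 VOF candidates")
  }
  c(
    lapply(0:4, function(i) landmark(paste0("AIF_", i), coords[aif_sel[i + 1], ])),
    lapply(0:2, function(i) landmark(paste0("VOF_", i), coords[vof_sel[i + 1], ]))
  )
}
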