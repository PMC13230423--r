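#' Relative CBF map
#'
#' Normalizes the CBF map by a reference flow so the rCBF < 30% threshold
#' can be applied. Reference strategies:
#' \describe{
#'   \item{`global_median`}{median CBF over masked voxels that are not
#'     delay-hypoperfused (Tmax <= 6 s) and have positive flow — robust and
#'     anatomy-free (default).}
#'   \item{`contralateral`}{each voxel is divided by the median CBF of the
#'     opposite hemisphere (mid-sagittal split along the first axis), the
#'     convention of commercial packages on anatomical data.}
#'   \item{`explicit_value`}{divide by a supplied constant.}
#' }
#'
#' @param maps A `perfusion_maps` object.
#' @param reference One of `"global_median"`, `"contralateral"`,
#'   `"explicit_value"`.
#' @param value Reference CBF for `explicit_value`.
#' @param tmax_cutoff Tmax cutoff (s) defining non-hypoperfused tissue for
#'   `global_median` (default 6).
#' @return A 3D array of unitless rCBF (0 outside the mask).
#' @export
rcbf_map <- function(maps, reference = c("global_median", "contralateral",
                                         "explicit_value"),
                     value = NULL, tmax_cutoff = 6) {
  stopifnot(inherits(maps, "perfusion_maps"))
  reference <- match.arg(reference)
  cbf <- maps$cbf
  mask <- maps$mask
  out <- array(0, dim(cbf))
  if (reference == "explicit_value") {
    if (is.null(value) || !is.finite(value) || value == 0) {
      stop("undefined reference: explicit_value requires a nonzero value")
    }
    out[mask] <- cbf[mask] / value
    return(out)
  }
  if (reference == "global_median") {
    sel <- mask & maps$tmax <= tmax_cutoff & cbf > 0
    ref <- stats::median(cbf[sel])
    if (!isTRUE(ref > 0)) stop("undefined reference: non-positive median CBF")
    out[mask] <- cbf[mask] / ref
    return(out)
  }
  # contralateral: mirror across the mid-sagittal plane (first axis)
  d <- dim(cbf)
  half <- d[1] %/% 2
  left <- mask & slice_mask(d, 1:half)
  right <- mask & slice_mask(d, (d[1] - half + 1):d[1])
  ref_left <- stats::median(cbf[right])   # left voxels referenced to right
  ref_right <- stats::median(cbf[left])
  if (!isTRUE(ref_left > 0) || !isTRUE(ref_right > 0)) {
    stop("undefined reference: non-positive hemisphere median")
  }
  out[left] <- cbf[left] / ref_left
  out[right] <- cbf[right] / ref_right
  mid <- mask & !left & !right
  out[mid] <- cbf[mid] / stats::median(cbf[mask])
  out
}

slice_mask <- function(d, xs) {
  m <- array(FALSE, d)
  m[xs, , ] <- TRUE
  m
}

voxel_ml <- function(spacing) prod(spacing) / 1000

#' Hypoperfusion core volume (Volume F)
#'
#' Volume of masked tissue with rCBF strictly below the threshold, in mL.
#'
#' @param rcbf 3D rCBF array (see [rcbf_map()]).
#' @param mask 3D logical brain mask.
#' @param spacing Voxel spacing in mm.
#' @param threshold rCBF threshold in `(0, 1)` (default 0.30; a voxel at
#'   exactly the threshold is excluded).
#' @return Exact volume in mL (round for reporting).
#' @export
volume_f <- function(rcbf, mask, spacing, threshold = 0.30) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  sum(mask & rcbf < threshold) * voxel_ml(spacing)
}

#' Delay-hypoperfusion volume (Volume T)
#'
#' Volume of masked tissue with Tmax strictly above the threshold, in mL.
#'
#' @param tmax 3D Tmax array in seconds.
#' @param mask 3D logical brain mask.
#' @param spacing Voxel spacing in mm.
#' @param threshold Tmax threshold in seconds (default 6; exactly 6 s is
#'   excluded).
#' @return Exact volume in mL.
#' @export
volume_t <- function(tmax, mask, spacing, threshold = 6) {
  if (threshold <= 0) stop("threshold must be > 0")
  sum(mask & tmax > threshold) * voxel_ml(spacing)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Assemble the volume report
#'
#' When the AIF/VOF pair selection ended in a warning, the report carries
#' the warning and claims no volumes; otherwise it reports integer-mL
#' Volume F and Volume T (exact values retained) together with the
#' thresholds, reference strategy and pair identities used.
#'
#' @param maps A `perfusion_maps` object, or `NULL` when pair selection
#'   failed.
#' @param pair A `pair_selection` result (see [select_pair()]).
#' @param rcbf_threshold,tmax_threshold Lesion thresholds (defaults 0.30
#'   and 6 s).
#' @param reference rCBF reference strategy passed to [rcbf_map()].
#' @param reference_value Constant for the `explicit_value` strategy.
#' @param landmarks Optional landmark data.frame recorded as provenance.
#' @return A `volume_report` list; serialize with [write_report()].
#' @export
make_report <- function(maps, pair, rcbf_threshold = 0.30, tmax_threshold = 6,
                        reference = "global_median", reference_value = NULL,
                        landmarks = NULL) {
  prov <- list(
    rcbf_threshold = rcbf_threshold,
    tmax_threshold = tmax_threshold,
    reference = reference,
    landmarks = landmarks
  )
  if (inherits(pair, "pair_selection") && pair$status == "warning") {
    return(structure(list(
      warnings = pair$warning, volume_f_ml = NULL, volume_t_ml = NULL,
      volume_f_ml_exact = NULL, volume_t_ml_exact = NULL,
      pair = NULL, provenance = prov
    ), class = "volume_report"))
  }
  stopifnot(inherits(maps, "perfusion_maps"))
  rcbf <- rcbf_map(maps, reference = reference, value = reference_value)
  vf <- volume_f(rcbf, maps$mask, maps$spacing, rcbf_threshold)
  vt <- volume_t(maps$tmax, maps$mask, maps$spacing, tmax_threshold)
  pair_ids <- if (inherits(pair, "pair_selection")) {
    list(aif = paste0("AIF_", pair$aif_index - 1L),
         vof = paste0("VOF_", pair$vof_index - 1L),
         peak_delay_s = pair$peak_delay)
  }
  structure(list(
    warnings = character(0),
    volume_f_ml = as.integer(round_half_away(vf)),
    volume_t_ml = as.integer(round_half_away(vt)),
    volume_f_ml_exact = vf,
    volume_t_ml_exact = vt,
    pair = pair_ids,
    provenance = prov
  ), class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  if (length(x$warnings) > 0) {
    cat("<volume_report> WARNING:", paste(x$warnings, collapse = "; "),
        "- no volumes reported\n")
  } else {
    cat(sprintf("<volume_report> Volume F = %d mL, Volume T = %d mL\n",
                x$volume_f_ml, x$volume_t_ml))
  }
  invisible(x)
}
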