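#' Write a CTP series as 4D NIfTI with a timing sidecar
#'
#' Voxel spacing goes in the NIfTI header (pixdim); the frame interval is
#' recorded both in the header's temporal pixdim and in a JSON sidecar
#' (`<path minus extensions>.json`) with field `frame_interval_s`.
#'
#' @param series A [ctp_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_ctp_nifti <- function(series, path) {
  stopifnot(inherits(series, "ctp_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$spacing, series$dt)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(frame_interval_s = series$dt, spacing_mm = series$spacing),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read a CTP series from NIfTI
#'
#' @param path Path to a 4D NIfTI file.
#' @param dt Frame interval in seconds; when `NULL`, read from the JSON
#'   sidecar, falling back to the header's temporal pixdim.
#' @return A [ctp_series()].
#' @export
read_ctp_nifti <- function(path, dt = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  pd <- RNifti::pixdim(img)
  spacing <- pd[1:3]
  if (is.null(dt)) {
    sc <- sidecar_path(path)
    dt <- if (file.exists(sc)) {
      jsonlite::read_json(sc)$frame_interval_s
    } else if (length(pd) >= 4 && pd[4] > 0) {
      pd[4]
    } else {
      stop("frame interval not found; pass dt explicitly")
    }
  }
  ctp_series(arr, spacing = spacing, dt = as.numeric(dt))
}

#' Write a 3D map (or mask) as NIfTI
#'
#' @param vol 3D numeric or logical array.
#' @param path Output path.
#' @param spacing Voxel spacing in mm.
#' @return The path, invisibly.
#' @export
write_map_nifti <- function(vol, path, spacing = c(1, 1, 4)) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI volume
#' @param path Path to the file.
#' @return A 3D numeric array with a `spacing` attribute.
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "spacing") <- RNifti::pixdim(img)[1:3]
  arr
}

#' Write perfusion maps as one NIfTI per parameter
#'
#' @param maps A `perfusion_maps` object.
#' @param dir Output directory (created if missing).
#' @return Named vector of the four file paths, invisibly.
#' @export
write_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "perfusion_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(c("cbf", "cbv", "mtt", "tmax"), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_map_nifti(maps[[nm]], p, maps$spacing)
    p
  }, character(1))
  invisible(paths)
}

#' Write landmarks as JSON
#'
#' Serialized as an array of `{"name": "AIF_0", "index": [x, y, z]}`
#' objects (1-based voxel indices).
#'
#' @param lms List of [landmark()]s.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_landmarks <- function(lms, path) {
  recs <- lapply(lms, function(l) list(name = l$name, index = l$index))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmarks from JSON
#' @param path Path to a landmark JSON file.
#' @return List of [landmark()]s.
#' @export
read_landmarks <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) landmark(r$name, unlist(r$index)))
}

#' Write an intensity curve as CSV
#'
#' Columns `frame` (0-based), `time_s`, `hu`.
#'
#' @param curve An `intensity_curve`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read an intensity curve from CSV
#' @param path Path to a curve CSV (columns frame, time_s, hu).
#' @param baseline_frames Baseline frames for the resulting curve.
#' @return An `intensity_curve`.
#' @export
read_curve_csv <- function(path, baseline_frames = 4L) {
  df <- utils::read.csv(path)
  dt <- if (nrow(df) >= 2) df$time_s[2] - df$time_s[1] else 1
  intensity_curve(df$hu, dt, baseline_frames = baseline_frames)
}

#' Serialize a volume report to JSON
#'
#' @param report A `volume_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "volume_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a volume report from JSON
#' @param path Path to a report JSON file.
#' @return A `volume_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(obj$warnings) == 0) obj$warnings <- character(0)
  structure(obj, class = "volume_report")
}

#' Save a curve classifier as a text artifact
#'
#' The fitted state is stored as versioned JSON with an embedded feature
#' contract: xgboost boosters in their native JSON dump, the feed-forward
#' network as its weight vector plus architecture.
#'
#' @param model A `curve_classifier`.
#' @param path Output path (`.json`).
#' @return The path, invisibly.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "curve_classifier"))
  payload <- list(format_version = 1L, role = model$role,
                  engine = model$engine, features = model$features,
                  seed = model$seed)
  if (model$engine == "xgboost") {
    raw <- xgboost::xgb.save.raw(model$fit, raw_format = "json")
    payload$booster_json <- rawToChar(raw)
  } else {
    payload$wts <- model$fit$wts
    payload$n <- model$fit$n
    payload$center <- as.list(model$center)
    payload$scale <- as.list(model$scale)
  }
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a curve classifier saved by [save_classifier()]
#' @param path Path to the JSON artifact.
#' @return A `curve_classifier`.
#' @export
load_classifier <- function(path) {
  payload <- jsonlite::read_json(path)
  feats <- unlist(payload$features)
  if (!identical(feats, classifier_features)) {
    stop("classifier artifact feature contract does not match this version")
  }
  if (payload$engine == "xgboost") {
    fit <- xgboost::xgb.load.raw(charToRaw(payload$booster_json))
    new_curve_classifier(payload$role, "xgboost", fit,
                         extra = list(seed = payload$seed))
  } else {
    n <- unlist(payload$n)
    wts <- unlist(payload$wts)
    # rebuild the network skeleton, then install the stored weights
    dummy_x <- matrix(0, 2, n[1])
    fit <- nnet::nnet(dummy_x, c(0, 1), size = n[2], maxit = 0, trace = FALSE)
    fit$wts <- wts
    new_curve_classifier(payload$role, "nnet", fit,
                         extra = list(center = unlist(payload$center),
                                      scale = unlist(payload$scale),
                                      seed = payload$seed))
  }
}
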