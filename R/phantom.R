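#' Digital perfusion phantom specification
#'
#' Defines a synthetic CTP acquisition with known ground truth: a gamma-variate
#' arterial bolus, a delayed/dispersed venous curve, tissue compartments
#' generated by the discrete convolution forward model, named vessel
#' landmarks, and additive Gaussian noise. Defaults emulate a standard stroke
#' protocol: 30 frames at 1.5 s (45 s acquisition), 4 mm slices, a
#' hypoperfused core at 20% of normal flow (12 mL) and a delayed penumbra
#' (7.5 s arrival delay, 40 mL).
#'
#' @param dims Grid dimensions c(X, Y, Z, T). Default `c(64, 64, 8, 30)`,
#'   a desk-scale stand-in for the clinical 512 x 512 x 27 x 30 grid.
#' @param spacing Voxel spacing in mm, c(dx, dy, dz). Default `c(1, 1, 4)`.
#' @param dt Frame interval in seconds. Default 1.5.
#' @param aif [bolus_params()] for the arterial input. Default peaks at
#'   150 HU enhancement, 9 s post scan start.
#' @param vof_delay Venous delay relative to the AIF in seconds (default 4.5,
#'   i.e. 3 frames — inside the physiological 3–12 s window).
#' @param vof_dispersion Multiplier on the bolus time scale for the venous
#'   curve (default 1.3).
#' @param vof_amplitude Multiplier on the bolus amplitude for the venous
#'   curve (default 1.5 — veins enhance more than arteries).
#' @param tissue Named list of tissue regions. Each entry is a list with a
#'   `class` ([tissue_class()]) and a `box` (2 x 3 integer matrix,
#'   inclusive voxel index ranges rbind(from, to), 1-based). Voxels outside
#'   every box are "normal". Boxes must be pairwise disjoint.
#' @param normal [tissue_class()] for unlabelled tissue. The default CBF of
#'   0.01 per second with MTT 4 s corresponds to a 4% blood-volume fraction
#'   and gives tissue enhancement of a few HU against a ~150 HU arterial
#'   peak, the ratio seen on real scanners.
#' @param aif_box,vof_box 2 x 3 boxes of vessel voxels carrying the arterial
#'   and venous curves.
#' @param landmarks Optional data.frame of true landmarks (columns `name`,
#'   `x`, `y`, `z`); by default 5 AIF voxels inside `aif_box` and 3 VOF
#'   voxels inside `vof_box`.
#' @param noise_sigma Additive Gaussian noise SD in HU (default 2, a clean
#'   acquisition).
#' @param vessel_corruption Optional [corrupt_curve()] mode applied to the
#'   vessel curves (e.g. `"truncated_bolus"` emulates bad bolus timing and
#'   should trip the invalid-curve warning); `NULL` for clean vessels.
#' @param baseline_hu Constant pre-contrast attenuation added everywhere
#'   (default 40 HU).
#' @param baseline_frames Pre-contrast frames recorded on extracted curves.
#' @param residue_shape Residue model passed to [make_tissue_curve()].
#' @param seed Integer RNG seed for the noise field.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(64L, 64L, 8L, 30L),
                         spacing = c(1, 1, 4),
                         dt = 1.5,
                         aif = bolus_params(amplitude = 150, t0 = 6,
                                            alpha = 2, beta = 1.5),
                         vof_delay = 4.5,
                         vof_dispersion = 1.3,
                         vof_amplitude = 1.5,
                         tissue = NULL,
                         normal = tissue_class("normal", cbf = 0.01, mtt = 4),
                         aif_box = rbind(c(54, 10, 4), c(58, 14, 5)),
                         vof_box = rbind(c(54, 40, 4), c(58, 44, 5)),
                         landmarks = NULL,
                         noise_sigma = 2,
                         vessel_corruption = NULL,
                         baseline_hu = 40,
                         baseline_frames = 4L,
                         residue_shape = "exponential",
                         seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 4L || any(dims < 1L)) stop("dims must be 4 positive integers")
  if (dims[4] < 2L) stop("need at least 2 frames")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(tissue)) {
    tissue <- list(
      core = list(
        class = tissue_class("core", cbf = 0.2 * normal$cbf, mtt = 8, delay = 0),
        # 20 x 25 x 6 voxels * 4 mm^3 = 12.0 mL
        box = rbind(c(30, 5, 1), c(49, 29, 6))
      ),
      penumbra = list(
        class = tissue_class("penumbra", cbf = 0.875 * normal$cbf, mtt = 6,
                             delay = 7.5),
        # 25 x 50 x 8 voxels * 4 mm^3 = 40.0 mL
        box = rbind(c(2, 5, 1), c(26, 54, 8))
      )
    )
  }
  for (reg in tissue) check_box(reg$box, dims[1:3])
  check_box(aif_box, dims[1:3])
  check_box(vof_box, dims[1:3])
  if (is.null(landmarks)) {
    ax <- aif_box[1, ]
    vx <- vof_box[1, ]
    landmarks <- data.frame(
      name = c(paste0("AIF_", 0:4), paste0("VOF_", 0:2)),
      x = c(ax[1] + c(0, 1, 2, 3, 4), vx[1] + c(0, 2, 4)),
      y = c(ax[2] + c(0, 1, 2, 3, 4), vx[2] + c(0, 2, 4)),
      z = c(ax[3] + c(0, 1, 0, 1, 0), vx[3] + c(0, 1, 0)),
      stringsAsFactors = FALSE
    )
  }
  if (any(landmarks$x < 1 | landmarks$x > dims[1] |
          landmarks$y < 1 | landmarks$y > dims[2] |
          landmarks$z < 1 | landmarks$z > dims[3])) {
    stop("landmark indices fall outside the grid")
  }
  structure(list(
    dims = dims, spacing = spacing, dt = dt, aif = aif,
    vof_delay = vof_delay, vof_dispersion = vof_dispersion,
    vof_amplitude = vof_amplitude, tissue = tissue, normal = normal,
    aif_box = aif_box, vof_box = vof_box, landmarks = landmarks,
    noise_sigma = noise_sigma, vessel_corruption = vessel_corruption,
    baseline_hu = baseline_hu,
    baseline_frames = as.integer(baseline_frames),
    residue_shape = residue_shape, seed = as.integer(seed)
  ), class = "phantom_spec")
}

check_box <- function(box, dims3) {
  if (!is.matrix(box) || !all(dim(box) == c(2, 3))) {
    stop("a region box must be a 2 x 3 matrix rbind(from, to)")
  }
  if (any(box[1, ] > box[2, ])) stop("box 'from' must be <= 'to'")
  if (any(box[1, ] < 1) || any(box[2, ] > dims3)) stop("box exceeds the grid")
  invisible(box)
}

box_mask <- function(box, dims3) {
  m <- array(FALSE, dims3)
  m[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3]] <- TRUE
  m
}

#' The phantom's venous output curve
#'
#' The AIF delayed by `vof_delay`, dispersed (`beta * vof_dispersion`) and
#' scaled (`amplitude * vof_amplitude`) — a vein peaks later, wider and
#' higher than the feeding artery.
#'
#' @param spec A [phantom_spec()].
#' @return An `intensity_curve` of venous enhancement (baseline-free).
#' @export
phantom_vof_curve <- function(spec) {
  p <- spec$aif
  vof <- bolus_params(amplitude = p$amplitude * spec$vof_amplitude,
                      t0 = p$t0 + spec$vof_delay,
                      alpha = p$alpha,
                      beta = p$beta * spec$vof_dispersion)
  make_bolus_curve(vof, n_frames = spec$dims[4], dt = spec$dt,
                   baseline_frames = spec$baseline_frames)
}

#' Build a synthetic CTP series with ground truth
#'
#' Generates the 4D HU series (vessel voxels carry AIF/VOF curves, tissue
#' voxels the forward-model curves of their class, everything offset by the
#' baseline HU and perturbed by i.i.d. Gaussian noise) together with exact
#' truth maps (CBF/CBV/MTT/Tmax), per-class lesion masks, the true landmark
#' table, and rule-based validity labels for the landmark curves.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `series` (a [ctp_series()]) and `truth`
#'   (class `phantom_truth`: `cbf`, `cbv`, `mtt`, `tmax` 3D arrays, `masks`
#'   list of logical arrays incl. `vessel`, `volumes_ml` per class,
#'   `landmarks`, `labels`, plus the noiseless class curves).
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  d <- spec$dims
  n3 <- prod(d[1:3])
  xyz <- d[1:3]

  masks <- lapply(spec$tissue, function(reg) box_mask(reg$box, xyz))
  if (length(masks) >= 2L) {
    overlap <- Reduce(`+`, lapply(masks, as.integer))
    if (any(overlap > 1L)) stop("tissue region masks overlap")
  }
  vessel_aif <- box_mask(spec$aif_box, xyz)
  vessel_vof <- box_mask(spec$vof_box, xyz)
  vessel <- vessel_aif | vessel_vof
  if (any(vessel & Reduce(`|`, c(masks, list(array(FALSE, xyz)))))) {
    stop("vessel boxes overlap a tissue region")
  }

  aif_curve <- make_bolus_curve(spec$aif, n_frames = d[4], dt = spec$dt,
                                baseline_frames = spec$baseline_frames)
  vof_curve <- phantom_vof_curve(spec)
  # tissue is always driven by the clean AIF; corruption models an
  # acquisition/vessel problem visible in the measured vessel curves
  aif_measured <- aif_curve
  vof_measured <- vof_curve
  if (!is.null(spec$vessel_corruption)) {
    aif_measured <- corrupt_curve(aif_curve, spec$vessel_corruption,
                                  seed = spec$seed + 101L)
    vof_measured <- corrupt_curve(vof_curve, spec$vessel_corruption,
                                  seed = spec$seed + 211L)
  }

  class_curves <- lapply(spec$tissue, function(reg) {
    make_tissue_curve(aif_curve, reg$class, spec$residue_shape)
  })
  normal_curve <- make_tissue_curve(aif_curve, spec$normal, spec$residue_shape)

  # assemble frame by frame: normal everywhere, then regions, then vessels
  data <- array(0, d)
  idx_regions <- lapply(masks, which)
  idx_aif <- which(vessel_aif)
  idx_vof <- which(vessel_vof)
  for (t in seq_len(d[4])) {
    frame <- rep(normal_curve$values[t], n3)
    for (k in seq_along(idx_regions)) {
      frame[idx_regions[[k]]] <- class_curves[[k]]$values[t]
    }
    frame[idx_aif] <- aif_measured$values[t]
    frame[idx_vof] <- vof_measured$values[t]
    data[, , , t] <- frame
  }
  data <- data + spec$baseline_hu
  if (spec$noise_sigma > 0) {
    data <- data + withr_seed(spec$seed,
                              array(stats::rnorm(length(data), 0, spec$noise_sigma), d))
  }

  # exact truth maps
  cbf <- array(spec$normal$cbf, xyz)
  cbv <- array(spec$normal$cbv, xyz)
  mtt <- array(spec$normal$mtt, xyz)
  tmax <- array(spec$normal$delay, xyz)
  for (k in seq_along(spec$tissue)) {
    cls <- spec$tissue[[k]]$class
    cbf[idx_regions[[k]]] <- cls$cbf
    cbv[idx_regions[[k]]] <- cls$cbv
    mtt[idx_regions[[k]]] <- cls$mtt
    tmax[idx_regions[[k]]] <- cls$delay
  }

  voxel_ml <- prod(spec$spacing) / 1000
  volumes_ml <- vapply(masks, function(m) sum(m) * voxel_ml, numeric(1))

  lm <- spec$landmarks
  lm$kind <- ifelse(grepl("^AIF", lm$name), "AIF", "VOF")
  labels <- data.frame(
    name = c("AIF", "VOF"),
    valid = c(rule_check(aif_measured, "AIF")$valid,
              rule_check(vof_measured, "VOF")$valid),
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    cbf = cbf, cbv = cbv, mtt = mtt, tmax = tmax,
    masks = c(masks, list(vessel = vessel, vessel_aif = vessel_aif,
                          vessel_vof = vessel_vof)),
    volumes_ml = volumes_ml,
    landmarks = lm,
    labels = labels,
    aif_curve = aif_measured,
    vof_curve = vof_measured,
    normal_curve = normal_curve,
    class_curves = class_curves,
    spacing = spec$spacing,
    baseline_hu = spec$baseline_hu
  ), class = "phantom_truth")

  list(series = ctp_series(data, spacing = spec$spacing, dt = spec$dt),
       truth = truth)
}

#' Rule-based validity label for a phantom curve
#'
#' Applies the same rule set the validity module uses ([rule_check()]),
#' plus — when a partner curve is given — the 3–12 s AIF-to-VOF peak-delay
#' rule. This is how training labels for the learned validity classifiers
#' are produced.
#'
#' @param curve An `intensity_curve`.
#' @param kind `"AIF"` or `"VOF"`.
#' @param partner Optional partner curve (the VOF for an AIF and vice
#'   versa) used for the peak-delay rule.
#' @param rules Rule thresholds, see [validity_rules()].
#' @return A list with `label` (logical) and `result` (the
#'   `validity_result`).
#' @export
label_curve <- function(curve, kind, partner = NULL, rules = validity_rules()) {
  res <- rule_check(curve, kind, rules)
  label <- res$valid
  failed <- res$failed_rules
  if (!is.null(partner)) {
    f_self <- featurize(curve)
    f_part <- featurize(partner)
    delay <- if (kind == "AIF") f_part$time_to_peak - f_self$time_to_peak
             else f_self$time_to_peak - f_part$time_to_peak
    if (delay < rules$pair_delay[1] || delay > rules$pair_delay[2]) {
      label <- FALSE
      failed <- c(failed, "pair_delay")
    }
  }
  list(label = label, failed_rules = failed, result = res)
}
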