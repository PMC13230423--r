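#' Pipeline configuration
#'
#' Central configuration for the end-to-end run, with the defaults the
#' method prescribes: an 8-voxel ROI-correction search radius, bcSVD
#' deconvolution with 10% singular-value truncation, rCBF < 0.30 and
#' Tmax > 6 s lesion thresholds, and the global-median rCBF reference.
#' Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults, e.g. `deconv = list(mode = "sSVD")`.
#'   Nested lists are merged key by key.
#' @return A `ctp_config` list with blocks `prep`, `roi`, `validity`,
#'   `deconv`, `quant`, `seed`.
#' @export
ctp_config <- function(...) {
  defaults <- list(
    prep = list(
      motion_correct = FALSE,  # phantoms are motion-free; enable for clinical data
      reference_frame = 1L,
      max_shift = 3L
    ),
    roi = list(
      radius = 8,
      metric = "euclidean",
      extraction_radius = 0,
      baseline_frames = 4L
    ),
    validity = list(
      use_rules = TRUE,
      use_iv = TRUE,
      use_lv = TRUE,
      augment_sigma = 5,
      n_augment = 2L,
      rules = list()          # overrides forwarded to validity_rules()
    ),
    deconv = list(
      mode = "bcSVD",
      truncation_fraction = 0.10
    ),
    quant = list(
      rcbf_threshold = 0.30,
      tmax_threshold = 6,
      reference = "global_median",
      reference_value = NULL
    ),
    seed = 1L
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      bad2 <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      if (length(bad2) > 0) {
        stop("unknown config keys in '", nm, "': ", paste(bad2, collapse = ", "))
      }
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  structure(defaults, class = "ctp_config")
}

config_rules <- function(config) {
  do.call(validity_rules, config$validity$rules)
}

#' Synthetic training set for the validity classifiers
#'
#' Generates labelled arterial and venous curves spanning the clean and
#' corrupted regimes the classifiers must separate: gamma-variate curves
#' with varying amplitude/timing (valid when they satisfy the rule set)
#' plus multi-peak, jagged, truncated-bolus, flat and low-enhancement
#' curves (invalid).
#'
#' @param n_per_class Curves per (kind, validity) cell (default 100, i.e.
#'   400 curves total).
#' @param n_frames,dt Acquisition geometry (defaults 30 frames at 1.5 s).
#' @param seed Integer seed.
#' @return A list with `curves`, `labels` (logical), `kind` (character),
#'   `is_vof` (logical).
#' @export
synthesize_training_curves <- function(n_per_class = 100L, n_frames = 30L,
                                       dt = 1.5, seed = 1L) {
  out_curves <- list()
  out_labels <- logical(0)
  out_kind <- character(0)
  withr_seed(seed, {
    for (kind in c("AIF", "VOF")) {
      for (i in seq_len(n_per_class)) {
        # valid: a clean bolus with kind-appropriate timing and amplitude
        amp <- if (kind == "AIF") stats::runif(1, 100, 220)
               else stats::runif(1, 150, 320)
        # veins trail arteries by the physiological 3-12 s arteriovenous delay
        t0 <- if (kind == "AIF") stats::runif(1, 4, 9)
              else stats::runif(1, 9, 16)
        beta <- stats::runif(1, 1.2, if (kind == "AIF") 1.8 else 2.4)
        # curves ride on a pre-contrast baseline as on a real scanner
        baseline <- stats::runif(1, 30, 55)
        cv <- make_bolus_curve(bolus_params(amp, t0, 2, beta), n_frames, dt)
        cv$values <- cv$values + baseline
        cv <- corrupt_curve(cv, "gaussian", severity = 1.5, seed = seed + i)
        out_curves <- c(out_curves, list(cv))
        out_labels <- c(out_labels, TRUE)
        out_kind <- c(out_kind, kind)
        # invalid: one of the corruption modes, or too little enhancement
        mode <- sample(c("multi_peak", "jagged", "truncated_bolus", "flat",
                         "weak"), 1)
        base <- make_bolus_curve(bolus_params(
          if (mode == "weak") stats::runif(1, 20, 60) else amp,
          t0, 2, beta), n_frames, dt)
        base$values <- base$values + stats::runif(1, 30, 55)
        bad <- if (mode == "weak") {
          corrupt_curve(base, "gaussian", severity = 1.5, seed = seed + 7 * i)
        } else {
          corrupt_curve(base, mode, seed = seed + 7 * i)
        }
        out_curves <- c(out_curves, list(bad))
        out_labels <- c(out_labels, FALSE)
        out_kind <- c(out_kind, kind)
      }
    }
  })
  list(curves = out_curves, labels = out_labels, kind = out_kind,
       is_vof = out_kind == "VOF")
}

#' Train the full validity-model set
#'
#' Trains the arterial IV model, the venous IV model, and the LV
#' (venous-vs-arterial) model on a synthetic labelled curve set.
#'
#' @param training Output of [synthesize_training_curves()] (generated with
#'   `seed` when `NULL`).
#' @param seed Integer seed.
#' @return List with `iv_aif`, `iv_vof`, `lv` (`curve_classifier`s).
#' @export
train_validity_models <- function(training = NULL, seed = 1L) {
  if (is.null(training)) training <- synthesize_training_curves(seed = seed)
  sel_a <- training$kind == "AIF"
  sel_v <- training$kind == "VOF"
  # LV training uses the clean (valid) curves of both kinds
  sel_clean <- training$labels
  list(
    iv_aif = train_iv(training$curves[sel_a], training$labels[sel_a],
                      kind = "AIF", seed = seed),
    iv_vof = train_iv(training$curves[sel_v], training$labels[sel_v],
                      kind = "VOF", seed = seed),
    lv = train_lv(training$curves[sel_clean], training$is_vof[sel_clean],
                  seed = seed)
  )
}

#' Run the full CTP pipeline
#'
#' Orchestrates: optional motion correction, grid-search ROI correction of
#' each landmark, curve extraction, rule-based + learned AIF/VOF pair
#' selection, deconvolution maps, and the volume report. When pair
#' selection fails, the report carries the `"invalid curve"` warning and no
#' volumes — a valid result, not an error.
#'
#' @param series A [ctp_series()].
#' @param landmarks List of 8 [landmark()]s (5 AIF + 3 VOF), e.g. from a
#'   detector, a JSON sidecar, or [heuristic_localize()].
#' @param mask Optional 3D logical brain mask (default: all voxels).
#' @param config A [ctp_config()].
#' @param models Validity models from [train_validity_models()]; trained on
#'   the fly (configured seed) when `NULL` and the config enables them.
#' @return A list: `report` (a `volume_report`), `maps` (or `NULL` on
#'   warning), `pair`, `landmarks` (corrected), `manifest` (stages run,
#'   seeds, thresholds).
#' @export
run_ctp_pipeline <- function(series, landmarks, mask = NULL,
                             config = ctp_config(), models = NULL) {
  stopifnot(inherits(series, "ctp_series"))
  if (length(landmarks) != 8L) stop("expected 8 landmarks (5 AIF + 3 VOF)")
  kinds <- vapply(landmarks, `[[`, character(1), "kind")
  if (sum(kinds == "AIF") != 5L || sum(kinds == "VOF") != 3L) {
    stop("expected 5 AIF and 3 VOF landmarks")
  }
  d <- dim(series$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])

  if (isTRUE(config$prep$motion_correct)) {
    series <- motion_correct(series, config$prep$reference_frame,
                             config$prep$max_shift)
  }

  corrected <- if (config$roi$radius > 0) {
    lapply(landmarks, function(l) {
      correct_roi(series, l, radius = config$roi$radius,
                  metric = config$roi$metric,
                  extraction_radius = config$roi$extraction_radius,
                  baseline_frames = config$roi$baseline_frames)
    })
  } else {
    landmarks
  }

  curves <- lapply(corrected, function(l) {
    extract_curve(series, l, radius = config$roi$extraction_radius,
                  baseline_frames = config$roi$baseline_frames)
  })
  aif_curves <- curves[kinds == "AIF"]
  vof_curves <- curves[kinds == "VOF"]

  use_iv <- isTRUE(config$validity$use_iv)
  use_lv <- isTRUE(config$validity$use_lv)
  if (is.null(models) && (use_iv || use_lv)) {
    models <- train_validity_models(seed = config$seed)
  }
  rules <- config_rules(config)
  pair <- select_pair(aif_curves, vof_curves,
                      iv_aif = if (use_iv) models$iv_aif,
                      iv_vof = if (use_iv) models$iv_vof,
                      lv = if (use_lv) models$lv,
                      rules = rules)

  manifest <- list(
    stages = c(
      motion_correct = isTRUE(config$prep$motion_correct),
      roi_correction = config$roi$radius > 0,
      iv_model = use_iv, lv_model = use_lv
    ),
    seed = config$seed,
    deconv = config$deconv,
    quant = config$quant[c("rcbf_threshold", "tmax_threshold", "reference")]
  )

  lm_df <- landmarks_to_df(corrected)
  if (pair$status == "warning") {
    report <- make_report(NULL, pair,
                          rcbf_threshold = config$quant$rcbf_threshold,
                          tmax_threshold = config$quant$tmax_threshold,
                          reference = config$quant$reference,
                          landmarks = lm_df)
    return(list(report = report, maps = NULL, pair = pair,
                landmarks = corrected, manifest = manifest))
  }

  aif_enh <- with_baseline_subtracted(pair$aif)
  maps <- make_maps(series, aif_enh, mask = mask,
                    mode = config$deconv$mode,
                    truncation_fraction = config$deconv$truncation_fraction,
                    baseline_frames = config$roi$baseline_frames)
  report <- make_report(maps, pair,
                        rcbf_threshold = config$quant$rcbf_threshold,
                        tmax_threshold = config$quant$tmax_threshold,
                        reference = config$quant$reference,
                        reference_value = config$quant$reference_value,
                        landmarks = lm_df)
  list(report = report, maps = maps, pair = pair, landmarks = corrected,
       manifest = manifest)
}

# subtract the pre-contrast baseline so the curve is pure enhancement
with_baseline_subtracted <- function(curve) {
  intensity_curve(curve$values - curve_baseline(curve), curve$dt,
                  curve$baseline_frames)
}
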