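#' Curve feature extraction
#'
#' Summarizes an intensity curve by the quantities the validity rules and
#' classifiers operate on.
#'
#' @param curve An `intensity_curve`.
#' @param prominence_frac Fraction of the peak enhancement a local maximum
#'   must protrude to count as a peak (default 0.1).
#' @param decay_window Window after the peak, in seconds, over which the
#'   decay fraction is measured (default 15). When the window overruns the
#'   acquisition, the last frame is used — a curve cut off mid-bolus thus
#'   shows little decay.
#' @return A `curve_features` list: `baseline` (HU), `peak_enhancement`
#'   (HU above baseline), `time_to_peak` (s), `fwhm` (s), `n_peaks`,
#'   `decay_fraction` in `[0, 1]`, `auc` (HU * s).
#' @export
featurize <- function(curve, prominence_frac = 0.1, decay_window = 15) {
  stopifnot(inherits(curve, "intensity_curve"))
  v <- curve$values
  t <- curve_times(curve)
  base <- curve_baseline(curve)
  e <- v - base
  peak_i <- which.max(e)
  enh <- max(e[peak_i], 0)
  ttp <- t[peak_i]
  fwhm <- curve_fwhm(e, t, peak_i)
  npk <- if (enh <= 0) 0L else count_peaks(e, prominence_frac * enh)
  decay <- if (enh <= 0) 0 else {
    j <- min(peak_i + as.integer(round(decay_window / curve$dt)), length(v))
    max(0, min(1, (e[peak_i] - e[j]) / enh))
  }
  structure(list(
    baseline = base, peak_enhancement = enh, time_to_peak = ttp,
    fwhm = fwhm, n_peaks = npk, decay_fraction = decay,
    auc = curve_auc(curve)
  ), class = "curve_features")
}

#' @export
as.data.frame.curve_features <- function(x, ...) {
  as.data.frame(unclass(x))
}

# full width at half maximum with linear interpolation at the crossings;
# edges that never cross half-height extend to the curve ends
curve_fwhm <- function(e, t, peak_i) {
  h <- e[peak_i] / 2
  if (e[peak_i] <= 0) return(0)
  left <- t[1]
  if (peak_i > 1) {
    for (i in peak_i:2) {
      if (e[i - 1] <= h && e[i] > h) {
        left <- t[i - 1] + (t[i] - t[i - 1]) * (h - e[i - 1]) / (e[i] - e[i - 1])
        break
      }
    }
  }
  n <- length(e)
  right <- t[n]
  if (peak_i < n) {
    for (i in peak_i:(n - 1)) {
      if (e[i] > h && e[i + 1] <= h) {
        right <- t[i] + (t[i + 1] - t[i]) * (e[i] - h) / (e[i] - e[i + 1])
        break
      }
    }
  }
  right - left
}

# local maxima whose prominence (height above the higher of the two
# bounding valleys toward taller terrain) reaches the floor
count_peaks <- function(e, floor_prom) {
  n <- length(e)
  if (n < 3L) return(0L)
  cand <- which(diff(sign(diff(e))) < 0) + 1L
  # plateau peaks: strict rise before, strict fall after a run of equals
  if (length(cand) == 0L && e[1] < max(e)) cand <- which.max(e)
  count <- 0L
  for (p in cand) {
    # walk left/right to the nearest strictly higher sample (or the ends)
    lmin <- e[p]
    i <- p
    while (i > 1L && e[i - 1L] <= e[p]) {
      i <- i - 1L
      lmin <- min(lmin, e[i])
    }
    left_base <- if (i == 1L && e[i] <= e[p]) min(lmin, e[1]) else lmin
    rmin <- e[p]
    i <- p
    while (i < n && e[i + 1L] <= e[p]) {
      i <- i + 1L
      rmin <- min(rmin, e[i])
    }
    right_base <- if (i == n && e[i] <= e[p]) min(rmin, e[n]) else rmin
    prom <- e[p] - max(left_base, right_base)
    # the global maximum's prominence is its height over the lower side
    if (e[p] >= max(e)) prom <- e[p] - min(left_base, right_base)
    if (prom >= floor_prom) count <- count + 1L
  }
  count
}

#' Validity rule thresholds
#'
#' The quantified defaults behind the qualitative rule set: peak enhancement
#' above 80 HU, a single sharp peak, fast post-peak decay, an early arterial
#' peak, and a 3–12 s venous-minus-arterial peak delay for a pair. Any
#' scalar rule can be disabled by setting it to `NA`.
#'
#' @param peak_hu Minimum peak value in HU (default 80).
#' @param peak_mode `"enhancement"` (peak above baseline, default) or
#'   `"absolute"` (raw HU).
#' @param fwhm_max Named numeric `c(AIF = 12, VOF = 20)` seconds.
#' @param decay_min Minimum decay fraction within `decay_window` (default
#'   0.4).
#' @param decay_window Seconds after the peak for the decay rule (default 15).
#' @param early_fraction AIF must peak within this fraction of the scan
#'   duration (default 2/3).
#' @param prominence_frac Peak-counting prominence floor as a fraction of
#'   the peak enhancement (default 0.1).
#' @param pair_delay Allowed VOF-minus-AIF peak delay window in seconds
#'   (default `c(3, 12)`).
#' @return A `validity_rules` list.
#' @export
validity_rules <- function(peak_hu = 80, peak_mode = "enhancement",
                           fwhm_max = c(AIF = 12, VOF = 20),
                           decay_min = 0.4, decay_window = 15,
                           early_fraction = 2 / 3, prominence_frac = 0.1,
                           pair_delay = c(3, 12)) {
  structure(list(peak_hu = peak_hu, peak_mode = peak_mode,
                 fwhm_max = fwhm_max, decay_min = decay_min,
                 decay_window = decay_window, early_fraction = early_fraction,
                 prominence_frac = prominence_frac, pair_delay = pair_delay),
            class = "validity_rules")
}

#' Rule-based curve validity check
#'
#' Applies, in order: the peak rule (enhancement > 80 HU), the single-peak
#' rule, the sharpness rule (FWHM cap, kind-specific), the decay rule, and —
#' for AIF curves — the early-peak rule. All failures are reported, not just
#' the first.
#'
#' @param curve An `intensity_curve`.
#' @param kind `"AIF"` or `"VOF"`.
#' @param rules A [validity_rules()] object.
#' @return A `validity_result`: `valid` (logical), `failed_rules`
#'   (character), `features` (`curve_features`).
#' @export
rule_check <- function(curve, kind = c("AIF", "VOF"), rules = validity_rules()) {
  kind <- match.arg(kind)
  prom <- if (is.na(rules$prominence_frac)) 0.1 else rules$prominence_frac
  f <- featurize(curve, prominence_frac = prom,
                 decay_window = rules$decay_window)
  failed <- character(0)
  peak_val <- if (identical(rules$peak_mode, "absolute")) {
    f$baseline + f$peak_enhancement
  } else {
    f$peak_enhancement
  }
  if (!is.na(rules$peak_hu) && !(peak_val > rules$peak_hu)) {
    failed <- c(failed, "peak")
  }
  if (!is.na(rules$prominence_frac) && f$n_peaks != 1L &&
      f$peak_enhancement > 0) {
    failed <- c(failed, "single_peak")
  }
  if (f$peak_enhancement <= 0) failed <- unique(c(failed, "peak", "single_peak"))
  fmax <- rules$fwhm_max[[kind]]
  if (!is.na(fmax) && f$fwhm > fmax) failed <- c(failed, "sharpness")
  if (!is.na(rules$decay_min) && f$decay_fraction < rules$decay_min) {
    failed <- c(failed, "decay")
  }
  if (kind == "AIF" && !is.na(rules$early_fraction)) {
    duration <- (length(curve$values) - 1L) * curve$dt
    if (f$time_to_peak > rules$early_fraction * duration) {
      failed <- c(failed, "early_peak")
    }
  }
  structure(list(valid = length(failed) == 0L, failed_rules = failed,
                 features = f),
            class = "validity_result")
}

#' @export
print.validity_result <- function(x, ...) {
  if (x$valid) cat("<validity_result> valid\n")
  else cat("<validity_result> invalid:", paste(x$failed_rules, collapse = ", "), "\n")
  invisible(x)
}

# feature matrix for the classifiers; fixed column contract
classifier_features <- c("baseline", "peak_enhancement", "time_to_peak",
                         "fwhm", "n_peaks", "decay_fraction", "auc")

feature_matrix <- function(curves) {
  rows <- lapply(curves, function(cv) {
    f <- featurize(cv)
    vapply(classifier_features, function(nm) as.numeric(f[[nm]]), numeric(1))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- classifier_features
  m
}

# content-derived seed so augmentation noise follows a curve, not its
# position in the training list (training is then order-invariant)
curve_content_seed <- function(curve, seed) {
  h <- sum(abs(curve$values) * seq_along(curve$values))
  (as.integer(seed) + (floor(h * 97) %% 1000003L)) %% .Machine$integer.max
}

augment_curves <- function(curves, sigma, n_augment, seed) {
  if (n_augment <= 0L || sigma <= 0) return(list())
  out <- list()
  for (cv in curves) {
    s <- curve_content_seed(cv, seed)
    aug <- withr_seed(s, lapply(seq_len(n_augment), function(k) {
      intensity_curve(cv$values + stats::rnorm(length(cv$values), 0, sigma),
                      cv$dt, cv$baseline_frames)
    }))
    out <- c(out, aug)
  }
  out
}

new_curve_classifier <- function(role, engine, fit, extra = list()) {
  structure(c(list(role = role, engine = engine, fit = fit,
                   features = classifier_features), extra),
            class = "curve_classifier")
}

#' @export
print.curve_classifier <- function(x, ...) {
  cat(sprintf("<curve_classifier> role %s (%s), %d features\n",
              x$role, x$engine, length(x$features)))
  invisible(x)
}

#' Train an intensity-validity (IV) classifier
#'
#' Fits a gradient-boosted binary classifier (one per curve kind) on curve
#' features of the originals plus Gaussian-noise-augmented copies. The
#' augmentation emulates the jagged / multi-peak curves caused by patient
#' motion. Training is deterministic given the seed and invariant to the
#' order of the input curves.
#'
#' @param curves List of `intensity_curve`s (all the same length).
#' @param labels Logical vector of validity labels, one per curve.
#' @param kind `"AIF"` or `"VOF"` — the model is kind-specific.
#' @param augment_sigma Noise SD in HU for augmentation (default 5).
#' @param n_augment Augmented copies per curve (default 2).
#' @param seed Integer seed.
#' @param nrounds Boosting rounds (default 50).
#' @param params Extra xgboost parameters merged over the defaults.
#' @return A `curve_classifier` with role `IV_AIF` or `IV_VOF`.
#' @export
train_iv <- function(curves, labels, kind = c("AIF", "VOF"),
                     augment_sigma = 5, n_augment = 2L, seed = 1L,
                     nrounds = 50L, params = list()) {
  kind <- match.arg(kind)
  labels <- as.logical(labels)
  if (length(curves) != length(labels)) stop("one label per curve required")
  if (length(unique(labels)) < 2L) {
    stop("training error: labels contain a single class")
  }
  lens <- vapply(curves, length, integer(1))
  if (length(unique(lens)) != 1L) stop("all curves must have the same length")
  aug <- augment_curves(curves, augment_sigma, n_augment, seed)
  aug_labels <- rep(labels, each = max(n_augment, 0L) * (augment_sigma > 0))
  x <- feature_matrix(c(curves, aug))
  y <- as.numeric(c(labels, aug_labels))
  ord <- do.call(order, c(as.data.frame(x), list(y)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  p <- utils::modifyList(list(objective = "binary:logistic", max_depth = 3,
                              eta = 0.3, nthread = 1, seed = as.integer(seed)),
                         params)
  fit <- xgboost::xgb.train(params = p,
                            data = xgboost::xgb.DMatrix(x, label = y),
                            nrounds = nrounds, verbose = 0)
  new_curve_classifier(paste0("IV_", kind), "xgboost", fit,
                       extra = list(seed = as.integer(seed)))
}

#' Predict curve validity with an IV model
#'
#' @param model A `curve_classifier` with an `IV_*` role.
#' @param curve An `intensity_curve`.
#' @param kind Optional kind cross-checked against the model role.
#' @return List with `probability` in `[0, 1]` and `valid`
#'   (probability >= 0.5).
#' @export
iv_predict <- function(model, curve, kind = NULL) {
  stopifnot(inherits(model, "curve_classifier"))
  if (!startsWith(model$role, "IV_")) stop("model role is not IV")
  if (!is.null(kind) && !identical(paste0("IV_", kind), model$role)) {
    stop("usage error: model role ", model$role, " does not match kind ", kind)
  }
  x <- feature_matrix(list(curve))
  prob <- as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(x)))
  list(probability = prob, valid = prob >= 0.5)
}

#' Train a landmark-validity (LV) classifier
#'
#' A feed-forward network (single hidden layer) deciding whether a curve is
#' venous: veins peak later and higher than arteries, so `time_to_peak` and
#' `peak_enhancement` carry most of the signal. Features are standardized
#' internally; training is deterministic given the seed and order-invariant.
#'
#' @param curves List of `intensity_curve`s.
#' @param is_vof_labels Logical vector, `TRUE` for venous curves.
#' @param seed Integer seed.
#' @param size Hidden units (default 4).
#' @param maxit Optimizer iterations (default 300).
#' @return A `curve_classifier` with role `LV`.
#' @export
train_lv <- function(curves, is_vof_labels, seed = 1L, size = 4L, maxit = 300L) {
  labels <- as.logical(is_vof_labels)
  if (length(curves) != length(labels)) stop("one label per curve required")
  if (length(unique(labels)) < 2L) {
    stop("training error: labels contain a single class")
  }
  x <- feature_matrix(curves)
  y <- as.numeric(labels)
  ord <- do.call(order, c(as.data.frame(x), list(y)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, `/`)
  fit <- withr_seed(seed, nnet::nnet(xs, y, size = size, maxit = maxit,
                                     decay = 1e-3, trace = FALSE))
  new_curve_classifier("LV", "nnet", fit,
                       extra = list(center = center, scale = scale_,
                                    seed = as.integer(seed)))
}

#' Predict venous vs arterial with the LV model
#'
#' @param model A `curve_classifier` with role `LV`.
#' @param curve An `intensity_curve`.
#' @return List with `probability` (of being a VOF) and `is_vof`
#'   (probability >= 0.5).
#' @export
lv_predict <- function(model, curve) {
  stopifnot(inherits(model, "curve_classifier"))
  if (model$role != "LV") stop("usage error: model role is not LV")
  x <- feature_matrix(list(curve))
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
  prob <- as.numeric(stats::predict(model$fit, xs))
  prob <- max(0, min(1, prob))
  list(probability = prob, is_vof = prob >= 0.5)
}

#' Select the final AIF/VOF pair
#'
#' Filters the 5 arterial and 3 venous candidate curves through the rule
#' check, the IV classifiers, and the LV classifier (arterial candidates
#' must classify as non-venous and vice versa — this is what prevents
#' VOF-with-VOF or AIF-with-AIF pairs), then requires the venous peak to lag
#' the arterial peak by 3–12 s. Among admissible cross pairs, arterial
#' candidates are ranked by earlier peak then higher enhancement, venous by
#' higher enhancement. When no admissible pair survives, an
#' `"invalid curve"` warning state is returned instead of a pair — a result,
#' not an error.
#'
#' @param aif_cands List of 5 arterial candidate curves.
#' @param vof_cands List of 3 venous candidate curves.
#' @param iv_aif,iv_vof Optional IV `curve_classifier`s (skipped if `NULL`,
#'   e.g. in ablations).
#' @param lv Optional LV `curve_classifier` (skipped if `NULL`).
#' @param rules A [validity_rules()] object.
#' @return A `pair_selection` list: `status` (`"ok"` or `"warning"`),
#'   `warning` (`"invalid curve"` or `NULL`), `aif_index`, `vof_index`,
#'   `aif`, `vof`, and a per-candidate `detail` data.frame.
#' @export
select_pair <- function(aif_cands, vof_cands, iv_aif = NULL, iv_vof = NULL,
                        lv = NULL, rules = validity_rules()) {
  if (length(aif_cands) != 5L || length(vof_cands) != 3L) {
    stop("expected 5 AIF and 3 VOF candidate curves")
  }
  assess <- function(curve, kind) {
    rc <- rule_check(curve, kind, rules)
    ivp <- if (kind == "AIF" && !is.null(iv_aif)) iv_predict(iv_aif, curve)$valid
           else if (kind == "VOF" && !is.null(iv_vof)) iv_predict(iv_vof, curve)$valid
           else NA
    lvp <- if (!is.null(lv)) lv_predict(lv, curve)$is_vof else NA
    pass <- rc$valid &&
      (is.na(ivp) || ivp) &&
      (is.na(lvp) || (kind == "VOF") == lvp)
    list(pass = pass, rc = rc, iv = ivp, lv = lvp,
         ttp = rc$features$time_to_peak, enh = rc$features$peak_enhancement)
  }
  a <- lapply(aif_cands, assess, kind = "AIF")
  v <- lapply(vof_cands, assess, kind = "VOF")
  detail <- data.frame(
    candidate = c(paste0("AIF_", 0:4), paste0("VOF_", 0:2)),
    pass = c(vapply(a, `[[`, logical(1), "pass"),
             vapply(v, `[[`, logical(1), "pass")),
    time_to_peak = c(vapply(a, `[[`, numeric(1), "ttp"),
                     vapply(v, `[[`, numeric(1), "ttp")),
    peak_enhancement = c(vapply(a, `[[`, numeric(1), "enh"),
                         vapply(v, `[[`, numeric(1), "enh")),
    stringsAsFactors = FALSE
  )
  ai <- which(vapply(a, `[[`, logical(1), "pass"))
  vi <- which(vapply(v, `[[`, logical(1), "pass"))
  if (length(ai) > 0L && length(vi) > 0L) {
    ai <- ai[order(vapply(a[ai], `[[`, numeric(1), "ttp"),
                   -vapply(a[ai], `[[`, numeric(1), "enh"))]
    vi <- vi[order(-vapply(v[vi], `[[`, numeric(1), "enh"))]
    for (i in ai) {
      for (j in vi) {
        delay <- v[[j]]$ttp - a[[i]]$ttp
        if (delay >= rules$pair_delay[1] && delay <= rules$pair_delay[2]) {
          return(structure(list(status = "ok", warning = NULL,
                                aif_index = i, vof_index = j,
                                aif = aif_cands[[i]], vof = vof_cands[[j]],
                                peak_delay = delay, detail = detail),
                           class = "pair_selection"))
        }
      }
    }
  }
  structure(list(status = "warning", warning = "invalid curve",
                 aif_index = NA_integer_, vof_index = NA_integer_,
                 aif = NULL, vof = NULL, peak_delay = NA_real_,
                 detail = detail),
            class = "pair_selection")
}

#' @export
print.pair_selection <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<pair_selection> AIF_%d + VOF_%d (peak delay %.1f s)\n",
                x$aif_index - 1L, x$vof_index - 1L, x$peak_delay))
  } else {
    cat("<pair_selection> warning:", x$warning, "\n")
  }
  invisible(x)
}
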