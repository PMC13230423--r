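#' Intensity curve (time-attenuation curve)
#'
#' Container for a single voxel's (or small ROI's) contrast time course: HU
#' values sampled at a fixed frame interval. Carries the frame interval `dt`
#' and the number of pre-contrast baseline frames used for baseline
#' subtraction throughout the package.
#'
#' @param values Numeric vector of HU values, one per frame (length >= 2).
#' @param dt Frame interval in seconds (> 0).
#' @param baseline_frames Number of leading pre-contrast frames
#'   (1 <= baseline_frames < length(values)). Default 4, about 6 s at the
#'   1.5 s frame interval of a standard stroke CTP protocol.
#' @return An object of class `intensity_curve`.
#' @export
intensity_curve <- function(values, dt, baseline_frames = 4L) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("intensity curve needs at least 2 frames")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number of seconds")
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 1L || baseline_frames >= length(values)) {
    stop("baseline_frames must lie in [1, length(values) - 1]")
  }
  structure(
    list(values = values, dt = dt, baseline_frames = baseline_frames),
    class = "intensity_curve"
  )
}

#' @export
print.intensity_curve <- function(x, ...) {
  cat(sprintf(
    "<intensity_curve> %d frames @ %.3g s (baseline %d frames), peak %.1f HU\n",
    length(x$values), x$dt, x$baseline_frames, max(x$values)
  ))
  invisible(x)
}

#' @export
length.intensity_curve <- function(x) length(x$values)

#' @export
as.data.frame.intensity_curve <- function(x, ...) {
  data.frame(
    frame = seq_along(x$values) - 1L,
    time_s = (seq_along(x$values) - 1L) * x$dt,
    hu = x$values
  )
}

#' Curve time axis
#' @param curve An `intensity_curve`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
curve_times <- function(curve) (seq_along(curve$values) - 1L) * curve$dt

#' Baseline level of a curve
#'
#' Mean HU over the leading pre-contrast frames.
#'
#' @param curve An `intensity_curve`.
#' @return Baseline HU (scalar).
#' @export
curve_baseline <- function(curve) mean(curve$values[seq_len(curve$baseline_frames)])

#' Gamma-variate bolus parameters
#'
#' The standard parametric form for a first-pass contrast bolus:
#' `c(t) = amplitude * ((t - t0)/(alpha*beta))^alpha * exp(alpha - (t - t0)/beta)`
#' for `t > t0`, zero before onset. Normalised so the peak value equals
#' `amplitude`, reached at `t0 + alpha*beta`.
#'
#' @param amplitude Peak enhancement in HU (>= 0).
#' @param t0 Bolus onset time in seconds (>= 0).
#' @param alpha Shape parameter (> 0).
#' @param beta Time scale in seconds (> 0).
#' @return A `bolus_params` list.
#' @export
bolus_params <- function(amplitude = 150, t0 = 6, alpha = 2, beta = 1.5) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (t0 < 0) stop("t0 must be >= 0")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  structure(list(amplitude = amplitude, t0 = t0, alpha = alpha, beta = beta),
            class = "bolus_params")
}

#' Sample a gamma-variate bolus curve
#'
#' @param params A [bolus_params()] object.
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame interval in seconds (> 0).
#' @param baseline_frames Baseline frames recorded on the returned curve.
#' @return An `intensity_curve` of length `n_frames`; zero before onset,
#'   single-peaked, non-negative.
#' @export
make_bolus_curve <- function(params, n_frames = 30L, dt = 1.5,
                             baseline_frames = 4L) {
  if (!inherits(params, "bolus_params")) stop("params must be a bolus_params object")
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  t <- (seq_len(n_frames) - 1L) * dt
  values <- gamma_variate(t, params)
  intensity_curve(values, dt, baseline_frames = baseline_frames)
}

# gamma-variate sampled at arbitrary times; vectorised, zero for t <= t0
gamma_variate <- function(t, params) {
  y <- numeric(length(t))
  s <- t > params$t0
  tau <- t[s] - params$t0
  y[s] <- params$amplitude *
    (tau / (params$alpha * params$beta))^params$alpha *
    exp(params$alpha - tau / params$beta)
  y
}

#' Tissue class specification
#'
#' Perfusion state of a tissue compartment: flow (CBF, arbitrary internal
#' flow units), mean transit time (seconds) and bolus-arrival delay relative
#' to the arterial input (seconds). Blood volume follows from the central
#' volume theorem, CBV = CBF * MTT.
#'
#' @param name Class label, e.g. "normal", "core", "penumbra".
#' @param cbf Cerebral blood flow (> 0), arbitrary units.
#' @param mtt Mean transit time in seconds (> 0).
#' @param delay Arrival delay in seconds (>= 0).
#' @return A `tissue_class` list with the derived `cbv` field.
#' @export
tissue_class <- function(name, cbf, mtt, delay = 0) {
  if (cbf <= 0) stop("cbf must be > 0")
  if (mtt <= 0) stop("mtt must be > 0")
  if (delay < 0) stop("delay must be >= 0")
  structure(list(name = name, cbf = cbf, mtt = mtt, delay = delay,
                 cbv = cbf * mtt),
            class = "tissue_class")
}

# residue function: fraction of tracer still present t seconds after an
# impulse input. Mono-exponential by default; box-car alternative retained
# for sensitivity checks.
residue_function <- function(t, mtt, shape = c("exponential", "boxcar")) {
  shape <- match.arg(shape)
  out <- numeric(length(t))
  nonneg <- t >= 0
  if (shape == "exponential") {
    out[nonneg] <- exp(-t[nonneg] / mtt)
  } else {
    out[nonneg & t < mtt] <- 1
  }
  out
}

#' Forward-model a tissue curve from an AIF
#'
#' Discrete convolution forward model: the tissue enhancement is
#' `dt * CBF * sum_i AIF(t_i) Fr(t_j - t_i)` with residue
#' `Fr(t) = exp(-t / MTT)`, the AIF shifted by the class delay (rounded to
#' whole frames).
#'
#' @param aif An `intensity_curve` holding the arterial input (baseline-free,
#'   i.e. enhancement above baseline).
#' @param cls A [tissue_class()].
#' @param residue_shape `"exponential"` (default) or `"boxcar"`.
#' @return An `intensity_curve` of the same length and `dt` as `aif`.
#' @export
make_tissue_curve <- function(aif, cls, residue_shape = "exponential") {
  if (!inherits(aif, "intensity_curve")) stop("aif must be an intensity_curve")
  if (!inherits(cls, "tissue_class")) stop("cls must be a tissue_class")
  n <- length(aif$values)
  dt <- aif$dt
  d_frames <- as.integer(round(cls$delay / dt))
  a <- if (d_frames > 0) c(rep(0, d_frames), aif$values)[seq_len(n)] else aif$values
  fr <- residue_function((seq_len(n) - 1L) * dt, cls$mtt, residue_shape)
  # causal discrete convolution, truncated to the acquisition window
  v <- numeric(n)
  for (j in seq_len(n)) {
    v[j] <- dt * cls$cbf * sum(a[seq_len(j)] * fr[j:1])
  }
  intensity_curve(v, dt, baseline_frames = aif$baseline_frames)
}

#' Corrupt an intensity curve
#'
#' Emulates the failure modes seen in clinical acquisitions: additive noise
#' (`gaussian`), a spurious second bolus (`multi_peak`), high-frequency
#' shaking (`jagged`), bad bolus timing where the curve has not returned
#' toward baseline by the last frame (`truncated_bolus`), and an off-vessel
#' near-constant trace (`flat`).
#'
#' @param curve An `intensity_curve`.
#' @param mode One of `"gaussian"`, `"multi_peak"`, `"jagged"`,
#'   `"truncated_bolus"`, `"flat"`.
#' @param severity Mode-dependent scale: noise SD in HU for `gaussian` /
#'   `jagged`, relative bump height for `multi_peak` (default gives a bump at
#'   60% of the original peak), ignored for `flat`.
#' @param seed Integer seed for the modes that draw random numbers.
#' @return A corrupted `intensity_curve` of the same length.
#' @export
corrupt_curve <- function(curve, mode, severity = NULL, seed = 1L) {
  if (!inherits(curve, "intensity_curve")) stop("curve must be an intensity_curve")
  modes <- c("gaussian", "multi_peak", "jagged", "truncated_bolus", "flat")
  if (!mode %in% modes) {
    stop("unknown corruption mode '", mode, "'; must be one of ",
         paste(modes, collapse = ", "))
  }
  v <- curve$values
  n <- length(v)
  t <- curve_times(curve)
  base <- curve_baseline(curve)
  enh <- max(v) - base
  out <- switch(mode,
    gaussian = {
      if (is.null(severity)) severity <- 2
      withr_seed(seed, v + stats::rnorm(n, 0, severity))
    },
    multi_peak = {
      if (is.null(severity)) severity <- 0.6
      # second bump placed well after the main peak, same gamma shape
      t_peak <- t[which.max(v)]
      bump <- bolus_params(amplitude = max(severity * enh, 1),
                           t0 = min(t_peak + 4.5, t[n] - 6),
                           alpha = 2, beta = 1.2)
      v + gamma_variate(t, bump)
    },
    jagged = {
      if (is.null(severity)) severity <- 15
      withr_seed(seed, {
        noise <- stats::rnorm(n, 0, severity)
        v + noise * rep_len(c(1, -1), n)  # alternating sign -> shaking HU
      })
    },
    truncated_bolus = {
      # shift the onset late so the tail is cut by the acquisition window
      shift <- max(1L, as.integer(round((t[n] - t[which.max(v)]) / curve$dt)) - 1L)
      c(rep(base, shift), v)[seq_len(n)]
    },
    flat = {
      if (is.null(severity)) severity <- 0.5
      withr_seed(seed, rep(base, n) + stats::rnorm(n, 0, severity))
    }
  )
  intensity_curve(out, curve$dt, baseline_frames = curve$baseline_frames)
}

# run expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}
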