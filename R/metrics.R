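#' Euclidean landmark distance
#'
#' Distance between two landmarks in millimetres over spacing-scaled voxel
#' coordinates. `mode = "2d"` uses the in-plane axes only; `"3d"` (default,
#' appropriate for anisotropic voxels) includes the slice axis.
#'
#' @param p,q [landmark()]s or integer voxel triples on the same grid.
#' @param spacing Voxel spacing in mm.
#' @param mode `"3d"` (default) or `"2d"`.
#' @return Distance in mm.
#' @export
euclidean_distance <- function(p, q, spacing = c(1, 1, 1), mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  pi_ <- if (inherits(p, "landmark")) p$index else as.numeric(p)
  qi <- if (inherits(q, "landmark")) q$index else as.numeric(q)
  delta <- (pi_ - qi) * spacing
  if (mode == "2d") delta <- delta[1:2]
  sqrt(sum(delta^2))
}

# CCC with Lin's population (1/n) moments; degenerate cases resolved for
# bootstrap use: identical sequences -> 1, constant-but-unequal -> 0
ccc_value <- function(x, y, denom = c("population", "sample")) {
  denom <- match.arg(denom)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  f <- if (denom == "population") (n - 1) / n else 1
  vx <- stats::var(x) * f
  vy <- stats::var(y) * f
  sxy <- stats::cov(x, y) * f
  if (vx == 0 && vy == 0) return(if (mx == my) 1 else 0)
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements: penalizes both decorrelation and
#' location/scale bias. `CCC = 2 * PCC * sx * sy / (sx^2 + sy^2 +
#' (mean_x - mean_y)^2)`, with population (1/n) moments by Lin's convention
#' (`denom = "sample"` switches to 1/(n-1); the two differ only when the
#' means differ).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param denom `"population"` (default) or `"sample"` moment denominators.
#' @return An `agreement_stats` list: `ccc`, `pcc`, `mean_x`, `mean_y`,
#'   `sd_x`, `sd_y`, `n` (and `ci_low` / `ci_high` once
#'   [bootstrap_ccc()] has been applied).
#' @export
ccc <- function(x, y, denom = "population") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("usage error: x and y lengths differ")
  if (length(x) < 2L) stop("need at least 2 pairs")
  constant_x <- stats::sd(x) == 0
  constant_y <- stats::sd(y) == 0
  if (constant_x && constant_y && !all(x == y)) {
    stop("undefined CCC: both sequences constant and unequal")
  }
  val <- ccc_value(x, y, denom)
  n <- length(x)
  f <- if (denom == "population") sqrt((n - 1) / n) else 1
  pcc <- if (constant_x || constant_y) {
    if (all(x == y)) 1 else NA_real_
  } else {
    stats::cor(x, y)
  }
  structure(list(ccc = val, pcc = pcc,
                 mean_x = mean(x), mean_y = mean(y),
                 sd_x = stats::sd(x) * f, sd_y = stats::sd(y) * f,
                 n = n, ci_low = NA_real_, ci_high = NA_real_,
                 denom = denom),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> CCC %.4f (PCC %.4f, n %d)", x$ccc, x$pcc, x$n))
  if (!is.na(x$ci_low)) cat(sprintf(", 95%% CI [%.4f, %.4f]", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.agreement_stats <- function(x, ...) {
  data.frame(ccc = x$ccc, pcc = x$pcc, mean_x = x$mean_x, mean_y = x$mean_y,
             sd_x = x$sd_x, sd_y = x$sd_y, n = x$n,
             ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Percentile bootstrap interval for the CCC
#'
#' Resamples pairs with replacement and returns the 2.5 / 97.5 percentile
#' bounds over `n_boot` replicates. Deterministic given the seed.
#'
#' @param x,y Paired numeric vectors.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param denom Moment convention, see [ccc()].
#' @return An `agreement_stats` object with `ci_low` / `ci_high` filled in.
#' @export
bootstrap_ccc <- function(x, y, n_boot = 1000L, seed = 1L,
                          denom = "population") {
  stats_obj <- ccc(x, y, denom)
  n <- length(x)
  boots <- withr_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    ccc_value(x[i], y[i], denom)
  }, numeric(1)))
  qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
  stats_obj$ci_low <- qs[1]
  stats_obj$ci_high <- qs[2]
  stats_obj
}

#' Warning accuracy
#'
#' Fraction of issued warnings that were correct:
#' `correct / (correct + incorrect)`.
#'
#' @param correct Number of correct warnings (issued on truly inadequate
#'   inputs).
#' @param incorrect Number of incorrect warnings.
#' @return Accuracy in `[0, 1]`.
#' @export
warning_accuracy <- function(correct, incorrect) {
  if (correct < 0 || incorrect < 0) stop("counts must be non-negative")
  total <- correct + incorrect
  if (total == 0) stop("undefined accuracy: no warnings tallied")
  correct / total
}

#' Mean absolute error
#'
#' @param y Ground-truth values.
#' @param yhat Predicted values (same length).
#' @return Mean of `|y - yhat|`, in the units of `y`.
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("usage error: lengths differ")
  if (length(y) < 1L) stop("need at least one pair")
  mean(abs(y - yhat))
}

#' Two-proportion z-test statistic
#'
#' Pooled-variance z statistic for comparing two binomial proportions:
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with pooled
#' `p = (k1 + k2) / (n1 + n2)`. No continuity correction (matches the
#' chi-square relation `z^2 = X^2`).
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return The z statistic (signed: positive when group 1's proportion is
#'   larger).
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("trial counts must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("counts out of range")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) stop("undefined z: pooled proportion is 0 or 1")
  (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}

#' Log-odds contrast of two proportions
#'
#' The 2 x 2 log odds-ratio `ln(k1/(n1-k1)) - ln(k2/(n2-k2))` — the
#' logistic-regression coefficient of a group indicator, and the contrast a
#' GEE logistic model with method as the sole predictor reduces to.
#'
#' @inheritParams two_proportion_ztest
#' @return Log odds-ratio (no continuity correction).
#' @export
logodds_contrast <- function(k1, n1, k2, n2) {
  cells <- c(k1, n1 - k1, k2, n2 - k2)
  if (any(cells <= 0)) stop("undefined log-odds: zero cell in the 2 x 2 table")
  log(k1 / (n1 - k1)) - log(k2 / (n2 - k2))
}
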