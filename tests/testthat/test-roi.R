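test_that("curve extraction reads the planted vessel curve and respects radius", {
  ph <- build_phantom(small_phantom_spec(noise_sigma = 0))
  lm <- landmarks_from_df(ph$truth$landmarks)[[1]]
  cv <- extract_curve(ph$series, lm, radius = 0)
  expect_length(cv$values, 30)
  expect_equal(cv$values, ph$truth$aif_curve$values + 40, tolerance = 1e-12)
  # constant region: any radius gives the same curve
  s <- ctp_series(array(rep(c(5, 9), each = 6 * 6 * 4), c(6, 6, 4, 2)), dt = 1)
  c0 <- extract_curve(s, c(3, 3, 2), radius = 0, baseline_frames = 1)
  c1 <- extract_curve(s, c(3, 3, 2), radius = 1.5, baseline_frames = 1)
  expect_equal(c0$values, c1$values)
  expect_error(extract_curve(s, c(9, 1, 1)), "outside")
})

test_that("baseline-subtracted AUC matches hand and quadrature oracles", {
  # hand trapezoid: [0, 0, 10, 0, 0], dt = 1, baseline 2 frames -> 10
  cv <- intensity_curve(c(0, 0, 10, 0, 0), dt = 1, baseline_frames = 2)
  expect_equal(curve_auc(cv), 10)
  # constant curve -> 0
  expect_equal(curve_auc(intensity_curve(rep(7, 10), 1.5)), 0)
  # trapezoid vs dense rectangle rule on the analytic bolus
  p <- bolus_params(150, 6, 2, 1.5)
  cv2 <- make_bolus_curve(p, n_frames = 400, dt = 0.15)
  dense <- oracle_auc_dense(function(tt) ctperf:::gamma_variate(tt, p),
                            t_max = 399 * 0.15)
  expect_equal(curve_auc(cv2), dense, tolerance = 1e-4)
})

test_that("grid-search correction finds the displaced vessel and is conservative", {
  ph <- build_phantom(small_phantom_spec(noise_sigma = 0))
  truth_lm <- ph$truth$landmarks[1, ]
  true_index <- as.integer(c(truth_lm$x, truth_lm$y, truth_lm$z))
  # displace by (0, 1, 2): off the vessel, onto flat-ish tissue
  displaced <- landmark("AIF_0", true_index + c(0, 1, -2))
  corrected <- correct_roi(ph$series, displaced, radius = 8)
  got <- extract_curve(ph$series, corrected)
  want <- curve_auc(extract_curve(ph$series, landmark("AIF_0", true_index)))
  expect_equal(curve_auc(got), want, tolerance = 1e-9)
  # exhaustive oracle over the ball agrees on the achieved AUC
  d <- dim(ph$series$data)
  best <- -Inf
  for (dx in -8:8) for (dy in -8:8) for (dz in -8:8) {
    if (dx^2 + dy^2 + dz^2 > 64) next
    p <- displaced$index + c(dx, dy, dz)
    if (any(p < 1) || any(p > d[1:3])) next
    best <- max(best, curve_auc(extract_curve(ph$series, p)))
  }
  expect_equal(curve_auc(got), best, tolerance = 1e-9)
  # radius 0 is the identity
  same <- correct_roi(ph$series, displaced, radius = 0)
  expect_identical(same$index, displaced$index)
  # already-optimal voxel stays put
  stay <- correct_roi(ph$series, landmark("AIF_0", true_index), radius = 3)
  expect_identical(stay$index, true_index)
})

test_that("correction never lowers AUC, stays in the ball, improves with radius", {
  ph <- build_phantom(small_phantom_spec(noise_sigma = 2, seed = 5))
  start <- landmark("VOF_0", c(16, 17, 3))
  auc0 <- curve_auc(extract_curve(ph$series, start))
  prev <- -Inf
  for (r in c(0, 2, 4, 8)) {
    cor_lm <- correct_roi(ph$series, start, radius = r)
    auc_r <- curve_auc(extract_curve(ph$series, cor_lm))
    expect_gte(auc_r, auc0)
    expect_gte(auc_r + 1e-9, prev)
    expect_lte(sqrt(sum((cor_lm$index - start$index)^2)), r + 1e-9)
    expect_identical(cor_lm$name, "VOF_0")
    prev <- auc_r
  }
})

test_that("heuristic localization lands on the vessels with the 5 + 3 contract", {
  # realistic noise level: a noiseless phantom has degenerate (tied)
  # time-to-peak values across tissue, which no scanner produces
  ph <- build_phantom(small_phantom_spec(noise_sigma = 2))
  mask <- array(TRUE, dim(ph$series$data)[1:3])
  lms <- heuristic_localize(ph$series, mask)
  expect_length(lms, 8)
  kinds <- vapply(lms, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "AIF"), 5L)
  expect_identical(sum(kinds == "VOF"), 3L)
  # top candidates sit on (or adjacent to) the true vessel voxels
  aif0 <- lms[[1]]$index
  vof0 <- lms[[6]]$index
  expect_true(ph$truth$masks$vessel_aif[aif0[1], aif0[2], aif0[3]])
  expect_true(ph$truth$masks$vessel_vof[vof0[1], vof0[2], vof0[3]])
  # empty mask errors
  expect_error(heuristic_localize(ph$series, array(FALSE, dim(ph$series$data)[1:3])),
               "localization error")
})

test_that("landmark naming and JSON round trip are stable", {
  expect_error(landmark("AIF_7", c(1, 1, 1)), "name")
  lms <- landmarks_from_df(data.frame(
    name = c(paste0("AIF_", 0:4), paste0("VOF_", 0:2)),
    x = 1:8, y = 2:9, z = rep(1:2, 4)
  ))
  path <- tempfile(fileext = ".json")
  write_landmarks(lms, path)
  back <- read_landmarks(path)
  expect_identical(landmarks_to_df(back), landmarks_to_df(lms))
})
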