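test_that("featurize matches hand-computed values on a triangular curve", {
  cv <- intensity_curve(c(0, 0, 50, 100, 50, 0, 0), dt = 1, baseline_frames = 2)
  f <- featurize(cv)
  expect_equal(f$baseline, 0)
  expect_equal(f$peak_enhancement, 100)
  expect_equal(f$time_to_peak, 3)
  expect_equal(f$fwhm, 2)  # linear interpolation at half height 50
  expect_equal(f$n_peaks, 1L)
})

test_that("featurize handles flat and analytic curves", {
  flat <- intensity_curve(rep(40, 30), dt = 1.5)
  f <- featurize(flat)
  expect_equal(f$peak_enhancement, 0)
  expect_equal(f$n_peaks, 0L)
  expect_equal(f$decay_fraction, 0)
  # gamma-variate peaks at the sample nearest t0 + alpha*beta
  cv <- test_aif()
  expect_equal(featurize(cv)$time_to_peak, 9)
  expect_gt(featurize(cv)$decay_fraction, 0.9)
})

test_that("peak counting respects the prominence floor", {
  # two clear humps
  two <- intensity_curve(c(0, 0, 10, 60, 10, 0, 50, 5, 0, 0), dt = 1,
                         baseline_frames = 2)
  expect_equal(featurize(two)$n_peaks, 2L)
  # a wiggle below 10% of the peak does not count
  wiggle <- intensity_curve(c(0, 0, 10, 100, 12, 14, 12, 5, 0, 0), dt = 1,
                            baseline_frames = 2)
  expect_equal(featurize(wiggle)$n_peaks, 1L)
})

test_that("rule check enforces the 80 HU threshold and reports all failures", {
  # clean arterial curve passes every rule
  expect_true(rule_check(test_aif(), "AIF")$valid)
  # 50 HU enhancement fails the peak rule
  weak <- make_bolus_curve(bolus_params(50, 6, 2, 1.5), 30, 1.5)
  rc <- rule_check(weak, "AIF")
  expect_false(rc$valid)
  expect_true("peak" %in% rc$failed_rules)
  # multi-peak corruption fails the single-peak rule
  mp <- corrupt_curve(test_aif(), "multi_peak")
  expect_true("single_peak" %in% rule_check(mp, "AIF")$failed_rules)
  # truncated bolus fails the decay rule
  tb <- corrupt_curve(test_aif(), "truncated_bolus")
  expect_true("decay" %in% rule_check(tb, "AIF")$failed_rules)
  # a weak jagged curve reports multiple failures at once
  bad <- corrupt_curve(weak, "jagged", severity = 20, seed = 2)
  expect_gt(length(rule_check(bad, "AIF")$failed_rules), 1L)
})

test_that("with every threshold disabled, only flat curves are rejected", {
  off <- validity_rules(peak_hu = NA, fwhm_max = c(AIF = NA, VOF = NA),
                        decay_min = NA, early_fraction = NA,
                        prominence_frac = NA)
  set.seed(42)
  for (k in 1:20) {
    cv <- make_bolus_curve(bolus_params(runif(1, 5, 300), runif(1, 0, 20),
                                        2, runif(1, 0.8, 3)), 30, 1.5)
    cv <- corrupt_curve(cv, sample(c("gaussian", "multi_peak", "jagged",
                                     "truncated_bolus"), 1), seed = k)
    if (featurize(cv)$peak_enhancement > 0) {
      expect_true(rule_check(cv, "AIF", off)$valid)
    }
  }
  flat <- intensity_curve(rep(40, 30), 1.5)
  expect_false(rule_check(flat, "AIF", off)$valid)
})

test_that("IV classifiers separate clean from corrupted curves", {
  tr <- synthesize_training_curves(n_per_class = 100, seed = 3)
  sel <- tr$kind == "AIF"
  curves <- tr$curves[sel]
  labels <- tr$labels[sel]
  set.seed(33)
  idx_test <- sort(sample(seq_along(curves), length(curves) %/% 4))
  model <- train_iv(curves[-idx_test], labels[-idx_test], kind = "AIF",
                    seed = 3)
  pred <- vapply(curves[idx_test],
                 function(cv) iv_predict(model, cv)$valid, logical(1))
  truth <- labels[idx_test]
  bal_acc <- mean(c(mean(pred[truth]), mean(!pred[!truth])))
  expect_gte(bal_acc, 0.9)
  # probabilities stay in [0, 1]
  probs <- vapply(curves[idx_test],
                  function(cv) iv_predict(model, cv)$probability, numeric(1))
  expect_true(all(probs >= 0 & probs <= 1))
  # flat curve is rejected
  expect_false(iv_predict(model, intensity_curve(rep(40, 30), 1.5))$valid)
})

test_that("IV training is deterministic and order-invariant", {
  tr <- synthesize_training_curves(n_per_class = 40, seed = 5)
  sel <- tr$kind == "VOF"
  curves <- tr$curves[sel]
  labels <- tr$labels[sel]
  probe <- curves[1:10]
  m1 <- train_iv(curves, labels, kind = "VOF", seed = 9)
  m2 <- train_iv(curves, labels, kind = "VOF", seed = 9)
  perm <- sample(seq_along(curves))
  m3 <- train_iv(curves[perm], labels[perm], kind = "VOF", seed = 9)
  p1 <- vapply(probe, function(cv) iv_predict(m1, cv)$probability, numeric(1))
  p2 <- vapply(probe, function(cv) iv_predict(m2, cv)$probability, numeric(1))
  p3 <- vapply(probe, function(cv) iv_predict(m3, cv)$probability, numeric(1))
  expect_identical(p1, p2)
  expect_equal(p1, p3, tolerance = 1e-12)
  # degenerate labels and role mismatches error
  expect_error(train_iv(curves, rep(TRUE, length(curves)), kind = "VOF"),
               "single class")
  expect_error(iv_predict(m1, probe[[1]], kind = "AIF"), "usage error")
})

test_that("LV model tells veins from arteries", {
  tr <- synthesize_training_curves(n_per_class = 100, seed = 7)
  sel <- tr$labels  # clean curves only
  curves <- tr$curves[sel]
  is_vof <- tr$is_vof[sel]
  set.seed(71)
  idx_test <- sort(sample(seq_along(curves), length(curves) %/% 4))
  model <- train_lv(curves[-idx_test], is_vof[-idx_test], seed = 7)
  pred <- vapply(curves[idx_test],
                 function(cv) lv_predict(model, cv)$is_vof, logical(1))
  truth <- is_vof[idx_test]
  bal_acc <- mean(c(mean(pred[truth]), mean(!pred[!truth])))
  expect_gte(bal_acc, 0.9)
  # the phantom's own vessel curves are classified correctly
  ph <- build_phantom(small_phantom_spec(noise_sigma = 0))
  aif_shift <- ph$truth$aif_curve
  aif_shift$values <- aif_shift$values + 40
  vof_shift <- ph$truth$vof_curve
  vof_shift$values <- vof_shift$values + 40
  expect_false(lv_predict(model, aif_shift)$is_vof)
  expect_true(lv_predict(model, vof_shift)$is_vof)
  # deterministic
  expect_identical(lv_predict(model, aif_shift)$probability,
                   lv_predict(model, aif_shift)$probability)
})

test_that("pair selection returns the planted pair on a clean phantom", {
  ph <- build_phantom(small_phantom_spec(noise_sigma = 0))
  lms <- landmarks_from_df(ph$truth$landmarks)
  curves <- lapply(lms, function(l) extract_curve(ph$series, l))
  models <- train_validity_models(seed = 1)
  pair <- select_pair(curves[1:5], curves[6:8],
                      models$iv_aif, models$iv_vof, models$lv)
  expect_identical(pair$status, "ok")
  expect_equal(pair$peak_delay, 6)  # venous peak trails by 4.5 s delay + dispersion
  expect_gte(pair$peak_delay, 3)
  expect_lte(pair$peak_delay, 12)
})

test_that("pair selection warns on flat candidates and on zero peak delay", {
  models <- train_validity_models(seed = 1)
  flats <- lapply(1:8, function(i) intensity_curve(rep(40, 30), 1.5))
  w <- select_pair(flats[1:5], flats[6:8],
                   models$iv_aif, models$iv_vof, models$lv)
  expect_identical(w$status, "warning")
  expect_identical(w$warning, "invalid curve")
  # two arterial-shaped populations (0 s delay) cannot form a pair even
  # without the classifiers: the 3-12 s delay window rejects them
  aifish <- lapply(1:8, function(i) {
    cv <- test_aif()
    cv$values <- cv$values + 40
    cv
  })
  w2 <- select_pair(aifish[1:5], aifish[6:8], NULL, NULL, NULL)
  expect_identical(w2$status, "warning")
})

test_that("selected pairs always respect the delay window", {
  # property: whatever the inputs, a returned pair never violates 3-12 s
  set.seed(31)
  models <- NULL
  for (k in 1:10) {
    cands <- lapply(1:8, function(i) {
      cv <- make_bolus_curve(bolus_params(runif(1, 60, 300),
                                          runif(1, 2, 20), 2,
                                          runif(1, 1, 2.5)), 30, 1.5)
      cv$values <- cv$values + 40
      corrupt_curve(cv, "gaussian", severity = 2, seed = k * 10 + i)
    })
    res <- select_pair(cands[1:5], cands[6:8], NULL, NULL, NULL)
    if (res$status == "ok") {
      expect_gte(res$peak_delay, 3)
      expect_lte(res$peak_delay, 12)
      f_a <- featurize(res$aif)
      f_v <- featurize(res$vof)
      expect_gt(f_v$time_to_peak, f_a$time_to_peak)
    }
  }
})

test_that("classifier artifacts survive a save/load round trip", {
  tr <- synthesize_training_curves(n_per_class = 30, seed = 13)
  sel <- tr$kind == "AIF"
  iv <- train_iv(tr$curves[sel], tr$labels[sel], kind = "AIF", seed = 13)
  lv <- train_lv(tr$curves[tr$labels], tr$is_vof[tr$labels], seed = 13)
  probe <- tr$curves[seq(1, 40, by = 3)]
  p_iv <- tempfile(fileext = ".json")
  p_lv <- tempfile(fileext = ".json")
  save_classifier(iv, p_iv)
  save_classifier(lv, p_lv)
  iv2 <- load_classifier(p_iv)
  lv2 <- load_classifier(p_lv)
  for (cv in probe) {
    expect_equal(iv_predict(iv2, cv)$probability,
                 iv_predict(iv, cv)$probability, tolerance = 1e-6)
    expect_equal(lv_predict(lv2, cv)$probability,
                 lv_predict(lv, cv)$probability, tolerance = 1e-6)
  }
})
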