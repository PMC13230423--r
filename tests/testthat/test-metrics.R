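test_that("landmark distance handles spacing and 2d/3d modes", {
  expect_equal(euclidean_distance(c(3, 3, 2), c(3, 3, 2), c(1, 1, 4)), 0)
  # 3-4-5 triangle in plane: identical in both modes
  p <- c(4, 5, 2); q <- c(1, 1, 2)
  expect_equal(euclidean_distance(p, q, c(1, 1, 4), "2d"), 5)
  expect_equal(euclidean_distance(p, q, c(1, 1, 4), "3d"), 5)
  # one-slice offset: invisible in 2d, 4 mm in 3d
  expect_equal(euclidean_distance(c(1, 1, 2), c(1, 1, 1), c(1, 1, 4), "2d"), 0)
  expect_equal(euclidean_distance(c(1, 1, 2), c(1, 1, 1), c(1, 1, 4), "3d"), 4)
  # works on landmark objects
  expect_equal(euclidean_distance(landmark("AIF_0", c(4, 5, 2)),
                                  landmark("AIF_1", c(1, 1, 2)),
                                  c(1, 1, 4)), 5)
})

test_that("concordance correlation matches hand and closed-form cases", {
  x <- c(1, 5, 3, 8, 2, 9, 4)
  expect_equal(ccc(x, x)$ccc, 1)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1))$ccc, -1)
  # constant shift: ccc = sigma^2 / (sigma^2 + c^2 / 2) with 1/n moments
  shift <- 2.5
  s2 <- mean((x - mean(x))^2)
  expect_equal(ccc(x, x + shift)$ccc, 2 * s2 / (2 * s2 + shift^2),
               tolerance = 1e-12)
  # errors
  expect_error(ccc(1:3, 1:4), "usage error")
  expect_error(ccc(c(2, 2, 2), c(3, 3, 3)), "undefined")
})

test_that("ccc equals the direct formula and is symmetric on random inputs", {
  set.seed(17)
  for (k in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n, 50, 20)
    y <- 0.8 * x + rnorm(n, 5, 10)
    got <- ccc(x, y)
    expect_equal(got$ccc, oracle_ccc(x, y), tolerance = 1e-12)
    expect_equal(got$ccc, ccc(y, x)$ccc, tolerance = 1e-12)
    expect_lte(abs(got$ccc), abs(got$pcc) + 1e-12)
    # invariant under a common permutation of the pairs
    perm <- sample(n)
    expect_equal(ccc(x[perm], y[perm])$ccc, got$ccc, tolerance = 1e-12)
  }
})

test_that("bootstrap CI is reproducible, degenerate at identity, and covers", {
  x <- c(3, 9, 14, 22, 31, 40, 44, 52)
  b1 <- bootstrap_ccc(x, x, n_boot = 200, seed = 4)
  expect_equal(c(b1$ci_low, b1$ci_high), c(1, 1))
  y <- x + rnorm(8, 0, 4)
  b2 <- bootstrap_ccc(x, y, n_boot = 500, seed = 9)
  b3 <- bootstrap_ccc(x, y, n_boot = 500, seed = 9)
  expect_identical(c(b2$ci_low, b2$ci_high), c(b3$ci_low, b3$ci_high))
  expect_lte(b2$ci_low, b2$ccc)
  expect_gte(b2$ci_high, b2$ccc)
  # coverage on a generator with known concordance: x and y exchangeable
  # bivariate normal with correlation rho and equal moments -> CCC = rho
  rho <- 0.8
  n <- 100
  hits <- 0
  set.seed(123)
  for (rep in 1:200) {
    z1 <- rnorm(n); z2 <- rnorm(n)
    x_ <- z1
    y_ <- rho * z1 + sqrt(1 - rho^2) * z2
    ci <- bootstrap_ccc(x_, y_, n_boot = 300, seed = rep)
    if (ci$ci_low <= rho && rho <= ci$ci_high) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
})

test_that("warning accuracy and MAE match hand arithmetic", {
  expect_equal(warning_accuracy(48, 12), 0.80)
  expect_equal(warning_accuracy(37, 23), 37 / 60)
  expect_equal(round(warning_accuracy(37, 23), 2), 0.62)
  expect_equal(warning_accuracy(5, 0), 1)
  expect_error(warning_accuracy(0, 0), "undefined")
  expect_equal(mae(c(1, 2), c(2, 4)), 1.5)
  expect_equal(mae(1:5, 1:5), 0)
  expect_error(mae(1:3, 1:2), "usage error")
  # triangle inequality property
  set.seed(5)
  y <- rnorm(30); yh <- rnorm(30)
  expect_gte(mae(y, yh), abs(mean(y) - mean(yh)))
})

test_that("two-proportion z-test matches the chi-square relation and prop.test", {
  expect_equal(two_proportion_ztest(10, 50, 10, 50), 0)
  z <- two_proportion_ztest(48, 60, 37, 60)
  expect_equal(round(z, 2), 2.21)
  # antisymmetry
  expect_equal(two_proportion_ztest(37, 60, 48, 60), -z)
  # z^2 equals the uncorrected chi-square statistic on random tables
  set.seed(21)
  for (k in 1:20) {
    n1 <- sample(20:80, 1); n2 <- sample(20:80, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    zz <- two_proportion_ztest(k1, n1, k2, n2)
    chi <- suppressWarnings(
      stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$statistic
    )
    expect_equal(zz^2, unname(chi), tolerance = 1e-9)
  }
  expect_error(two_proportion_ztest(0, 10, 0, 10), "undefined")
})

test_that("log-odds contrast equals the 2x2 odds ratio", {
  expect_equal(logodds_contrast(10, 20, 10, 20), 0)
  expect_equal(round(logodds_contrast(48, 60, 37, 60), 3), 0.911)
  expect_equal(exp(logodds_contrast(48, 60, 37, 60)),
               (48 * 23) / (12 * 37), tolerance = 1e-12)
  expect_error(logodds_contrast(60, 60, 37, 60), "undefined")
})
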