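test_that("Toeplitz system matches hand example and brute-force oracle", {
  sys <- build_conv_matrix(c(1, 2, 0), dt = 1)
  expect_identical(sys$A, matrix(c(1, 2, 0, 0, 1, 2, 0, 0, 1), 3, 3))
  # impulse input gives the identity
  expect_identical(build_conv_matrix(c(1, 0, 0, 0), dt = 1)$A, diag(4))
  # strict lower-triangular structure and elementwise oracle, N = 2..30
  set.seed(8)
  for (n in 2:30) {
    a <- runif(n, 0, 100)
    A <- build_conv_matrix(a, dt = 1.5)$A
    expect_identical(A, oracle_toeplitz(a, 1.5))
    expect_true(all(A[upper.tri(A)] == 0))
  }
})

test_that("circulant system matches hand example and brute-force oracle", {
  sys <- build_circulant_matrix(c(1, 2), dt = 1)
  expect_identical(sys$A, matrix(c(1, 2, 0, 0,
                                   0, 1, 2, 0,
                                   0, 0, 1, 2,
                                   2, 0, 0, 1), 4, 4))
  set.seed(9)
  for (n in 2:30) {
    a <- runif(n, 0, 100)
    Abar <- build_circulant_matrix(a, dt = 1.5)$A
    expect_identical(Abar, oracle_circulant(a, 1.5))
    # the top-left N x N block is the Toeplitz matrix
    expect_identical(Abar[1:n, 1:n], oracle_toeplitz(a, 1.5))
    # circulant: all row sums equal
    expect_lt(max(abs(rowSums(Abar) - sum(Abar[1, ]))), 1e-9)
  }
  expect_error(build_circulant_matrix(rep(0, 10), dt = 1.5), "singular")
})

test_that("deconvolution inverts the forward model", {
  aif <- test_aif()
  cls <- tissue_class("t", cbf = 0.01, mtt = 4)
  tissue <- make_tissue_curve(aif, cls)
  # identity system: residue equals the tissue curve
  n <- length(tissue$values)
  ident <- build_conv_matrix(c(1, rep(0, n - 1)), dt = 1)
  r_id <- deconvolve(tissue$values, ident, truncation_fraction = 0)
  expect_equal(r_id$r, tissue$values, tolerance = 1e-9)
  # zero tissue gives a zero residue
  sys <- build_circulant_matrix(aif)
  r0 <- deconvolve(rep(0, n), sys, truncation_fraction = 0)
  expect_true(all(r0$r == 0))
  # round trip: reconvolution reproduces the tissue curve
  r <- deconvolve(tissue, sys, truncation_fraction = 0)
  recon <- as.vector(sys$A %*% r$r)[1:n]
  expect_lt(max(abs(recon - tissue$values)) / max(tissue$values), 1e-6)
})

test_that("perfusion parameters recover the planted physiology", {
  # impulse AIF: exponential tissue, cbf within 2%, mtt within 5%
  n <- 30; dt <- 1.5; cbf <- 0.3; mtt <- 4
  impulse <- intensity_curve(c(1, rep(0, n - 1)), dt)
  tissue <- dt * cbf * exp(-(0:(n - 1)) * dt / mtt)
  sys <- build_conv_matrix(impulse$values / dt, dt = dt)  # identity * dt scaling
  sys2 <- build_conv_matrix(impulse)
  r <- deconvolve(tissue, sys2, truncation_fraction = 0)
  pp <- estimate_params(r, tissue, impulse$values)
  expect_lt(abs(pp$cbf / cbf - 1), 0.02)
  expect_lt(abs(pp$mtt / mtt - 1), 0.05)
  expect_equal(pp$tmax, 0)
  # central volume theorem holds by construction
  expect_equal(pp$cbv, pp$cbf * pp$mtt, tolerance = 1e-9)
  # zero tissue
  pp0 <- estimate_params(deconvolve(rep(0, n), sys2, 0), rep(0, n),
                         impulse$values)
  expect_equal(pp0$cbf, 0)
  expect_equal(pp0$cbv, 0)
})

test_that("planted delay appears as Tmax under bcSVD", {
  aif <- test_aif()
  cls <- tissue_class("t", cbf = 0.01, mtt = 4, delay = 4.5)  # 3 frames
  tissue <- make_tissue_curve(aif, cls)
  sys <- build_circulant_matrix(aif)
  r <- deconvolve(tissue, sys, truncation_fraction = 0)
  pp <- estimate_params(r, tissue, aif)
  expect_lte(abs(pp$tmax - 4.5), 1.5)  # within one frame
  expect_lt(abs(pp$cbf / 0.01 - 1), 0.02)
})

test_that("residue scaling is linear and truncation degrades reconvolution", {
  aif <- test_aif()
  tissue <- make_tissue_curve(aif, tissue_class("t", 0.01, 4))
  sys <- build_circulant_matrix(aif)
  r1 <- deconvolve(tissue$values, sys, 0.05)
  r3 <- deconvolve(3 * tissue$values, sys, 0.05)
  expect_equal(r3$r, 3 * r1$r, tolerance = 1e-9)
  # raising the truncation threshold never improves ||A r - v||
  v <- c(tissue$values, rep(0, length(tissue$values)))
  resid <- vapply(c(0, 0.02, 0.05, 0.1, 0.2), function(tf) {
    r <- deconvolve(tissue$values, sys, tf)
    sqrt(sum((as.vector(sys$A %*% r$r) - v)^2))
  }, numeric(1))
  expect_true(all(diff(resid) >= -1e-9))
})

test_that("voxelwise maps recover the phantom and respect the mask", {
  ph <- build_phantom(small_phantom_spec(noise_sigma = 0))
  aif <- ph$truth$aif_curve
  mask <- !ph$truth$masks$vessel
  maps <- make_maps(ph$series, aif, mask = mask, mode = "bcSVD",
                    truncation_fraction = 0)
  nm <- mask & !(ph$truth$masks$core | ph$truth$masks$penumbra)
  rel_err <- abs(maps$cbf[nm] / ph$truth$cbf[nm] - 1)
  expect_lte(stats::median(rel_err), 0.05)
  # masked-out voxels are zero everywhere
  expect_true(all(maps$cbf[!mask] == 0))
  expect_true(all(maps$tmax[!mask] == 0))
  # sSVD and bcSVD agree on the zero-delay tissue
  maps_s <- make_maps(ph$series, aif, mask = nm, mode = "sSVD",
                      truncation_fraction = 0)
  rel_diff <- abs(maps_s$cbf[nm] - maps$cbf[nm]) /
    pmax(maps$cbf[nm], .Machine$double.eps)
  expect_lte(stats::median(rel_diff), 0.05)
})
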