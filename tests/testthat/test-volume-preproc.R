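test_that("Gaussian volume smoothing matches the closed form and conserves mass", {
  d <- c(41, 41, 41)
  imp <- array(0, d); imp[21, 21, 21] <- 1
  v <- VolumeImage(imp)
  expect_identical(volData(gaussianSmoothVolume(v, fwhm_mm = 0)), imp)
  sigma <- 2
  sm <- gaussianSmoothVolume(v, sigma_mm = sigma)
  # peak of a 3-D Gaussian: (2 pi sigma^2)^(-3/2) * voxel volume
  expect_equal(volData(sm)[21, 21, 21], (2 * pi * sigma^2)^(-3 / 2),
               tolerance = 0.02)
  expect_equal(sum(volData(sm)), 1, tolerance = 1e-3)
  # anisotropic voxels: kernel scaled per axis so smoothing is world-
  # isotropic (profile SD in mm equal along axes)
  aff <- diag(c(1, 2, 1, 1))
  va <- VolumeImage(imp, aff)
  sma <- volData(gaussianSmoothVolume(va, sigma_mm = 4))
  profX <- sma[, 21, 21]
  profY <- sma[21, , 21]
  sdOf <- function(p, spacing) {
    x <- (seq_along(p) - 21) * spacing
    sqrt(sum(p * x^2) / sum(p))
  }
  expect_equal(sdOf(profX, 1), sdOf(profY, 2), tolerance = 0.02)
})

test_that("adaptive brain masking behaves at its edge cases", {
  sc <- fixtureScene()
  m <- brainMask(sc$anatomical)
  truth <- volData(sc$brain_mask_truth) > 0
  got <- volData(m) > 0
  expect_gte(mean(got[truth]), 0.99)
  expect_lte(mean(got[!truth]), 0.01)
  # coefficient 1.0 thresholds at the robust maximum: near-empty mask
  m1 <- brainMask(sc$anatomical, intensity_coefficient = 1.0)
  expect_lt(mean(volData(m1)), 0.001)
  expect_error(brainMask(VolumeImage(array(3, c(5, 5, 5)))),
               "constant")
})

test_that("NCC matches hand computation and detects degeneracy", {
  a <- VolumeImage(array(c(1, 2, 3, 4), c(2, 2, 1)))
  b <- VolumeImage(array(c(2, 2, 4, 4), c(2, 2, 1)))
  expect_equal(ncc(a, a), 1.0)
  expect_equal(ncc(a, VolumeImage(-volData(a) + 7)), -1.0)
  expect_equal(ncc(a, b), 0.8944, tolerance = 1e-4)
  expect_equal(ncc(a, b), ncc(b, a))
  # invariant to affine intensity rescaling
  expect_equal(ncc(VolumeImage(3 * volData(a) - 5), b), ncc(a, b))
  expect_error(ncc(a, VolumeImage(array(1, c(2, 2, 1)))), "variance")
})

test_that("affine resampling is exact on linear fields and guards labels", {
  d <- c(12, 12, 12)
  idx <- zmapsoz:::voxelIndexGrid(d)
  ramp <- array(2 * idx[, 1] + 3 * idx[, 2] - idx[, 3], d)
  v <- VolumeImage(ramp)
  same <- resampleAffine(v, diag(4), v)
  expect_equal(volData(same), ramp, tolerance = 1e-12)
  sameN <- resampleAffine(v, diag(4), v, mode = "nearest")
  expect_identical(volData(sameN), ramp)
  # pure translation of a linear ramp: interior values follow the field
  tr <- affineTransform(translation = c(1.5, 0.5, 0.25))
  shifted <- resampleAffine(v, tr, v)
  inner <- 3:9
  expected <- array(2 * (idx[, 1] + 1.5) + 3 * (idx[, 2] + 0.5) -
                      (idx[, 3] + 0.25), d)
  expect_equal(volData(shifted)[inner, inner, inner],
               expected[inner, inner, inner], tolerance = 1e-10)
  lab <- VolumeImage(array(rep(1:2, 864), d), units = "label")
  expect_error(resampleAffine(lab, diag(4), lab), "nearest")
  expect_silent(resampleAffine(lab, diag(4), lab, mode = "nearest"))
})

test_that("affine parameterization composes and inverts consistently", {
  tr <- affineTransform(translation = c(4, -3, 2),
                        rotation = c(0.1, -0.05, 0.2),
                        scale = c(1.1, 0.9, 1), shear = c(0.05, 0, -0.02))
  M <- tr@matrix
  expect_equal(det(M[1:3, 1:3]), 1.1 * 0.9 * 1, tolerance = 1e-12)
  expect_equal(M[1:3, 4], c(4, -3, 2))
  expect_equal(solve(M) %*% M, diag(4), tolerance = 1e-12)
})

test_that("self-registration recovers the identity with NCC near 1", {
  sc <- fixtureScene()
  reg <- affineRegister(sc$anatomical, sc$anatomical, dof = 6L)
  expect_true(reg$report@passedGate)
  expect_gt(reg$report@finalNCC, 0.999)
  expect_lt(max(abs(reg$transform@parameters[1:3])), 1e-2)
  expect_lt(max(abs(reg$transform@parameters[4:6])), 1e-3)
})

test_that("registration reports, not hides, a failed NCC gate", {
  set.seed(4)
  mk <- function() {
    v <- VolumeImage(array(rnorm(24^3), c(24, 24, 24)),
                     diag(c(4, 4, 4, 1)))
    gaussianSmoothVolume(v, fwhm_mm = 10)
  }
  a <- mk(); b <- mk()    # independent structured noise
  expect_warning(reg <- affineRegister(a, b, dof = 6L,
                                       translation_starts = 2),
                 "gate")
  expect_false(reg$report@passedGate)
  expect_lte(reg$report@finalNCC, 0.85)
})

test_that("van Cittert deconvolution sharpens a matched-PSF blur", {
  sc <- fixtureScene()
  blurred <- sc$pet                  # scene PET carries the 5 mm PSF
  expect_identical(volData(vanCittertPVC(blurred, 5, 1, n_iter = 0)),
                   volData(blurred))
  # vanishing PSF: the operator is the identity at any iteration count
  expect_equal(volData(vanCittertPVC(blurred, 1e-4, 1, n_iter = 5)),
               volData(blurred), tolerance = 1e-12)
  rmse <- function(a, b) sqrt(mean((volData(a) - volData(b))^2))
  corrected <- vanCittertPVC(blurred, 5, 1, 10)
  expect_lt(rmse(corrected, sc$true_activity),
            rmse(blurred, sc$true_activity))
  # residual norm decreases monotonically with matched PSF
  rn <- sapply(c(1, 3, 6, 10), function(k) {
    f <- vanCittertPVC(blurred, 5, 1, k)
    hf <- gaussianSmoothVolume(f, fwhm_mm = 5)
    sqrt(sum((volData(blurred) - volData(hf))^2))
  })
  expect_true(all(diff(rn) < 0))
})

test_that("SUVR conversion is a pure reference-mean rescaling", {
  sc <- fixtureScene()
  s1 <- suvr(sc$pet, sc$cerebellum_mask)
  ref <- volData(sc$cerebellum_mask) > 0
  expect_equal(mean(volData(s1)[ref]), 1.0, tolerance = 1e-12)
  # invariant to global rescaling of the input
  s2 <- suvr(VolumeImage(7.3 * volData(sc$pet), volAffine(sc$pet)),
             sc$cerebellum_mask)
  expect_equal(volData(s2), volData(s1), tolerance = 1e-12)
  # uniform reference value c: output = input / c
  u <- VolumeImage(array(5, c(4, 4, 4)))
  msk <- array(0, c(4, 4, 4)); msk[2, 2, 2] <- 1
  expect_equal(volData(suvr(u, msk)), volData(u) / 5)
  expect_error(suvr(u, array(0, c(4, 4, 4))), "empty")
})
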