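test_that("vol_image and grid_spec validate geometry invariants", {
  expect_error(vol_image(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  bad_orient <- diag(3); bad_orient[1, 1] <- 1.1
  expect_error(vol_image(array(0, c(2, 2, 2)), orientation = bad_orient),
               "orthonormal")
  a <- vol_image(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
  b <- vol_image(array(0, c(4, 4, 4)), spacing = c(1, 1, 1 + 1e-4))
  expect_true(grid_compatible(a, a))
  expect_false(grid_compatible(a, b))
})

test_that("resampling is exact for identity, constant and linear fields", {
  set.seed(11)
  v <- vol_image(array(rnorm(15^3), c(15, 15, 15)), spacing = c(2, 2, 2))
  same <- resample(v, grid_of(v))
  expect_lt(max(abs(same$values - v$values)), 1e-9)

  const <- vol_image(array(7, c(10, 10, 10)), spacing = c(3, 3, 3),
                     modality = "MR")
  tgt <- grid_spec(c(12, 12, 12), c(2, 2, 2), origin = c(2, 2, 2))
  rc <- resample(const, tgt)
  # in-domain voxels (within the source extent 0..27 mm) must all be 7
  in_dom <- rc$values[1:12 <= 12, , ]  # whole target lies inside source
  expect_true(all(abs(in_dom - 7) < 1e-12))

  ramp <- ramp_volume(c(16, 16, 16), c(2, 2, 2), a = 2)
  half <- grid_spec(c(28, 8, 8), c(1, 1, 1), origin = c(1.5, 3, 3))
  rr <- resample(ramp, half)
  expect_lt(max(abs(rr$values[, 1, 1] - 2 * ((0:27) + 1.5))), 1e-6)
})

test_that("out-of-domain voxels receive the modality fill value", {
  v <- vol_image(array(5, c(4, 4, 4)), spacing = c(1, 1, 1))
  far <- grid_spec(c(4, 4, 4), c(1, 1, 1), origin = c(100, 0, 0))
  expect_true(all(resample(v, far)$values == -1000))
  vm <- vol_image(array(5, c(4, 4, 4)), spacing = c(1, 1, 1),
                  modality = "MR")
  expect_true(all(resample(vm, far)$values == 0))
})

test_that("body extraction thresholds, keeps one component and fills holes", {
  empty <- vol_image(array(-1000, c(8, 8, 8)), spacing = c(2, 2, 2))
  expect_error(extract_body_mask(empty), "empty foreground")

  e <- ellipsoid_ct()
  m <- extract_body_mask(e$vol)
  expect_identical(m$values, e$inside)

  # carve an internal air cavity: hole filling must recover it
  withhole <- e$vol
  withhole$values[10:13, 10:13, 10:13] <- -1000
  m2 <- extract_body_mask(withhole)
  expect_identical(m2$values, e$inside)
  # oracle: voxels unreachable from the border are holes by definition
  fg <- withhole$values > -250
  reach <- array(masct:::cpp_border_background(as.logical(fg), dim(fg)),
                 dim(fg))
  expect_identical(m2$values, fg | !reach)
})

test_that("MR body extraction uses an automatic (Otsu) threshold", {
  e <- ellipsoid_ct(hu_in = 300, hu_out = 2)
  mr <- vol_image(e$vol$values, spacing = e$vol$spacing, modality = "MR")
  m <- extract_body_mask(mr)
  expect_identical(m$values, e$inside)
})

test_that("morphology follows the ball structuring-element contracts", {
  e <- ellipsoid_ct()
  m <- bin_mask(e$inside, like = e$vol)
  expect_identical(mask_morphology(m, "dilate", 0)$values, m$values)

  # a convex solid is invariant under closing; opening is anti-extensive
  # and idempotent (discrete ball openings round a cube's corners, so exact
  # cube invariance under close-then-open is not expected)
  cube <- array(FALSE, c(15, 15, 15)); cube[4:12, 4:12, 4:12] <- TRUE
  cm <- bin_mask(cube, spacing = c(1, 1, 1))
  expect_identical(mask_morphology(cm, "close", 2)$values, cube)
  opened <- mask_morphology(cm, "open", 2)
  expect_true(all(cube | !opened$values))
  expect_identical(mask_morphology(opened, "open", 2)$values,
                   opened$values)

  # single voxel dilated by one voxel-spacing: 6-neighbourhood + center,
  # cross-checked by brute-force enumeration of voxels within the radius
  single <- array(FALSE, c(9, 9, 9)); single[5, 5, 5] <- TRUE
  sm <- bin_mask(single, spacing = c(2, 2, 2))
  d1 <- mask_morphology(sm, "dilate", 2)
  brute <- array(FALSE, c(9, 9, 9))
  for (i in 1:9) for (j in 1:9) for (k in 1:9)
    if (sum((2 * (c(i, j, k) - c(5, 5, 5)))^2) <= 4 + 1e-9)
      brute[i, j, k] <- TRUE
  expect_identical(d1$values, brute)

  # set monotonicity
  set.seed(7)
  rnd <- bin_mask(array(runif(12^3) > 0.6, c(12, 12, 12)),
                  spacing = c(1.5, 1.5, 1.5))
  expect_true(all(mask_morphology(rnd, "close", 2)$values | !rnd$values))
  expect_true(all(rnd$values | !mask_morphology(rnd, "open", 2)$values))
})

test_that("NIfTI round-trip preserves values bit-exactly and geometry", {
  set.seed(12)
  orient <- diag(3)[, c(2, 1, 3)]  # permuted axes, still orthonormal
  v <- vol_image(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                 spacing = c(1.25, 2, 0.5), origin = c(-10, 4, 2.5),
                 orientation = orient, modality = "MR")
  f <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(v, f)
  r <- read_nifti_volume(f, "MR")
  expect_identical(r$values, v$values)
  expect_lt(max(abs(r$spacing - v$spacing)), 1e-6)
  expect_lt(max(abs(r$origin - v$origin)), 1e-6)
  expect_lt(max(abs(r$orientation - v$orientation)), 1e-6)

  m <- bin_mask(v$values > 0, like = v)
  fm <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(m, fm)
  rm_ <- read_nifti_mask(fm)
  expect_identical(rm_$values, m$values)
})
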