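test_that("MAE follows its defining arithmetic", {
  ct <- vol_image(array(0, c(6, 6, 6)), spacing = c(2, 2, 2))
  reg <- full_mask(ct)
  expect_equal(mae(ct, ct, reg), 0)
  plus10 <- ct; plus10$values <- ct$values + 10
  expect_equal(mae(ct, plus10, reg), 10)

  ct3 <- vol_image(array(0, c(3, 1, 1)), spacing = c(1, 1, 1))
  ct3$values[] <- c(0, 100, -50)
  s3 <- ct3; s3$values[] <- c(10, 90, -40)
  expect_equal(mae(ct3, s3, full_mask(ct3)), 10)

  empty <- bin_mask(array(FALSE, dim(ct$values)), like = ct)
  expect_error(mae(ct, ct, empty), "empty region")

  # translation equivariance
  set.seed(21)
  a <- vol_image(array(rnorm(6^3), c(6, 6, 6)), spacing = c(2, 2, 2))
  b <- vol_image(array(rnorm(6^3), c(6, 6, 6)), spacing = c(2, 2, 2))
  ac <- a; ac$values <- a$values + 37
  bc <- b; bc$values <- b$values + 37
  expect_equal(mae(a, b, reg), mae(ac, bc, reg))
})

test_that("bone region uses a strict 150 HU threshold with closing and fill", {
  water <- vol_image(array(0, c(10, 10, 10)), spacing = c(2, 2, 2))
  fov <- full_mask(water)
  expect_equal(sum(bone_region(water, fov)$values), 0)

  # voxel exactly at 150 HU is excluded (strict inequality)
  v <- water; v$values[5, 5, 5] <- 150
  expect_equal(sum(bone_region(v, fov)$values), 0)
  v$values[5, 5, 5] <- 150.001
  expect_gte(sum(bone_region(v, fov)$values), 1)

  # cortical cylinder with low-HU marrow core: core included after
  # closing + fill; oracle = border flood fill of the thresholded shell
  shape <- c(20, 20, 12)
  ct <- array(-1000, shape)
  for (i in 1:20) for (j in 1:20) {
    r2 <- (i - 10.5)^2 + (j - 10.5)^2
    if (r2 <= 36) ct[i, j, 3:10] <- if (r2 <= 9) -20 else 900
  }
  ctv <- vol_image(ct, spacing = c(2, 2, 2))
  fov2 <- full_mask(ctv)
  br <- bone_region(ctv, fov2)
  shell <- ct > 150
  reach <- array(masct:::cpp_border_background(as.logical(shell), shape),
                 shape)
  oracle <- shell | !reach
  expect_true(all(br$values[oracle]))  # marrow core recovered
})

test_that("soft-tissue region excludes air and bone, includes water", {
  shape <- c(10, 10, 10)
  ct <- array(0, shape)
  ct[2, 2, 2] <- -1000      # air cavity voxel
  ct[8, 8, 8] <- 900        # bone voxel
  ctv <- vol_image(ct, spacing = c(2, 2, 2))
  fov <- full_mask(ctv)
  bone <- bone_region(ctv, fov, region_thresholds(morph_radius_mm = 0))
  soft <- soft_tissue_region(ctv, fov, bone)
  expect_false(soft$values[2, 2, 2])
  expect_false(soft$values[8, 8, 8])
  expect_true(soft$values[5, 5, 5])
  expect_equal(sum(bone$values & soft$values), 0)
})

test_that("volume index matches its definition and direction convention", {
  g <- grid_spec(c(10, 10, 10), c(10, 10, 10))  # 1 cm^3 voxels
  mk <- function(n) {
    v <- array(FALSE, c(10, 10, 10)); v[seq_len(n)] <- TRUE
    bin_mask(v, spacing = c(10, 10, 10))
  }
  expect_equal(volume_index(mk(50), mk(50)), 1.0)
  expect_equal(volume_index(mk(100), mk(90)), 1.1)   # reference larger
  expect_equal(volume_index(mk(100), mk(120)), 0.8)  # evaluated larger
  expect_error(volume_index(mk(0), mk(10)), "empty reference")
})

test_that("Dice matches its definition, is symmetric, flags good overlap", {
  mk <- function(idx) {
    v <- array(FALSE, c(6, 6, 6)); v[idx] <- TRUE
    bin_mask(v, spacing = c(1, 1, 1))
  }
  a <- mk(1:8); b <- mk(3:10)
  expect_equal(as.numeric(dice(a, a)), 1.0)
  expect_equal(as.numeric(dice(mk(1:4), mk(10:13))), 0.0)
  expect_equal(as.numeric(dice(a, b)), 2 * 6 / 16)  # |A|=|B|=8, overlap 6
  expect_equal(as.numeric(dice(a, b)), as.numeric(dice(b, a)))
  expect_true(attr(dice(a, b), "good_overlap"))
  expect_error(dice(mk(integer(0)), mk(integer(0))), "both masks empty")
})

test_that("bone and soft-tissue regions partition within the FOV", {
  set.seed(22)
  e <- ellipsoid_ct(shape = c(16, 16, 16))
  ct <- e$vol
  ct$values[e$inside] <- ct$values[e$inside] +
    ifelse(runif(sum(e$inside)) < 0.2, 800, 0)
  fov <- full_mask(ct)
  bone <- bone_region(ct, fov)
  soft <- soft_tissue_region(ct, fov, bone)
  expect_equal(sum(bone$values & soft$values), 0)
  expect_true(all(fov$values | !(bone$values | soft$values)))
})
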