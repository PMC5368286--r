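reg_fast <- reg_config(pyramid_levels = 2, max_iterations = 40)

test_that("affine self-registration recovers the identity", {
  ph <- generate_phantom(small_spec(), 51)
  tr <- affine_register(ph$ct, ph$ct, reg_fast)
  expect_lt(max(abs(tr$translation)), 0.5)
  expect_lt(max(abs(tr$matrix - diag(3))), 1e-2)
  expect_error(affine_register(ph$ct,
                               vol_image(array(1, dim(ph$ct$values)),
                                         spacing = ph$ct$spacing)),
               "constant")
})

test_that("affine registration recovers a known shift and scale", {
  ph <- generate_phantom(small_spec(), 52)
  # known (6, -4, 2) mm displacement expressed through the moving image's
  # origin (no resampling, so the ground-truth pose is unambiguous)
  shift <- c(6, -4, 2)
  mov <- vol_image(ph$ct$values, spacing = ph$ct$spacing, origin = -shift)
  tr <- affine_register(ph$ct, mov, reg_config())
  expect_lt(max(abs(tr$translation + shift)), 1)

  # isotropic 1.05 magnification expressed through the moving geometry
  # (same lattice, 5% larger voxels), so the true pose is T(x) = 1.05 x
  mov2 <- vol_image(ph$ct$values, spacing = ph$ct$spacing * 1.05)
  tr2 <- affine_register(ph$ct, mov2, reg_config())
  expect_lt(max(abs(diag(tr2$matrix) - 1.05)), 0.02)
  # the optimum is at least as good as the identity by construction
  expect_gte(attr(tr2, "nmi"),
             masct:::nmi_of_affine(ph$ct, mov2, affine_transform(), 64) -
               1e-9)
})

test_that("NMI is symmetric under intensity inversion up to binning", {
  ph <- generate_phantom(small_spec(), 53)
  a <- ph$mr_channels$T2
  b <- ph$ct
  inv <- b
  inv$values <- max(b$values) - b$values
  expect_equal(nmi(a, b), nmi(a, inv), tolerance = 0.02)
})

test_that("warp matches resample for the identity and shifts ramps exactly", {
  ramp <- ramp_volume(c(16, 16, 16), c(2, 2, 2), a = 2)
  idt <- affine_transform()
  w <- warp(ramp, idt, grid_of(ramp))
  r <- resample(ramp, grid_of(ramp))
  expect_equal(w$values, r$values)

  tr <- affine_transform(diag(3), c(3, 0, 0))
  ws <- warp(ramp, tr, grid_of(ramp))
  # in-domain: f(x + 3) = 2x + 6
  xs <- (0:15) * 2
  ok <- xs + 3 <= 30
  expect_lt(max(abs(ws$values[ok, 1, 1] - (2 * xs[ok] + 6))), 1e-6)

  mask_vol <- vol_image((ramp$values > 10) * 1, spacing = ramp$spacing,
                        modality = "LABEL")
  wn <- warp(mask_vol, tr, grid_of(ramp), "nearest")
  expect_true(all(wn$values %in% c(0, 1)))
})

test_that("field inversion satisfies its composition-residual contract", {
  g <- grid_spec(c(16, 16, 16), c(2, 2, 2))
  zero <- deformation_field(array(0, c(g$shape, 3)), g)
  expect_equal(max(abs(invert_field(zero)$displacement)), 0)

  const <- array(0, c(g$shape, 3)); const[, , , 1] <- 3
  cf <- deformation_field(const, g)
  ci <- invert_field(cf)
  expect_lt(max(abs(ci$displacement[, , , 1] + 3)), 1e-3)
  expect_lt(max(abs(ci$displacement[, , , 2:3])), 1e-3)

  set.seed(54)
  U <- array(0, c(g$shape, 3))
  for (c_ in 1:3) {
    f <- array(rnorm(prod(g$shape)), g$shape)
    f <- array(masct:::cpp_gauss3d(as.numeric(f), g$shape, rep(3, 3)),
               g$shape)
    U[, , , c_] <- 2.5 * f / max(abs(f))
  }
  fld <- deformation_field(U, g)
  inv <- invert_field(fld)
  expect_lt(attr(inv, "residual_mm"), 0.5 * mean(g$spacing))
})

test_that("non-rigid self-registration stays near the identity", {
  ph <- generate_phantom(small_spec(), 55)
  fld <- nonrigid_register(ph$mr_channels$T2, ph$mr_channels$T2,
                           config = reg_fast, mask = ph$masks$body)
  mag <- sqrt(apply(fld$displacement^2, 1:3, sum))
  expect_lt(mean(mag[ph$masks$body$values]), 0.5 * mean(ph$ct$spacing))
})

test_that("a zero-weight channel does not influence the registration", {
  ph <- generate_phantom(small_spec(), 56)
  g <- grid_of(ph$ct)
  U <- array(0, c(g$shape, 3))
  xs <- (seq_len(g$shape[1]) - 1) * g$spacing[1]
  U[, , , 1] <- 3 * sin(2 * pi * xs / max(xs))
  fixed <- warp(ph$mr_channels$T2, deformation_field(U, g), g)
  noise <- vol_image(array(rnorm(prod(g$shape), sd = 50), g$shape),
                     spacing = g$spacing, modality = "MR")
  cfg1 <- reg_config(pyramid_levels = 2, max_iterations = 30,
                     channel_weights = 1)
  cfg2 <- reg_config(pyramid_levels = 2, max_iterations = 30,
                     channel_weights = c(1, 0))
  f1 <- nonrigid_register(fixed, ph$mr_channels$T2, config = cfg1,
                          mask = ph$masks$body)
  f2 <- nonrigid_register(list(fixed, fixed),
                          list(ph$mr_channels$T2, noise), config = cfg2,
                          mask = ph$masks$body)
  dd <- sqrt(apply((f1$displacement - f2$displacement)^2, 1:3, sum))
  expect_lt(mean(dd), 1e-6)
  expect_error(nonrigid_register(list(fixed, fixed),
                                 list(ph$mr_channels$T2)),
               "equal length")
})

test_that("a known smooth warp is recovered within tolerance", {
  ph <- generate_phantom(small_spec(), 57)
  g <- grid_of(ph$ct)
  ext <- (g$shape - 1) * g$spacing
  xs <- (seq_len(g$shape[1]) - 1) * g$spacing[1]
  ys <- (seq_len(g$shape[2]) - 1) * g$spacing[2]
  zs <- (seq_len(g$shape[3]) - 1) * g$spacing[3]
  U <- array(0, c(g$shape, 3))
  U[, , , 1] <- 4 * outer(outer(sin(2 * pi * xs / ext[1]),
                                cos(2 * pi * ys / ext[2])),
                          rep(1, g$shape[3]))
  U[, , , 2] <- 4 * outer(outer(rep(1, g$shape[1]),
                                sin(2 * pi * ys / ext[2])),
                          cos(2 * pi * zs / ext[3]))
  U[, , , 3] <- 2 * outer(outer(cos(2 * pi * xs / ext[1]),
                                rep(1, g$shape[2])),
                          sin(2 * pi * zs / ext[3]))
  fixed <- warp(ph$mr_channels$T2, deformation_field(U, g), g)
  rec <- nonrigid_register(fixed, ph$mr_channels$T2, config = reg_config(),
                           mask = ph$masks$body)
  err <- sqrt(apply((rec$displacement - U)^2, 1:3, sum))
  expect_lt(mean(err[ph$masks$body$values]), 1.5)
})

test_that("affine and deformation-field round-trip through disk", {
  tr <- affine_transform(matrix(c(1.02, 0.01, 0, -0.01, 0.98, 0, 0, 0, 1),
                                3), c(4, -2, 1))
  f <- tempfile(fileext = ".txt")
  write_affine(tr, f)
  tr2 <- read_affine(f)
  expect_equal(tr2$matrix, tr$matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tr2$translation, tr$translation, tolerance = 1e-12)

  g <- grid_spec(c(8, 8, 8), c(2.5, 2.5, 2.5), origin = c(1, 2, 3))
  set.seed(58)
  fld <- deformation_field(array(rnorm(8^3 * 3), c(g$shape, 3)), g, 20)
  fp <- tempfile(fileext = ".nii.gz")
  write_deformation_field(fld, fp)
  fld2 <- read_deformation_field(fp, 20)
  expect_equal(fld2$displacement, fld$displacement, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(grid_compatible(fld2$grid, fld$grid))
})
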