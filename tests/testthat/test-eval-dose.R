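test_that("gamma of identical doses is zero with a 100% pass rate", {
  p <- random_dose_pair(41)
  gm <- gamma_map(p$ref, p$ref, gamma_criteria(3, 3))
  vals <- gm$values[is.finite(gm$values)]
  expect_gt(length(vals), 0)
  expect_lt(max(vals), 1e-9)
  expect_equal(gamma_pass_rate(gm), 100)
})

test_that("uniform field at exactly the dose criterion gives gamma = 1", {
  shape <- c(12, 12, 12)
  ref <- vol_image(array(2, shape), spacing = c(2, 2, 2), modality = "DOSE")
  ev <- vol_image(array(2.06, shape), spacing = c(2, 2, 2),
                  modality = "DOSE")
  gm <- gamma_map(ref, ev, gamma_criteria(3, 3, "local"))
  # no spatial gain on a uniform field: gamma = dose difference / criterion
  inner <- gm$values[4:9, 4:9, 4:9]
  expect_true(all(abs(inner - 1) < 1e-6))
})

test_that("gamma pass rate counts defined passing voxels", {
  p <- random_dose_pair(42)
  gm <- gamma_map(p$ref, p$ref, gamma_criteria(2, 2))
  gm$values[is.finite(gm$values)] <- 1.5
  expect_equal(gamma_pass_rate(gm), 0)
  n <- sum(is.finite(gm$values))
  v <- gm$values
  v[is.finite(v)] <- rep(c(0.5, 2), length.out = n)
  gm$values <- v
  expect_equal(gamma_pass_rate(gm), 100 * sum(v[is.finite(v)] <= 1) / n)
})

test_that("gamma is asymmetric and monotone in the criteria", {
  p <- random_dose_pair(43)
  g_ab <- gamma_map(p$ref, p$eval, gamma_criteria(2, 2))
  g_ba <- gamma_map(p$eval, p$ref, gamma_criteria(2, 2))
  expect_false(isTRUE(all.equal(g_ab$values, g_ba$values)))
  g_loose <- gamma_map(p$ref, p$eval, gamma_criteria(3, 3))
  # loosening the criteria never increases gamma (up to the search
  # discretization, which differs between the two settings)
  def <- is.finite(g_ab$values) & is.finite(g_loose$values)
  expect_true(all(g_loose$values[def] <= g_ab$values[def] + 0.02))
  expect_gte(gamma_pass_rate(g_loose), gamma_pass_rate(g_ab))
})

test_that("gamma map agrees with the exhaustive fine-grid evaluator", {
  p <- random_dose_pair(44)
  for (cr in list(gamma_criteria(3, 3, "local"),
                  gamma_criteria(2, 2, "global"))) {
    gm <- gamma_map(p$ref, p$eval, cr)
    or <- gamma_map_reference(p$ref, p$eval, cr)
    def <- is.finite(gm$values) & is.finite(or$values)
    expect_true(all(def == is.finite(or$values)))
    expect_lt(max(abs(gm$values[def] - or$values[def])), 0.02)
  }
})

test_that("FOV density override assigns water outside FOV and air to missing tissue", {
  shape <- c(10, 10, 10)
  sp <- c(2, 2, 2)
  v <- vol_image(array(100, shape), spacing = sp)
  body <- bin_mask(array(TRUE, shape), spacing = sp)
  fov_all <- bin_mask(array(TRUE, shape), spacing = sp)
  expect_identical(override_outside_fov(v, body, fov_all)$values, v$values)

  fov <- array(TRUE, shape); fov[, , 1:3] <- FALSE
  fovm <- bin_mask(fov, spacing = sp)
  ov <- override_outside_fov(v, body, fovm)
  expect_true(all(ov$values[, , 1:3] == 0))
  expect_true(all(ov$values[, , 4:10] == 100))

  missing <- array(FALSE, shape); missing[, , 1:2] <- TRUE
  ov2 <- override_outside_fov(v, body, fovm, bin_mask(missing, spacing = sp))
  expect_true(all(ov2$values[, , 1:2] == -1000))  # air wins the overlap
  expect_true(all(ov2$values[, , 3] == 0))
})

test_that("cumulative DVH is a correct monotone step/fraction curve", {
  shape <- c(8, 8, 8)
  sp <- c(2, 2, 2)
  st <- bin_mask(array(TRUE, shape), spacing = sp)
  uni <- vol_image(array(5, shape), spacing = sp, modality = "DOSE")
  c1 <- cumulative_dvh(uni, st)
  expect_equal(c1$volume_fraction[c1$dose_gy <= 5][1], 1)
  expect_true(all(c1$volume_fraction[c1$dose_gy > 5] == 0))

  half <- array(1, shape); half[1:4, , ] <- 3
  dv <- vol_image(half, spacing = sp, modality = "DOSE")
  c2 <- cumulative_dvh(dv, st)
  expect_equal(c2$volume_fraction[which.min(abs(c2$dose_gy - 2))], 0.5)

  set.seed(45)
  rv <- vol_image(array(runif(prod(shape)) * 10, shape), spacing = sp,
                  modality = "DOSE")
  c3 <- cumulative_dvh(rv, st)
  expect_true(all(diff(c3$volume_fraction) <= 0))
  expect_equal(c3$volume_fraction[1], 1)
  expect_error(cumulative_dvh(rv, bin_mask(array(FALSE, shape),
                                           spacing = sp)),
               "empty structure")
})

test_that("DVH point metrics follow the percentile convention", {
  shape <- c(10, 10, 1)
  sp <- c(2, 2, 2)
  st <- bin_mask(array(TRUE, shape), spacing = sp)
  uni <- vol_image(array(7, shape), spacing = sp, modality = "DOSE")
  expect_equal(dvh_point(uni, st, "D98"), 7)
  expect_equal(dvh_point(uni, st, "Dmean"), 7)
  expect_equal(dvh_point(uni, st, "D2"), 7)

  seqd <- vol_image(array(1:100, shape), spacing = sp, modality = "DOSE")
  expect_equal(dvh_point(seqd, st, "Dmean"), 50.5)
  # linear-interpolated percentile of 1..100: D2 = 98.02, D98 = 2.98
  expect_equal(dvh_point(seqd, st, "D2"), 98.02)
  expect_equal(dvh_point(seqd, st, "D98"), 2.98)

  # D98 <= Dmean <= D2 on random fields
  set.seed(46)
  for (s in 1:5) {
    rv <- vol_image(array(rexp(100, 0.1), shape), spacing = sp,
                    modality = "DOSE")
    expect_lte(dvh_point(rv, st, "D98"), dvh_point(rv, st, "Dmean"))
    expect_lte(dvh_point(rv, st, "Dmean"), dvh_point(rv, st, "D2"))
  }
})

test_that("PPD is the signed relative difference in percent", {
  expect_equal(ppd(65, 65), 0)
  expect_equal(ppd(65, 64.35), 1.0)
  expect_equal(ppd(65, 66.3), -2.0)
  expect_error(ppd(0, 1), "must be > 0")
})
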