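test_that("MR air segmentation applies the <8 threshold and opening", {
  shape <- c(16, 16, 16)
  body <- bin_mask(array(TRUE, shape), spacing = c(2, 2, 2))
  mr <- vol_image(array(200, shape), spacing = c(2, 2, 2), modality = "MR")
  expect_equal(sum(segment_air_mr(mr, body)$values), 0)

  # cavity of intensity 3 inside body of 200: selected (opening rounds the
  # cavity's corners but keeps its bulk)
  mr2 <- mr
  mr2$values[6:10, 6:10, 6:10] <- 3
  air <- segment_air_mr(mr2, body)
  expect_true(air$values[8, 8, 8])
  expect_true(all(which(air$values) %in%
                    which(array(mr2$values < 8, dim(mr2$values)))))
  expect_gte(sum(air$values), 0.6 * 125)

  # isolated single dark voxel removed by the opening
  mr3 <- mr
  mr3$values[3, 3, 3] <- 0
  expect_equal(sum(segment_air_mr(mr3, body)$values), 0)

  # monotone in the threshold (pre-opening thresholding)
  set.seed(31)
  mr4 <- vol_image(array(runif(prod(shape)) * 20, shape),
                   spacing = c(2, 2, 2), modality = "MR")
  m_lo <- mr4$values < 5 & body$values
  m_hi <- mr4$values < 12 & body$values
  expect_true(all(m_hi | !m_lo))
})

test_that("class map is an exhaustive partition with bone precedence", {
  shape <- c(12, 12, 12)
  sp <- c(2, 2, 2)
  body <- array(FALSE, shape); body[3:10, 3:10, 3:10] <- TRUE
  bone <- array(FALSE, shape); bone[5:7, 5:7, 5:7] <- TRUE
  air <- array(FALSE, shape); air[7:9, 7:9, 7:9] <- TRUE  # overlaps bone
  cm <- assemble_class_map(bin_mask(body, spacing = sp),
                           bin_mask(bone, spacing = sp),
                           bin_mask(air, spacing = sp))
  lab <- cm$values
  counts <- table(factor(lab, levels = 0:3))
  expect_equal(sum(counts), prod(shape))          # partition conserves voxels
  expect_true(all(lab[bone & body] == 2L))        # bone wins overlap
  expect_true(all(lab[!body] == 0L))
  # empty bone and air: body entirely water
  none <- bin_mask(array(FALSE, shape), spacing = sp)
  cm2 <- assemble_class_map(bin_mask(body, spacing = sp), none, none)
  expect_equal(sum(cm2$values == 1L), sum(body))
})

test_that("bulk sCT assigns the site-specific class densities", {
  shape <- c(10, 10, 10)
  sp <- c(2, 2, 2)
  body <- array(FALSE, shape); body[2:9, 2:9, 2:9] <- TRUE
  bone <- array(FALSE, shape); bone[4:6, 4:6, 4:6] <- TRUE
  air <- array(FALSE, shape); air[7:8, 7:8, 7:8] <- TRUE
  none <- bin_mask(array(FALSE, shape), spacing = sp)

  cm_pro <- assemble_class_map(bin_mask(body, spacing = sp),
                               bin_mask(bone, spacing = sp), none)
  pro <- build_bulk_sct(cm_pro, density_table("prostate"))
  expect_setequal(unique(as.numeric(pro$density$values)),
                  c(0.001, 1.00, 1.22))
  expect_true(all(pro$density$values[bone] == 1.22))
  expect_true(all(pro$density$values[body & !bone] == 1.00))

  cm_hn <- assemble_class_map(bin_mask(body, spacing = sp),
                              bin_mask(bone, spacing = sp),
                              bin_mask(air, spacing = sp))
  hn <- build_bulk_sct(cm_hn, density_table("head_neck"))
  expect_setequal(unique(as.numeric(hn$density$values)),
                  c(0.001, 1.00, 1.53))
  expect_true(all(hn$density$values[bone] == 1.53))
  expect_true(all(hn$density$values[air & !bone] == 0.001))
  # at most 4 distinct densities; HU monotone in density
  expect_lte(length(unique(as.numeric(hn$density$values))), 4)
  o <- order(as.numeric(hn$density$values))
  expect_true(!is.unsorted(as.numeric(hn$hu$values)[o]))
  # calibration anchors: water -> 0 HU, air -> -1000 HU
  expect_true(all(hn$hu$values[body & !bone & !air] == 0))
  expect_true(all(hn$hu$values[air & !bone] == -1000))
})

test_that("density-to-HU calibration interpolates through its anchors", {
  expect_equal(density_to_hu(1.0), 0)
  expect_equal(density_to_hu(0.001), -1000)
  # linear between (1.0, 0) and (1.53, 883)
  expect_equal(density_to_hu(1.22), (1.22 - 1) / (1.53 - 1) * 883,
               tolerance = 1e-12)
  expect_warning(density_to_hu(2.5), "clamped")
  expect_error(density_to_hu(-1), "density must be > 0")
  # round trip within the hull
  d <- c(0.2, 0.7, 1.0, 1.3)
  expect_equal(hu_to_density(density_to_hu(d)), d, tolerance = 1e-10)
})
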