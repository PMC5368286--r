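# direct windowed-Pearson LNCC oracle: explicit 3-D window sums with the
# same reflected boundary and Gaussian weights, no separable filtering
lncc_brute <- function(tv, av, sigma_vox) {
  d <- dim(tv)
  r <- max(1, ceiling(3 * sigma_vox))
  off <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  w <- exp(-0.5 * (off$i^2 + off$j^2 + off$k^2) / sigma_vox^2)
  # the separable kernel normalizes per axis; replicate that product
  k1 <- exp(-0.5 * (-r:r)^2 / sigma_vox^2); k1 <- k1 / sum(k1)
  w <- k1[off$i + r + 1] * k1[off$j + r + 1] * k1[off$k + r + 1]
  refl <- function(p, n) {
    p <- ifelse(p < 0, -p - 1, p)
    ifelse(p >= n, 2 * n - p - 1, p)
  }
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    ii <- refl(x - 1 + off$i, d[1]) + 1
    jj <- refl(y - 1 + off$j, d[2]) + 1
    kk <- refl(z - 1 + off$k, d[3]) + 1
    idx <- cbind(ii, jj, kk)
    t_ <- tv[idx]; a_ <- av[idx]
    mt <- sum(w * t_); ma <- sum(w * a_)
    vt <- sum(w * t_^2) - mt^2; va <- sum(w * a_^2) - ma^2
    cv <- sum(w * t_ * a_) - mt * ma
    out[x, y, z] <- if (vt <= 0 || va <= 0) 0 else cv / sqrt(vt * va)
  }
  out
}

test_that("LNCC is 1 for self, -1 for negation, and matches the oracle", {
  set.seed(61)
  v <- vol_image(array(rnorm(16^3), c(16, 16, 16)), spacing = c(2, 2, 2),
                 modality = "MR")
  s_self <- lncc_map(v, v, sigma_mm = 4)
  expect_lt(max(abs(s_self$values - 1)), 1e-6)
  neg <- v; neg$values <- -v$values
  s_neg <- lncc_map(v, neg, sigma_mm = 4)
  expect_lt(max(abs(s_neg$values + 1)), 1e-6)

  a <- vol_image(array(rnorm(16^3), c(16, 16, 16)), spacing = c(2, 2, 2),
                 modality = "MR")
  s <- lncc_map(v, a, sigma_mm = 4)
  brute <- lncc_brute(v$values, a$values, 2)
  expect_lt(max(abs(s$values - pmin(pmax(brute, -1), 1))), 1e-5)
  expect_true(all(abs(s$values) <= 1 + 1e-6))
})

test_that("similarity weights follow the rank-exponential scheme", {
  shp <- c(4, 4, 4)
  mk <- function(x) array(x, shp)
  sims <- list(mk(0.9), mk(0.5), mk(0.1))
  w0 <- weights_from_similarity(sims, beta = 0)
  for (j in 1:3) expect_equal(max(abs(w0$weights[[j]] - 1 / 3)), 0)

  w1 <- weights_from_similarity(sims, top_k = 1)
  expect_true(all(w1$weights[[1]] == 1))
  expect_true(all(w1$weights[[2]] == 0))

  wb <- weights_from_similarity(sims, beta = 1, top_k = 3)
  expected <- exp(-(0:2)) / sum(exp(-(0:2)))
  expect_equal(wb$weights[[1]][1], expected[1], tolerance = 1e-3)
  expect_equal(wb$weights[[2]][1], expected[2], tolerance = 1e-3)
  expect_equal(wb$weights[[3]][1], expected[3], tolerance = 1e-3)
  expect_equal(round(expected, 4), c(0.6652, 0.2447, 0.0900),
               tolerance = 1e-3)

  # ties broken by atlas index, deterministically
  wt <- weights_from_similarity(list(mk(0.5), mk(0.5)), top_k = 1)
  expect_true(all(wt$weights[[1]] == 1))

  # all-NA voxels drop out of the normalization mask
  s_na <- list(mk(NA_real_), mk(NA_real_))
  w_na <- weights_from_similarity(s_na)
  expect_false(any(w_na$norm_mask))
})

test_that("weights always sum to one inside the normalization mask", {
  set.seed(62)
  for (rep in 1:5) {
    J <- sample(2:6, 1)
    sims <- lapply(seq_len(J), function(j) array(runif(5^3), c(5, 5, 5)))
    w <- weights_from_similarity(sims, beta = runif(1, 0, 2),
                                 top_k = sample(J, 1))
    tot <- Reduce(`+`, w$weights)
    expect_lt(max(abs(tot[w$norm_mask] - 1)), 1e-6)
    expect_true(all(vapply(w$weights, function(x) all(x >= 0),
                           logical(1))))
  }
})

test_that("fusion is a convex combination with declared edge cases", {
  shp <- c(5, 5, 5)
  sp <- c(2, 2, 2)
  mkct <- function(x) vol_image(array(x, shp), spacing = sp)
  sims <- list(array(0.8, shp), array(0.2, shp))
  w <- weights_from_similarity(sims)

  same <- fuse_ct(list(mkct(123), mkct(123)), w)
  expect_true(all(same$values == 123))

  w1 <- weights_from_similarity(sims, top_k = 1)
  pick <- fuse_ct(list(mkct(10), mkct(99)), w1)
  expect_true(all(pick$values == 10))

  wu <- weights_from_similarity(list(array(0.5, shp), array(0.5, shp)),
                                beta = 0)
  mid <- fuse_ct(list(mkct(0), mkct(1000)), wu)
  expect_true(all(mid$values == 500))

  expect_error(fuse_ct(list(mkct(0)), w), "count mismatch")

  # convexity on random data
  set.seed(63)
  cts <- lapply(1:3, function(j)
    vol_image(array(rnorm(prod(shp), sd = 300), shp), spacing = sp))
  sims3 <- lapply(1:3, function(j) array(runif(prod(shp)), shp))
  w3 <- weights_from_similarity(sims3, beta = 1)
  fused <- fuse_ct(cts, w3)
  lo <- pmin(cts[[1]]$values, cts[[2]]$values, cts[[3]]$values)
  hi <- pmax(cts[[1]]$values, cts[[2]]$values, cts[[3]]$values)
  expect_true(all(fused$values >= lo - 1e-6 & fused$values <= hi + 1e-6))
})

test_that("atlas-order permutation leaves the fused sCT unchanged", {
  set.seed(64)
  shp <- c(6, 6, 6)
  sp <- c(2, 2, 2)
  cts <- lapply(1:4, function(j)
    vol_image(array(rnorm(prod(shp), 100, 200), shp), spacing = sp))
  sims <- lapply(1:4, function(j) array(runif(prod(shp)), shp))
  perm <- c(3, 1, 4, 2)
  f1 <- fuse_ct(cts, weights_from_similarity(sims, beta = 0.7, top_k = 2))
  f2 <- fuse_ct(cts[perm],
                weights_from_similarity(sims[perm], beta = 0.7, top_k = 2))
  expect_identical(f1$values, f2$values)
})

test_that("a database of perfect atlases reproduces the true CT", {
  ph <- generate_phantom(small_spec(), 65)
  pair <- atlas_pair(ph$mr_channels, ph$ct, "self")
  db <- atlas_database(list(atlas_pair(ph$mr_channels, ph$ct, "a"),
                            atlas_pair(ph$mr_channels, ph$ct, "b"),
                            atlas_pair(ph$mr_channels, ph$ct, "c")))
  cfg <- fusion_config(registration = reg_config(pyramid_levels = 2,
                                                 max_iterations = 30))
  syn <- synthesize(ph$mr_channels, db, cfg, seed = 1,
                    body_mask = ph$masks$body)
  expect_equal(syn$iteration, 0L)
  expect_lt(mae(ph$ct, syn$sct, ph$masks$body), 1)

  ref <- refine(syn, ph$mr_channels, db, n_iter = 1,
                body_mask = ph$masks$body)
  expect_equal(ref$iteration, 1L)
  expect_lt(mae(ph$ct, ref$sct, ph$masks$body), 1)
  expect_error(refine(syn, ph$mr_channels, db, n_iter = 0), "n_iter")
  expect_error(synthesize(ph$mr_channels,
                          atlas_database(list(pair)), cfg),
               ">= 2 atlases")
})

test_that("map_to_ct_space applies the MR-to-CT mapping", {
  ph <- generate_phantom(small_spec(), 66)
  g <- grid_of(ph$ct)
  res <- list(sct = ph$ct)
  class(res) <- "synthesis_result"
  idf <- deformation_field(array(0, c(g$shape, 3)), g)
  out <- map_to_ct_space(res, idf, g)
  expect_equal(out$values, resample(ph$ct, g)$values)

  U <- array(0, c(g$shape, 3)); U[, , , 1] <- 6
  sh <- map_to_ct_space(res, deformation_field(U, g), g)
  direct <- warp(ph$ct, affine_transform(diag(3), c(6, 0, 0)), g)
  expect_lt(max(abs(sh$values - direct$values)), 1e-9)

  # MR -> CT -> MR round trip through a smooth field and its inverse; a
  # band-limited volume isolates the composition residual from the large
  # interpolation error at piecewise-constant tissue edges
  set.seed(67)
  smooth_ct <- array(rnorm(prod(g$shape)), g$shape)
  smooth_ct <- array(masct:::cpp_gauss3d(as.numeric(smooth_ct), g$shape,
                                         rep(3, 3)), g$shape)
  smooth_ct <- vol_image(300 * smooth_ct / max(abs(smooth_ct)),
                         spacing = g$spacing)
  U2 <- array(0, c(g$shape, 3))
  for (c_ in 1:3) {
    f <- array(rnorm(prod(g$shape)), g$shape)
    f <- array(masct:::cpp_gauss3d(as.numeric(f), g$shape, rep(4, 3)),
               g$shape)
    U2[, , , c_] <- 3 * f / max(abs(f))
  }
  fld <- deformation_field(U2, g)
  inv <- invert_field(fld)
  there <- warp(smooth_ct, fld, g)
  back <- warp(there, inv, g)
  core <- mask_morphology(ph$masks$body, "erode",
                          2 * mean(g$spacing))$values
  expect_lt(mae(smooth_ct, back, bin_mask(core, like = smooth_ct)), 2)
})
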