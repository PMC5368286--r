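#' Affine transform in world coordinates
#'
#' Maps a fixed-space world point x to the moving-space sampling point
#' `matrix %*% x + translation` (pull-back convention: warping samples the
#' moving image there).
#'
#' @param matrix invertible 3x3 matrix.
#' @param translation length-3 vector in mm.
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- as.matrix(matrix)
  if (abs(det(matrix)) <= 1e-9)
    stop("affine_transform: matrix is singular", call. = FALSE)
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(cbind(x$matrix, x$translation))
  invisible(x)
}

#' Registration configuration
#'
#' Defaults: 64-bin NMI, 3 pyramid levels (downsampling factor 2 with
#' Gaussian pre-smoothing), control-point spacing 20 mm at the finest level
#' (doubled at each coarser level), bending-energy weight 0.001, 60
#' optimizer iterations per level.
#'
#' @param nmi_bins joint-histogram bins (>= 8).
#' @param pyramid_levels multi-resolution levels (>= 1).
#' @param control_spacing_mm B-spline knot spacing at the finest level.
#' @param bending_energy_weight regularization weight on the control-lattice
#'   bending energy.
#' @param max_iterations optimizer iterations per level.
#' @param channel_weights non-negative per-channel weights, sum > 0.
#' @param multistart_mm translation multi-start offset for the robust affine
#'   initialization (0 disables the multi-start).
#' @return A `reg_config` list.
#' @export
reg_config <- function(nmi_bins = 64, pyramid_levels = 3,
                       control_spacing_mm = 20,
                       bending_energy_weight = 1e-4,
                       max_iterations = 60, channel_weights = 1,
                       multistart_mm = 5) {
  stopifnot(nmi_bins >= 8, pyramid_levels >= 1, control_spacing_mm > 0,
            bending_energy_weight >= 0, max_iterations >= 1)
  channel_weights <- as.numeric(channel_weights)
  if (any(channel_weights < 0) || sum(channel_weights) <= 0)
    stop("channel_weights must be non-negative with positive sum",
         call. = FALSE)
  structure(list(nmi_bins = as.integer(nmi_bins),
                 pyramid_levels = as.integer(pyramid_levels),
                 control_spacing_mm = control_spacing_mm,
                 bending_energy_weight = bending_energy_weight,
                 max_iterations = as.integer(max_iterations),
                 channel_weights = channel_weights,
                 multistart_mm = multistart_mm),
            class = "reg_config")
}

#' Normalized mutual information of two same-grid volumes
#'
#' NMI = (H(A)+H(B))/H(A,B) with a linear (partial-volume) binned joint
#' histogram.
#'
#' @param a,b grid-compatible `vol_image`s.
#' @param mask optional `bin_mask` restricting the histogram.
#' @param bins histogram bins per axis.
#' @return NMI value (>= 1; higher = more shared information).
#' @export
nmi <- function(a, b, mask = NULL, bins = 64) {
  stop_if_incompatible(a, b, "nmi inputs")
  inc <- if (is.null(mask)) rep(TRUE, length(a$values)) else
    as.logical(mask$values)
  cpp_nmi_vec(as.numeric(a$values), as.numeric(b$values), inc,
              as.integer(bins))
}

# coarse-to-fine downsampling factors; coarsening is capped so every level
# keeps at least ~16 voxels per axis (NMI histograms degenerate below that)
pyramid_factors <- function(levels, shape) {
  f <- 2^((levels - 1):0)
  f <- pmin(f, max(1, floor(min(shape) / 16)))
  unique(f)
}

# Gaussian-smoothed downsampling by integer factor (for pyramids)
downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  sm <- array(cpp_gauss3d(as.numeric(vol$values), dim(vol$values),
                          rep(factor / 2, 3)), dim(vol$values))
  smv <- vol_image(sm, vol$spacing, vol$origin, vol$orientation,
                   vol$modality)
  shp <- pmax(2L, as.integer(ceiling(dim(vol$values) / factor)))
  g <- grid_spec(shp, vol$spacing * factor, vol$origin, vol$orientation)
  resample(smv, g, "trilinear")
}

com_world <- function(vol) {
  w <- as.numeric(vol$values) - min(vol$values)
  if (sum(w) == 0) w <- rep(1, length(w))
  xyz <- voxel_world_coords(vol)
  colSums(xyz * w) / sum(w)
}

affine_from_params <- function(p, center) {
  # p: t(3), rotation angles (3, rad), log-scales (3)
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  M <- Rz %*% Ry %*% Rx %*% diag(exp(p[7:9]))
  affine_transform(M, center + p[1:3] - M %*% center)
}

nmi_of_affine <- function(fixed, moving, tr, bins, stride = 1L,
                          mask = NULL) {
  cpp_nmi_affine(as.numeric(fixed$values), dim(fixed$values), fixed$spacing,
                 fixed$origin, as.numeric(fixed$orientation),
                 as.numeric(moving$values), dim(moving$values),
                 moving$spacing, moving$origin,
                 as.numeric(moving$orientation),
                 c(as.numeric(tr$matrix), tr$translation),
                 as.integer(bins), as.integer(stride),
                 if (is.null(mask)) NULL else as.logical(mask$values))
}

#' Robust affine registration by multi-start NMI optimization
#'
#' Initializes with center-of-mass alignment plus a small multi-start over
#' translations, then refines translation, rotation and (log-)scale with
#' Nelder-Mead over a Gaussian image pyramid, maximizing NMI. The returned
#' transform's NMI is never below that of the identity.
#'
#' @param fixed,moving non-constant `vol_image`s.
#' @param config a [reg_config()].
#' @param seed integer; fixed ordering makes the procedure deterministic,
#'   the seed only feeds optional jitter of the multi-start pattern.
#' @return An `affine_transform` with attribute `"nmi"`.
#' @export
affine_register <- function(fixed, moving, config = reg_config(),
                            seed = NULL) {
  if (sd(fixed$values) == 0 || sd(moving$values) == 0)
    stop("affine_register: constant input volume", call. = FALSE)
  center <- com_world(fixed)
  t_com <- com_world(moving) - center
  d <- config$multistart_mm
  starts <- list(c(0, 0, 0), t_com)
  if (d > 0)
    for (ax in 1:3) for (s in c(-d, d)) {
      o <- t_com; o[ax] <- o[ax] + s
      starts <- c(starts, list(o))
    }
  factors <- pyramid_factors(config$pyramid_levels, dim(fixed$values))
  f_pyr <- lapply(factors, function(f) downsample_volume(fixed, f))
  m_pyr <- lapply(factors, function(f) downsample_volume(moving, f))
  bins_coarse <- max(16L, as.integer(config$nmi_bins / 2))
  score_start <- function(t0) {
    tr <- affine_transform(diag(3), t0)
    nmi_of_affine(f_pyr[[1]], m_pyr[[1]], tr, bins_coarse)
  }
  sc <- vapply(starts, score_start, numeric(1))
  sc[is.na(sc)] <- -Inf
  p_com <- c(starts[[which.max(sc)]], rep(0, 6))
  p <- p_com
  for (lev in seq_along(factors)) {
    fl <- f_pyr[[lev]]; ml <- m_pyr[[lev]]
    bins <- if (lev == length(factors)) config$nmi_bins else bins_coarse
    obj <- function(par) {
      v <- nmi_of_affine(fl, ml, affine_from_params(par, center), bins)
      if (is.na(v)) return(1e6)
      if (!is.finite(v))
        stop("affine_register: non-finite objective", call. = FALSE)
      -v
    }
    # the center-of-mass start stays a candidate at every level: coarse
    # levels can drift off a narrow NMI peak that finer levels then miss
    if (obj(p_com) < obj(p)) p <- p_com
    # coarse exploration then fine polish (the NMI peak is narrow when
    # the optimum realigns voxel lattices exactly)
    for (scale_par in list(c(rep(10, 3), rep(0.3, 3), rep(0.3, 3)),
                           c(rep(1, 3), rep(0.03, 3), rep(0.03, 3)))) {
      opt <- optim(p, obj, method = "Nelder-Mead",
                   control = list(maxit = 5 * config$max_iterations,
                                  reltol = 1e-10, parscale = scale_par))
      p <- opt$par
    }
  }
  best <- affine_from_params(p, center)
  v_best <- nmi_of_affine(fixed, moving, best, config$nmi_bins)
  v_id <- nmi_of_affine(fixed, moving, affine_transform(), config$nmi_bins)
  if (is.na(v_best) || (!is.na(v_id) && v_id > v_best)) {
    best <- affine_transform()
    v_best <- v_id
  }
  attr(best, "nmi") <- v_best
  best
}

#' Dense deformation field
#'
#' Per-voxel displacement in mm (world axes) on the fixed grid: warping
#' samples the moving image at x + u(x).
#'
#' @param displacement array of dim `c(shape, 3)`, mm.
#' @param grid the fixed `grid_spec`.
#' @param control_spacing_mm knot spacing used to generate the field (NA for
#'   analytic/synthetic fields).
#' @return A `deformation_field` object.
#' @export
deformation_field <- function(displacement, grid, control_spacing_mm = NA) {
  displacement <- as.array(displacement)
  if (length(dim(displacement)) != 4L || dim(displacement)[4] != 3L)
    stop("displacement must have dim c(shape, 3)", call. = FALSE)
  if (!all(dim(displacement)[1:3] == grid$shape))
    stop("displacement shape does not match grid", call. = FALSE)
  if (any(!is.finite(displacement)))
    stop("deformation field must be finite everywhere", call. = FALSE)
  structure(list(displacement = displacement, grid = grid,
                 control_spacing_mm = control_spacing_mm),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$displacement, ncol = 3)^2))
  cat(sprintf("<deformation_field> %s grid, |u| mean %.3f mm, max %.3f mm\n",
              paste(x$grid$shape, collapse = "x"), mean(mag), max(mag)))
  invisible(x)
}

# number of control points per axis for a knot spacing in voxels
ffd_nc <- function(shape, delta_vox) {
  as.integer(floor((shape - 1) / delta_vox) + 4)
}

#' Multi-channel non-rigid B-spline registration
#'
#' Optimizes a cubic B-spline free-form deformation over a Gaussian pyramid,
#' maximizing the channel-weighted sum of NMI terms minus a bending-energy
#' penalty, with analytic gradients (L-BFGS-B). The affine initialization is
#' folded into the returned dense field.
#'
#' @param fixed_channels `vol_image` or list of grid-compatible
#'   `vol_image`s.
#' @param moving_channels matching list for the moving subject (all
#'   grid-compatible with each other; any grid).
#' @param init an `affine_transform` initialization (default identity).
#' @param config a [reg_config()]; `channel_weights` is recycled/validated
#'   against the channel count.
#' @param mask optional `bin_mask` on the fixed grid restricting the
#'   similarity computation.
#' @return A `deformation_field` on the fixed grid.
#' @export
nonrigid_register <- function(fixed_channels, moving_channels, init = NULL,
                              config = reg_config(), mask = NULL) {
  if (inherits(fixed_channels, "vol_image"))
    fixed_channels <- list(fixed_channels)
  if (inherits(moving_channels, "vol_image"))
    moving_channels <- list(moving_channels)
  if (length(fixed_channels) != length(moving_channels))
    stop("nonrigid_register: channel lists must have equal length",
         call. = FALSE)
  nch <- length(fixed_channels)
  if (nch < 1) stop("need at least one channel", call. = FALSE)
  for (c in seq_len(nch)[-1]) {
    stop_if_incompatible(fixed_channels[[1]], fixed_channels[[c]],
                         "fixed channels")
    stop_if_incompatible(moving_channels[[1]], moving_channels[[c]],
                         "moving channels")
  }
  cw <- rep_len(as.numeric(config$channel_weights), nch)
  if (sum(cw) <= 0) stop("channel weights sum to zero", call. = FALSE)
  if (is.null(init)) init <- affine_transform()
  fixed0 <- fixed_channels[[1]]
  # pre-warp moving channels onto the fixed grid through the affine init
  target0 <- grid_of(fixed0)
  moving_pw <- lapply(moving_channels, function(m)
    warp(m, init, target0, "trilinear"))

  factors <- pyramid_factors(config$pyramid_levels,
                             dim(fixed0$values))
  params <- NULL
  prev_grid <- NULL
  prev_delta <- NULL
  for (lev in seq_along(factors)) {
    f <- factors[lev]
    fl <- lapply(fixed_channels, downsample_volume, factor = f)
    ml <- lapply(moving_pw, downsample_volume, factor = f)
    gl <- grid_of(fl[[1]])
    delta_mm <- config$control_spacing_mm * f
    delta_vox <- delta_mm / gl$spacing
    nc <- ffd_nc(gl$shape, delta_vox)
    msk <- if (is.null(mask)) logical(0) else {
      mm <- resample_mask(mask, gl)
      as.logical(mm$values)
    }
    # warm start: sample previous level's field (in fine-level voxel units)
    # at the new control locations
    p0 <- numeric(3 * prod(nc))
    if (!is.null(params)) {
      uprev <- cpp_ffd_field(params, prev_grid$shape,
                             prev_delta, ffd_nc(prev_grid$shape, prev_delta))
      n_prev <- prod(prev_grid$shape)
      arr <- array(0, c(nc, 3))
      cg <- expand.grid(gx = seq_len(nc[1]) - 2, gy = seq_len(nc[2]) - 2,
                        gz = seq_len(nc[3]) - 2)
      # control location in fine voxel coords -> previous (coarser) coords
      ratio <- gl$spacing / prev_grid$spacing
      px <- cg$gx * delta_vox[1] * ratio[1]
      py <- cg$gy * delta_vox[2] * ratio[2]
      pz <- cg$gz * delta_vox[3] * ratio[3]
      for (comp in 1:3) {
        uc <- array(uprev[((comp - 1) * n_prev + 1):(comp * n_prev)],
                    prev_grid$shape)
        vals <- interp_trilinear_clamped(uc, px, py, pz)
        # previous-level voxel units -> this level's voxel units
        arr[, , , comp] <- array(vals / ratio[comp], nc)
      }
      p0 <- as.numeric(arr)
    }
    mgrad <- lapply(ml, function(v) cpp_grad3d(as.numeric(v$values),
                                               dim(v$values)))
    fl_v <- lapply(fl, function(v) as.numeric(v$values))
    ml_v <- lapply(ml, function(v) as.numeric(v$values))
    fn <- function(par) {
      r <- cpp_ffd_obj(par, fl_v, ml_v, mgrad, gl$shape, delta_vox,
                       nc, config$nmi_bins, cw,
                       config$bending_energy_weight, msk, FALSE)
      -r$value
    }
    gr <- function(par) {
      r <- cpp_ffd_obj(par, fl_v, ml_v, mgrad, gl$shape, delta_vox,
                       nc, config$nmi_bins, cw,
                       config$bending_energy_weight, msk, TRUE)
      -r$grad
    }
    opt <- optim(p0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = config$max_iterations))
    params <- opt$par
    prev_grid <- gl
    prev_delta <- delta_vox
  }
  # dense field at full resolution (voxel units) -> mm world displacement,
  # composed with the affine init: sample point = M (x + R S u_vox) + t
  shape <- grid_of(fixed0)$shape
  uv <- cpp_ffd_field(params, shape, prev_delta, ffd_nc(shape, prev_delta))
  n <- prod(shape)
  U <- matrix(uv, ncol = 3)
  RS <- fixed0$orientation %*% diag(fixed0$spacing)
  d_mm <- U %*% t(RS)
  w <- voxel_world_coords(fixed0)
  mapped <- (w + d_mm) %*% t(init$matrix) +
    matrix(init$translation, n, 3, byrow = TRUE)
  disp <- array(mapped - w, c(shape, 3))
  deformation_field(disp, grid_of(fixed0),
                    control_spacing_mm = config$control_spacing_mm)
}

# clamped trilinear interpolation of one 3-D array at continuous 0-based
# coordinates (vectors px/py/pz)
interp_trilinear_clamped <- function(arr, px, py, pz) {
  cpp_interp_points(as.numeric(arr), dim(arr), cbind(px, py, pz))
}

#' Apply a transform to a volume (pull-back warping)
#'
#' Output voxel x takes the interpolated input value at T(x): `x + u(x)` for
#' a deformation field, `M x + t` for an affine.
#'
#' @param volume a `vol_image`.
#' @param transform `affine_transform` or `deformation_field`.
#' @param target target `grid_spec`; defaults to the field grid (field) or
#'   the volume grid (affine).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill out-of-domain fill (default per modality).
#' @return A `vol_image` on the target grid.
#' @export
warp <- function(volume, transform, target = NULL,
                 interpolation = c("trilinear", "nearest"), fill = NULL) {
  interpolation <- match.arg(interpolation)
  if (is.null(fill)) fill <- default_fill(volume$modality)
  interp <- if (interpolation == "nearest") 0L else 1L
  if (inherits(transform, "affine_transform")) {
    if (is.null(target)) target <- grid_of(volume)
    if (!inherits(target, "grid_spec")) target <- grid_of(target)
    out <- cpp_resample(as.numeric(volume$values), dim(volume$values),
                        volume$spacing, volume$origin,
                        as.numeric(volume$orientation), target$shape,
                        target$spacing, target$origin,
                        as.numeric(target$orientation),
                        c(as.numeric(transform$matrix),
                          transform$translation), NULL, interp, fill)
  } else if (inherits(transform, "deformation_field")) {
    if (is.null(target)) target <- transform$grid
    if (!inherits(target, "grid_spec")) target <- grid_of(target)
    disp <- transform$displacement
    if (!grid_compatible(target, transform$grid)) {
      # resample each displacement component onto the target grid
      disp <- array(0, c(target$shape, 3))
      for (comp in 1:3) {
        v <- vol_image(transform$displacement[, , , comp],
                       transform$grid$spacing, transform$grid$origin,
                       transform$grid$orientation, "DOSE")
        disp[, , , comp] <- resample(v, target, "trilinear", fill = 0)$values
      }
    }
    out <- cpp_resample(as.numeric(volume$values), dim(volume$values),
                        volume$spacing, volume$origin,
                        as.numeric(volume$orientation), target$shape,
                        target$spacing, target$origin,
                        as.numeric(target$orientation), NULL,
                        as.numeric(disp), interp, fill)
  } else stop("warp: unknown transform type", call. = FALSE)
  vol_image(array(out, target$shape), target$spacing, target$origin,
            target$orientation, volume$modality)
}

#' Warp a binary mask (nearest neighbour)
#' @inheritParams warp
#' @param mask a `bin_mask`.
#' @return A `bin_mask` on the target grid.
#' @export
warp_mask <- function(mask, transform, target = NULL) {
  v <- vol_image(mask$values * 1, mask$spacing, mask$origin,
                 mask$orientation, "LABEL")
  r <- warp(v, transform, target, "nearest", fill = 0)
  bin_mask(r$values != 0, like = r)
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration `v <- -u(x + v(x))`. The composition residual
#' (mean of |u(x + v(x)) + v(x)|) is attached as attribute `"residual_mm"`;
#' an error is raised if it exceeds half the mean voxel spacing.
#'
#' @param field a `deformation_field`.
#' @param max_iter iteration cap.
#' @param tol_mm early-stop tolerance on the update magnitude.
#' @return The inverse `deformation_field`.
#' @export
invert_field <- function(field, max_iter = 50, tol_mm = 1e-4) {
  g <- field$grid
  V <- cpp_invert_field(as.numeric(field$displacement), g$shape, g$spacing,
                        as.numeric(g$orientation), as.integer(max_iter),
                        tol_mm)
  inv <- deformation_field(array(V, c(g$shape, 3)), g,
                           field$control_spacing_mm)
  res <- composition_residual(field, inv)
  if (res > 0.5 * mean(g$spacing))
    stop(sprintf("invert_field: did not converge (mean residual %.3f mm)",
                 res), call. = FALSE)
  attr(inv, "residual_mm") <- res
  inv
}

#' Mean composition residual |u(x + v(x)) + v(x)| in mm
#' @param field,inverse two `deformation_field`s on one grid.
#' @return Mean residual displacement in mm.
#' @export
composition_residual <- function(field, inverse) {
  g <- field$grid
  n <- prod(g$shape)
  V <- matrix(inverse$displacement, ncol = 3)
  # sample u at x + v(x): voxel offset of v in index coords
  RS_inv <- diag(1 / g$spacing) %*% t(g$orientation)
  offs <- V %*% t(RS_inv)
  idx <- as.matrix(expand.grid(x = seq_len(g$shape[1]) - 1,
                               y = seq_len(g$shape[2]) - 1,
                               z = seq_len(g$shape[3]) - 1))
  pts <- idx + offs
  res2 <- 0
  Uc <- matrix(0, n, 3)
  for (comp in 1:3)
    Uc[, comp] <- interp_trilinear_clamped(field$displacement[, , , comp],
                                           pts[, 1], pts[, 2], pts[, 3])
  mean(sqrt(rowSums((Uc + V)^2)))
}

#' Write/read an affine transform as a 4x4 text matrix
#' @param transform an `affine_transform`.
#' @param path text file path.
#' @return `path` (write) or an `affine_transform` (read).
#' @export
write_affine <- function(transform, path) {
  m <- rbind(cbind(transform$matrix, transform$translation), c(0, 0, 0, 1))
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  affine_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Store a deformation field as a displacement NIfTI (x,y,z components on
#' the 4th dimension, mm)
#' @param field a `deformation_field`.
#' @param path .nii/.nii.gz path.
#' @return `path`, invisibly.
#' @export
write_deformation_field <- function(field, path) {
  g <- field$grid
  img <- RNifti::asNifti(field$displacement, pixdim = g$spacing)
  m <- diag(4)
  m[1:3, 1:3] <- g$orientation %*% diag(g$spacing)
  m[1:3, 4] <- g$origin
  RNifti::`sform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_deformation_field
#' @param control_spacing_mm knot spacing to record on the read field.
#' @export
read_deformation_field <- function(path, control_spacing_mm = NA) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  A <- xf[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(A^2))
  arr <- as.array(img)
  g <- grid_spec(dim(arr)[1:3], spacing, xf[1:3, 4],
                 sweep(A, 2, spacing, "/"))
  deformation_field(arr, g, control_spacing_mm)
}
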