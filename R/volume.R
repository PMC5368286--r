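#' 3-D volume with world geometry
#'
#' The basic container used throughout the package: a 3-D numeric lattice
#' together with its voxel spacing (mm), world origin (mm), direction-cosine
#' matrix and a modality tag. The world coordinate of 0-based voxel index
#' \eqn{i} is \eqn{origin + R (spacing \circ i)} (RAS convention, taken from
#' the NIfTI s-form at the I/O boundary).
#'
#' @param values 3-D numeric array.
#' @param spacing length-3 positive voxel size in mm.
#' @param origin length-3 world position of voxel (0,0,0) in mm.
#' @param orientation 3x3 orthonormal direction-cosine matrix.
#' @param modality one of `"CT"`, `"MR"`, `"DOSE"`, `"DENSITY"`, `"LABEL"`.
#' @return A `vol_image` object.
#' @export
vol_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      orientation = diag(3),
                      modality = c("CT", "MR", "DOSE", "DENSITY", "LABEL")) {
  modality <- match.arg(modality)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("vol_image: `values` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- as.matrix(orientation)
  check_geometry(spacing, orientation)
  structure(list(values = values, spacing = spacing, origin = origin,
                 orientation = orientation, modality = modality),
            class = "vol_image")
}

check_geometry <- function(spacing, orientation) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive on every axis", call. = FALSE)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation matrix must be orthonormal (within 1e-6)",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.vol_image <- function(x, ...) {
  cat(sprintf("<vol_image %s> %s voxels, spacing %s mm, range [%.6g, %.6g]\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Resampling target grid
#'
#' A grid without values: shape, spacing, origin and orientation. Used as
#' the target of [resample()] and [warp()].
#'
#' @param shape length-3 integer voxel counts.
#' @param spacing,origin,orientation as in [vol_image()].
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      orientation = diag(3)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("grid_spec: shape must be 3 positive integers", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- as.matrix(orientation)
  check_geometry(spacing, orientation)
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 orientation = orientation), class = "grid_spec")
}

#' Grid of an existing volume or mask
#' @param x a `vol_image` or `bin_mask`.
#' @return The `grid_spec` describing `x`'s lattice.
#' @export
grid_of <- function(x) {
  grid_spec(dim(x$values), x$spacing, x$origin, x$orientation)
}

#' Binary mask on a volume grid
#'
#' @param values 3-D logical array.
#' @param like a `vol_image`/`bin_mask`/`grid_spec` providing geometry, or
#'   NULL to pass geometry explicitly.
#' @inheritParams vol_image
#' @return A `bin_mask` object.
#' @export
bin_mask <- function(values, like = NULL, spacing = c(1, 1, 1),
                     origin = c(0, 0, 0), orientation = diag(3)) {
  values <- as.array(values)
  storage.mode(values) <- "logical"
  if (length(dim(values)) != 3L)
    stop("bin_mask: `values` must be a 3-D array", call. = FALSE)
  if (!is.null(like)) {
    spacing <- like$spacing; origin <- like$origin
    orientation <- like$orientation
    shp <- if (inherits(like, "grid_spec")) like$shape else dim(like$values)
    if (!all(dim(values) == shp))
      stop("bin_mask: shape does not match `like`", call. = FALSE)
  }
  check_geometry(spacing, orientation)
  structure(list(values = values, spacing = spacing, origin = origin,
                 orientation = orientation), class = "bin_mask")
}

#' @export
print.bin_mask <- function(x, ...) {
  cat(sprintf("<bin_mask> %s voxels, %d set (%.2f cm^3)\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              mask_volume_cm3(x)))
  invisible(x)
}

#' Physical volume of a mask in cm^3
#' @param mask a `bin_mask`.
#' @return Voxel count times voxel volume, in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$values) * prod(mask$spacing) / 1000
}

#' Are two volumes/masks/grids on the same lattice?
#'
#' Shape, spacing, origin and orientation must all agree within `tol`.
#' Every voxelwise operation in the package requires this.
#'
#' @param a,b `vol_image`, `bin_mask` or `grid_spec` objects.
#' @param tol numeric tolerance (default 1e-6).
#' @return Logical scalar.
#' @export
grid_compatible <- function(a, b, tol = 1e-6) {
  sa <- if (inherits(a, "grid_spec")) a$shape else dim(a$values)
  sb <- if (inherits(b, "grid_spec")) b$shape else dim(b$values)
  all(sa == sb) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$orientation - b$orientation)) <= tol
}

stop_if_incompatible <- function(a, b, what = "volumes") {
  if (!grid_compatible(a, b))
    stop(sprintf("%s are not grid-compatible (shape/spacing/origin/orientation must match within 1e-6)",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Geometry is taken from the s-form/q-form; the NIfTI RAS world is used as
#' the internal world coordinate system throughout the package.
#'
#' @param path .nii or .nii.gz file.
#' @param modality modality tag to attach (default `"CT"`).
#' @return A `vol_image`.
#' @export
read_nifti_volume <- function(path, modality = "CT") {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  A <- xf[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(A^2))
  orientation <- sweep(A, 2, spacing, "/")
  vals <- array(as.vector(as.array(img)), dim(img))
  vol_image(vals, spacing = spacing, origin = xf[1:3, 4],
            orientation = orientation, modality = modality)
}

#' Read a NIfTI mask
#' @param path .nii or .nii.gz file; non-zero voxels become TRUE.
#' @return A `bin_mask`.
#' @export
read_nifti_mask <- function(path) {
  v <- read_nifti_volume(path, modality = "LABEL")
  bin_mask(v$values != 0, like = v)
}

#' Write a volume or mask to NIfTI
#' @param x a `vol_image` or `bin_mask`.
#' @param path output .nii or .nii.gz path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  vals <- x$values
  if (inherits(x, "bin_mask")) storage.mode(vals) <- "integer"
  img <- RNifti::asNifti(vals, pixdim = x$spacing)
  m <- diag(4)
  m[1:3, 1:3] <- x$orientation %*% diag(x$spacing)
  m[1:3, 4] <- x$origin
  RNifti::`sform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

# world coordinates of all voxel centers (n x 3), 0-based indexing
voxel_world_coords <- function(g) {
  shp <- if (inherits(g, "grid_spec")) g$shape else dim(g$values)
  idx <- as.matrix(expand.grid(x = seq_len(shp[1]) - 1,
                               y = seq_len(shp[2]) - 1,
                               z = seq_len(shp[3]) - 1))
  sweep(t(g$orientation %*% t(sweep(idx, 2, g$spacing, "*"))), 2,
        g$origin, "+")
}
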