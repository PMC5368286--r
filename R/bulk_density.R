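#' Tissue-class density table
#'
#' Physical densities for the bulk-density-assignment baseline: water 1.0
#' and air 0.001 g/cm^3 for both sites; bone 1.53 (head & neck) or 1.22
#' (prostate) g/cm^3. The prostate site defines no air class.
#'
#' @param site `"head_neck"` or `"prostate"`.
#' @param bone,water,air overrides in g/cm^3.
#' @param calibration HU calibration passed to [density_to_hu()].
#' @return A `density_table`.
#' @export
density_table <- function(site = c("head_neck", "prostate"), bone = NULL,
                          water = 1.0, air = 0.001,
                          calibration = hu_calibration()) {
  site <- match.arg(site)
  if (is.null(bone)) bone <- if (site == "head_neck") 1.53 else 1.22
  stopifnot(air > 0, water > 0, bone > 0, air < water, water < bone)
  structure(list(site = site,
                 densities = c(outside = air, water = water, bone = bone,
                               air = air),
                 calibration = calibration),
            class = "density_table")
}

#' Piecewise-linear density-to-HU calibration
#'
#' Default anchors: (0.001 g/cm^3, -1000 HU), (1.0, 0), (1.53, 883) — water
#' and air exact, bone on a conventional CT calibration slope. Densities
#' outside the hull are clamped with a warning.
#'
#' @param density anchor densities (g/cm^3), ascending.
#' @param hu anchor HU values, same length.
#' @return An `hu_calibration`.
#' @export
hu_calibration <- function(density = c(0.001, 1.0, 1.53),
                           hu = c(-1000, 0, 883)) {
  stopifnot(length(density) == length(hu), length(density) >= 2,
            !is.unsorted(density, strictly = TRUE),
            !is.unsorted(hu, strictly = TRUE))
  structure(list(density = density, hu = hu), class = "hu_calibration")
}

#' Convert physical density to HU (and back)
#'
#' Monotone piecewise-linear interpolation through the calibration anchors.
#'
#' @param density densities in g/cm^3 (> 0).
#' @param calibration an [hu_calibration()].
#' @return HU values.
#' @export
density_to_hu <- function(density, calibration = hu_calibration()) {
  if (any(density <= 0)) stop("density must be > 0", call. = FALSE)
  r <- range(calibration$density)
  if (any(density < r[1] | density > r[2]))
    warning("density outside calibration hull; clamped", call. = FALSE)
  stats::approx(calibration$density, calibration$hu,
                xout = pmin(pmax(density, r[1]), r[2]),
                rule = 2)$y
}

#' @rdname density_to_hu
#' @param hu HU values.
#' @export
hu_to_density <- function(hu, calibration = hu_calibration()) {
  r <- range(calibration$hu)
  stats::approx(calibration$hu, calibration$density,
                xout = pmin(pmax(hu, r[1]), r[2]), rule = 2)$y
}

#' Air segmentation from MR intensity
#'
#' Voxels inside the body with MR intensity strictly below `threshold`
#' (default 8, presuming a comparable absolute MR intensity scale), then a
#' morphological opening with a 1-voxel-spacing radius to suppress
#' single-voxel noise. An empty mask is allowed (the prostate site defines
#' no air class).
#'
#' @param mr MR `vol_image`.
#' @param body `bin_mask` grid-compatible with `mr`.
#' @param threshold absolute intensity threshold (default 8).
#' @return A `bin_mask` of air voxels.
#' @export
segment_air_mr <- function(mr, body, threshold = 8) {
  stop_if_incompatible(mr, body, "segment_air_mr inputs")
  air <- bin_mask(mr$values < threshold & body$values, like = mr)
  mask_morphology(air, "open", radius_mm = min(mr$spacing))
}

#' Assemble the tissue-class label map
#'
#' Partition of the grid into outside / water / bone / air: outside = not
#' body; bone = bone within body; air = air within body minus bone (bone
#' has precedence on overlap); water = the remaining body.
#'
#' @param body,bone,air grid-compatible `bin_mask`s (bone/air are clipped
#'   to the body).
#' @return A `tissue_class_map` (integer labels with a `labels` attribute).
#' @export
assemble_class_map <- function(body, bone, air) {
  stop_if_incompatible(body, bone, "class-map masks")
  stop_if_incompatible(body, air, "class-map masks")
  lab <- array(0L, dim(body$values))  # 0 = outside
  b <- body$values
  bo <- bone$values & b
  ai <- air$values & b & !bo
  lab[b] <- 1L                        # water
  lab[bo] <- 2L                       # bone
  lab[ai] <- 3L                       # air
  structure(list(values = lab, spacing = body$spacing, origin = body$origin,
                 orientation = body$orientation,
                 labels = c(outside = 0L, water = 1L, bone = 2L, air = 3L)),
            class = "tissue_class_map")
}

#' Bulk-density synthetic CT (sCT_bda)
#'
#' Assigns each tissue class its physical density and converts to HU via
#' the table's calibration. Outside the body gets the air density/HU.
#'
#' @param classes a [assemble_class_map()] result.
#' @param table a [density_table()].
#' @return List with `density` (g/cm^3) and `hu` `vol_image`s.
#' @export
build_bulk_sct <- function(classes, table = density_table()) {
  lab <- classes$values
  known <- lab %in% classes$labels
  if (!all(known)) stop("build_bulk_sct: unknown label", call. = FALSE)
  dens <- array(NA_real_, dim(lab))
  dens[lab == 0L] <- table$densities[["outside"]]
  dens[lab == 1L] <- table$densities[["water"]]
  dens[lab == 2L] <- table$densities[["bone"]]
  dens[lab == 3L] <- table$densities[["air"]]
  hu <- array(density_to_hu(as.numeric(dens), table$calibration), dim(lab))
  geo <- list(spacing = classes$spacing, origin = classes$origin,
              orientation = classes$orientation)
  list(density = vol_image(dens, geo$spacing, geo$origin, geo$orientation,
                           "DENSITY"),
       hu = vol_image(hu, geo$spacing, geo$origin, geo$orientation, "CT"))
}
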