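#' Resample a volume onto a target grid
#'
#' Pull-back resampling: every target voxel center is mapped to world
#' coordinates and the input volume is interpolated there. Voxels sampling
#' outside the input domain receive `fill` (default -1000 for CT, 0
#' otherwise — air for CT, signal-free for MR/dose).
#'
#' @param volume a `vol_image`.
#' @param target a `grid_spec` (or object with a grid, see [grid_of()]).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill out-of-domain fill value; default depends on modality.
#' @return A `vol_image` on the target grid.
#' @export
resample <- function(volume, target,
                     interpolation = c("trilinear", "nearest"),
                     fill = NULL) {
  interpolation <- match.arg(interpolation)
  if (!inherits(target, "grid_spec")) target <- grid_of(target)
  if (is.null(fill)) fill <- default_fill(volume$modality)
  if (any(!is.finite(volume$values)))
    stop("resample: volume contains non-finite values", call. = FALSE)
  out <- cpp_resample(as.numeric(volume$values), dim(volume$values),
                      volume$spacing, volume$origin,
                      as.numeric(volume$orientation),
                      target$shape, target$spacing, target$origin,
                      as.numeric(target$orientation),
                      NULL, NULL,
                      if (interpolation == "nearest") 0L else 1L, fill)
  vol_image(array(out, target$shape), spacing = target$spacing,
            origin = target$origin, orientation = target$orientation,
            modality = volume$modality)
}

default_fill <- function(modality) {
  if (identical(modality, "CT")) -1000 else 0
}

#' Resample a binary mask (nearest neighbour)
#' @param mask a `bin_mask`.
#' @param target a `grid_spec`.
#' @return A `bin_mask` on the target grid.
#' @export
resample_mask <- function(mask, target) {
  v <- vol_image(mask$values * 1, spacing = mask$spacing,
                 origin = mask$origin, orientation = mask$orientation,
                 modality = "LABEL")
  r <- resample(v, target, interpolation = "nearest", fill = 0)
  bin_mask(r$values != 0, like = r)
}
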