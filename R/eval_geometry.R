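#' Region thresholds for the MAE evaluation
#'
#' Bone: CT strictly above 150 HU within the FOV, then morphological
#' closing (default 3 mm ball) and hole filling to include softer bone and
#' marrow. Soft tissue: CT strictly above -150 HU within the FOV, minus the
#' bone region.
#'
#' @param bone_hu bone threshold (default 150 HU).
#' @param soft_hu soft-tissue threshold (default -150 HU).
#' @param morph_radius_mm closing radius for the bone region (default 3).
#' @return A `region_thresholds` list.
#' @export
region_thresholds <- function(bone_hu = 150, soft_hu = -150,
                              morph_radius_mm = 3) {
  stopifnot(bone_hu > soft_hu, morph_radius_mm >= 0)
  structure(list(bone_hu = bone_hu, soft_hu = soft_hu,
                 morph_radius_mm = morph_radius_mm),
            class = "region_thresholds")
}

#' Mean absolute error in HU over a region
#'
#' `MAE = (1/N) * sum_{x in region} |sCT(x) - CT(x)|`.
#'
#' @param ct,sct grid-compatible `vol_image`s (HU).
#' @param region non-empty `bin_mask`.
#' @return MAE in HU.
#' @export
mae <- function(ct, sct, region) {
  stop_if_incompatible(ct, sct, "mae volumes")
  stop_if_incompatible(ct, region, "mae region")
  if (!any(region$values))
    stop("mae: empty region (metric undefined)", call. = FALSE)
  mean(abs(sct$values[region$values] - ct$values[region$values]))
}

#' Bone region from the planning CT
#'
#' @param ct planning CT `vol_image`.
#' @param fov MRI field-of-view `bin_mask`.
#' @param thr a [region_thresholds()].
#' @return A `bin_mask`.
#' @export
bone_region <- function(ct, fov, thr = region_thresholds()) {
  stop_if_incompatible(ct, fov, "bone_region inputs")
  m <- bin_mask(ct$values > thr$bone_hu & fov$values, like = ct)
  m <- mask_morphology(m, "close", thr$morph_radius_mm)
  m <- mask_morphology(m, "fill_holes")
  bin_mask(m$values & fov$values, like = ct)
}

#' Soft-tissue region from the planning CT
#'
#' @inheritParams bone_region
#' @param bone the [bone_region()] mask to subtract.
#' @return A `bin_mask`, disjoint from `bone`.
#' @export
soft_tissue_region <- function(ct, fov, bone, thr = region_thresholds()) {
  stop_if_incompatible(ct, fov, "soft_tissue_region inputs")
  bin_mask(ct$values > thr$soft_hu & fov$values & !bone$values, like = ct)
}

#' Volume index of two contours
#'
#' `VI = (V(ref) - V(eval)) / V(ref) + 1`, volumes in cm^3. VI = 1 means
#' identical volumes; VI > 1 means the reference (clinical) contour is
#' larger than the evaluated one, VI < 1 the reverse.
#'
#' @param ref non-empty reference `bin_mask` (clinical contour).
#' @param eval_mask evaluated `bin_mask`.
#' @return VI value.
#' @export
volume_index <- function(ref, eval_mask) {
  va <- mask_volume_cm3(ref)
  if (va <= 0)
    stop("volume_index: empty reference (metric undefined)", call. = FALSE)
  (va - mask_volume_cm3(eval_mask)) / va + 1
}

#' Dice similarity coefficient
#'
#' `DSC = 2|A∩B| / (|A| + |B|)`; the attribute `"good_overlap"` records the
#' conventional DSC > 0.7 pass flag.
#'
#' @param a,b grid-compatible `bin_mask`s, not both empty.
#' @param good_threshold overlap considered good above this value
#'   (default 0.7).
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b, good_threshold = 0.7) {
  stop_if_incompatible(a, b, "dice masks")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0)
    stop("dice: both masks empty (metric undefined)", call. = FALSE)
  d <- 2 * sum(a$values & b$values) / (na + nb)
  attr(d, "good_overlap") <- d > good_threshold
  d
}

#' Geometric accuracy report for one or more synthetic CTs
#'
#' Computes the MAE within the external (body ∩ FOV), bone and soft-tissue
#' regions, plus VI and DSC of the external and bone contours extracted
#' from each sCT against the CT-derived ones.
#'
#' @param ct planning CT `vol_image`.
#' @param scts named list of synthetic CT `vol_image`s (e.g.
#'   `list(sct_a = ..., sct_bda = ...)`).
#' @param fov MRI FOV `bin_mask`.
#' @param thr a [region_thresholds()].
#' @param body_threshold CT body-contour threshold in HU.
#' @return A tibble with one row per (sct, region/contour, metric).
#' @export
geometry_report <- function(ct, scts, fov, thr = region_thresholds(),
                            body_threshold = -250) {
  body_ct <- extract_body_mask(ct, "CT", body_threshold)
  external <- bin_mask(body_ct$values & fov$values, like = ct)
  bone <- bone_region(ct, fov, thr)
  soft <- soft_tissue_region(ct, fov, bone, thr)
  rows <- list()
  for (nm in names(scts)) {
    s <- scts[[nm]]
    stop_if_incompatible(ct, s, "geometry_report volumes")
    rows[[length(rows) + 1]] <- tibble::tibble(
      sct = nm, metric = "MAE",
      region = c("external", "bone", "soft_tissue"),
      value = c(mae(ct, s, external), mae(ct, s, bone), mae(ct, s, soft)))
    body_s <- extract_body_mask(s, "CT", body_threshold)
    ext_s <- bin_mask(body_s$values & fov$values, like = s)
    bone_s <- bone_region(s, fov, thr)
    rows[[length(rows) + 1]] <- tibble::tibble(
      sct = nm, metric = c("VI", "VI", "DSC", "DSC"),
      region = c("external", "bone", "external", "bone"),
      value = c(volume_index(external, ext_s), volume_index(bone, bone_s),
                as.numeric(dice(external, ext_s)),
                as.numeric(dice(bone, bone_s))))
  }
  do.call(rbind, rows)
}
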