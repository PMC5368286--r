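#' Gamma analysis criteria
#'
#' @param dd_percent dose-difference criterion in percent (e.g. 3 or 2).
#' @param dta_mm distance-to-agreement criterion in mm (e.g. 3 or 2).
#' @param mode `"local"` (DD normalized by the local reference dose) or
#'   `"global"` (by the reference maximum).
#' @param search_radius_factor search radius as a multiple of DTA
#'   (default 3).
#' @param interp_step_factor search-lattice step as a fraction of DTA
#'   (default 0.1, at which the search is converged to well under 0.02 in
#'   gamma on smooth dose fields; coarser steps overestimate gamma near
#'   steep dose gradients).
#' @param dose_floor_fraction voxels with reference dose below this
#'   fraction of the reference maximum are excluded (default 0.01).
#' @return A `gamma_criteria` list.
#' @export
gamma_criteria <- function(dd_percent = 3, dta_mm = 3,
                           mode = c("local", "global"),
                           search_radius_factor = 3,
                           interp_step_factor = 0.1,
                           dose_floor_fraction = 0.01) {
  mode <- match.arg(mode)
  stopifnot(dd_percent > 0, dta_mm > 0, search_radius_factor > 0,
            interp_step_factor > 0, dose_floor_fraction >= 0)
  structure(list(dd_percent = dd_percent, dta_mm = dta_mm, mode = mode,
                 search_radius_factor = search_radius_factor,
                 interp_step_factor = interp_step_factor,
                 dose_floor_fraction = dose_floor_fraction),
            class = "gamma_criteria")
}

#' 3-D gamma map
#'
#' For each reference voxel above the dose floor,
#' \deqn{\gamma(x) = \min_r \sqrt{\|r-x\|^2/DTA^2 +
#'   (D_e(r)-D_r(x))^2/(dd \cdot D_n)^2}}
#' over candidate points within `search_radius_factor * DTA`, with the
#' evaluated dose interpolated trilinearly; `D_n` is the local reference
#' dose (local mode) or the global reference maximum. Floor-excluded and
#' out-of-mask voxels are NA.
#'
#' @param ref_dose,eval_dose grid-compatible non-negative dose
#'   `vol_image`s (Gy).
#' @param criteria a [gamma_criteria()].
#' @param mask non-empty analysis `bin_mask` (e.g. the MRI FOV).
#' @param subvoxel_refine if TRUE, a local sub-lattice refinement (a fifth
#'   of the search step) follows the lattice search, giving gamma values
#'   slightly below the lattice-converged ones near steep dose gradients.
#' @return A `gamma_map` object (values array + criteria).
#' @export
gamma_map <- function(ref_dose, eval_dose, criteria = gamma_criteria(),
                      mask = NULL, subvoxel_refine = FALSE) {
  stop_if_incompatible(ref_dose, eval_dose, "gamma doses")
  if (is.null(mask))
    mask <- bin_mask(array(TRUE, dim(ref_dose$values)), like = ref_dose)
  stop_if_incompatible(ref_dose, mask, "gamma mask")
  if (!any(mask$values)) stop("gamma_map: empty mask", call. = FALSE)
  if (min(ref_dose$values) < 0 || min(eval_dose$values) < 0)
    stop("gamma_map: doses must be non-negative", call. = FALSE)
  dmax <- max(ref_dose$values)
  floor_abs <- criteria$dose_floor_fraction * dmax
  g <- cpp_gamma(as.numeric(ref_dose$values), as.numeric(eval_dose$values),
                 dim(ref_dose$values), ref_dose$spacing,
                 as.logical(mask$values), criteria$dd_percent / 100,
                 criteria$dta_mm, criteria$mode == "local", dmax,
                 criteria$search_radius_factor * criteria$dta_mm,
                 criteria$interp_step_factor * criteria$dta_mm,
                 floor_abs, subvoxel_refine)
  g <- array(g, dim(ref_dose$values))
  if (!any(is.finite(g)))
    stop("gamma_map: all voxels excluded by the dose floor", call. = FALSE)
  structure(list(values = g, criteria = criteria, grid = grid_of(ref_dose),
                 floor_abs = floor_abs,
                 n_excluded = sum(mask$values & !is.finite(g))),
            class = "gamma_map")
}

#' Exhaustive fine-grid gamma evaluator (reference implementation)
#'
#' Brute-force scan of a fine offset lattice (step `DTA/10`, radius
#' `3*DTA` by default) used as an independent check of [gamma_map()].
#'
#' @inheritParams gamma_map
#' @param fine_step_factor offset-lattice step as a fraction of DTA.
#' @param radius_factor search radius as a multiple of DTA.
#' @return A `gamma_map` object.
#' @export
gamma_map_reference <- function(ref_dose, eval_dose,
                                criteria = gamma_criteria(), mask = NULL,
                                fine_step_factor = 0.1, radius_factor = 3) {
  stop_if_incompatible(ref_dose, eval_dose, "gamma doses")
  if (is.null(mask))
    mask <- bin_mask(array(TRUE, dim(ref_dose$values)), like = ref_dose)
  dmax <- max(ref_dose$values)
  floor_abs <- criteria$dose_floor_fraction * dmax
  g <- cpp_gamma_oracle(as.numeric(ref_dose$values),
                        as.numeric(eval_dose$values),
                        dim(ref_dose$values), ref_dose$spacing,
                        as.logical(mask$values), criteria$dd_percent / 100,
                        criteria$dta_mm, criteria$mode == "local", dmax,
                        radius_factor * criteria$dta_mm,
                        fine_step_factor * criteria$dta_mm, floor_abs)
  g <- array(g, dim(ref_dose$values))
  structure(list(values = g, criteria = criteria, grid = grid_of(ref_dose),
                 floor_abs = floor_abs,
                 n_excluded = sum(mask$values & !is.finite(g))),
            class = "gamma_map")
}

#' Gamma pass rate in percent
#'
#' `100 * #(defined voxels in mask with gamma <= 1) / #(defined voxels in
#' mask)`.
#'
#' @param gmap a [gamma_map()] result.
#' @param mask optional `bin_mask` restriction (default: all defined
#'   voxels).
#' @return Pass rate in \[0, 100\].
#' @export
gamma_pass_rate <- function(gmap, mask = NULL) {
  g <- gmap$values
  sel <- is.finite(g)
  if (!is.null(mask)) sel <- sel & mask$values
  n <- sum(sel)
  if (n == 0)
    stop("gamma_pass_rate: no defined voxels in mask", call. = FALSE)
  100 * sum(g[sel] <= 1) / n
}

#' Density override outside the MRI FOV
#'
#' For a fair CT-vs-sCT dose comparison with a reduced MRI FOV: voxels
#' inside the body but outside the FOV are set to water (0 HU); voxels in
#' `missing_tissue` are set to air (-1000 HU), air taking precedence on
#' overlap (worst-case convention).
#'
#' @param volume CT or sCT `vol_image` (HU).
#' @param body body-contour `bin_mask`.
#' @param fov MRI FOV `bin_mask`.
#' @param missing_tissue optional `bin_mask` of tissue absent from the MR
#'   coverage.
#' @return The overridden `vol_image`.
#' @export
override_outside_fov <- function(volume, body, fov, missing_tissue = NULL) {
  stop_if_incompatible(volume, body, "override volumes")
  stop_if_incompatible(volume, fov, "override volumes")
  v <- volume$values
  v[body$values & !fov$values] <- 0
  if (!is.null(missing_tissue)) {
    stop_if_incompatible(volume, missing_tissue, "override volumes")
    v[missing_tissue$values] <- -1000
  }
  out <- volume
  out$values <- v
  out
}

#' Cumulative dose-volume histogram
#'
#' `v(d)` = fraction of structure voxels receiving at least `d` Gy,
#' evaluated at bin edges of width `bin_width_gy`.
#'
#' @param dose dose `vol_image` (Gy).
#' @param structure non-empty `bin_mask`.
#' @param bin_width_gy bin width (default 0.01 Gy).
#' @return A `dvh_curve` with `dose_gy` and `volume_fraction`.
#' @export
cumulative_dvh <- function(dose, structure, bin_width_gy = 0.01) {
  stop_if_incompatible(dose, structure, "dvh inputs")
  if (!any(structure$values))
    stop("cumulative_dvh: empty structure", call. = FALSE)
  d <- dose$values[structure$values]
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  vf <- vapply(edges, function(e) mean(d >= e), numeric(1))
  structure(list(dose_gy = edges, volume_fraction = vf,
                 bin_width_gy = bin_width_gy), class = "dvh_curve")
}

#' DVH point metrics
#'
#' `Dx` = dose received by at least x% of the structure, computed as the
#' (100 - x)-th percentile of the structure's voxel doses with linear
#' interpolation between order statistics; `Dmean` is the arithmetic mean.
#'
#' @param dose dose `vol_image` (Gy).
#' @param structure non-empty `bin_mask`.
#' @param metric `"D98"`, `"Dmean"` or `"D2"`.
#' @return Dose in Gy.
#' @export
dvh_point <- function(dose, structure, metric = c("D98", "Dmean", "D2")) {
  metric <- match.arg(metric)
  stop_if_incompatible(dose, structure, "dvh inputs")
  if (!any(structure$values))
    stop("dvh_point: empty structure", call. = FALSE)
  d <- dose$values[structure$values]
  switch(metric,
         Dmean = mean(d),
         D98 = unname(quantile(d, probs = 0.02, type = 7)),
         D2 = unname(quantile(d, probs = 0.98, type = 7)))
}

#' Percentage point difference of a DVH metric
#'
#' `PPD = 100 * (ref - eval) / ref`, signed: positive means the evaluated
#' (sCT-based) dose is lower than the reference (CT-based) one.
#'
#' @param ref_value reference DVH point in Gy (> 0).
#' @param eval_value evaluated DVH point in Gy.
#' @return Signed percentage.
#' @export
ppd <- function(ref_value, eval_value) {
  if (ref_value <= 0)
    stop("ppd: reference value must be > 0", call. = FALSE)
  100 * (ref_value - eval_value) / ref_value
}

#' Dosimetric report: gamma pass rates and DVH point differences
#'
#' @param ref_dose CT-based dose `vol_image` (reference).
#' @param eval_doses named list of sCT-based dose `vol_image`s.
#' @param fov analysis `bin_mask` (gamma within the MRI FOV).
#' @param structures named list of `bin_mask`s (target first by
#'   convention).
#' @param criteria_list list of [gamma_criteria()] to evaluate.
#' @return A tibble: gamma rows (per sct x criteria) and DVH rows (per
#'   sct x structure x metric, with reference/evaluated dose and PPD).
#' @export
dose_report <- function(ref_dose, eval_doses, fov, structures,
                        criteria_list = list(gamma_criteria(3, 3),
                                             gamma_criteria(2, 2))) {
  rows <- list()
  for (nm in names(eval_doses)) {
    ev <- eval_doses[[nm]]
    for (cr in criteria_list) {
      gm <- gamma_map(ref_dose, ev, cr, fov)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sct = nm, kind = "gamma",
        structure = "fov",
        metric = sprintf("pass_%g%%_%gmm_%s", cr$dd_percent, cr$dta_mm,
                         cr$mode),
        reference = NA_real_, evaluated = NA_real_,
        value = gamma_pass_rate(gm))
    }
    for (sn in names(structures)) {
      st <- structures[[sn]]
      for (m in c("D98", "Dmean", "D2")) {
        rv <- dvh_point(ref_dose, st, m)
        ev_v <- dvh_point(ev, st, m)
        rows[[length(rows) + 1]] <- tibble::tibble(
          sct = nm, kind = "dvh", structure = sn, metric = m,
          reference = rv, evaluated = ev_v, value = ppd(rv, ev_v))
      }
    }
  }
  do.call(rbind, rows)
}
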