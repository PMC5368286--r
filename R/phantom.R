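#' Digital phantom specification
#'
#' Defines the study conditions the generator emulates: an ellipsoidal body
#' with bone structures (and, for the head-and-neck style, air cavities),
#' paired CT / T1-like / T2-like contrasts with shared smooth texture,
#' multiplicative MR bias field and additive noise, a spherical target and
#' an organ-at-risk, and a reduced cranio-caudal MRI FOV.
#'
#' Default intensities (mean, sd): CT — soft tissue 40/60, bone 700/120,
#' air/background -1000/0; T2-like MR — soft 300/60, bone 40/15, air 2/1;
#' T1-like MR — soft 200/50, bone 70/20, air 2/1. Bone is CT-bright and
#' MR-dark, air dark in both.
#'
#' @param site_style `"head_neck_like"` (bone + air cavities) or
#'   `"prostate_like"` (bone + soft tissue only).
#' @param shape,spacing_mm grid voxels and voxel size.
#' @param body_semiaxes_mm body ellipsoid semi-axes.
#' @param n_bone,bone_radius_mm bone structure count and typical radius.
#' @param n_air,air_radius_mm air cavity count/radius (head-neck only).
#' @param intensities nested list class -> c(mean, sd) per modality; NULL
#'   for the defaults above.
#' @param bias_amplitude multiplicative MR bias amplitude (fraction).
#' @param noise_sd_ct,noise_sd_mr additive Gaussian noise.
#' @param deformation_amplitude_mm target mean displacement magnitude of
#'   the random inter-subject deformations.
#' @param deformation_smoothness_mm Gaussian smoothness of those fields.
#' @param fov_crop_fraction fraction of the cranio-caudal (z) extent
#'   removed from the MRI FOV (default 0.25).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(site_style = c("head_neck_like", "prostate_like"),
                         shape = c(32L, 32L, 32L),
                         spacing_mm = c(3, 3, 3),
                         body_semiaxes_mm = NULL,
                         n_bone = 2L, bone_radius_mm = 10,
                         n_air = 2L, air_radius_mm = 6,
                         intensities = NULL,
                         bias_amplitude = 0.1,
                         noise_sd_ct = 10, noise_sd_mr = 2,
                         deformation_amplitude_mm = 3,
                         deformation_smoothness_mm = 25,
                         fov_crop_fraction = 0.25) {
  site_style <- match.arg(site_style)
  shape <- as.integer(shape)
  ext <- (shape - 1) * spacing_mm
  if (is.null(body_semiaxes_mm)) body_semiaxes_mm <- 0.42 * ext
  if (is.null(intensities))
    intensities <- list(
      CT = list(soft = c(40, 60), bone = c(700, 120), air = c(-1000, 0)),
      T2 = list(soft = c(300, 60), bone = c(40, 15), air = c(2, 1)),
      T1 = list(soft = c(200, 50), bone = c(70, 20), air = c(2, 1)))
  stopifnot(bias_amplitude >= 0, noise_sd_ct >= 0, noise_sd_mr >= 0,
            deformation_amplitude_mm >= 0, deformation_smoothness_mm > 0,
            fov_crop_fraction > 0, fov_crop_fraction < 1)
  # bone must be CT-bright / MR-dark, air dark in both
  stopifnot(intensities$CT$bone[1] > intensities$CT$soft[1],
            intensities$T2$bone[1] < intensities$T2$soft[1],
            intensities$CT$air[1] < intensities$CT$soft[1],
            intensities$T2$air[1] < intensities$T2$soft[1])
  structure(list(site_style = site_style, shape = shape,
                 spacing_mm = as.numeric(spacing_mm),
                 body_semiaxes_mm = body_semiaxes_mm,
                 n_bone = as.integer(n_bone),
                 bone_radius_mm = bone_radius_mm,
                 n_air = as.integer(n_air), air_radius_mm = air_radius_mm,
                 intensities = intensities,
                 bias_amplitude = bias_amplitude,
                 noise_sd_ct = noise_sd_ct, noise_sd_mr = noise_sd_mr,
                 deformation_amplitude_mm = deformation_amplitude_mm,
                 deformation_smoothness_mm = deformation_smoothness_mm,
                 fov_crop_fraction = fov_crop_fraction),
            class = "phantom_spec")
}

# voxel-center coordinate arrays in mm (identity orientation, origin 0)
coord_arrays <- function(shape, spacing) {
  list(x = array(rep((seq_len(shape[1]) - 1) * spacing[1],
                     times = shape[2] * shape[3]), shape),
       y = array(rep(rep((seq_len(shape[2]) - 1) * spacing[2],
                         each = shape[1]), times = shape[3]), shape),
       z = array(rep((seq_len(shape[3]) - 1) * spacing[3],
                     each = shape[1] * shape[2]), shape))
}

ellipsoid_mask <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

smooth_noise <- function(shape, sigma_vox) {
  f <- array(rnorm(prod(shape)), shape)
  f <- array(cpp_gauss3d(as.numeric(f), shape, rep(sigma_vox, 3)), shape)
  s <- sd(f)
  if (s > 0) f <- f / s
  f
}

# anatomical texture: two-scale field (coarse organs + fine structure) so
# local similarity measures can sense sub-voxel misalignment
anatomy_texture <- function(shape, spacing_mm) {
  coarse <- smooth_noise(shape, 6 / mean(spacing_mm))
  fine <- smooth_noise(shape, 2 / mean(spacing_mm))
  (coarse + fine) / sqrt(2)
}

# structural masks of one anatomy (base case); deterministic given the spec
phantom_masks <- function(spec) {
  shape <- spec$shape; sp <- spec$spacing_mm
  co <- coord_arrays(shape, sp)
  center <- (shape - 1) * sp / 2
  body <- ellipsoid_mask(co, center, spec$body_semiaxes_mm)
  semi <- spec$body_semiaxes_mm
  bone <- array(FALSE, shape)
  # bone structures placed deterministically around the body center
  bone_centers <- list(center + c(0, -0.35 * semi[2], 0),
                       center + c(0, 0.3 * semi[2], 0.3 * semi[3]),
                       center + c(-0.35 * semi[1], 0, -0.3 * semi[3]),
                       center + c(0.35 * semi[1], 0, 0.3 * semi[3]))
  for (b in seq_len(min(spec$n_bone, length(bone_centers)))) {
    r <- spec$bone_radius_mm * c(1, 0.8, 1.4)
    bone <- bone | ellipsoid_mask(co, bone_centers[[b]], r)
  }
  bone <- bone & body
  air <- array(FALSE, shape)
  if (spec$site_style == "head_neck_like" && spec$n_air > 0) {
    air_centers <- list(center + c(0.3 * semi[1], -0.05 * semi[2],
                                   0.25 * semi[3]),
                        center + c(-0.3 * semi[1], 0.15 * semi[2],
                                   -0.25 * semi[3]))
    for (a in seq_len(min(spec$n_air, length(air_centers))))
      air <- air | ellipsoid_mask(co, air_centers[[a]],
                                  rep(spec$air_radius_mm, 3))
    air <- air & body & !bone
  }
  target <- ellipsoid_mask(co, center + c(0, 0.05 * semi[2], 0),
                           rep(0.3 * min(semi), 3)) & body & !bone & !air
  oar <- ellipsoid_mask(co, center + c(0, -0.55 * semi[2], 0),
                        0.22 * min(semi) * c(1.4, 0.8, 1.2)) &
    body & !target
  z0 <- ceiling(spec$fov_crop_fraction * shape[3])
  fov <- array(FALSE, shape)
  fov[, , (z0 + 1):shape[3]] <- TRUE
  list(body = body, bone = bone, air = air, target = target, oar = oar,
       fov = fov)
}

# render CT + MR channels from structural masks and the anatomical texture
# field (the texture deforms with the subject; only noise and bias are
# drawn fresh per acquisition, from the current RNG)
render_case <- function(masks, tex, spec) {
  shape <- spec$shape
  render_mod <- function(tab, noise_sd, bias) {
    v <- array(tab$air[1], shape)
    v[masks$body] <- tab$soft[1] + tab$soft[2] * tex[masks$body]
    v[masks$bone] <- tab$bone[1] + tab$bone[2] * tex[masks$bone]
    v[masks$air] <- tab$air[1] + tab$air[2] * tex[masks$air]
    if (!is.null(bias)) v <- v * bias
    if (noise_sd > 0) v <- v + rnorm(length(v), sd = noise_sd)
    v
  }
  ct <- render_mod(spec$intensities$CT, spec$noise_sd_ct, NULL)
  bias <- if (spec$bias_amplitude > 0)
    1 + spec$bias_amplitude * smooth_noise(shape,
                                           15 / mean(spec$spacing_mm))
  else NULL
  t2 <- pmax(render_mod(spec$intensities$T2, spec$noise_sd_mr, bias), 0)
  t1 <- pmax(render_mod(spec$intensities$T1, spec$noise_sd_mr, bias), 0)
  list(ct = ct, t1 = t1, t2 = t2)
}

masks_to_binmasks <- function(masks, g) {
  lapply(masks, function(m) bin_mask(m, spacing = g$spacing,
                                     origin = g$origin,
                                     orientation = g$orientation))
}

#' Generate one seeded phantom case
#'
#' Deterministic given `(spec, seed)`. CT and MR channels share the grid
#' (intra-subject aligned by construction) and a smooth anatomical texture;
#' the MR channels additionally carry a multiplicative bias field; both get
#' additive Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return A `phantom_case`: `ct`, `mr_channels` (T1, T2), `masks` (body,
#'   bone, air, target, oar, fov), `true_deformation` (NULL for a base
#'   anatomy).
#' @export
generate_phantom <- function(spec, seed = 0L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  g <- grid_spec(spec$shape, spec$spacing_mm)
  masks <- phantom_masks(spec)
  if (!any(masks$target))
    stop("generate_phantom: target does not fit in the body", call. = FALSE)
  tex <- anatomy_texture(spec$shape, spec$spacing_mm)
  vals <- render_case(masks, tex, spec)
  case <- list(
    ct = vol_image(vals$ct, g$spacing, g$origin, g$orientation, "CT"),
    mr_channels = list(
      T1 = vol_image(vals$t1, g$spacing, g$origin, g$orientation, "MR"),
      T2 = vol_image(vals$t2, g$spacing, g$origin, g$orientation, "MR")),
    masks = masks_to_binmasks(masks, g),
    true_deformation = NULL, spec = spec, seed = as.integer(seed))
  class(case) <- "phantom_case"
  case
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case %s> seed %d\n", x$spec$site_style, x$seed))
  print(x$ct)
  invisible(x)
}

# one smooth random deformation field (mm) on grid g; mean |u| = amp
random_deformation <- function(g, amplitude_mm, smoothness_mm) {
  sig <- smoothness_mm / mean(g$spacing)
  U <- array(0, c(g$shape, 3))
  for (comp in 1:3) U[, , , comp] <- smooth_noise(g$shape, sig)
  mag <- sqrt(apply(U^2, 1:3, sum))
  mbar <- mean(mag)
  if (mbar > 0) U <- U * (amplitude_mm / mbar)
  deformation_field(U, g)
}

# deform a base case's masks and anatomical texture, then re-render with
# fresh bias and noise so subjects differ the way scan sessions do
deform_case <- function(base_masks, base_tex, field, spec) {
  g <- field$grid
  warped <- lapply(base_masks, function(m) {
    v <- vol_image(m * 1, g$spacing, g$origin, g$orientation, "LABEL")
    warp(v, field, g, "nearest", fill = 0)$values != 0
  })
  # FOV stays a fixed scanner-side crop, not part of the anatomy
  warped$fov <- base_masks$fov
  tex_w <- warp(vol_image(base_tex, g$spacing, g$origin, g$orientation,
                          "MR"),
                field, g, "trilinear", fill = 0)$values
  vals <- render_case(warped, tex_w, spec)
  list(masks = warped, vals = vals)
}

#' Generate a deformed atlas population plus a held-out subject
#'
#' A base anatomy is deformed by `n + 1` independent smooth random fields;
#' the first `n` become the atlas database (each atlas's MR and CT share
#' one deformation), the last is returned separately as the leave-one-out
#' test subject with its ground-truth CT, masks and deformation.
#'
#' @param spec a [phantom_spec()].
#' @param n number of atlases (>= 3).
#' @param seed integer seed.
#' @return List with `db` (an [atlas_database()]), `held_out` (a
#'   `phantom_case` with `true_deformation`) and `base` (the undeformed
#'   `phantom_case`).
#' @export
generate_atlas_population <- function(spec, n, seed = 0L) {
  if (n < 3) stop("generate_atlas_population: n must be >= 3",
                  call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  g <- grid_spec(spec$shape, spec$spacing_mm)
  base_masks <- phantom_masks(spec)
  base_tex <- anatomy_texture(spec$shape, spec$spacing_mm)
  base_vals <- render_case(base_masks, base_tex, spec)
  base <- list(
    ct = vol_image(base_vals$ct, g$spacing, g$origin, g$orientation, "CT"),
    mr_channels = list(
      T1 = vol_image(base_vals$t1, g$spacing, g$origin, g$orientation,
                     "MR"),
      T2 = vol_image(base_vals$t2, g$spacing, g$origin, g$orientation,
                     "MR")),
    masks = masks_to_binmasks(base_masks, g),
    true_deformation = NULL, spec = spec, seed = as.integer(seed))
  class(base) <- "phantom_case"
  atlases <- vector("list", n)
  held <- NULL
  for (i in seq_len(n + 1)) {
    field <- random_deformation(g, spec$deformation_amplitude_mm,
                                spec$deformation_smoothness_mm)
    dc <- deform_case(base_masks, base_tex, field, spec)
    if (i <= n) {
      atlases[[i]] <- atlas_pair(
        list(T1 = vol_image(dc$vals$t1, g$spacing, g$origin,
                            g$orientation, "MR"),
             T2 = vol_image(dc$vals$t2, g$spacing, g$origin,
                            g$orientation, "MR")),
        vol_image(dc$vals$ct, g$spacing, g$origin, g$orientation, "CT"),
        id = sprintf("atlas%02d", i))
    } else {
      held <- list(
        ct = vol_image(dc$vals$ct, g$spacing, g$origin, g$orientation,
                       "CT"),
        mr_channels = list(
          T1 = vol_image(dc$vals$t1, g$spacing, g$origin, g$orientation,
                         "MR"),
          T2 = vol_image(dc$vals$t2, g$spacing, g$origin, g$orientation,
                         "MR")),
        masks = masks_to_binmasks(dc$masks, g),
        true_deformation = field, spec = spec, seed = as.integer(seed))
      class(held) <- "phantom_case"
    }
  }
  list(db = atlas_database(atlases), held_out = held, base = base)
}

#' Beam specification for the toy dose model
#'
#' @param directions matrix of unit beam direction rows (beam travel
#'   direction; dose upstream of a voxel attenuates along `-direction`).
#' @param fluence entry fluence per beam.
#' @param mu_per_cm linear attenuation per cm of water-equivalent depth.
#' @param sigma_mm lateral Gaussian penumbra sigma.
#' @param prescription_gy mean target dose after scaling.
#' @return A `beam_spec`.
#' @export
beam_spec <- function(directions = rbind(c(1, 0, 0), c(-1, 0, 0),
                                         c(0, 1, 0), c(0, -1, 0)),
                      fluence = 1, mu_per_cm = 0.05, sigma_mm = 15,
                      prescription_gy = 65) {
  directions <- as.matrix(directions)
  if (nrow(directions) < 1) stop("need >= 1 beam", call. = FALSE)
  stopifnot(mu_per_cm > 0, sigma_mm > 0, prescription_gy > 0)
  nrm <- sqrt(rowSums(directions^2))
  directions <- directions / nrm
  structure(list(directions = directions, fluence = fluence,
                 mu_per_cm = mu_per_cm, sigma_mm = sigma_mm,
                 prescription_gy = prescription_gy), class = "beam_spec")
}

#' Density-sensitive toy dose model
#'
#' Per beam, the water-equivalent depth of every voxel is ray-cast through
#' the density volume (inverse HU calibration) along the beam direction;
#' dose = fluence * exp(-mu * WED) * lateral Gaussian around the beam axis
#' through the target centroid. Beams are summed and globally scaled so
#' the target mean equals the prescription. A test harness standing in for
#' a treatment planning system, not a dose engine: it exists so gamma/DVH
#' comparisons respond to HU errors qualitatively.
#'
#' @param ct CT `vol_image` in HU (identity orientation).
#' @param beams a [beam_spec()].
#' @param target non-empty `bin_mask`.
#' @param calibration HU-to-density calibration.
#' @return Dose `vol_image` (Gy).
#' @export
toy_dose <- function(ct, beams, target, calibration = hu_calibration()) {
  if (!any(target$values)) stop("toy_dose: empty target", call. = FALSE)
  if (max(abs(ct$orientation - diag(3))) > 1e-9)
    stop("toy_dose: identity orientation required", call. = FALSE)
  dens <- array(hu_to_density(as.numeric(ct$values), calibration),
                dim(ct$values))
  co <- coord_arrays(dim(ct$values), ct$spacing)
  iso <- c(mean(co$x[target$values]), mean(co$y[target$values]),
           mean(co$z[target$values])) + ct$origin
  total <- array(0, dim(ct$values))
  for (b in seq_len(nrow(beams$directions))) {
    dirv <- beams$directions[b, ]
    dose <- cpp_beam_dose(as.numeric(dens), dim(ct$values), ct$spacing,
                          ct$origin, dirv, iso, beams$fluence,
                          beams$mu_per_cm, beams$sigma_mm,
                          min(ct$spacing) / 2)
    total <- total + array(dose, dim(ct$values))
  }
  mt <- mean(total[target$values])
  if (mt <= 0) stop("toy_dose: beams miss the target", call. = FALSE)
  total <- total * (beams$prescription_gy / mt)
  vol_image(total, ct$spacing, ct$origin, ct$orientation, "DOSE")
}
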