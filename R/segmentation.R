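#' Automatic body (external) contour extraction
#'
#' Threshold (CT: above `ct_threshold` HU; MR: above the Otsu threshold of
#' the intensity histogram), keep the largest 6-connected 3-D component,
#' then fill internal holes so air cavities belong to the body.
#'
#' @param volume a `vol_image`.
#' @param modality `"CT"` or `"MR"`; defaults to the volume's tag.
#' @param ct_threshold CT body threshold in HU (default -250).
#' @return A `bin_mask` with one connected, hole-free body region.
#' @export
extract_body_mask <- function(volume, modality = NULL, ct_threshold = -250) {
  if (is.null(modality)) modality <- volume$modality
  modality <- match.arg(modality, c("CT", "MR"))
  thr <- if (modality == "CT") ct_threshold else otsu_threshold(volume$values)
  fg <- volume$values > thr
  if (!any(fg))
    stop("extract_body_mask: empty foreground after thresholding",
         call. = FALSE)
  lab <- array(cpp_label6(as.logical(fg), dim(fg)), dim(fg))
  counts <- tabulate(lab[lab > 0])
  body <- lab == which.max(counts)
  body <- fill_holes_array(body)
  bin_mask(body, like = volume)
}

# Otsu's histogram threshold (maximum between-class variance), 256 bins
otsu_threshold <- function(x, bins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins)),
                nbins = bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- r[1] + (seq_len(bins) - 0.5) / bins * (r[2] - r[1])
  mu <- cumsum(p * centers)
  mu_t <- mu[bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  centers[which.max(sigma_b)]
}

fill_holes_array <- function(mask) {
  reach <- array(cpp_border_background(as.logical(mask), dim(mask)),
                 dim(mask))
  mask | (!reach)
}

#' Binary morphology with a physical-radius ball
#'
#' The ball structuring element's physical radius is converted to voxels per
#' axis (rounded half-up, minimum 1 voxel whenever `radius_mm > 0`), so
#' anisotropic voxels give an anisotropic voxel-space ellipsoid that is a
#' ball in mm. `radius_mm = 0` is the identity.
#'
#' @param mask a `bin_mask`.
#' @param op one of `"dilate"`, `"erode"`, `"close"`, `"open"`,
#'   `"fill_holes"`.
#' @param radius_mm structuring-element radius in mm (ignored by
#'   `"fill_holes"`).
#' @return A `bin_mask`.
#' @export
mask_morphology <- function(mask,
                            op = c("dilate", "erode", "close", "open",
                                   "fill_holes"),
                            radius_mm = 0) {
  op <- match.arg(op)
  if (radius_mm < 0) stop("radius_mm must be >= 0", call. = FALSE)
  if (op == "fill_holes")
    return(bin_mask(fill_holes_array(mask$values), like = mask))
  if (radius_mm == 0) return(mask)
  se <- ball_offsets(radius_mm, mask$spacing)
  m <- as.logical(mask$values)
  d <- dim(mask$values)
  out <- switch(op,
    dilate = cpp_morph(m, d, se, 0L),
    erode = cpp_morph(m, d, se, 1L),
    close = cpp_morph(cpp_morph(m, d, se, 0L), d, se, 1L),
    open = cpp_morph(cpp_morph(m, d, se, 1L), d, se, 0L))
  bin_mask(array(out, d), like = mask)
}

# voxel offsets of a ball of physical radius radius_mm
ball_offsets <- function(radius_mm, spacing) {
  rv <- pmax(1L, as.integer(floor(radius_mm / spacing + 0.5)))
  g <- expand.grid(x = -rv[1]:rv[1], y = -rv[2]:rv[2], z = -rv[3]:rv[3])
  keep <- (g$x / rv[1])^2 + (g$y / rv[2])^2 + (g$z / rv[3])^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}
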