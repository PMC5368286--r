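#' Atlas MR/CT pair
#'
#' An intra-subject-aligned set: one or more MR channels plus the planning
#' CT, all on one grid.
#'
#' @param mr_channels named list of `vol_image`s (MR channels).
#' @param ct a `vol_image` in HU, grid-compatible with the MR channels.
#' @param id atlas label.
#' @return An `atlas_pair`.
#' @export
atlas_pair <- function(mr_channels, ct, id) {
  if (inherits(mr_channels, "vol_image")) mr_channels <- list(mr_channels)
  if (length(mr_channels) < 1) stop("need >= 1 MR channel", call. = FALSE)
  if (is.null(names(mr_channels)))
    names(mr_channels) <- paste0("ch", seq_along(mr_channels))
  for (m in mr_channels) stop_if_incompatible(m, ct, "atlas members")
  structure(list(mr_channels = mr_channels, ct = ct, id = id),
            class = "atlas_pair")
}

#' Atlas database
#'
#' @param atlases list of [atlas_pair()]s exposing identical channel names;
#'   at least 2 for meaningful fusion.
#' @return An `atlas_database`.
#' @export
atlas_database <- function(atlases) {
  if (length(atlases) < 1) stop("empty atlas database", call. = FALSE)
  chn <- names(atlases[[1]]$mr_channels)
  for (a in atlases)
    if (!identical(names(a$mr_channels), chn))
      stop("all atlases must expose the same channel names", call. = FALSE)
  structure(list(atlases = atlases, channel_names = chn),
            class = "atlas_database")
}

#' @export
print.atlas_database <- function(x, ...) {
  cat(sprintf("<atlas_database> %d atlases, channels: %s\n",
              length(x$atlases), paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Local normalized cross-correlation map
#'
#' Windowed Pearson correlation with a Gaussian window: local means,
#' variances and covariance are Gaussian-weighted (sigma in mm, converted
#' per axis); LNCC = cov / (sd_t * sd_a). Voxels where either local sd is
#' below `eps` times the image's dynamic range get similarity 0.
#'
#' @param target,mapped_atlas grid-compatible `vol_image`s.
#' @param sigma_mm Gaussian window sigma in mm (default 3).
#' @param eps relative sd floor (default 1e-6 of the dynamic range).
#' @return A `similarity_map` (values in \[-1, 1\]).
#' @export
lncc_map <- function(target, mapped_atlas, sigma_mm = 3, eps = 1e-6) {
  stop_if_incompatible(target, mapped_atlas, "lncc inputs")
  if (sigma_mm <= 0) stop("sigma_mm must be > 0", call. = FALSE)
  d <- dim(target$values)
  sig <- sigma_mm / target$spacing
  g <- function(x) array(cpp_gauss3d(as.numeric(x), d, sig), d)
  t_ <- target$values
  a_ <- mapped_atlas$values
  mt <- g(t_); ma <- g(a_)
  vt <- pmax(g(t_ * t_) - mt^2, 0)
  va <- pmax(g(a_ * a_) - ma^2, 0)
  cov <- g(t_ * a_) - mt * ma
  floor_t <- eps * max(diff(range(t_)), .Machine$double.eps)
  floor_a <- eps * max(diff(range(a_)), .Machine$double.eps)
  st <- sqrt(vt); sa <- sqrt(va)
  lncc <- ifelse(st < floor_t | sa < floor_a, 0, cov / (st * sa))
  lncc <- pmin(pmax(lncc, -1), 1)
  structure(list(values = array(lncc, d), grid = grid_of(target),
                 atlas_id = mapped_atlas$modality,
                 kernel_sigma_mm = sigma_mm),
            class = "similarity_map")
}

#' Spatially-varying fusion weights from similarity maps
#'
#' At each voxel, atlases are ranked by similarity (descending, ties broken
#' by atlas index); the `top_k` best get weight proportional to
#' `exp(-beta * rank)` (rank 0 = most similar) under the default `"rank"`
#' scheme, or to `exp(beta * similarity)` under `"softmax"`. Weights are
#' normalized to sum 1. Voxels where every similarity is NA are excluded
#' from the normalization mask.
#'
#' @param sims list of `similarity_map`s (or numeric arrays) on one grid.
#' @param beta non-negative sharpness (default 0.5; 0 = uniform).
#' @param top_k number of atlases kept per voxel (default all).
#' @param scheme `"rank"` (default) or `"softmax"`.
#' @return A `weight_maps` object: list of per-atlas weight arrays plus the
#'   normalization mask.
#' @export
weights_from_similarity <- function(sims, beta = 0.5, top_k = NULL,
                                    scheme = c("rank", "softmax")) {
  scheme <- match.arg(scheme)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  J <- length(sims)
  if (J < 1) stop("need >= 1 similarity map", call. = FALSE)
  if (is.null(top_k)) top_k <- J
  if (top_k < 1 || top_k > J) stop("1 <= top_k <= n_atlases", call. = FALSE)
  grid <- if (inherits(sims[[1]], "similarity_map")) sims[[1]]$grid else NULL
  S <- vapply(sims, function(s)
    as.numeric(if (is.list(s)) s$values else s),
    numeric(length(if (is.list(sims[[1]])) sims[[1]]$values else sims[[1]])))
  defined <- !is.na(S)
  norm_mask <- rowSums(defined) > 0
  S[!defined] <- -Inf
  # rank r_j = #(better) + #(equal with smaller index): a per-voxel
  # permutation 0..J-1 whenever similarities are comparable, which both
  # drives the rank weights and fixes a canonical summation order so the
  # fused sCT is bit-identical under atlas-order permutation
  R <- matrix(0L, nrow(S), J)
  for (j in seq_len(J)) {
    rj <- integer(nrow(S))
    for (jj in seq_len(J)) {
      if (jj == j) next
      rj <- rj + (S[, jj] > S[, j]) +
        ((S[, jj] == S[, j]) & (jj < j) & is.finite(S[, j]))
    }
    R[, j] <- rj
  }
  if (scheme == "rank") {
    W <- exp(-beta * R)
    W[R >= top_k] <- 0
  } else {
    W <- exp(beta * S)
    W[R >= top_k] <- 0
  }
  W[!defined] <- 0
  W[!norm_mask, ] <- 0
  tot <- rowSums(W)
  W[norm_mask, ] <- W[norm_mask, , drop = FALSE] / tot[norm_mask]
  nv <- nrow(S)
  ord <- matrix(0L, nv, J)
  for (j in seq_len(J)) ord[cbind(seq_len(nv), R[, j] + 1L)] <- j
  shp <- if (!is.null(grid)) grid$shape else dim(
    if (is.list(sims[[1]])) sims[[1]]$values else sims[[1]])
  structure(list(weights = lapply(seq_len(J),
                                  function(j) array(W[, j], shp)),
                 norm_mask = array(norm_mask, shp), grid = grid,
                 order_idx = ord),
            class = "weight_maps")
}

#' Fuse mapped atlas CTs with spatial weights
#'
#' Voxelwise convex combination inside the normalization mask; outside it
#' the output is -1000 HU (air).
#'
#' @param mapped_cts list of grid-compatible `vol_image`s (HU).
#' @param weights a [weights_from_similarity()] result with matching count.
#' @return A `vol_image` (HU).
#' @export
fuse_ct <- function(mapped_cts, weights) {
  J <- length(mapped_cts)
  if (J != length(weights$weights))
    stop("fuse_ct: weight/CT count mismatch", call. = FALSE)
  for (j in seq_len(J)[-1])
    stop_if_incompatible(mapped_cts[[1]], mapped_cts[[j]], "mapped CTs")
  shp <- dim(mapped_cts[[1]]$values)
  nv <- prod(shp)
  Wm <- vapply(weights$weights, as.numeric, numeric(nv))
  Cm <- vapply(mapped_cts, function(m) as.numeric(m$values), numeric(nv))
  acc <- numeric(nv)
  if (!is.null(weights$order_idx)) {
    # canonical (rank-descending) summation order: permutation-invariant
    # bit-for-bit when similarities are distinct
    vox <- seq_len(nv)
    for (r in J:1) {
      j <- weights$order_idx[, r]
      sel <- cbind(vox, j)
      acc <- acc + Wm[sel] * Cm[sel]
    }
  } else {
    for (j in seq_len(J)) acc <- acc + Wm[, j] * Cm[, j]
  }
  acc <- array(acc, shp)
  acc[!weights$norm_mask] <- -1000
  out <- mapped_cts[[1]]
  out$values <- acc
  out$modality <- "CT"
  out
}

#' Fusion/synthesis configuration
#'
#' @param sigma_mm LNCC Gaussian kernel sigma (default 3 mm).
#' @param beta rank-weight sharpness (default 0.5).
#' @param top_k atlases kept per voxel (default all).
#' @param scheme `"rank"` or `"softmax"` weighting.
#' @param similarity_channel MR channel driving iteration-0 similarity
#'   (default `"T2"` if present, else the first channel).
#' @param registration a [reg_config()] used for all registrations.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(sigma_mm = 3, beta = 0.5, top_k = NULL,
                          scheme = "rank", similarity_channel = NULL,
                          registration = reg_config()) {
  structure(list(sigma_mm = sigma_mm, beta = beta, top_k = top_k,
                 scheme = scheme, similarity_channel = similarity_channel,
                 registration = registration), class = "fusion_config")
}

pick_similarity_channel <- function(channel_names, config) {
  if (!is.null(config$similarity_channel)) {
    stopifnot(config$similarity_channel %in% channel_names)
    return(config$similarity_channel)
  }
  if ("T2" %in% channel_names) "T2" else channel_names[1]
}

#' Multi-atlas synthetic CT (iteration 0)
#'
#' For each atlas: robust affine then non-rigid registration of the shared
#' MR channels onto the target MR, warping of the atlas MR and CT to the
#' target grid, LNCC against the designated similarity channel, rank-based
#' spatial weighting and weighted fusion. Atlases whose registration fails
#' are dropped with a warning; at least 2 must survive.
#'
#' @param target_mrs named list of target MR `vol_image`s (or a single
#'   `vol_image`); names must be a subset of the database channels.
#' @param db an [atlas_database()] (>= 2 atlases).
#' @param config a [fusion_config()].
#' @param seed integer controlling any stochastic step; the pipeline is
#'   reproducible bit-for-bit for a fixed seed.
#' @param body_mask optional `bin_mask` on the target grid focusing the
#'   registration similarity.
#' @return A `synthesis_result`: `sct`, `weights`, `mapped_cts`,
#'   `mapped_mrs`, `affines`, `iteration = 0`.
#' @export
synthesize <- function(target_mrs, db, config = fusion_config(),
                       seed = 0L, body_mask = NULL) {
  if (inherits(target_mrs, "vol_image")) {
    target_mrs <- list(target_mrs)
    names(target_mrs) <- db$channel_names[1]
  }
  if (length(db$atlases) < 2)
    stop("synthesize: atlas database must contain >= 2 atlases",
         call. = FALSE)
  if (!all(names(target_mrs) %in% db$channel_names))
    stop("target channels must be a subset of the database channels",
         call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  chans <- names(target_mrs)
  sim_ch <- pick_similarity_channel(chans, config)
  target_grid <- grid_of(target_mrs[[1]])
  reg <- config$registration
  mapped_cts <- list(); mapped_mrs <- list(); affines <- list()
  ids <- character(0)
  for (a in db$atlases) {
    res <- tryCatch({
      aff <- affine_register(target_mrs[[sim_ch]], a$mr_channels[[sim_ch]],
                             reg)
      field <- nonrigid_register(unname(target_mrs[chans]),
                                 unname(a$mr_channels[chans]),
                                 init = aff, config = reg,
                                 mask = body_mask)
      mct <- warp(a$ct, field, target_grid, "trilinear")
      mmr <- lapply(a$mr_channels[chans], warp, transform = field,
                    target = target_grid, interpolation = "trilinear")
      list(ct = mct, mrs = mmr, aff = aff)
    }, error = function(e) {
      warning(sprintf("atlas '%s' dropped: %s", a$id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      mapped_cts <- c(mapped_cts, list(res$ct))
      mapped_mrs <- c(mapped_mrs, list(res$mrs))
      affines <- c(affines, list(res$aff))
      ids <- c(ids, a$id)
    }
  }
  if (length(mapped_cts) < 2)
    stop("synthesize: fewer than 2 atlases survived registration",
         call. = FALSE)
  sims <- lapply(mapped_mrs, function(m)
    lncc_map(target_mrs[[sim_ch]], m[[sim_ch]], config$sigma_mm))
  w <- weights_from_similarity(sims, beta = config$beta,
                               top_k = config$top_k, scheme = config$scheme)
  sct <- fuse_ct(mapped_cts, w)
  structure(list(sct = sct, weights = w, mapped_cts = mapped_cts,
                 mapped_mrs = mapped_mrs, affines = affines,
                 atlas_ids = ids, iteration = 0L,
                 config = config, target_channels = chans,
                 similarity_channel = sim_ch),
            class = "synthesis_result")
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat(sprintf("<synthesis_result> iteration %d, %d atlases fused\n",
              x$iteration, length(x$mapped_cts)))
  print(x$sct)
  invisible(x)
}

#' Iterative multi-channel refinement of a synthesis
#'
#' Each iteration re-registers every atlas (CT + MR channels) to the
#' current (sCT + target MR) channel set with a multi-channel non-rigid
#' registration, recomputes similarity as the channel-weighted mean of
#' LNCC(sCT, mapped CT) and LNCC(target MR, mapped MR), and re-fuses.
#'
#' @param result a `synthesis_result`.
#' @param target_mrs the target MR channels used in [synthesize()].
#' @param db the same [atlas_database()].
#' @param n_iter number of refinement iterations (>= 1).
#' @param config a [fusion_config()]; NULL reuses the result's.
#' @param body_mask optional registration mask.
#' @return The refined `synthesis_result` (iteration incremented).
#' @export
refine <- function(result, target_mrs, db, n_iter = 1, config = NULL,
                   body_mask = NULL) {
  if (n_iter < 1)
    stop("refine: n_iter must be >= 1 (call synthesize for iteration 0)",
         call. = FALSE)
  if (inherits(target_mrs, "vol_image")) {
    target_mrs <- list(target_mrs)
    names(target_mrs) <- result$target_channels[1]
  }
  if (is.null(config)) config <- result$config
  chans <- result$target_channels
  target_grid <- grid_of(target_mrs[[1]])
  reg <- config$registration
  keep <- vapply(db$atlases, function(a) a$id %in% result$atlas_ids,
                 logical(1))
  atlases <- db$atlases[keep]
  for (it in seq_len(n_iter)) {
    fixed_ch <- c(list(result$sct), unname(target_mrs[chans]))
    mapped_cts <- list(); mapped_mrs <- list()
    for (ai in seq_along(atlases)) {
      a <- atlases[[ai]]
      moving_ch <- c(list(a$ct), unname(a$mr_channels[chans]))
      field <- nonrigid_register(fixed_ch, moving_ch,
                                 init = result$affines[[ai]],
                                 config = reg, mask = body_mask)
      mapped_cts[[ai]] <- warp(a$ct, field, target_grid, "trilinear")
      mapped_mrs[[ai]] <- lapply(a$mr_channels[chans], warp,
                                 transform = field, target = target_grid,
                                 interpolation = "trilinear")
    }
    sims <- lapply(seq_along(atlases), function(ai) {
      s <- lncc_map(result$sct, mapped_cts[[ai]], config$sigma_mm)$values
      for (ch in chans)
        s <- s + lncc_map(target_mrs[[ch]], mapped_mrs[[ai]][[ch]],
                          config$sigma_mm)$values
      structure(list(values = s / (1 + length(chans)), grid = target_grid,
                     atlas_id = atlases[[ai]]$id,
                     kernel_sigma_mm = config$sigma_mm),
                class = "similarity_map")
    })
    w <- weights_from_similarity(sims, beta = config$beta,
                                 top_k = config$top_k,
                                 scheme = config$scheme)
    result$sct <- fuse_ct(mapped_cts, w)
    result$weights <- w
    result$mapped_cts <- mapped_cts
    result$mapped_mrs <- mapped_mrs
    result$iteration <- result$iteration + 1L
  }
  result
}

#' Map a synthetic CT back to the planning-CT space
#'
#' @param result a `synthesis_result`.
#' @param mr_to_ct_field `deformation_field` on the CT grid mapping CT
#'   voxels into MR space (pull-back).
#' @param ct_grid target `grid_spec`.
#' @return The sCT resampled on the CT grid.
#' @export
map_to_ct_space <- function(result, mr_to_ct_field, ct_grid) {
  warp(result$sct, mr_to_ct_field, ct_grid, "trilinear")
}

#' Write/read an atlas database manifest (YAML) with NIfTI members
#'
#' The manifest lists, per atlas, a path per MR channel and the CT path.
#'
#' @param db an `atlas_database`.
#' @param dir output directory (volumes written as NIfTI).
#' @return Path to the manifest (write); an `atlas_database` (read).
#' @export
write_atlas_database <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(db$atlases, function(a) {
    chans <- list()
    for (ch in names(a$mr_channels)) {
      p <- file.path(dir, sprintf("%s_%s.nii.gz", a$id, ch))
      write_nifti_volume(a$mr_channels[[ch]], p)
      chans[[ch]] <- basename(p)
    }
    ctp <- file.path(dir, sprintf("%s_ct.nii.gz", a$id))
    write_nifti_volume(a$ct, ctp)
    list(id = a$id, channels = chans, ct = basename(ctp))
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(channel_names = db$channel_names,
                        atlases = entries), manifest)
  invisible(manifest)
}

#' @rdname write_atlas_database
#' @param path manifest path.
#' @export
read_atlas_database <- function(path) {
  m <- yaml::read_yaml(path)
  dir <- dirname(path)
  atlases <- lapply(m$atlases, function(e) {
    mrs <- lapply(e$channels, function(p)
      read_nifti_volume(file.path(dir, p), modality = "MR"))
    atlas_pair(mrs, read_nifti_volume(file.path(dir, e$ct), "CT"), e$id)
  })
  atlas_database(atlases)
}
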