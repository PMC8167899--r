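#' Anisotropy-aware scale-normalized 3D Laplacian-of-Gaussian filter
#'
#' Smooths the volume with a separable Gaussian whose per-axis sigma in
#' voxels is `radius_um / sqrt(3)` divided by that axis's voxel size (the
#' optimal LoG scale for a 3D Gaussian blob of the given characteristic
#' radius), applies the 3D Laplacian in physical units, and multiplies by
#' `sigma_um^2` for scale normalization. Bright blobs of matching radius
#' yield negative response minima of comparable depth across scales.
#'
#' @param volume Numeric 3D array (z, y, x).
#' @param radius_um Characteristic blob radius in micrometres (> 0).
#' @param voxel_size_um Voxel size `(z, y, x)` in micrometres.
#' @return Response array, same shape as `volume`.
#' @export
log_filter_3d <- function(volume, radius_um, voxel_size_um) {
  if (radius_um <= 0) stop("`radius_um` must be positive")
  d <- dim(volume)
  if (length(d) != 3L) stop("`volume` must be a 3D array (z, y, x)")
  sigma_um <- radius_um / sqrt(3)
  sigma_vox <- sigma_um / voxel_size_um
  if (any(sigma_vox < 0.5))
    warning("LoG scale is undersampled (sigma < 0.5 voxel on some axis)")
  sm <- volume
  for (ax in 1:3) {
    half <- max(1L, ceiling(3.5 * sigma_vox[ax]))
    k <- exp(-((-half:half)^2) / (2 * sigma_vox[ax]^2))
    k <- k / sum(k)
    sm <- array(.conv1d_axis3d(sm, d, k, ax - 1L), dim = d)
  }
  lap <- array(0, dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    d2 <- switch(ax,
                 sm[ip, , , drop = FALSE] - 2 * sm + sm[im, , , drop = FALSE],
                 sm[, ip, , drop = FALSE] - 2 * sm + sm[, im, , drop = FALSE],
                 sm[, , ip, drop = FALSE] - 2 * sm + sm[, , im, drop = FALSE])
    lap <- lap + array(d2, dim = d) / voxel_size_um[ax]^2
  }
  lap * sigma_um^2
}

#' Find 3D local minima of a LoG response
#'
#' Voxels strictly smaller than all 26-connected neighbours and with negative
#' response become candidates; positions are refined per axis by a quadratic
#' fit through the voxel and its two neighbours (offset clamped to half a
#' voxel) and converted to micrometres. Quality is minus the response value.
#'
#' @param response Response array from [log_filter_3d()].
#' @param voxel_size_um Voxel size `(z, y, x)` in micrometres.
#' @return Tibble with `z_um`, `y_um`, `x_um`, `quality` (possibly empty),
#'   sorted in scan order (z fastest).
#' @export
find_local_minima <- function(response, voxel_size_um) {
  d <- dim(response)
  idx <- .local_minima3d(response, d)
  if (length(idx) == 0)
    return(tibble(z_um = numeric(), y_um = numeric(), x_um = numeric(),
                  quality = numeric()))
  sub <- arrayInd(idx, d)
  # per-axis quadratic subvoxel refinement
  refined <- matrix(NA_real_, nrow(sub), 3)
  for (ax in 1:3) {
    i0 <- sub[, ax]
    im <- pmax(i0 - 1L, 1L); ip <- pmin(i0 + 1L, d[ax])
    get_at <- function(shifted) {
      s2 <- sub; s2[, ax] <- shifted
      response[cbind(s2[, 1], s2[, 2], s2[, 3])]
    }
    y0 <- response[idx]; ym <- get_at(im); yp <- get_at(ip)
    denom <- ym - 2 * y0 + yp
    frac <- ifelse(denom > 0, pmax(-0.5, pmin(0.5, 0.5 * (ym - yp) / denom)), 0)
    refined[, ax] <- (i0 - 1 + frac) * voxel_size_um[ax]
  }
  tibble(z_um = refined[, 1], y_um = refined[, 2], x_um = refined[, 3],
         quality = -response[idx])
}

#' Strongest-minima pruning of detection candidates
#'
#' Discards candidates below the quality threshold, then greedily suppresses
#' near-duplicates: candidates are visited in decreasing quality (ties broken
#' by scan order, i.e. input row), and one is accepted only if no
#' already-accepted candidate lies within the suppression radius
#' (micrometre-space Euclidean distance). When candidates carry their own
#' `radius_um` column and `radius_um = NULL`, the pairwise suppression radius
#' is the larger of the two candidates' radii (used when merging detection
#' scales).
#'
#' @param candidates Tibble with `z_um`, `y_um`, `x_um`, `quality` and
#'   optionally `radius_um`.
#' @param radius_um Scalar suppression radius, or `NULL` to use per-candidate
#'   radii.
#' @param quality_threshold Minimum quality retained (default 0).
#' @return Pruned tibble (original row order preserved within the result).
#' @export
prune_candidates <- function(candidates, radius_um = NULL,
                             quality_threshold = 0) {
  keep <- candidates$quality >= quality_threshold
  cand <- candidates[keep, , drop = FALSE]
  if (nrow(cand) <= 1) return(cand)
  ord <- order(-cand$quality, seq_len(nrow(cand)))
  pos <- as.matrix(cand[, c("z_um", "y_um", "x_um")])
  rad <- if (is.null(radius_um)) cand$radius_um else rep(radius_um, nrow(cand))
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) > 0) {
      dist <- sqrt(colSums((t(pos[accepted, , drop = FALSE]) - pos[i, ])^2))
      lim <- pmax(rad[accepted], rad[i])
      if (any(dist < lim)) next
    }
    accepted <- c(accepted, i)
  }
  cand[sort(accepted), , drop = FALSE]
}

#' Detect nuclei in every frame of a movie
#'
#' Runs the adjusted 3D LoG filter, 3D local-minima detection and
#' strongest-minima pruning at one or more characteristic radii (by default
#' the two nuclear populations' radii, 1.5 and 3 um), then merges scales with
#' cross-scale pruning. Each detection's estimated diameter is twice its
#' detection-scale radius. If a drift table is supplied the movie is
#' drift-compensated first; returned coordinates are then in compensated
#' space and can be mapped back with [restore_coordinates()].
#'
#' @param movie A [movie_stack()].
#' @param radius_um Vector of characteristic radii (um), one per scale.
#' @param quality_threshold Minimum detection quality; `NULL` (default) uses
#'   5 times the standard deviation of each scale's response volume, which
#'   sits far above the deepest minima a pure-noise response produces.
#' @param drift Optional drift table (see [estimate_drift()]).
#' @return Tibble: `frame`, `z_um`, `y_um`, `x_um`, `quality`, `radius_um`,
#'   `diameter_um`.
#' @export
detect_nuclei <- function(movie, radius_um = c(1.5, 3.0),
                          quality_threshold = NULL, drift = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  nt <- n_frames(movie)
  if (nt < 1 || length(movie$data) == 0) stop("empty movie")
  if (!is.null(drift)) movie <- apply_drift(movie, drift)
  voxel <- movie$voxel_size_um
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    vol <- movie_frame(movie, t)
    per_scale <- lapply(radius_um, function(r) {
      resp <- log_filter_3d(vol, r, voxel)
      thr <- if (is.null(quality_threshold)) 5 * sd(resp) else quality_threshold
      cand <- find_local_minima(resp, voxel)
      cand$radius_um <- r
      prune_candidates(cand, radius_um = r, quality_threshold = thr)
    })
    merged <- prune_candidates(dplyr::bind_rows(per_scale), radius_um = NULL,
                               quality_threshold = 0)
    if (nrow(merged) > 0) merged$frame <- t
    out[[t]] <- merged
  }
  det <- dplyr::bind_rows(out)
  if (nrow(det) == 0)
    return(tibble(frame = integer(), z_um = numeric(), y_um = numeric(),
                  x_um = numeric(), quality = numeric(), radius_um = numeric(),
                  diameter_um = numeric()))
  det$diameter_um <- 2 * det$radius_um
  dplyr::select(det, "frame", "z_um", "y_um", "x_um", "quality",
                "radius_um", "diameter_um")
}
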