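# integer + subpixel displacement of b relative to a (b ~ a translated by +d)
# via FFT cross-correlation of mean-subtracted images; when `center` and
# `window` are given, the correlation peak is searched only within
# `center +/- window` (resolving the circular-shift ambiguity from a
# prediction)
xcorr_displacement <- function(a, b, center = NULL, window = NULL) {
  a <- a - mean(a); b <- b - mean(b)
  if (all(a == 0) || all(b == 0)) {
    warning("blank frame in drift estimation; assuming zero shift")
    return(c(0, 0))
  }
  r <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  d <- dim(r)
  search <- r
  if (!is.null(center)) {
    mask <- matrix(TRUE, d[1], d[2])
    for (ax in 1:2) {
      allowed <- (round(center[ax]) + (-window:window)) %% d[ax] + 1
      drop_idx <- setdiff(seq_len(d[ax]), unique(allowed))
      if (ax == 1) mask[drop_idx, ] <- FALSE else mask[, drop_idx] <- FALSE
    }
    search[!mask] <- -Inf
  }
  pk <- arrayInd(which.max(search), d)
  out <- numeric(2)
  for (ax in 1:2) {
    n <- d[ax]
    i0 <- pk[ax]
    im <- if (i0 == 1) n else i0 - 1
    ip <- if (i0 == n) 1 else i0 + 1
    idx <- function(i, j) if (ax == 1) r[i, j] else r[j, i]
    other <- pk[3 - ax]
    y0 <- idx(i0, other)
    ym <- idx(im, other); yp <- idx(ip, other)
    denom <- ym - 2 * y0 + yp
    frac <- if (denom < 0) max(-0.5, min(0.5, 0.5 * (ym - yp) / denom)) else 0
    shift <- (i0 - 1) + frac
    if (is.null(center)) {
      if (shift > n / 2) shift <- shift - n
    } else {
      # unwrap toward the predicted displacement
      k <- round((center[ax] - shift) / n)
      shift <- shift + k * n
    }
    out[ax] <- shift
  }
  out
}

#' Estimate global drift of a movie
#'
#' Each frame's translation is estimated by FFT cross-correlation of
#' maximum-intensity projections (z-projection for the lateral shift,
#' y-projection for the axial one) in two passes: consecutive frame pairs
#' give a cumulative prediction that can follow arbitrarily large total
#' displacement, and a correlation against the first frame — with the peak
#' search restricted to a small window around the prediction — removes the
#' accumulation of per-pair subpixel bias, bounding the error at about one
#' voxel independent of sequence length. The refined displacement is rounded
#' to integer voxels. Note that any motion coherent across the field
#' (including coordinated migration) is part of the estimated "overall
#' movement", not only mounting drift.
#'
#' @param movie A [movie_stack()] with at least 2 frames.
#' @return A drift table: tibble with columns `frame`, `dz`, `dy`, `dx`
#'   (cumulative integer voxel displacement of the field relative to frame
#'   1; frame 1 row is zero).
#' @export
estimate_drift <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  nt <- n_frames(movie)
  if (nt < 2) stop("need at least 2 frames to estimate drift")
  cum <- matrix(0, nt, 3)
  mip <- function(vol, axis) {
    d <- dim(vol)
    slices <- lapply(seq_len(d[axis]), function(i)
      switch(axis, vol[i, , ], vol[, i, ], vol[, , i]))
    do.call(pmax, slices)
  }
  ref <- movie_frame(movie, 1)
  mz_ref <- mip(ref, 1); my_ref <- mip(ref, 2)
  mz_prev <- mz_ref; my_prev <- my_ref
  pred <- c(0, 0, 0)
  for (t in 2:nt) {
    cur <- movie_frame(movie, t)
    mz_cur <- mip(cur, 1)   # (y, x)
    my_cur <- mip(cur, 2)   # (z, x)
    # consecutive-pair prediction, then windowed reference-frame refinement
    step_yx <- xcorr_displacement(mz_prev, mz_cur)
    step_zx <- xcorr_displacement(my_prev, my_cur)
    pred <- pred + c(step_zx[1], step_yx[1], step_yx[2])
    dyx <- xcorr_displacement(mz_ref, mz_cur, center = pred[2:3], window = 6L)
    dzx <- xcorr_displacement(my_ref, my_cur, center = pred[c(1, 3)],
                              window = 6L)
    cum[t, ] <- c(dzx[1], dyx[1], dyx[2])
    pred <- cum[t, ]
    mz_prev <- mz_cur; my_prev <- my_cur
  }
  tibble(frame = seq_len(nt),
         dz = as.integer(round(cum[, 1])),
         dy = as.integer(round(cum[, 2])),
         dx = as.integer(round(cum[, 3])))
}

# shift a 3D array so that new(x) = old(x + s); vacated voxels get `fill`
shift_volume <- function(vol, s, fill) {
  d <- dim(vol)
  if (any(abs(s) >= d)) stop("drift shift exceeds the image extent")
  out <- array(fill, dim = d)
  dst <- lapply(1:3, function(ax) max(1, 1 - s[ax]):min(d[ax], d[ax] - s[ax]))
  src <- lapply(1:3, function(ax) dst[[ax]] + s[ax])
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

# modal intensity of a stack after rounding (used as the fill value)
modal_background <- function(x) {
  tb <- tabulate(as.integer(round(as.numeric(x))) + 1L)
  which.max(tb) - 1L
}

#' Apply a drift table to a movie
#'
#' Uniformly shifts each frame by minus its cumulative drift so the field is
#' stationary; vacated voxels are filled with the stack's modal background
#' value.
#'
#' @param movie A [movie_stack()].
#' @param drift Drift table from [estimate_drift()] (or ground truth),
#'   with one row per frame.
#' @return A drift-compensated [movie_stack()].
#' @export
apply_drift <- function(movie, drift) {
  stopifnot(inherits(movie, "movie_stack"))
  nt <- n_frames(movie)
  if (nrow(drift) != nt) stop("drift table length must match frame count")
  fill <- modal_background(movie$data)
  out <- movie$data
  for (t in seq_len(nt)) {
    s <- c(drift$dz[t], drift$dy[t], drift$dx[t])
    if (any(s != 0))
      out[t, , , ] <- shift_volume(movie_frame(movie, t), s, fill)
  }
  movie_stack(out, movie$voxel_size_um, movie$frame_interval_min)
}

#' Restore original acquisition coordinates of detections
#'
#' Inverts the image shifts of [apply_drift()] on point coordinates: the
#' cumulative drift (in micrometres) of each point's frame is added back, so
#' positions detected on the compensated movie return to the original
#' acquisition frame.
#'
#' @param points Tibble with columns `frame`, `z_um`, `y_um`, `x_um`.
#' @param drift Drift table (integer voxels) used for compensation.
#' @param voxel_size_um Voxel size `(z, y, x)` in micrometres.
#' @return `points` with coordinates shifted back.
#' @export
restore_coordinates <- function(points, drift, voxel_size_um) {
  if (nrow(points) == 0) return(points)
  if (any(points$frame < 1 | points$frame > nrow(drift)))
    stop("point frame index outside the drift table")
  i <- match(points$frame, drift$frame)
  points$z_um <- points$z_um + drift$dz[i] * voxel_size_um[1]
  points$y_um <- points$y_um + drift$dy[i] * voxel_size_um[2]
  points$x_um <- points$x_um + drift$dx[i] * voxel_size_um[3]
  points
}
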