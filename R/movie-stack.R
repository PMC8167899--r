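#' Calibrated 4D movie stack
#'
#' Container for a time-lapse volume with axis order (t, z, y, x) and physical
#' calibration. Voxel `(iz, iy, ix)` (1-based) sits at
#' `((iz - 1) * vz, (iy - 1) * vy, (ix - 1) * vx)` micrometres.
#'
#' @param data Numeric 4D array with dimensions (t, z, y, x).
#' @param voxel_size_um Numeric length-3 vector `(z, y, x)` of voxel sizes in
#'   micrometres; all strictly positive.
#' @param frame_interval_min Time between frames in minutes; strictly positive.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, voxel_size_um, frame_interval_min) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array with axes (t, z, y, x)")
  voxel_size_um <- unname(as.numeric(voxel_size_um))
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be 3 positive numbers (z, y, x)")
  if (!is.numeric(frame_interval_min) || length(frame_interval_min) != 1L ||
      frame_interval_min <= 0)
    stop("`frame_interval_min` must be a single positive number")
  structure(
    list(data = data,
         voxel_size_um = voxel_size_um,
         frame_interval_min = as.numeric(frame_interval_min)),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames, %d x %d x %d voxels (z,y,x)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (z,y,x): %s um; frame interval: %g min\n",
              paste(signif(x$voxel_size_um, 3), collapse = " x "),
              x$frame_interval_min))
  invisible(x)
}

n_frames <- function(movie) dim(movie$data)[1]

movie_frame <- function(movie, t) {
  d <- dim(movie$data)
  array(movie$data[t, , , ], dim = d[2:4])
}

#' Write a movie stack to a multi-page TIFF with a JSON calibration sidecar
#'
#' Frames and z-slices are stored as consecutive TIFF pages in (t, z) order;
#' the sidecar `<path>.json` records the shape, voxel sizes and frame
#' interval so the movie round-trips exactly through [read_movie_tiff()].
#' Intensities are scaled by `max_value` into the unit range the TIFF writer
#' expects.
#'
#' @param movie A [movie_stack()].
#' @param path Output TIFF path.
#' @param max_value Full-scale intensity (default 255).
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, max_value = 255) {
  d <- dim(movie$data)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[k]] <- matrix(movie$data[t, z, , ], d[3], d[4]) / max_value
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(shape_tzyx = as.integer(d),
               voxel_size_um = movie$voxel_size_um,
               frame_interval_min = movie$frame_interval_min,
               max_value = max_value)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie stack written by [write_movie_tiff()]
#'
#' @param path TIFF path; `<path>.json` must exist.
#' @return A [movie_stack()].
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape_tzyx)
  data <- array(0, dim = d)
  k <- 1L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      data[t, z, , ] <- pages[[k]] * meta$max_value
      k <- k + 1L
    }
  }
  movie_stack(data, meta$voxel_size_um, meta$frame_interval_min)
}
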