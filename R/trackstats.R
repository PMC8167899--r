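#' Instantaneous speeds along tracks
#'
#' The 3D Euclidean frame-to-frame displacement of each track, divided by the
#' frame interval.
#'
#' @param tracks Tracks tibble (`track_id`, `frame`, `z_um`, `y_um`, `x_um`).
#' @param frame_interval_min Frame interval in minutes.
#' @return Tibble with one row per consecutive frame pair per track:
#'   `track_id`, `frame` (the later frame), per-axis velocity components
#'   (um/min) and `speed_um_per_min`.
#' @export
instantaneous_speeds <- function(tracks, frame_interval_min) {
  if (frame_interval_min <= 0) stop("`frame_interval_min` must be positive")
  out <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      vz = (.data$z_um - dplyr::lag(.data$z_um)) / frame_interval_min,
      vy = (.data$y_um - dplyr::lag(.data$y_um)) / frame_interval_min,
      vx = (.data$x_um - dplyr::lag(.data$x_um)) / frame_interval_min) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$vz))
  if (nrow(out) == 0) stop("tracks need at least 2 detections for speeds")
  out$speed_um_per_min <- sqrt(out$vz^2 + out$vy^2 + out$vx^2)
  dplyr::select(out, "track_id", "frame", "vz", "vy", "vx",
                "speed_um_per_min")
}

#' Per-track average velocity
#'
#' Arithmetic mean of the instantaneous speeds of each track, in um/min.
#'
#' @inheritParams instantaneous_speeds
#' @return Tibble `track_id`, `velocity_um_per_min`.
#' @export
track_velocity <- function(tracks, frame_interval_min) {
  instantaneous_speeds(tracks, frame_interval_min) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(velocity_um_per_min = mean(.data$speed_um_per_min),
                     .groups = "drop")
}

#' Directional persistence of tracks
#'
#' Net displacement (start to end) divided by total path length; 1 for a
#' straight path, 0 for a path returning to its start. Zero-path-length
#' tracks get `NA` with a warning.
#'
#' @param tracks Tracks tibble.
#' @return Tibble `track_id`, `persistence`.
#' @export
directional_persistence <- function(tracks) {
  out <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      net = sqrt((dplyr::last(.data$z_um) - dplyr::first(.data$z_um))^2 +
                   (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2 +
                   (dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2),
      path = sum(sqrt(diff(.data$z_um)^2 + diff(.data$y_um)^2 +
                        diff(.data$x_um)^2)),
      .groups = "drop")
  if (any(out$path == 0))
    warning("zero-path-length track(s): persistence undefined")
  tibble(track_id = out$track_id,
         persistence = ifelse(out$path > 0, out$net / out$path, NA_real_))
}

#' Coordination with the nearest neighbouring track
#'
#' For each track, the partner is the track whose first-frame position is
#' nearest (self excluded; ties broken by lower track id). Coordination is
#' the Pearson correlation between the two tracks' instantaneous-velocity
#' series over their common frames, computed on the concatenated (z, y, x)
#' components (`method = "correlation"`, the default, capturing direction and
#' magnitude) or as the mean cosine similarity of the paired velocity
#' vectors (`method = "cosine"`). Zero-variance series give `NA` with a
#' warning.
#'
#' @param tracks Tracks tibble with at least two tracks of overlapping span.
#' @param frame_interval_min Frame interval in minutes.
#' @param method `"correlation"` (default) or `"cosine"`.
#' @return Tibble `track_id`, `partner_track_id`, `coordination`.
#' @export
coordination <- function(tracks, frame_interval_min = 1,
                         method = c("correlation", "cosine")) {
  method <- match.arg(method)
  ids <- sort(unique(tracks$track_id))
  if (length(ids) < 2) stop("coordination needs at least 2 tracks")
  first_pos <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice_min(.data$frame, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$track_id)
  pos <- as.matrix(first_pos[, c("z_um", "y_um", "x_um")])
  vel <- instantaneous_speeds(tracks, frame_interval_min)
  vel_by_id <- split(vel, vel$track_id)
  zero_var <- FALSE
  res <- purrr::map_dfr(seq_along(ids), function(i) {
    d <- sqrt(rowSums((pos - matrix(pos[i, ], nrow(pos), 3,
                                    byrow = TRUE))^2))
    d[i] <- Inf
    j <- which.min(d)   # which.min takes the first (lowest id) on ties
    vi <- vel_by_id[[as.character(ids[i])]]
    vj <- vel_by_id[[as.character(ids[j])]]
    common <- intersect(vi$frame, vj$frame)
    vi <- vi[match(common, vi$frame), ]
    vj <- vj[match(common, vj$frame), ]
    co <- NA_real_
    if (length(common) >= 2) {
      if (method == "correlation") {
        a <- c(vi$vz, vi$vy, vi$vx)
        b <- c(vj$vz, vj$vy, vj$vx)
        if (sd(a) > 0 && sd(b) > 0) co <- cor(a, b) else zero_var <<- TRUE
      } else {
        num <- vi$vz * vj$vz + vi$vy * vj$vy + vi$vx * vj$vx
        den <- sqrt(vi$vz^2 + vi$vy^2 + vi$vx^2) *
          sqrt(vj$vz^2 + vj$vy^2 + vj$vx^2)
        ok <- den > 0
        if (any(ok)) co <- mean(num[ok] / den[ok]) else zero_var <<- TRUE
      }
    }
    tibble(track_id = ids[i], partner_track_id = ids[j], coordination = co)
  })
  if (zero_var) warning("zero-variance velocity series: coordination NA")
  res
}

#' Per-track migration metrics
#'
#' Convenience wrapper computing velocity, directional persistence and
#' coordination for every track, carrying the cell type through.
#'
#' @inheritParams coordination
#' @return Tibble: `track_id`, `cell_type` (if present),
#'   `velocity_um_per_min`, `persistence`, `partner_track_id`,
#'   `coordination`.
#' @export
track_metrics <- function(tracks, frame_interval_min,
                          method = c("correlation", "cosine")) {
  out <- track_velocity(tracks, frame_interval_min) |>
    dplyr::left_join(directional_persistence(tracks), by = "track_id") |>
    dplyr::left_join(coordination(tracks, frame_interval_min,
                                  method = match.arg(method)),
                     by = "track_id")
  if ("cell_type" %in% names(tracks)) {
    types <- dplyr::distinct(tracks, .data$track_id, .data$cell_type)
    out <- dplyr::left_join(out, types, by = "track_id") |>
      dplyr::relocate("cell_type", .after = "track_id")
  }
  out
}

#' Embryo-level summary of track metrics
#'
#' One mean value per metric per cell type for one embryo; warns when a cell
#' type has fewer than `min_tracks` tracks (default 15). Undefined per-track
#' values are dropped from the means, with the contributing count reported.
#'
#' @param metrics Per-track metrics from [track_metrics()].
#' @param embryo_id Identifier recorded in the output.
#' @param min_tracks Expected minimum tracks per cell type.
#' @return Tibble: `embryo_id`, `cell_type`, `n_tracks`,
#'   `velocity_um_per_min`, `persistence`, `coordination` and `n_*` counts of
#'   defined values.
#' @export
embryo_summary <- function(metrics, embryo_id, min_tracks = 15) {
  if (nrow(metrics) == 0) stop("no tracks to summarise")
  if (!"cell_type" %in% names(metrics)) metrics$cell_type <- "all"
  metrics <- dplyr::filter(metrics, .data$cell_type != "unclassified")
  out <- metrics |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n_tracks = dplyr::n(),
      n_velocity = sum(!is.na(.data$velocity_um_per_min)),
      n_persistence = sum(!is.na(.data$persistence)),
      n_coordination = sum(!is.na(.data$coordination)),
      velocity_um_per_min = mean(.data$velocity_um_per_min, na.rm = TRUE),
      persistence = mean(.data$persistence, na.rm = TRUE),
      coordination = mean(.data$coordination, na.rm = TRUE),
      .groups = "drop")
  if (any(out$n_tracks < min_tracks))
    warning(sprintf("fewer than %d tracks for some cell type", min_tracks))
  dplyr::bind_cols(tibble(embryo_id = rep(embryo_id, nrow(out))), out)
}
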