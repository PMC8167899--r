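#' Link detections into tracks by gated frame-to-frame assignment
#'
#' For each consecutive frame pair the optimal linear assignment on squared
#' micrometre distances is solved with birth/death alternatives costed at
#' `max_link_dist_um^2`; links longer than `max_link_dist_um` are forbidden.
#' Unmatched detections terminate their track or start a new one. No gap
#' closing: a missed frame ends a track. Detections are put in a canonical
#' within-frame order first, so the result does not depend on input row
#' order.
#'
#' @param detections Tibble with at least `frame`, `z_um`, `y_um`, `x_um`
#'   (e.g. from [detect_nuclei()]).
#' @param max_link_dist_um Maximum allowed frame-to-frame displacement (um).
#' @param n_frames Total frame count; defaults to `max(detections$frame)`.
#' @return The detections with a `track_id` column, ordered by track then
#'   frame. The summed gated assignment cost is attached as attribute
#'   `"link_cost"`.
#' @export
link_frames <- function(detections, max_link_dist_um = 4, n_frames = NULL) {
  if (max_link_dist_um <= 0) stop("`max_link_dist_um` must be positive")
  det <- dplyr::arrange(as_tibble(detections),
                        .data$frame, .data$z_um, .data$y_um, .data$x_um)
  if (is.null(n_frames)) n_frames <- max(det$frame, 0L)
  track_id <- integer(nrow(det))
  rows_by_frame <- split(seq_len(nrow(det)), factor(det$frame,
                                                    levels = seq_len(n_frames)))
  next_id <- 1L
  total_cost <- 0
  prev_rows <- rows_by_frame[[1]] %||% integer(0)
  if (length(prev_rows) > 0) {
    track_id[prev_rows] <- seq_len(length(prev_rows))
    next_id <- length(prev_rows) + 1L
  }
  pos_of <- function(rows)
    as.matrix(det[rows, c("z_um", "y_um", "x_um"), drop = FALSE])
  for (t in seq_len(max(0L, n_frames - 1L))) {
    cur_rows <- rows_by_frame[[t + 1]] %||% integer(0)
    sol <- assign_frame_pair(pos_of(prev_rows), pos_of(cur_rows),
                             max_link_dist_um)
    total_cost <- total_cost + sol$cost
    linked_b <- rep(FALSE, length(cur_rows))
    if (nrow(sol$links) > 0) {
      track_id[cur_rows[sol$links[, 2]]] <- track_id[prev_rows[sol$links[, 1]]]
      linked_b[sol$links[, 2]] <- TRUE
    }
    new_b <- which(!linked_b)
    if (length(new_b) > 0) {
      track_id[cur_rows[new_b]] <- next_id + seq_along(new_b) - 1L
      next_id <- next_id + length(new_b)
    }
    prev_rows <- cur_rows
  }
  det$track_id <- track_id
  det <- dplyr::arrange(det, .data$track_id, .data$frame)
  det <- dplyr::relocate(det, "track_id")
  attr(det, "link_cost") <- total_cost
  det
}

#' Curate tracks: full span and region of interest
#'
#' Keeps only tracks whose first detection lies inside the given axis-aligned
#' box and which span the whole video (one detection in every frame).
#'
#' @param tracks Tibble from [link_frames()].
#' @param n_frames Total number of frames in the video.
#' @param roi Optional list with elements `z`, `y`, `x`, each `c(min, max)`
#'   in micrometres; `NULL` keeps the full field.
#' @return Curated tracks tibble.
#' @export
curate_tracks <- function(tracks, n_frames, roi = NULL) {
  keep <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      len = dplyr::n(),
      z0 = .data$z_um[which.min(.data$frame)],
      y0 = .data$y_um[which.min(.data$frame)],
      x0 = .data$x_um[which.min(.data$frame)],
      .groups = "drop") |>
    dplyr::filter(.data$len == .env$n_frames)
  if (!is.null(roi)) {
    keep <- dplyr::filter(keep,
      .data$z0 >= roi$z[1], .data$z0 <= roi$z[2],
      .data$y0 >= roi$y[1], .data$y0 <= roi$y[2],
      .data$x0 >= roi$x[1], .data$x0 <= roi$x[2])
  }
  dplyr::filter(tracks, .data$track_id %in% keep$track_id)
}

#' Classify tracks by nuclear diameter
#'
#' Tracks with median estimated diameter below `pmec_max_um` are labelled
#' PMEC, above `icp_min_um` ICP, and in between (or with missing diameters)
#' unclassified; unclassified tracks are excluded from downstream
#' statistics.
#'
#' @param tracks Tracks tibble with a `diameter_um` column.
#' @param pmec_max_um,icp_min_um Classification thresholds in micrometres
#'   (defaults 3.5 and 5.5).
#' @return `tracks` with a `cell_type` column.
#' @export
classify_tracks <- function(tracks, pmec_max_um = 3.5, icp_min_um = 5.5) {
  med <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(med_dia = median(.data$diameter_um, na.rm = TRUE),
                     .groups = "drop")
  if (any(is.na(med$med_dia)))
    warning("tracks without diameter estimates are left unclassified")
  med$cell_type <- dplyr::case_when(
    is.na(med$med_dia) ~ "unclassified",
    med$med_dia < pmec_max_um ~ "PMEC",
    med$med_dia > icp_min_um ~ "ICP",
    TRUE ~ "unclassified")
  tracks$cell_type <- NULL
  dplyr::left_join(tracks, med[, c("track_id", "cell_type")], by = "track_id")
}
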