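#' Match detections to ground-truth nuclei
#'
#' Per frame, detections and ground-truth positions are matched greedily by
#' increasing distance, each at most once, within `match_radius_um`.
#'
#' @param detections Tibble `frame`, `z_um`, `y_um`, `x_um`.
#' @param truth Ground-truth tibble (`cell_id`, `frame`, `z_um`, `y_um`,
#'   `x_um`), in the same coordinate frame as the detections.
#' @param match_radius_um Maximum match distance (um).
#' @return List: `per_frame` tibble (`frame`, `n_truth`, `n_detected`,
#'   `n_matched`, `recall`, `precision`), overall `recall` and `precision`,
#'   and `matches` (`frame`, `cell_id`, detection row, distance).
#' @export
match_detections <- function(detections, truth, match_radius_um) {
  frames <- sort(unique(truth$frame))
  matches <- vector("list", length(frames))
  per_frame <- vector("list", length(frames))
  det_idx <- seq_len(nrow(detections))
  for (k in seq_along(frames)) {
    f <- frames[k]
    tr <- truth[truth$frame == f, ]
    dr <- which(detections$frame == f)
    dd <- detections[dr, ]
    if (nrow(dd) > 0 && nrow(tr) > 0) {
      dist <- outer(rowSums(as.matrix(tr[, c("z_um", "y_um", "x_um")])^2),
                    rowSums(as.matrix(dd[, c("z_um", "y_um", "x_um")])^2),
                    "+") -
        2 * as.matrix(tr[, c("z_um", "y_um", "x_um")]) %*%
        t(as.matrix(dd[, c("z_um", "y_um", "x_um")]))
      dist <- sqrt(pmax(dist, 0))
      pairs <- which(dist <= match_radius_um, arr.ind = TRUE)
      ord <- order(dist[pairs])
      used_t <- logical(nrow(tr)); used_d <- logical(nrow(dd))
      got <- list()
      for (i in ord) {
        ti <- pairs[i, 1]; di <- pairs[i, 2]
        if (used_t[ti] || used_d[di]) next
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        got[[length(got) + 1]] <- tibble(
          frame = f, cell_id = tr$cell_id[ti], det_row = dr[di],
          distance_um = dist[ti, di])
      }
      m <- dplyr::bind_rows(got)
    } else m <- tibble(frame = integer(), cell_id = integer(),
                       det_row = integer(), distance_um = numeric())
    matches[[k]] <- m
    per_frame[[k]] <- tibble(
      frame = f, n_truth = nrow(tr), n_detected = nrow(dd),
      n_matched = nrow(m),
      recall = if (nrow(tr) > 0) nrow(m) / nrow(tr) else NA_real_,
      precision = if (nrow(dd) > 0) nrow(m) / nrow(dd) else NA_real_)
  }
  pf <- dplyr::bind_rows(per_frame)
  list(per_frame = pf,
       recall = sum(pf$n_matched) / sum(pf$n_truth),
       precision = sum(pf$n_matched) / sum(pf$n_detected),
       matches = dplyr::bind_rows(matches))
}

#' Evaluate track identity against ground truth
#'
#' A ground-truth cell counts as recovered when one single track matches its
#' position in every frame within `match_radius_um` and spans all frames.
#' Classification correctness is reported for recovered cells.
#'
#' @param tracks Curated, classified tracks tibble (acquisition
#'   coordinates).
#' @param truth Ground-truth tibble with `cell_id`, `cell_type`, `frame`,
#'   positions.
#' @param match_radius_um Match radius (um), typically the nucleus radius.
#' @return List: `per_cell` tibble (`cell_id`, `cell_type`, `recovered`,
#'   `track_id`, `correct_type`), `fraction_recovered`,
#'   `fraction_recovered_correct_type`.
#' @export
evaluate_tracking <- function(tracks, truth, match_radius_um) {
  n_frames <- length(unique(truth$frame))
  cells <- dplyr::distinct(truth, .data$cell_id, .data$cell_type)
  track_ids <- unique(tracks$track_id)
  per_cell <- purrr::pmap_dfr(cells, function(cell_id, cell_type) {
    tr <- truth[truth$cell_id == cell_id, ]
    tr <- tr[order(tr$frame), ]
    best <- NA_integer_
    for (tid in track_ids) {
      tk <- tracks[tracks$track_id == tid, ]
      if (nrow(tk) != n_frames) next
      tk <- tk[order(tk$frame), ]
      if (!identical(as.integer(tk$frame), as.integer(tr$frame))) next
      d <- sqrt((tk$z_um - tr$z_um)^2 + (tk$y_um - tr$y_um)^2 +
                  (tk$x_um - tr$x_um)^2)
      if (all(d <= match_radius_um)) { best <- tid; break }
    }
    correct <- if (!is.na(best) && "cell_type" %in% names(tracks))
      tracks$cell_type[match(best, tracks$track_id)] == cell_type
    else NA
    tibble(cell_id = cell_id, cell_type = cell_type,
           recovered = !is.na(best), track_id = best,
           correct_type = correct)
  })
  list(per_cell = per_cell,
       fraction_recovered = mean(per_cell$recovered),
       fraction_recovered_correct_type =
         mean(per_cell$recovered & !is.na(per_cell$correct_type) &
                per_cell$correct_type))
}
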