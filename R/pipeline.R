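#' Run the end-to-end tracking pipeline on simulated conditions
#'
#' For every condition and embryo: simulate a movie, estimate and compensate
#' global drift, detect nuclei at both population scales, link them into
#' tracks, keep full-span tracks starting in the ROI, classify PMEC/ICP by
#' nuclear diameter, and compute per-track and per-embryo migration metrics.
#' Conditions are then compared per metric and cell type with unpaired
#' two-tailed t tests (and one-way ANOVA across three or more conditions).
#' Detection and linking run in drift-compensated coordinates (compensation
#' lowers the burden on the linker); positions are then restored to the
#' original acquisition frame (`z_um`/`y_um`/`x_um`; the compensated
#' coordinates are kept in `*_comp_um`) and all track statistics are
#' computed on the restored positions.
#'
#' @param config Configuration list (or path to a YAML file with the same
#'   structure): `seed`; `conditions` (list of `label`, `n_embryos`, `movie`
#'   parameter overrides for [movie_sim_params()]); optional `detect`
#'   (`radius_um`, `quality_threshold`), `link` (`max_link_dist_um`),
#'   `classify` (`pmec_max_um`, `icp_min_um`), `roi` (list of `z`, `y`, `x`
#'   ranges in um).
#' @param out_dir Optional directory; when given, track/metric CSVs, the
#'   group summary JSON and a provenance record are written there.
#' @return List of class `tracking_report`: `tracks` (all curated tracks),
#'   `metrics` (per track), `embryo_summaries`, `comparisons` (named list of
#'   `group_comparison` objects per metric and cell type), `provenance`.
#' @export
run_tracking_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  seed <- cfg$seed %||% 1L
  det_cfg <- cfg$detect %||% list()
  link_cfg <- cfg$link %||% list()
  cls_cfg <- cfg$classify %||% list()
  radius_um <- unlist(det_cfg$radius_um) %||% c(1.5, 3.0)
  max_link <- link_cfg$max_link_dist_um %||% 4

  all_tracks <- list()
  all_metrics <- list()
  summaries <- list()
  for (ci in seq_along(cfg$conditions)) {
    cc <- cfg$conditions[[ci]]
    n_emb <- cc$n_embryos %||% 6
    for (e in seq_len(n_emb)) {
      emb_seed <- (seed * 1000L + ci * 100L + e) %% .Machine$integer.max
      mp <- do.call(movie_sim_params,
                    c(cc$movie %||% list(), list(seed = emb_seed)))
      sim <- simulate_movie(mp)
      drift <- estimate_drift(sim$movie)
      det <- detect_nuclei(sim$movie, radius_um = radius_um,
                           quality_threshold = det_cfg$quality_threshold,
                           drift = drift)
      nt <- n_frames(sim$movie)
      tracks <- link_frames(det, max_link_dist_um = max_link,
                            n_frames = nt) |>
        curate_tracks(n_frames = nt, roi = cfg$roi) |>
        classify_tracks(pmec_max_um = cls_cfg$pmec_max_um %||% 3.5,
                        icp_min_um = cls_cfg$icp_min_um %||% 5.5)
      # keep compensated coordinates, but base all statistics on the
      # restored (original acquisition) positions, as the exported tracks do
      restored <- restore_coordinates(
        tracks[, c("frame", "z_um", "y_um", "x_um")], drift,
        sim$movie$voxel_size_um)
      tracks$z_comp_um <- tracks$z_um
      tracks$y_comp_um <- tracks$y_um
      tracks$x_comp_um <- tracks$x_um
      tracks$z_um <- restored$z_um
      tracks$y_um <- restored$y_um
      tracks$x_um <- restored$x_um
      tracks$condition <- cc$label
      tracks$embryo_id <- sprintf("%s_%d", cc$label, e)
      all_tracks[[length(all_tracks) + 1]] <- tracks
      if (nrow(tracks) > 0) {
        m <- track_metrics(tracks, mp$frame_interval_min)
        m$embryo_id <- tracks$embryo_id[1]
        m$condition <- cc$label
        all_metrics[[length(all_metrics) + 1]] <- m
        summaries[[length(summaries) + 1]] <-
          suppressWarnings(embryo_summary(m, tracks$embryo_id[1])) |>
          dplyr::mutate(condition = cc$label)
      }
    }
  }
  tracks <- dplyr::bind_rows(all_tracks)
  embryo_summaries <- dplyr::bind_rows(summaries)
  metrics <- dplyr::bind_rows(all_metrics)

  comparisons <- list()
  if (length(cfg$conditions) >= 2) {
    control <- cfg$control %||% cfg$conditions[[1]]$label
    for (metric in c("velocity_um_per_min", "persistence", "coordination")) {
      for (ct in unique(embryo_summaries$cell_type)) {
        sub <- dplyr::filter(embryo_summaries, .data$cell_type == ct)
        if (length(unique(sub$condition)) >= 2 &&
            all(table(sub$condition) >= 2)) {
          comparisons[[paste(metric, ct, sep = ".")]] <-
            compare_groups(sub, metric, condition = "condition",
                           control = control)
        }
      }
    }
  }
  report <- structure(
    list(tracks = tracks, metrics = metrics,
         embryo_summaries = embryo_summaries, comparisons = comparisons,
         provenance = provenance_record(cfg, seed)),
    class = "tracking_report")
  if (!is.null(out_dir)) write_tracking_report(report, out_dir)
  report
}

#' Run the end-to-end apicobasal profiling pipeline on simulated conditions
#'
#' For every condition and embryo: simulate a polarized-epithelium slice per
#' marker, preprocess it (8-bit, invert, sliding-paraboloid background
#' subtraction, stacked-histogram threshold), sample one wide-line profile
#' per cell, average cells into an embryo profile, then average embryos into
#' condition profiles, extract windowed peak amplitude and FWHM per embryo,
#' and compare conditions against the control with unpaired two-tailed
#' t tests.
#'
#' @param config Configuration list or YAML path: `seed`; `conditions` (list
#'   of `label`, `n_embryos`, `epithelium` overrides for
#'   [epithelium_sim_params()]); optional `preprocess` (`radius_px`,
#'   `signal_fraction`), `windows` (named list of um ranges), `control`.
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @return List of class `profile_report`: `embryo_profiles`,
#'   `condition_profiles`, `peak_metrics`, `peak_tests`, `provenance`.
#' @export
run_profile_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  seed <- cfg$seed %||% 1L
  pp <- cfg$preprocess %||% list()
  windows <- lapply(cfg$windows %||% list(apical = c(0, 10),
                                          basal = c(10, 20)), unlist)
  emb_profiles <- list()
  for (ci in seq_along(cfg$conditions)) {
    cc <- cfg$conditions[[ci]]
    n_emb <- cc$n_embryos %||% 6
    for (e in seq_len(n_emb)) {
      emb_seed <- (seed * 1000L + ci * 100L + e) %% .Machine$integer.max
      ep_over <- cc$epithelium %||% list()
      if (!is.null(ep_over$peaks)) ep_over$peaks <- as_tibble(ep_over$peaks)
      ep <- do.call(epithelium_sim_params, c(ep_over, list(seed = emb_seed)))
      sim <- simulate_epithelium(ep)
      for (m in names(sim$images)) {
        img <- preprocess_fixed_image(
          sim$images[[m]],
          radius_px = pp$radius_px %||% 200,
          signal_fraction = pp$signal_fraction %||% 0.03)
        cells <- purrr::map_dfr(seq_len(nrow(sim$rois)), function(i) {
          prof <- sample_line_profile(img, sim$rois[i, ], ep$pixel_size_um)
          prof$cell_id <- sim$rois$cell_id[i]
          prof
        })
        emb <- suppressWarnings(average_cell_profiles(cells))
        emb$embryo_id <- sprintf("%s_%d", cc$label, e)
        emb$condition <- cc$label
        emb$marker <- m
        emb_profiles[[length(emb_profiles) + 1]] <- emb
      }
    }
  }
  embryo_profiles <- dplyr::bind_rows(emb_profiles)
  condition_profiles <- embryo_profiles |>
    dplyr::group_by(.data$condition, .data$marker) |>
    dplyr::group_modify(~ condition_average(.x)) |>
    dplyr::ungroup()
  pm <- embryo_profiles |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(~ peak_metrics(.x, windows = windows)) |>
    dplyr::ungroup()
  tests <- NULL
  control <- cfg$control %||% cfg$conditions[[1]]$label
  if (length(unique(pm$condition)) >= 2)
    tests <- peak_stats(pm, control = control)
  report <- structure(
    list(embryo_profiles = embryo_profiles,
         condition_profiles = condition_profiles,
         peak_metrics = pm, peak_tests = tests,
         provenance = provenance_record(cfg, seed)),
    class = "profile_report")
  if (!is.null(out_dir)) write_profile_report(report, out_dir)
  report
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path")
  if (is.null(config$conditions)) stop("config needs a `conditions` list")
  config
}

provenance_record <- function(cfg, seed) {
  list(package = "metquant",
       version = as.character(utils::packageVersion("metquant")),
       seed = seed,
       config_hash = rlang::hash(cfg),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_tracking_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$tracks, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(report$metrics, file.path(out_dir, "track_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$embryo_summaries,
                   file.path(out_dir, "embryo_summaries.csv"),
                   row.names = FALSE)
  summary_json <- list(
    comparisons = lapply(report$comparisons, function(gc) list(
      summary = gc$summary, tests = gc$tests, anova = gc$anova)),
    provenance = report$provenance)
  jsonlite::write_json(summary_json,
                       file.path(out_dir, "group_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

write_profile_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$embryo_profiles,
                   file.path(out_dir, "embryo_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(report$condition_profiles,
                   file.path(out_dir, "condition_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(report$peak_metrics,
                   file.path(out_dir, "peak_metrics.csv"), row.names = FALSE)
  if (!is.null(report$peak_tests))
    utils::write.csv(report$peak_tests,
                     file.path(out_dir, "peak_tests.csv"), row.names = FALSE)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
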