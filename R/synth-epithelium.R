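#' Parameters for the synthetic polarized-epithelium generator
#'
#' Emulates a single confocal z-slice through a band of columnar epithelial
#' cells sitting on a mesoderm layer, as used for apicobasal marker
#' profiling. Each marker is rendered as its own single-channel image in
#' which the intensity along the apical-to-basal axis is a sum of Gaussian
#' peaks of programmed position, amplitude and full width at half maximum,
#' on top of a smooth background gradient and pixel noise. Peak positions are
#' measured in micrometres from the apical membrane (apical = 0, increasing
#' basally), so they stay aligned across cells despite per-cell length
#' jitter.
#'
#' By default the image is emitted with dark signal on a light background
#' (`signal_polarity = "dark"`), matching raw exports whose processing chain
#' is 8-bit conversion, inversion, background subtraction and thresholding.
#'
#' @param image_shape_px Integer `(y, x)` pixel counts.
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @param n_cells Number of cells in the band.
#' @param cell_length_um Mean apical-to-basal cell length (um).
#' @param cell_length_jitter_um Per-cell uniform length jitter half-width
#'   (um); lengths are `cell_length_um +/- jitter`.
#' @param cell_width_um Lateral width of one cell (um).
#' @param mesoderm_band_um Thickness of the mesoderm layer beneath the basal
#'   membrane (um); line ROIs end 1 um below it.
#' @param apical_y_um Image y-coordinate of the (flat) apical membrane (um).
#' @param peaks Data frame with columns `marker`, `position_um` (from the
#'   apical membrane), `amplitude` (0-255 gray) and `fwhm_um`.
#' @param amplitude_jitter_sd Per-cell multiplicative amplitude jitter SD.
#' @param background_level,background_gradient Constant background and the
#'   amplitude of a smooth vertical gradient added to it.
#' @param noise_sd Additive Gaussian pixel noise SD.
#' @param signal_polarity `"dark"` (default) or `"bright"`.
#' @param line_width_px Width of the emitted line ROIs in pixels.
#' @param seed Integer RNG seed.
#' @return An `epithelium_sim_params` list.
#' @export
epithelium_sim_params <- function(image_shape_px = c(y = 1024, x = 1024),
                                  pixel_size_um = 0.1,
                                  n_cells = 10,
                                  cell_length_um = 15,
                                  cell_length_jitter_um = 1,
                                  cell_width_um = 7,
                                  mesoderm_band_um = 5,
                                  apical_y_um = 20,
                                  peaks = tibble::tibble(
                                    marker = c("apical_marker", "basal_marker"),
                                    position_um = c(2, 15),
                                    amplitude = c(120, 120),
                                    fwhm_um = c(0.8, 1.3)),
                                  amplitude_jitter_sd = 0.05,
                                  background_level = 10,
                                  background_gradient = 10,
                                  noise_sd = 2,
                                  signal_polarity = c("dark", "bright"),
                                  line_width_px = 60,
                                  seed = 1L) {
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  image_shape_px <- as.integer(unlist(image_shape_px))
  if (length(image_shape_px) != 2L || any(image_shape_px <= 0))
    stop("`image_shape_px` must be 2 positive counts (y, x)")
  peaks <- as_tibble(peaks)
  req <- c("marker", "position_um", "amplitude", "fwhm_um")
  if (!all(req %in% names(peaks))) stop("`peaks` needs columns ",
                                        paste(req, collapse = ", "))
  if (any(peaks$amplitude < 0) || any(peaks$amplitude > 255))
    stop("peak amplitudes must lie in [0, 255]")
  if (any(peaks$fwhm_um <= 0)) stop("peak FWHMs must be positive")
  lim <- cell_length_um + mesoderm_band_um + 1
  if (any(peaks$position_um < -1) || any(peaks$position_um > lim))
    stop("peak positions must lie within [-1, cell length + mesoderm + 1] um")
  structure(
    list(image_shape_px = image_shape_px, pixel_size_um = pixel_size_um,
         n_cells = as.integer(n_cells), cell_length_um = cell_length_um,
         cell_length_jitter_um = cell_length_jitter_um,
         cell_width_um = cell_width_um, mesoderm_band_um = mesoderm_band_um,
         apical_y_um = apical_y_um, peaks = peaks,
         amplitude_jitter_sd = amplitude_jitter_sd,
         background_level = background_level,
         background_gradient = background_gradient,
         noise_sd = noise_sd,
         signal_polarity = match.arg(signal_polarity),
         line_width_px = as.integer(line_width_px),
         seed = as.integer(seed)),
    class = "epithelium_sim_params")
}

#' Simulate a polarized-epithelium cross-section with ground truth
#'
#' Renders one image per marker (see [epithelium_sim_params()]) plus the line
#' ROIs the profiling stage consumes: one vertical line per cell, from 1 um
#' above the apical membrane to 1 um below the basal surface of the mesoderm
#' band, centred laterally in the cell.
#'
#' @param params An [epithelium_sim_params()].
#' @return A list of class `epithelium_sim` with `images` (named list of
#'   y-by-x matrices, one per marker), `rois` (tibble: cell_id, x0_um, y0_um,
#'   x1_um, y1_um, width_px, apical_offset_um), `cells` (per-cell geometry),
#'   `peaks` (programmed peak table) and `params`.
#' @export
simulate_epithelium <- function(params) {
  stopifnot(inherits(params, "epithelium_sim_params"))
  p <- params
  with_seed(p$seed, {
    ny <- p$image_shape_px[1]; nx <- p$image_shape_px[2]
    px <- p$pixel_size_um
    y_um <- (seq_len(ny) - 1) * px
    x_um <- (seq_len(nx) - 1) * px

    band_w <- p$n_cells * p$cell_width_um
    x_start <- (nx - 1) * px / 2 - band_w / 2
    if (x_start < 0) stop("cell band wider than the image")
    cells <- tibble(
      cell_id = seq_len(p$n_cells),
      x_left_um = x_start + (seq_len(p$n_cells) - 1) * p$cell_width_um,
      length_um = p$cell_length_um +
        runif(p$n_cells, -p$cell_length_jitter_um, p$cell_length_jitter_um))
    cells$x_centre_um <- cells$x_left_um + p$cell_width_um / 2

    markers <- unique(p$peaks$marker)
    # per-cell, per-peak multiplicative amplitude jitter (shared across the
    # image of one marker)
    images <- list()
    dist_um <- y_um - p$apical_y_um      # apicobasal coordinate of each row
    for (m in markers) {
      pk <- p$peaks[p$peaks$marker == m, ]
      img <- matrix(p$background_level +
                      p$background_gradient * (y_um / max(y_um)),
                    ny, nx)
      for (i in seq_len(p$n_cells)) {
        cols <- which(x_um >= cells$x_left_um[i] &
                        x_um < cells$x_left_um[i] + p$cell_width_um)
        prof <- numeric(ny)
        for (k in seq_len(nrow(pk))) {
          amp <- pk$amplitude[k] *
            max(0, 1 + rnorm(1, 0, p$amplitude_jitter_sd))
          sig <- pk$fwhm_um[k] / (2 * sqrt(2 * log(2)))
          prof <- prof + amp * exp(-(dist_um - pk$position_um[k])^2 /
                                     (2 * sig^2))
        }
        img[, cols] <- img[, cols] + prof
      }
      if (p$noise_sd > 0) img <- img + rnorm(length(img), 0, p$noise_sd)
      img[img < 0] <- 0
      img[img > 255] <- 255
      if (p$signal_polarity == "dark") img <- 255 - img
      images[[m]] <- img
    }

    rois <- tibble(
      cell_id = cells$cell_id,
      x0_um = cells$x_centre_um,
      y0_um = p$apical_y_um - 1,
      x1_um = cells$x_centre_um,
      y1_um = p$apical_y_um + cells$length_um + p$mesoderm_band_um + 1,
      width_px = p$line_width_px,
      apical_offset_um = 1)

    structure(list(images = images, rois = rois, cells = cells,
                   peaks = p$peaks, params = p),
              class = "epithelium_sim")
  })
}
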