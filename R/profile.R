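# bilinear interpolation of matrix `img` (rows = y, cols = x) at continuous
# um coordinates; errors if any point falls outside the image
bilinear <- function(img, y_um, x_um, pixel_size_um) {
  ry <- y_um / pixel_size_um
  cx <- x_um / pixel_size_um
  nr <- nrow(img); nc <- ncol(img)
  if (any(ry < 0 | ry > nr - 1 | cx < 0 | cx > nc - 1))
    stop("sample point outside the image")
  r0 <- pmin(floor(ry), nr - 2); c0 <- pmin(floor(cx), nc - 2)
  fy <- ry - r0; fx <- cx - c0
  i00 <- (r0 + 1) + c0 * nr    # linear index of (r0 + 1, c0 + 1)
  img[i00] * (1 - fy) * (1 - fx) +
    img[i00 + 1] * fy * (1 - fx) +
    img[i00 + nr] * (1 - fy) * fx +
    img[i00 + nr + 1] * fy * fx
}

#' Sample a wide-line apicobasal intensity profile
#'
#' Samples the image every pixel step along the line from `(x0, y0)` to
#' `(x1, y1)`; at each step the intensity is averaged over a perpendicular
#' band of `width_px` bilinear samples at one-pixel spacing, symmetric about
#' the line. Distances are reported relative to the apical membrane: the
#' line is assumed to start `apical_offset_um` above it (default 1), so
#' distance 0 is the apical membrane and values increase basally.
#'
#' @param image Numeric matrix (rows = y, cols = x), typically preprocessed
#'   with [preprocess_fixed_image()].
#' @param roi One-row data frame or list with `x0_um`, `y0_um`, `x1_um`,
#'   `y1_um`, `width_px` (default 60) and optionally `apical_offset_um`.
#' @param pixel_size_um Pixel size in micrometres.
#' @return Tibble `distance_um`, `mean_gray` (one row per step).
#' @export
sample_line_profile <- function(image, roi, pixel_size_um) {
  w <- roi$width_px %||% 60
  off <- roi$apical_offset_um %||% 1
  if (w < 1) stop("`width_px` must be >= 1")
  dx <- roi$x1_um - roi$x0_um
  dy <- roi$y1_um - roi$y0_um
  len <- sqrt(dx^2 + dy^2)
  if (len <= 0) stop("degenerate line ROI")
  u <- c(dx, dy) / len
  v <- c(-u[2], u[1])
  s <- seq(0, len, by = pixel_size_um)
  band <- (seq_len(w) - (w + 1) / 2) * pixel_size_um
  sx <- outer(roi$x0_um + s * u[1], band * v[1], "+")
  sy <- outer(roi$y0_um + s * u[2], band * v[2], "+")
  vals <- bilinear(image, as.numeric(sy), as.numeric(sx), pixel_size_um)
  tibble(distance_um = s - off,
         mean_gray = rowMeans(matrix(vals, length(s), w)))
}

#' Average cell profiles into an embryo profile
#'
#' Enforces the similar-length rule: profiles whose length differs from the
#' median by more than `length_tol_um` are dropped with a warning, and fewer
#' than `min_cells` admissible profiles warns. The remaining profiles (all
#' aligned at the apical end) are interpolated onto the grid of the
#' median-length profile and averaged pointwise; grid points outside a
#' profile's domain are dropped from that point's mean.
#'
#' @param profiles Tibble with `cell_id`, `distance_um`, `mean_gray`.
#' @param min_cells Expected minimum number of cells (default 10).
#' @param length_tol_um Admissible deviation from the median profile length
#'   in micrometres (default 1).
#' @return Tibble `distance_um`, `mean_gray`, `n` (cells contributing per
#'   point).
#' @export
average_cell_profiles <- function(profiles, min_cells = 10,
                                  length_tol_um = 1) {
  by_cell <- split(profiles, profiles$cell_id)
  lens <- vapply(by_cell, function(p) max(p$distance_um), numeric(1))
  med <- median(lens)
  ok <- abs(lens - med) <= length_tol_um
  if (any(!ok)) {
    warning(sprintf("dropping %d profile(s) outside +/-%g um of the median length",
                    sum(!ok), length_tol_um))
    by_cell <- by_cell[ok]
    lens <- lens[ok]
  }
  if (length(by_cell) < 2) stop("fewer than 2 admissible profiles")
  if (length(by_cell) < min_cells)
    warning(sprintf("only %d admissible profiles (expected >= %d)",
                    length(by_cell), min_cells))
  ref <- by_cell[[which.min(abs(lens - median(lens)))]]
  grid <- ref$distance_um
  mat <- vapply(by_cell, function(p)
    approx(p$distance_um, p$mean_gray, xout = grid, rule = 1)$y,
    numeric(length(grid)))
  mat <- matrix(mat, length(grid), length(by_cell))
  tibble(distance_um = grid,
         mean_gray = rowMeans(mat, na.rm = TRUE),
         n = rowSums(!is.na(mat)))
}

#' Average embryo profiles into a condition profile
#'
#' Pointwise mean of the embryo-level profiles on the grid of the
#' median-length embryo profile; the per-embryo curves are retained in the
#' `"embryos"` attribute for plotting.
#'
#' @param embryo_profiles Tibble with `embryo_id`, `distance_um`,
#'   `mean_gray`.
#' @return Tibble `distance_um`, `mean_gray`, `n`, with attribute
#'   `"embryos"`.
#' @export
condition_average <- function(embryo_profiles) {
  by_embryo <- split(embryo_profiles, embryo_profiles$embryo_id)
  if (length(by_embryo) < 2) stop("need at least 2 embryo profiles")
  lens <- vapply(by_embryo, function(p) max(p$distance_um), numeric(1))
  ref <- by_embryo[[which.min(abs(lens - median(lens)))]]
  grid <- ref$distance_um
  mat <- vapply(by_embryo, function(p)
    approx(p$distance_um, p$mean_gray, xout = grid, rule = 1)$y,
    numeric(length(grid)))
  mat <- matrix(mat, length(grid), length(by_embryo))
  if (all(is.na(mat[, -1]))) stop("embryo profile grids do not overlap")
  out <- tibble(distance_um = grid,
                mean_gray = rowMeans(mat, na.rm = TRUE),
                n = rowSums(!is.na(mat)))
  attr(out, "embryos") <- as_tibble(embryo_profiles)
  out
}

#' Plot a condition profile with its embryo curves
#'
#' Per-embryo averages as dashed black lines, the condition average as a
#' solid red line.
#'
#' @param condition_profile Output of [condition_average()].
#' @return A ggplot object.
#' @export
plot_condition_profile <- function(condition_profile) {
  emb <- attr(condition_profile, "embryos")
  p <- ggplot2::ggplot()
  if (!is.null(emb))
    p <- p + ggplot2::geom_line(
      data = emb,
      ggplot2::aes(x = .data$distance_um, y = .data$mean_gray,
                   group = .data$embryo_id),
      linetype = "dashed", colour = "black", linewidth = 0.3)
  p + ggplot2::geom_line(
    data = condition_profile,
    ggplot2::aes(x = .data$distance_um, y = .data$mean_gray),
    colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "distance from apical membrane (um)",
                  y = "mean gray value") +
    ggplot2::theme_classic()
}

#' Mean nuclear gray value of an embryo
#'
#' Averages the image intensity within each elliptical nucleus ROI, then
#' averages the per-nucleus means; warns when fewer than `expected_n` nuclei
#' are supplied (default 30).
#'
#' @param image Numeric matrix.
#' @param nucleus_rois Tibble with `cx_um`, `cy_um`, `rx_um`, `ry_um`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param expected_n Expected number of nuclei per embryo.
#' @return The embryo mean gray value (scalar), with the per-nucleus means
#'   as attribute `"per_nucleus"`.
#' @export
nuclear_mean_gray <- function(image, nucleus_rois, pixel_size_um,
                              expected_n = 30) {
  if (nrow(nucleus_rois) < expected_n)
    warning(sprintf("only %d nuclei (expected %d)", nrow(nucleus_rois),
                    expected_n))
  y_um <- (seq_len(nrow(image)) - 1) * pixel_size_um
  x_um <- (seq_len(ncol(image)) - 1) * pixel_size_um
  per <- purrr::pmap_dbl(nucleus_rois, function(cx_um, cy_um, rx_um, ry_um,
                                                ...) {
    rows <- which(abs(y_um - cy_um) <= ry_um)
    cols <- which(abs(x_um - cx_um) <= rx_um)
    if (length(rows) == 0 || length(cols) == 0) stop("empty nucleus ROI")
    sub <- image[rows, cols, drop = FALSE]
    mask <- outer(((y_um[rows] - cy_um) / ry_um)^2,
                  ((x_um[cols] - cx_um) / rx_um)^2, "+") <= 1
    if (!any(mask)) stop("empty nucleus ROI")
    mean(sub[mask])
  })
  structure(mean(per), per_nucleus = per)
}
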