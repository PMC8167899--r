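#' Windowed peak amplitude
#'
#' Maximum profile value within the window (e.g. 0-10 um for apical peaks,
#' 10-20 um for basal peaks), with parabolic sub-sample refinement of the
#' peak position. An all-zero window returns amplitude 0, `NA` position and
#' `bounded = FALSE`.
#'
#' @param profile Tibble `distance_um`, `mean_gray`.
#' @param window_um Length-2 `(lo, hi)` window in micrometres.
#' @return One-row tibble `amplitude`, `peak_position_um`, `bounded`.
#' @export
peak_amplitude <- function(profile, window_um) {
  sel <- which(profile$distance_um >= window_um[1] &
                 profile$distance_um <= window_um[2])
  if (length(sel) == 0) stop("window outside the profile domain")
  y <- profile$mean_gray[sel]
  x <- profile$distance_um[sel]
  i <- which.max(y)
  if (y[i] <= 0)
    return(tibble(amplitude = 0, peak_position_um = NA_real_,
                  bounded = FALSE))
  amp <- y[i]
  pos <- x[i]
  if (i > 1 && i < length(y)) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom < 0) {
      frac <- 0.5 * (y[i - 1] - y[i + 1]) / denom
      frac <- max(-0.5, min(0.5, frac))
      step <- x[i + 1] - x[i]
      pos <- x[i] + frac * step
      amp <- y[i] - 0.25 * (y[i - 1] - y[i + 1]) * frac
    }
  }
  tibble(amplitude = amp, peak_position_um = pos, bounded = TRUE)
}

#' Full width at half maximum of a windowed peak
#'
#' The half level is half the windowed peak amplitude above a zero baseline
#' (profiles are background-subtracted upstream). Starting from the peak,
#' each flank is followed outward across the full profile domain until it
#' first descends through the half level; the crossing is located by linear
#' interpolation and the width is the distance between the two crossings. A
#' flank that never reaches the half level marks the peak unbounded and the
#' width is `NA`.
#'
#' @inheritParams peak_amplitude
#' @return One-row tibble `fwhm_um`, `amplitude`, `peak_position_um`,
#'   `bounded`.
#' @export
fwhm <- function(profile, window_um) {
  pk <- peak_amplitude(profile, window_um)
  if (!pk$bounded)
    return(tibble(fwhm_um = NA_real_, amplitude = pk$amplitude,
                  peak_position_um = pk$peak_position_um, bounded = FALSE))
  x <- profile$distance_um
  y <- profile$mean_gray
  half <- pk$amplitude / 2
  ipk <- which.min(abs(x - pk$peak_position_um))
  cross_out <- function(idx_seq) {
    prev <- ipk
    for (i in idx_seq) {
      if (y[i] <= half) {
        # interpolate between prev (above) and i (at/below)
        if (y[prev] == y[i]) return(x[i])
        return(x[prev] + (x[i] - x[prev]) * (y[prev] - half) /
                 (y[prev] - y[i]))
      }
      prev <- i
    }
    NA_real_
  }
  left <- if (ipk > 1) cross_out(seq(ipk - 1, 1)) else NA_real_
  right <- if (ipk < length(x)) cross_out(seq(ipk + 1, length(x))) else NA_real_
  if (is.na(left) || is.na(right))
    return(tibble(fwhm_um = NA_real_, amplitude = pk$amplitude,
                  peak_position_um = pk$peak_position_um, bounded = FALSE))
  tibble(fwhm_um = right - left, amplitude = pk$amplitude,
         peak_position_um = pk$peak_position_um, bounded = TRUE)
}

#' Windowed peak metrics for a set of embryo profiles
#'
#' Computes amplitude and FWHM in each requested window for each embryo
#' profile of each marker.
#'
#' @param embryo_profiles Tibble with `embryo_id`, `marker`, `distance_um`,
#'   `mean_gray` (embryo-level profiles).
#' @param windows Named list of length-2 windows in micrometres, e.g.
#'   `list(apical = c(0, 10), basal = c(10, 20))` (the defaults).
#' @return Tibble: `embryo_id`, `marker`, `window`, `window_lo_um`,
#'   `window_hi_um`, `amplitude`, `fwhm_um`, `peak_position_um`, `bounded`.
#' @export
peak_metrics <- function(embryo_profiles,
                         windows = list(apical = c(0, 10),
                                        basal = c(10, 20))) {
  groups <- dplyr::distinct(embryo_profiles, .data$embryo_id, .data$marker)
  purrr::pmap_dfr(groups, function(embryo_id, marker) {
    prof <- dplyr::filter(embryo_profiles,
                          .data$embryo_id == .env$embryo_id,
                          .data$marker == .env$marker)
    purrr::imap_dfr(windows, function(w, label) {
      res <- fwhm(prof, w)
      dplyr::bind_cols(
        tibble(embryo_id = embryo_id, marker = marker, window = label,
               window_lo_um = w[1], window_hi_um = w[2]),
        res[, c("amplitude", "fwhm_um", "peak_position_um", "bounded")])
    })
  })
}

#' Condition-level statistics on peak metrics
#'
#' For each marker/window/metric, compares every mutant condition with the
#' control by an unpaired two-tailed t test on the per-embryo values, with
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param metrics_by_condition [peak_metrics()] output with an added
#'   `condition` column.
#' @param control Control condition label.
#' @param metrics Which metric columns to test.
#' @return Tibble: `marker`, `window`, `metric`, `condition`, `control`,
#'   per-condition mean/SD, t statistic, `p.value`, `stars`.
#' @export
peak_stats <- function(metrics_by_condition, control,
                       metrics = c("amplitude", "fwhm_um")) {
  if (!control %in% metrics_by_condition$condition)
    stop("control condition missing")
  groups <- dplyr::distinct(metrics_by_condition, .data$marker, .data$window)
  purrr::pmap_dfr(groups, function(marker, window) {
    sub <- dplyr::filter(metrics_by_condition,
                         .data$marker == .env$marker,
                         .data$window == .env$window)
    conds <- setdiff(unique(sub$condition), control)
    purrr::map_dfr(metrics, function(metric) {
      purrr::map_dfr(conds, function(g) {
        a <- sub[[metric]][sub$condition == g]
        b <- sub[[metric]][sub$condition == control]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2 || length(b) < 2)
          return(tibble(marker = marker, window = window, metric = metric,
                        condition = g, control = control,
                        mean = mean(a), sd = sd(a),
                        control_mean = mean(b), control_sd = sd(b),
                        statistic = NA_real_, p.value = NA_real_,
                        stars = NA_character_))
        tt <- stats::t.test(a, b, var.equal = TRUE)
        tibble(marker = marker, window = window, metric = metric,
               condition = g, control = control,
               mean = mean(a), sd = sd(a),
               control_mean = mean(b), control_sd = sd(b),
               statistic = unname(tt$statistic), p.value = tt$p.value,
               stars = significance_stars(tt$p.value))
      })
    })
  })
}

#' Scatter plot of per-embryo peak metrics by condition
#'
#' Embryo dots with mean and SD bars, faceted by marker and window.
#'
#' @param metrics_by_condition [peak_metrics()] output with a `condition`
#'   column.
#' @param metric Metric column to plot (default `"fwhm_um"`).
#' @return A ggplot object.
#' @export
plot_peak_metrics <- function(metrics_by_condition, metric = "fwhm_um") {
  ggplot2::ggplot(metrics_by_condition,
                  ggplot2::aes(x = .data$condition,
                               y = .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1),
                          geom = "errorbar", width = 0.25) +
    ggplot2::facet_grid(ggplot2::vars(.data$marker),
                        ggplot2::vars(.data$window)) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic()
}
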