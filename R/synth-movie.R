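#' Parameters for the synthetic nucleus-movie generator
#'
#' Defaults emulate the acquisition the tracking pipeline targets: 31 frames
#' at 2-min intervals, z step 1.5 um, ~21 um deep stacks, two nuclear
#' populations (15 small ~3 um "PMEC-like" and 15 large ~6 um "ICP-like")
#' undergoing directed, partially coordinated migration at 1.2 um/min under a
#' slow global embryo drift, transverse to the migration axis. The lateral
#' field (512 x 192 px at 0.25 um/px, i.e. 128 x 48 um) is long enough along
#' the migration axis to contain 60 min of directed motion with room to seed
#' all nuclei at a resolvable spacing.
#'
#' Coordination is injected as a convex mixture of a shared population
#' fluctuation and an independent per-cell fluctuation:
#' `step = speed * dt * direction + rho * shared + (1 - rho) * independent`,
#' so the correlation of neighbouring cells' step fluctuations grows
#' monotonically from 0 (rho = 0) to 1 (rho = 1).
#'
#' @param image_shape Integer (t, z, y, x) voxel counts.
#' @param voxel_size_um Voxel size (z, y, x) in micrometres.
#' @param frame_interval_min Frame interval in minutes.
#' @param n_pmec,n_icp Number of nuclei in each population.
#' @param diameter_um_pmec,diameter_um_icp Length-2 `(mean, sd)` of nuclear
#'   diameters (um). Defaults straddle the 3.5 / 5.5 um classification
#'   thresholds.
#' @param speed_um_per_min Directed-motion speed; scalar or `(pmec, icp)`.
#' @param direction Unit direction of migration, `(z, y, x)` (normalised
#'   internally).
#' @param coordination_rho Fraction in \[0, 1\] of each step fluctuation drawn
#'   from the shared population fluctuation.
#' @param step_noise_sd_um Per-axis SD (um) of the step fluctuations.
#' @param global_drift_um_per_frame Global embryo drift per frame, `(z, y, x)`
#'   in um.
#' @param peak_intensity,background_level,noise_sd Rendering intensities:
#'   blob peak amplitude, constant background, and additive Gaussian noise SD
#'   (all on a 0-255 scale).
#' @param poisson_noise If `TRUE`, Poisson resampling of the noise-free signal
#'   is applied before the additive Gaussian noise.
#' @param dynamic_range Intensities are clipped to `[0, dynamic_range]`.
#' @param min_separation_um Floor on the initial centre-to-centre distance
#'   between nuclei; independent of it, nuclei are seeded as hard spheres
#'   (pairwise separation at least the sum of their radii).
#' @param seed Integer RNG seed.
#' @return A `movie_sim_params` list.
#' @export
movie_sim_params <- function(image_shape = c(t = 31, z = 14, y = 192, x = 512),
                             voxel_size_um = c(z = 1.5, y = 0.25, x = 0.25),
                             frame_interval_min = 2,
                             n_pmec = 15, n_icp = 15,
                             diameter_um_pmec = c(mean = 3.0, sd = 0.15),
                             diameter_um_icp = c(mean = 6.0, sd = 0.25),
                             speed_um_per_min = 1.2,
                             direction = c(z = 0, y = 0, x = 1),
                             coordination_rho = 0.8,
                             step_noise_sd_um = 0.2,
                             global_drift_um_per_frame = c(z = 0.1, y = 0.15, x = 0),
                             peak_intensity = 200,
                             background_level = 20,
                             noise_sd = 10,
                             poisson_noise = FALSE,
                             dynamic_range = 255,
                             min_separation_um = 5,
                             seed = 1L) {
  image_shape <- as.integer(unlist(image_shape))
  if (length(image_shape) != 4L || any(image_shape <= 0))
    stop("`image_shape` must be 4 positive counts (t, z, y, x)")
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be positive")
  if (frame_interval_min <= 0) stop("`frame_interval_min` must be positive")
  if (coordination_rho < 0 || coordination_rho > 1)
    stop("`coordination_rho` must lie in [0, 1]")
  if (n_pmec < 0 || n_icp < 0 || n_pmec + n_icp < 1)
    stop("need at least one nucleus")
  if (any(c(diameter_um_pmec, diameter_um_icp) <= 0))
    stop("diameters must be positive")
  speed_um_per_min <- rep_len(as.numeric(unlist(speed_um_per_min)), 2L)
  direction <- as.numeric(unlist(direction))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("`direction` must be non-zero")
  structure(
    list(image_shape = image_shape,
         voxel_size_um = unname(as.numeric(unlist(voxel_size_um))),
         frame_interval_min = frame_interval_min,
         n_pmec = as.integer(n_pmec), n_icp = as.integer(n_icp),
         diameter_um_pmec = unname(unlist(diameter_um_pmec)),
         diameter_um_icp = unname(unlist(diameter_um_icp)),
         speed_um_per_min = speed_um_per_min,
         direction = direction / nrm,
         coordination_rho = coordination_rho,
         step_noise_sd_um = step_noise_sd_um,
         global_drift_um_per_frame = unname(as.numeric(unlist(global_drift_um_per_frame))),
         peak_intensity = peak_intensity,
         background_level = background_level,
         noise_sd = noise_sd,
         poisson_noise = isTRUE(poisson_noise),
         dynamic_range = dynamic_range,
         min_separation_um = min_separation_um,
         seed = as.integer(seed)),
    class = "movie_sim_params")
}

# run `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# draw n points uniformly in box (3 x 2 matrix, rows z/y/x) by rejection;
# nuclei behave as hard spheres: pair (i, j) must be at least
# max(min_sep, (dia_i + dia_j) / 2) apart
seed_positions <- function(n, box, min_sep, diameters) {
  pts <- matrix(NA_real_, n, 3)
  i <- 1L
  tries <- 0L
  while (i <= n) {
    cand <- c(runif(1, box[1, 1], box[1, 2]),
              runif(1, box[2, 1], box[2, 2]),
              runif(1, box[3, 1], box[3, 2]))
    ok <- TRUE
    if (i > 1L) {
      prev <- pts[seq_len(i - 1L), , drop = FALSE]
      d <- sqrt(rowSums((prev - matrix(cand, i - 1L, 3, byrow = TRUE))^2))
      lim <- pmax(min_sep, (diameters[seq_len(i - 1L)] + diameters[i]) / 2)
      ok <- all(d >= lim)
    }
    if (ok) {
      pts[i, ] <- cand
      i <- i + 1L
    }
    tries <- tries + 1L
    if (tries > 50000L)
      stop("could not place nuclei at the requested minimum separation")
  }
  pts
}

# add an isotropic Gaussian blob (um-space sigma) to a (z,y,x) volume in place
render_blob <- function(vol, centre_um, sigma_um, amplitude, voxel) {
  d <- dim(vol)
  for (ax in 1:3) {
    if (centre_um[ax] < 0 || centre_um[ax] > (d[ax] - 1) * voxel[ax])
      return(vol) # fully outside handled by caller; partial clip is fine
  }
  idx <- lapply(1:3, function(ax) {
    half <- ceiling(3.5 * sigma_um / voxel[ax])
    c0 <- round(centre_um[ax] / voxel[ax]) + 1
    max(1, c0 - half):min(d[ax], c0 + half)
  })
  g <- lapply(1:3, function(ax) {
    x <- (idx[[ax]] - 1) * voxel[ax]
    exp(-((x - centre_um[ax])^2) / (2 * sigma_um^2))
  })
  blob <- amplitude * outer(outer(g[[1]], g[[2]]), g[[3]])
  vol[idx[[1]], idx[[2]], idx[[3]]] <-
    vol[idx[[1]], idx[[2]], idx[[3]]] + blob
  vol
}

#' Simulate a ground-truthed 4D nucleus movie
#'
#' Renders each nucleus as an isotropic 3D Gaussian blob in micrometre space
#' (through anisotropic voxels) whose full width at half maximum equals the
#' nuclear diameter, i.e. `sigma = diameter / (2 * sqrt(2 * log(2)))`. Each
#' frame, every nucleus takes a directed step plus a mixture of shared and
#' independent fluctuations (see [movie_sim_params()]); the whole field is
#' additionally translated by the cumulative global drift. Noise is added
#' last; ground truth records the exact pre-noise blob centres (drift
#' included, i.e. in acquisition coordinates) and the per-frame cumulative
#' drift.
#'
#' @param params A [movie_sim_params()].
#' @return A list of class `movie_sim` with elements `movie`
#'   ([movie_stack()]), `truth` (tibble: cell_id, cell_type, frame, z_um,
#'   y_um, x_um, diameter_um), `drift` (tibble: frame, dz_um, dy_um, dx_um,
#'   cumulative), and `params`.
#' @export
simulate_movie <- function(params) {
  stopifnot(inherits(params, "movie_sim_params"))
  p <- params
  with_seed(p$seed, {
    d <- p$image_shape            # (t, z, y, x)
    voxel <- p$voxel_size_um
    extent <- (d[2:4] - 1) * voxel
    n <- p$n_pmec + p$n_icp
    dt <- p$frame_interval_min

    # seed nuclei so that the mean path (directed motion + drift) stays inside
    # the field with a margin on every axis
    disp_end <- (p$direction * max(p$speed_um_per_min) * dt +
                   p$global_drift_um_per_frame) * (d[1] - 1)
    margin <- pmin(c(3.5, 4, 4), extent * 0.2)
    lo <- margin + pmax(0, -disp_end)
    hi <- extent - margin - pmax(0, disp_end)
    box <- cbind(lo, hi)
    if (any(hi <= lo))
      stop("field too small to contain the programmed motion")

    cell_type <- rep(c("PMEC", "ICP"), c(p$n_pmec, p$n_icp))
    dia_par <- rbind(p$diameter_um_pmec, p$diameter_um_icp)[
      match(cell_type, c("PMEC", "ICP")), , drop = FALSE]
    diameter <- pmax(0.5, rnorm(n, dia_par[, 1], dia_par[, 2]))
    speed <- p$speed_um_per_min[match(cell_type, c("PMEC", "ICP"))]
    pos0 <- seed_positions(n, box, p$min_separation_um, diameter)

    # motion model: positions[cell, axis, frame] excluding drift
    pos <- array(NA_real_, c(n, 3, d[1]))
    pos[, , 1] <- pos0
    rho <- p$coordination_rho
    sn <- p$step_noise_sd_um
    for (t in 2:max(2, d[1])) {
      if (d[1] < 2) break
      shared <- rnorm(3, 0, sn)
      indep <- matrix(rnorm(3 * n, 0, sn), n, 3)
      step <- matrix(p$direction, n, 3, byrow = TRUE) * speed * dt +
        rho * matrix(shared, n, 3, byrow = TRUE) + (1 - rho) * indep
      pos[, , t] <- pos[, , t - 1] + step
    }

    cum_drift <- t(vapply(seq_len(d[1]), function(t)
      (t - 1) * p$global_drift_um_per_frame, numeric(3)))

    if (any(pos0 < 0) || any(sweep(pos0, 2, extent) > 0))
      stop("nuclei initialized outside the field")

    sigma <- diameter / (2 * sqrt(2 * log(2)))
    data <- array(p$background_level, dim = d)
    truth <- vector("list", d[1])
    for (t in seq_len(d[1])) {
      vol <- array(p$background_level, dim = d[2:4])
      centres <- matrix(pos[, , t], n, 3) +
        matrix(cum_drift[t, ], n, 3, byrow = TRUE)
      for (i in seq_len(n))
        vol <- render_blob(vol, centres[i, ], sigma[i], p$peak_intensity, voxel)
      if (p$poisson_noise) vol[] <- stats::rpois(length(vol), pmax(vol, 0))
      if (p$noise_sd > 0) vol <- vol + rnorm(length(vol), 0, p$noise_sd)
      vol[vol < 0] <- 0
      vol[vol > p$dynamic_range] <- p$dynamic_range
      data[t, , , ] <- vol
      truth[[t]] <- tibble(
        cell_id = seq_len(n), cell_type = cell_type, frame = t,
        z_um = centres[, 1], y_um = centres[, 2], x_um = centres[, 3],
        diameter_um = diameter)
    }

    list(movie = movie_stack(data, voxel, dt),
         truth = dplyr::arrange(dplyr::bind_rows(truth),
                                .data$cell_id, .data$frame),
         drift = tibble(frame = seq_len(d[1]),
                        dz_um = cum_drift[, 1], dy_um = cum_drift[, 2],
                        dx_um = cum_drift[, 3]),
         params = p) |>
      structure(class = "movie_sim")
  })
}

#' Write a simulated movie and its ground truth to disk
#'
#' Emits `movie.tif` (+ JSON calibration sidecar), `truth.csv` and
#' `drift.csv` under `dir`.
#'
#' @param sim A `movie_sim` from [simulate_movie()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_movie_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "movie_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_movie_tiff(sim$movie, file.path(dir, "movie.tif"),
                   max_value = sim$params$dynamic_range)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(sim$drift, file.path(dir, "drift.csv"), row.names = FALSE)
  invisible(dir)
}
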