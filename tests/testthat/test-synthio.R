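test_that("movie simulation is deterministic and respects the motion model", {
  p <- small_movie_params(seed = 7)
  a <- simulate_movie(p)
  b <- simulate_movie(p)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth, b$truth)

  # bookkeeping: one ground-truth row per cell per frame
  expect_equal(nrow(a$truth), (p$n_pmec + p$n_icp) * p$image_shape[1])
  expect_false(anyNA(a$movie$data))
  expect_true(all(a$movie$data >= 0 & a$movie$data <= p$dynamic_range))
})

test_that("a static, noise-free movie has identical frames", {
  p <- small_movie_params(speed_um_per_min = 0, step_noise_sd_um = 0,
                          global_drift_um_per_frame = c(0, 0, 0),
                          noise_sd = 0, seed = 3)
  sim <- simulate_movie(p)
  f1 <- sim$movie$data[1, , , ]
  for (t in 2:dim(sim$movie$data)[1])
    expect_equal(sim$movie$data[t, , , ], f1)
})

test_that("invalid movie parameters error", {
  expect_error(movie_sim_params(frame_interval_min = 0), "positive")
  expect_error(movie_sim_params(coordination_rho = 1.5), "0, 1")
  expect_error(movie_sim_params(n_pmec = 0, n_icp = 0), "at least one")
  # programmed motion that cannot fit the field
  p <- small_movie_params(speed_um_per_min = 10)
  expect_error(simulate_movie(p), "field too small")
})

test_that("rendered blob centroids match ground truth within half a voxel", {
  # two isolated small blobs so the box centroid sees one blob, untruncated
  p <- small_movie_params(noise_sd = 0, step_noise_sd_um = 0,
                          global_drift_um_per_frame = c(0, 0, 0),
                          n_pmec = 2, n_icp = 0, min_separation_um = 8,
                          seed = 11)
  sim <- simulate_movie(p)
  voxel <- sim$movie$voxel_size_um
  vol <- sim$movie$data[1, , , ]
  tr <- sim$truth[sim$truth$frame == 1, ]
  for (i in seq_len(nrow(tr))) {
    ctr <- c(tr$z_um[i], tr$y_um[i], tr$x_um[i])
    # intensity-weighted centroid in a box around the true centre
    half <- tr$diameter_um[i]
    idx <- lapply(1:3, function(ax) {
      rng <- round((ctr[ax] + c(-half, half)) / voxel[ax]) + 1
      max(1, rng[1]):min(dim(vol)[ax], rng[2])
    })
    sub <- vol[idx[[1]], idx[[2]], idx[[3]]] - p$background_level
    sub[sub < 0] <- 0
    w <- sum(sub)
    for (ax in 1:3) {
      coords <- (idx[[ax]] - 1) * voxel[ax]
      est <- sum(apply(sub, ax, sum) * coords) / w
      expect_lt(abs(est - ctr[ax]), voxel[ax] / 2)
    }
  }
})

test_that("programmed coordination increases neighbour step correlation", {
  cors <- vapply(c(0, 0.5, 1), function(rho) {
    p <- movie_sim_params(image_shape = c(t = 25, z = 10, y = 96, x = 160),
                          n_pmec = 8, n_icp = 0, speed_um_per_min = 0.3,
                          global_drift_um_per_frame = c(0, 0, 0),
                          min_separation_um = 3.5,
                          coordination_rho = rho, step_noise_sd_um = 0.3,
                          noise_sd = 0, seed = 5)
    sim <- simulate_movie(p)
    # step-fluctuation correlation between the first two cells, from truth
    steps <- function(cid) {
      tr <- sim$truth[sim$truth$cell_id == cid, ]
      tr <- tr[order(tr$frame), ]
      cbind(diff(tr$z_um), diff(tr$y_um), diff(tr$x_um))
    }
    s1 <- steps(1); s2 <- steps(2)
    cor(as.numeric(scale(s1, scale = FALSE)),
        as.numeric(scale(s2, scale = FALSE)))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_lt(abs(cors[1]), 0.35)
  expect_gt(cors[3], 0.99)
})

test_that("epithelium renders programmed peaks at the programmed place", {
  p <- small_epithelium_params(
    peaks = tibble::tibble(marker = "m", position_um = 2,
                           amplitude = 120, fwhm_um = 1.0),
    noise_sd = 0, amplitude_jitter_sd = 0, background_gradient = 0,
    signal_polarity = "bright", seed = 1)
  sim <- simulate_epithelium(p)
  img <- sim$images[["m"]]
  mid_col <- round(sim$rois$x0_um[3] / p$pixel_size_um) + 1
  prof <- img[, mid_col]
  peak_row <- which.max(prof)
  peak_um <- (peak_row - 1) * p$pixel_size_um - p$apical_y_um
  expect_lt(abs(peak_um - 2), p$pixel_size_um + 1e-9)
  expect_equal(max(prof), 120 + p$background_level, tolerance = 1e-6)

  # rendered FWHM of the generating profile equals the programmed value
  dist_um <- (seq_len(nrow(img)) - 1) * p$pixel_size_um - p$apical_y_um
  tb <- tibble::tibble(distance_um = dist_um,
                       mean_gray = prof - p$background_level)
  r <- fwhm(tb, c(0, 10))
  expect_lt(abs(r$fwhm_um - 1.0), p$pixel_size_um + 1e-9)
})

test_that("epithelium seeds vary noise but not geometry", {
  base <- list(seed = 1)
  a <- simulate_epithelium(small_epithelium_params(seed = 1))
  b <- simulate_epithelium(small_epithelium_params(seed = 2))
  expect_false(identical(a$images[[1]], b$images[[1]]))
  expect_identical(a$rois$x0_um, b$rois$x0_um)
  expect_identical(a$peaks, b$peaks)
  expect_error(epithelium_sim_params(pixel_size_um = 0),
               "positive")
  expect_false(anyNA(a$images[[1]]))
  expect_true(all(a$images[[1]] >= 0 & a$images[[1]] <= 255))
})

test_that("movies round-trip through TIFF with calibration sidecar", {
  p <- small_movie_params(image_shape = c(t = 2, z = 4, y = 16, x = 16),
                          n_pmec = 1, n_icp = 0, speed_um_per_min = 0,
                          global_drift_um_per_frame = c(0, 0, 0),
                          min_separation_um = 2, seed = 2)
  sim <- simulate_movie(p)
  path <- tempfile(fileext = ".tif")
  write_movie_tiff(sim$movie, path)
  back <- read_movie_tiff(path)
  expect_equal(back$voxel_size_um, sim$movie$voxel_size_um)
  expect_equal(back$frame_interval_min, sim$movie$frame_interval_min)
  # 16-bit storage quantizes to ~1/257 of the dynamic range
  expect_lt(max(abs(back$data - sim$movie$data)), 255 / 65535 * 1.01)
  file.remove(path, paste0(path, ".json"))
})
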