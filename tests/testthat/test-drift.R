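test_that("a constructed integer translation is estimated exactly", {
  set.seed(1)
  f1 <- array(rnorm(8 * 32 * 32, 50, 10), c(8, 32, 32))
  # smooth so correlation has a well-defined peak
  for (z in 1:8) f1[z, , ] <- mean3x3_ref(f1[z, , ])
  f2 <- array(0, dim = dim(f1))
  f2[, 4:32, 2:32] <- f1[, 1:29, 1:31]   # content moved +3 in y, +1 in x
  f2[f2 == 0] <- mean(f1)
  data <- array(0, c(2, 8, 32, 32))
  data[1, , , ] <- f1
  data[2, , , ] <- f2
  movie <- movie_stack(data, c(1.5, 0.25, 0.25), 2)
  dr <- estimate_drift(movie)
  expect_equal(unlist(dr[2, c("dz", "dy", "dx")]), c(dz = 0, dy = 3, dx = 1))
})

test_that("a static movie estimates zero drift everywhere", {
  p <- small_movie_params(speed_um_per_min = 0, step_noise_sd_um = 0,
                          global_drift_um_per_frame = c(0, 0, 0), seed = 4)
  sim <- simulate_movie(p)
  dr <- estimate_drift(sim$movie)
  expect_true(all(dr$dz == 0 & dr$dy == 0 & dr$dx == 0))
})

test_that("sub-voxel per-frame drift accumulates to within one voxel", {
  # 0.5 px/frame in y (0.125 um at 0.25 um/px), static cells
  p <- movie_sim_params(image_shape = c(t = 31, z = 10, y = 128, x = 160),
                        n_pmec = 5, n_icp = 5,
                        speed_um_per_min = 0, step_noise_sd_um = 0,
                        global_drift_um_per_frame = c(0, 0.125, 0),
                        seed = 9)
  sim <- simulate_movie(p)
  dr <- estimate_drift(sim$movie)
  true_vox <- (dr$frame - 1) * 0.125 / 0.25
  expect_true(all(abs(dr$dy - true_vox) <= 1))
  expect_true(all(abs(dr$dz) <= 1))
  expect_true(all(abs(dr$dx) <= 1))
})

test_that("applying a zero drift table is the identity", {
  p <- small_movie_params(seed = 5)
  sim <- simulate_movie(p)
  nt <- dim(sim$movie$data)[1]
  zero <- tibble::tibble(frame = 1:nt, dz = 0L, dy = 0L, dx = 0L)
  expect_equal(apply_drift(sim$movie, zero)$data, sim$movie$data)

  one <- movie_stack(sim$movie$data[1, , , , drop = FALSE],
                     sim$movie$voxel_size_um, 2)
  expect_equal(apply_drift(one, zero[1, ])$data, one$data)
})

test_that("apply-then-estimate leaves at most one voxel of residual drift", {
  p <- small_movie_params(global_drift_um_per_frame = c(0, 0.25, 0.5),
                          speed_um_per_min = 0, seed = 6)
  sim <- simulate_movie(p)
  dr <- estimate_drift(sim$movie)
  comp <- apply_drift(sim$movie, dr)
  resid <- estimate_drift(comp)
  expect_true(all(abs(resid$dz) <= 1))
  expect_true(all(abs(resid$dy) <= 1))
  expect_true(all(abs(resid$dx) <= 1))
})

test_that("excessive shifts error and blank frames warn", {
  p <- small_movie_params(seed = 2, image_shape = c(t = 2, z = 4, y = 16, x = 16),
                          n_pmec = 1, n_icp = 0, speed_um_per_min = 0,
                          global_drift_um_per_frame = c(0, 0, 0),
                          min_separation_um = 2)
  sim <- simulate_movie(p)
  bad <- tibble::tibble(frame = 1:2, dz = c(0L, 0L), dy = c(0L, 20L),
                        dx = c(0L, 0L))
  expect_error(apply_drift(sim$movie, bad), "exceeds")
  blank <- movie_stack(array(5, c(2, 4, 16, 16)), c(1.5, 0.25, 0.25), 2)
  # each projection and pass warns once
  w <- testthat::capture_warnings(dr <- estimate_drift(blank))
  expect_true(length(w) > 0 && all(grepl("blank", w)))
  expect_true(all(dr$dy == 0))
})

test_that("restore_coordinates inverts the applied image shifts", {
  pts <- tibble::tibble(frame = c(1L, 2L), z_um = c(3, 3), y_um = c(5, 5),
                        x_um = c(7, 7))
  dr <- tibble::tibble(frame = 1:2, dz = c(0L, 1L), dy = c(0L, 3L),
                       dx = c(0L, 1L))
  voxel <- c(1.5, 0.25, 0.25)
  out <- restore_coordinates(pts, dr, voxel)
  expect_equal(out$z_um, c(3, 3 + 1.5))
  expect_equal(out$y_um, c(5, 5 + 0.75))
  expect_equal(out$x_um, c(7, 7.25))

  zero <- tibble::tibble(frame = 1:2, dz = 0L, dy = 0L, dx = 0L)
  expect_equal(restore_coordinates(pts, zero, voxel), pts)
  bad <- pts; bad$frame <- c(1L, 9L)
  expect_error(restore_coordinates(bad, dr, voxel), "outside")
})

test_that("detection commutes with drift compensation after restoration", {
  p <- small_movie_params(global_drift_um_per_frame = c(0, 0.25, 0.5),
                          speed_um_per_min = 0, noise_sd = 5, seed = 8)
  sim <- simulate_movie(p)
  det_plain <- detect_nuclei(sim$movie, radius_um = c(1.5, 3))
  dr <- estimate_drift(sim$movie)
  det_comp <- detect_nuclei(sim$movie, radius_um = c(1.5, 3), drift = dr)
  restored <- restore_coordinates(det_comp, dr, sim$movie$voxel_size_um)
  # match restored detections against plain detections frame by frame
  m <- match_detections(
    restored,
    dplyr::mutate(det_plain, cell_id = dplyr::row_number()),
    match_radius_um = 1.5)
  expect_gte(m$recall, 0.95)
  got <- dplyr::left_join(
    m$matches,
    dplyr::mutate(det_plain, cell_id = dplyr::row_number()),
    by = "cell_id")
  expect_true(all(got$distance_um <= 1.5))
})
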