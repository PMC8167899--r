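px <- 0.1

test_that("line profiles reproduce flat and gradient images", {
  img <- matrix(100, 200, 200)
  roi <- list(x0_um = 10, y0_um = 5, x1_um = 10, y1_um = 15, width_px = 60,
              apical_offset_um = 1)
  prof <- sample_line_profile(img, roi, px)
  expect_true(all(prof$mean_gray == 100))
  expect_equal(prof$distance_um[1], -1)
  expect_equal(diff(prof$distance_um), rep(px, nrow(prof) - 1))

  grad <- matrix(rep(seq(0, 199) * 2, 200), 200, 200)  # ramp along y
  pg <- sample_line_profile(grad, roi, px)
  expect_equal(pg$mean_gray[1], 2 * 5 / px, tolerance = 1e-6)
  expect_equal(tail(pg$mean_gray, 1), 2 * 15 / px, tolerance = 1e-6)
  steps <- diff(pg$mean_gray)
  expect_lt(max(abs(steps - steps[1])), 1e-8)

  outside <- list(x0_um = 1, y0_um = -5, x1_um = 1, y1_um = 5, width_px = 3)
  expect_error(sample_line_profile(img, outside, px), "outside")
})

test_that("profile intensity is linear in image intensity", {
  sim <- simulate_epithelium(small_epithelium_params(
    noise_sd = 0, amplitude_jitter_sd = 0, signal_polarity = "bright",
    seed = 3))
  img <- sim$images[[1]]
  roi <- sim$rois[2, ]
  p1 <- sample_line_profile(img, roi, px)
  p3 <- sample_line_profile(3 * img, roi, px)
  expect_equal(p3$mean_gray, 3 * p1$mean_gray, tolerance = 1e-12)
})

test_that("cell averaging enforces the similar-length rule and preserves shape", {
  grid <- seq(-1, 17, by = px)
  shape <- function(len_um) {
    g <- seq(-1, len_um, by = px)
    tibble::tibble(distance_um = g,
                   mean_gray = 100 * exp(-(g - 5)^2 / (2 * 0.5^2)))
  }
  profs <- dplyr::bind_rows(
    purrr::imap_dfr(seq(15, 15.9, by = 0.1), function(len, i) {
      p <- shape(len); p$cell_id <- i; p
    }))
  avg <- average_cell_profiles(profs)
  expect_equal(avg$distance_um[which.max(avg$mean_gray)], 5,
               tolerance = px + 1e-9)

  ident <- dplyr::bind_rows(lapply(1:10, function(i) {
    p <- shape(15); p$cell_id <- i; p
  }))
  avg2 <- average_cell_profiles(ident)
  expect_equal(avg2$mean_gray, shape(15)$mean_gray)

  flat <- dplyr::bind_rows(
    tibble::tibble(cell_id = 1, distance_um = grid, mean_gray = 50),
    tibble::tibble(cell_id = 2, distance_um = grid, mean_gray = 150))
  expect_warning(avg3 <- average_cell_profiles(flat), "only 2")
  expect_true(all(avg3$mean_gray == 100))

  # length outliers are dropped with a warning
  bad <- dplyr::bind_rows(ident,
                          {
                            p <- shape(20); p$cell_id <- 11L; p
                          })
  expect_warning(avg4 <- average_cell_profiles(bad), "median length")
  expect_equal(avg4$mean_gray, avg2$mean_gray)

  expect_error(suppressWarnings(average_cell_profiles(
    dplyr::bind_rows(ident[ident$cell_id == 1, ],
                     {
                       p <- shape(20); p$cell_id <- 2L; p
                     }))), "fewer than 2")
})

test_that("condition averaging is a pointwise mean that keeps embryo curves", {
  grid <- seq(-1, 16, by = px)
  mk <- function(id, amp) tibble::tibble(
    embryo_id = id, distance_um = grid,
    mean_gray = amp * exp(-(grid - 2)^2 / (2 * 0.4^2)))
  cond <- condition_average(dplyr::bind_rows(mk("a", 100), mk("b", 140)))
  expect_equal(max(cond$mean_gray), 120, tolerance = 1e-9)
  expect_false(is.null(attr(cond, "embryos")))

  same <- condition_average(dplyr::bind_rows(lapply(1:6, function(i)
    mk(paste0("e", i), 100))))
  expect_equal(same$mean_gray, mk("x", 100)$mean_gray)
  expect_error(condition_average(mk("a", 100)), "at least 2")

  p <- plot_condition_profile(cond)
  expect_s3_class(p, "ggplot")
})

test_that("resampling conserves flat profiles exactly", {
  profs <- dplyr::bind_rows(lapply(1:3, function(i) tibble::tibble(
    cell_id = i, distance_um = seq(-1, 15 + 0.03 * i, by = px),
    mean_gray = 80)))
  avg <- suppressWarnings(average_cell_profiles(profs))
  expect_true(all(avg$mean_gray == 80))
})

test_that("nuclear mean gray averages ellipses then embryos", {
  img <- matrix(100, 300, 300)
  rois <- tibble::tibble(cx_um = runif(30, 5, 25), cy_um = runif(30, 5, 25),
                         rx_um = 1.5, ry_um = 1)
  expect_equal(as.numeric(nuclear_mean_gray(img, rois, px)), 100)

  # 15 nuclei over a value-80 region, 15 over a value-120 region
  img2 <- img
  img2[1:150, ] <- 80
  img2[151:300, ] <- 120
  rois2 <- tibble::tibble(cx_um = rep(15, 30),
                          cy_um = c(runif(15, 3, 12), runif(15, 18, 27)),
                          rx_um = 1.5, ry_um = 1)
  expect_equal(as.numeric(nuclear_mean_gray(img2, rois2, px)), 100)

  expect_warning(nuclear_mean_gray(img, rois[1:5, ], px), "expected 30")
  bad <- tibble::tibble(cx_um = 200, cy_um = 200, rx_um = 0.01,
                        ry_um = 0.01)
  expect_error(suppressWarnings(nuclear_mean_gray(img, bad, px)), "empty")
})

test_that("wider line averaging reduces profile noise monotonically", {
  set.seed(31)
  base <- matrix(50, 300, 300)
  widths <- c(4, 60)
  vars <- vapply(widths, function(w) {
    vals <- replicate(16, {
      img <- base + matrix(rnorm(300 * 300, 0, 10), 300, 300)
      roi <- list(x0_um = 15, y0_um = 5, x1_um = 15, y1_um = 20,
                  width_px = w, apical_offset_um = 1)
      mean(sample_line_profile(img, roi, px)$mean_gray[50])
    })
    var(vals)
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})
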