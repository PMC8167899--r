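test_that("instantaneous speeds follow displacement over time", {
  trk <- make_track(cbind(0, 0, 2.4 * (0:9)))
  sp <- instantaneous_speeds(trk, frame_interval_min = 2)
  expect_equal(sp$speed_um_per_min, rep(1.2, 9))

  still <- make_track(cbind(1, 1, rep(1, 5)))
  expect_equal(instantaneous_speeds(still, 2)$speed_um_per_min, rep(0, 4))

  sp4 <- instantaneous_speeds(trk, frame_interval_min = 4)
  expect_equal(sp4$speed_um_per_min, sp$speed_um_per_min / 2)

  expect_error(instantaneous_speeds(make_track(cbind(0, 0, 0)), 2),
               "at least 2")
})

test_that("track velocity is the mean instantaneous speed", {
  trk <- make_track(cbind(0, 0, c(0, 0, 2.4)))
  expect_equal(track_velocity(trk, 2)$velocity_um_per_min, 0.6)
  const <- make_track(cbind(0, 0, 1.7 * (0:5)))
  expect_equal(track_velocity(const, 2)$velocity_um_per_min, 0.85)
})

test_that("directional persistence matches the net-over-path geometry", {
  straight <- make_track(cbind(0, 0, 0:10))
  expect_equal(directional_persistence(straight)$persistence, 1.0)

  outback <- make_track(cbind(0, 0, c(0:5, 4:0)))
  expect_equal(directional_persistence(outback)$persistence, 0.0)

  right_angle <- make_track(cbind(c(0, 0, 0), c(0, 0, 3), c(0, 3, 3)))
  expect_equal(directional_persistence(right_angle)$persistence,
               sqrt(2) / 2)

  degenerate <- make_track(cbind(0, 0, c(1, 1, 1)))
  expect_warning(out <- directional_persistence(degenerate), "zero-path")
  expect_true(is.na(out$persistence))
})

test_that("coordination is 1 for identical, -1 for opposed, ~0 for independent", {
  set.seed(2)
  steps <- cbind(rnorm(10), rnorm(10), rnorm(10))
  pos <- apply(rbind(0, steps), 2, cumsum)
  a <- make_track(pos, 1L)
  b <- make_track(sweep(pos, 2, c(0, 2, 0), "+"), 2L)
  co <- coordination(dplyr::bind_rows(a, b), 2)
  expect_equal(co$coordination, c(1, 1))
  expect_equal(co$partner_track_id, c(2L, 1L))

  opp <- make_track(sweep(-pos, 2, c(0, 2, 0), "+"), 2L)
  co2 <- coordination(dplyr::bind_rows(a, opp), 2)
  expect_equal(co2$coordination, c(-1, -1))

  # 30 independent random walks: mean coordination within 0.1 of 0
  set.seed(77)
  walks <- purrr::map_dfr(1:30, function(i) {
    st <- cbind(rnorm(29), rnorm(29), rnorm(29))
    p0 <- runif(3, 0, 50)
    make_track(sweep(apply(rbind(0, st), 2, cumsum), 2, p0, "+"), i)
  })
  co3 <- coordination(walks, 2)
  expect_lt(abs(mean(co3$coordination)), 0.1)

  # cosine variant agrees on the exact cases
  co4 <- coordination(dplyr::bind_rows(a, b), 2, method = "cosine")
  expect_equal(co4$coordination, c(1, 1))
})

test_that("coordination flags zero-variance series and needs two tracks", {
  a <- make_track(cbind(0, 0, rep(1, 5)), 1L)
  b <- make_track(cbind(0, 2, rep(1, 5)), 2L)
  expect_warning(co <- coordination(dplyr::bind_rows(a, b), 2),
                 "zero-variance")
  expect_true(all(is.na(co$coordination)))
  expect_error(coordination(a, 2), "at least 2")
})

test_that("metrics are invariant to a constant position offset", {
  set.seed(5)
  trk <- dplyr::bind_rows(
    make_track(cbind(cumsum(rnorm(8, 0.1)), cumsum(rnorm(8, 0.2)),
                     cumsum(rnorm(8, 1))), 1L),
    make_track(cbind(5 + cumsum(rnorm(8, 0.1)), 5 + cumsum(rnorm(8, 0.2)),
                     5 + cumsum(rnorm(8, 1))), 2L))
  shifted <- trk
  shifted$z_um <- shifted$z_um + 11
  shifted$y_um <- shifted$y_um - 7
  shifted$x_um <- shifted$x_um + 3
  m1 <- track_metrics(trk, 2)
  m2 <- track_metrics(shifted, 2)
  expect_equal(m1, m2)
})

test_that("embryo summaries average per cell type and report counts", {
  m <- tibble::tibble(track_id = 1:15, cell_type = "PMEC",
                      velocity_um_per_min = 1.1, persistence = 0.9,
                      partner_track_id = 1L, coordination = 0.8)
  s <- embryo_summary(m, "e1")
  expect_equal(s$velocity_um_per_min, 1.1)
  expect_equal(s$n_tracks, 15)

  m2 <- tibble::tibble(track_id = 1:3, cell_type = "ICP",
                       velocity_um_per_min = c(1, 2, 3),
                       persistence = c(0.5, NA, 0.7),
                       partner_track_id = 1L,
                       coordination = c(0.1, 0.2, 0.3))
  expect_warning(s2 <- embryo_summary(m2, "e2"), "fewer than 15")
  expect_equal(s2$velocity_um_per_min, 2)
  expect_equal(s2$persistence, 0.6)
  expect_equal(s2$n_persistence, 2)

  expect_error(embryo_summary(m[0, ], "e3"), "no tracks")
})

test_that("group comparison matches closed-form t and F statistics", {
  # identical samples: t = 0, p = 1
  same <- tibble::tibble(condition = rep(c("a", "b"), each = 3),
                         v = rep(c(2, 3, 4), 2))
  gc0 <- compare_groups(same, "v")
  expect_equal(gc0$tests$statistic, 0)
  expect_equal(gc0$tests$p.value, 1)

  # forced separation: three stars
  set.seed(8)
  sep <- tibble::tibble(condition = rep(c("wt", "mut"), each = 6),
                        v = c(rnorm(6, 0, 0.01), rnorm(6, 10, 0.01)))
  gc1 <- compare_groups(sep, "v", control = "wt")
  expect_lt(gc1$tests$p.value, 0.001)
  expect_equal(gc1$tests$stars, "***")

  # closed-form oracle for the equal-variance t test and one-way ANOVA
  set.seed(10)
  x <- rnorm(6, 1, 0.3); y <- rnorm(7, 1.4, 0.3); z <- rnorm(6, 0.8, 0.3)
  dat <- tibble::tibble(condition = rep(c("wt", "m1", "m2"),
                                        c(6, 7, 6)), v = c(x, y, z))
  gc <- compare_groups(dat, "v", control = "wt")
  tt_oracle <- function(a, b) {
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    list(t = t, p = 2 * stats::pt(-abs(t), length(a) + length(b) - 2))
  }
  o1 <- tt_oracle(y, x)
  expect_equal(gc$tests$statistic[gc$tests$condition == "m1"], o1$t,
               tolerance = 1e-10)
  expect_equal(gc$tests$p.value[gc$tests$condition == "m1"], o1$p,
               tolerance = 1e-10)
  groups <- list(x, y, z)
  gm <- vapply(groups, mean, numeric(1))
  n <- vapply(groups, length, numeric(1))
  grand <- sum(gm * n) / sum(n)
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / 2) / (ssw / (sum(n) - 3))
  p_f <- stats::pf(f, 2, sum(n) - 3, lower.tail = FALSE)
  expect_equal(gc$anova$statistic, f, tolerance = 1e-10)
  expect_equal(gc$anova$p.value, p_f, tolerance = 1e-10)

  expect_error(compare_groups(tibble::tibble(condition = c("a", "b", "b"),
                                             v = 1:3), "v"),
               "at least 2")
})

test_that("significance stars switch exactly at the declared thresholds", {
  expect_equal(significance_stars(c(0.049, 0.05, 0.051)), c("*", "*", ""))
  expect_equal(significance_stars(c(0.009, 0.01, 0.011)), c("**", "**", "*"))
  expect_equal(significance_stars(c(0.0009, 0.001, 0.0011)),
               c("***", "***", "**"))
})

test_that("tidy and glance expose comparison results as tibbles", {
  set.seed(4)
  dat <- tibble::tibble(condition = rep(c("wt", "m1", "m2"), each = 4),
                        v = rnorm(12))
  gc <- compare_groups(dat, "v", control = "wt")
  td <- tidy(gc)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$condition, c("m1", "m2"))
  gl <- glance(gc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_conditions, 3)
  expect_false(is.na(gl$anova_p.value))
  p <- autoplot(gc)
  expect_s3_class(p, "ggplot")
})
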