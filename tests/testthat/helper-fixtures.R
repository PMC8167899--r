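# shared fixtures: everything is generated in code at test time

# small, fast movie for unit tests (full-size defaults are exercised in the
# acceptance tests)
small_movie_params <- function(...) {
  defaults <- list(image_shape = c(t = 8, z = 10, y = 96, x = 160),
                   n_pmec = 3, n_icp = 3)
  do.call(movie_sim_params, utils::modifyList(defaults, list(...)))
}

# small epithelium for unit tests
small_epithelium_params <- function(...) {
  defaults <- list(image_shape_px = c(y = 512, x = 512),
                   n_cells = 6, cell_width_um = 5, line_width_px = 40)
  do.call(epithelium_sim_params, utils::modifyList(defaults, list(...)))
}

# full detect -> link -> curate -> classify -> restore chain
track_chain <- function(sim, radius_um = c(1.5, 3.0), max_link = 4) {
  dr <- estimate_drift(sim$movie)
  det <- detect_nuclei(sim$movie, radius_um = radius_um, drift = dr)
  nt <- dim(sim$movie$data)[1]
  trk <- link_frames(det, max_link, n_frames = nt) |>
    curate_tracks(n_frames = nt) |>
    classify_tracks()
  rest <- restore_coordinates(trk[, c("frame", "z_um", "y_um", "x_um")], dr,
                              sim$movie$voxel_size_um)
  trk$z_um <- rest$z_um
  trk$y_um <- rest$y_um
  trk$x_um <- rest$x_um
  trk
}

# embryo-level profile of one marker image through the standard chain
profile_chain <- function(sim, marker, pixel_size_um = NULL, ...) {
  px <- pixel_size_um %||% sim$params$pixel_size_um
  img <- preprocess_fixed_image(sim$images[[marker]], ...)
  cells <- purrr::map_dfr(seq_len(nrow(sim$rois)), function(i) {
    p <- sample_line_profile(img, sim$rois[i, ], px)
    p$cell_id <- sim$rois$cell_id[i]
    p
  })
  suppressWarnings(average_cell_profiles(cells))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent gated-assignment optimum by bitmask dynamic programming:
# min over all partial matchings of sum(linked d^2) + dmax^2 per unmatched
# point, links forbidden beyond dmax
oracle_link_cost <- function(pos_a, pos_b, dmax) {
  n <- nrow(pos_a)
  m <- nrow(pos_b)
  if (n == 0 || m == 0) return((n + m) * dmax^2)
  d2 <- outer(rowSums(pos_a^2), rowSums(pos_b^2), "+") -
    2 * pos_a %*% t(pos_b)
  d2 <- pmax(d2, 0)
  gate <- d2 <= dmax^2
  popcount <- function(mask) sum(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) > 0)
  memo <- matrix(NA_real_, n + 1, bitwShiftL(1L, m))
  rec <- function(i, mask) {
    if (i > n) return((m - popcount(mask)) * dmax^2)
    if (!is.na(memo[i, mask + 1])) return(memo[i, mask + 1])
    best <- dmax^2 + rec(i + 1L, mask)       # leave a_i unmatched
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (gate[i, j] && bitwAnd(mask, bit) == 0L)
        best <- min(best, d2[i, j] + rec(i + 1L, bitwOr(mask, bit)))
    }
    memo[i, mask + 1] <<- best
    best
  }
  rec(1L, 0L)
}

# build a track tibble from a matrix of positions (rows = frames, cols z/y/x)
make_track <- function(pos, track_id = 1L, diameter_um = 3) {
  tibble::tibble(track_id = track_id, frame = seq_len(nrow(pos)),
                 z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
                 diameter_um = diameter_um)
}

# reference 3x3 mean smoother (brute force, edge-truncated)
mean3x3_ref <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (r in 1:nr) for (c in 1:nc) {
    rs <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, c - 1):min(nc, c + 1)
    out[r, c] <- mean(m[rs, cs])
  }
  out
}

# render one isotropic Gaussian blob into a (z, y, x) volume, in um space
render_gaussian_volume <- function(dims, voxel, centre_um, diameter_um,
                                   amplitude = 100, background = 0) {
  sigma <- diameter_um / (2 * sqrt(2 * log(2)))
  g <- lapply(1:3, function(ax) {
    x <- (seq_len(dims[ax]) - 1) * voxel[ax]
    exp(-((x - centre_um[ax])^2) / (2 * sigma^2))
  })
  background + amplitude * outer(outer(g[[1]], g[[2]]), g[[3]])
}
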