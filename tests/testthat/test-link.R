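test_that("an unambiguous moving spot links into one full-length track", {
  spots <- data.frame(frame = 1:10, x_um = 0.2 * (1:10), y_um = 1)
  tr <- link_spots(spots, link_radius = 0.5, max_gap = 1)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
})

test_that("two well-separated static spots give exactly two tracks", {
  spots <- rbind(data.frame(frame = 1:5, x_um = 1, y_um = 1),
                 data.frame(frame = 1:5, x_um = 5, y_um = 5))
  tr <- link_spots(spots, link_radius = 0.5, max_gap = 1)
  expect_equal(length(unique(tr$track_id)), 2)
})

test_that("a single missed detection is bridged by gap closing", {
  spots <- data.frame(frame = c(1:4, 6:9), x_um = 0.2 * c(1:4, 6:9), y_um = 2)
  tr <- link_spots(spots, link_radius = 0.5, max_gap = 1)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(attr(tr, "n_gaps"), 1L)
  # without gap closing the track splits
  tr0 <- link_spots(spots, link_radius = 0.5, max_gap = 0)
  expect_equal(length(unique(tr0$track_id)), 2)
})

test_that("frame-to-frame linking equals the exhaustive-assignment oracle", {
  set.seed(99)
  for (rep in 1:40) {
    na <- sample(0:6, 1); nb <- sample(0:6, 1)
    if (na == 0 && nb == 0) next
    a <- data.frame(frame = rep(1, na), x_um = runif(na, 0, 5),
                    y_um = runif(na, 0, 5))
    b <- data.frame(frame = rep(2, nb), x_um = runif(nb, 0, 5),
                    y_um = runif(nb, 0, 5))
    radius <- runif(1, 0.5, 3)
    spots <- rbind(a, b)
    tr <- link_spots(spots, link_radius = radius, max_gap = 0)
    # cost realized by link_spots
    links <- extract_links(tr)
    d2 <- if (nrow(links))
      sum((tr$x_um[links$from] - tr$x_um[links$to])^2 +
          (tr$y_um[links$from] - tr$y_um[links$to])^2) else 0
    cost <- d2 + radius^2 * (na + nb - 2 * nrow(links))
    oracle <- oracle_pair_matching(a$x_um, a$y_um, b$x_um, b$y_um, radius)
    expect_equal(cost, oracle$cost, tolerance = 1e-9)
  }
})

test_that("multi-frame linking of a crossing pair matches per-pair optima", {
  # two comets crossing at constant speed: optimal assignment keeps each
  # on its own straight line
  fr <- 1:6
  a <- data.frame(frame = fr, x_um = 0.3 * fr, y_um = 1.0)
  b <- data.frame(frame = fr, x_um = 2.1 - 0.3 * fr, y_um = 1.5)
  spots <- rbind(a, b)[sample(12), ]
  # link radius admits the 0.3 um steps but not the 0.5 um lane change
  tr <- link_spots(spots, link_radius = 0.35, max_gap = 0)
  expect_equal(length(unique(tr$track_id)), 2)
  for (id in unique(tr$track_id)) {
    y <- tr$y_um[tr$track_id == id]
    expect_equal(length(unique(y)), 1)   # never swaps between the two lines
  }
})

test_that("invalid link radius is rejected", {
  expect_error(link_spots(data.frame(frame = 1, x_um = 1, y_um = 1),
                          link_radius = 0), "link_radius")
})

test_that("track filtering applies the process-inclusion rule", {
  g <- straight_geom(1)
  rois <- geometry_to_rois(g)
  path <- g$neurite_paths[[1]]
  on_path <- point_at_arclength(path, c(10, 10.3, 10.6))
  keep <- data.frame(track_id = 1, frame = 1:3,
                     x_um = on_path[, 1], y_um = on_path[, 2])
  off <- data.frame(track_id = 2, frame = 1:3,
                    x_um = on_path[, 1] + 5, y_um = on_path[, 2] + 5)
  short <- data.frame(track_id = 3, frame = 1:2,
                      x_um = on_path[1:2, 1], y_um = on_path[1:2, 2])
  out <- filter_tracks(rbind(keep, off, short), rois, min_length = 3)
  expect_equal(unique(out$track_id), 1)
  expect_equal(unique(out$neurite_id), 1)
  expect_error(filter_tracks(keep, list(), 3), "ROI")
})
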