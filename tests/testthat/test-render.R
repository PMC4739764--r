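test_that("zero particles with noise off give constant background frames", {
  g <- straight_geom(1)
  p <- sim_params(shot_noise = FALSE, read_noise = 0, n_frames = 3, seed = 1)
  m <- render_movie(g, NULL, p, channels = "particles")
  expect_true(all(m$pixels == p$background_photons))
})

test_that("a static particle's rendered centroid matches truth within 0.1 px", {
  g <- straight_geom(2)
  p <- sim_params(shot_noise = FALSE, read_noise = 0, n_frames = 1, seed = 1)
  s <- 10.37
  m <- render_single_spot(g, s, frames = 1, params = p)
  truth <- point_at_arclength(g$neurite_paths[[1]], s)
  fr <- movie_channel(m, "particles")[[1]] - p$background_photons
  idx <- which(fr > 0, arr.ind = TRUE)
  w <- fr[idx]
  est <- index_to_um(sum(w * idx[, 1]) / sum(w), sum(w * idx[, 2]) / sum(w),
                     p$pixel_size)
  expect_lt(abs(est$x - truth[1, 1]), 0.1 * p$pixel_size)
  expect_lt(abs(est$y - truth[1, 2]), 0.1 * p$pixel_size)
})

test_that("rendering is bit-identical for a fixed seed", {
  g <- straight_geom(3)
  p <- sim_params(seed = 5)
  gt <- simulate_comet_tracks(g, p)
  m1 <- render_movie(g, gt$tracks, p)
  m2 <- render_movie(g, gt$tracks, p)
  expect_identical(m1$pixels, m2$pixels)
})

test_that("every ground-truth track point is rendered exactly once", {
  g <- straight_geom(4)
  p <- sim_params(seed = 6)
  gt <- simulate_comet_tracks(g, p)
  m <- render_movie(g, gt$tracks, p, channels = "particles")
  expect_equal(attr(m, "n_particles_rendered"), nrow(gt$tracks))
})

test_that("optics preconditions are enforced", {
  g <- straight_geom(5)
  p <- sim_params(seed = 1)
  p$psf_sigma <- 0.04          # < pixel_size / 2
  expect_error(render_movie(g, NULL, p), "optics")
  p2 <- sim_params(seed = 1)
  bad <- data.frame(track_id = 1, frame = 1, x_um = -5, y_um = 2)
  expect_error(render_movie(g, bad, p2), "outside the field")
})

test_that("membrane tube follows the tip series", {
  g <- straight_geom(6)
  p <- sim_params(tip_mode = "camsap_growth", tip_dwell_fraction = 1,
                  frame_interval = 60, n_frames = 5, shot_noise = FALSE,
                  read_noise = 0, seed = 7)
  tt <- simulate_tip_dynamics(g, p)
  m <- render_movie(g, NULL, p, tip_series = tt$tip_series,
                    channels = "membrane")
  path <- g$neurite_paths[[1]]
  # a point 1 um beyond the frame-1 tip is dark at frame 1, bright by the
  # frame where the tip has passed it
  probe_s <- tt$tip_series$tip_arclength_um[1] + 0.6
  probe <- point_at_arclength(path, probe_s)
  ij <- um_to_index(probe[1, 1], probe[1, 2], p$pixel_size)
  v1 <- m$pixels[round(ij$row), round(ij$col), 1, 1]
  v5 <- m$pixels[round(ij$row), round(ij$col), 1, 5]
  expect_lt(v1, p$background_photons / 2 + p$membrane_photons / 2)
  expect_gt(v5, p$background_photons / 2 + p$membrane_photons / 2)
})
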