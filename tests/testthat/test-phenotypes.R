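test_that("a static membrane tube yields a constant tip series at its true length", {
  g <- straight_geom(41)
  p <- sim_params(tip_mode = "tip_accumulated", frame_interval = 60,
                  n_frames = 5, tip_start_frac = 0.75, seed = 41)
  tt <- simulate_tip_dynamics(g, p)
  m <- render_movie(g, NULL, p, tip_series = tt$tip_series,
                    channels = "membrane")
  roi <- geometry_to_rois(g)[[1]]
  est <- track_tip(m, roi)
  expect_true(all(est$valid))
  expect_lt(max(abs(est$tip_arclength_um - 15)), 0.15)
})

test_that("linear tip growth is tracked within about a pixel per frame", {
  g <- straight_geom(42, length_um = 25)
  p <- sim_params(tip_mode = "eb1_like", frame_interval = 60, n_frames = 11,
                  tip_start_frac = 0.4, seed = 42)
  tt <- simulate_tip_dynamics(g, p)
  pu <- tt$puncta; pu$peak <- p$punctum_peak_photons
  m <- render_movie(g, pu, p, tip_series = tt$tip_series)
  est <- track_tip(m, geometry_to_rois(g)[[1]])
  cmp <- merge(est, tt$tip_series, by = c("frame", "neurite_id"))
  expect_true(all(cmp$valid.x))
  expect_lt(max(abs(cmp$tip_arclength_um.x - cmp$tip_arclength_um.y)), 0.15)
})

test_that("a blank membrane channel marks every frame invalid", {
  g <- straight_geom(43)
  px <- array(0, c(60, 60, 1, 3))
  m <- mt_movie(px, 0.1, 60, "membrane")
  roi <- new_roi(1, rbind(c(1, 3), c(5, 3)), 1)
  est <- track_tip(m, roi)
  expect_true(all(!est$valid))
})

test_that("growth events follow the non-negative-velocity run rule", {
  mk <- function(s) data.frame(frame = seq_along(s), neurite_id = 1,
                               tip_arclength_um = s, valid = TRUE)
  # monotonic advance of 5 um: one event spanning the series
  ev <- detect_growth_events(mk(seq(10, 15, by = 0.5)), min_growth = 1,
                             smooth_window = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$advance_um, 5)
  expect_equal(c(ev$start_frame, ev$end_frame), c(1, 11))
  # flat series: no events
  expect_equal(nrow(detect_growth_events(mk(rep(10, 8)), 1, 1)), 0)
  # advance - retraction - advance: the retraction splits two events
  s <- c(10, 11, 12, 11.5, 11.5, 12.5, 13.5)
  ev2 <- detect_growth_events(mk(s), min_growth = 1, smooth_window = 1)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$advance_um, c(2, 2))
  # a pure pause does not split a run
  s3 <- c(10, 11, 12, 12, 12, 13, 14)
  ev3 <- detect_growth_events(mk(s3), min_growth = 1, smooth_window = 1)
  expect_equal(nrow(ev3), 1)
  expect_error(detect_growth_events(mk(10), 1, 1), "3 valid")
})

test_that("tip colocalization counts event frames with a punctum in range", {
  roi <- new_roi(1, rbind(c(0, 0), c(20, 0)), 1)
  tip <- data.frame(frame = 1:10, neurite_id = 1,
                    tip_arclength_um = 10 + 0.5 * (0:9), valid = TRUE)
  ev <- data.frame(neurite_id = 1, start_frame = 1, end_frame = 10,
                   advance_um = 4.5)
  at_tip <- data.frame(frame = 1:10, x_um = 10 + 0.5 * (0:9), y_um = 0)
  expect_equal(tip_colocalization_fraction(at_tip, tip, ev, roi, 1), 1)
  away <- data.frame(frame = 1:10, x_um = 2, y_um = 0)
  expect_equal(tip_colocalization_fraction(away, tip, ev, roi, 1), 0)
  half <- at_tip; half$x_um[1:5] <- 2
  expect_equal(tip_colocalization_fraction(half, tip, ev, roi, 1), 0.5)
  expect_error(tip_colocalization_fraction(at_tip, tip, ev[0, ], roi, 1),
               "no growth events")
})

test_that("tip-accumulation classification separates the generative modes", {
  roi <- new_roi(1, rbind(c(0, 0), c(20, 0)), 1)
  tip <- data.frame(frame = 1, neurite_id = 1, tip_arclength_um = 20,
                    valid = TRUE)
  all_at_tip <- data.frame(frame = 1, x_um = c(19.5, 19.8, 20), y_um = 0,
                           intensity = c(5, 3, 2))
  r <- classify_tip_accumulation(all_at_tip, roi, tip)
  expect_equal(r$class, "tip_accumulated")
  expect_equal(r$mass_fraction, 1)
  spread <- data.frame(frame = 1, x_um = seq(1, 19, by = 2), y_um = 0)
  r2 <- classify_tip_accumulation(spread, roi, tip)
  expect_equal(r2$class, "scattered")
  expect_lt(r2$mass_fraction, 0.25)
  # invariance to uniform intensity rescaling
  scaled <- all_at_tip; scaled$intensity <- scaled$intensity * 137
  expect_equal(classify_tip_accumulation(scaled, roi, tip)$mass_fraction,
               r$mass_fraction)
  no_tip <- tip; no_tip$valid <- FALSE
  expect_equal(classify_tip_accumulation(spread, roi, no_tip)$class,
               "not_assessed")
})

test_that("retrograde clearing requires a somaward centroid shift", {
  roi <- new_roi(1, rbind(c(0, 0), c(20, 0)), 1)
  tip <- data.frame(frame = 1:10, neurite_id = 1, tip_arclength_um = 15,
                    valid = TRUE)
  static <- data.frame(track_id = 1, frame = 1:10, x_um = 14.5, y_um = 0)
  r <- detect_retrograde_clearing(static, roi, tip, treatment_frame = 5)
  expect_false(r$retrograde)
  # static puncta stay put for every positive threshold
  for (thr in c(0.1, 1, 2))
    expect_false(detect_retrograde_clearing(static, roi, tip, 5,
                                            min_displacement = thr)$retrograde)
  moving <- data.frame(track_id = 1, frame = 1:10,
                       x_um = c(rep(14.5, 4), 14.5 - 0.5 * (1:6)), y_um = 0)
  r2 <- detect_retrograde_clearing(moving, roi, tip, treatment_frame = 5)
  expect_true(r2$retrograde)
  expect_equal(r2$displacement_um, 3, tolerance = 1e-9)
  antero <- data.frame(track_id = 1, frame = 1:10,
                       x_um = c(rep(14.5, 4), 14.5 + 0.5 * (1:6)), y_um = 0)
  expect_false(detect_retrograde_clearing(antero, roi, tip, 5)$retrograde)
  # no tip-zone puncta before treatment: not assessed
  far <- data.frame(track_id = 1, frame = 1:10, x_um = 2, y_um = 0)
  expect_true(is.na(detect_retrograde_clearing(far, roi, tip, 5)$retrograde))
  expect_error(detect_retrograde_clearing(static[static$frame > 5, ], roi,
                                          tip, 5), "both sides")
})
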