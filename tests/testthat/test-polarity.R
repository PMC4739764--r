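test_that("comet angle is measured CCW from the outward radial direction", {
  expect_equal(comet_angle(c(1, 0), c(5, 0), c(0, 0)), 0)
  expect_equal(comet_angle(c(-1, 0), c(5, 0), c(0, 0)), 180)
  expect_equal(comet_angle(c(0, 1), c(5, 0), c(0, 0)), 90)
  expect_equal(comet_angle(c(0, -1), c(5, 0), c(0, 0)), 270)
  expect_error(comet_angle(c(0, 0), c(5, 0), c(0, 0)), "zero displacement")
  expect_error(comet_angle(c(1, 0), c(0, 0), c(0, 0)), "radial")
})

test_that("segment subdivision splits at corners and respects the tolerance", {
  straight <- cbind(0:5, 0)
  expect_length(split_linear_segments(straight, 30), 1)
  corner <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(2, 2))
  segs <- split_linear_segments(corner, 30)
  expect_length(segs, 2)
  expect_equal(segs[[1]], corner[1:3, ])
  expect_equal(segs[[2]], corner[3:5, ])
  expect_length(split_linear_segments(corner, 180), 1)
  # concatenation (dropping shared first vertices) reproduces the input
  reassembled <- do.call(rbind, c(list(segs[[1]]),
                                  lapply(segs[-1], function(s) s[-1, , drop = FALSE])))
  expect_equal(reassembled, corner)
})

test_that("single-segment tracks classify by the printed thresholds", {
  expect_equal(classify_comet(track_at_angle(0), c(0, 0))$label, "plus_end_out")
  expect_equal(classify_comet(track_at_angle(180), c(0, 0))$label, "plus_end_in")
  expect_equal(classify_comet(track_at_angle(90), c(0, 0))$label, "excluded")
  expect_equal(classify_comet(track_at_angle(320), c(0, 0))$label, "plus_end_out")
  expect_equal(classify_comet(track_at_angle(240), c(0, 0))$label, "plus_end_in")
  # boundary angles are excluded: the inequalities are strict
  for (theta in c(70, 110, 250, 290))
    expect_equal(classify_comet(track_at_angle(theta), c(0, 0))$label, "excluded")
  expect_error(classify_comet(track_at_angle(0), c(NA, NA)), "center")
})

test_that("every angle receives exactly one of the three labels (partition)", {
  theta <- seq(0, 359.5, by = 0.5)
  lab <- classify_angle(theta)
  expect_true(all(lab %in% c("plus_end_out", "plus_end_in", "excluded")))
  expect_true(all(lab[theta < 70 | theta > 290] == "plus_end_out"))
  expect_true(all(lab[theta > 110 & theta < 250] == "plus_end_in"))
  dead <- (theta >= 70 & theta <= 110) | (theta >= 250 & theta <= 290)
  expect_true(all(lab[dead] == "excluded"))
})

test_that("labels are invariant under a common rotation of the scene", {
  set.seed(21)
  for (rep in 1:25) {
    theta <- runif(1, 0, 360)
    tr <- track_at_angle(theta, radius = runif(1, 2, 15))
    phi <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    tr_rot <- tr %*% t(R)
    expect_equal(classify_comet(tr, c(0, 0))$label,
                 classify_comet(tr_rot, c(0, 0))$label)
  }
})

test_that("curved-track classification uses the majority over segments", {
  # outward run then a corner with a short sideways run: majority = out
  center <- c(0, 0)
  up <- cbind(5, seq(1, 4))                  # radial outward along +y
  side <- cbind(5 + seq(1, 2), 4)            # perpendicular spur
  cl <- classify_comet(rbind(up, side), center, straightness_tol = 30)
  expect_equal(length(cl$segment_angles), 2)
  expect_equal(cl$label, "plus_end_out")
  # one outward and one inward segment tie -> excluded
  out_in <- rbind(c(9, 0), c(10, 0), c(9, 0))
  cl2 <- classify_comet(out_in, c(0, 0), straightness_tol = 30)
  expect_equal(cl2$segment_labels, c("plus_end_out", "plus_end_in"))
  expect_equal(cl2$label, "excluded")
})

test_that("ground-truth tracks away from the soma recover their labels", {
  g <- straight_geom(31, n = 3, curvature = 2)
  p <- sim_params(f_plus_end_out = 0.5, comet_birth_rate = 0.03, seed = 31)
  gt <- simulate_comet_tracks(g, p)
  checked <- 0
  for (id in unique(gt$tracks$track_id)) {
    tr <- gt$tracks[gt$tracks$track_id == id, ]
    if (nrow(tr) < 2) next
    r <- sqrt((tr$x_um - g$soma_center[1])^2 + (tr$y_um - g$soma_center[2])^2)
    if (min(r) <= 2) next
    cl <- classify_comet(cbind(tr$x_um, tr$y_um), g$soma_center)
    expect_equal(cl$label, tr$label[1])
    checked <- checked + 1
  }
  expect_gt(checked, 20)
})

test_that("polarity summaries count and normalize per neurite", {
  g <- straight_geom(32)
  calls <- data.frame(
    track_id = 1:6, neurite_id = c(1, 1, 1, 2, 2, 2),
    n_segments = 1,
    label = c("plus_end_out", "plus_end_out", "plus_end_in",
              "excluded", "excluded", "excluded"),
    angles = "0.00")
  s <- summarize_polarity(calls)
  expect_equal(s$n_out, c(2, 0))
  expect_equal(s$f_out[1], 2 / 3)
  expect_true(is.na(s$f_out[2]))
  expect_equal(s$defined, c(TRUE, FALSE))
  expect_error(summarize_polarity(calls[0, ]), "empty")
})

test_that("condition aggregation reports per-axon mean, s.d. and totals", {
  s2 <- data.frame(neurite_id = 1:2, n_out = c(3, 5), n_in = c(0, 0),
                   n_excluded = 0, f_out = c(1, 1), f_in = c(0, 0),
                   defined = TRUE)
  a <- aggregate_condition(s2)
  expect_equal(a$mean_f_out, 1); expect_equal(a$sd_f_out, 0)
  expect_equal(a$n_axons, 2); expect_equal(a$n_comets, 8)
  s3 <- s2; s3$f_out <- c(0, 1); s3$n_out <- c(0, 5); s3$n_in <- c(3, 0)
  a3 <- aggregate_condition(s3)
  expect_equal(a3$mean_f_out, 0.5)
  expect_equal(a3$sd_f_out, sqrt(0.5), tolerance = 1e-9)
  a1 <- aggregate_condition(s2[1, ])
  expect_true(is.na(a1$sd_f_out))
})

test_that("the cell center estimate honors overrides and finds the soma", {
  m_dummy <- mt_movie(array(1, c(4, 4, 1, 1)), 0.1, 2, "membrane")
  expect_equal(estimate_center(m_dummy, manual_override = c(3.3, 4.4)),
               c(3.3, 4.4))
  # symmetric disk: centre recovered exactly (up to pixel quantization)
  nr <- 101
  img <- matrix(10, nr, nr)
  ctr_px <- c(51, 51)
  for (i in 1:nr) for (j in 1:nr)
    if ((i - ctr_px[1])^2 + (j - ctr_px[2])^2 <= 20^2) img[i, j] <- 200
  m <- mt_movie(array(img, c(nr, nr, 1, 1)), 0.1, 2, "membrane")
  est <- estimate_center(m)
  expect_equal(est, c((51 - 0.5) * 0.1, (51 - 0.5) * 0.1), tolerance = 0.05)
  blank <- mt_movie(array(0, c(8, 8, 1, 1)), 0.1, 2, "membrane")
  expect_error(estimate_center(blank), "soma")
})

test_that("center estimated from a rendered movie is within 1 um of truth", {
  g <- straight_geom(33, n = 2)
  p <- sim_params(seed = 33)
  m <- render_movie(g, NULL, p, channels = "membrane")
  est <- estimate_center(m)
  expect_lt(sqrt(sum((est - g$soma_center)^2)), 1)
})
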