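test_that("degenerate mixtures produce pure label sets", {
  g <- straight_geom(1)
  p <- sim_params(f_plus_end_out = 1, seed = 2)
  gt <- simulate_comet_tracks(g, p)
  expect_true(all(gt$tracks$label == "plus_end_out"))
  p0 <- sim_params(f_plus_end_out = 0, seed = 2)
  gt0 <- simulate_comet_tracks(g, p0)
  expect_true(all(gt0$tracks$label == "plus_end_in"))
  pe <- sim_params(comet_birth_rate = 0, comet_lifetime_mean = 1e-6, seed = 2)
  # note: birth rate 0 also suppresses the steady-state population
  ge <- simulate_comet_tracks(g, pe)
  expect_equal(nrow(ge$tracks), 0)
})

test_that("comet births follow the Poisson expectation (20 um, 0.01/(um s), 60 s -> 12)", {
  g <- straight_geom(3)
  counts <- vapply(1:100, function(i) {
    # long-lived, near-static comets: a birth is lost only if it dies
    # before the next frame (P ~ 0.3%), negligible against the 4 sigma band
    p <- sim_params(comet_birth_rate = 0.01, comet_lifetime_mean = 600,
                    comet_speed = 1e-4, n_frames = 31, frame_interval = 2,
                    seed = 1000 + i)
    gt <- simulate_comet_tracks(g, p)
    first <- tapply(gt$tracks$frame, gt$tracks$track_id, min)
    sum(first >= 2)        # born strictly after t = 0
  }, 0)
  expected <- 0.01 * 20 * 60
  se_mean <- sqrt(expected / 100)
  expect_lt(abs(mean(counts) - expected), 4 * se_mean)
})

test_that("track kinematics are consistent with the polarity label", {
  g <- straight_geom(4)
  p <- sim_params(f_plus_end_out = 0.5, seed = 9)
  gt <- simulate_comet_tracks(g, p)
  for (id in unique(gt$tracks$track_id)) {
    tr <- gt$tracks[gt$tracks$track_id == id, ]
    if (nrow(tr) < 2) next
    ds <- tr$s_um[nrow(tr)] - tr$s_um[1]
    if (tr$label[1] == "plus_end_out") expect_gt(ds, 0) else expect_lt(ds, 0)
  }
})

test_that("empirical plus-end-out fraction matches f within 3 binomial sigma", {
  g <- straight_geom(5)
  for (f in c(0.5, 0.8)) {
    labs <- character(0)
    i <- 0
    while (length(labs) < 1000) {
      i <- i + 1
      p <- sim_params(f_plus_end_out = f, comet_birth_rate = 0.05,
                      seed = 2000 + i)
      gt <- simulate_comet_tracks(g, p)
      labs <- c(labs, tapply(gt$tracks$label, gt$tracks$track_id,
                             function(x) x[1]))
    }
    n <- length(labs)
    f_hat <- mean(labs == "plus_end_out")
    expect_lt(abs(f_hat - f), 3 * sqrt(f * (1 - f) / n))
  }
})

test_that("simulation output is reproducible from (config, seed)", {
  g <- straight_geom(6)
  p <- sim_params(seed = 77)
  expect_identical(simulate_comet_tracks(g, p)$tracks,
                   simulate_comet_tracks(g, p)$tracks)
  p2 <- sim_params(tip_mode = "camsap_growth", seed = 77)
  expect_identical(simulate_tip_dynamics(g, p2)$puncta,
                   simulate_tip_dynamics(g, p2)$puncta)
})

test_that("camsap_growth couples tip advance exactly to punctum presence", {
  g <- straight_geom(7, length_um = 40)
  # pinned punctum: tip advances every frame
  p <- sim_params(tip_mode = "camsap_growth", tip_dwell_fraction = 1,
                  frame_interval = 60, n_frames = 17, tip_start_frac = 0.3,
                  seed = 8)
  tt <- simulate_tip_dynamics(g, p)
  tip <- tt$tip_series$tip_arclength_um
  expect_true(all(diff(tip) > 0))
  expect_equal(diff(tip), rep(p$elongation_rate * 60, 16))

  # stochastic dwell: total advance == rate * interval * (# coupled frames)
  p2 <- sim_params(tip_mode = "camsap_growth", tip_dwell_fraction = 0.6,
                   frame_interval = 60, n_frames = 17, tip_start_frac = 0.3,
                   seed = 9)
  t2 <- simulate_tip_dynamics(g, p2)
  at <- t2$at_tip$at_tip
  adv <- t2$tip_series$tip_arclength_um[17] - t2$tip_series$tip_arclength_um[1]
  expect_equal(adv, p2$elongation_rate * 60 * sum(at[1:16]))
})

test_that("scattered mode places puncta uniformly (tip-zone mass ~ zone/length)", {
  fr <- vapply(1:200, function(i) {
    g <- straight_geom(10)
    p <- sim_params(tip_mode = "scattered", tip_start_frac = 1, n_frames = 2,
                    n_scattered = 8, seed = 3000 + i)
    tt <- simulate_tip_dynamics(g, p)
    pu <- tt$puncta[tt$puncta$frame == 1, ]
    mean(20 - pu$s_um <= 2)
  }, 0)
  expected <- 2 / 20
  n <- 200 * 8
  expect_lt(abs(mean(fr) - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("retrograde clearing displaces the cluster at the configured speed", {
  g <- straight_geom(11)
  p <- sim_params(tip_mode = "retrograde_clearing", treatment_frame = 6,
                  clearing_speed = 0.005, frame_interval = 60, n_frames = 17,
                  seed = 12)
  tt <- simulate_tip_dynamics(g, p)
  pu <- tt$puncta
  c_pre <- mean(pu$s_um[pu$frame == 6])
  c_end <- mean(pu$s_um[pu$frame == 17])
  K <- 17 - 6
  expect_equal(c_pre - c_end, 0.005 * 60 * K, tolerance = 1e-9)
})

test_that("retrograde_clearing without a treatment frame is a configuration error", {
  g <- straight_geom(13)
  p <- sim_params(tip_mode = "retrograde_clearing", seed = 1)
  expect_error(simulate_tip_dynamics(g, p), "treatment_frame")
})

test_that("treatment_frame beyond the movie is rejected", {
  expect_error(sim_params(tip_mode = "retrograde_clearing",
                          treatment_frame = 31, n_frames = 31), "treatment_frame")
  expect_error(sim_params(f_plus_end_out = 1.5), "f_plus_end_out")
})
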