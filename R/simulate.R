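#' Simulation parameters for synthetic neurite time-lapse movies
#'
#' Bundles and validates every knob of the synthetic-data generator.  The
#' defaults emulate spinning-disk imaging of EB1-GFP comets in young
#' neurites: frames every 2 s for 1 min (31 frames), 0.1 um/px sampling and
#' a 0.15 um PSF.  Punctum (minus-end marker) movies use the same machinery
#' with a slower cadence (60 s) set explicitly by the caller.
#'
#' @param f_plus_end_out fraction of comets whose plus-end points to the
#'   neurite tip (i.e. that move tipward); in [0, 1]
#' @param comet_speed comet speed along the path, um/s
#' @param comet_lifetime_mean mean comet lifetime, s (exponential)
#' @param comet_birth_rate comet nucleation rate, comets per um of neurite
#'   per second (Poisson)
#' @param frame_interval time between frames, s
#' @param n_frames number of frames
#' @param pixel_size um per pixel
#' @param psf_sigma standard deviation of the Gaussian PSF, um
#' @param background_photons expected background photons per pixel per frame
#' @param comet_peak_photons peak (amplitude) photons of one comet
#' @param punctum_peak_photons peak photons of one minus-end punctum
#' @param membrane_photons added photons per pixel inside the membrane tube
#' @param read_noise camera read noise, counts s.d. (Gaussian, additive)
#' @param photon_scale global multiplier on expected photon counts
#' @param shot_noise logical; FALSE renders noise-free expected counts
#'   (rounded), used for localization ground-truth checks
#' @param tip_mode one of "eb1_like", "camsap_growth", "tip_accumulated",
#'   "scattered", "retrograde_clearing" (punctum/tip simulations only)
#' @param treatment_frame frame index (1-based) at which treatment takes
#'   effect; required by "retrograde_clearing"
#' @param elongation_rate neurite tip elongation rate, um/s
#' @param coupling_radius punctum-to-tip distance (um) within which the tip
#'   is considered coupled and allowed to advance ("camsap_growth")
#' @param tip_dwell_fraction stationary fraction of frames the punctum
#'   spends at the tip (2-state Markov chain); NULL picks 0.85 for
#'   "camsap_growth" and 0.3 for "eb1_like"
#' @param dwell_mean_frames mean length (frames) of an at-tip visit
#' @param punctum_retract_um distance (um) behind the tip a punctum sits
#'   while retracted
#' @param n_scattered number of puncta in "scattered" mode
#' @param n_tip_cluster number of puncta in the tip cluster
#'   ("tip_accumulated" / "retrograde_clearing")
#' @param clearing_speed retrograde speed of the tip cluster after
#'   treatment, um/s ("retrograde_clearing")
#' @param tip_start_frac initial tip position as a fraction of path length
#' @param seed integer seed
#' @return validated list of class `mt_sim_params`
#' @examples
#' p <- sim_params(f_plus_end_out = 0.8, seed = 2)
#' snr_of(p)
#' @export
sim_params <- function(f_plus_end_out = 0.5,
                       comet_speed = 0.15,
                       comet_lifetime_mean = 15,
                       comet_birth_rate = 0.01,
                       frame_interval = 2,
                       n_frames = 31,
                       pixel_size = 0.1,
                       psf_sigma = 0.15,
                       background_photons = 100,
                       comet_peak_photons = 120,
                       punctum_peak_photons = 250,
                       membrane_photons = 200,
                       read_noise = 2,
                       photon_scale = 1,
                       shot_noise = TRUE,
                       tip_mode = "eb1_like",
                       treatment_frame = NULL,
                       elongation_rate = 0.005,
                       coupling_radius = 1,
                       tip_dwell_fraction = NULL,
                       dwell_mean_frames = 2,
                       punctum_retract_um = 3,
                       n_scattered = 8,
                       n_tip_cluster = 4,
                       clearing_speed = 0.01,
                       tip_start_frac = 0.6,
                       seed = 1) {
  check_fraction(f_plus_end_out, "f_plus_end_out")
  check_positive(comet_speed, "comet_speed")
  check_positive(comet_lifetime_mean, "comet_lifetime_mean")
  if (comet_birth_rate < 0) stop_f("'comet_birth_rate' must be >= 0")
  check_positive(frame_interval, "frame_interval")
  if (n_frames < 1) stop_f("'n_frames' must be >= 1")
  check_positive(pixel_size, "pixel_size")
  check_positive(psf_sigma, "psf_sigma")
  check_positive(photon_scale, "photon_scale")
  if (read_noise < 0) stop_f("'read_noise' must be >= 0")
  tip_mode <- match.arg(tip_mode, c("eb1_like", "camsap_growth",
                                    "tip_accumulated", "scattered",
                                    "retrograde_clearing"))
  if (!is.null(treatment_frame) && treatment_frame >= n_frames)
    stop_f("'treatment_frame' (%d) must be < n_frames (%d)",
           treatment_frame, n_frames)
  if (is.null(tip_dwell_fraction))
    tip_dwell_fraction <- if (tip_mode == "camsap_growth") 0.85 else 0.3
  check_fraction(tip_dwell_fraction, "tip_dwell_fraction")
  check_positive(dwell_mean_frames, "dwell_mean_frames")
  check_fraction(tip_start_frac, "tip_start_frac")

  structure(list(
    f_plus_end_out = f_plus_end_out, comet_speed = comet_speed,
    comet_lifetime_mean = comet_lifetime_mean,
    comet_birth_rate = comet_birth_rate, frame_interval = frame_interval,
    n_frames = as.integer(n_frames), pixel_size = pixel_size,
    psf_sigma = psf_sigma, background_photons = background_photons,
    comet_peak_photons = comet_peak_photons,
    punctum_peak_photons = punctum_peak_photons,
    membrane_photons = membrane_photons, read_noise = read_noise,
    photon_scale = photon_scale, shot_noise = isTRUE(shot_noise),
    tip_mode = tip_mode, treatment_frame = treatment_frame,
    elongation_rate = elongation_rate, coupling_radius = coupling_radius,
    tip_dwell_fraction = tip_dwell_fraction,
    dwell_mean_frames = dwell_mean_frames,
    punctum_retract_um = punctum_retract_um,
    n_scattered = as.integer(n_scattered),
    n_tip_cluster = as.integer(n_tip_cluster),
    clearing_speed = clearing_speed, tip_start_frac = tip_start_frac,
    seed = as.integer(seed)), class = "mt_sim_params")
}

#' Peak signal-to-noise ratio of the rendered comet channel
#'
#' SNR is the comet peak amplitude over the background noise standard
#' deviation (shot noise of the background plus read noise).
#'
#' @param params an `mt_sim_params`
#' @return numeric SNR
#' @export
snr_of <- function(params) {
  params$comet_peak_photons * params$photon_scale /
    sqrt(params$background_photons * params$photon_scale + params$read_noise^2)
}

#' Comet peak photons needed for a target SNR
#'
#' @param snr target peak signal-to-noise ratio
#' @param params an `mt_sim_params` supplying background and read noise
#' @return peak photon count to pass as `comet_peak_photons`
#' @export
peak_for_snr <- function(snr, params) {
  snr * sqrt(params$background_photons * params$photon_scale +
             params$read_noise^2) / params$photon_scale
}

#' Simulate ground-truth EB1 comet trajectories on a neuron geometry
#'
#' Comets nucleate as a Poisson process at `comet_birth_rate` per
#' micrometre of neurite per second, uniformly positioned along each path,
#' plus a steady-state population alive at time zero (density = birth rate x
#' mean lifetime).  Each comet is independently plus-end-out with
#' probability `f_plus_end_out`; it then moves at constant `comet_speed`
#' toward the tip (plus-end-out) or the soma (plus-end-in), lives an
#' exponential lifetime with mean `comet_lifetime_mean`, and is removed on
#' reaching either end of its path.  Positions are sampled at the frame
#' times (k - 1) * frame_interval.
#'
#' @param geometry an `mt_geometry`
#' @param params an `mt_sim_params`
#' @return object of class `mt_ground_truth`: list with `tracks` (data.frame
#'   track_id, frame, x_um, y_um, s_um, neurite_id, label), `params`,
#'   `geometry`.  `label` is "plus_end_out" or "plus_end_in".
#' @export
simulate_comet_tracks <- function(geometry, params) {
  stopifnot(inherits(geometry, "mt_geometry"), inherits(params, "mt_sim_params"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  t_end <- (params$n_frames - 1L) * params$frame_interval
  frame_times <- (seq_len(params$n_frames) - 1L) * params$frame_interval
  rows <- list(); tid <- 0L
  for (ni in seq_along(geometry$neurite_paths)) {
    path <- geometry$neurite_paths[[ni]]
    L <- path_length(path)
    # steady-state comets alive at t = 0 (memoryless residual lifetime)
    n0 <- stats::rpois(1, params$comet_birth_rate * L * params$comet_lifetime_mean)
    nb <- if (t_end > 0)
      stats::rpois(1, params$comet_birth_rate * L * t_end) else 0L
    n <- n0 + nb
    if (n == 0) next
    t0 <- c(rep(0, n0), stats::runif(nb, 0, t_end))
    s0 <- stats::runif(n, 0, L)
    life <- stats::rexp(n, 1 / params$comet_lifetime_mean)
    out <- stats::runif(n) < params$f_plus_end_out
    for (i in seq_len(n)) {
      v <- if (out[i]) params$comet_speed else -params$comet_speed
      # time to reach a path end
      t_exit <- if (v > 0) (L - s0[i]) / v else s0[i] / (-v)
      t_death <- t0[i] + min(life[i], t_exit)
      k <- which(frame_times >= t0[i] & frame_times <= t_death)
      if (length(k) == 0) next
      s <- s0[i] + v * (frame_times[k] - t0[i])
      xy <- point_at_arclength(path, s)
      tid <- tid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = tid, frame = k, x_um = xy[, 1], y_um = xy[, 2],
        s_um = s, neurite_id = ni,
        label = if (out[i]) "plus_end_out" else "plus_end_in")
    }
  }
  tracks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(), x_um = numeric(),
               y_um = numeric(), s_um = numeric(), neurite_id = integer(),
               label = character())
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, params = params, geometry = geometry),
            class = "mt_ground_truth")
}

#' Simulate neurite tip dynamics and minus-end puncta
#'
#' Generates, per neurite, a ground-truth tip arc-length series and punctum
#' trajectories according to `params$tip_mode`:
#' \describe{
#'   \item{camsap_growth}{A punctum alternates between the tip and a
#'     retracted position (2-state Markov chain with stationary at-tip
#'     fraction `tip_dwell_fraction`).  The tip advances by
#'     `elongation_rate * frame_interval` from frame k to k+1 if and only if
#'     a punctum lies within `coupling_radius` of the tip at frame k;
#'     otherwise it pauses.}
#'   \item{eb1_like}{The punctum visits the tip with the same Markov
#'     dynamics (default dwell 0.3) but the tip advances every frame,
#'     uncoupled.}
#'   \item{tip_accumulated}{A static cluster of `n_tip_cluster` puncta sits
#'     within 1 um of the (static) tip.}
#'   \item{scattered}{`n_scattered` static puncta placed uniformly along
#'     [0, tip position].}
#'   \item{retrograde_clearing}{A tip cluster as in tip_accumulated; from
#'     `treatment_frame` on, every cluster punctum moves toward the soma at
#'     `clearing_speed`.}
#' }
#'
#' @param geometry an `mt_geometry`
#' @param params an `mt_sim_params` with `tip_mode` set
#' @return list of class `mt_tip_truth` with `tip_series` (data.frame frame,
#'   neurite_id, tip_arclength_um, valid), `puncta` (data.frame track_id,
#'   frame, x_um, y_um, s_um, neurite_id), `at_tip` (data.frame frame,
#'   neurite_id, at_tip logical; Markov modes only), `params`, `geometry`
#' @export
simulate_tip_dynamics <- function(geometry, params) {
  stopifnot(inherits(geometry, "mt_geometry"), inherits(params, "mt_sim_params"))
  mode <- params$tip_mode
  if (mode == "retrograde_clearing" && is.null(params$treatment_frame))
    stop_f("'treatment_frame' must be set for tip_mode = \"retrograde_clearing\"")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(params$seed + 1L)

  nf <- params$n_frames
  tip_rows <- list(); punc_rows <- list(); attip_rows <- list()
  tid <- 0L
  for (ni in seq_along(geometry$neurite_paths)) {
    path <- geometry$neurite_paths[[ni]]
    L <- path_length(path)
    tip0 <- params$tip_start_frac * L
    adv <- params$elongation_rate * params$frame_interval

    if (mode %in% c("camsap_growth", "eb1_like")) {
      # 2-state chain with stationary at-tip fraction p_at; if the return
      # rate would exceed 1, clamp it and rescale the leave rate so the
      # stationary fraction is preserved exactly
      p_at <- params$tip_dwell_fraction
      q_leave <- min(1, 1 / params$dwell_mean_frames)
      q_return <- q_leave * p_at / max(1 - p_at, .EPS)
      if (q_return > 1) {
        q_return <- 1
        q_leave <- (1 - p_at) / max(p_at, .EPS)
      }
      at <- logical(nf)
      at[1] <- stats::runif(1) < p_at
      for (k in 2:nf) at[k] <- if (at[k - 1]) stats::runif(1) >= q_leave
                               else stats::runif(1) < q_return
      tip <- numeric(nf); tip[1] <- tip0
      for (k in 2:nf) {
        grow <- if (mode == "camsap_growth") at[k - 1] else TRUE
        tip[k] <- min(L, tip[k - 1] + if (grow) adv else 0)
      }
      s_p <- ifelse(at, tip, pmax(0, tip - params$punctum_retract_um))
      tid <- tid + 1L
      xy <- point_at_arclength(path, s_p)
      punc_rows[[length(punc_rows) + 1L]] <- data.frame(
        track_id = tid, frame = seq_len(nf), x_um = xy[, 1], y_um = xy[, 2],
        s_um = s_p, neurite_id = ni)
      attip_rows[[length(attip_rows) + 1L]] <-
        data.frame(frame = seq_len(nf), neurite_id = ni, at_tip = at)
    } else if (mode == "tip_accumulated" || mode == "retrograde_clearing") {
      tip <- rep(tip0, nf)
      off <- stats::runif(params$n_tip_cluster, 0, 1)
      for (j in seq_len(params$n_tip_cluster)) {
        s0 <- max(0, tip0 - off[j])
        s_p <- rep(s0, nf)
        if (mode == "retrograde_clearing") {
          tf <- params$treatment_frame
          post <- seq_len(nf) > tf
          s_p[post] <- pmax(0, s0 - params$clearing_speed *
                              params$frame_interval * (seq_len(nf)[post] - tf))
        }
        tid <- tid + 1L
        xy <- point_at_arclength(path, s_p)
        punc_rows[[length(punc_rows) + 1L]] <- data.frame(
          track_id = tid, frame = seq_len(nf), x_um = xy[, 1], y_um = xy[, 2],
          s_um = s_p, neurite_id = ni)
      }
    } else { # scattered
      tip <- rep(tip0, nf)
      s0 <- stats::runif(params$n_scattered, 0, tip0)
      for (j in seq_len(params$n_scattered)) {
        tid <- tid + 1L
        s_p <- rep(s0[j], nf)
        xy <- point_at_arclength(path, s_p)
        punc_rows[[length(punc_rows) + 1L]] <- data.frame(
          track_id = tid, frame = seq_len(nf), x_um = xy[, 1], y_um = xy[, 2],
          s_um = s_p, neurite_id = ni)
      }
    }
    tip_rows[[length(tip_rows) + 1L]] <- data.frame(
      frame = seq_len(nf), neurite_id = ni, tip_arclength_um = tip,
      valid = TRUE)
  }
  structure(list(
    tip_series = do.call(rbind, tip_rows),
    puncta = if (length(punc_rows)) do.call(rbind, punc_rows) else NULL,
    at_tip = if (length(attip_rows)) do.call(rbind, attip_rows) else NULL,
    params = params, geometry = geometry), class = "mt_tip_truth")
}
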