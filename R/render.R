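#' Render a synthetic multi-channel fluorescence time-lapse movie
#'
#' Rasterizes ground-truth particle positions into a calibrated movie.  Each
#' particle appearance is drawn as an isotropic 2-D Gaussian of standard
#' deviation `psf_sigma`; an optional membrane channel renders each neurite
#' as a tube of `neurite_width` (up to the current tip position, when a tip
#' series is supplied) plus a soma disk, blurred by the same PSF.  Expected
#' photon counts are corrupted by Poisson shot noise (if
#' `params$shot_noise`) and additive Gaussian read noise, then rounded to
#' integer camera counts in [0, 65535].
#'
#' @param geometry an `mt_geometry`
#' @param tracks data.frame of true particle appearances with columns
#'   `frame`, `x_um`, `y_um` and optionally `peak` (peak photons per
#'   appearance; default `params$comet_peak_photons`)
#' @param params an `mt_sim_params`
#' @param tip_series optional data.frame (frame, neurite_id,
#'   tip_arclength_um) limiting the membrane tube of each neurite to its
#'   current tip; NULL renders full-length tubes
#' @param channels character subset of c("particles", "membrane")
#' @return an [mt_movie()] with integer count pixels; attribute
#'   `n_particles_rendered` counts the particle appearances drawn
#' @export
render_movie <- function(geometry, tracks, params,
                         tip_series = NULL,
                         channels = c("particles", "membrane")) {
  stopifnot(inherits(geometry, "mt_geometry"), inherits(params, "mt_sim_params"))
  if (params$pixel_size <= 0) stop_f("optics error: pixel_size must be > 0")
  if (params$psf_sigma < params$pixel_size / 2)
    stop_f("optics error: psf_sigma (%g um) must be >= pixel_size/2 (%g um)",
           params$psf_sigma, params$pixel_size / 2)
  channels <- match.arg(channels, several.ok = TRUE)
  if (!is.null(tracks) && nrow(tracks)) {
    if (any(tracks$x_um < 0 | tracks$x_um > geometry$field_size[1] |
            tracks$y_um < 0 | tracks$y_um > geometry$field_size[2]))
      stop_f("tracks contain positions outside the field")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(params$seed + 2L)

  px <- params$pixel_size
  nr <- ceiling(geometry$field_size[2] / px)
  nc <- ceiling(geometry$field_size[1] / px)
  nf <- params$n_frames
  sig <- params$psf_sigma / px          # PSF sigma in pixels
  half <- ceiling(4 * sig)
  nch <- length(channels)
  pixels <- array(0, dim = c(nr, nc, nch, nf))
  n_drawn <- 0L

  # --- particle channel ------------------------------------------------
  if ("particles" %in% channels) {
    ci <- match("particles", channels)
    peaks <- if (!is.null(tracks) && "peak" %in% names(tracks))
      tracks$peak else rep(params$comet_peak_photons, NROW(tracks))
    for (k in seq_len(nf)) {
      E <- matrix(params$background_photons, nr, nc)
      if (!is.null(tracks) && nrow(tracks)) {
        idx <- which(tracks$frame == k)
        for (i in idx) {
          ij <- um_to_index(tracks$x_um[i], tracks$y_um[i], px)
          r0 <- max(1L, floor(ij$row) - half); r1 <- min(nr, floor(ij$row) + half + 1L)
          c0 <- max(1L, floor(ij$col) - half); c1 <- min(nc, floor(ij$col) + half + 1L)
          if (r0 > r1 || c0 > c1) next
          dr <- (r0:r1) - ij$row; dc <- (c0:c1) - ij$col
          E[r0:r1, c0:c1] <- E[r0:r1, c0:c1] +
            peaks[i] * exp(-dr^2 / (2 * sig^2)) %o% exp(-dc^2 / (2 * sig^2))
          n_drawn <- n_drawn + 1L
        }
      }
      pixels[, , ci, k] <- E
    }
  }

  # --- membrane channel ------------------------------------------------
  if ("membrane" %in% channels) {
    ci <- match("membrane", channels)
    xs <- (seq_len(nc) - 0.5) * px
    ys <- (seq_len(nr) - 0.5) * px
    gx <- matrix(xs, nr, nc, byrow = TRUE)
    gy <- matrix(ys, nr, nc)
    soma <- (gx - geometry$soma_center[1])^2 + (gy - geometry$soma_center[2])^2 <=
      geometry$soma_radius^2
    # per-neurite projection of corridor pixels onto the path
    proj <- lapply(geometry$neurite_paths, function(path) {
      w2 <- geometry$neurite_width / 2
      bb <- apply(path, 2, range)
      sel <- which(gx >= bb[1, 1] - 2 * w2 & gx <= bb[2, 1] + 2 * w2 &
                   gy >= bb[1, 2] - 2 * w2 & gy <= bb[2, 2] + 2 * w2)
      pr <- project_to_path(path, cbind(gx[sel], gy[sel]))
      keep <- pr$dist <= w2
      list(idx = sel[keep], s = pr$s[keep])
    })
    tip_of <- function(ni, k) {
      if (is.null(tip_series))
        return(path_length(geometry$neurite_paths[[ni]]))
      r <- tip_series$frame == k & tip_series$neurite_id == ni
      if (!any(r)) return(path_length(geometry$neurite_paths[[ni]]))
      tip_series$tip_arclength_um[r][1]
    }
    static_tube <- is.null(tip_series)
    blur_one <- function(k) {
      amp <- matrix(0, nr, nc)
      for (ni in seq_along(proj)) {
        pz <- proj[[ni]]
        amp[pz$idx[pz$s <= tip_of(ni, k)]] <- params$membrane_photons
      }
      amp[soma] <- params$membrane_photons
      params$background_photons / 2 +
        as.matrix(EBImage::gblur(amp, sigma = sig))
    }
    if (static_tube) {
      E0 <- blur_one(1L)
      for (k in seq_len(nf)) pixels[, , ci, k] <- E0
    } else {
      for (k in seq_len(nf)) pixels[, , ci, k] <- blur_one(k)
    }
  }

  # --- camera noise ----------------------------------------------------
  pixels <- pixels * params$photon_scale
  if (params$shot_noise) {
    pixels[] <- stats::rpois(length(pixels), pixels)
  } else {
    pixels[] <- round(pixels)
  }
  if (params$read_noise > 0)
    pixels[] <- pixels + round(stats::rnorm(length(pixels), 0, params$read_noise))
  pixels[] <- pmin(pmax(pixels, 0), 65535)

  m <- mt_movie(pixels, pixel_size = px, frame_interval = params$frame_interval,
                channel_names = channels)
  attr(m, "n_particles_rendered") <- n_drawn
  m
}
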