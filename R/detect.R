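#' Detect diffraction-limited spots in one frame
#'
#' Band-pass detection at the expected spot scale: a difference-of-Gaussians
#' (sigma and 1.6 sigma) filter, local-maximum candidates above a robust
#' background threshold (median + k * MAD of the filtered image), greedy
#' non-maximum suppression within `min_separation_px`, and sub-pixel
#' refinement by the intensity-weighted centroid of the positive band-pass
#' response in a window of radius 2 * psf_sigma.
#'
#' @param frame numeric matrix of pixel counts (single channel, single frame)
#' @param pixel_size micrometres per pixel
#' @param psf_sigma PSF standard deviation in micrometres
#' @param k MAD multiplier for the detection threshold
#' @param min_separation_px minimum distance between accepted spots, pixels
#' @return data.frame of spots sorted by decreasing quality: columns
#'   `x_um`, `y_um` (sub-pixel, micrometre convention of [um_to_index()]),
#'   `row`, `col` (integer peak pixel), `intensity` (raw peak counts),
#'   `quality` (band-pass peak response)
#' @export
detect_spots <- function(frame, pixel_size, psf_sigma, k = 5,
                         min_separation_px = 2) {
  if (!all(is.finite(frame))) stop_f("frame contains non-finite pixels")
  check_positive(pixel_size, "pixel_size")
  sig <- psf_sigma / pixel_size
  g1 <- .gblur(frame, sig)
  g2 <- .gblur(frame, 1.6 * sig)
  dog <- g1 - g2
  thr <- mad_threshold(dog, k)

  nr <- nrow(dog); nc <- ncol(dog)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- dog
  is_max <- dog > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (dog >= pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  # strictness against at least one neighbour kills flat background plateaus
  any_greater <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    any_greater <- any_greater | (dog > pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  is_max <- is_max & any_greater
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x_um = numeric(), y_um = numeric(), row = integer(),
                      col = integer(), intensity = numeric(),
                      quality = numeric()))
  q <- dog[idx]
  ord <- order(-q, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]; q <- q[ord]
  # greedy non-maximum suppression
  keep <- rep(TRUE, nrow(idx))
  if (nrow(idx) > 1 && min_separation_px > 0) {
    for (i in seq_len(nrow(idx))) {
      if (!keep[i]) next
      if (i < nrow(idx)) {
        later <- (i + 1):nrow(idx)
        d2 <- (idx[later, 1] - idx[i, 1])^2 + (idx[later, 2] - idx[i, 2])^2
        keep[later[d2 < min_separation_px^2]] <- FALSE
      }
    }
  }
  idx <- idx[keep, , drop = FALSE]; q <- q[keep]

  wr <- ceiling(2 * sig)
  n <- nrow(idx)
  xs <- numeric(n); ys <- numeric(n); inten <- numeric(n)
  for (i in seq_len(n)) {
    r <- idx[i, 1]; cc <- idx[i, 2]
    r0 <- max(1L, r - wr); r1 <- min(nr, r + wr)
    c0 <- max(1L, cc - wr); c1 <- min(nc, cc + wr)
    w <- pmax(dog[r0:r1, c0:c1, drop = FALSE], 0)
    sw <- sum(w)
    if (sw <= 0) { rc <- r; ccc <- cc } else {
      rc <- sum(w * matrix(r0:r1, nrow = r1 - r0 + 1L, ncol = c1 - c0 + 1L)) / sw
      ccc <- sum(w * matrix(c0:c1, nrow = r1 - r0 + 1L, ncol = c1 - c0 + 1L,
                            byrow = TRUE)) / sw
    }
    um <- index_to_um(rc, ccc, pixel_size)
    xs[i] <- um$x; ys[i] <- um$y
    inten[i] <- frame[r, cc]
  }
  data.frame(x_um = xs, y_um = ys, row = idx[, 1], col = idx[, 2],
             intensity = inten, quality = q)
}

.gblur <- function(m, sigma) {
  EBImage::imageData(EBImage::gblur(m, sigma = sigma))
}

#' Detect spots in every frame of a movie channel
#'
#' @param movie an `mt_movie`
#' @param channel channel name or index
#' @param psf_sigma PSF sigma in micrometres (defaults are the caller's
#'   responsibility; typically the simulation/optics value)
#' @param k MAD multiplier
#' @param min_separation_px minimum spot separation in pixels
#' @return data.frame of spots with a `frame` column prepended
#' @export
detect_movie_spots <- function(movie, channel = "particles", psf_sigma,
                               k = 5, min_separation_px = 2) {
  frames <- movie_channel(movie, channel)
  out <- lapply(seq_along(frames), function(fk) {
    sp <- detect_spots(frames[[fk]], movie$pixel_size, psf_sigma, k,
                       min_separation_px)
    if (nrow(sp)) cbind(frame = fk, sp) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      row = integer(), col = integer(), intensity = numeric(),
                      quality = numeric())
  rownames(out) <- NULL
  out
}
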