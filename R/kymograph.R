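#' Build a kymograph along a neurite polyline
#'
#' For each frame, intensity is sampled by bilinear interpolation at
#' arc-length steps of one pixel along the polyline, taking the maximum
#' over `width_px` samples perpendicular to the path (max projection keeps
#' dim comets visible).  Rows are frames (top = first), columns arc length
#' (left = soma end).  Sampling positions are bin centres
#' s_i = (i - 0.5) * L / ncol, so reversing the polyline vertex order
#' mirrors the kymograph left-right exactly.
#'
#' @param movie an `mt_movie`
#' @param roi an `mt_roi`; every vertex must lie inside the field
#' @param channel channel name or index
#' @param width_px odd number of transverse samples (1 px apart)
#' @return object of class `mt_kymograph`: `image` (frames x columns),
#'   `dt` seconds per row, `ds` micrometres per column, `neurite_id`
#' @export
make_kymograph <- function(movie, roi, channel = "particles", width_px = 5) {
  stopifnot(inherits(movie, "mt_movie"), inherits(roi, "mt_roi"))
  if (width_px %% 2 != 1) stop_f("'width_px' must be odd")
  frames <- movie_channel(movie, channel)
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  px <- movie$pixel_size
  v <- roi$vertices
  bad <- which(v[, 1] < 0 | v[, 1] > nc * px | v[, 2] < 0 | v[, 2] > nr * px)
  if (length(bad))
    stop_f("polyline exits the field at vertex/vertices %s",
           paste(bad, collapse = ", "))
  L <- path_length(v)
  ncol_k <- ceiling(L / px)
  s <- (seq_len(ncol_k) - 0.5) * L / ncol_k
  pts <- point_at_arclength(v, s)
  tg <- tangent_at_arclength(v, s)
  nrm <- cbind(-tg[, 2], tg[, 1])
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * px
  # sample positions: ncol_k x width_px grid
  sx <- outer(pts[, 1], rep(1, width_px)) + outer(nrm[, 1], offs)
  sy <- outer(pts[, 2], rep(1, width_px)) + outer(nrm[, 2], offs)
  idx <- um_to_index(as.vector(sx), as.vector(sy), px)
  img <- matrix(0, length(frames), ncol_k)
  for (k in seq_along(frames)) {
    vals <- matrix(bilinear(frames[[k]], idx$row, idx$col), ncol_k, width_px)
    img[k, ] <- apply(vals, 1, max)
  }
  structure(list(image = img, dt = movie$frame_interval, ds = L / ncol_k,
                 neurite_id = roi$neurite_id), class = "mt_kymograph")
}

#' Fit the speed of the dominant moving particle in a kymograph
#'
#' Takes the intensity-weighted centroid column of the background-subtracted
#' signal in each row and fits arc length against time by least squares.
#' Rows without signal above the robust threshold are skipped.
#'
#' @param kymo an `mt_kymograph`
#' @param k MAD multiplier for the per-kymograph background threshold
#' @return list: `speed_um_s` (signed; positive = tipward), `n_rows` used
#' @export
kymograph_speed <- function(kymo, k = 5) {
  img <- kymo$image
  thr <- mad_threshold(as.vector(img), k)
  ss <- numeric(0); tt <- numeric(0)
  for (r in seq_len(nrow(img))) {
    w <- pmax(img[r, ] - thr, 0)
    if (sum(w) <= 0) next
    ss <- c(ss, sum(w * seq_len(ncol(img))) / sum(w) * kymo$ds)
    tt <- c(tt, (r - 1) * kymo$dt)
  }
  if (length(ss) < 2) stop_f("not enough signal rows to fit a speed")
  fit <- stats::lm(ss ~ tt)
  list(speed_um_s = unname(stats::coef(fit)[2]), n_rows = length(ss))
}

#' Write a kymograph as TIFF plus JSON scale sidecar
#'
#' @param kymo an `mt_kymograph`
#' @param path TIFF path
#' @export
write_kymograph <- function(kymo, path) {
  img <- kymo$image
  mx <- max(img, 1)
  tiff::writeTIFF(img / mx, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(list(seconds_per_row = kymo$dt,
                            um_per_column = kymo$ds,
                            neurite_id = kymo$neurite_id,
                            intensity_scale = mx),
                       paste0(.sidecar_path(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
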