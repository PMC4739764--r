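#' Calibrated multi-channel movie container
#'
#' @param pixels numeric array with dimensions (row, column, channel, frame)
#' @param pixel_size micrometres per pixel (> 0)
#' @param frame_interval seconds between frames (> 0)
#' @param channel_names character vector, one name per channel
#' @return object of class `mt_movie`
#' @export
mt_movie <- function(pixels, pixel_size, frame_interval, channel_names) {
  if (length(dim(pixels)) == 2L) dim(pixels) <- c(dim(pixels), 1L, 1L)
  if (length(dim(pixels)) == 3L) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(length(dim(pixels)) == 4L)
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  if (length(channel_names) != dim(pixels)[3])
    stop_f("channel_names length (%d) != number of channels (%d)",
           length(channel_names), dim(pixels)[3])
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_names = as.character(channel_names)),
            class = "mt_movie")
}

#' @export
print.mt_movie <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mt_movie> %d x %d px, %d channel(s) [%s], %d frame(s), %.3g um/px, %.3g s/frame\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              d[4], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Extract one channel of a movie as a list of frame matrices
#'
#' @param movie an `mt_movie`
#' @param channel channel name or index
#' @return list of numeric matrices, one per frame
#' @export
movie_channel <- function(movie, channel) {
  stopifnot(inherits(movie, "mt_movie"))
  if (is.character(channel)) {
    ci <- match(channel, movie$channel_names)
    if (is.na(ci)) stop_f("no channel named '%s' (have: %s)", channel,
                          paste(movie$channel_names, collapse = ", "))
  } else ci <- as.integer(channel)
  lapply(seq_len(dim(movie$pixels)[4]),
         function(k) movie$pixels[, , ci, k])
}

.sidecar_path <- function(path) sub("\\.tiff?$", "", path, ignore.case = TRUE)

#' Write / read a calibrated movie as multi-page TIFF plus JSON sidecar
#'
#' Pixel counts (integers in [0, 65535]) are stored as 16-bit TIFF pages and
#' round-trip bit-exactly.  Calibration (pixel size, frame interval, channel
#' names, page layout) lives in a JSON sidecar next to the TIFF; reading a
#' TIFF without its sidecar is an error — calibration is never defaulted
#' silently.  With `interleaved = TRUE` all channels go into one file with
#' page order frame-major (frame 1 channel 1, frame 1 channel 2, ...);
#' otherwise one file per channel is written (`<base>_<channel>.tif`).
#'
#' @param movie an `mt_movie`
#' @param path TIFF path (the sidecar is `<path minus extension>.json`)
#' @param interleaved logical, see above
#' @return `write_movie` invisibly returns the paths written; `read_movie`
#'   returns the `mt_movie`.
#' @export
write_movie <- function(movie, path, interleaved = TRUE) {
  stopifnot(inherits(movie, "mt_movie"))
  d <- dim(movie$pixels)
  norm <- function(m) m / 65535
  files <- character()
  if (interleaved) {
    pages <- vector("list", d[3] * d[4])
    p <- 0L
    for (k in seq_len(d[4])) for (ci in seq_len(d[3])) {
      p <- p + 1L
      pages[[p]] <- norm(movie$pixels[, , ci, k])
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
    files <- path
  } else {
    base <- .sidecar_path(path)
    for (ci in seq_len(d[3])) {
      f <- sprintf("%s_%s.tif", base, movie$channel_names[ci])
      pages <- lapply(seq_len(d[4]), function(k) norm(movie$pixels[, , ci, k]))
      tiff::writeTIFF(pages, f, bits.per.sample = 16, compression = "none")
      files <- c(files, f)
    }
  }
  sidecar <- paste0(.sidecar_path(path), ".json")
  jsonlite::write_json(list(
    pixel_size_um = movie$pixel_size,
    frame_interval_s = movie$frame_interval,
    channel_names = movie$channel_names,
    n_frames = d[4], n_channels = d[3],
    interleaved = interleaved, max_count = 65535,
    files = basename(files)), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sidecar))
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  sidecar <- paste0(.sidecar_path(path), ".json")
  if (!file.exists(sidecar))
    stop_f("calibration sidecar '%s' not found; movies cannot be read without pixel size and frame interval", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  nch <- meta$n_channels; nf <- meta$n_frames
  denorm <- function(m) round(m * meta$max_count)
  if (isTRUE(meta$interleaved)) {
    if (!file.exists(path)) stop_f("movie file '%s' not found", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != nch * nf)
      stop_f("expected %d pages (%d frames x %d channels), found %d",
             nch * nf, nf, nch, length(pages))
    d <- dim(pages[[1]])
    pixels <- array(0, dim = c(d[1], d[2], nch, nf))
    p <- 0L
    for (k in seq_len(nf)) for (ci in seq_len(nch)) {
      p <- p + 1L
      pixels[, , ci, k] <- denorm(pages[[p]])
    }
  } else {
    base <- .sidecar_path(path)
    d <- NULL; pixels <- NULL
    for (ci in seq_len(nch)) {
      f <- sprintf("%s_%s.tif", base, meta$channel_names[ci])
      if (!file.exists(f)) stop_f("channel file '%s' not found", f)
      pages <- tiff::readTIFF(f, all = TRUE)
      if (is.null(d)) {
        d <- dim(pages[[1]])
        pixels <- array(0, dim = c(d[1], d[2], nch, nf))
      }
      for (k in seq_len(nf)) pixels[, , ci, k] <- denorm(pages[[k]])
    }
  }
  mt_movie(pixels, pixel_size = as.numeric(meta$pixel_size_um),
           frame_interval = as.numeric(meta$frame_interval_s),
           channel_names = meta$channel_names)
}

#' Write / read particle track tables
#'
#' Tracks are plain CSV with a header row; coordinates are always
#' micrometres.  Rows are sorted by (track_id, frame) on both write and
#' read; duplicate (track_id, frame) pairs are rejected with the offending
#' row number.
#'
#' @param tracks data.frame with at least track_id, frame, x_um, y_um
#' @param path CSV path
#' @return `read_tracks` returns the sorted data.frame
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  .check_track_dupes(tracks)
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_f("track file '%s' not found", path)
  tracks <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
    stop_f("'%s' is not a track table (needs track_id, frame, x_um, y_um)", path)
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  .check_track_dupes(tracks)
  tracks
}

.check_track_dupes <- function(tracks) {
  dup <- duplicated(tracks[, c("track_id", "frame")])
  if (any(dup))
    stop_f("duplicate (track_id, frame) pair at row %d (track %s, frame %s)",
           which(dup)[1], tracks$track_id[which(dup)[1]],
           tracks$frame[which(dup)[1]])
  invisible(tracks)
}

#' Write / read tip-position series
#'
#' CSV with columns frame, neurite_id, tip_arclength_um, valid; arc lengths
#' in micrometres along the neurite polyline.
#'
#' @param tip data.frame as above
#' @param path CSV path
#' @export
write_tip_series <- function(tip, path) {
  stopifnot(all(c("frame", "neurite_id", "tip_arclength_um", "valid") %in% names(tip)))
  tip <- tip[order(tip$neurite_id, tip$frame), , drop = FALSE]
  utils::write.csv(tip, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tip_series
#' @export
read_tip_series <- function(path) {
  if (!file.exists(path)) stop_f("tip series file '%s' not found", path)
  tip <- utils::read.csv(path, stringsAsFactors = FALSE)
  tip$valid <- as.logical(tip$valid)
  tip[order(tip$neurite_id, tip$frame), , drop = FALSE]
}

#' Polyline region of interest (one neurite)
#'
#' @param neurite_id identifier
#' @param vertices n x 2 matrix of (x, y) micrometre vertices, soma end first
#' @param width neurite width in micrometres
#' @return object of class `mt_roi`
#' @export
new_roi <- function(neurite_id, vertices, width) {
  vertices <- rbind(vertices)
  if (nrow(vertices) < 2L) stop_f("ROI needs >= 2 vertices")
  if (any(rowSums(diff(vertices)^2) == 0))
    stop_f("ROI has consecutive duplicate vertices")
  check_positive(width, "width")
  structure(list(neurite_id = neurite_id,
                 vertices = unname(as.matrix(vertices)), width = width),
            class = "mt_roi")
}

#' Write / read polyline ROIs as JSON
#'
#' @param rois list of `mt_roi`
#' @param path JSON path
#' @return `read_roi` returns a list of `mt_roi`
#' @export
write_roi <- function(rois, path) {
  if (inherits(rois, "mt_roi")) rois <- list(rois)
  jsonlite::write_json(lapply(rois, function(r) list(
    neurite_id = r$neurite_id, width_um = r$width,
    vertices = unname(apply(r$vertices, 1, function(v) c(v[1], v[2]),
                            simplify = FALSE)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop_f("ROI file '%s' not found", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    v <- do.call(rbind, lapply(r$vertices, unlist))
    new_roi(neurite_id = r$neurite_id, vertices = v, width = r$width_um)
  })
}
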