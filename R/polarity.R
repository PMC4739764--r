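#' Polarity classifier angle thresholds
#'
#' Trajectory angles are measured relative to the outward radial direction
#' from the cell center (0 degrees = directly away from the center).  A
#' trajectory segment is plus-end-out when its angle is strictly below
#' `out_low` or strictly above `out_high`, plus-end-in when strictly
#' between `in_low` and `in_high`; angles in the two dead zones
#' [out_low, in_low] and [in_high, out_high] carry no label.  Defaults are
#' 70 / 110 / 250 / 290 degrees.
#'
#' @param out_low,in_low,in_high,out_high degrees, with
#'   0 < out_low < in_low < in_high < out_high < 360
#' @return object of class `mt_thresholds`
#' @export
classifier_thresholds <- function(out_low = 70, in_low = 110,
                                  in_high = 250, out_high = 290) {
  if (!(0 < out_low && out_low < in_low && in_low < in_high &&
        in_high < out_high && out_high < 360))
    stop_f("thresholds must satisfy 0 < out_low < in_low < in_high < out_high < 360")
  structure(list(out_low = out_low, in_low = in_low, in_high = in_high,
                 out_high = out_high), class = "mt_thresholds")
}

#' Classify a single trajectory angle
#'
#' @param theta angle(s) in degrees, any real value (reduced mod 360)
#' @param thresholds an [classifier_thresholds()]
#' @return character vector: "plus_end_out", "plus_end_in" or "excluded";
#'   boundary angles (strict inequalities) are excluded
#' @export
classify_angle <- function(theta, thresholds = classifier_thresholds()) {
  theta <- theta %% 360
  # strict inequalities with a small guard so angles that are boundary
  # values up to floating-point error stay excluded
  eps <- 1e-9
  out <- theta < thresholds$out_low - eps | theta > thresholds$out_high + eps
  inn <- theta > thresholds$in_low + eps & theta < thresholds$in_high - eps
  ifelse(out, "plus_end_out", ifelse(inn, "plus_end_in", "excluded"))
}

#' Angle of a displacement relative to the outward radial direction
#'
#' Measures, counter-clockwise in [0, 360) degrees, the angle from the
#' outward radial direction (cell center to the given position) to the
#' displacement vector.  0 degrees means motion directly away from the
#' center; 180 degrees directly toward it.
#'
#' @param displacement length-2 vector (dx, dy), micrometres
#' @param position length-2 position at which the motion occurs
#' @param center length-2 cell-center point
#' @return angle in degrees, in [0, 360)
#' @export
comet_angle <- function(displacement, position, center) {
  if (sum(displacement^2) == 0)
    stop_f("zero displacement: trajectory angle is undefined")
  radial <- position - center
  if (sum(radial^2) == 0)
    stop_f("position coincides with the cell center: radial direction undefined")
  cr <- radial[1] * displacement[2] - radial[2] * displacement[1]
  dt <- radial[1] * displacement[1] + radial[2] * displacement[2]
  (atan2(cr, dt) * 180 / pi) %% 360
}

#' Subdivide a trajectory into approximately linear segments
#'
#' Greedy rule: the current segment is extended step by step; when the
#' bearing of the next step deviates from the running mean bearing of the
#' segment by more than `straightness_tol`, the segment is closed at the
#' shared vertex and a new one starts there.  Concatenating the segments
#' (dropping each subsequent segment's first, shared, vertex) reproduces
#' the input polyline.  Zero-length steps are absorbed into the current
#' segment.
#'
#' @param pts n x 2 matrix of points in time/arc order (n >= 2)
#' @param straightness_tol tolerance in degrees; 180 never splits
#' @return list of point matrices, each with >= 2 rows
#' @export
split_linear_segments <- function(pts, straightness_tol = 30) {
  pts <- rbind(pts)
  if (nrow(pts) < 2L) stop_f("need at least 2 points to form a segment")
  steps <- diff(pts)
  len <- sqrt(rowSums(steps^2))
  segs <- list()
  start <- 1L
  mean_vec <- c(0, 0)
  for (i in seq_len(nrow(steps))) {
    if (len[i] == 0) next
    u <- steps[i, ] / len[i]
    if (sum(mean_vec^2) > 0) {
      mb <- mean_vec / sqrt(sum(mean_vec^2))
      dev <- acos(pmin(pmax(sum(mb * u), -1), 1)) * 180 / pi
      if (dev > straightness_tol) {
        segs[[length(segs) + 1L]] <- pts[start:i, , drop = FALSE]
        start <- i
        mean_vec <- c(0, 0)
      }
    }
    mean_vec <- mean_vec + u
  }
  segs[[length(segs) + 1L]] <- pts[start:nrow(pts), , drop = FALSE]
  segs
}

#' Classify one comet track as plus-end-out, plus-end-in or excluded
#'
#' The track is subdivided into linear segments
#' ([split_linear_segments()]); each segment's angle is computed from its
#' net displacement, referenced to the outward radial direction at the
#' segment midpoint ([comet_angle()]); each angle is labelled by the strict
#' thresholds ([classify_angle()]); and the track label is the majority of
#' the labelled segments.  Ties between out and in votes, or no labelled
#' segment at all, give "excluded".
#'
#' @param track_pts n x 2 matrix of positions in time order (n >= 2),
#'   micrometres
#' @param center length-2 cell-center point
#' @param thresholds an [classifier_thresholds()]
#' @param straightness_tol segment-subdivision tolerance, degrees
#' @return list of class `mt_comet_call`: `label`, `segment_angles`
#'   (degrees), `segment_labels`
#' @export
classify_comet <- function(track_pts, center,
                           thresholds = classifier_thresholds(),
                           straightness_tol = 30) {
  if (is.null(center) || any(!is.finite(center)))
    stop_f("cell center is undefined")
  track_pts <- rbind(track_pts)
  if (nrow(track_pts) < 2L) stop_f("track needs >= 2 positions")
  segs <- split_linear_segments(track_pts, straightness_tol)
  angles <- numeric(0); labels <- character(0)
  for (sg in segs) {
    disp <- sg[nrow(sg), ] - sg[1L, ]
    if (sum(disp^2) == 0) next
    mid <- (sg[1L, ] + sg[nrow(sg), ]) / 2
    if (all(mid == center)) next
    th <- comet_angle(disp, mid, center)
    angles <- c(angles, th)
    labels <- c(labels, classify_angle(th, thresholds))
  }
  n_out <- sum(labels == "plus_end_out")
  n_in <- sum(labels == "plus_end_in")
  label <- if (n_out > n_in) "plus_end_out"
           else if (n_in > n_out) "plus_end_in"
           else "excluded"
  structure(list(label = label, segment_angles = angles,
                 segment_labels = labels), class = "mt_comet_call")
}

#' Classify every track in a track table
#'
#' @param tracks data.frame with track_id, frame, x_um, y_um and (from
#'   [filter_tracks()]) neurite_id
#' @param center length-2 cell-center point, micrometres
#' @param thresholds an [classifier_thresholds()]
#' @param straightness_tol degrees
#' @return data.frame of calls: track_id, neurite_id, n_segments, label,
#'   angles (semicolon-joined, 2 decimals)
#' @export
classify_tracks <- function(tracks, center,
                            thresholds = classifier_thresholds(),
                            straightness_tol = 30) {
  ids <- unique(tracks$track_id)
  calls <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    cl <- classify_comet(cbind(tr$x_um, tr$y_um), center, thresholds,
                         straightness_tol)
    data.frame(track_id = id,
               neurite_id = if ("neurite_id" %in% names(tr)) tr$neurite_id[1] else NA,
               n_segments = length(cl$segment_angles),
               label = cl$label,
               angles = paste(sprintf("%.2f", cl$segment_angles),
                              collapse = ";"))
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Per-neurite polarity summary
#'
#' Counts plus-end-out / plus-end-in / excluded comets per neurite and the
#' fractions over classified (non-excluded) comets.  Neurites with zero
#' classified comets are flagged `defined = FALSE` and are skipped by
#' [aggregate_condition()].
#'
#' @param calls data.frame from [classify_tracks()] (non-empty)
#' @return data.frame: neurite_id, n_out, n_in, n_excluded, f_out, f_in,
#'   defined
#' @export
summarize_polarity <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0)
    stop_f("empty call list: nothing to summarize")
  out <- lapply(sort(unique(calls$neurite_id)), function(ni) {
    cc <- calls[calls$neurite_id == ni, , drop = FALSE]
    n_out <- sum(cc$label == "plus_end_out")
    n_in <- sum(cc$label == "plus_end_in")
    n_ex <- sum(cc$label == "excluded")
    ncl <- n_out + n_in
    data.frame(neurite_id = ni, n_out = n_out, n_in = n_in,
               n_excluded = n_ex,
               f_out = if (ncl > 0) n_out / ncl else NA_real_,
               f_in = if (ncl > 0) n_in / ncl else NA_real_,
               defined = ncl > 0)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate per-axon polarity summaries for one condition
#'
#' Mirrors the "n axons with m comets" reporting: the unweighted mean and
#' sample s.d. of the per-axon plus-end-out fraction, together with the
#' pooled fraction (all classified comets lumped) and both totals.  With a
#' single axon the s.d. is undefined (NA).
#'
#' @param summaries data.frame from [summarize_polarity()], possibly
#'   row-bound over many cells (at least one row with `defined = TRUE`)
#' @return one-row data.frame: mean_f_out, sd_f_out, pooled_f_out,
#'   n_axons, n_comets
#' @export
aggregate_condition <- function(summaries) {
  s <- summaries[summaries$defined, , drop = FALSE]
  if (nrow(s) == 0) stop_f("no axon with classified comets")
  data.frame(
    mean_f_out = mean(s$f_out),
    sd_f_out = if (nrow(s) > 1) stats::sd(s$f_out) else NA_real_,
    pooled_f_out = sum(s$n_out) / sum(s$n_out + s$n_in),
    n_axons = nrow(s),
    n_comets = sum(s$n_out + s$n_in))
}

#' Estimate the cell center from a membrane (or transmitted) channel
#'
#' With a manual override the point is returned verbatim.  Otherwise the
#' time-averaged channel is thresholded (median + k * MAD) and the largest
#' connected component taken.  Because the soma is contiguous with the
#' neurite tubes, the component is narrowed to its thickest region — the
#' pixels whose distance to background is at least 60\% of the maximum
#' (the soma body, whose radius exceeds any neurite half-width) — and the
#' intensity-weighted centroid of that region (micrometres) is returned.
#' For a symmetric disk mask this is exactly the disk center.
#'
#' @param movie an `mt_movie`
#' @param manual_override optional length-2 point, returned as-is
#' @param channel channel name or index
#' @param k MAD multiplier for the soma threshold
#' @return length-2 numeric (x, y) in micrometres
#' @export
estimate_center <- function(movie, manual_override = NULL,
                            channel = "membrane", k = 3) {
  if (!is.null(manual_override)) {
    stopifnot(length(manual_override) == 2L)
    return(as.numeric(manual_override))
  }
  frames <- movie_channel(movie, channel)
  avg <- Reduce("+", frames) / length(frames)
  mask <- avg > mad_threshold(avg, k)
  if (!any(mask)) stop_f("no segmentable soma in channel '%s'", channel)
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  sel <- lab == big
  dm <- EBImage::imageData(EBImage::distmap(sel * 1))
  core <- sel & dm >= 0.6 * max(dm)
  w <- avg[core]
  idx <- which(core, arr.ind = TRUE)
  rc <- sum(w * idx[, 1]) / sum(w)
  cc <- sum(w * idx[, 2]) / sum(w)
  um <- index_to_um(rc, cc, movie$pixel_size)
  c(um$x, um$y)
}
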