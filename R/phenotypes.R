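#' Track a neurite tip along its polyline from the membrane channel
#'
#' Per frame: pixels within a corridor around the ROI polyline (half-width
#' = ROI width/2 + `corridor_pad`) are thresholded at median + k * MAD of
#' the corridor intensities; connected components are labelled; the
#' component reaching closest to the soma end of the polyline (within
#' `soma_attach` of arc length 0) is taken as the neurite, and the tip is
#' the maximal arc length covered by that component.  Frames with no such
#' component are marked invalid, never interpolated.
#'
#' @param movie an `mt_movie` with a membrane channel
#' @param roi an `mt_roi` tracing the neurite beyond its maximal extent
#' @param channel membrane channel name or index
#' @param k MAD multiplier for the corridor threshold
#' @param corridor_pad extra corridor half-width beyond the ROI, micrometres
#' @param soma_attach maximal arc length (micrometres) at which the neurite
#'   component may start and still count as soma-attached
#' @return data.frame: frame, neurite_id, tip_arclength_um, valid
#' @export
track_tip <- function(movie, roi, channel = "membrane", k = 5,
                      corridor_pad = 2, soma_attach = 3) {
  stopifnot(inherits(movie, "mt_movie"), inherits(roi, "mt_roi"))
  frames <- movie_channel(movie, channel)
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  px <- movie$pixel_size
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px
  gx <- matrix(xs, nr, nc, byrow = TRUE)
  gy <- matrix(ys, nr, nc)
  bb <- apply(roi$vertices, 2, range)
  w2 <- roi$width / 2 + corridor_pad
  sel <- which(gx >= bb[1, 1] - w2 & gx <= bb[2, 1] + w2 &
               gy >= bb[1, 2] - w2 & gy <= bb[2, 2] + w2)
  pr <- project_to_path(roi$vertices, cbind(gx[sel], gy[sel]))
  inside <- pr$dist <= w2
  corridor <- sel[inside]
  s_of <- pr$s[inside]

  out <- lapply(seq_along(frames), function(fk) {
    vals <- frames[[fk]][corridor]
    thr <- mad_threshold(vals, k)
    mask <- matrix(0L, nr, nc)
    mask[corridor[vals > thr]] <- 1L
    if (!any(mask == 1L))
      return(data.frame(frame = fk, neurite_id = roi$neurite_id,
                        tip_arclength_um = NA_real_, valid = FALSE))
    lab <- EBImage::imageData(EBImage::bwlabel(mask))
    lab_of <- lab[corridor]
    tip <- NA_real_
    # component whose minimal arc length attaches to the soma end
    cand <- unique(lab_of[lab_of > 0])
    s_min <- vapply(cand, function(l) min(s_of[lab_of == l]), 0)
    attached <- cand[s_min <= soma_attach]
    if (length(attached)) {
      tip <- max(s_of[lab_of %in% attached])
    }
    if (is.na(tip))
      data.frame(frame = fk, neurite_id = roi$neurite_id,
                 tip_arclength_um = NA_real_, valid = FALSE)
    else
      data.frame(frame = fk, neurite_id = roi$neurite_id,
                 tip_arclength_um = tip, valid = TRUE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect growth events in a tip-position series
#'
#' After moving-median smoothing, maximal runs of frames with non-negative
#' tip velocity whose cumulative advance reaches `min_growth` become
#' growth events.
#'
#' @param tip data.frame (frame, neurite_id, tip_arclength_um, valid) for
#'   one neurite, with at least 3 valid frames
#' @param min_growth minimal net advance of an event, micrometres
#' @param smooth_window moving-median window, frames (odd; 1 = no smoothing)
#' @return data.frame of events: neurite_id, start_frame, end_frame,
#'   advance_um (possibly 0 rows)
#' @export
detect_growth_events <- function(tip, min_growth = 1, smooth_window = 3) {
  tip <- tip[tip$valid, , drop = FALSE]
  if (nrow(tip) < 3) stop_f("need >= 3 valid frames to detect growth events")
  tip <- tip[order(tip$frame), , drop = FALSE]
  s <- tip$tip_arclength_um
  if (smooth_window > 1 && nrow(tip) >= smooth_window)
    s <- stats::runmed(s, k = smooth_window, endrule = "median")
  v <- diff(s)
  nonneg <- v >= -.EPS
  events <- list()
  i <- 1L
  while (i <= length(v)) {
    if (!nonneg[i]) { i <- i + 1L; next }
    j <- i
    while (j < length(v) && nonneg[j + 1L]) j <- j + 1L
    advance <- s[j + 1L] - s[i]
    if (advance >= min_growth)
      events[[length(events) + 1L]] <- data.frame(
        neurite_id = tip$neurite_id[1],
        start_frame = tip$frame[i], end_frame = tip$frame[j + 1L],
        advance_um = advance)
    i <- j + 1L
  }
  if (!length(events))
    return(data.frame(neurite_id = integer(), start_frame = integer(),
                      end_frame = integer(), advance_um = numeric()))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Fraction of growth-event time with a punctum at the neurite tip
#'
#' Over all frames inside growth events (with a valid tip position), the
#' fraction in which at least one punctum lies within `radius` of the tip.
#' Colocalization is binary per frame, not distance-weighted.
#'
#' @param puncta data.frame of punctum positions (frame, x_um, y_um)
#' @param tip data.frame (frame, tip_arclength_um, valid) for the neurite
#' @param events data.frame from [detect_growth_events()] (>= 1 row)
#' @param roi the neurite `mt_roi` (to map arc length to xy)
#' @param radius colocalization radius, micrometres
#' @return fraction in [0, 1]
#' @export
tip_colocalization_fraction <- function(puncta, tip, events, roi, radius = 1) {
  if (nrow(events) == 0) stop_f("no growth events: colocalization fraction undefined")
  ev_frames <- sort(unique(unlist(lapply(seq_len(nrow(events)), function(i)
    events$start_frame[i]:events$end_frame[i]))))
  tip <- tip[tip$valid & tip$frame %in% ev_frames, , drop = FALSE]
  if (nrow(tip) == 0) stop_f("no valid tip frames inside events")
  hits <- 0L
  for (i in seq_len(nrow(tip))) {
    fk <- tip$frame[i]
    tp <- point_at_arclength(roi$vertices, tip$tip_arclength_um[i])
    pp <- puncta[puncta$frame == fk, , drop = FALSE]
    if (nrow(pp) &&
        any((pp$x_um - tp[1, 1])^2 + (pp$y_um - tp[1, 2])^2 <= radius^2))
      hits <- hits + 1L
  }
  hits / nrow(tip)
}

#' Classify the minus-end distribution of a neurite
#'
#' Time-averaged fraction of punctum intensity mass lying within `tip_zone`
#' (arc length) of the current tip; at or above `mass_threshold` the
#' neurite is "tip_accumulated", otherwise "scattered".  The call is
#' invariant to uniform intensity rescaling.
#'
#' @param puncta data.frame (frame, x_um, y_um, optional intensity;
#'   missing intensity counts every punctum equally)
#' @param roi the neurite `mt_roi`
#' @param tip data.frame (frame, tip_arclength_um, valid)
#' @param tip_zone tip-proximal zone, micrometres of arc length
#' @param mass_threshold fraction of mass that defines accumulation
#' @return list: `class` ("tip_accumulated" | "scattered" |
#'   "not_assessed"), `mass_fraction` (time-averaged; NA if not assessed)
#' @export
classify_tip_accumulation <- function(puncta, roi, tip, tip_zone = 2,
                                      mass_threshold = 0.5) {
  tip <- tip[tip$valid, , drop = FALSE]
  if (nrow(tip) == 0 || is.null(puncta) || nrow(puncta) == 0)
    return(list(class = "not_assessed", mass_fraction = NA_real_))
  if (!"intensity" %in% names(puncta)) puncta$intensity <- 1
  fracs <- numeric(0)
  for (i in seq_len(nrow(tip))) {
    pp <- puncta[puncta$frame == tip$frame[i], , drop = FALSE]
    if (nrow(pp) == 0) next
    pr <- project_to_path(roi$vertices, cbind(pp$x_um, pp$y_um))
    near <- abs(pr$s - tip$tip_arclength_um[i]) <= tip_zone
    fracs <- c(fracs, sum(pp$intensity[near]) / sum(pp$intensity))
  }
  if (!length(fracs))
    return(list(class = "not_assessed", mass_fraction = NA_real_))
  mf <- mean(fracs)
  list(class = if (mf >= mass_threshold) "tip_accumulated" else "scattered",
       mass_fraction = mf)
}

#' Detect retrograde clearing of a tip punctum cluster after treatment
#'
#' The tip cluster is seeded from the pre-treatment frames: puncta within
#' `tip_zone` (arc length) of the mean pre-treatment tip position.  Its
#' intensity-weighted arc-length centroid is then followed frame by frame —
#' each frame, the puncta within `tip_zone` of the previous centroid define
#' the cluster — so the read-out does not depend on particle identities
#' surviving the whole movie.  The call is TRUE iff the centroid decreases
#' (moves somawards) by at least `min_displacement` between its
#' pre-treatment mean and its value in the final frame.
#'
#' @param puncta_tracks data.frame of punctum detections (frame, x_um,
#'   y_um, optional intensity); track ids are not required
#' @param roi the neurite `mt_roi`
#' @param tip data.frame (frame, tip_arclength_um, valid)
#' @param treatment_frame 1-based frame index of treatment onset; frames
#'   strictly before it are "pre"
#' @param min_displacement micrometres
#' @param tip_zone micrometres
#' @return list: `retrograde` (TRUE/FALSE/NA for not-assessed),
#'   `displacement_um` (pre-mean minus final centroid; positive =
#'   somaward)
#' @export
detect_retrograde_clearing <- function(puncta_tracks, roi, tip,
                                       treatment_frame,
                                       min_displacement = 2, tip_zone = 2) {
  frames <- sort(unique(puncta_tracks$frame))
  if (!any(frames < treatment_frame) || !any(frames >= treatment_frame))
    stop_f("need punctum data on both sides of treatment_frame")
  if (!"intensity" %in% names(puncta_tracks)) puncta_tracks$intensity <- 1
  pr <- project_to_path(roi$vertices,
                        cbind(puncta_tracks$x_um, puncta_tracks$y_um))
  puncta_tracks$s_um <- pr$s
  pre_tip <- tip[tip$valid & tip$frame < treatment_frame, , drop = FALSE]
  if (nrow(pre_tip) == 0)
    return(list(retrograde = NA, displacement_um = NA_real_))
  tip_ref <- mean(pre_tip$tip_arclength_um)
  centroid <- function(d) sum(d$s_um * d$intensity) / sum(d$intensity)
  # pre-treatment cluster centroid, averaged over pre frames
  pre_frames <- frames[frames < treatment_frame]
  pre_cs <- numeric(0)
  for (fk in pre_frames) {
    pp <- puncta_tracks[puncta_tracks$frame == fk &
                          abs(puncta_tracks$s_um - tip_ref) <= tip_zone, ,
                        drop = FALSE]
    if (nrow(pp)) pre_cs <- c(pre_cs, centroid(pp))
  }
  if (!length(pre_cs))
    return(list(retrograde = NA, displacement_um = NA_real_))
  pre_c <- mean(pre_cs)
  # follow the cluster centroid through the post-treatment frames
  cur <- pre_c
  for (fk in frames[frames >= treatment_frame]) {
    pp <- puncta_tracks[puncta_tracks$frame == fk &
                          abs(puncta_tracks$s_um - cur) <= tip_zone, ,
                        drop = FALSE]
    if (nrow(pp)) cur <- centroid(pp)
  }
  disp <- pre_c - cur
  list(retrograde = disp >= min_displacement, displacement_um = disp)
}

#' Phenotype a neurite: distribution class and retrograde clearing
#'
#' Convenience wrapper combining [classify_tip_accumulation()] and (when a
#' treatment frame is given) [detect_retrograde_clearing()].
#'
#' @inheritParams classify_tip_accumulation
#' @inheritParams detect_retrograde_clearing
#' @return one-row data.frame: neurite_id, distribution_class,
#'   mass_fraction, retrograde_clearing ("yes"/"no"/"not_assessed"),
#'   displacement_um
#' @export
phenotype_neurite <- function(puncta_tracks, roi, tip, tip_zone = 2,
                              mass_threshold = 0.5, treatment_frame = NULL,
                              min_displacement = 2) {
  acc <- classify_tip_accumulation(puncta_tracks, roi, tip, tip_zone,
                                   mass_threshold)
  if (is.null(treatment_frame)) {
    retro <- "not_assessed"; disp <- NA_real_
  } else {
    r <- detect_retrograde_clearing(puncta_tracks, roi, tip, treatment_frame,
                                    min_displacement, tip_zone)
    retro <- if (is.na(r$retrograde)) "not_assessed"
             else if (r$retrograde) "yes" else "no"
    disp <- r$displacement_um
  }
  data.frame(neurite_id = roi$neurite_id, distribution_class = acc$class,
             mass_fraction = acc$mass_fraction, retrograde_clearing = retro,
             displacement_um = disp)
}
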