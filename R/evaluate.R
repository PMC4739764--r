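#' Score estimated tracks against ground truth
#'
#' Matches estimated to true positions frame by frame (nearest neighbour
#' within `match_radius`) and summarizes recovery of the ground-truth
#' track set:
#' \itemize{
#'   \item a true track (with >= `min_length` sampled points) is
#'     \emph{recovered} when a single estimated track matches at least half
#'     of its points;
#'   \item an estimated track (>= `min_length` points) is \emph{spurious}
#'     when fewer than half of its points match any true point;
#'   \item localization error is the mean matched-pair distance.
#' }
#'
#' @param truth data.frame of true appearances (track_id, frame, x_um,
#'   y_um)
#' @param est data.frame of estimated tracks (track_id, frame, x_um, y_um)
#' @param match_radius micrometres; a pair further apart never matches
#' @param min_length minimal track length entering either count
#' @return list: `recall`, `spurious_fraction`, `mean_error_um`,
#'   `n_truth`, `n_est`, `n_matched_points`
#' @export
evaluate_tracking <- function(truth, est, match_radius = 0.3,
                              min_length = 3) {
  pair_rows <- list()
  for (fk in intersect(unique(truth$frame), unique(est$frame))) {
    tt <- truth[truth$frame == fk, , drop = FALSE]
    ee <- est[est$frame == fk, , drop = FALSE]
    d2 <- outer(tt$x_um, ee$x_um, "-")^2 + outer(tt$y_um, ee$y_um, "-")^2
    # greedy nearest-neighbour matching, closest pairs first
    repeat {
      mn <- which.min(d2)
      if (!length(mn) || d2[mn] > match_radius^2) break
      i <- (mn - 1L) %% nrow(d2) + 1L
      j <- (mn - 1L) %/% nrow(d2) + 1L
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        true_track = tt$track_id[i], est_track = ee$track_id[j],
        dist = sqrt(d2[mn]))
      d2[i, ] <- Inf; d2[, j] <- Inf
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(true_track = integer(), est_track = integer(), dist = numeric())

  t_len <- table(truth$track_id)
  t_ids <- as.numeric(names(t_len))[t_len >= min_length]
  recovered <- vapply(t_ids, function(id) {
    pp <- pairs[pairs$true_track == id, , drop = FALSE]
    if (!nrow(pp)) return(FALSE)
    max(table(pp$est_track)) >= sum(truth$track_id == id) / 2
  }, TRUE)
  e_len <- table(est$track_id)
  e_ids <- as.numeric(names(e_len))[e_len >= min_length]
  spurious <- vapply(e_ids, function(id) {
    sum(pairs$est_track == id) < sum(est$track_id == id) / 2
  }, TRUE)

  list(recall = if (length(t_ids)) mean(recovered) else NA_real_,
       spurious_fraction = if (length(e_ids)) mean(spurious) else NA_real_,
       mean_error_um = if (nrow(pairs)) mean(pairs$dist) else NA_real_,
       n_truth = length(t_ids), n_est = length(e_ids),
       n_matched_points = nrow(pairs))
}
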