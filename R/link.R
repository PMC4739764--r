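#' Solve a square linear assignment problem exactly
#'
#' Jonker-Volgenant style shortest-augmenting-path algorithm (O(n^3)).
#' Deterministic: among equal-cost alternatives the lowest column index is
#' taken first, so ties are broken by lowest spot index.
#'
#' @param cost numeric n x n matrix (finite; use a large sentinel for
#'   forbidden assignments)
#' @return integer vector a with a[i] = column assigned to row i
#' @export
solve_lap <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop_f("cost matrix must be square")
  if (n == 0L) return(integer())
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      free_j <- which(!used[2:(n + 1L)])
      if (length(free_j)) {
        cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
        upd <- cur < minv[free_j]
        if (any(upd)) {
          minv[free_j[upd]] <- cur[upd]
          way[free_j[upd] + 1L] <- j0
        }
        jbest <- free_j[which.min(minv[free_j])]
        delta <- minv[jbest]; j1 <- jbest
      }
      usedj <- which(used)
      pr <- p[usedj]
      u[pr + 1L] <- u[pr + 1L] + delta
      v[usedj] <- v[usedj] - delta
      if (length(free_j)) minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (j0 == 0L || p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

.LAP_BIG <- 1e9

# Cost matrix for linking n1 source to n2 target spots with per-item
# alternative (birth/death) cost `alt`: the standard (n1+n2) square layout
# with real costs top-left, death/birth alternatives on the diagonals of the
# top-right / bottom-left blocks, and zeros bottom-right.
.link_cost_matrix <- function(d2, alt) {
  n1 <- nrow(d2); n2 <- ncol(d2)
  n <- n1 + n2
  A <- matrix(.LAP_BIG, n, n)
  if (n1 && n2) A[1:n1, 1:n2] <- d2
  if (n1) A[cbind(1:n1, n2 + 1:n1)] <- alt
  if (n2) A[cbind(n1 + 1:n2, 1:n2)] <- alt
  if (n1 && n2) A[n1 + 1:n2, n2 + 1:n1] <- 0
  A
}

#' Link per-frame spots into trajectories
#'
#' Frame-to-frame linking by optimal bipartite assignment minimizing total
#' squared displacement, with a hard displacement cutoff `link_radius`
#' (pairs beyond it cannot link; the alternative birth/death cost is
#' `link_radius^2`).  A second pass closes gaps of up to `max_gap` missing
#' frames between track ends and track starts, with the cutoff scaled by
#' the time elapsed (`link_radius * (gap + 1)`).  Unassigned spots start
#' new tracks.  Ties are broken deterministically by lowest spot index.
#'
#' @param spots data.frame with columns `frame`, `x_um`, `y_um` (plus any
#'   others, carried through)
#' @param link_radius maximum frame-to-frame displacement, micrometres (> 0)
#' @param max_gap maximum number of bridged (detection-less) frames
#' @return data.frame of the input spots with `track_id` prepended, sorted
#'   by (track_id, frame); attribute `n_gaps` counts bridged frames
#' @export
link_spots <- function(spots, link_radius, max_gap = 1) {
  if (!is.numeric(link_radius) || link_radius <= 0)
    stop_f("'link_radius' must be > 0")
  if (nrow(spots) == 0) {
    out <- cbind(track_id = integer(), spots)
    attr(out, "n_gaps") <- 0L
    return(out)
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  n <- nrow(spots)
  nxt <- rep(NA_integer_, n)   # successor spot index within a track
  by_frame <- split(seq_len(n), spots$frame)
  fr_ids <- as.integer(names(by_frame))

  r2 <- link_radius^2
  for (fi in seq_len(length(fr_ids) - 1L)) {
    if (fr_ids[fi + 1L] != fr_ids[fi] + 1L) next    # not consecutive frames
    a <- by_frame[[fi]]; b <- by_frame[[fi + 1L]]
    d2 <- outer(spots$x_um[a], spots$x_um[b], "-")^2 +
          outer(spots$y_um[a], spots$y_um[b], "-")^2
    d2[d2 > r2] <- .LAP_BIG
    sol <- solve_lap(.link_cost_matrix(d2, r2))
    for (i in seq_along(a)) {
      j <- sol[i]
      if (j <= length(b) && d2[i, j] < .LAP_BIG) nxt[a[i]] <- b[j]
    }
  }

  # assemble segments
  has_pred <- rep(FALSE, n); has_pred[nxt[!is.na(nxt)]] <- TRUE
  heads <- which(!has_pred)
  segs <- lapply(heads, function(h) {
    out <- h
    while (!is.na(nxt[out[length(out)]])) out <- c(out, nxt[out[length(out)]])
    out
  })

  # gap closing: track ends -> track starts, gap in [1, max_gap]
  if (max_gap >= 1 && length(segs) > 1) {
    ends <- vapply(segs, function(s) s[length(s)], 0L)
    starts <- vapply(segs, function(s) s[1L], 0L)
    ef <- spots$frame[ends]; sf <- spots$frame[starts]
    nE <- length(ends)
    gap <- outer(sf, ef, "-") - 1L                  # gap[j_start, i_end]
    d2 <- (outer(spots$x_um[starts], spots$x_um[ends], "-")^2 +
           outer(spots$y_um[starts], spots$y_um[ends], "-")^2)
    cutoff <- (link_radius * (gap + 1L))^2
    ok <- gap >= 1L & gap <= max_gap & d2 <= cutoff
    diag(ok) <- FALSE
    if (any(ok)) {
      cost <- t(ifelse(ok, d2, .LAP_BIG))           # rows = ends, cols = starts
      alt <- (link_radius * (max_gap + 1L))^2
      sol <- solve_lap(.link_cost_matrix(cost, alt))
      join_to <- rep(NA_integer_, nE)               # for each start seg, its end seg
      for (i in seq_len(nE)) {
        j <- sol[i]
        if (j <= nE && cost[i, j] < .LAP_BIG) join_to[j] <- i
      }
      # merge chains, starting from segments that are not themselves joined
      merged <- vector("list", 0)
      consumed <- logical(nE)
      root <- which(is.na(join_to))
      # follow forward: which start attaches to my end?
      attach_after <- rep(NA_integer_, nE)
      for (j in seq_len(nE)) if (!is.na(join_to[j])) attach_after[join_to[j]] <- j
      for (r in root) {
        chain <- segs[[r]]; consumed[r] <- TRUE
        cur <- r
        while (!is.na(attach_after[cur])) {
          cur <- attach_after[cur]
          chain <- c(chain, segs[[cur]])
          consumed[cur] <- TRUE
        }
        merged[[length(merged) + 1L]] <- chain
      }
      segs <- merged
    }
  }

  # deterministic track ids: by first frame, then first spot index
  ord <- order(vapply(segs, function(s) as.numeric(spots$frame[s[1L]]), 0),
               vapply(segs, function(s) s[1L], 0L))
  segs <- segs[ord]
  tid <- integer(n)
  for (i in seq_along(segs)) tid[segs[[i]]] <- i
  out <- cbind(track_id = tid, spots)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  n_gaps <- sum(vapply(segs, function(s)
    as.numeric(spots$frame[s[length(s)]] - spots$frame[s[1L]] + 1L - length(s)),
    0))
  attr(out, "n_gaps") <- n_gaps
  out
}

#' Keep tracks inside neurite ROIs and long enough to classify
#'
#' Implements the inclusion rule that only comets contained in processes
#' enter the analysis: a track is kept if it has at least `min_length`
#' spots and its median position lies within width/2 of an ROI polyline.
#' Kept tracks are annotated with the `neurite_id` of the nearest ROI.
#'
#' @param tracks data.frame with track_id, frame, x_um, y_um
#' @param rois non-empty list of `mt_roi`
#' @param min_length minimum number of spots per track
#' @return filtered data.frame with `neurite_id` column added
#' @export
filter_tracks <- function(tracks, rois, min_length = 3) {
  if (length(rois) == 0)
    stop_f("empty ROI list: the process-inclusion rule cannot be applied")
  if (inherits(rois, "mt_roi")) rois <- list(rois)
  if (nrow(tracks) == 0) return(cbind(tracks, neurite_id = integer()))
  keep_rows <- list()
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    if (nrow(tr) < min_length) next
    med <- c(stats::median(tr$x_um), stats::median(tr$y_um))
    best <- NULL; best_d <- Inf
    for (r in rois) {
      pr <- project_to_path(r$vertices, rbind(med))
      if (pr$dist <= r$width / 2 && pr$dist < best_d) {
        best <- r$neurite_id; best_d <- pr$dist
      }
    }
    if (is.null(best)) next
    tr$neurite_id <- best
    keep_rows[[length(keep_rows) + 1L]] <- tr
  }
  if (!length(keep_rows)) {
    out <- tracks[0, , drop = FALSE]
    out$neurite_id <- integer()
    return(out)
  }
  out <- do.call(rbind, keep_rows)
  rownames(out) <- NULL
  out
}
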