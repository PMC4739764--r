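#' Polyline arc-length utilities
#'
#' A neurite path is an n x 2 matrix of (x, y) vertices in micrometres,
#' ordered soma-end first.  These helpers interpolate positions and tangents
#' along the path and project arbitrary points onto it.
#'
#' @param path numeric n x 2 matrix of vertices (micrometres)
#' @return `path_length` returns the total arc length; `path_cumlen` the
#'   cumulative arc length at each vertex (first entry 0).
#' @export
path_length <- function(path) {
  sum(sqrt(rowSums(diff(path)^2)))
}

#' @rdname path_length
#' @export
path_cumlen <- function(path) {
  c(0, cumsum(sqrt(rowSums(diff(path)^2))))
}

#' Interpolate a point (and tangent) at a given arc length along a polyline
#'
#' @param path numeric n x 2 matrix of vertices
#' @param s arc lengths (micrometres), clamped to [0, path length]
#' @return `point_at_arclength`: matrix of (x, y); `tangent_at_arclength`:
#'   matrix of unit tangents (direction of increasing arc length).
#' @export
point_at_arclength <- function(path, s) {
  cl <- path_cumlen(path)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  seg <- findInterval(s, cl, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(path) - 1L)
  seglen <- cl[seg + 1L] - cl[seg]
  f <- ifelse(seglen > 0, (s - cl[seg]) / seglen, 0)
  path[seg, , drop = FALSE] * (1 - f) + path[seg + 1L, , drop = FALSE] * f
}

#' @rdname point_at_arclength
#' @export
tangent_at_arclength <- function(path, s) {
  cl <- path_cumlen(path)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  seg <- findInterval(s, cl, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(path) - 1L)
  d <- path[seg + 1L, , drop = FALSE] - path[seg, , drop = FALSE]
  d / sqrt(rowSums(d^2))
}

#' Project points onto a polyline
#'
#' For each query point, finds the closest point on the polyline and returns
#' its arc-length coordinate and the Euclidean distance to it.
#'
#' @param path numeric n x 2 matrix of polyline vertices (micrometres)
#' @param pts m x 2 matrix of query points
#' @return data.frame with columns `s` (arc length of the nearest point,
#'   micrometres) and `dist` (distance to it)
#' @export
project_to_path <- function(path, pts) {
  pts <- rbind(pts)
  cl <- path_cumlen(path)
  nseg <- nrow(path) - 1L
  best_d2 <- rep(Inf, nrow(pts))
  best_s <- numeric(nrow(pts))
  for (k in seq_len(nseg)) {
    a <- path[k, ]; b <- path[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d2 <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cl[k] + t[upd] * sqrt(len2)
  }
  data.frame(s = best_s, dist = sqrt(best_d2))
}

#' Generate a synthetic neuron geometry
#'
#' Builds a soma centre and one or more neurite paths radiating from it, the
#' scaffold on which comets, puncta and movies are simulated.  Neurites start
#' at the soma centre and are laid out at evenly spaced base angles (with a
#' small seeded jitter); `curvature` bends each path by a Gaussian random
#' walk of the local bearing.
#'
#' @param n_neurites number of neurite paths (>= 1)
#' @param neurite_length length of each path in micrometres
#' @param curvature standard deviation of the per-step bearing change,
#'   degrees per step; 0 gives perfectly straight 2-vertex paths
#' @param step_length polyline vertex spacing in micrometres (curved paths)
#' @param neurite_width neurite (tube) width in micrometres
#' @param soma_radius soma disk radius in micrometres (rendering / masks)
#' @param field_size optional c(width, height) of the field in micrometres;
#'   if NULL, sized to contain the soma and all neurites with a 2 um margin
#' @param seed integer seed; the geometry is a pure function of the
#'   arguments and the seed
#' @return an object of class `mt_geometry`: list with `soma_center`,
#'   `neurite_paths` (list of matrices, soma end first), `neurite_width`,
#'   `soma_radius`, `field_size`
#' @examples
#' g <- make_geometry(n_neurites = 3, neurite_length = 20, curvature = 2, seed = 1)
#' length(g$neurite_paths)
#' @export
make_geometry <- function(n_neurites = 1, neurite_length = 20, curvature = 0,
                          step_length = 1, neurite_width = 1, soma_radius = 2.5,
                          field_size = NULL, seed = 1) {
  check_positive(neurite_length, "neurite_length")
  check_positive(step_length, "step_length")
  check_positive(neurite_width, "neurite_width")
  check_positive(soma_radius, "soma_radius")
  if (n_neurites < 1) stop_f("at least one neurite must be requested")
  if (curvature < 0) stop_f("'curvature' must be >= 0")
  if (neurite_length <= 2 * neurite_width)
    stop_f("neurite_length (%g) must exceed 2 x neurite_width (%g)",
           neurite_length, 2 * neurite_width)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  spacing <- 2 * pi / n_neurites
  base <- runif(1, 0, 2 * pi) + (seq_len(n_neurites) - 1L) * spacing +
    runif(n_neurites, -0.1, 0.1) * spacing
  paths <- vector("list", n_neurites)
  for (i in seq_len(n_neurites)) {
    if (curvature == 0) {
      d <- c(cos(base[i]), sin(base[i]))
      paths[[i]] <- rbind(c(0, 0), neurite_length * d)
    } else {
      nstep <- max(2L, ceiling(neurite_length / step_length))
      step <- neurite_length / nstep
      bearing <- base[i] + cumsum(c(0, rnorm(nstep - 1L, 0, curvature * pi / 180)))
      v <- rbind(c(0, 0), cbind(cumsum(step * cos(bearing)),
                                cumsum(step * sin(bearing))))
      paths[[i]] <- v
    }
  }

  # field: bounding box of soma disk and all paths plus a margin
  allv <- do.call(rbind, paths)
  margin <- max(soma_radius, neurite_width) + 1.5
  lo <- pmin(apply(allv, 2, min), 0) - margin
  hi <- pmax(apply(allv, 2, max), 0) + margin
  if (is.null(field_size)) {
    field_size <- hi - lo
    soma <- -lo
  } else {
    if (length(field_size) == 1L) field_size <- rep(field_size, 2L)
    soma <- field_size / 2
  }
  paths <- lapply(paths, function(p) sweep(p, 2, soma, "+"))

  margin <- neurite_width / 2
  ok <- vapply(paths, function(p)
    all(p[, 1] >= margin & p[, 1] <= field_size[1] - margin &
        p[, 2] >= margin & p[, 2] <= field_size[2] - margin), TRUE)
  if (!all(ok))
    stop_f("field (%g x %g um) too small to contain the requested neurites",
           field_size[1], field_size[2])

  structure(list(soma_center = soma, neurite_paths = paths,
                 neurite_width = neurite_width, soma_radius = soma_radius,
                 field_size = field_size),
            class = "mt_geometry")
}

# Save/restore .Random.seed so seeded constructors do not perturb the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Convert a geometry's neurite paths to polyline ROIs
#'
#' @param geometry an `mt_geometry`
#' @return list of `mt_roi` objects (see [read_roi()])
#' @export
geometry_to_rois <- function(geometry) {
  stopifnot(inherits(geometry, "mt_geometry"))
  lapply(seq_along(geometry$neurite_paths), function(i)
    new_roi(neurite_id = i, vertices = geometry$neurite_paths[[i]],
            width = geometry$neurite_width))
}

#' @export
print.mt_geometry <- function(x, ...) {
  cat(sprintf("<mt_geometry> soma (%.1f, %.1f) um, %d neurite(s), width %.2f um, field %.1f x %.1f um\n",
              x$soma_center[1], x$soma_center[2], length(x$neurite_paths),
              x$neurite_width, x$field_size[1], x$field_size[2]))
  invisible(x)
}
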