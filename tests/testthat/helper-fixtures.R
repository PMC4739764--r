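# Shared fixture builders: everything is generated in code, no stored data.

# 2-point track whose net displacement makes angle `theta` (degrees) with
# the outward radial direction at its midpoint
track_at_angle <- function(theta, center = c(0, 0), radius = 10, step = 1) {
  pos <- center + c(radius, 0)              # outward radial = +x
  d <- step * c(cos(theta * pi / 180), sin(theta * pi / 180))
  rbind(pos - d / 2, pos + d / 2)
}

# single straight neurite, 20 um, deterministic
straight_geom <- function(seed = 1, length_um = 20, n = 1, curvature = 0) {
  make_geometry(n_neurites = n, neurite_length = length_um,
                curvature = curvature, seed = seed)
}

# comet-movie parameters at a given SNR
snr_params <- function(snr = 8, ...) {
  base <- sim_params(...)
  sim_params(..., comet_peak_photons = peak_for_snr(snr, base))
}

# render a single particle track on a quiet background
render_single_spot <- function(geom, s_um, frames = 1, params) {
  xy <- point_at_arclength(geom$neurite_paths[[1]], rep(s_um, length(frames)))
  tracks <- data.frame(track_id = 1L, frame = frames,
                       x_um = xy[, 1], y_um = xy[, 2])
  render_movie(geom, tracks, params, channels = "particles")
}

# brute-force frame-pair assignment oracle: enumerates every injective
# partial matching between two spot sets, scoring sum(d^2) for matched
# pairs (only allowed within `radius`) plus radius^2 per unmatched spot.
# Independent of the LAP path.
oracle_pair_matching <- function(ax, ay, bx, by, radius) {
  na <- length(ax); nb <- length(bx)
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  best <- list(cost = Inf, match = rep(NA_integer_, na))
  recurse <- function(i, used_b, match, cost) {
    if (cost >= best$cost) return()
    if (i > na) {
      cost_total <- cost + radius^2 * (sum(is.na(match)) + nb - sum(!is.na(match)))
      if (cost_total < best$cost)
        best <<- list(cost = cost_total, match = match)
      return()
    }
    recurse(i + 1L, used_b, match, cost)           # leave i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && d2[i, j] <= radius^2) {
        used_b[j] <- TRUE; match[i] <- j
        recurse(i + 1L, used_b, match, cost + d2[i, j])
        used_b[j] <- FALSE; match[i] <- NA_integer_
      }
    }
  }
  recurse(1L, logical(nb), rep(NA_integer_, na), 0)
  best
}

# frame-to-frame links chosen by link_spots (max_gap = 0), as a data.frame
# of (from_row, to_row) in the sorted spot table
extract_links <- function(linked) {
  out <- list()
  for (id in unique(linked$track_id)) {
    rows <- which(linked$track_id == id)
    if (length(rows) > 1)
      out[[length(out) + 1L]] <- data.frame(from = rows[-length(rows)],
                                            to = rows[-1])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(from = integer(), to = integer())
}

# independent exact Mann-Whitney oracle by full enumeration over group
# assignments (midranks), two-sided symmetric-tail rule
oracle_mw_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  rk <- rank(c(a, b))
  U_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * (n - na) / 2
  cmb <- utils::combn(n, na)
  Uall <- apply(cmb, 2, function(ix) sum(rk[ix])) - na * (na + 1) / 2
  mean(abs(Uall - mu) >= abs(U_obs - mu) - 1e-9)
}

# independent Fisher oracle: enumerate all tables with the observed margins
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  pr <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1), 0)
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, tab[2, 1]) / choose(r1 + r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
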