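#' Pressure-diameter orbits
#'
#' An orbit is the trajectory of paired (diameter, pressure) values along a
#' chosen path through a composite map -- typically a fixed position followed
#' through time. Its near-linear phases ("steady states") are the unit of
#' mechanical-state classification.
#'
#' @param time strictly increasing numeric vector, s (>= 2 samples).
#' @param diameter,pressure numeric vectors of the same length (mm, mmHg).
#' @return A data.frame of class `orbit` with columns `time`, `diameter`,
#'   `pressure`.
#' @export
orbit <- function(time, diameter, pressure) {
  if (length(time) < 2) stop("orbit needs at least 2 samples", call. = FALSE)
  if (any(diff(time) <= 0)) stop("orbit times must be strictly increasing", call. = FALSE)
  if (length(diameter) != length(time) || length(pressure) != length(time))
    stop("time, diameter and pressure must have equal length", call. = FALSE)
  structure(data.frame(time = time, diameter = diameter, pressure = pressure),
            class = c("orbit", "data.frame"))
}

#' Extract an orbit along a space-time path of a composite map
#'
#' Samples diameter and pressure by bilinear interpolation at each path point.
#' A line of any length and orientation can be drawn across the composite map;
#' the vertical (fixed-position) path is the common case, provided by
#' `orbit_at()`.
#'
#' @param cmap a [composite_map()].
#' @param path two-column matrix or data.frame of (position cm, time s)
#'   points; times non-decreasing (consecutive duplicate times are dropped).
#' @return An [orbit()].
#' @export
extract_orbit <- function(cmap, path) {
  stopifnot(inherits(cmap, "composite_map"))
  path <- as.matrix(path)
  if (ncol(path) != 2) stop("path must have two columns (position, time)", call. = FALSE)
  if (any(diff(path[, 2]) < 0)) stop("path times must be non-decreasing", call. = FALSE)
  keep <- c(TRUE, diff(path[, 2]) > 0)
  path <- path[keep, , drop = FALSE]
  if (nrow(path) < 2) stop("orbit needs at least 2 samples", call. = FALSE)
  sample_one <- function(map, x, t)
    interp_bilinear(map$values, map$positions, map$times, x, t)[1, 1]
  d <- mapply(sample_one, x = path[, 1], t = path[, 2],
              MoreArgs = list(map = cmap$diameter))
  p <- mapply(sample_one, x = path[, 1], t = path[, 2],
              MoreArgs = list(map = cmap$pressure))
  orbit(path[, 2], d, p)
}

#' @rdname extract_orbit
#' @param x fixed position, cm.
#' @param t0,t1 time window, s (defaults to the full map).
#' @export
orbit_at <- function(cmap, x, t0 = NULL, t1 = NULL) {
  times <- cmap$diameter$times
  if (is.null(t0)) t0 <- times[1]
  if (is.null(t1)) t1 <- times[length(times)]
  tt <- times[times >= t0 - 1e-9 & times <= t1 + 1e-9]
  if (length(tt) < 2) stop("time window contains fewer than 2 samples", call. = FALSE)
  extract_orbit(cmap, cbind(rep(x, length(tt)), tt))
}

# Robust per-axis scale used to normalise orbits before geometric tests:
# 5th-95th percentile range, degrading to full range, then to 1.
robust_range <- function(x) {
  q <- stats::quantile(x, c(0.05, 0.95), na.rm = TRUE, names = FALSE)
  r <- q[2] - q[1]
  if (r <= 0) r <- diff(range(x, na.rm = TRUE))
  if (!is.finite(r) || r <= 0) r <- 1
  r
}

# Max perpendicular distance of interior points from the chord i0--i1 in the
# normalised orbit plane; returns list(dist, index).
max_chord_deviation <- function(d, p, i0, i1) {
  if (i1 - i0 < 2) return(list(dist = 0, index = NA_integer_))
  idx <- (i0 + 1):(i1 - 1)
  vx <- d[i1] - d[i0]; vy <- p[i1] - p[i0]
  len <- sqrt(vx^2 + vy^2)
  if (len < 1e-15) {
    dist <- sqrt((d[idx] - d[i0])^2 + (p[idx] - p[i0])^2)
  } else {
    dist <- abs(vx * (p[idx] - p[i0]) - vy * (d[idx] - d[i0])) / len
  }
  j <- which.max(dist)
  list(dist = dist[j], index = idx[j])
}

#' Segment an orbit into near-linear phases
#'
#' Recursive endpoint-split polyline simplification in per-axis-normalised
#' orbit space: the orbit is split at the sample of greatest perpendicular
#' deviation from the current chord until every piece deviates by at most
#' `tol`. Adjacent pieces whose (delta-D, delta-P) sign classification is
#' identical are merged, and pieces shorter than `min_len` samples are
#' absorbed into a neighbour. Each axis is normalised by its robust
#' (5th-95th percentile) range before distance tests.
#'
#' @param orb an [orbit()].
#' @param tol maximum normalised perpendicular deviation (default 0.05).
#' @param min_len minimum segment length in samples (default 5).
#' @return A data.frame of class `orbit_segments`: one row per phase with
#'   sample indices `start`/`end`, times `t_start`/`t_end`, total changes
#'   `dD` (mm) and `dP` (mmHg), `mean_diameter` (mm) and the achieved
#'   normalised `residual`.
#' @export
segment_orbit <- function(orb, tol = 0.05, min_len = 5) {
  stopifnot(inherits(orb, "orbit"))
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  n <- nrow(orb)
  rd <- robust_range(orb$diameter)
  rp <- robust_range(orb$pressure)
  dn <- orb$diameter / rd
  pn <- orb$pressure / rp

  # recursive greatest-deviation bisection
  split_rec <- function(i0, i1) {
    dev <- max_chord_deviation(dn, pn, i0, i1)
    if (dev$dist <= tol || i1 - i0 < 2) return(c(i0, i1))
    left <- split_rec(i0, dev$index)
    right <- split_rec(dev$index, i1)
    c(left[-length(left)], right)
  }
  brk <- split_rec(1L, n)

  seg_sign <- function(i0, i1) {
    # zero band tied to the segmentation tolerance, in normalised units
    c(sign_band(dn[i1] - dn[i0], tol), sign_band(pn[i1] - pn[i0], tol))
  }
  # merge adjacent segments with identical sign classification
  repeat {
    if (length(brk) <= 2) break
    merged <- FALSE
    for (k in seq_len(length(brk) - 2)) {
      s1 <- seg_sign(brk[k], brk[k + 1])
      s2 <- seg_sign(brk[k + 1], brk[k + 2])
      if (identical(s1, s2)) { brk <- brk[-(k + 1)]; merged <- TRUE; break }
    }
    if (!merged) break
  }
  # absorb segments shorter than min_len into a neighbour
  repeat {
    lens <- diff(brk)
    short <- which(lens < min_len)
    if (!length(short) || length(brk) <= 2) break
    k <- short[which.min(lens[short])]
    drop_at <- if (k == 1) 2L else if (k == length(lens)) length(brk) - 1L
               else if (lens[k - 1] <= lens[k + 1]) k else k + 1L
    brk <- brk[-drop_at]
  }

  make_row <- function(i0, i1) {
    dev <- max_chord_deviation(dn, pn, i0, i1)
    data.frame(start = i0, end = i1,
               t_start = orb$time[i0], t_end = orb$time[i1],
               dD = orb$diameter[i1] - orb$diameter[i0],
               dP = orb$pressure[i1] - orb$pressure[i0],
               mean_diameter = mean(orb$diameter[i0:i1], na.rm = TRUE),
               residual = dev$dist)
  }
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1),
                               function(k) make_row(brk[k], brk[k + 1])))
  attr(out, "scales") <- c(diameter = rd, pressure = rp)
  class(out) <- c("orbit_segments", "data.frame")
  out
}

# sign with a symmetric zero band
sign_band <- function(x, eps) {
  if (abs(x) <= eps) 0L else if (x > 0) 1L else -1L
}

#' Classify an orbit phase into a mechanical state
#'
#' Applies zero-banded signs to the phase's total pressure and diameter
#' changes and the occlusion boundary to its mean diameter, then looks the
#' state up via [state_from_signs()]. Classification depends only on the
#' geometry of the phase in the pressure-diameter plane, so it is invariant
#' under uniform time reparameterisation.
#'
#' @param seg one row of [segment_orbit()] output, or any list with `dD`,
#'   `dP`, `mean_diameter`.
#' @param occl_boundary diameter (mm) separating occluded from distended.
#' @param eps_P,eps_D zero bands (mmHg, mm): changes of magnitude at most the
#'   band count as "no change". Defaults of 3x the robust scale of the
#'   sample-to-sample changes can be obtained with [default_zero_bands()].
#' @return State label (character).
#' @export
classify_segment <- function(seg, occl_boundary, eps_P, eps_D) {
  if (eps_P <= 0 || eps_D <= 0) stop("zero bands must be positive", call. = FALSE)
  sP <- sign_band(seg$dP, eps_P)
  sD <- sign_band(seg$dD, eps_D)
  lumen <- if (seg$mean_diameter < occl_boundary) "occluded" else "distended"
  state_from_signs(sP, sD, lumen)
}

#' @rdname classify_segment
#' @param segs an `orbit_segments` table.
#' @return `classify_segments()`: the table with a `state` column appended.
#' @export
classify_segments <- function(segs, occl_boundary, eps_P, eps_D) {
  segs$state <- vapply(seq_len(nrow(segs)), function(i)
    classify_segment(segs[i, ], occl_boundary, eps_P, eps_D), character(1))
  segs
}

#' @rdname classify_segment
#' @param orb an [orbit()].
#' @return `default_zero_bands()`: named vector `c(eps_P=, eps_D=)`, 3x the
#'   MAD-based robust scale of the respective sample-to-sample changes.
#' @export
default_zero_bands <- function(orb) {
  c(eps_P = 3 * robust_scale(diff(orb$pressure), floor_sd = 1e-6),
    eps_D = 3 * robust_scale(diff(orb$diameter), floor_sd = 1e-6))
}
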