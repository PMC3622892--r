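#' Convert an admittance map to an internal-diameter map
#'
#' Inverse impedance (admittance) is proportional to the internal
#' cross-sectional area of the gut so long as the conductance of the luminal
#' content stays constant: `CSA = k * G`. Assuming a circular lumen, the
#' internal diameter is `D_int = 2 sqrt(CSA / pi)`. Cells with nonpositive
#' admittance become missing.
#'
#' @param imap an [stmap()] with quantity `admittance_mS`.
#' @param k area per admittance unit (mm^2/mS, > 0); either supplied from a
#'   calibration or estimated with [estimate_admittance_scale()].
#' @return An [stmap()] with quantity `internal_diameter_mm`.
#' @export
admittance_to_internal_diameter <- function(imap, k) {
  stopifnot(inherits(imap, "stmap"))
  if (imap$quantity != "admittance_mS")
    stop("imap must carry quantity 'admittance_mS'", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  g <- imap$values
  g[!is.na(g) & g <= 0] <- NA_real_
  csa <- k * g
  stmap(2 * sqrt(csa / pi), imap$positions, imap$times,
        quantity = "internal_diameter_mm", source = imap$source)
}

#' @rdname admittance_to_internal_diameter
#' @param internal_dmap an [stmap()] of internal diameters (mm) on the same
#'   grid, providing the cross-sectional-area proxy to regress on.
#' @return `estimate_admittance_scale()`: the least-squares proportionality
#'   constant `k` (mm^2 per admittance unit).
#' @export
estimate_admittance_scale <- function(imap, internal_dmap) {
  stopifnot(inherits(imap, "stmap"), inherits(internal_dmap, "stmap"))
  g <- as.vector(imap$values)
  csa <- pi * (as.vector(internal_dmap$values) / 2)^2
  ok <- is.finite(g) & is.finite(csa) & g > 0
  if (sum(ok) < 3) stop("need at least 3 paired samples", call. = FALSE)
  sum(g[ok] * csa[ok]) / sum(g[ok]^2)
}

#' Cross-correlate two co-registered maps
#'
#' Pearson correlation between two maps on a shared grid, pooled over all
#' non-missing paired samples (positions and times flattened together), at
#' the integer-sample time lag in `[-max_lag, max_lag]` that maximises |r|.
#' Used to quantify the agreement between video-derived diameter and
#' impedance-derived internal diameter.
#'
#' @param mapA,mapB [stmap()]s on identical grids (use [align()] first if
#'   they are not).
#' @param max_lag maximum time lag searched, s (default 2).
#' @return A list of class `correlation_report`: `pearson_r`, `n` (samples
#'   compared), `lag_s` (the applied lag of B relative to A) and
#'   `lag_samples`.
#' @export
correlate_maps <- function(mapA, mapB, max_lag = 2) {
  stopifnot(inherits(mapA, "stmap"), inherits(mapB, "stmap"))
  if (!isTRUE(all.equal(mapA$positions, mapB$positions)) ||
      !isTRUE(all.equal(mapA$times, mapB$times)))
    stop("maps must be co-registered to the same grid (see align)", call. = FALSE)
  dt <- stmap_dt(mapA)
  L <- if (is.na(dt)) 0L else as.integer(round(max_lag / dt))
  nt <- ncol(mapA$values)
  best <- NULL
  for (lag in -L:L) {
    if (lag >= nt || -lag >= nt) next
    if (lag >= 0) { ja <- seq_len(nt - lag); jb <- ja + lag }
    else { jb <- seq_len(nt + lag); ja <- jb - lag }
    va <- as.vector(mapA$values[, ja, drop = FALSE])
    vb <- as.vector(mapB$values[, jb, drop = FALSE])
    ok <- is.finite(va) & is.finite(vb)
    if (sum(ok) < 3) next
    if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0)
      stop("undefined correlation: zero variance in a map", call. = FALSE)
    r <- stats::cor(va[ok], vb[ok])
    if (is.null(best) || abs(r) > abs(best$pearson_r))
      best <- list(pearson_r = r, n = sum(ok), lag_s = lag * dt,
                   lag_samples = lag)
  }
  if (is.null(best)) stop("fewer than 3 paired non-missing samples", call. = FALSE)
  class(best) <- "correlation_report"
  best
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f over n = %d samples (lag %.3g s)\n",
              x$pearson_r, x$n, x$lag_s))
  invisible(x)
}
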