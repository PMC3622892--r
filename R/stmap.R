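#' Spatiotemporal maps of gut diameter, pressure or admittance
#'
#' An `stmap` holds one physical quantity sampled on a position (cm) by
#' time (s) grid: a DMap (external diameter, mm), a PMap (intraluminal
#' pressure, mmHg), an IMap (admittance, mS) or an impedance-derived internal
#' diameter map. Position 0 cm is the oral end, increasing anally; missing
#' samples are stored as `NA`. Units are fixed internally to mm, cm, s and
#' mmHg; pressure is converted to kPa only at reporting boundaries
#' (1 mmHg = 0.133322 kPa).
#'
#' @param values numeric matrix, rows = positions, columns = times.
#' @param positions strictly increasing numeric vector, cm.
#' @param times strictly increasing numeric vector, s.
#' @param quantity one of `"diameter_mm"`, `"pressure_mmHg"`,
#'   `"admittance_mS"`, `"internal_diameter_mm"`.
#' @param source free-text provenance tag.
#' @return An object of class `stmap`.
#' @export
#' @examples
#' m <- stmap(matrix(1:6, 2, 3), positions = c(0, 1),
#'            times = c(0, 0.5, 1), quantity = "diameter_mm")
#' dim(m$values)
stmap <- function(values, positions, times,
                  quantity = c("diameter_mm", "pressure_mmHg",
                               "admittance_mS", "internal_diameter_mm"),
                  source = "") {
  quantity <- match.arg(quantity)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  positions <- as.numeric(positions)
  times <- as.numeric(times)
  if (nrow(values) == 0L || ncol(values) == 0L) stop("empty map", call. = FALSE)
  if (nrow(values) != length(positions))
    stop("values row count must equal positions length", call. = FALSE)
  if (ncol(values) != length(times))
    stop("values column count must equal times length", call. = FALSE)
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("non-increasing position axis", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("non-increasing time axis", call. = FALSE)
  if (any(is.infinite(values))) stop("map values must be finite or missing", call. = FALSE)
  values[is.nan(values)] <- NA_real_
  dimnames(values) <- NULL
  structure(list(values = values, positions = positions, times = times,
                 quantity = quantity, source = source),
            class = "stmap")
}

#' @export
print.stmap <- function(x, ...) {
  cat(sprintf("<stmap> %s: %d positions x %d times\n", x$quantity,
              length(x$positions), length(x$times)))
  cat(sprintf("  positions: %.3g .. %.3g cm | times: %.4g .. %.4g s\n",
              x$positions[1], x$positions[length(x$positions)],
              x$times[1], x$times[length(x$times)]))
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat(sprintf("  %d missing cells\n", nmiss))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @export
dim.stmap <- function(x) dim(x$values)

# sampling steps (median spacing; axes are usually uniform)
stmap_dx <- function(map) if (length(map$positions) > 1) stats::median(diff(map$positions)) else NA_real_
stmap_dt <- function(map) if (length(map$times) > 1) stats::median(diff(map$times)) else NA_real_

#' Read and write spatiotemporal maps
#'
#' The exchange format is UTF-8 tab-separated text: cell (1,1) is the literal
#' `pos\time`, the first row is the time axis in s, the first column the
#' position axis in cm, the body numeric with `nan` marking missing cells.
#' One file per quantity. Values are written with 9 significant digits.
#'
#' @param path file path.
#' @param quantity quantity tag to attach on read (see [stmap()]).
#' @return `read_stmap()`: an [stmap()]; `write_stmap()`: `path`, invisibly.
#' @export
read_stmap <- function(path, quantity = c("diameter_mm", "pressure_mmHg",
                                          "admittance_mS", "internal_diameter_mm")) {
  quantity <- match.arg(quantity)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("format error: file has fewer than 2 rows", call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (header[1] != "pos\\time")
    stop("format error: cell (1,1) must be 'pos\\time'", call. = FALSE)
  parse_num <- function(x, what, row, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & !(tolower(x) %in% c("nan", "na"))
    if (any(bad)) {
      j <- which(bad)[1]
      stop(sprintf("format error: non-numeric %s at row %d, column %d ('%s')",
                   what, row, col[j], x[j]), call. = FALSE)
    }
    v
  }
  times <- parse_num(header[-1], "time", 1L, seq_along(header[-1]) + 1L)
  if (anyNA(times) || (length(times) > 1 && any(diff(times) <= 0)))
    stop("non-increasing time axis", call. = FALSE)
  nt <- length(times)
  body <- cells[-1]
  np <- length(body)
  positions <- numeric(np)
  values <- matrix(NA_real_, np, nt)
  for (i in seq_len(np)) {
    row <- body[[i]]
    if (length(row) != nt + 1L)
      stop(sprintf("format error: row %d has %d cells, expected %d",
                   i + 1L, length(row), nt + 1L), call. = FALSE)
    positions[i] <- parse_num(row[1], "position", i + 1L, 1L)
    values[i, ] <- parse_num(row[-1], "value", i + 1L, seq_len(nt) + 1L)
  }
  if (anyNA(positions) || (np > 1 && any(diff(positions) <= 0)))
    stop("non-increasing position axis", call. = FALSE)
  values[is.nan(values)] <- NA_real_
  stmap(values, positions, times, quantity, source = path)
}

#' @rdname read_stmap
#' @param map an [stmap()].
#' @export
write_stmap <- function(map, path) {
  stopifnot(inherits(map, "stmap"))
  fmt <- function(x) {
    out <- sprintf("%.9g", x)
    out[is.na(x)] <- "nan"
    out
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("pos\\time", fmt(map$times)), collapse = "\t"), con)
  for (i in seq_along(map$positions))
    writeLines(paste(c(fmt(map$positions[i]), fmt(map$values[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Resample a map onto a regular grid by bilinear interpolation
#'
#' Interpolates the map onto a grid with spacings `dx` (cm) and `dt` (s)
#' spanning the source extent. Bilinear interpolation is exact on linear
#' fields, preserves constants, and bounds output by the source min/max.
#' Any interpolation stencil touching a missing cell yields a missing cell.
#'
#' @param map an [stmap()].
#' @param dx,dt positive target spacings (cm, s).
#' @param positions,times optionally, explicit target axes (overriding
#'   `dx`/`dt`); must lie within the source extent.
#' @return A resampled [stmap()].
#' @export
resample <- function(map, dx = NULL, dt = NULL, positions = NULL, times = NULL) {
  stopifnot(inherits(map, "stmap"))
  if (is.null(positions)) {
    if (is.null(dx) || dx <= 0) stop("dx must be > 0", call. = FALSE)
    positions <- seq(map$positions[1], map$positions[length(map$positions)], by = dx)
  }
  if (is.null(times)) {
    if (is.null(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
    times <- seq(map$times[1], map$times[length(map$times)], by = dt)
  }
  vals <- interp_bilinear(map$values, map$positions, map$times, positions, times)
  stmap(vals, positions, times, map$quantity, map$source)
}

#' Remove slow baseline drift from a map
#'
#' Subtracts a per-position running-median baseline. The median is robust to
#' contraction transients, so genuine motility events survive while slow
#' sensor drift is removed. Pressure maps are drift-corrected this way before
#' composite-map construction.
#'
#' @param map an [stmap()].
#' @param window baseline window in seconds (default 120 s); must span more
#'   than 10 samples.
#' @return An [stmap()] of the same shape: input minus baseline.
#' @export
remove_baseline_drift <- function(map, window = 120) {
  stopifnot(inherits(map, "stmap"))
  dt <- stmap_dt(map)
  if (is.na(dt)) stop("map has a single time sample", call. = FALSE)
  k <- round(window / dt)
  if (k <= 10) stop("baseline window must span more than 10 samples", call. = FALSE)
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (ncol(map$values) %% 2 == 1) ncol(map$values) else ncol(map$values) - 1L)
  vals <- map$values
  for (i in seq_len(nrow(vals))) {
    row <- vals[i, ]
    ok <- !is.na(row)
    if (sum(ok) < 3) next
    filled <- row
    if (any(!ok))  # bridge missing cells so the running median stays defined
      filled[!ok] <- stats::approx(which(ok), row[ok], xout = which(!ok), rule = 2)$y
    base <- stats::runmed(filled, k, endrule = "median")
    vals[i, ] <- row - base
  }
  stmap(vals, map$positions, map$times, map$quantity, map$source)
}

#' Synchronisation event tables
#'
#' Sync events are the times (one recording's clock, s) of shared marker
#' pulses -- e.g. an LED flash in the video field of view triggered together
#' with a marker on the manometry clock -- used to co-register recordings.
#'
#' @param times strictly increasing numeric vector of event times (s).
#' @return An object of class `sync_events` (numeric vector).
#' @export
sync_events <- function(times) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("sync events must be strictly increasing", call. = FALSE)
  structure(times, class = "sync_events")
}

#' @rdname sync_events
#' @param path two-column TSV `index<TAB>time_s`.
#' @export
read_sync_events <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("index", "time_s"))
  sync_events(d$time_s)
}

#' @rdname sync_events
#' @param events a `sync_events` object.
#' @export
write_sync_events <- function(events, path) {
  d <- data.frame(index = seq_along(events) - 1L, time_s = as.numeric(events))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Composite diameter-pressure maps
#'
#' A composite map holds a diameter map (video- or impedance-derived) and a
#' pressure map co-registered on one shared grid; it is the substrate for
#' orbit analysis and state decoding.
#'
#' @param diameter an [stmap()] with quantity `diameter_mm` or
#'   `internal_diameter_mm`.
#' @param pressure an [stmap()] with quantity `pressure_mmHg`.
#' @return An object of class `composite_map`.
#' @export
composite_map <- function(diameter, pressure) {
  stopifnot(inherits(diameter, "stmap"), inherits(pressure, "stmap"))
  if (!diameter$quantity %in% c("diameter_mm", "internal_diameter_mm"))
    stop("diameter member must be a diameter map", call. = FALSE)
  if (pressure$quantity != "pressure_mmHg")
    stop("pressure member must be a pressure map", call. = FALSE)
  if (!isTRUE(all.equal(diameter$positions, pressure$positions)) ||
      !isTRUE(all.equal(diameter$times, pressure$times)))
    stop("composite members must share identical axes", call. = FALSE)
  structure(list(diameter = diameter, pressure = pressure),
            class = "composite_map")
}

#' @export
print.composite_map <- function(x, ...) {
  cat("<composite_map>\n  ")
  print(x$diameter)
  cat("  ")
  print(x$pressure)
  al <- attr(x, "alignment")
  if (!is.null(al))
    cat(sprintf("  clock fit: alpha = %.6g, beta = %.4g s, event RMS = %.3g s\n",
                al$alpha, al$beta, al$residual_rms))
  invisible(x)
}

#' Align two recordings on a shared grid via sync events
#'
#' Fits the affine clock mapping `t_B = alpha * t_A + beta` by least squares
#' over order-paired sync events, brings map B onto map A's clock, and
#' resamples both maps onto the coarser of the two grids over their
#' overlapping spatial and temporal extent. A fitted clock rate differing from
#' 1 by more than 5% triggers a warning (clock-rate anomaly). The residual
#' event mismatch after the fit is attached to the result.
#'
#' @param mapA,mapB [stmap()]s; one must be a diameter-type map and the other
#'   a pressure map.
#' @param syncA,syncB [sync_events()] with equal counts (>= 2).
#' @return A [composite_map()] with an `alignment` attribute
#'   (`alpha`, `beta`, `residuals`, `residual_rms`).
#' @export
align <- function(mapA, syncA, mapB, syncB) {
  stopifnot(inherits(mapA, "stmap"), inherits(mapB, "stmap"))
  syncA <- as.numeric(syncA); syncB <- as.numeric(syncB)
  if (length(syncA) != length(syncB))
    stop("alignment error: unequal sync event counts", call. = FALSE)
  if (length(syncA) < 2)
    stop("alignment error: need at least 2 sync events", call. = FALSE)
  fit <- stats::lsfit(syncA, syncB)
  beta <- fit$coefficients[[1]]
  alpha <- fit$coefficients[[2]]
  if (abs(alpha - 1) > 0.05)
    warning(sprintf("clock-rate anomaly: fitted rate %.4f deviates from 1 by more than 5%%", alpha))
  resid <- syncB - (alpha * syncA + beta)
  # map B's time axis into A's clock
  timesB_inA <- (mapB$times - beta) / alpha
  mapB_inA <- stmap(mapB$values, mapB$positions, timesB_inA, mapB$quantity, mapB$source)

  p0 <- max(mapA$positions[1], mapB$positions[1])
  p1 <- min(mapA$positions[length(mapA$positions)], mapB$positions[length(mapB$positions)])
  t0 <- max(mapA$times[1], timesB_inA[1])
  t1 <- min(mapA$times[length(mapA$times)], timesB_inA[length(timesB_inA)])
  if (p0 >= p1 || t0 >= t1)
    stop("alignment error: maps do not overlap in space and time", call. = FALSE)
  dx <- max(stmap_dx(mapA), stmap_dx(mapB), na.rm = TRUE)
  dt <- max(stmap_dt(mapA), stmap_dt(mapB) / alpha, na.rm = TRUE)
  pos <- seq(p0, p1, by = dx)
  tim <- seq(t0, t1, by = dt)
  rA <- resample(mapA, positions = pos, times = tim)
  rB <- resample(mapB_inA, positions = pos, times = tim)

  is_d <- function(m) m$quantity %in% c("diameter_mm", "internal_diameter_mm")
  if (is_d(rA) && rB$quantity == "pressure_mmHg") cm <- composite_map(rA, rB)
  else if (is_d(rB) && rA$quantity == "pressure_mmHg") cm <- composite_map(rB, rA)
  else stop("align requires one diameter-type map and one pressure map", call. = FALSE)
  attr(cm, "alignment") <- list(alpha = alpha, beta = beta, residuals = resid,
                                residual_rms = sqrt(mean(resid^2)))
  cm
}

#' Tangential wall tension by the modified law of Laplace
#'
#' For a thin-walled cylinder, tangential tension = pressure x radius / wall
#' thickness. Pressure is converted to kPa (1 mmHg = 0.133322 kPa) unless
#' `units = "mmHg"` requests the raw mmHg-scale value.
#'
#' @param pressure intraluminal pressure, mmHg.
#' @param outer_diameter outer diameter, mm (must exceed twice the wall
#'   thickness).
#' @param wall_thickness wall thickness, mm (> 0).
#' @param units `"kPa"` (default) or `"mmHg"`.
#' @return Tangential tension (kPa or mmHg scale).
#' @export
#' @examples
#' laplace_tension(2, 6, 1, units = "mmHg")  # 6
laplace_tension <- function(pressure, outer_diameter, wall_thickness,
                            units = c("kPa", "mmHg")) {
  units <- match.arg(units)
  if (any(wall_thickness <= 0)) stop("wall thickness must be positive", call. = FALSE)
  if (any(outer_diameter <= 2 * wall_thickness))
    stop("outer diameter must exceed twice the wall thickness", call. = FALSE)
  tension <- pressure * (outer_diameter / 2) / wall_thickness
  if (units == "kPa") tension <- tension * 0.133322
  tension
}
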